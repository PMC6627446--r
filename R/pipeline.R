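#' Load a cohort from a manifest and its FASTA files
#'
#' @param manifest_path Path to a manifest TSV; `fasta_path` entries are
#'   resolved relative to the manifest's directory unless absolute.
#' @return List with elements `manifest`, `reads` (and `truth = NULL`).
#' @export
load_cohort <- function(manifest_path) {
  manifest <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  reads <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$fasta_path[i]
    if (!file.exists(p))
      p <- file.path(base, manifest$fasta_path[i])
    read_fasta(p, manifest$sample_id[i])
  }))
  list(manifest = manifest, reads = reads, truth = NULL, config = NULL)
}

as_cohort <- function(x) {
  if (inherits(x, "synthetic_cohort"))
    return(x)
  if (inherits(x, "cohort_config"))
    return(generate_cohort(x))
  if (is.character(x) && length(x) == 1L)
    return(load_cohort(x))
  if (is.list(x) && all(c("manifest", "reads") %in% names(x)))
    return(x)
  stop("cannot interpret input as a cohort: supply a cohort_config, a ",
       "synthetic_cohort, a manifest path, or a list(manifest, reads)")
}

analyze_timepoint <- function(reads, m_tp, tp, threshold, mode, truth,
                              cluster_by) {
  run_unit <- function(m_unit) {
    r <- reads[reads$sample_id %in% m_unit$sample_id, , drop = FALSE]
    otus <- dereplicate(r)
    tab <- build_otu_table(otus, m_unit)
    tax <- if (!is.null(truth))
      truth_taxonomy(tab, truth)
    else stats::setNames(rep("unclassified", nrow(tab)), rownames(tab))
    cfg <- cooc_config(threshold = threshold, mode = mode, timepoint = tp)
    scores <- score_cooccurrence(tab, m_unit, cfg)
    events <- call_events(scores, threshold)
    list(table = tab, taxonomy = tax, scores = scores, events = events,
         profiles = summarize_group_profiles(events, tab, m_unit, tax, tp))
  }
  if (cluster_by == "timepoint") {
    res <- run_unit(m_tp)
    res$total_otus <- nrow(res$table)
    res$diversity <- NULL
    res
  } else {
    groups <- intersect(GROUP_LEVELS, unique(m_tp$group))
    per_group <- lapply(groups, function(g)
      run_unit(m_tp[m_tp$group == g, , drop = FALSE]))
    names(per_group) <- groups
    # stitch the per-group profiles into one matrix on the taxon union
    taxa <- sort(unique(unlist(lapply(per_group, function(r)
      colnames(r$profiles$taxon_freq)))))
    freq <- matrix(0, length(groups), length(taxa),
                   dimnames = list(groups, taxa))
    summ <- do.call(rbind, lapply(groups, function(g) {
      pr <- per_group[[g]]$profiles
      row <- pr$summary[pr$summary$group == g, , drop = FALSE]
      freq[g, colnames(pr$taxon_freq)] <<- pr$taxon_freq[g, ]
      row
    }))
    rownames(summ) <- NULL
    list(per_group = per_group,
         scores = do.call(rbind, lapply(groups, function(g)
           cbind(group = g, per_group[[g]]$scores))),
         events = do.call(rbind, lapply(groups, function(g)
           cbind(group = g, per_group[[g]]$events))),
         profiles = structure(list(summary = summ, taxon_freq = freq),
                              class = "group_profiles"),
         total_otus = sum(vapply(per_group,
                                 function(r) nrow(r$table), 1L)))
  }
}

#' Run the full saliva-feces co-occurrence analysis
#'
#' End-to-end orchestration: (optionally generate and) load a paired
#' cohort, then per timepoint dereplicate reads at 100% identity, build
#' the OTU table, score saliva-feces co-occurrence, call biological
#' events, summarize them per group and cluster the group taxon
#' profiles; compute per-sample alpha diversity; and compare F1 vs F2
#' diversity per group with Wilcoxon rank-sum tests and BH-corrected
#' q-values.
#'
#' @param x A [cohort_config()] (the cohort is generated), a
#'   `synthetic_cohort`, a manifest TSV path, or a
#'   `list(manifest, reads)`.
#' @param out_dir If non-`NULL`, all tables are written there
#'   (`otu_table.F1.tsv`, `cooccurrence_scores.F1.tsv`, `events.F1.tsv`,
#'   ... per timepoint, plus `group_profiles.tsv`, `diversity.tsv`,
#'   `stats.tsv`, `profiles.nwk` and `report.json`).
#' @param threshold LLR event threshold (strict); default 0.5.
#' @param mode Probability estimator, `"read_pair"` or `"presence"`.
#' @param rare_threshold ACE rare/abundant cut.
#' @param cluster_by `"timepoint"` pools all groups of a timepoint into
#'   one clustering universe (default); `"group"` clusters each group
#'   separately.
#' @return Invisibly, a list of class `cooc_run` with per-timepoint
#'   results (`$F1`, `$F2`), `$diversity`, `$stats` and a `$report` of
#'   summary counts.
#' @export
run_pipeline <- function(x, out_dir = NULL, threshold = 0.5,
                         mode = c("read_pair", "presence"),
                         rare_threshold = 10L,
                         cluster_by = c("timepoint", "group")) {
  mode <- match.arg(mode)
  cluster_by <- match.arg(cluster_by)
  cohort <- as_cohort(x)
  manifest <- validate_manifest(as.data.frame(cohort$manifest))
  reads <- cohort$reads
  tps <- intersect(TIMEPOINT_LEVELS, unique(manifest$timepoint))
  if (length(tps) == 0L)
    stop("stage error [input]: manifest lists no known timepoints")
  res <- list()
  diversity <- list()
  for (tp in tps) {
    m_tp <- manifest[manifest$timepoint == tp, , drop = FALSE]
    res[[tp]] <- analyze_timepoint(reads, m_tp, tp, threshold, mode,
                                   cohort$truth, cluster_by)
    div_tab <- if (cluster_by == "timepoint")
      alpha_diversity_table(res[[tp]]$table, rare_threshold)
    else do.call(rbind, lapply(res[[tp]]$per_group, function(r)
      alpha_diversity_table(r$table, rare_threshold)))
    diversity[[tp]] <- cbind(timepoint = tp, div_tab)
  }
  diversity <- do.call(rbind, diversity)
  rownames(diversity) <- NULL
  diversity$subject_id <-
    manifest$subject_id[match(diversity$sample_id, manifest$sample_id)]
  diversity$site <- manifest$site[match(diversity$sample_id,
                                        manifest$sample_id)]
  diversity$group <- manifest$group[match(diversity$sample_id,
                                          manifest$sample_id)]
  stats_tab <- if (all(c("F1", "F2") %in% tps)) {
    d1 <- diversity[diversity$timepoint == "F1", ]
    d2 <- diversity[diversity$timepoint == "F2", ]
    compare_timepoints(d1, d2, d1$group, d2$group)
  } else NULL
  trees <- lapply(tps, function(tp) {
    hc <- tryCatch(suppressWarnings(cluster_profiles(res[[tp]]$profiles)),
                   error = function(e) NULL)
    if (is.null(hc)) NULL else profiles_newick(hc)
  })
  names(trees) <- tps
  report <- list(
    cluster_by = cluster_by, mode = mode, threshold = threshold,
    timepoints = tps,
    total_otus = lapply(res, function(r) r$total_otus),
    n_events = lapply(res, function(r) nrow(r$events)),
    events_per_group = lapply(res, function(r) {
      s <- r$profiles$summary
      stats::setNames(as.list(s$event_count), s$group)
    }),
    n_samples = nrow(manifest),
    n_subjects = length(unique(manifest$subject_id)))
  if (!is.null(cohort$config))
    report$config <- {
      cfg <- unclass(cohort$config)
      cfg$groups <- as.list(cfg$groups)
      cfg
    }
  out <- structure(c(res, list(diversity = diversity, stats = stats_tab,
                               trees = trees, report = report)),
                   class = "cooc_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tp in tps) {
      tab <- if (cluster_by == "timepoint") res[[tp]]$table else NULL
      if (!is.null(tab))
        write_tsv(data.frame(otu_id = rownames(tab), as.data.frame(tab),
                             check.names = FALSE),
                  file.path(out_dir, sprintf("otu_table.%s.tsv", tp)))
      write_tsv(res[[tp]]$scores,
                file.path(out_dir, sprintf("cooccurrence_scores.%s.tsv", tp)))
      write_tsv(res[[tp]]$events,
                file.path(out_dir, sprintf("events.%s.tsv", tp)))
    }
    profs <- do.call(rbind, lapply(tps, function(tp) {
      pr <- res[[tp]]$profiles
      freq_long <- as.data.frame.table(pr$taxon_freq,
                                       stringsAsFactors = FALSE)
      names(freq_long) <- c("group", "taxon", "frequency")
      merge(pr$summary, freq_long, by = "group", all.x = TRUE, sort = TRUE)
    }))
    write_tsv(profs, file.path(out_dir, "group_profiles.tsv"))
    write_tsv(diversity, file.path(out_dir, "diversity.tsv"))
    if (!is.null(stats_tab))
      write_tsv(stats_tab, file.path(out_dir, "stats.tsv"))
    nwk <- unlist(trees[!vapply(trees, is.null, TRUE)])
    if (length(nwk))
      writeLines(nwk, file.path(out_dir, "profiles.nwk"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' @export
print.cooc_run <- function(x, ...) {
  cat("cooc_run:\n")
  for (tp in x$report$timepoints)
    cat("  ", tp, ": ", x$report$total_otus[[tp]], " OTUs, ",
        x$report$n_events[[tp]], " biological events\n", sep = "")
  invisible(x)
}

#' Compare F1 vs F2 alpha diversity per group
#'
#' For each group and each diversity index, a two-sided Wilcoxon
#' rank-sum test of the F1 values against the F2 values; all p-values of
#' the battery are then BH-corrected together into q-values. Groups
#' present at only one timepoint are skipped with a warning.
#'
#' @param diversity_f1,diversity_f2 Per-sample diversity tables (as from
#'   [alpha_diversity_table()]) for the two timepoints.
#' @param group_f1,group_f2 Group labels aligned to the rows of the two
#'   tables.
#' @param indices Diversity columns to compare.
#' @return `data.frame(group, index, n_f1, n_f2, statistic, p_value,
#'   q_value)`.
#' @export
compare_timepoints <- function(diversity_f1, diversity_f2, group_f1,
                               group_f2 = group_f1,
                               indices = c("observed_otus", "shannon",
                                           "simpson_1mD",
                                           "chao1_bias_corrected", "ace")) {
  stopifnot(nrow(diversity_f1) == length(group_f1),
            nrow(diversity_f2) == length(group_f2))
  groups <- intersect(GROUP_LEVELS, unique(c(group_f1, group_f2)))
  only_one <- groups[!(groups %in% group_f1 & groups %in% group_f2)]
  if (length(only_one)) {
    warning("group(s) present at only one timepoint, skipped: ",
            paste(only_one, collapse = ", "))
    groups <- setdiff(groups, only_one)
  }
  rows <- list()
  for (g in groups) {
    for (idx in indices) {
      v1 <- diversity_f1[group_f1 == g, idx]
      v2 <- diversity_f2[group_f2 == g, idx]
      v1 <- v1[is.finite(v1)]
      v2 <- v2[is.finite(v2)]
      if (!length(v1) || !length(v2))
        next
      wt <- wilcoxon_rank_sum(v1, v2)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, index = idx, n_f1 = length(v1), n_f2 = length(v2),
        statistic = wt$statistic, p_value = wt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(group = character(), index = character(),
                      n_f1 = integer(), n_f2 = integer(),
                      statistic = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}
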