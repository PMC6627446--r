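#' Co-occurrence scoring configuration
#'
#' @param threshold Log-likelihood-ratio threshold above which (strictly)
#'   an OTU with at least one same-subject saliva-feces read pair is
#'   called a biological event. Default 0.5, a conservative margin above
#'   the independence point 0.
#' @param mode `"read_pair"` estimates the site probabilities from read
#'   frequencies over paired subjects (pair counting); `"presence"` uses
#'   per-subject presence/absence indicators instead.
#' @param timepoint Timepoint whose samples the OTU table was built from.
#' @return A list of class `cooc_config`.
#' @export
cooc_config <- function(threshold = 0.5, mode = c("read_pair", "presence"),
                        timepoint = "F1") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold), timepoint %in% TIMEPOINT_LEVELS)
  structure(list(threshold = threshold, mode = mode, timepoint = timepoint),
            class = "cooc_config")
}

#' Score saliva-feces co-occurrence for every OTU
#'
#' For each exact OTU k, counts how many same-subject (saliva read, feces
#' read) pairs fall inside the OTU and computes a log2 likelihood ratio
#' comparing the joint pairing probability to the product of the marginal
#' site probabilities (a pointwise mutual information):
#' \deqn{LLR_k = \log_2 \frac{P(S,F)}{P(S)\,P(F)}}
#' With paired subjects i of depths \eqn{d_i^S, d_i^F} and OTU counts
#' \eqn{c_{ik}^S, c_{ik}^F}:
#' `pair_count = sum_i cS*cF`, `P(S,F) = pair_count / sum_i dS*dF`,
#' `P(S) = sum_i cS / sum_i dS`, `P(F) = sum_i cF / sum_i dF`.
#' In `presence` mode counts are replaced by presence indicators and
#' depths by 1. An LLR of 0 means the two sites carry the OTU
#' independently; positive values mean same-subject pairing in excess of
#' independence. OTUs with no read in any paired-subject sample are
#' omitted (their LLR is undefined); OTUs with reads on one side only get
#' `llr = -Inf`.
#'
#' Subjects lacking one of the two sites at the timepoint cannot form
#' pairs and are excluded from the pairing universe; their reads still
#' participated in clustering. Paired samples with zero depth are dropped
#' with a warning.
#'
#' @param table OTU count matrix from [build_otu_table()], built from the
#'   samples of `config$timepoint`.
#' @param manifest A `sample_manifest` covering the table's samples.
#' @param config A [cooc_config()].
#' @return `data.frame` with columns `otu_id`, `pair_count`,
#'   `n_subjects_with_pair`, `prob_s`, `prob_f`, `prob_sf`, `llr`,
#'   `is_biological`.
#' @export
score_cooccurrence <- function(table, manifest, config = cooc_config()) {
  stopifnot(is.matrix(table), inherits(config, "cooc_config"))
  manifest <- validate_manifest(as.data.frame(manifest))
  m <- manifest[manifest$timepoint == config$timepoint &
                  manifest$sample_id %in% colnames(table), ]
  subj <- paired_subjects(m, config$timepoint)
  if (length(subj) == 0L)
    stop("co-occurrence configuration error: no paired subjects ",
         "(both saliva and feces) at timepoint ", config$timepoint)
  sal <- m$sample_id[match(paste(subj, "saliva"),
                           paste(m$subject_id, m$site))]
  fec <- m$sample_id[match(paste(subj, "feces"),
                           paste(m$subject_id, m$site))]
  Cs <- table[, sal, drop = FALSE]
  Cf <- table[, fec, drop = FALSE]
  dS <- colSums(Cs)
  dF <- colSums(Cf)
  empty <- dS == 0 | dF == 0
  if (any(empty)) {
    warning("excluding paired subject(s) with a zero-depth sample: ",
            paste(subj[empty], collapse = ", "))
    Cs <- Cs[, !empty, drop = FALSE]
    Cf <- Cf[, !empty, drop = FALSE]
    dS <- dS[!empty]
    dF <- dF[!empty]
    subj <- subj[!empty]
    if (length(subj) == 0L)
      stop("co-occurrence configuration error: no paired subjects left ",
           "after zero-depth exclusion")
  }
  if (config$mode == "presence") {
    Cs <- (Cs > 0) + 0L
    Cf <- (Cf > 0) + 0L
    dS <- rep(1, length(subj))
    dF <- rep(1, length(subj))
  }
  keep <- rowSums(Cs) + rowSums(Cf) > 0
  Cs <- Cs[keep, , drop = FALSE]
  Cf <- Cf[keep, , drop = FALSE]
  pair_count <- as.vector(rowSums(Cs * Cf))
  prob_sf <- pair_count / sum(dS * dF)
  prob_s <- rowSums(Cs) / sum(dS)
  prob_f <- rowSums(Cf) / sum(dF)
  llr <- ifelse(pair_count > 0, log2(prob_sf / (prob_s * prob_f)), -Inf)
  data.frame(
    otu_id = rownames(table)[keep],
    pair_count = pair_count,
    n_subjects_with_pair = as.vector(rowSums(Cs > 0 & Cf > 0)),
    prob_s = as.vector(prob_s),
    prob_f = as.vector(prob_f),
    prob_sf = prob_sf,
    llr = llr,
    is_biological = llr > config$threshold,
    stringsAsFactors = FALSE)
}

#' Call biological co-occurrence events
#'
#' Keeps exactly the OTUs with at least one same-subject saliva-feces
#' read pair and an LLR *strictly* greater than the threshold, sorted by
#' descending LLR (ties broken by `otu_id`).
#'
#' @param scores Output of [score_cooccurrence()].
#' @param threshold Strict lower bound on the LLR; default 0.5.
#' @return The qualifying rows of `scores`.
#' @export
call_events <- function(scores, threshold = 0.5) {
  stopifnot(is.data.frame(scores), is.numeric(threshold), is.finite(threshold))
  ev <- scores[scores$pair_count >= 1L & scores$llr > threshold, , drop = FALSE]
  ev <- ev[order(-ev$llr, ev$otu_id, method = "radix"), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Per-subject pair contribution matrix for the event OTUs:
# entry (k, i) is TRUE when subject i contributes >= 1 S-F read pair to
# event OTU k.
subject_pair_matrix <- function(events, table, manifest, timepoint) {
  m <- manifest[manifest$timepoint == timepoint &
                  manifest$sample_id %in% colnames(table), ]
  subj <- paired_subjects(m, timepoint)
  sal <- m$sample_id[match(paste(subj, "saliva"), paste(m$subject_id, m$site))]
  fec <- m$sample_id[match(paste(subj, "feces"), paste(m$subject_id, m$site))]
  ok <- table[events$otu_id, sal, drop = FALSE] > 0 &
    table[events$otu_id, fec, drop = FALSE] > 0
  colnames(ok) <- subj
  ok
}

#' Summarize co-occurrence events per subject group
#'
#' An event OTU is attributed to every group in which at least one
#' subject contributes a same-subject saliva-feces read pair to it (one
#' OTU can therefore count in several groups). For each (group,
#' timepoint) the function reports the event count, events per paired
#' subject (group sizes differ, so the per-subject rate is the comparable
#' "frequency of co-occurrences"), and the relative frequency of each
#' taxon among the group's events.
#'
#' @param events Output of [call_events()].
#' @param table OTU count matrix the events were scored from.
#' @param manifest A `sample_manifest`.
#' @param taxonomy Named character vector `otu_id -> taxon`; must cover
#'   every event OTU (use `"unclassified"` for unknowns), e.g. from
#'   [truth_taxonomy()].
#' @param timepoint Timepoint of the table.
#' @return List of class `group_profiles` with elements `summary`
#'   (`data.frame(group, timepoint, n_paired_subjects, event_count,
#'   events_per_paired_subject)`) and `taxon_freq` (group x taxon matrix
#'   of relative frequencies; rows sum to 1 where events exist).
#' @export
summarize_group_profiles <- function(events, table, manifest, taxonomy,
                                     timepoint = "F1") {
  manifest <- validate_manifest(as.data.frame(manifest))
  missing_otu <- setdiff(events$otu_id, rownames(table))
  if (length(missing_otu))
    stop("consistency error: event OTU(s) absent from the table: ",
         paste(utils::head(missing_otu, 3L), collapse = ", "))
  if (nrow(events) && any(!events$otu_id %in% names(taxonomy)))
    stop("taxonomy must cover every event OTU")
  m <- manifest[manifest$timepoint == timepoint, ]
  groups <- intersect(GROUP_LEVELS, unique(m$group))
  subj_group <- unique(m[, c("subject_id", "group")])
  paired <- paired_subjects(m, timepoint)
  taxa <- sort(unique(unname(taxonomy[events$otu_id])))
  pair_mat <- if (nrow(events))
    subject_pair_matrix(events, table, manifest, timepoint)
  else matrix(FALSE, 0L, length(paired), dimnames = list(NULL, paired))
  summary <- data.frame(group = groups, timepoint = timepoint,
                        n_paired_subjects = NA_integer_,
                        event_count = NA_integer_,
                        events_per_paired_subject = NA_real_,
                        stringsAsFactors = FALSE)
  freq <- matrix(0, nrow = length(groups), ncol = length(taxa),
                 dimnames = list(groups, taxa))
  for (g in seq_along(groups)) {
    gs <- intersect(paired,
                    subj_group$subject_id[subj_group$group == groups[g]])
    attributed <- if (length(gs) && nrow(events))
      rowSums(pair_mat[, gs, drop = FALSE]) > 0
    else rep(FALSE, nrow(events))
    summary$n_paired_subjects[g] <- length(gs)
    summary$event_count[g] <- sum(attributed)
    summary$events_per_paired_subject[g] <-
      if (length(gs)) sum(attributed) / length(gs) else NA_real_
    if (any(attributed)) {
      tab <- table(factor(unname(taxonomy[events$otu_id[attributed]]),
                          levels = taxa))
      freq[g, ] <- as.vector(tab) / sum(tab)
    }
  }
  structure(list(summary = summary, taxon_freq = freq),
            class = "group_profiles")
}

#' @export
print.group_profiles <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Cluster per-group co-occurrence taxon profiles
#'
#' Agglomerative (average-linkage) clustering of the groups' taxon
#' frequency profiles, used to ask which groups share a similar
#' co-occurrence spectrum. Profiles with no events (all-zero frequency
#' vectors) are dropped with a warning because Bray-Curtis is undefined
#' for them.
#'
#' @param profiles A `group_profiles` object or a numeric matrix of
#'   profiles (rows = labelled profiles, columns = taxa; absent taxa 0).
#' @param metric `"bray_curtis"` or `"correlation"` (1 - Pearson r).
#' @param linkage Only `"average"` is offered.
#' @return An [stats::hclust] tree; leaves are profile labels. Rows are
#'   sorted lexicographically first so the result is label-deterministic.
#' @export
cluster_profiles <- function(profiles,
                             metric = c("bray_curtis", "correlation"),
                             linkage = "average") {
  metric <- match.arg(metric)
  stopifnot(identical(linkage, "average"))
  x <- if (inherits(profiles, "group_profiles")) profiles$taxon_freq
  else as.matrix(profiles)
  if (is.null(rownames(x)))
    stop("profile matrix must have row labels")
  zero <- rowSums(abs(x)) == 0
  if (any(zero)) {
    warning("dropping profile(s) with no events: ",
            paste(rownames(x)[zero], collapse = ", "))
    x <- x[!zero, , drop = FALSE]
  }
  if (nrow(x) < 2L)
    stop("need at least 2 non-empty profiles to cluster")
  x <- x[order(rownames(x), method = "radix"), , drop = FALSE]
  d <- switch(metric,
              bray_curtis = vegan::vegdist(x, method = "bray"),
              correlation = stats::as.dist(1 - stats::cor(t(x))))
  stats::hclust(d, method = "average")
}

#' Export a profile dendrogram as Newick
#' @param hc An `hclust` tree from [cluster_profiles()].
#' @param path Output file; if `NULL`, the Newick string is returned.
#' @export
profiles_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path))
    ape::write.tree(phy)
  else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}
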