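#' Configuration for the synthetic paired-site cohort generator
#'
#' Defines a cohort of subjects in up to four groups, each sampled at two
#' body sites (saliva, feces) and two timepoints (F1 baseline, F2
#' post-intervention). Each site has its own pool of background taxa —
#' disjoint at the sequence level, so at `error_rate = 0` cross-site
#' sequence identity can arise *only* through taxa deliberately planted
#' in both sites of one subject. That makes false-positive co-occurrence
#' events well-defined.
#'
#' @param groups Named integer vector of subjects per group; names must
#'   be among `Control`, `INR`, `IR`, `VU`. Defaults follow the baseline
#'   design of the emulated study (14, 9, 18, 12).
#' @param depth Reads per sample (every sample gets exactly this many).
#' @param n_taxa_site Background taxa per site pool.
#' @param n_shared_subject_taxa Taxa planted in BOTH sites of each
#'   subject (subject-exclusive).
#' @param shared_abundance Relative abundance given to each planted
#'   shared taxon in each site at F1; `shared_abundance *
#'   n_shared_subject_taxa` must stay below 1.
#' @param lognormal_sigma sdlog of the log-normal background abundances.
#' @param error_rate Per-base substitution probability applied
#'   independently to every read (no indels, so read length is fixed and
#'   exact-identity clustering stays length-safe).
#' @param intervention_evenness_factor In (0, 1]: at F2, relative
#'   abundances are raised to the power `1/factor` and renormalized.
#'   Values below 1 sharpen the distribution, lowering evenness — and
#'   hence Shannon/Simpson diversity — as after the prebiotic
#'   intervention the generator emulates.
#' @param seed Integer seed; all randomness derives from it.
#' @param amplicon_length Reference sequence length (V3-V4-like scale).
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(groups = c(Control = 14L, INR = 9L, IR = 18L,
                                     VU = 12L),
                          depth = 500L,
                          n_taxa_site = 100L,
                          n_shared_subject_taxa = 2L,
                          shared_abundance = 0.05,
                          lognormal_sigma = 1,
                          error_rate = 0,
                          intervention_evenness_factor = 0.5,
                          seed = 1L,
                          amplicon_length = 250L) {
  if (is.null(names(groups)) || any(!names(groups) %in% GROUP_LEVELS))
    stop("config validation error: group labels must be among ",
         paste(GROUP_LEVELS, collapse = ", "))
  if (any(groups < 1) || any(groups != round(groups)))
    stop("config validation error: group sizes must be positive integers")
  stopifnot(depth >= 1, n_taxa_site >= 1, n_shared_subject_taxa >= 0,
            shared_abundance >= 0, lognormal_sigma >= 0,
            error_rate >= 0, error_rate < 1,
            intervention_evenness_factor > 0,
            intervention_evenness_factor <= 1,
            amplicon_length >= 50)
  if (shared_abundance * n_shared_subject_taxa >= 1)
    stop("config validation error: shared_abundance * n_shared_subject_taxa ",
         "must be < 1")
  structure(list(groups = groups, depth = as.integer(depth),
                 n_taxa_site = as.integer(n_taxa_site),
                 n_shared_subject_taxa = as.integer(n_shared_subject_taxa),
                 shared_abundance = shared_abundance,
                 lognormal_sigma = lognormal_sigma,
                 error_rate = error_rate,
                 intervention_evenness_factor = intervention_evenness_factor,
                 seed = as.integer(seed),
                 amplicon_length = as.integer(amplicon_length)),
            class = "cohort_config")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}

# i.i.d. substitutions at `rate` per base; a substitution always changes
# the base (draws from the three alternatives).
mutate_reads <- function(seqs, rate) {
  if (rate == 0 || length(seqs) == 0L)
    return(seqs)
  len <- nchar(seqs)
  n_mut <- stats::rbinom(length(seqs), len, rate)
  hit <- which(n_mut > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(len[i], n_mut[i])
    for (p in pos)
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Generate a synthetic paired-site two-timepoint amplicon cohort
#'
#' For each subject and site, a background community is drawn from the
#' site's taxon pool with subject-specific log-normal relative
#' abundances, scaled to leave room for the subject's planted shared
#' taxa at `shared_abundance` each (in both sites). Reads are a
#' multinomial draw of size `depth` over the community; each read is the
#' taxon's reference sequence with i.i.d. substitutions at `error_rate`.
#' At F2 the same community is passed through the evenness transform
#' (see [cohort_config()]). All randomness flows from `config$seed`, so
#' equal configs give byte-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`:
#'   \describe{
#'     \item{manifest}{`sample_manifest` covering every sample}
#'     \item{reads}{`data.frame(read_id, sample_id, sequence)`}
#'     \item{truth}{planted-taxon table: `taxon_id`, `origin`
#'       (`site_pool`/`subject_shared`), `subject_id` (`shared_pool` for
#'       pool taxa), `sites`, realized planted abundances per
#'       site/timepoint (`NA` for background pool taxa, whose abundances
#'       are subject-specific random draws), `reference_sequence`}
#'     \item{config}{the config used}
#'   }
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  subjects <- unlist(lapply(names(config$groups), function(g)
    sprintf("%s%02d", g, seq_len(config$groups[[g]]))), use.names = FALSE)
  subject_group <- rep(names(config$groups), config$groups)
  n_subj <- length(subjects)
  n_shared <- config$n_shared_subject_taxa

  # reference sequences: site pools + per-subject shared taxa, all distinct
  n_total <- 2L * config$n_taxa_site + n_subj * n_shared
  refs <- random_dna(n_total, config$amplicon_length)
  for (tries in 1:5) {
    dup <- duplicated(refs)
    if (!any(dup)) break
    refs[dup] <- random_dna(sum(dup), config$amplicon_length)
  }
  if (anyDuplicated(refs))
    stop("failed to generate pairwise-distinct reference sequences")
  sal_idx <- seq_len(config$n_taxa_site)
  fec_idx <- config$n_taxa_site + seq_len(config$n_taxa_site)
  taxa_ids <- c(sprintf("tax_sal%04d", sal_idx),
                sprintf("tax_fec%04d", seq_along(fec_idx)))
  shared_ids <- if (n_shared > 0)
    unlist(lapply(subjects, function(s) sprintf("tax_shr_%s_%02d", s,
                                                seq_len(n_shared))))
  else character()
  taxa_ids <- c(taxa_ids, shared_ids)
  names(refs) <- taxa_ids

  manifest <- expand.grid(site = SITE_LEVELS, timepoint = TIMEPOINT_LEVELS,
                          subject_id = subjects, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  manifest$group <- subject_group[match(manifest$subject_id, subjects)]
  manifest$sample_id <- paste(manifest$subject_id, manifest$site,
                              manifest$timepoint, sep = "_")
  manifest$fasta_path <- paste0(manifest$sample_id, ".fasta")
  manifest <- validate_manifest(manifest)

  shared_mass <- n_shared * config$shared_abundance
  reads_by_sample <- vector("list", nrow(manifest))
  truth_shared <- vector("list", n_subj)
  k <- 0L
  for (si in seq_len(n_subj)) {
    subj <- subjects[si]
    subj_shared_ids <- if (n_shared > 0)
      sprintf("tax_shr_%s_%02d", subj, seq_len(n_shared)) else character()
    shared_ab <- matrix(NA_real_, nrow = n_shared, ncol = 4,
                        dimnames = list(subj_shared_ids,
                                        c("saliva_F1", "feces_F1",
                                          "saliva_F2", "feces_F2")))
    for (site in SITE_LEVELS) {
      pool_ids <- if (site == "saliva") taxa_ids[sal_idx] else
        taxa_ids[fec_idx]
      bg <- stats::rlnorm(config$n_taxa_site, 0, config$lognormal_sigma)
      bg <- bg / sum(bg) * (1 - shared_mass)
      p1 <- c(stats::setNames(bg, pool_ids),
              stats::setNames(rep(config$shared_abundance, n_shared),
                              subj_shared_ids))
      p2 <- p1^(1 / config$intervention_evenness_factor)
      p2 <- p2 / sum(p2)
      if (n_shared > 0) {
        shared_ab[, paste0(site, "_F1")] <- p1[subj_shared_ids]
        shared_ab[, paste0(site, "_F2")] <- p2[subj_shared_ids]
      }
      for (tp in TIMEPOINT_LEVELS) {
        p <- if (tp == "F1") p1 else p2
        counts <- as.vector(stats::rmultinom(1L, config$depth, p))
        seqs <- rep(unname(refs[names(p)]), counts)
        seqs <- mutate_reads(seqs, config$error_rate)
        sid <- paste(subj, site, tp, sep = "_")
        k <- k + 1L
        reads_by_sample[[k]] <- data.frame(
          read_id = sprintf("%s_r%05d", sid, seq_along(seqs)),
          sample_id = sid, sequence = seqs, stringsAsFactors = FALSE)
      }
    }
    if (n_shared > 0)
      truth_shared[[si]] <- data.frame(
        taxon_id = subj_shared_ids, origin = "subject_shared",
        subject_id = subj, sites = "saliva,feces",
        abundance_saliva_F1 = shared_ab[, "saliva_F1"],
        abundance_feces_F1 = shared_ab[, "feces_F1"],
        abundance_saliva_F2 = shared_ab[, "saliva_F2"],
        abundance_feces_F2 = shared_ab[, "feces_F2"],
        reference_sequence = unname(refs[subj_shared_ids]),
        stringsAsFactors = FALSE)
  }
  pool_truth <- data.frame(
    taxon_id = taxa_ids[c(sal_idx, fec_idx)],
    origin = "site_pool", subject_id = "shared_pool",
    sites = rep(SITE_LEVELS, each = config$n_taxa_site),
    abundance_saliva_F1 = NA_real_, abundance_feces_F1 = NA_real_,
    abundance_saliva_F2 = NA_real_, abundance_feces_F2 = NA_real_,
    reference_sequence = unname(refs[c(sal_idx, fec_idx)]),
    stringsAsFactors = FALSE)
  truth <- rbind(pool_truth, do.call(rbind, truth_shared))
  rownames(truth) <- NULL
  reads <- do.call(rbind, reads_by_sample)
  rownames(reads) <- NULL
  structure(list(manifest = manifest, reads = reads, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: ", length(unique(x$manifest$subject_id)),
      " subjects, ", nrow(x$manifest), " samples, ",
      nrow(x$reads), " reads\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one FASTA per sample (at the manifest's `fasta_path`, relative
#' to `out_dir`), `manifest.tsv`, `truth.tsv` and a `config.yaml` echo
#' for provenance.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite)
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  split_reads <- split(cohort$reads,
                       factor(cohort$reads$sample_id,
                              levels = cohort$manifest$sample_id))
  for (i in seq_len(nrow(cohort$manifest))) {
    sid <- cohort$manifest$sample_id[i]
    write_fasta(split_reads[[sid]],
                file.path(out_dir, cohort$manifest$fasta_path[i]))
  }
  write_manifest(cohort$manifest, file.path(out_dir, "manifest.tsv"))
  write_tsv(cohort$truth, file.path(out_dir, "truth.tsv"))
  cfg <- unclass(cohort$config)
  cfg$groups <- as.list(cfg$groups)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Map exact OTUs to planted taxa
#'
#' Labels each OTU with the planted taxon whose reference sequence its
#' representative matches exactly; OTUs arising from sequencing error
#' (or any unmatched sequence) get `"unclassified"`.
#'
#' @param table OTU count matrix from [build_otu_table()] (carries the
#'   `representatives` attribute), or an `exact_otus` object.
#' @param truth Truth table from [generate_cohort()].
#' @return Named character vector `otu_id -> taxon_id`.
#' @export
truth_taxonomy <- function(table, truth) {
  reps <- if (inherits(table, "exact_otus"))
    stats::setNames(table$otus$representative, table$otus$otu_id)
  else attr(table, "representatives")
  if (is.null(reps))
    stop("table carries no representative sequences")
  hit <- match(reps, truth$reference_sequence)
  out <- ifelse(is.na(hit), "unclassified", truth$taxon_id[hit])
  stats::setNames(out, names(reps))
}
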