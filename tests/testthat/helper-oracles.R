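# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: clustering by all-pairs string comparison,
# co-occurrence by literal enumeration of every same-subject read pair,
# and test p-values by exhaustive permutation.

# Random paired cohort with sequences drawn from a small shared pool so
# that cross-site identity actually happens.
random_cohort <- function(n_subjects, min_depth = 10L, max_depth = 50L,
                          pool_size = 8L, seq_len = 6L,
                          add_unpaired = FALSE) {
  pool <- unique(replicate(pool_size, paste(
    sample(c("A", "C", "G", "T"), seq_len, replace = TRUE), collapse = "")))
  subjects <- sprintf("Control%02d", seq_len(n_subjects))
  rows <- list()
  reads <- list()
  for (s in subjects) {
    for (site in c("saliva", "feces")) {
      sid <- paste(s, site, "F1", sep = "_")
      d <- sample(min_depth:max_depth, 1L)
      rows[[sid]] <- data.frame(sample_id = sid, subject_id = s,
                                site = site, timepoint = "F1",
                                group = "Control",
                                fasta_path = paste0(sid, ".fasta"),
                                stringsAsFactors = FALSE)
      reads[[sid]] <- data.frame(
        read_id = sprintf("%s_r%03d", sid, seq_len(d)), sample_id = sid,
        sequence = sample(pool, d, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (add_unpaired) {
    sid <- "IR99_saliva_F1"
    rows[[sid]] <- data.frame(sample_id = sid, subject_id = "IR99",
                              site = "saliva", timepoint = "F1",
                              group = "IR", fasta_path = paste0(sid, ".fasta"),
                              stringsAsFactors = FALSE)
    reads[[sid]] <- data.frame(
      read_id = sprintf("%s_r%03d", sid, 1:15), sample_id = sid,
      sequence = sample(pool, 15, replace = TRUE), stringsAsFactors = FALSE)
  }
  list(manifest = validate_manifest(do.call(rbind, rows)),
       reads = do.call(rbind, reads))
}

# Literal enumeration of every same-subject (saliva read, feces read)
# pair; statistics keyed by sequence, not by OTU id.
oracle_pair_scores <- function(reads, manifest, timepoint = "F1") {
  m <- manifest[manifest$timepoint == timepoint, ]
  tab <- table(m$subject_id, m$site)
  subj <- rownames(tab)[rowSums(tab > 0) == 2L]
  pair_n <- new.env(parent = emptyenv())
  total_pairs <- 0
  sal_seqs <- character()
  fec_seqs <- character()
  for (s in subj) {
    a <- reads$sequence[reads$sample_id ==
                          m$sample_id[m$subject_id == s & m$site == "saliva"]]
    b <- reads$sequence[reads$sample_id ==
                          m$sample_id[m$subject_id == s & m$site == "feces"]]
    total_pairs <- total_pairs + length(a) * length(b)
    sal_seqs <- c(sal_seqs, a)
    fec_seqs <- c(fec_seqs, b)
    for (x in a)
      for (y in b)
        if (identical(x, y))
          assign(x, mget(x, pair_n, ifnotfound = 0)[[1]] + 1, envir = pair_n)
  }
  seqs <- unique(c(sal_seqs, fec_seqs))
  res <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  res$pair_count <- vapply(seqs, function(q)
    mget(q, pair_n, ifnotfound = 0)[[1]], numeric(1))
  res$prob_s <- vapply(seqs, function(q) sum(sal_seqs == q), 1) /
    length(sal_seqs)
  res$prob_f <- vapply(seqs, function(q) sum(fec_seqs == q), 1) /
    length(fec_seqs)
  res$prob_sf <- res$pair_count / total_pairs
  res$llr <- ifelse(res$pair_count > 0,
                    log2(res$prob_sf / (res$prob_s * res$prob_f)), -Inf)
  res
}

# O(n^2) all-pairs exact clustering: label each read by the index of the
# first read whose sequence it equals.
oracle_partition <- function(seqs) {
  n <- length(seqs)
  labels <- integer(n)
  for (i in seq_len(n)) {
    j <- 1L
    while (!identical(seqs[j], seqs[i])) j <- j + 1L
    labels[i] <- j
  }
  labels
}

# canonical form of a read partition: set of sorted read-id groups
partition_signature <- function(otu_ids, read_keys) {
  groups <- split(read_keys, otu_ids)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, "", 1L))])
}

# Exact two-sided rank-sum p by full enumeration of group labelings.
perm_wilcox_p <- function(a, b) {
  na <- length(a)
  vals <- c(a, b)
  r <- rank(vals)
  combs <- utils::combn(length(vals), na)
  ws <- apply(combs, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Independently coded ACE (follows the standard estimator directly).
oracle_ace <- function(x, k = 10) {
  x <- x[x > 0]
  rare <- x[x <= k]
  s_abund <- sum(x > k)
  if (length(rare) == 0) return(as.numeric(length(x)))
  f1 <- sum(rare == 1)
  n_rare <- sum(rare)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(NA_real_)
  g2 <- 0
  for (j in 1:k)
    g2 <- g2 + j * (j - 1) * sum(rare == j)
  g2 <- max(length(rare) / c_ace * g2 / (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + length(rare) / c_ace + f1 / c_ace * g2
}

digest_reads <- function(reads) sort(reads$sequence)

# tiny manifest builder for hand-made tables
make_manifest <- function(subjects, timepoint = "F1", group = "Control") {
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    g <- if (length(group) > 1L) group[i] else group
    data.frame(
      sample_id = paste(subjects[i], c("saliva", "feces"), timepoint,
                        sep = "_"),
      subject_id = subjects[i], site = c("saliva", "feces"),
      timepoint = timepoint, group = g,
      fasta_path = "", stringsAsFactors = FALSE)
  }))
}
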