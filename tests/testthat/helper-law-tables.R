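# Hand-built OTU tables with known analytic LLR values (equal depths).

# One taxon confined to both sites of subject 1 (count `c_shared` each),
# all other mass in sample-unique filler OTUs; I paired subjects, depth d.
exclusive_taxon_table <- function(I, d = 100L, c_shared = 10L) {
  subjects <- sprintf("Control%02d", seq_len(I))
  manifest <- validate_manifest(make_manifest(subjects))
  samples <- manifest$sample_id
  n_samp <- length(samples)
  tab <- matrix(0L, nrow = 1L + n_samp, ncol = n_samp,
                dimnames = list(c("OTU_shared",
                                  paste0("OTU_fill_", samples)), samples))
  s1 <- samples[manifest$subject_id == subjects[1]]
  tab["OTU_shared", s1] <- c_shared
  for (s in samples)
    tab[paste0("OTU_fill_", s), s] <- d - tab["OTU_shared", s]
  list(table = tab, manifest = manifest)
}

# One taxon at identical count in every sample plus unique fillers.
ubiquitous_taxon_table <- function(I, d = 100L, c_ubiq = 10L) {
  subjects <- sprintf("Control%02d", seq_len(I))
  manifest <- validate_manifest(make_manifest(subjects))
  samples <- manifest$sample_id
  tab <- matrix(0L, nrow = 1L + length(samples), ncol = length(samples),
                dimnames = list(c("OTU_ubiq",
                                  paste0("OTU_fill_", samples)), samples))
  tab["OTU_ubiq", ] <- c_ubiq
  for (s in samples)
    tab[paste0("OTU_fill_", s), s] <- d - c_ubiq
  list(table = tab, manifest = manifest)
}

# vectorized all-pairs O(n^2) clustering oracle
oracle_partition_allpairs <- function(seqs) {
  eq <- outer(seqs, seqs, "==")
  apply(eq, 2, which.max)  # label = first read equal to this one
}
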