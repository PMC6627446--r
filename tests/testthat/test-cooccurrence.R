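make_reads <- function(sample_id, seqs) {
  data.frame(read_id = sprintf("%s_r%03d", sample_id, seq_along(seqs)),
             sample_id = sample_id, sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("two subject-exclusive taxa give the worked pair-count example", {
  # subject 1 is pure taxon A at both sites, subject 2 pure taxon B:
  # OTU_A has 10*10 = 100 pairs, P(S,F) = 100/200 = 0.5, P(S) = P(F) = 0.5
  manifest <- validate_manifest(make_manifest(c("sub1", "sub2")))
  reads <- rbind(
    make_reads("sub1_saliva_F1", rep("AAAA", 10)),
    make_reads("sub1_feces_F1", rep("AAAA", 10)),
    make_reads("sub2_saliva_F1", rep("CCCC", 10)),
    make_reads("sub2_feces_F1", rep("CCCC", 10)))
  tab <- build_otu_table(dereplicate(reads), manifest)
  sc <- score_cooccurrence(tab, manifest, cooc_config(timepoint = "F1"))
  a <- sc[attr(tab, "representatives")[sc$otu_id] == "AAAA", ]
  expect_equal(a$pair_count, 100)
  expect_equal(a$prob_sf, 0.5)
  expect_equal(a$prob_s, 0.5)
  expect_equal(a$prob_f, 0.5)
  expect_equal(a$llr, 1)
  expect_true(a$is_biological)
  expect_equal(a$n_subjects_with_pair, 1)
})

test_that("a saliva-only OTU scores -Inf and is never biological", {
  manifest <- validate_manifest(make_manifest("sub1"))
  reads <- rbind(make_reads("sub1_saliva_F1", c("AAAA", "CCCC")),
                 make_reads("sub1_feces_F1", c("CCCC", "CCCC")))
  tab <- build_otu_table(dereplicate(reads), manifest)
  sc <- score_cooccurrence(tab, manifest, cooc_config())
  a <- sc[attr(tab, "representatives")[sc$otu_id] == "AAAA", ]
  expect_equal(a$pair_count, 0)
  expect_equal(a$prob_sf, 0)
  expect_equal(a$llr, -Inf)
  expect_false(a$is_biological)
})

test_that("a taxon at uniform relative abundance scores llr = 0", {
  # same relative abundance in every sample, equal depths: independence
  manifest <- validate_manifest(make_manifest(c("sub1", "sub2", "sub3")))
  reads <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    filler <- strrep("C", 4 + match(manifest$subject_id[i],
                                    unique(manifest$subject_id)))
    make_reads(manifest$sample_id[i], c(rep("AAAA", 3), rep(filler, 7)))
  }))
  tab <- build_otu_table(dereplicate(reads), manifest)
  sc <- score_cooccurrence(tab, manifest, cooc_config())
  a <- sc[attr(tab, "representatives")[sc$otu_id] == "AAAA", ]
  expect_lt(abs(a$llr), 1e-12)
  expect_false(a$is_biological)
})

test_that("scoring requires paired subjects and drops zero-depth pairs", {
  m <- make_manifest("sub1")
  m <- m[m$site == "saliva", ]
  manifest <- validate_manifest(m)
  reads <- make_reads("sub1_saliva_F1", "AAAA")
  tab <- build_otu_table(dereplicate(reads), manifest)
  expect_error(score_cooccurrence(tab, manifest, cooc_config()),
               "no paired subjects")

  manifest2 <- validate_manifest(make_manifest(c("sub1", "sub2")))
  reads2 <- rbind(make_reads("sub1_saliva_F1", rep("AAAA", 5)),
                  make_reads("sub1_feces_F1", rep("AAAA", 5)),
                  make_reads("sub2_saliva_F1", "CCCC"))
  tab2 <- build_otu_table(dereplicate(reads2), manifest2)
  expect_warning(sc <- score_cooccurrence(tab2, manifest2, cooc_config()),
                 "zero-depth")
  expect_equal(sc$pair_count[1], 25)
})

test_that("read-pair scoring matches the exhaustive enumeration oracle", {
  set.seed(21)
  for (rep in 1:8) {
    co <- random_cohort(sample(2:5, 1), add_unpaired = rep %% 2 == 0)
    tab <- build_otu_table(dereplicate(co$reads), co$manifest)
    sc <- score_cooccurrence(tab, co$manifest, cooc_config())
    orc <- oracle_pair_scores(co$reads, co$manifest)
    sc$sequence <- unname(attr(tab, "representatives")[sc$otu_id])
    merged <- merge(sc, orc, by = "sequence",
                    suffixes = c("_got", "_orc"))
    expect_equal(nrow(merged), nrow(sc))
    expect_equal(nrow(merged), nrow(orc))
    expect_equal(merged$pair_count_got, merged$pair_count_orc)
    fin <- is.finite(merged$llr_orc)
    expect_equal(merged$llr_got[!fin], merged$llr_orc[!fin])
    expect_lt(max(abs(merged$llr_got[fin] - merged$llr_orc[fin]), 0), 1e-9)
    # conservation: paired pair-counts never exceed the pair universe
    m <- co$manifest
    paired <- paired_subjects(m, "F1")
    tot <- sum(vapply(paired, function(s) {
      sal <- m$sample_id[m$subject_id == s & m$site == "saliva"]
      fec <- m$sample_id[m$subject_id == s & m$site == "feces"]
      sum(co$reads$sample_id == sal) * sum(co$reads$sample_id == fec)
    }, 1))
    expect_lte(sum(sc$pair_count), tot)
  }
})

test_that("presence mode satisfies the llr identity", {
  set.seed(22)
  co <- random_cohort(4)
  tab <- build_otu_table(dereplicate(co$reads), co$manifest)
  sc <- score_cooccurrence(tab, co$manifest, cooc_config(mode = "presence"))
  expect_true(all(sc$prob_s >= 0 & sc$prob_s <= 1))
  expect_true(all(sc$prob_f >= 0 & sc$prob_f <= 1))
  fin <- sc$pair_count > 0
  expect_equal(sc$llr[fin],
               log2(sc$prob_sf[fin] / (sc$prob_s[fin] * sc$prob_f[fin])))
  expect_true(all(sc$llr[!fin] == -Inf))
  expect_equal(sc$prob_sf > 0, sc$pair_count > 0)
})

test_that("event calling applies a strict threshold and sorts by llr", {
  scores <- data.frame(
    otu_id = sprintf("OTU%06d", 1:5),
    pair_count = c(0L, 3L, 5L, 2L, 1L),
    llr = c(-Inf, 0, 0.5, 0.51, 1.0))
  ev <- call_events(scores, 0.5)
  expect_equal(ev$llr, c(1.0, 0.51))  # 0.5 itself excluded

  expect_equal(nrow(call_events(scores[0, ], 0.5)), 0L)

  # monotonicity: raising the threshold never adds events
  set.seed(23)
  co <- random_cohort(3)
  tab <- build_otu_table(dereplicate(co$reads), co$manifest)
  sc <- score_cooccurrence(tab, co$manifest, cooc_config())
  n_ev <- vapply(seq(-2, 3, by = 0.25), function(th)
    nrow(call_events(sc, th)), 1L)
  expect_true(all(diff(n_ev) <= 0))
})

test_that("group profiles attribute events per contributing subject", {
  manifest <- validate_manifest(make_manifest(c("c1", "i1"),
                                              group = c("Control", "IR")))
  # OTU shared by both groups' subjects + one Control-only OTU
  reads <- rbind(
    make_reads("c1_saliva_F1", c(rep("AAAA", 4), rep("GGGG", 4), "TTTT",
                                 "TTTT")),
    make_reads("c1_feces_F1", c(rep("AAAA", 5), rep("GGGG", 5))),
    make_reads("i1_saliva_F1", c(rep("AAAA", 8), "CCCC", "CCCC")),
    make_reads("i1_feces_F1", c(rep("AAAA", 10))))
  tab <- build_otu_table(dereplicate(reads), manifest)
  sc <- score_cooccurrence(tab, manifest, cooc_config())
  ev <- call_events(sc, 0)
  reps <- attr(tab, "representatives")
  tax <- setNames(paste0("taxon_", substr(unname(reps), 1, 1)), names(reps))
  pr <- summarize_group_profiles(ev, tab, manifest, tax, "F1")
  s <- pr$summary
  expect_setequal(s$group, c("Control", "IR"))
  # AAAA is an event in both groups; GGGG only in Control
  expect_true(all(c("taxon_A", "taxon_G") %in% colnames(pr$taxon_freq)))
  expect_equal(s$event_count[s$group == "Control"], 2L)
  expect_equal(s$event_count[s$group == "IR"], 1L)
  expect_equal(unname(pr$taxon_freq["Control", c("taxon_A", "taxon_G")]),
               c(0.5, 0.5))
  expect_equal(unname(pr$taxon_freq["IR", "taxon_A"]), 1)
  expect_equal(s$events_per_paired_subject, s$event_count / 1)

  # frequency rows sum to one where events exist
  expect_equal(unname(rowSums(pr$taxon_freq)), c(1, 1))

  # no events: zero counts, empty frequencies
  pr0 <- summarize_group_profiles(ev[0, ], tab, manifest, tax, "F1")
  expect_equal(pr0$summary$event_count, c(0L, 0L))
  expect_equal(ncol(pr0$taxon_freq), 0L)

  # taxon normalization: 2 OTUs of one taxon, 1 of another -> 2/3, 1/3
  tax2 <- setNames(c("X", "X", "Y", "Y")[seq_along(reps)], names(reps))
  tax2[] <- ifelse(unname(reps) %in% c("AAAA", "GGGG"), "X", "Y")
  ev2 <- call_events(sc, -10)   # keep everything with pairs
  pr2 <- summarize_group_profiles(ev2, tab, manifest, tax2, "F1")
  expect_equal(unname(pr2$taxon_freq["Control", "X"]), 1)

  ghost <- ev
  ghost$otu_id[1] <- "OTU999999"
  expect_error(summarize_group_profiles(ghost, tab, manifest, tax, "F1"),
               "consistency error")
})

test_that("profile clustering is deterministic with sane distances", {
  x <- rbind(Control = c(1, 0), IR = c(0, 1))
  colnames(x) <- c("tA", "tB")
  hc <- cluster_profiles(x, metric = "bray_curtis")
  expect_equal(max(hc$height), 1)  # disjoint profiles: Bray-Curtis 1

  y <- rbind(Control = c(0.5, 0.5), IR = c(0.5, 0.5))
  colnames(y) <- c("tA", "tB")
  expect_equal(cluster_profiles(y)$height, 0)  # identical: height 0

  z <- rbind(Control = c(1, 0), IR = c(1, 0), VU = c(0, 1))
  colnames(z) <- c("tA", "tB")
  hc3 <- cluster_profiles(z)
  # the identical pair merges first, at height 0
  expect_equal(hc3$height[1], 0)
  first <- hc3$merge[1, ]
  expect_setequal(hc3$labels[-first], c("Control", "IR"))

  expect_error(cluster_profiles(z[1, , drop = FALSE]), "at least 2")
  zz <- rbind(z, INR = c(0, 0))
  expect_warning(cluster_profiles(zz), "no events")

  nwk <- profiles_newick(hc3)
  expect_match(nwk, "Control")
  expect_match(nwk, ";$")
})
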