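---
title: "Detecting oral–gut bacterial co-occurrence from paired amplicon samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting oral–gut bacterial co-occurrence from paired amplicon samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orogut)
```

## The question

Saliva and feces host very different bacterial communities, yet the mouth
continuously seeds the gut. Given paired 16S rRNA amplicon samples —
one salivary and one fecal sample per individual — we ask which exact
sequences occur in *both* body sites of the *same* person more often than
chance would allow. Such sequences are candidates for genuine oral–gut
transit (in either direction) rather than coincidental presence of a
ubiquitous organism. The package was designed around a four-group HIV
cohort study design (uninfected controls, immunological ART responders
IR, non-responders INR, and viremic untreated VU), sampled at baseline
(F1) and after a six-week prebiotic intervention (F2), but nothing in the
method is specific to that cohort.

## Exact OTUs

Reads are dereplicated at 100% identity: two reads belong to the same
OTU if and only if their sequences are equal character for character —
same length, same letters, `N` comparing literally. We deliberately do
not use substring or length-tolerant matching: any tolerance would need
an alignment definition, and the point of the exact criterion is that a
shared OTU is the strongest possible sequence-level evidence of a shared
organism. One consequence worth knowing: a single sequencing error
splits a read off its OTU, so exact OTU counts are an undercount of true
taxon sharing; the co-occurrence score below is robust to this because
it only needs *some* identical read pairs, not all of them.

By default all samples of a timepoint are pooled into one clustering
universe (saliva + feces, all groups) and co-occurrence is then
evaluated per subject and summarized per group; `cluster_by = "group"`
clusters each group separately instead. Pooled clustering keeps OTU
identities comparable across groups, which the per-group taxon profiles
rely on.

## The co-occurrence score

For OTU $k$, restricted to *paired* subjects $i$ (those with both sites
sampled at the timepoint) with read depths $d_i^S, d_i^F$ and OTU counts
$c_{ik}^S, c_{ik}^F$, the number of same-subject saliva–feces read pairs
inside the OTU is

$$\mathrm{pairs}_k = \sum_i c_{ik}^S \, c_{ik}^F ,$$

and the score is the log~2~ pointwise mutual information

$$\mathrm{LLR}_k \;=\; \log_2 \frac{P(S,F)}{P(S)\,P(F)}, \qquad
P(S,F) = \frac{\mathrm{pairs}_k}{\sum_i d_i^S d_i^F},\quad
P(S) = \frac{\sum_i c_{ik}^S}{\sum_i d_i^S},\quad
P(F) = \frac{\sum_i c_{ik}^F}{\sum_i d_i^F}.$$

$\mathrm{LLR} = 0$ means the OTU's presence in the two sites is exactly
what independent sampling of the two marginals would give;
$\mathrm{LLR} > 0$ means same-subject pairing in excess of independence.
Two analytic facts anchor the interpretation (both are enforced by unit
tests, exactly, not approximately):

* a taxon confined to both sites of a single subject among $I$
  equal-depth paired subjects scores $\mathrm{LLR} = \log_2 I$ — the
  score grows with the cohort because subject-exclusivity becomes more
  surprising;
* a taxon at identical relative abundance in every sample scores
  $\mathrm{LLR} = 0$ and is never called, however abundant.

An OTU is a **biological event** when it has at least one same-subject
read pair *and* $\mathrm{LLR}$ strictly exceeds the threshold. The
shipped threshold is 0.5: zero is the independence point, and the extra
half-bit is a deliberate conservative margin ($P(S,F)$ at least
$\sqrt2$ times the independence expectation). With equal depths the
exclusive-taxon law above means any subject-exclusive shared taxon is
called as soon as the cohort has $I \ge 2$ paired subjects.

How the three probabilities are estimated is a genuinely open choice —
pair counting over reads is the default (`mode = "read_pair"`, matching
the pair-counting definition of the score), and a per-subject
presence/absence estimator (`mode = "presence"`) is provided as a
robustness check; both satisfy the same LLR identity and threshold
semantics. Subjects missing one of the two sites cannot form pairs and
are excluded from the pairing universe, though their reads still
participate in clustering. OTUs absent from all paired-subject samples
have an undefined LLR and are omitted; OTUs seen on one side only score
$-\infty$.

Events are attributed to every group containing at least one
contributing subject (an OTU can be an event in two groups), because the
per-group taxon spectra are drawn from a shared OTU universe; the
alternative — attributing an event only to the group where it was
discovered — would make the spectra incomparable. Group profiles are
normalized to taxon relative frequencies, and `events_per_paired_subject`
is the headline rate because group sizes differ. Profiles are compared
by average-linkage clustering of Bray–Curtis distances (a correlation
option exists); profiles with no events are dropped from the dendrogram
since Bray–Curtis is undefined on an all-zero vector.

## Alpha diversity

`alpha_diversity()` reports observed OTUs, Shannon $H = -\sum p_i \ln
p_i$ (natural log by default, the convention of the R toolchain this
field mostly uses; the base is an argument), Simpson's index of
diversity $1 - D = 1 - \sum p_i^2$, classic Chao1
($S_{obs} + F_1^2 / 2F_2$), bias-corrected Chao1
($S_{obs} + F_1(F_1{-}1)/(2(F_2{+}1))$, the variant `vegan::estimateR`
reports, and our headline column), and ACE with the standard
rare/abundant cut at 10 reads (configurable). Degenerate corners are
handled explicitly: no doubletons switches Chao1 to its $F_2 = 0$ form;
ACE is `NA` with a warning when every rare read is a singleton (sample
coverage 0) and equals $S_{obs}$ when no OTU is rare. There is no
rarefaction: the synthetic generator uses equal depths precisely so that
depth is not a confound, and real unequal-depth data should be
interpreted accordingly.

F1-vs-F2 comparisons use the two-sided Wilcoxon rank-sum test per group
and index — exact by enumeration when the combined sample size is at
most 12 and tie-free (small groups need exact behaviour), otherwise the
normal approximation with tie and continuity corrections — with
Benjamini–Hochberg correction applied across the whole battery.
Kruskal–Wallis is available for multi-group contrasts. These delegate
to `stats::kruskal.test`, `stats::wilcox.test` and `stats::p.adjust`;
the package adds validation, the exact/approximate switching rule, and
a uniform result container.

## What the synthetic generator does and does not emulate

`generate_cohort()` builds a cohort with known ground truth:

* **Design**: groups × subjects × 2 sites × 2 timepoints; defaults are
  the four-group design with 14/9/18/12 subjects, every subject fully
  paired at both timepoints.
* **Communities**: each site has its own pool of background taxa
  (`n_taxa_site = 100`) with subject-specific log-normal relative
  abundances (`lognormal_sigma = 1`, a typical amplicon-scale
  dispersion); the two pools are disjoint at the sequence level.
* **Planted truth**: `n_shared_subject_taxa = 2` taxa per subject are
  planted in *both* of that subject's sites at `shared_abundance =
  0.05` each. At zero error rate these are the *only* possible source
  of cross-site identity, so every called event can be labelled true or
  false against the truth table.
* **Reads**: exactly `depth = 500` reads per sample (a desk-scale
  working size; the analysis is linear in depth and the acceptance
  checks also run at depth 200), drawn multinomially, each read the
  taxon's reference sequence (250 bp, uniform-random, pairwise
  distinctness asserted) with i.i.d. substitutions at `error_rate`
  (default 0). Substitution-only error keeps read length fixed, which
  matters because exact clustering is length-sensitive, and produces
  the realistic "near-identical but unclustered" reads that probe the
  100%-identity decision.
* **Intervention**: at F2 relative abundances are raised to the power
  `1/intervention_evenness_factor` and renormalized. The default 0.5
  squares the abundances, concentrating mass on dominant taxa — an
  evenness (hence Shannon/Simpson) drop with richness held constant,
  mimicking a post-prebiotic diversity decrease while keeping the
  richness and evenness knobs independent.

It does **not** emulate chimeras, PCR or GC bias, indels, paired-end
artefacts, unequal depths, taxonomic names, or subject dropout between
timepoints. Passing tests on this generator therefore demonstrate the
*correctness of the computation* and the qualitative direction of the
intervention effect — not that any particular real dataset will show
those effects.

## Numerical and reproducibility choices

* All generator randomness flows from one integer seed; identical
  configs give byte-identical FASTA/TSV outputs (tested).
* OTU ids are `OTU000001…` by first appearance after sorting reads by
  `(sample_id, read_id)`, so labels are independent of input order.
* Event calling uses a *strict* inequality; an LLR of exactly 0.5 is
  not an event. $-\infty$ is represented explicitly and excluded.
* Dendrogram rows are sorted lexicographically before clustering, so
  tie handling never depends on input order.
* The Wilcoxon exact/approximate switch is at combined $n = 12$;
  two-sided throughout, $\alpha = 0.05$.

## A short run

```{r}
cfg <- cohort_config(groups = c(Control = 4L, IR = 4L), depth = 200L,
                     n_taxa_site = 40L, seed = 7L)
run <- run_pipeline(cfg)
run
run$F1$profiles$summary
head(run$stats[run$stats$index == "shannon", ])
```

Per-subject planted taxa are subject-exclusive, so with 8 paired
subjects each scores $\log_2 8 = 3$:

```{r}
head(run$F1$events[, c("otu_id", "pair_count", "llr", "is_biological")])
```

## Known limitations

* Exact identity is conservative by construction: sequencing error and
  intra-genome 16S copy variation both *reduce* sensitivity, and the
  score cannot distinguish oral→gut from gut→oral transit.
* The LLR has no null-distribution calibration here; 0.5 is a fixed
  conservative margin, not a controlled error rate. Treat called
  events as ranked candidates.
* Group attribution multi-counts shared events; summed per-group event
  counts can exceed the number of distinct event OTUs by design.
* With very small paired cohorts ($I < 2$) the exclusive-taxon law
  caps the achievable LLR below the threshold and nothing can be
  called — intended behaviour, since one subject cannot establish
  non-randomness.
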