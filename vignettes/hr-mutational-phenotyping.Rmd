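---
title: "Mutational phenotyping of HR deficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational phenotyping of HR deficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrsig)
```

## Scope and model

Cells that lose homologous recombination (HR) — through defects in BRCA1,
BRCA2, PALB2, the RAD51 paralogs, or RAD54 — accumulate somatic mutations
with characteristic patterns: a flat, "featureless" base-substitution
signature; short deletions whose breakpoints carry microhomology; and
small/mid-size non-clustered structural deletions. `hrsig` implements the
analyses that turn per-clone mutation catalogs from an isogenic knockout
panel into those phenotypes:

1. **Substitution spectra.** Each SNV is classified into one of 96
   channels: the six pyrimidine-referenced substitution classes (C>A, C>G,
   C>T, T>A, T>C, T>G) crossed with the 5' and 3' flanking bases. A
   purine-referenced mutation is reverse-complemented together with its
   context, so both strands of the same event map to one channel. Channel
   order is fixed (classes in the order above; within a class, 5' then 3'
   base alphabetically).
2. **De novo signatures.** Spectra from several samples (or per-genotype
   sums, the default input) are factorized as `V ≈ W H` with nonnegative
   `W` (channels x k signatures) and `H` (k x samples exposures),
   minimizing the Frobenius loss by Lee–Seung multiplicative updates.
3. **Reference fitting.** A spectrum is decomposed over a reference
   signature matrix by non-negative least squares (NNLS); contributions
   below a pruning floor (default 6%) are zeroed and the rest refit once.
4. **Indel phenotypes.** Short deletions are classified by sequence
   context — `repeat` if the deleted sequence has at least two tandem
   copies in the reference, else `microhomology` if the breakpoints share
   at least 1 bp, else `none` — and all indels into the standard 83
   channels (1 bp events by homopolymer context, longer events by length,
   repeat copies, and microhomology length).
5. **Rearrangement phenotypes.** Filtered structural variants are
   assigned to 32 categories (clustered/non-clustered x del/dup/inv x five
   size bins, plus translocations); clustered breakpoints are found by an
   exact piecewise-constant fit on log10 inter-breakpoint distances;
   signature contributions again come from NNLS.
6. **Cut-site spectra.** Merged amplicon reads spanning a Cas9 cut are
   globally aligned to the reference amplicon and gap runs near the cut
   are summarized as deletion/insertion/mixed events.

## Parameters that matter

* `nmf_extract(rank, n_restarts = 50, seed)` — rank is chosen from the
  cophenetic correlation coefficient of the restart-consensus matrix
  (`nmf_rank_survey()`); on the clone-panel design a rank of two (an
  HR-deficiency-like and a background-like signature) is the stable
  optimum. Restarts guard against local minima of the multiplicative
  updates; the best-RSS restart is kept, and a fixed seed makes the result
  reproducible. Convergence: relative RSS change below `tol = 1e-9`,
  checked every 10 iterations, capped at `max_iter = 2000`.
* `fit_signatures(min_contribution = 0.06)` — the pruning floor mirrors
  the default of the widely used deconstruction tools: contributions under
  6% are indistinguishable from noise at typical burdens. The pruning is a
  single pass (NNLS, zero the small columns, NNLS again), not a forward
  selection.
* `tune_control_threshold(max_snv = 5, max_indel = 1)` — ancestral clones
  are internal negative controls; thresholds are the smallest values that
  leave every control with at most five SNVs and one indel, filtering with
  score strictly greater than the threshold.
* `summarize_rates()` — fold changes are ratios of per-clone means against
  the wild-type group; p-values come from a goodness-of-fit chi-square on
  the summed counts (expected proportional to clone numbers, every genome
  assumed to present equal mutational opportunity, no continuity
  correction), Bonferroni-multiplied and capped at 1. A 2x2 contingency
  form would need a callable-genome opportunity, which the summed-count
  reading does not require; both agree in the large-opportunity limit.
* `detect_clusters(kmin = 10, gamma = 25)` — the penalized least-squares
  segmentation is solved exactly by dynamic programming (O(n^2) per
  chromosome). The signal is each breakpoint's log10 distance to its
  nearest sorted neighbour; a segment is clustered when its mean
  inter-breakpoint distance is at least 10-fold below the chromosome
  average. Size bins for the 32 categories are half-open with exclusive
  upper edges ([1,10) kb, [10,100) kb, ...), so a deletion of exactly
  10 kb falls in the second bin.
* `filter_svs(min_softclip = 5, tol = 10)` — breakpoint uniqueness across
  samples is tested within +/-10 bp, absorbing caller jitter; "covered in
  all samples" is encoded as depth >= 1 in a user-supplied coverage table
  (depth extraction from alignments is a documented pre-step, keeping the
  module desk-testable).
* `alignment_params()` — match +5, mismatch −4, gap open 10, gap extend
  0.5, end gaps free (the defaults of the classic global DNA aligner), so
  a gap of length L costs `10 + (L−1)·0.5` and trimmed read ends do not
  register as events. `extract_events(window = 20)` keeps only events
  within 20 bp of the cut site; the window and the all-reads denominator
  for percentages are this package's own conventions. A deletion and an
  insertion within 3 bp merge into one `mixed` event — likewise a
  package convention, since mixed events are observed but not formally
  defined in the field.
* `classify_indels(max_len = 50)` — events of 50 bp and longer are routed
  to the rearrangement analysis.

## The synthetic-data generators

The package analyses sequencing-derived catalogs, but ships
seed-deterministic generators that emulate the study design and emit
machine-readable truth:

* `simulate_catalog()` draws per-sample 96-channel counts multinomially
  from exposure-weighted signature mixtures. It emulates mutation
  *counts*, not genomic positions; selection, clustered mutagenesis and
  copy-number structure of real genomes are outside its scope.
* `simulate_genome_with_indels()` plants deletions whose local context
  *forces* a requested class: repeat deletions inside a tandem array,
  microhomology deletions with a copied k-bp prefix just past the 3'
  breakpoint, and `none` sites re-randomized until free of incidental
  homology. Because contexts are constructed, the classifier is expected
  to recover planted classes exactly — the tests assert equality, not
  statistical closeness. Backgrounds are i.i.d. uniform bases (optionally
  GC-weighted); real genomes' repeat landscape is *not* emulated, so
  passing tests validate the classification rules, not genome-wide class
  prevalence.
* `simulate_sv_catalog()` draws 32-channel counts from a rearrangement
  signature mixture, sizes log-uniform within each size bin, positions on
  a synthetic 10 x 100 Mb karyotype, and lays clustered-channel events in
  dense runs so that the cluster detector has a signal to find.
* `separability_experiment()` is the simulation study behind the headline
  robustness claim: samples are drawn from preset mixtures of two similar
  flat signatures, rank-2 NMF is run, recovered signatures are matched to
  the generators by best cosine, and the mean absolute error over the
  2 x 96 probability entries is reported in percentage points. Defaults —
  mixture grid {0.2, 0.35, 0.5, 0.65, 0.8}, 33 samples (the 11-genotype x
  3-clone panel), 1,000 mutations per sample, 10 replicates — mirror the
  scale of the cell-line experiment.

```{r}
ref <- reference_signatures("cosmic_v2_synthetic")
sep <- separability_experiment(ref[, "Sig3"], ref[, "Sig5"],
                               replicates = 2, seed = 1)
round(sep$mae, 3)
```

## Bundled reference sets are synthetic

The published reference signature matrices cannot be redistributed with
this package, so `reference_signatures()` returns *synthetic stand-ins*,
generated deterministically by `scripts/make_reference_data.R` and named
accordingly. Each synthetic signature reproduces the documented
qualitative shape of its namesake: a CpG-focused C>T profile for Sig1,
TpC-focused APOBEC-like profiles for Sig2/Sig13, mismatch-repair-like
profiles for Sig6/15/20/26, a POLE-like profile for Sig11, and flat
"featureless" profiles for Sig3 and Sig5 whose cosine similarity (0.82)
was set to match the published similarity of the real pair, since that
similarity is what governs how hard the two are to separate. The
32-channel set follows the same logic (RS5 = non-clustered small/mid
deletions, RS3 = small tandem duplications, RS4 = clustered
translocations, ...). Analyses of real data should substitute the
published matrices; every function accepts any column-stochastic matrix
of the right dimension.

## Numerical choices and degenerate inputs

* NMF: random `U(0.1, 1)` initialization; a small epsilon guards the
  multiplicative-update denominators; all-zero sample rows are excluded
  with a warning (their exposures are undefined); signatures are
  column-normalized with the scale folded into exposures and ordered by
  total exposure, descending. Signature matching across runs uses greedy
  best-cosine assignment, since NMF column order is arbitrary.
* Cophenetic coefficient: restart-wise dominant-signature assignments
  build a consensus matrix; average-linkage clustering of `1 − consensus`
  gives the cophenetic distances; a degenerate (perfectly consistent)
  consensus is reported as 1.
* NNLS satisfies the KKT conditions at the solution (checked in the test
  suite to 1e-8); an all-zero reference column or an empty catalog is an
  error rather than a silent zero fit.
* Deletion classification left-aligns events first, so any placement of
  the same deletion inside a repeat tract yields the identical call;
  repeat takes precedence over microhomology (a full-length breakpoint
  match *is* a tandem copy), and microhomology is measured on both
  breakpoint sides with the maximum taken, capped at deletion length − 1.
  At contig edges flanks are truncated with a warning.
* Rates: a zero wild-type mean makes fold changes NaN (with a warning);
  identical summed counts give a chi-square statistic of 0 and an
  adjusted p of 1.
* The deletion-length median uses the lower-midpoint convention (even
  counts report the lower central order statistic), matching how 1 bp
  medians are reported for heavily 1 bp-skewed distributions.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data,
sized to finish in minutes on one core while leaving the statistical
margins wide: the separability simulation at its default scale (33
samples x 1,000 mutations, 10 replicates); clone-panel rate recovery at
3 clones per genotype around a 30-SNV wild-type burden; 10,000 random
deletions for the classifier-versus-oracle equivalence; exhaustive
alignment enumeration on short sequence pairs; and segmentation
instances of up to ~55 breakpoints against the exact enumeration oracle.

## Known limitations

* The generators emulate counts and local contexts, not reads; caller
  artefacts (strand bias, mapping error, panel-of-normals effects) are
  upstream of this package.
* The ITX category of breakpoint callers has no one-to-one mapping onto
  the del/dup/inv scheme; without orientation information ITX calls are
  excluded from the 32-channel catalog and reported separately.
* The 6% pruning pass is a simplification of forward-selection
  deconstruction; with many highly collinear reference signatures the two
  can differ near the floor.
* Exposure recovery accuracy for two signatures as similar as the flat
  pair is burden-limited: below roughly 1,000 mutations per sample the
  split between them is noisy even when the signature *shapes* are
  recovered well — which is precisely the regime the separability
  simulation quantifies.
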