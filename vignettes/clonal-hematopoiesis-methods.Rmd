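---
title: "Methods: detecting and reconstructing radiation-induced clonal hematopoiesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and reconstructing radiation-induced clonal hematopoiesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonoscope)
```

`clonoscope` analyzes deep amplicon resequencing of candidate somatic
mutations across many tissues of the same animal, with the goal of
separating *clonal hematopoiesis* (CH) — somatic clones expanded within
the blood system — from ordinary developmental mosaicism, and of
reconstructing the clonal architecture of individual animals from
single-cell-derived colony data. This vignette documents the model, the
thresholds and their rationale, the statistical procedures, and the
scope of the cohort simulator.

## 1. Data model

The atomic observation is one variant measured in one tissue of one
animal: `animal_id`, `tissue`, `chrom`, `pos`, `ref`, `alt`,
`alt_reads`, `depth`, with `vaf = alt_reads / depth` recomputed from the
counts on ingest. Variants are identified by the key
`chrom.pos.ref.alt`. Tissue names are normalized to a fixed vocabulary:
hematopoietic tissues `BM` (bone marrow), `spleen`, `thymus` and the
sorted lineages `T`, `B`, `GRAN`, `ERY`; non-hematopoietic tissues
`tail`, `brain`, `testis`, `thyroid`, `liver`, `kidney`, `lung`.

Long observation tables are pivoted into per-variant *profiles* — one
row per (animal, variant) with `vaf_<tissue>` / `depth_<tissue>`
columns — by `build_profiles()`. Supported input formats are a TSV
variant table, a minimal VCF with `AD` genotype fields
(`read_variant_table(format = "vcf")`, parsed with **vcfR**), and a
colony CSV (`read_colony_matrix()`) holding per-colony VAF/depth pairs.
Thresholds live in a plain YAML config (`read_config()`).

## 2. Candidate filtering and three-way classification

`filter_candidates()` applies three filters to the bone-marrow signal,
recording a rejection reason with fixed precedence
(`germline_vaf` > `low_vaf` > `read_support` > `recurrence`):

* **VAF band** `[0.02, 0.35]`, boundaries inclusive. The lower bound is
  the assay's reliable detection limit; the upper bound excludes
  germline heterozygous variants (which cluster at 0.5).
* **Read support**: at least `min_alt_reads = 6` alternate reads;
  variants supported by 5 or fewer reads are treated as amplification
  or sequencing artifacts.
* **Recurrence**: a variant detected (VAF ≥ `detect_vaf = 0.005`) in
  more than `recurrence_fraction = 0.5` of the cohort's animals is
  treated as a systematic artifact (an in-cohort panel of normals).
  The detection threshold is deliberately *separate from* and lower
  than `vaf_min`: a site can betray artifact status at sub-candidate
  levels.

`classify_variants()` then labels each survivor by its tissue
distribution. Let `v_bm` be the BM VAF and `v_nh` the maximum VAF over
the non-hematopoietic reference tissues (`tail`, `brain`, `testis`,
`thyroid` by default — the classic mosaicism references; blood-filtering
organs such as liver and kidney are excluded because circulating cells
contaminate them):

* `CH_NONMOSAIC` — `v_nh < detect_vaf`: the clone exists only in the
  blood system, so the mutation arose in a hematopoietic cell.
* `CH_MOSAIC` — `v_bm / v_nh ≥ expanded_fold (5)`: an embryonic mosaic
  mutation whose carrying clone has *expanded* in blood.
* `MOSAIC_NOT_CH` — `v_bm / v_nh ≤ similar_fold (3)`: similar VAFs
  everywhere; plain developmental mosaicism.
* `UNCLASSIFIED` — the fold ratio falls in the open gap (3, 5). The gap
  is reported explicitly rather than silently forcing a label.

Because the mutations are heterozygous in diploid cells, a clone
carrying a variant at VAF *v* comprises `clone_fraction(v) = 2v` of
nucleated cells; a BM VAF of 0.29 means the clone accounts for 58% of
bone-marrow cells, and VAF 0.1 means 20%. `clone_fraction()` errors on
VAF > 0.5 rather than reporting an impossible fraction.

`summarize_cohort()` aggregates per animal and per exposure group:
counts of each class, sub-counts of "large" clones (BM VAF strictly
greater than `vaf_high = 0.1`), group means, and the number of animals
carrying at least one CH clone. Multisite clusters (Section 3) are
collapsed to single events before counting so one mutational event is
never counted twice.

## 3. Mutation spectrum

`variant_type()` classes each variant from the anchored ref/alt pair as
`SNV`, `DEL`, `INS`, or `COMPLEX`. Single-nucleotide substitutions are
collapsed onto the pyrimidine strand into the six classes C>A, C>G,
C>T, T>A, T>C, T>G (`substitution_class()`).

Deletion lengths (`len(ref) − len(alt)`) are binned as 1–3, 4, 5–31 and
>31 nt. The empty 4-nt bin is kept explicit so the short/long split is
checkable. For deletions with junction context (columns `deleted_seq`,
`left_flank`, `right_flank`),

```
microhomology_length(d, lf, rf) =
  max( longest common prefix(d, rf), longest common suffix(d, lf) )
```

and `has_microhomology()` calls a junction positive at ≥ 2 nt — the
signature of microhomology-mediated end joining of a DNA double-strand
break. Either-end homology counts, since repair can anneal at either
junction.

`detect_multisite()` flags *clustered* mutations — multiple lesions
from a single radiation track — by single-linkage clustering (union
–find): two variants of the same animal link if they lie on the same
chromosome within `window_bp = 100` and their BM VAFs differ by at most
`vaf_tol = 0.05` (same-clone evidence). The window and tolerance are
decisions, not measurements, and are config-exposed.

## 4. Clone architecture from colony data

Single HSC/MPP-derived colonies are clonal, so a truly carried
heterozygous mutation reads out near VAF 0.5. `genotype_colonies()`
calls each (colony, mutation):

* `PRESENT` — depth ≥ `min_depth (20)` and VAF in `[0.3, 0.7]`;
* `ABSENT` — deep and VAF < 0.3;
* `AMBIGUOUS` — insufficient depth, or VAF above 0.7 (not a clean
  heterozygous site). Ambiguity is a first-class outcome so allelic
  dropout cannot fabricate absence.

`group_mutations()` merges mutations whose PRESENT/ABSENT patterns
agree on every colony unambiguous for both (up to
`max_pattern_mismatch`, default 0): co-occurring mutations belong to
one clone. `infer_relations()` compares support sets restricted, for
each pair, to colonies unambiguous for both groups: strict subset ⇒
*nested* (subclone), disjoint ⇒ *exclusive* (independent clones),
crossing ⇒ *conflict* (reported, never resolved silently).

`estimate_fractions()` sets each clone's BM fraction to twice the mean
of its members' bulk BM VAFs (members of one clone must agree;
disagreement beyond `vaf_tol = 0.05` is warned about), checks that
children do not exceed parents and that top-level fractions do not
exceed 1 (within `frac_tol`), and reports the *delivered fraction* —
the share of bone marrow produced by the detected clones — in both
available senses: the sum of top-level doubled VAFs, and the proportion
of colonies carrying any clone mutation. `render_composition()` prints
the nested tree with the unexplained remainder.

## 5. Group statistics

**Exact rate contrast.** With per-animal exposure, comparing `y1`
events in `n1` exposed animals against `y0` in `n0` controls is exact
Poisson regression with one binary covariate; conditioning on the total
`T = y1 + y0` reduces it to `y1 | T ~ Binomial(T, n1/(n1+n0))`.
`exact_rate_test()` reports the one-sided upper-tail p and a two-sided
p under the minimum-likelihood convention (sum of all outcome
probabilities no larger than the observed one, with a `1 + 1e-7`
relative slack for floating-point ties). For a zero reference count the
one-sided p is the closed form `(n1/(n1+n0))^T`. The rate-ratio MLE is
`(y1/n1)/(y0/n0)`, `Inf` when `y0 = 0 < y1`, undefined when `T = 0`.
Two-sided conventions differ across software; both p-values are always
reported.

**Weighted regression.** `wls_fit()` fits outcome ~ group + covariates
by weighted least squares via `stats::lm(weights=)`. When no weights
are given it uses two-step feasible weights: an unweighted first pass,
then weights equal to the inverse of the within-group residual
variance, so the noisier exposure group is down-weighted. Rows with
missing outcomes are dropped with a message; singular designs error.
Each fit carries a Breusch–Pagan heteroskedasticity check:
`breusch_pagan()` regresses squared residuals on the design and refers
`n · R²` to χ²(k−1). It is hand-rolled (two lines on top of `lm.fit`)
and cross-checked against `lmtest::bptest` in the test suite.

## 6. Cohort simulator

`simulate_cohort(sim_config(...))` generates a full synthetic cohort
with embedded ground truth, for power studies and for validating the
pipeline end to end:

* Per irradiated animal, a Poisson number of CH clones
  (`ch_rate_irradiated`, default 4; controls default to 0), clone
  fractions from a Dirichlet split of a total drawn in
  `clone_fraction_total`, and a zero-truncated Poisson number of
  mutations per clone parameterized by its *mean*
  (`mutations_per_clone_mean`; the underlying rate is solved with
  `uniroot`). Mosaic mutations are planted across all tissues; with
  probability `mosaic_expansion_prob` one mosaic clone is expanded in
  blood (a true `CH_MOSAIC`).
* Mutation types follow the configured substitution weights (C>T
  dominant by default), deletion fraction and length weights;
  microhomology is planted at junctions with probability
  `microhomology_prob`; `multisite_prob` produces clustered pairs.
* Reads are Binomial(depth, true VAF + `seq_error = 0.001`) per
  tissue; sorted lineages get multiplicative jitter and optional
  T-cell exclusion. Colony matrices draw colony assignments
  multinomially from the clone mixture and per-colony VAFs from a
  Beta(100, 100) heterozygous model; `noise = "none"` /
  `assignment = "expected"` give deterministic matrices for exact
  recovery tests.
* Everything is reproducible from `sim_config(seed=)`; `write_cohort()`
  emits the TSV/CSV inputs plus a `truth.json`.

The simulator is generative-parametric, not mechanistic: it does not
model hematopoietic stem-cell birth–death dynamics, sequencing reads,
or alignment artifacts.

## 7. Numerical and testing choices

* Exact tests are computed from `pbinom`/`dbinom` tail sums, never by
  simulation; the test suite checks them against a brute-force pmf
  enumeration oracle over totals up to 200.
* WLS coefficients are checked against the closed-form weighted normal
  equations at 1e-8 relative tolerance; Breusch–Pagan against the
  auxiliary-regression form and against `lmtest`.
* Microhomology is checked against a brute-force overlap scan on 10⁴
  random contexts; clone reconstruction against 100 random noise-free
  clone forests (exact partition and nesting recovery) and against
  noisy simulations (fraction error ≤ 0.02 in ≥ 95% of cases).
* Profile tables round-trip through TSV at full precision (`%.17g`).
* Problem sizes in the property tests (cohorts of up to 1000 control
  animals, 200 replicate cohorts for count recovery, 10⁴ Monte-Carlo
  replicates for test size) were chosen to keep the whole suite under
  a few minutes while leaving Monte-Carlo margins of at least three
  standard errors.

## 8. Worked example

```{r example, eval = FALSE}
library(clonoscope)

# simulate, write, and re-ingest a cohort
sim <- simulate_cohort(sim_config(seed = 7))
dir <- tempfile(); write_cohort(sim, dir)

profiles <- build_profiles(read_variant_table(file.path(dir, "variants.tsv")))
animals  <- animal_records(read.csv(file.path(dir, "animals.csv")))

# filter, classify, summarize
prof <- classify_variants(filter_candidates(profiles))
summarize_cohort(prof, animals)

# spectrum and rate contrast
spectrum_summary(prof)
exact_rate_test(y1 = 65, n1 = 12, y0 = 0, n0 = 6)
```
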