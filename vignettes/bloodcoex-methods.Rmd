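---
title: "Methods: co-expression network analysis of case-control blood transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression network analysis of case-control blood transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bloodcoex)
```

# Scope and model

`bloodcoex` analyzes a genes × samples matrix of log2-scale normalized
expression from a two-group (case/control) blood study, with per-sample
sex, age, scan-date batch, and time-since-event covariates. It covers the
path from filtering through network construction, module detection,
module–trait association, hub identification, enrichment, and per-gene
differential expression. Normalization, probe summarization, alignment,
and pathway databases are out of scope: the pipeline consumes an already
normalized matrix and plain-text gene sets (GMT).

## Filtering

Three filters run in a fixed order, each idempotent:

1. **Maximum-expression filter** — remove a gene iff its maximum over all
   samples is strictly below 5 (log2 units).
2. **Sex-stratified prevalence filter** — per sex (pooled across
   diagnosis groups), compute the proportion of samples with expression
   below 3; remove the gene when that proportion strictly exceeds 50% in
   *either* sex. Stratifying prevents an uneven male/female balance from
   deciding which genes survive; the "either" reading is the conservative
   one and a `rule = "both"` switch provides the alternative. Whether the
   original procedure pooled or stratified diagnosis groups is ambiguous
   ("across all groups"); pooling within sex is implemented.
3. **QC** — remove genes with any missing value (no imputation) or zero
   variance.

Strictness matters at the boundary: a maximum of exactly 5, or a
prevalence of exactly 50%, is retained.

## Network construction

Pearson correlation is computed between all gene pairs, and the unsigned
adjacency is `a_ij = |cor_ij|^β`. The unsigned transform follows the
convention of treating strong negative co-expression as connectivity
(consistent with exporting edges unsigned).

**Soft-threshold selection.** For each candidate β (default 1–20),
connectivities `k_i = Σ_{j≠i} a_ij` are summarized in 10 equal-width bins
and `log10(frequency)` is regressed on `log10(mean k)`; the signed fit is
`−sign(slope)·R²`. The chosen β is the lowest candidate with signed
R² ≥ 0.8, falling back (with a warning) to the best-fitting candidate
when none passes. Bins are equal-width on the **raw k scale**, matching
the reference scale-free fit index in this field. An equal-width binning
of `log10(k)` is selectable (`bin_scale = "log10k"`) but is not the
default: on data with planted modules and a large unconnected background,
the log-scale histogram resolves the background's lognormal-shaped bulk
and the fit never crosses 0.8 at any power, so selection would always hit
the fallback; the raw-scale binning reproduces the expected
cross-and-stay behavior.

**Topological overlap.** `ω_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`
with `ℓ_ij = Σ_{u≠i,j} a_iu a_uj`, diagonal 1. Zero denominators (only
possible for fully disconnected pairs) yield ω = 0 with a warning.
Clustering uses average linkage on `1 − ω`; a `dissimilarity = "cor"`
switch clusters `1 − |cor|^β` instead for sensitivity analysis. The
TOM route is the default because shared-neighbor smoothing suppresses
single spurious correlations.

## Module detection

Branches of the dendrogram become modules when they contain at least
`min_module_size` genes (default 100); everything else is "grey"
(unassigned). The branch-defining cut is placed **adaptively**: candidate
cut heights are the midpoints of the widest gaps among merge heights in
the upper half of the height distribution, tried in decreasing gap width,
keeping the first that yields at least two full-sized branches (then at
least one; else all genes stay grey). The rationale is scale-invariance:
the gap between within-module merges and the background-joining region is
structural, but its absolute position depends strongly on β — at high
powers all TOM dissimilarities compress into a thin band under 1.0, where
any fixed cut such as 0.99 × max height fails outright (verified: every
gene grey at β ≥ 11 on simulated defaults). A `cut_method = "static"`
switch provides the fixed-fraction cut. With `deep_split = FALSE`
(default) accepted branches are not split further; with `deep_split =
TRUE` a branch is replaced by its sub-branches when at least two of them
are independently full-sized. This is not a bit-exact replica of the
reference dynamic tree-cut implementation; its contract is recovery of
planted modules, which the acceptance suite checks (adjusted Rand index
≥ 0.8 against ground truth, grey excluded, across seeds).

Modules are labeled by descending size from the conventional color
vocabulary (turquoise, blue, brown, …), grey reserved for unassigned.

## Eigengenes, module–trait association, hubs

A module's eigengene is the first right singular vector of its
standardized (per-gene mean 0, SD 1) member expression — the first
principal component over samples — unit-normalized and oriented so its
mean correlation with members is nonnegative. Variance explained is
`d₁²/Σd²`.

Eigengenes are associated with traits by Pearson correlation with a
Student-t p-value on n − 2 df; diagnosis is coded CTRL = 0 / ICH = 1, in
which case the test is algebraically the equal-variance two-sample
t-test. No covariate adjustment is applied by default (the convention the
module-selection threshold p(Dx) < 0.05 comes from), and no
multiple-testing correction across modules (a BH option exists, off by
default).

Hubs are the `ceiling(0.05 × module size)` genes with highest
intramodular connectivity kIN per module, ties broken lexicographically
by gene id so the hub set is deterministic and order-invariant. kIN was
chosen over eigengene-based membership correlation because
interconnectivity is the stated hub criterion in this workflow.

## Enrichment

Over-representation uses the exact hypergeometric upper tail
`P(X ≥ q)`, summed in log space so p-values far below double underflow
(< 1e-300) remain finite and exact; the test is symmetric in the two
lists. Only over-representation is offered. The universe is an explicit
argument on every call — by convention the post-filter analyzed gene set —
because enrichment p-values are meaningless without it and the original
choice is unstated in this field more often than not.

## Differential expression

Per gene: fixed effects diagnosis, sex, diagnosis×sex, age,
time-since-event; scan date as a random intercept; estimation by REML
(`lme4`); an ordinary ANCOVA fallback when fewer than two batches exist.
Design choices:

* **Tested quantity.** `p_dx` is the Wald test of the
  least-squares-means contrast `β_dx + ½·β_dx:sexM` — the ICH − CTRL
  difference averaged equally over sexes. With a 24M/9F design, testing
  the raw `diagnosisICH` coefficient would test the effect among the 18
  females only; the sex-averaged contrast matches the type-III
  main-effect convention of standard ANCOVA platforms and is what "the
  diagnosis effect" means marginally. A joint 2-df F-test of main effect
  plus interaction is available (`dx_test = "joint"`).
* **Degrees of freedom.** Residual df `n − p`. Satterthwaite
  approximations are deliberately out of scope; with 66 samples and 6
  batches the difference is small, and the null calibration is verified
  by simulation rather than assumed.
* **Fold change.** From the same adjusted contrast on the log2 scale:
  `FC = 2^Δ` if Δ ≥ 0 else `−2^{−Δ}`, so |FC| ≥ 1 and the sign encodes
  direction; raw group means are available by flag. Significance is
  exactly `FDR < 0.05 ∧ |FC| > 1.2`.
* **Failures.** Genes whose fit fails are excluded from the BH adjustment
  and counted, never silently dropped.

BH-FDR is the package's own step-up implementation, tested against a
brute-force application of the definition (and `p.adjust`) exactly.

# The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with defaults stating a 66-subject world: 33 ICH / 33 CTRL, 24
male / 9 female per group, draw times uniform on 4.2–124.3 h, ages
centered near 62, six scan-date batches assigned round-robin within
group so every batch spans both groups (this makes the batch random
intercept identifiable). Controls receive a simulated draw time too —
the differential-expression model includes time for all subjects, so the
generator must supply it; this is a modeling choice, not a claim about
the original study's handling.

Genes come in three roles. **Module members** follow
`baseline + loading·u_m + batch + sex + age·slope + time·slope + noise`
with per-sample latent factor `u_m ~ N(0,1)` shifted by the module's
diagnosis effect (in SD units) in ICH samples, loadings uniform on
0.4–0.9, noise SD 0.5 around a baseline of 6 log2 units. **Background
genes** carry baseline, covariates and noise only. **Low-expressed
genes** (default 10%) are constructed to fail exactly one of the two
expression filters — half with maximum below 5, half below 3 in every
male sample but high in females — so the filters' truth-table behavior is
testable exactly. Per-module cell-type gene sets contain 60% of the
module's genes (the purity default) plus ~25% background members, so
enrichment p-values are non-trivial. Covariate effect scales (batch SD
0.3, sex SD 0.2, age slope SD 0.01/year, time slope SD 0.002/h) were
chosen once as plausible for log2 array data — batch and demographic
effects smaller than biology but non-negligible — and are not tuned.

Everything is a pure function of the configuration including its seed.

**What the generator does not emulate**: probe-level array artifacts,
count-based noise, correlated module factors, hierarchically nested
modules, realistic gene symbols, missing-value patterns. A green
recovery test therefore establishes that the pipeline detects
latent-factor block structure of realistic strength at n = 66 — not that
it reproduces any particular real dataset's module count.

## Calibration tests and dependence

Two spec-level subtleties surfaced during development and shaped how the
null-calibration tests are posed:

* In any latent-factor world at n = 66, the factor's chance imbalance
  between groups (SD ≈ √(4/66) ≈ 0.25) shifts every member gene of a
  module coherently, so *conditionally on a dataset* the per-gene null
  p-value distribution is far from uniform even though it is uniform
  marginally. Unadjusted covariate effects (age/time slopes) add a
  smaller overdispersion of the same kind. KS-uniformity and binomial
  fraction bounds are therefore checked on background-only (iid) null
  configurations — the setting where those bounds are mathematically
  valid — while chance module-level association is checked by permutation
  nulls, which are valid under dependence.
* The hypergeometric test is discrete: under a permutation null the
  probability of `p < 0.05` is the largest attainable p-value below 0.05
  (≈ 0.036 for the default module/set sizes), not 0.05. The enrichment
  permutation test compares observed flags to that exact attainable
  level, computed with the package's own tail function.

# Numerical choices

* Soft-threshold scan: 10 bins, empty bins dropped, raw-k bin widths (see
  above); degenerate all-equal connectivity errors.
* TOM: computed via one matrix product; denominators ≥ `1 − a_ij` are
  guarded, zero denominators warn and yield 0.
* Eigengene sign: mean member correlation ≥ 0; exact ties (mean 0) keep
  the SVD's sign.
* Hub ties: lexicographic gene id; hub count `ceiling(fraction × size)`
  is never zero.
* Writers: expression at 12 significant digits (round trips to ~1e-9),
  result tables at 6 (stable goldens); eigengene unit norm to 1e-8;
  `kTotal = kIN + kOut` to 1e-12.

# Known limitations

* No Satterthwaite/Kenward-Roger df; small-batch-count designs with
  large batch variance will be slightly anticonservative.
* No module merging by eigengene similarity, no signed-network variant
  beyond the config switch, no block-wise scaling beyond ~20k genes
  (dense matrices).
* The adaptive gap cut assumes modules merge internally before the
  background joins; extremely gradual hierarchies may be cut at an
  unexpected level (the static cut remains available).
* Cell-type enrichment treats signatures as fixed gene lists; disease
  states that change cell-type specificity are outside the model.
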