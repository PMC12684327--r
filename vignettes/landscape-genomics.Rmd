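---
title: "Models and methods: from genotypes to genomic offset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from genotypes to genomic offset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

landgen implements the landscape-genomics workflow for a species sampled at
a small number of sites (order 10) across an environmental gradient, with a
few individuals per site and genome-wide bi-allelic SNPs. This vignette is
the package's own account of the models it fits, the parameters that matter,
the choices made where the design was genuinely open, and what the synthetic
studies used in its tests do and do not demonstrate.

## The synthetic study

Every stage of the pipeline is testable because the generator plants a known
truth.

**Landscape.** Each environmental layer on an `r`×`c` grid is a linear
gradient with a random orientation, standardised to unit spatial standard
deviation and scaled by `gradient_strength` (default 2), plus
Gaussian-smoothed noise (default unit standard deviation, smoothing radius
1.5 cells). The default mimics a strongly structured climate surface — for
the rainfall-like driver variable, the gradient component dominates —
while keeping local heterogeneity. Sites are placed uniformly at random.

**Genotypes.** Ancestral alternate-allele frequencies are Uniform(0.05,
0.95). Site frequencies follow the Balding–Nichols model: p_site ~
Beta(p(1−F)/F, (1−p)(1−F)/F) with `F_drift` (default 0.1), chosen because
it gives a closed-form differentiation target — the multilocus
Weir–Cockerham θ estimates F, which the test suite verifies to ±0.02.
An optional latent level (`F_group`) drifts three West/Central/East group
frequencies first and sites within groups at the residual
F solving (1−F_drift) = (1−F_group)(1−F_within), so the site-level target
is preserved for any group share. The default is `F_group = 0`: the flat
island model is the model under which the estimators and the outlier nulls
are derived, and it is the configuration used for calibration and recovery
tests. The latent-group option exists to exercise cluster assignment
(k-means on leading principal components recovers the three groups) and to
emulate data with real hierarchical structure.

**Adaptive loci.** A fraction `prop_adaptive` (default 1%) of loci receive
an environmental effect on the logit of the site-level mean frequency
before the drift draw: logit(p) ← logit(p) + β·z, where z is the driver
variable standardised across sites and β defaults to 1.5 logit units per
standard deviation. One driver variable per locus. Applying the shift to
the mean (rather than to the already-drifted frequency) avoids the logit
compression that would otherwise mute the effect at loci drifted toward
fixation; drift noise still acts on top of the shift, as it would in a real
population. Genotypes are Binomial(2, p_site); loci monomorphic across the
whole sample are redrawn up to 10 times, then kept and flagged, so the
locus count is exact.

**What this does not emulate.** No linkage (loci are independent, so LD
pruning on simulated data removes almost nothing), no realistic site
frequency spectrum (loci are ascertained polymorphisms with uniform
ancestral frequencies — Tajima's D is positive by construction on these
fixtures, and the D implementation is instead verified against a neutral
1/k spectrum constructed in the tests), no selfing, bottlenecks or spatial
kinship. Passing tests therefore demonstrate the correctness and
calibration of the statistics under the island model with independent loci
— not their power or error rates on data with linked sweeps, hierarchical
admixture or demographic complications.

## Estimators

Conventions that change numbers and are therefore worth stating:

* H_E is the unbiased Nei estimator 2p(1−p)·2n/(2n−1); multilocus values
  are means over callable loci.
* Multilocus F_IS is ratio-of-sums, 1 − ΣH_O/ΣH_E; its permutation test
  reshuffles alleles within a group (H_E is invariant under this, so only
  H_O is recomputed) and is one-sided for heterozygote deficit.
* π is the frequency-based per-locus estimator summed over SNPs and
  divided by a user-supplied accessible length L. The choice of L changes
  the scale; with variant-only normalisation (L = number of SNPs) π is
  numerically close to mean H_E, with genome-length normalisation it is
  orders of magnitude smaller. Both are available because the right L
  depends on how the callable genome was defined upstream.
* Tajima's D treats the 2n gene copies of a group as the sample and uses
  loci completely called within the group; groups with fewer than 4 copies
  or no segregating site are flagged undefined rather than given a value.
* Weir–Cockerham θ is ratio-of-sums over loci; negative estimates are
  reported, not truncated. Monomorphic loci are excluded from the sums.
* Allelic richness uses the exact hypergeometric rarefaction formula with
  symmetric locus exclusion (a locus enters only if every group has at
  least g copies; default g = 12).
* KING-robust kinship φ = (N_het,het − 2·N_opposite-hom)/(N_het,i +
  N_het,j) over pairwise-complete loci, with the standard powers-of-two
  classification bands.

## Selection scans and their calibration

The package treats null calibration as a first-class requirement: on
neutral island-model data each scan's p-values should be uniform, and the
test suite checks the empirical distribution function against a 1%
Kolmogorov band. Three choices follow from that requirement.

**Trimmed covariance for Mahalanobis scans.** The PC-regression scan
(pcadapt-style) and the RDA loading scan summarise per-SNP score vectors by
a Mahalanobis distance. A covariance matrix estimated over all SNPs is
inflated by the very outliers the scan is meant to find; location and
scatter are therefore re-estimated after dropping the 5% most extreme
points (the role robust covariance estimators play in the reference
implementations of both methods), and the distances are rescaled by the
genomic inflation factor λ = median(D²)/χ²_K(0.5).

**A parametric null for the F_ST outlier test.** The classical
Lewontin–Krakauer reference — (k−1)·F_ST/F̄ against χ²_{k−1} — is
substantially over-dispersed on island-model data at realistic sample sizes
(a Kolmogorov distance of ~0.16–0.21 from uniform on the package's null
fixtures, an order of magnitude outside the band). The default is
therefore a parametric Balding–Nichols null matched to the data: ancestral
frequencies resampled from observed locus means, Beta site frequencies at
the estimated multilocus θ, binomial genotypes at the observed sample
sizes; simulated and observed loci are compared within strata of folded
mean frequency (the null distribution of F̂_ST depends on it), and the
upper tail beyond the 99th percentile is modelled by a generalized Pareto
fit so that p-values are resolved beyond the Monte-Carlo floor
(`n_sim = 3e5` by default; deeper simulation changes results negligibly
because the Pareto tail carries the extrapolation). This is the same
island-model logic the Bayesian F_ST-outlier samplers are built on, in a
closed, fast, deterministic-given-seed form; the χ² reference remains
available (`p_mode = "chisq"`). The parametric null assumes the flat
island model: under strong hierarchical structure it becomes mildly
anti-conservative, which is a known limitation of F_ST outlier testing in
general.

**Variance-stabilised response for the RDA scan.** Raw site-frequency
responses give RDA loadings whose variance depends on each locus's
frequency; the resulting Mahalanobis distances are a variance mixture and
miss the χ² reference. The scan therefore runs on
(p − p̄)/√(p̄(1−p̄)) (`standardize_freqs()`); the genomic-offset RDA keeps
raw frequencies, where the biplot and projections are the point.

**LFMM.** Latent factors are the leading left singular vectors of the
genotype matrix projected off the environmental variable with a small
ridge (λ = 1e-5, numerical stabilisation only); per-locus t-statistics are
recalibrated by the genomic inflation factor. K = 3 confounders is the
default, matching the three-cluster structure the package's own group
assignment targets. Per-variable p-values are the calibrated objects; the
multi-variable scan flags a SNP if any variable flags it (the same
any-variable rule is applied to the Bayes-factor scan; the alternative of
summing per-variable counts is reported in the Venn output instead).

**Bayes factors.** Ω is the covariance across loci of standardised
population frequencies; SNP and environment are whitened by Ω^(−1/2) and a
closed-form Zellner g-prior Bayes factor (g = number of populations,
unit-information) is computed for slope versus null:
BF = (1+g)^(−1/2)·(1 − g/(1+g)·R²)^(−n/2) with the uncentred R² of the
whitened regression. 15 dB is kept as the outlier threshold. At 11
populations this threshold corresponds to a per-test tail probability of a
few per mille, so on hundreds of thousands of SNPs it will flag some
neutral loci; it is one vote in the consensus, not a calibrated test.

**Consensus.** Methods vote; SNPs detected by at least `m_min` methods
form the candidate set. The default `m_min = 4` (of five methods) mirrors
a conservative multi-method design; the recovery analyses in the test
suite use `m_min = 2` over four methods, where sensitivity around 60–75%
with an empirical FDR well under 20% is what these methods achieve at
their published thresholds on the default study (11 sites × 8 diploids,
5000 loci, 1% adaptive, β = 1.5, F = 0.1). The corresponding acceptance
test asserts a 70% sensitivity bar; on the default conditions the measured
median sits just below it, with the misses concentrated at loci whose
per-method statistics fall just short of the fixed thresholds
(BH q ≈ 0.05–0.12 for the PC scan; Bonferroni being ~10× stricter than
the RDA scan's near-misses). We report this rather than relaxing any
threshold.

**Forward selection.** ordiR2step-style: add the candidate maximising
adjusted R² if its marginal permutation p < 0.01 (999 permutations) and
the model's adjusted R² does not exceed the full-scope adjusted R². When
every other candidate is pure noise that cap is a mean-zero comparison
(Ezekiel's adjustment is unbiased), so it can stop selection before a
genuine variable enters; `r2_scope = FALSE` disables it, mirroring the
toggle the reference implementation exposes. Ties are broken by candidate
order.

## Genomic offset

The enriched RDA regresses candidate-locus site frequencies on climate
standardised by a `climate_standardizer` fitted once on the current
climate of the reference region and applied identically to current and
future layers — the standardisation is what makes compositions comparable
through time, and it also makes the offset exactly invariant to affine
unit changes of the raw climate (°C versus °F style), which the tests
check. Projection is linear: score_k(cell) = Σ_v coef[v,k]·(env_v −
training mean), so projected scores at the training sites equal the fitted
site scores exactly.

offset(cell) = √(Σ_k w_k (cur_k − fut_k)²) over K_axes = 2 axes by
default, with w_k the eigenvalue fraction of axis k. Eigenvalue weighting
is the convention of the enriched-RDA offset literature; an unweighted
mode is provided because the choice is not uniquely fixed, and the number
of axes is configurable (two mirrors the outlier convention). Offsets are
exactly linear in the climate displacement, hence monotone in scenario
severity. Cells whose climate lies outside the training-site range on any
variable are flagged as extrapolation but not masked; time-invariant
terrain variables should be excluded from the projection because they have
no future counterpart. The vulnerability report deliberately keeps
exposure (offset rank) and adaptive capacity (candidate-locus diversity
rank) side by side instead of collapsing them into one score.

## Numerical choices and degenerate inputs

* LD pruning removes the later SNP of a violating pair (position, then
  column order) — deterministic, and re-running the pruner on its own
  output is the identity; the reference implementation's survivor choice
  is not documented, so results can differ from it SNP-by-SNP while
  satisfying the same r² guarantee. Pairwise-complete r² is used for
  missing data.
* With variant-level missingness at 0 (the default), the subsequent
  sample-missingness filter cannot fire; the order (variants first) is
  logged.
* BED↔VCF coordinates: a SNP at 1-based position p is inside a 0-based
  half-open interval (s, e] iff s < p ≤ e; the boundary is pinned by
  tests.
* Conditioned RDAs drop predictors that are numerically inside the span of
  the conditioning block (residual column norm below 1e-8 of the
  original): keeping their noise-level residuals would fabricate
  constrained inertia. Conditioning a block on itself therefore yields
  exactly zero constrained inertia, and the variance partition is additive
  to machine precision by construction.
* Axis signs (PCA and RDA) are fixed by making the largest-|loading| entry
  positive, so scores are reproducible across platforms.
* Permutation p-values are (1 + #{extreme})/(1 + B); Monte-Carlo p-values
  from the parametric F_ST null are floored at the per-stratum resolution
  and extended by the Pareto tail.
* All stochastic functions take a seed and restore the caller's RNG state.

## Problem sizes used by the tests

Module tests run on matrices of roughly 6–200 individuals × 3–4000 loci;
calibration and recovery tests use the default study (88 individuals ×
5000 loci) with one seed for calibration and ten seeds for recovery;
offset properties use 800–1200 loci over ten seeds. These sizes keep the
full suite to a few minutes while leaving Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

Site-level GEA with 11 populations has limited degrees of freedom: the
Bayes-factor and RDA scans rank reliably but flag conservatively, and
forward selection with few sites is sensitive to the adjusted-R² scope
rule discussed above. The F_ST parametric null assumes the island model.
The offset model is linear in standardised climate and inherits all the
usual caveats of genomic-offset inference — it is a maladaptation *risk*
proxy, valid to the extent the GEA relationship is causal and stable over
the projection horizon.
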