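---
title: "Models and methods behind pairdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pairdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(pairdose)
```

# Scope

`pairdose` quantifies how dosage-sensitive a homologous X–Y gene pair is and
how its expression is buffered when dosage is perturbed. The motivating
biology is the handful of ancestral genes that survive on both the human X
and Y chromosomes: the most dosage-critical of them (DDX3X/DDX3Y being the
extreme case) are expressed from the inactive X, retain their Y homolog
across placental mammals, and — uniquely for DDX3X/DDX3Y — hold their summed
expression in a narrow band through negative post-transcriptional cross- and
auto-regulation. The package implements the whole quantitative chain:
evolutionary retention metrics, constraint and breadth composites, expression
dose-response to sex-chromosome copy number, allelic-ratio buffering tests,
knockdown compensation indices, and kinetic mRNA half-life estimation, plus
a synthetic-data module that generates each input class with the statistical
structure the estimators assume.

# Phylogenetic survival metrics

For a Y-linked gene and a rooted species tree with branch lengths in million
years (MY), `branch_length()` sums the branches of the minimal subtree
connecting the **root** to every species where the gene survives, each branch
counted once. Including the root path treats the gene as ancestrally present:
a gene surviving in a single deep lineage still accrues its full
root-to-leaf path. `survival_fraction()` divides this observed length by the
maximum possible (the stratum tree's total length): 1 means retention in
every lineage.

Two choices deserve comment.

* **Stratum maxima are an input, not an inference.** X–Y pairs arose in
  different evolutionary strata, so each gene's maximum possible branch
  length depends on when its stratum stopped recombining (663 MY of tree for
  the older eutherian stratum across 15 species, 967 MY for the therian
  stratum that includes SRY, 140 MY for the youngest). The packaged
  `load_xy_pair_table()` fixture carries the stratum maximum explicitly
  where it is determinable from published values (the branch length of
  fraction-1 genes) and `NA` where it is not; nothing tries to guess a
  stratum from the presence pattern.
* **Presence is binary per species.** Partial terminal branches for lineages
  where a gene is pseudogenized but detectable are not modelled.

Published branch lengths are printed as whole MY, so recomputing a survival
fraction from printed integers can differ from the printed 3-decimal
fraction by up to one unit in the last decimal (656/663 = 0.9894 prints as
0.990); tests compare at that printed precision.

# Constraint and breadth composites

`percentile_rank()` converts a per-gene constraint metric into a 0–100
percentile with 100 = most constrained; the direction flag covers both
LOEUF-like metrics (low = intolerant to loss of function) and conserved
miRNA-targeting probabilities (high = selected against over-expression).
Ties share the mean rank; missing values propagate. `pythagorean_combine()`
merges two scores as $\sqrt{(p_1^2+p_2^2)/2}$ — the root-mean-square, which
is symmetric, monotone in each argument, and normalized so the composite
stays on the input scale. Only the ordering of composites carries scientific
weight; the $\sqrt2$ normalization preserves ordering while keeping the
scale interpretable.

`expression_breadth()` is $\sum_i x_i / (N \max_i x_i)$ over $N$ tissues,
bounded by $[1/N, 1]$, scale-invariant, and 1 only for perfectly uniform
expression. For an X–Y pair, `pair_breadth()` averages the two homologs and
combines the pair mean with the breadth of the autosomal chicken ortholog
(a proxy for the ancestral state) on the unit scale; a missing outgroup
breadth yields a missing composite rather than a silently one-armed score.

# Dose-response to chromosome copy number

`fit_dose_response()` models TPM linearly on centred copy numbers
$(n_X - 1)$, $n_Y$, and optionally $(n_{21} - 2)$, so the intercept
$\beta_0$ is the expected expression of a 45,X-like baseline and each slope
is the TPM increment per added chromosome. The relative increments
$\Delta E_X = \beta_X/\beta_0$ and $\Delta E_Y = \beta_Y/\beta_0$ express
dosage response relative to a single active X; a gene whose expression from
Xi and Xa were independent and additive would show $\Delta E_X$ equal to its
allelic ratio (next section). Linear-scale TPM was chosen over log scale so
that the increment interpretation is exact rather than approximate; the
trisomy-21 predictor exists as a negative control for generic aneuploidy
effects. Rank-deficient designs (a constant predictor) raise an error naming
the predictor, and a non-positive fitted baseline makes the relative
increments `NA` with a warning rather than returning a misleading ratio.
`dose_correlation()` supplies the companion Pearson r and two-sided p.
When run across many genes, Benjamini–Hochberg adjustment across genes is
the package convention (`p.adjust`).

`classify_xy_retained()` reproduces the expression-based karyotype filter
for cancer cell line panels: a line is treated as 46,XY iff log2TPM(DDX3Y) >
0.2, log2TPM(RPS4Y) > 0.2, and log2TPM(XIST) < 2, all strict, with missing
values flagged and called not-retained.

# Allelic-ratio buffering test

The allelic ratio AR of an X-linked gene is the ratio of Xi- to Xa-derived
transcripts. `allelic_ratio()` sums allele-specific counts over informative
SNPs within a sample *before* dividing — coverage-weighting each SNP and
making the estimate invariant to how reads are split across SNPs — rather
than averaging per-SNP ratios. `ar_vs_deltaEx_test()` then asks whether the
per-sample ARs exceed a fixed reference $\Delta E_X$: under independent,
additive Xi and Xa expression the two quantities should agree, so a mean AR
significantly above $\Delta E_X$ (e.g. AR 0.55 vs $\Delta E_X$ 0.26 for
DDX3X in lymphoblastoid lines) indicates buffering downstream of Xi
transcription. The replicate unit is the per-sample AR; the reference is a
point value. The default test is two-sided (the directional alternative is
available) because the direction of departure is a finding, not an
assumption.

# Knockdown compensation

`compensation_indices()` reduces a paired control/knockdown experiment to
two indices computed on replicate means: the **summed ratio**
(summed pair TPM in knockdown over control; 1 = total expression fully
maintained) and the **recovery fraction** (partner's absolute rise over the
target's absolute loss). The synthetic generator implements cross-coupling
as a linear transfer: a fraction $\kappa$ of the target's absolute
expression loss is added to the partner. This is the simplest mechanism
consistent with full compensation ($\kappa = 1$ gives summed ratio 1), and
the recovery fraction equals $\kappa$ in expectation, which the parameter
recovery suite verifies for $\kappa \in \{0, 0.5, 1\}$. Guides are pooled
into one knockdown arm by default; a per-guide analysis is a matter of
subsetting the annotation. If the target is not actually reduced the
recovery fraction is undefined and returned as `NA` with a warning.

For qPCR, `ddct_fold()` computes $\Delta Ct$ against the reference gene,
$\Delta\Delta Ct$ against the control-group mean, and fold $2^{-\Delta\Delta
Ct}$. Each treated group is compared with control by a one-sided Welch
t-test on $\Delta Ct$ in the direction of increased target expression
(appropriate for an inhibitor expected to de-repress its target), with BH
adjustment across groups.

# Half-life from metabolic labeling

With constant synthesis $\alpha$ and first-order decay $\beta$, labeled
(nascent) RNA approaches steady state as $(\alpha/\beta)(1 - e^{-\beta t})$.
After normalizing nascent signal to the steady-state total, the curve is
$y(t) = A(1 - e^{-\beta t})$ with a free plateau $A$ absorbing labeling
efficiency and the normalization constant, and the half-life is $\ln 2 /
\beta$. The plateau-free parameterization sidesteps the exact normalization
constant entirely.

**Normalization.** `normalize_timecourse()` divides the spike-in-normalized
nascent TPM at each time point by the *mean* spike-normalized total TPM
across the series (per replicate). Total mRNA sits at steady state
throughout labeling, so pooling its measurements estimates one denominator
instead of injecting every point's total-library noise into the ratio;
with measurement CV $c$ on both channels, the per-point ratio would carry
CV $\approx \sqrt{2}c$ while the pooled version stays near $c$. A uniform
rescaling of all spike TPMs cancels exactly, and points with zero total are
dropped with a warning.

**Fitting.** `fit_saturation()` uses Levenberg–Marquardt least squares with
$A_0 = 1.05\max(y)$, $\beta_0 = \ln 2 / t_{1/2}^{guess}$ (first time the
series crosses half the starting plateau), bounds $A \in (0, 2\max(y)]$,
$\beta > 0$, and SSE tolerance $10^{-10}$ over at most 500 iterations. The
$t = 0$ point is included: the model form forces $y(0) = 0$, so measured
background at $t=0$ contributes to residuals instead of being subtracted.
A fit that cannot beat a flat mean (monotone-decreasing input, all-zero
input) is flagged `converged = FALSE` — such data carry no saturation
signal, and a silent estimate would be worse than a flagged failure.

**Uncertainty.** `bootstrap_halflife()` resamples centred residuals
(inflated by $\sqrt{n/(n-p)}$ to undo the downward bias of least-squares
residual variance) onto the fitted curve and refits. The interval is
studentized (bootstrap-t) using the delta-method standard error
$\widehat{se}(\hat h) = (\ln 2/\hat\beta^2)\,\widehat{se}(\hat\beta)$:
at the seven time points typical of labeling experiments, the plain
percentile interval is materially anti-conservative (in our simulations at
CV 0.1 it covered a true half-life in roughly three quarters of runs at
nominal 95%), while the studentized interval restores close-to-nominal
coverage (~90%). `compare_conditions()` reports the half-life ratio between
two conditions with a percentile interval over paired bootstrap draws.

# The synthetic-data generators

The generators define the package's study conditions; all statistical tests
run against them.

* **Aneuploidy panels** (`gen_aneuploidy_expression()`): expectation
  $\beta_0(1 + \Delta E_X(n_X-1) + \Delta E_Y n_Y)$, optional pairwise
  cross-coupling transferring $-\kappa \times$ (partner's deviation from its
  46,XY-reference expectation), multiplicative lognormal noise. Lognormal
  noise keeps TPMs non-negative and mimics the right-skewed technical
  variation of RNA-seq; the lognormal $\sigma$ is set so the coefficient of
  variation matches the requested CV exactly and the noise is
  mean-preserving. The default CV of 0.2 is a typical between-culture
  variation for primary fibroblast TPMs; it is a stated default, not a
  published estimate.
* **Allele-specific counts** (`gen_allele_counts()`): totals Poisson around
  the mean coverage; Xi counts beta-binomial with mean proportion
  $AR/(1+AR)$ and intra-class correlation $\rho$, capturing the
  overdispersion of allele-specific RNA-seq relative to pure binomial
  sampling.
* **Knockdowns** (`gen_knockdown_experiment()`): target mean reduced by the
  knockdown efficiency, partner raised by $\kappa \times$ the absolute
  loss, lognormal noise per replicate.
* **Labeling timecourses** (`gen_labeling_timecourse()`): noiseless nascent
  fraction exactly $1 - e^{-\beta t}$ (0 at $t=0$), constant spike-in,
  lognormal noise on nascent and total channels. Default sampling times 0,
  0.5, 1, 1.5, 2, 3.5, 7 h match the experimental design the estimator is
  meant for.
* **Phylogenies** (`gen_phylo_fixture()`): random rooted tree rescaled to a
  requested stratum total, presence patterns spanning survival fractions in
  (0, 1].

One global integer seed drives everything; `derive_seed()` derives
per-generator substreams deterministically so stages can re-run
independently and whole pipelines reproduce byte-identically
(`run_pipeline()` writes a manifest with the config hash and seed).

What the generators deliberately do **not** model: read-level sampling and
mapping bias, splice isoforms, batch effects, sex-stratified tissue panels
for the breadth metric, and cell-cycle or culture-condition drift. Passing
the recovery suites therefore shows the estimators are correct for the
assumed generative structure — linearity in copy number, beta-binomial
allelic sampling, first-order decay — not that real sequencing data meet
those assumptions.

# Numerical and testing choices

* Noiseless generate-then-fit identities are asserted to $10^{-6}$ (NLS) or
  $10^{-8}$ (OLS) relative error; floating-point-exact identities (spike
  rescaling, allelic-ratio splitting) to $10^{-6}$ or exactly.
* Monte-Carlo recovery checks compare a mean estimate against truth within
  2 Monte-Carlo standard errors; type-I error of the AR test is checked in
  [0.03, 0.07] at $\alpha = 0.05$ over 2000 null replicates.
* Problem sizes used by the test suite: 200 random trees (≤ 15 leaves)
  against a brute-force subtree oracle, 1000 random breadth vectors, 200
  simulation seeds for $\Delta E_X$ recovery, 100 seeds × 300 draws for
  bootstrap coverage, 40 seeds × 200 draws for ratio-CI power, 500 seeds
  for half-life error and qPCR fold recovery, 50 fits per condition for the
  half-life recovery medians.
* Degenerate inputs fail loudly and specifically: empty presence sets,
  unknown species, constant predictors, zero-variance ARs, zero Xa counts,
  unreduced knockdown targets, non-saturating timecourses.

# Known limitations

* The survival subtree assumes ancestral presence at the stratum root;
  genes that arrived on the Y later would be over-credited.
* $\Delta E$ ratios are undefined for genes with non-positive fitted
  baselines, which can occur for noisily measured, lowly expressed genes.
* The bootstrap-t interval can still undercover below ~7 time points or at
  CVs well above 0.1; the per-fit convergence flag and CI failure warnings
  are the guardrails.
* Compensation indices use replicate means; with very few replicates the
  recovery fraction is noisy, and no small-sample correction is applied.
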