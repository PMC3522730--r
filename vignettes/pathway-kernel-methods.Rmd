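---
title: "Kernel-machine pathway association: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-machine pathway association: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical methods it
implements, the tunable parameters that matter, the places where the design
was genuinely open and what was decided, and what the validation suite does
and does not establish.

## The model

The outcome is binary disease status $y_i$ for $i = 1,\dots,n$ subjects.
For a SNP set with genotype matrix $G$ ($n \times p$ minor-allele counts),
the logistic kernel-machine model writes

$$\operatorname{logit} P(y_i = 1) = X_i' \alpha + h(G_i),$$

where $X$ holds the adjustment covariates (intercept, age in years,
recruitment institution as indicator contrasts, and the first ancestry
principal component) and $h$ lies in the function space generated by a
kernel. With the linear kernel $K = GG'$ this is equivalent to an ordinary
multivariate logistic model in which each SNP coefficient independently
follows a distribution with mean zero and common variance $\psi$; the
SNP-set null hypothesis is $\psi = 0$. The score statistic for $\psi$ is

$$Q = (y - \hat\mu)' K (y - \hat\mu),$$

with $\hat\mu$ the fitted means of the *covariate-only* null model. $Q$
needs only one logistic fit per stratum, shared by every SNP set.

Under the null, $Q$ is distributed as $\sum_j \lambda_j \chi^2_{1,j}$ where
$\lambda_j$ are the non-zero eigenvalues of $P_0^{1/2} K P_0^{1/2}$,
$P_0 = V - VX(X'VX)^{-1}X'V$, $V = \mathrm{diag}\{\hat\mu_i(1-\hat\mu_i)\}$.
The package computes the spectrum on the $p \times p$ matrix $G'P_0G$,
which shares the non-zero eigenvalues and is much smaller than the
$n \times n$ form; eigenvalues below $10^{-10}\max_j \lambda_j$ are
discarded as numerical zeros. For a single-SNP set the statistic reduces
algebraically to the 1-df score test ($Q = (g'r)^2$, one weight
$\lambda = g'P_0 g$), and the test suite pins this equivalence to 1e-8.

### Tail probabilities

`quadform_pvalue()` evaluates $P(\sum_j \lambda_j \chi^2_1 > q)$ by
numerical inversion of the characteristic function (the Imhof integral
evaluated by adaptive quadrature, the same quantity the Davies algorithm
computes) to absolute accuracy 1e-6. Two special cases short-circuit the
inversion exactly: an empty (all-zero) spectrum returns p = 1, and equal
weights are a scaled chi-square evaluated in closed form. If the inversion
fails or leaves $[0,1]$, the Liu moment-matching chi-square approximation
is used instead and the result is labelled `method = "liu"`.

Moment matching is *not* uniformly accurate: on random spectra its error
against the exact inversion can reach a few times $10^{-2}$ in the central
p-value range. It is therefore a fallback and an explicit fast engine for
permutation loops (where only the comparability of observed and permuted
p-values matters, not their individual exactness), never a silent
substitute. The exactness of the default engine is validated against an
independently coded fixed-grid inversion with an analytic tail bound, to
1e-6 on one hundred random spectra.

### Null-model fitting

The covariate-only logistic model is fitted by iteratively reweighted least
squares with convergence tolerance 1e-10 and at most 100 iterations.
Non-convergence is an error, as is (quasi-)separation, detected as fitted
probabilities within 1e-8 of the boundary or coefficients beyond 15 on the
log-odds scale — a deliberately blunt rule that refuses to return the huge
unstable odds ratios separation produces. Within ethnicity-stratified runs,
covariates that are constant in a stratum (typically institution
indicators) are dropped; the ancestry component is retained because it
varies within strata.

## Quality control

A SNP is excluded when its call rate is below 0.90, or it deviates from
Hardy-Weinberg proportions at P < 0.01 in *both* ethnicity groups, or its
MAF is below 0.01 in *both* groups; samples with call rate below 0.90 are
excluded. Three conventions were open and are fixed as follows:

* **Thresholds are strict** (`<`, not `<=`): a sample at exactly 0.90 call
  rate is kept.
* **Order**: the sample filter runs first and SNP statistics are computed
  on retained samples, in one pass (no iteration).
* **Hardy-Weinberg test**: the 1-df chi-square against expected proportions
  at the observed allele frequency, not an exact test — the conventional
  screen for common variants; a monomorphic SNP scores 0 with p = 1 rather
  than dividing by zero.

The minor allele is defined on the full post-QC sample, not per ethnicity;
a frequency tie at 0.5 is broken lexicographically by allele symbol so that
re-reading written files is stable.

## Ancestry

Ancestry is estimated only from the panel's ancestry-informative markers,
never from the candidate SNPs. Genotypes are standardized per SNP
(mean-imputed, centred at $2\hat p$, scaled by $\sqrt{2\hat p(1-\hat p)}$ —
the binomial-sampling convention), monomorphic markers are dropped with a
record, and the principal component scores are the left singular vectors
scaled by their singular values. Each component's sign is fixed so its
largest-magnitude loading is positive; downstream association results are
invariant to this sign, which the suite checks. Only PC1 enters the
adjustment by default (it separates the two simulated populations with
correlation typically above 0.9 at Fst 0.15 with 39 markers), but any
number of components can be requested.

## Per-SNP models

Each SNP is tested in an unconditional multivariate logistic model under
two codings: codominant (heterozygote and rare-homozygote indicators
against the common-homozygote reference) and log-additive (0/1/2 trend,
whose exponentiated coefficient is the per-allele odds ratio). Intervals
and p-values are Wald (estimate ± 1.96 SE), matching the reporting style of
case-control candidate-gene tables. Missing genotypes are handled per SNP
as complete-case, so the effective n varies across SNPs.

A contrast is *undefined* — rendered as a dash, never as an enormous odds
ratio — when its status-by-genotype table has an empty cell: for the
heterozygote (rare-homozygote) contrast, any empty cell among status ×
{reference, heterozygote (rare homozygote)}; for the trend, after dropping
genotype levels absent from the whole stratum, fewer than two levels
remaining or any empty remaining cell. Zero-cell detection was chosen over
convergence heuristics because it is deterministic and explains itself.

## Multiplicity

Family-wise error is controlled per grouping level (pathway, sub-pathway,
gene, SNP) by the permutation distribution of the level's minimum p-value:
labels are permuted, every test at the level is recomputed, and the
adjusted p-value of a test observed at $p_0$ is
$(1 + \#\{b: \min_b P \le p_0\})/(B+1)$. Decisions taken:

* **Permutation scheme**: case/control labels are shuffled within
  ethnicity × institution strata by default, preserving the
  frequency-matched design; a simple unrestricted shuffle is available via
  `scheme = "simple"`. Neither is presented as the certified historical
  choice — the stratified scheme is this package's default because it
  respects the design that generated the data.
* **Estimator**: the add-one correction bounds adjusted p-values below by
  $1/(B+1)$ and avoids zeros; adjusted values are additionally clipped from
  below at the observed p-value, since the population min-P adjustment can
  never be smaller and any crossing is Monte-Carlo noise.
* **B = 1000** is the default; the demonstration scripts use B = 200 with
  the moment-matching engine inside the loop, which is the scale at which
  the calibration experiment below was run.
* Single-SNP genes are not tested at the gene level (there is no set to
  aggregate), so the gene family has 42 members on the packaged 46-gene
  annotation; min-P control is family-size agnostic.

Callback failures abort the procedure — a permutation whose recomputation
fails would silently bias the min-p distribution if skipped.

## Power

The detectable-odds-ratio calculator inverts, by bisection, the
normal-approximation power of the two-sided 1-df allelic test: control
allele frequency $p_0$, case frequency from odds multiplication,
$2n_{\text{cases}}$ and $2n_{\text{controls}}$ alleles, critical value from
the pooled-null standard error and power under the alternative standard
error. The significance level is configurable and defaults to the
Bonferroni level $0.05/320$ of a 320-SNP family: the study-scale
sample sizes then give detectable ORs of about 1.51 at MAF 0.5 and 2.21 at
MAF 0.05 (reciprocals 0.66 and 0.45 for protective effects), and this
Bonferroni level is the documented inference under which those bounds
reproduce — an unadjusted $\alpha = 0.05$ yields far smaller detectable
ORs. The protective bound is the reciprocal of the risk bound by
construction. Analytic power is cross-checked against binomial simulation
of the same test at five spot checks in the suite. No power is claimed for
the kernel set test itself, which has no closed form; its behaviour is
covered by the calibration simulations instead.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with defaults fixed at the study design: 494 cases / 536 controls;
two populations in a roughly 19/81 split; ages from a normal distribution
with mean 65.9 and SD 8.4 truncated to 40–90 (truncation avoids absurd
covariate values); three recruiting institutions; controls
frequency-matched to cases by ethnicity and 5-year age bin (largest
remainder allocation, borrowing from an adjacent bin — still within the
5-year matching width — when a bin runs short, and failing loudly when the
pool cannot support the match); per-SNP population frequencies from the
Balding-Nichols Beta model at Fst 0.15; within-gene linkage disequilibrium
from a latent AR(1) Gaussian copula (two haplotypes thresholded at the
frequency quantile and summed, so Hardy-Weinberg proportions hold by
construction) with latent correlation 0.5, consistent with a tag-SNP panel
pruned at $r^2 \ge 0.8$; tag-SNP ancestral frequencies uniform on
[0.05, 0.5]; 39 independent ancestry-informative markers with a mean
between-population frequency differential of 0.3; and disease assigned by a
logistic model whose intercept is calibrated by bisection to the target
case fraction before exact-count rejection sampling. Planted per-allele
effects enter this logistic model directly, so the conditional odds ratio
being estimated downstream is exactly the configured one.

What the generator does *not* emulate: realistic recombination maps or
haplotype-copying LD (the AR(1) copula gives smoothly decaying $r^2$, not
block structure), admixed individuals (each subject belongs to one
population; the ancestry axis is still continuous because allele counts are
random), genotyping-platform artefacts, or X-chromosome dosages. Passing
tests therefore show that the machinery is correct and calibrated under a
plausible two-population, LD-correlated, matched design — not that any
particular real-data finding is reproduced.

## Validation scale and numerical choices

The validation suite runs, among others: exactness of the quadratic-form
engine on 100 random spectra against an independent inversion (1e-6);
kernel-test agreement with a 10,000-permutation reference (n = 200, 5
SNPs); empirical type-I error over 2000 global-null simulations (n = 500,
10 LD-correlated SNPs) inside the 95% binomial band at $\alpha = 0.05$ with
a uniformity check; family-wise error of the gene-level min-P procedure
over 500 replicates of the full 42-gene family (n = 300, B = 200) inside
the 95% band; and recovery of a planted protective trend OR of 0.73 at MAF
0.3 in 500 matched 494/536 cohorts, requiring mean estimate within 5% and
interval coverage between 92% and 98%. These sizes are the package's
choices for a thorough desk-scale validation; the same machinery accepts
larger runs unchanged.

Numerical constants collected in one place: IRLS tolerance 1e-10 (max 100
iterations); separation guards 1e-8 / |coef| > 15; inversion accuracy 1e-6
with Liu fallback recorded; eigenvalue floor $10^{-10} \max \lambda$;
kernel genotypes mean-imputed per SNP; QC thresholds strict as printed;
allele-frequency tie at 0.5 broken lexicographically; detectable-OR
bisection tolerance 1e-9 with an upper search bound of OR 50.

## Known limitations

The linear kernel is the only kernel (no MAF weighting, IBS, or quadratic
kernels), matching the equivalence to unweighted multivariate logistic
regression that motivates it. Exact and Firth logistic regression are not
implemented; sparse strata yield dashes rather than penalized estimates.
The permutation procedure refits the null model per permutation, which is
honest but makes B = 1000 at the SNP level the most expensive step of the
workflow. The generator's Fst, LD, and AIM-differential defaults are stated
assumptions about the panel, not reconstructions of it.
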