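---
title: "Multivariate mixed-model F tests: model, estimation and simulation design"
author: "mvftest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate mixed-model F tests: model, estimation and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Genome-wide association scans in panels with related individuals are
usually run with a linear mixed model.  For a single trait,

$$ y = X\beta + u + e, \qquad
   u \sim \mathrm{MVN}(0, A\,\sigma_u^2), \qquad
   e \sim \mathrm{MVN}(0, I\,\sigma_e^2), $$

where $A$ is the genomic relationship matrix estimated from genome-wide
SNPs (VanRaden method 1 in this package) and $X$ contains an intercept and
the dosage of the SNP under test.  The phenotypic covariance is
$V = A\sigma_u^2 + I\sigma_e^2$, the fixed effects are estimated by
generalized least squares,
$\hat\beta = (X'V^{-1}X)^{-1}X'V^{-1}y$, and the tested effect is judged by
the Wald-type statistic

$$ F = \frac{(H'\hat\beta)'\,[H'(X'V^{-1}X)^{-1}H]^{-1}\,(H'\hat\beta)}
            {f\,\hat\sigma^2}, $$

with $H$ an indicator matrix selecting the $f$ tested effects.

With $d$ correlated variates (traits, years, environments) the responses
are stacked variate-major into a vector of length $nd$ and

$$ V_m = \Sigma_u^2 \otimes A + \Sigma_e^2 \otimes I, $$

with $d \times d$ genetic and residual covariance matrices.  The joint
test uses an $H$ with one column per variate, so all $d$ SNP effects are
tested simultaneously ($f = d$).  When phenotype records are missing, the
rows and columns of the missing records are deleted from the stacked
response, design and $V_m$; nothing is imputed.  Every individual must
keep at least one observed variate.  In the extreme case where each
individual carries exactly one variate (a meta-analysis-like layout), the
retained residual block of $V_m$ is block-diagonal per variate, and the
residual correlation parameter cancels from the model --- `build_Vm()`
reproduces this cancellation exactly, and the package's tests assert it.

Two decisions in the test itself deserve comment.

* **Denominator scale.**  When $V$ comes from REML estimates of the
  variance components, the residual quadratic form
  $(y - X\hat\beta)'V^{-1}(y - X\hat\beta)/(N - p)$ is 1 in expectation,
  and the denominator scale is fixed at 1.  `gls_fit()` still computes
  the quadratic form so it can be inspected, and `f_statistic()` accepts
  it through the `sigma2` argument (that route reproduces the classical
  OLS $t^2$ when $V = I$).
* **Degrees of freedom.**  The reference distribution is $F(f,\,N - p)$
  with $N$ the number of observed records and $p$ the number of fixed
  effects.  This ignores the loss of information from estimating the
  variance components; no Kenward--Roger-type adjustment is attempted.
  The package's negative-SNP QQ diagnostic (`negative_snp_qq()`) is the
  empirical check that this simplification does not inflate small
  p-values at these sample sizes.

## EM-REML with arbitrary missingness

`em_reml()` estimates $(\Sigma_u^2, \Sigma_e^2)$ by the classical EM
algorithm for restricted maximum likelihood, treating the stacked genetic
values and residuals (including those of unobserved records) as complete
data.  Each iteration computes, from
$P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$ on the observed records,
the conditional first and second moments of $u$ and $e$ and updates

$$ \Sigma_u^{2\,(t+1)}[j,k] = \tfrac1n\!\left(\hat u_j' A^{-1} \hat u_k
   + \mathrm{tr}(A^{-1}C_u^{jk})\right), \qquad
   \Sigma_e^{2\,(t+1)}[j,k] = \tfrac1n\!\left(\hat e_j'\hat e_k
   + \mathrm{tr}(C_e^{jk})\right). $$

Implementation notes, in the order they matter numerically:

* **Eigen-decoupling for complete tables.**  With no missing cells the
  model is rotated by the eigenvectors of $A$, which decouples the
  $nd$-dimensional system into $n$ blocks of size $d$; every quantity the
  update needs (quadratic forms in $A^{-1}$, block traces of $P$) is
  rotation-invariant, so the iterate sequence is identical to the direct
  computation at a small fraction of the cost.  Incomplete tables use the
  direct observed-record covariance, assembled blockwise from per-variate
  observed index sets.
* **Bending of $A$.**  The VanRaden matrix is singular (centering makes
  the all-ones vector a null direction), but the EM update needs
  $A^{-1}$.  Eigenvalues are floored at $10^{-6}$ of the largest before
  inversion; both code paths use the same bent matrix.
* **Acceleration.**  Plain EM converges linearly and can need thousands
  of iterations near $h^2 = 0.5$.  The fitter therefore takes two EM
  steps, extrapolates along the observed trajectory with the SQUAREM
  steplength $\alpha = -\lVert r\rVert/\lVert v\rVert$, and accepts the
  extrapolated point only if it is positive semidefinite and does not
  lower the restricted likelihood; otherwise it falls back to the plain
  EM step.  The recorded likelihood path is therefore non-decreasing, as
  for plain EM, and the tests assert this on every fit they run.
* **Convergence.**  Iteration stops when the largest absolute change in
  any component, relative to the largest current component, falls below
  `tol` (default $10^{-6}$).  A relative criterion keeps the fit --- and
  hence the F statistics --- equivariant under rescaling of the
  phenotypes, which an absolute criterion would break.
* **Non-PSD updates.**  An update with a negative eigenvalue is projected
  back by clipping at $10^{-8}$ and reconstructing; three consecutive
  projections abort the fit with `converged = FALSE`.  Callers treat a
  non-converged null model as fatal (`gwa_scan()`) or drop and count the
  replicate (`run_grid()`).
* **Identifiability.**  With $A = I$ the restricted likelihood is flat
  along $\sigma_u^2 + \sigma_e^2 = \mathrm{const}$ and EM stays wherever
  it starts on that ridge; a genomic relationship matrix with spread
  eigenvalues is what makes the partition estimable.  This is why the
  null-heritability checks in the test suite use a simulated-genotype GRM
  rather than the identity.
* **Starting values.**  Both components start at half the per-variate
  sample variance (diagonal), the conventional equal split.

## One null fit per scan

`gwa_scan()` fits the variance components once, under the null model with
only per-variate intercepts, and reuses them for every SNP ("population
parameters previously determined").  Each SNP then costs one GLS solve
against a pre-factorized $V_m$.  A per-SNP exact-REML mode
(`scan_config(exact_reml = TRUE)`) is available for small scans; the test
suite checks that the two modes broadly agree on null data.  SNPs whose
dosage is constant on the analysed samples are reported with `F = NA`.
p-values below the smallest positive double are floored there and
flagged.

## What the simulation engine emulates

The generator reproduces the study conditions the power analysis needs:

* **Panel**: 200 fully inbred (selfing) individuals --- dosages only 0
  or 2 --- on 5 chromosomes with 2,000 SNPs each; MAF pruning at 0.02.
* **Linkage disequilibrium**: each chromosome has a pool of 64 founder
  haplotypes; per-site ancestral frequencies are Beta(0.4, 0.4) (U-shaped,
  so rare variants exist and pruning is active), and each founder's
  alleles come from thresholding a latent stationary AR(1) Gaussian
  ($\varphi = 0.95$ between adjacent markers) at the frequency quantile.
  Individuals are recombinant mosaics of founder segments (segment ends
  with probability 0.01 per interval), doubled to homozygosity.  Adjacent
  markers reach $r^2 \approx 0.2$, decaying to $\approx 0.01$ by 60
  markers; chromosomes are independent.  An earlier prototype that built
  the pool by sequential copy-with-mutation was discarded because
  independent per-site mutations cap adjacent $r^2$ near 0.05 regardless
  of parameters.
* **Architecture**: 4 QTLs per chromosome (20 in total), one flagged as
  the *target* whose detection is scored.  The target effect on variate 1
  is $N(0,1)$; variate $j$ receives $a_j$ times that draw with the $a_j$
  evenly spaced from 1 to $a_d$ (so $d = 4$, $a_4 = 0.4$ gives 1, 0.8,
  0.6, 0.4).  Background effects are i.i.d. $\mathrm{MVN}(0, \Sigma)$
  with compound-symmetry correlation $r$.
* **Heritability 0.5**: residuals are $\mathrm{MVN}(0, S\Sigma S)$ with
  $S$ the diagonal of *realized* standard deviations of the genetic
  values, so each variate's genetic and residual variances match within
  each replicate.  Realized SDs (not expected ones) are used because the
  heritability is meant to be 0.5 per data set, not merely on average.
* **Missingness**: exactly $\mathrm{round}(m_{prop}\,n\,d)$ cells are
  masked.  Each individual first gets one uniformly chosen protected
  variate; the masked cells are a uniform draw from the unprotected
  ones.  (Naive rejection sampling of uniform cell subsets was rejected:
  at the maximal proportion its acceptance probability is of order
  $d^{-n}$.)  At $m_{prop} = (d-1)/d$ every individual keeps exactly its
  protected variate.
* **GRM**: built from all non-QTL SNPs, so the tested locus and its
  19 background companions do not leak into the relationship matrix.

What it does **not** emulate: coalescent genealogies (no megabase-scale
haplotype structure, no demographic history), residual heterozygosity,
genotyping error or missing genotypes, population stratification beyond
what founder sharing induces, and distinct genetic versus residual
correlations --- both use the same $\Sigma$, as the power comparison
concerns the phenotypic covariance, not the decomposition.  Power results
on these synthetic panels therefore demonstrate *relative* behaviour of
the tests (sign and ordering of the multivariate-minus-univariate
difference), not absolute detection rates for any real crop.

## The analytic power factor

Under $d = 2$, per-pair covariance $\begin{pmatrix}1&r\\r&1\end{pmatrix}$,
$A = I$ and a second effect equal to $a_2$ times the first, the numerator
of the joint F statistic factorizes as
$\hat\beta_1^2\,(x'x)\,f(a_2, r)$ with

$$ f(a_2, r) = \frac{a_2^2 - 2a_2r + 1}{1 - r^2}. $$

`f_a2_r()` implements it; the fixture tests verify the factorization
against the actual GLS machinery to $10^{-8}$.  The factor is 1 exactly
at $a_2 = r$ (its minimum in $a_2$), symmetric under
$(a_2, r) \to (-a_2, -r)$, and diverges as $|r| \to 1$ with $a_2 \neq r$:
the joint test gains most when the effect ratio and the phenotypic
correlation disagree.  `ad_fraction()` quantifies how often that happens
for effect pairs drawn from a correlated prior: even at $r = 0.95$ about
10% of pairs have opposite signs (closed form
$\tfrac12 - \arcsin(r)/\pi = 0.1011$) and about 80% fall below
$a_d = 0.9$.  The signed ratio of a pair is defined as smaller magnitude
over larger magnitude, carrying the sign of the product, with magnitude
ties mapped to $\pm 1$ --- the only definition on $[-1, 1]$ consistent
with "relative size of the smaller effect".

## Replicate grids and reproducibility

`run_grid()` simulates one genotype panel, one QTL placement and one GRM
per replicate and shares them across all scenarios of that replicate
(effect draws, residuals and masks get scenario-specific seeds), then
records the difference in $-\log_{10}p$ at the target QTL between the
joint test and the univariate test on variate 1 --- the variate with the
largest simulated effect, so the comparison is against the strongest
univariate competitor.  Replicates whose REML fit does not converge are
dropped from the mean and reported in `n_fail`; denominators are never
silently changed.  All seeds derive from one master seed through
`derive_seed()`, a deterministic multiplicative counter, so any replicate
or stage can be reproduced in isolation.  Default replicate count is 20
per condition: enough for the sign structure of the mean difference,
which is what the package's checks assert; surfaces from 100+ replicates
are smoother but change no conclusion of the sign-level checks.

The test suite exercises the grid at two scales chosen to keep a full run
in minutes: the headline 3x3 sign-pattern check runs the full panel
(n = 200, 10,000 SNPs, 20 replicates per cell), while structural checks
(reproducibility, maximal-missingness behaviour) use a reduced panel
(n = 80, 2 x 250 SNPs, 2 QTLs per chromosome).

## Known limitations

* Estimation cost grows as $(nd_{obs})^3$ per EM step for incomplete
  tables; the package targets panel-sized problems (hundreds of
  individuals, $d \le 8$), not biobank scales, and implements none of the
  eigen-transformation speedups that require complete (or imputed) data.
* High $d$ with heavy missingness is genuinely hard for variance
  component estimation; non-convergence is reported, counted, and never
  papered over.
* The denominator df is the naive $N - p$; exact small-sample p-values
  would need moment adjustment or resampling, neither of which is
  implemented.
* Univariate and multivariate tests share the dosage coding (minor-allele
  count, fixed at load time).  Any consistent coding gives the same F ---
  a flip only changes the sign of $\hat\beta$ --- and the tests assert
  this invariance.
* For $d > 2$ the package reports the same machinery with $f = d$; the
  analytic factor is derived for $d = 2$ only, and behaviour at higher
  $d$ is interpreted through the $d = 2$ surface.
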