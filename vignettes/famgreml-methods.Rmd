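---
title: "GREML variance decomposition for family-level environments: models and methods"
author: "famgreml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GREML variance decomposition for family-level environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famgreml)
```

## The question and the model

Family socioeconomic status (SES) is the textbook example of an
environmental measure: it varies *between* families and is identical for
children growing up in the same household.  Yet parents' education and
occupation are themselves partly heritable outcomes, so children's genotypes
— inherited from those same parents — can carry information about the family
environment they are raised in.  This package implements the DNA-based
analysis that quantifies this: GREML variance decomposition of a
family-level environmental measure and of children's IQ, on a sample of
conventionally *unrelated* children, followed by a bivariate decomposition
of the SES–IQ covariance.

The univariate model for a standardized phenotype $y$ on $n$ unrelated
individuals is the random-effect mixed model
$$ y = X\beta + g + e,\qquad g \sim N(0,\, \sigma^2_g A),\qquad
   e \sim N(0,\, \sigma^2_e I), $$
where $A$ is the genetic relatedness matrix (GRM) built from genotyped SNPs,
$$ A_{ij} = \frac{1}{m_{ij}} \sum_k
   \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}{2p_k(1-p_k)}, $$
with $p_k$ the sample allele frequency and $m_{ij}$ the SNPs non-missing in
both individuals.  The SNP heritability is $V(G)/V_p =
\sigma^2_g/(\sigma^2_g+\sigma^2_e)$: the fraction of phenotypic variance
tagged by common genotyped SNPs — a lower bound on twin-design heritability,
since rare variants and non-additive effects are invisible to it.  Because
all pairs are distantly related, the signal comes from correlating tiny
fluctuations of chance genomic similarity with phenotypic similarity across
thousands of pairs; samples of thousands are needed.

The bivariate extension stacks two traits measured on overlapping but
possibly unequal samples and decomposes their covariance into a genetic
covariance $C(G)_{12}$ (carried by the GRM, estimable from *all* pairs
across the two samples) and a residual covariance $C(e)_{12}$ (identified
only from individuals measured on both traits).  Derived statistics:

* genetic correlation $r_G = C(G)_{12}/\sqrt{V(G)_1 V(G)_2}$, reported
  clipped into $[0,1]$ with an audit flag (the reporting convention for this
  statistic; the SE stays unclipped),
* residual correlation $r_E = C(e)_{12}/\sqrt{V(e)_1 V(e)_2}$ with its
  delta-method SE written out in the residual components,
* the genetically mediated share of the phenotypic correlation,
  $100\cdot C(G)_{12}/r_p$ on standardized traits.

A key design point inherited from the study this emulates: the *children's*
genotypes are used, so the genetic influence on family SES is estimated as
it bears on the children — children cannot cause family SES; their genotypes
only reflect the parental genotypic factors behind it.

## Estimation: AI-REML

`fit_univariate()` maximizes the restricted likelihood
$$ \ell = -\tfrac12\left(\log|V| + \log|X^\top V^{-1}X| + y^\top P y\right),
 \qquad V = \sigma^2_g A + \sigma^2_e I, $$
(the additive constant $-(n-p)/2\log 2\pi$ is omitted, as GREML reports
conventionally do; differences and ratio tests are unaffected).  The GRM is
eigendecomposed once, making each iteration linear-time in $n$ after an
$O(n^3)$ setup; the dense evaluation `reml_loglik()` is kept public so a
grid oracle can audit the optimizer.  Updates are average-information (AI)
steps with an EM first step, step-halving whenever a step would decrease the
likelihood (accepted iterations are therefore monotone, and the trace is
stored on the fit), and variance components floored at $10^{-6}V_p$ when
constrained (the default).  Convergence: log-likelihood change below 1e-6 or
component change below 1e-8.  Standard errors come from the inverse AI
matrix at the optimum; the heritability SE by the delta method.  A
near-singular AI matrix (e.g. $A = I$, where $\sigma^2_g$ and $\sigma^2_e$
are indistinguishable) is flagged as unidentifiable rather than returning
arbitrary components.

`fit_bivariate()` works on the stacked covariance with six components
$(\sigma^2_{g1}, \sigma^2_{g2}, c_g, \sigma^2_{e1}, \sigma^2_{e2}, c_e)$,
dense Cholesky per iteration, Levenberg-damped AI updates, and the same
constraint policy.  Two numerical choices matter here:

* the 2x2 genetic and residual covariance matrices are kept inside the
  positive-definite cone by an *additive* margin
  ($10^{-5}\sqrt{V_{p1}V_{p2}}$).  A multiplicative margin (e.g.
  $|c_e| \le 0.999\sqrt{v_{e1}v_{e2}}$) makes the likelihood of a degenerate
  pair — trait 2 a copy of trait 1 — unbounded toward all-zero components,
  because shrinking every component also shrinks the capped difference
  variance.  With a fixed margin the difference variance is pinned and the
  informative part of the likelihood determines the components;
* when a covariance sits on its cap (or the projected line search stalls),
  the optimum lies *along* the moving constraint surface, which a projected
  Newton step cannot track.  The fit then switches to a derivative-free
  polish in a smooth parameterization (log variances, tanh-scaled
  covariances), restarted until stable.  In interior fits this path never
  triggers.  With a duplicated trait the bivariate fit reproduces the
  univariate components to about 1e-5, which the test suite asserts.

With zero overlap between the two samples $c_e$ is not identified and is
fixed at zero (flagged); overlaps below `min_overlap` (default 30) are
refused rather than silently producing a noise estimate.

### The boundary likelihood-ratio test

The null model (no genetic component) pins $\sigma^2_g$ to the boundary of
its parameter space, so $2(\log L - \log L_0)$ is asymptotically the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; `lrt()` reports half the
$\chi^2_1$ tail, equal to 0.5 at LRT = 0.  The acceptance suite verifies the
empirical size: under a zero-heritability null the test rejects at nominal
5% within the binomial band over 500 simulated replicates.

## Ancestry control: PCA and the Tracy-Widom test

Population stratification masquerades as genetic similarity, so the leading
principal components of standardized dosages are entered as fixed
covariates.  How many?  Each leading eigenvalue is tested against the
Tracy-Widom ($\beta = 1$) law, sequentially from the top, stopping at the
first non-significant axis (`tracy_widom_select()`, default
$\alpha = 0.05$).

Two implementation notes.  First, the TW distribution has no closed form; a
grid of right-tail probabilities was computed once from the
Fredholm-determinant representation $F_1(s) = \det(I-K)$ with kernel
$\mathrm{Ai}((x+y)/2)/2$ and frozen as package source, matching the standard
critical values (0.9793 at $p=.05$, 2.0234 at $p=.01$, 3.2724 at $p=.001$);
p-values interpolate log-linearly on that grid.  Second, the
effective-dimension correction: with $p$ remaining eigenvalues and
$S_1, S_2$ their sum and sum of squares, the effective number of markers is
the white-Wishart moment estimator $\hat n = R(p+1)/(p-R)$, $R = S_1^2/S_2$
(from $E\,\mathrm{tr}\,W = np$ and $E\,\mathrm{tr}\,W^2 = np(n+p+1)$), the
top eigenvalue is rescaled to the Wishart scale and standardized by the
Johnstone centering and scaling.  A frequently quoted variant of the
effective-$n$ formula, $n' = (p+1)S_1^2/((p-1)S_2 - S_1^2)$, differs in the
denominator by one unit of $S_2$; on column-centered data this inflates
$\hat n$ and shifted the whole statistic by roughly $+1.3$ in our null
simulations (21–24% rejections at nominal 5%).  The moment-derived form
tests at 2–3% on Gaussian and binomial-genotype nulls — slightly
conservative, which is the safe side for covariate selection.  The number of
axes is a cohort property, not a constant: the pipeline exposes a fixed
override (`n_pcs_fixed`) for reproducing a cohort-specific convention such
as eight axes.

LD pruning before PCA (`ld_prune()`, default $r^2 > 0.2$ within a sliding
window) removes the redundancy that would otherwise let a handful of
high-LD regions dominate axes.

## Phenotype preparation

The preparation pipeline is fixed and logged: for each cognitive test,
outliers beyond 3 SD of the raw score are excluded (flagged, never silently
dropped), scores are regressed on age and sex, and residuals are mapped to
normal quantiles by rank with the Blom offset $(r - 3/8)/(n + 1/4)$, ties
sharing average ranks.  The IQ composite is the unit-weighted mean of the
standardized tests, requiring at least 3 of the 4; the SES composite is the
first unrotated principal component of the standardized indicators, its sign
fixed to correlate positively with the first indicator, with the explained
variance fraction reported.  Two open choices were resolved as follows and
are asserted in configuration rather than inferred: outlier exclusion
precedes the regression (exclusion on raw scores is the interpretable
reading of "outliers ... were excluded" before "scores were regressed"), and
the Blom offset is used for the inverse-normal transform (the common default
in this literature; the transform is rank-based either way, so downstream
fits are insensitive to the offset choice).

## The synthetic cohort

No cohort data ship with the package (the motivating study's cohort is
access-restricted), so `simulate_genotypes()` / `simulate_phenotypes()`
generate a family-structured stand-in with known truth:

* unrelated nuclear families (two parents, one child); parents in
  Hardy-Weinberg proportions within their subpopulation; children by
  Mendelian transmission with stored transmitted-allele indicators, so
  Mendelian consistency is directly checkable;
* optional stratification by Balding-Nichols Beta draws of subpopulation
  allele frequencies around the ancestral frequency (`fst`), planting a
  leading eigenvalue for the Tracy-Widom test to find;
* effect sizes standard-normal at causal SNPs on dosages standardized by
  $\sqrt{2p(1-p)}$ — the same weighting as the GRM, so in child-genic mode
  the generating $h^2$ *is* the GREML estimand;
* a shared causal set with bivariate-normal effects at correlation
  `rho_eff`, giving a closed-form true genetic correlation
  $\approx$ `rho_eff` when the causal sets coincide;
* SES as a family-level trait in two modes bracketing the unknown generative
  relation: child-genic (the child's own additive score) and
  midparent-genic (the mean of the parents' scores).  In midparent mode the
  child GRM captures only part of the causal genotype — the child-midparent
  additive correlation is $1/\sqrt2$ — so the child-GRM estimate is
  attenuated below the generating parental $h^2$, the direction the study
  itself predicts for parental genotypes versus child genotypes;
* phenotypes scaled empirically: genetic values to variance $h^2$,
  residuals to $1-h^2$, then the sum standardized, so $V_p \approx 1$ as in
  the reported tables and small-sample tests are stable;
* observable layers for the preparation stage: five SES indicators and four
  IQ test scores loading 0.8 on their latents, the tests carrying small age
  and sex effects for the regression to remove.

Default parameters emulate the study conditions: 2000 families, 4000 SNPs,
MAF in [0.05, 0.5], $h^2_{SES} = 0.2$ and $h^2_{IQ} = 0.3$ (the reported
univariate estimates), `rho_eff = 1` (the reported age-7 genetic
correlation), one child per family, no twins.

What the generator deliberately does **not** emulate: linkage
disequilibrium beyond stratification, X-chromosome inheritance,
genotyping error, assortative mating, and direct environmental transmission
from parental phenotype to child phenotype.  Passing tests therefore show
that the estimators recover truth under the model's own assumptions — they
do not validate the identifying assumptions against real cohorts, where
passive gene-environment correlation and population structure are entangled
in ways no simulation settles.

One scale caveat: the genome-wide relatedness cutoff of 0.025 presumes
genome-wide SNP counts.  Chance GRM off-diagonals have sd
$\approx 1/\sqrt{m}$, so on a 400-SNP toy panel the cutoff would prune
almost everyone; small-panel examples and tests widen the threshold
accordingly, while the default stays at the genome-scale convention.

## Problem sizes used by the test suite

Module tests run at a few hundred families and SNPs.  The simulation-based
acceptance checks use the sizes the recovery properties were designed at:
univariate recovery of $h^2 = 0.3$ and $0.5$ and bivariate recovery of
$r_G = 0.6$ at $n = 2000$ children and $m = 4000$ SNPs (within two reported
SEs); an exhaustive two-stage 200x200 likelihood grid on an $n = 40$ toy
(agreement to 1e-4); LRT size under the null at $n = 500$ over 500
replicates; and the midparent-attenuation sign test over 20 replicates at
$n = 400$.

## Worked example

```{r example, eval = FALSE}
library(famgreml)
cfg <- pipeline_config(
  input_mode = "simulate",
  sim = list(n_families = 800, n_snps = 2000, h2_ses = 0.5, h2_iq = 0.5,
             rho_eff = 1, n_causal_ses = 500, n_causal_iq = 500),
  relatedness = 0.15,   # scaled to the 2000-SNP panel, see above
  seed = 9)
report <- run_pipeline(cfg)
print(report)
```

On this simulated cohort the run prints SES $h^2 = 0.437$ (SE 0.080) and IQ
$h^2 = 0.346$ (SE 0.081), $r_G = 0.76$, $r_E = 0.17$, $r_p = 0.40$, 76%
genetically mediated.  The attenuation relative to the generating latent
values ($h^2 = 0.5$, $r_G = 1$) is the composite measurement noise: the
indicators load 0.8 on their latents, so the composites carry extra
unshared residual variance — exactly the behavior expected of composite
phenotypes in real cohorts.

## Known limitations

* Single-GRM models only; no multi-component partitioning, no
  gene-environment interaction terms, no BLUP prediction.
* Two traits at most; the two SES ages are fitted separately, not jointly.
* The bivariate fit is dense ($O((n_1+n_2)^3)$ per iteration); samples of a
  few thousand per trait are comfortable, tens of thousands are not.
* The residual-correlation SE formula is singular at $C(e) = 0$; the
  general delta-method SE is substituted there with a note on the result.
* GREML estimates are lower bounds tied to the SNP panel; nothing here
  corrects for rare variants, non-additivity, or imperfect tagging.
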