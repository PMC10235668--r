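---
title: "Methods: familial co-aggregation and liability-threshold modelling in famliab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: familial co-aggregation and liability-threshold modelling in famliab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famliab)
```

## The scientific problem

Asthma and autism spectrum disorder (ASD) co-occur more often than chance
would predict, and the interesting question is *why*: shared genes, shared
family environment, or within-person environmental factors. Three designs
triangulate on that question:

1. **Familial co-aggregation.** If relatives of people with asthma have
   elevated odds of ASD, and the elevation grows with genetic relatedness
   (monozygotic twins > full siblings > half-siblings > cousins), shared
   genetic liability is implicated.
2. **Quantitative genetic (twin/sibling) models.** Tetrachoric and biserial
   correlations between relatives feed maximum-likelihood variance-component
   models that decompose each trait's latent liability — and the
   *correlation between* the two liabilities — into additive genetic (A),
   dominant genetic (D), shared-environment (C) and unique-environment (E)
   parts.
3. **LD score regression (LDSC).** GWAS summary statistics give a
   molecular estimate of SNP heritability and of the genetic correlation
   between the traits, independent of family data.

Real register and twin-cohort data are confidential, so famliab pairs each
estimator with a synthetic family-registry generator whose architecture is
fully known. Every stage can therefore be validated by parameter recovery:
simulate under known (A, C, D, E, r_A, ...), estimate, compare.

## The liability-threshold model

Each binary trait is assumed to reflect a latent standard-normal liability
L; the trait is present when L exceeds a threshold τ chosen so that
P(L > τ) equals the trait's prevalence. For two traits per person and two
relatives per pair, the joint liability vector is multivariate normal with
unit variances and

Cov(L_t(i), L_u(j)) = k_A r_A √(A_t A_u) + k_D r_D √(D_t D_u)
                      + k_C r_C √(C_t C_u) + 1{i=j} r_E √(E_t E_u),

where r_X(t, t) = 1 and the sharing coefficients k depend on the pair kind:

| kind | k_A | k_D | k_C |
|---|---|---|---|
| MZ twin | 1 | 1 | 1 |
| DZ twin / full sibling | 0.5 | 0.25 | 1 |
| maternal half-sibling | 0.25 | 0 | 1 |
| paternal half-sibling | 0.25 | 0 | 0 |
| full cousin | 0.125 | 0 | 0 |

The first four rows are the classical assumptions of register twin/sibling
designs (maternal half-siblings are reared with the shared mother, hence
k_C = 1; paternal half-siblings are not, hence k_C = 0). Cousins do not
appear in the model-fitting stage at all — they contribute only to the
co-aggregation gradient — and their coefficients follow standard kinship
theory (k_A = 1/8, reared in different households so k_C = 0). Both the
cousin k_A and the maternal-half k_C are exposed as configuration
overrides for sensitivity work.

Variance fractions satisfy A + C + D + E = 1 per trait with E > 0, so all
liabilities have unit variance and thresholds are interpretable as normal
quantiles. A joint ACDE model is not identified from twin/sibling data and
`fit_model()` refuses it; ACE and ADE are fitted separately and compared.

## The synthetic registry

`build_pedigrees()` generates nuclear families (configurable sibship
size), maternal and paternal half-sibling families, cousin clusters (two
married siblings linked through shared grandparents, one child each), and
twin families with a configurable MZ:DZ ratio. Children receive sex
(Bernoulli 1/2, MZ pairs forced identical), birth year (uniform over
1992–2007), parity (birth order within mother) and parental ages at birth.
Default prevalences are sex-specific and typical of register-based
childhood cohorts (asthma 13% female / 17% male; ASD 1.1% / 2.6%).

`draw_liabilities()` simulates family blocks: families sharing a
covariance template are drawn in one vectorized Cholesky block, so a
quarter-million-individual registry takes seconds. Non-positive-definite
family covariances (possible only at degenerate settings such as
|r_E| = 1 in MZ pairs) abort with an error naming the family structure —
nothing is silently repaired.

Two deliberately simple knobs support methodological experiments:

- **Confounding** (`confounding = c(birth_year = b, parental_age = p)`):
  standardized covariate scores enter *both* liabilities with the given
  path coefficients and the architecture part is rescaled by
  √(1 − b² − p²), keeping unit total variance. Default off, so covariates
  are independent of liabilities and crude = adjusted in expectation.
- **Exclusion** (`exclusion_prob`): an independent Bernoulli flag
  emulating emigration/death before age 6; flagged children are dropped by
  the association stage, not the generator.

What the generator does *not* emulate — and hence what passing tests do
not establish about real register data: diagnosis-code/medication-based
phenotype ascertainment and its errors, age-at-onset and right-censoring
structure, assortative mating, gene–environment interaction or
correlation, sibling-order effects, and secular trends in diagnostic
practice. The continuous twin trait is a clean affine transform of the ASD
liability (optionally rounded to a 0–17 item grid); a real 17-item
parent-report score is skewed and coarse.

## Co-aggregation odds ratios

`coaggregation_or()` regresses the relative's ASD on the index person's
asthma by logistic regression over *double-entered* pairs (each member
once per role), with cluster-robust (information-sandwich) standard errors
on extended-family clusters absorbing both the double entry and multiple
pairs per family. Double entry makes the estimate symmetric in pair
ordering; the register design's index-person/relative asymmetry
(birth-cohort membership) has no analogue in simulated data, which is a
documented simplification. Adjustment ladder:

1. crude;
2. \+ birth year, sex, parity of both members;
3. \+ asthma of the outcome person;
4. \+ maternal and paternal ages at birth of both members.

Numerical choices: Wald confidence intervals on the log-odds scale
(exponentiated), no profile likelihood; separation fails loudly rather
than being penalized (at register sample sizes penalization would change
the estimand); adjustment covariates that are constant or aliased in a
stratum (e.g. the relative's parity when every sibship has size two, so
parity_index + parity_relative is constant) are dropped before fitting,
while genuine rank deficiency in `fit_logistic()` itself remains an error
naming the offending columns. Parity enters as an integer covariate. The
plain sandwich (no small-sample cluster adjustment) is used, so with
singleton clusters it reduces exactly to the HC0 form.

## Familial correlations

The 2×2 table of two thresholded normals is just identified by
(ρ, τ1, τ2): the ML thresholds are the inverse-normal margins and ρ solves
the orthant equation P(L1 > τ1, L2 > τ2) = p11, found by monotone root
bracketing. Standard errors come from the observed information of the
three-parameter multinomial likelihood. Tables maximized at |ρ| = 1 (an
empty discordant diagonal) return ±1 with an explicit boundary flag.

The biserial estimator maximizes the exact factorized likelihood — normal
density of the observed score times the probit conditional of the binary
trait — over (μ, σ, τ, ρ), with ρ estimated on the atanh scale and a
moment (two-step) estimator as the starting value.

`pair_correlation_set()` assembles the correlation taxonomy per pair kind:
phenotypic (within-person cross-trait), intraclass per trait, and the
cross-relative cross-trait (CRCT) correlation, pooled over both pair
orientations. Pooling symmetrizes double-entered tables; their SEs treat
entries as independent and are therefore slightly optimistic — a
documented trade-off, since the correlation summary is descriptive and
all inference happens in the likelihood stage. Correlations are
unadjusted for covariates.

## Liability-model likelihoods and fitting

**Binary–binary pairs.** A pair's joint covariance has the exchangeable
form [[W, Γ], [Γ, W]] (W = within-person 2×2 block, Γ = cross-person
block). Conditional on the shared familial factor s ~ N(0, Γ) the two
members are independent with residual covariance W − Γ, so each of the 16
response-pattern probabilities is a two-dimensional Gauss–Hermite integral
of products of bivariate-normal quadrant probabilities. The node count
adapts to the largest eigenvalue of Γ (24 / 48 / 96 nodes below 0.45 /
0.65 / above), keeping absolute error under 1e-6 even for MZ-like sharing
(validated against adaptive Genz–Bretz integration). Two properties of
this scheme matter in practice: it is roughly an order of magnitude faster
than generic 4-d rectangle quadrature, and — because the nodes are fixed —
it is *smooth* in the parameters, so finite-difference gradients are clean.
(Generic deterministic 4-d quadrature at practical step counts carries
~1e-5-scale error that varies non-smoothly with the correlation matrix;
at a log-likelihood scale of 5×10⁴ this corrupts numerical gradients
enough to stall quasi-Newton optimizers.) The bivariate normal CDF itself
is evaluated by 48-point Gauss–Legendre quadrature on the arcsine-
transformed single-integral representation, accurate to ~1e-10 across the
correlation range.

**Mixed twin pairs.** The continuous ASD score is mean + sd × liability;
the pair likelihood is the bivariate normal density of the two scores
times the conditional bivariate quadrant probability of the two binary
asthma responses given the scores, vectorized over pairs.

**Parameterization and optimization.** Variance fractions use a softmax
anchored at E (logits log(A/E), log(X/E)), enforcing the unit-sum
constraint and E > 0; cross-trait correlations use atanh; the score SD
uses log. Thresholds are free per trait and shared across sexes (a
deliberate default — see below). Sibling fits use one randomly selected
pair per family (seeded) so multi-sibling families are not over-weighted,
and pool full, maternal-half and paternal-half kinds; at least two kinds
are required to separate A from C or D. Binary designs aggregate response
patterns first, which makes the fit cost independent of the number of
pairs. Bivariate fits are warm-started from the two univariate fits
(which pin fractions, thresholds and moments well), then multi-started
(default 5: neutral start plus seeded jitters), screened by Nelder–Mead
and polished by repeated BFGS until the objective stops improving. Wald
covariance comes from the inverted observed information on the estimation
scale, delta-methoded to the reporting scale; a non-positive-definite
Hessian yields a fit flagged `se_available = FALSE` instead of fabricated
intervals. Converged fits reach numerical gradient norms of order 1e-2 to
1e-3 on a log-likelihood of order 5×10⁴ — the practical floor for
quadrature-based objectives — and the gradient norm is stored as a
diagnostic.

**Sex-shared thresholds and misspecification.** The fitted likelihood
uses one threshold per trait. When data are generated with sex-specific
prevalences (the registry default), the model dichotomizes a 50:50 mixture
of thresholds; for a trait whose male prevalence is ~2.4× the female
prevalence (ASD) this mixture visibly distorts the variance decomposition.
Parameter-recovery validation therefore uses sex-shared prevalences chosen
inside those same ranges (asthma 15%, ASD 1.85%), so the estimator is
assessed under a correctly specified model; the sex-specific default
remains in place for the co-aggregation and correlation stages, which
condition on margins rather than model them.

**Model selection.** Likelihood-ratio tests for the nested drops
(ACE→AE, ADE→AE) and AIC across families, ties broken toward fewer
parameters. Because the dropped fraction sits on the boundary (C, D ≥ 0),
the naive χ² p-value is conservative: under the null the statistic is a
50:50 mixture of a point mass at zero and χ²(1). We report the naive
p-value with a boundary annotation by default — transparency over
correction — and offer the mixture correction as an option. Calibration is
checked conditionally: among replicates with a strictly positive
statistic, naive χ²(1) p-values are uniform.

**Statistical resolution.** Binary-trait variance components are
information-poor when a trait is rare: for ASD-like prevalence the
asymptotic SE of Â is ≈0.2 at 50,000 sibling pairs under a bivariate ACE
model (and ≈0.06 under AE). Recovery targets in the test suite are set
accordingly: AE-design recovery of (A = 0.59/0.75, r_A = 0.20) at 50,000
pairs, twin ADE broad-sense recovery at 4,000–8,000 pairs, and LRT
calibration on 200 replicates of 3,000 twin pairs — desk-scale versions of
register-scale analyses.

## LD score regression

`simulate_sumstats()` draws per-SNP Z-score pairs from the polygenic
expectation: Var(Z_t) = 1 + N_t h²_t l_j / M, cross-trait covariance
r_g √(h²_1 h²_2) √(N_1 N_2) l_j / M plus a sample-overlap cross-intercept
(overlap fraction × phenotypic correlation). LD scores come from a
block-diagonal LD model — blocks of `block_size` SNPs with a per-block
squared correlation drawn from a configurable range, so
l = 1 + (block_size − 1) r² — rather than a real reference panel; a reader
for externally supplied LD-score tables is provided, and no MAF/INFO
filtering or allele harmonization is attempted.

`ldsc_h2()` regresses χ² on N l/M with the standard
1 / (l (1 + N h² l / M)²) weights, h² taken from an unweighted first pass
and iterated once; the intercept is free or fixed (the classic robustness
sweep constrains it over 1.0 down to 0.7, and on fixed data the fitted
slope is monotone nonincreasing in the fixed intercept). `ldsc_rg()`
regresses Z₁Z₂ on √(N₁N₂) l/M and normalizes by the two heritabilities.
Standard errors use a delete-a-block jackknife (200 contiguous blocks by
default — the count follows common jackknife practice and is exposed); the r_g jackknife recomputes the full ratio per deleted
block so numerator/denominator correlation is respected. Negative fitted
heritability is reported with a warning, mirroring the behaviour of the
reference implementation; r_g is refused (with diagnostics) when either
heritability estimate is non-positive.

## The pipeline and reproducibility

`run_pipeline()` executes simulate → co-aggregation → correlations →
model fitting → LDSC from one declarative (YAML or list) configuration.
One top-level seed is expanded into per-stage sub-seeds by fixed offsets
(simulation: the seed itself; sibling-pair selection: +31; LDSC panel and
sumstats: +57/+58), so toggling one stage never shifts another's
randomness, and every stochastic entry point restores the caller's RNG
state. Each run archives its resolved configuration, a log, and a
manifest of sha256 checksums; identical configuration + seed reproduces
byte-identical checksums. Stage failures abort with the stage named.
`recovery_report()` wraps scenario grids (truth × replicates) into
bias/SE/coverage summaries — the package's validation surface. The
`inst/scripts/famliab-cli.R` script exposes subcommands
(simulate/coagg/corr/fit/ldsc/all/recovery) for shell use; the R
functions remain the primary interface.

## Known limitations

- Sibling binary fits assume shared thresholds across sexes; sex-limited
  threshold (or variance) models are not implemented.
- CRCT standard errors ignore double-entry dependence (descriptive stage
  only).
- The boundary LRT is reported conservatively by default; the mixture
  correction covers only a single boundary parameter.
- The LD panel is block-diagonal; long-range LD, MAF-dependent
  architecture and stratification are not simulated (the intercept sweep
  addresses the latter only as a sensitivity device).
- No assortative mating, G×E, or parent-of-origin effects; the maternal
  half-sibling vs paternal half-sibling contrast therefore reflects only
  shared-environment sharing, not maternal genetic effects.
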