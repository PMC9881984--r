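---
title: "Digital-twin Mendelian randomization: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-twin Mendelian randomization: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtwin)
```

## The problem

Mendelian randomization (MR) treats genetic variants as instrumental
variables: if a SNP influences an exposure trait $E$, is independent of
confounders of the exposure-outcome relationship, and affects the outcome
$O$ only through $E$, then the association pattern of the SNP with both
traits identifies the causal effect $\beta_{EO}$. The second assumption is
the fragile one. Under population stratification, subpopulations differ in
both allele frequencies and trait distributions, so every SNP acquires a
spurious association with the outcome that no amount of external data can
average away; standard summary-statistic estimators (IVW, Egger) then
reject the null far in excess of their nominal level, and the inflation
*grows* with sample size. Assortative mating and dynastic effects act the
same way, through the parental genotypes.

The escape route is a conditional argument: given the genotypes of an
individual's parents, the individual's own genotype is determined by
Mendelian segregation alone — a coin flip per heterozygous parental locus —
and is therefore independent of population membership and of anything else
upstream of the parents. Conditioning on parental genotypes $A$ turns the
confounded marginal independence assumption into one that holds by the
biology of inheritance.

## The test

`mrtwin()` implements a conditional randomization test built on that fact.
Writing $X_n$ for the instrument genotypes of the offspring in family $n$
and $O_n$ for their outcome value, the statistic is the negative squared
error of predicting the outcome from the genetically predicted exposure:

$$\hat E_n = \sum_j \hat\beta_{XE,j} X_{nj}, \qquad
  t = -\sum_n \left(\hat\beta_{EO}\,\hat E_n - O_n\right)^2,$$

where $\hat\beta_{XE,j}$ are per-SNP exposure effects from an external GWAS
and $\hat\beta_{EO}$ is a summary-statistic MR estimate (fixed-effect IVW by
default). The test computes $t^*$ on the true offspring, then draws $B$
"digital twins" — synthetic offspring genotypes sampled from the family
data under the same Mendelian law — and recomputes the statistic for each,
holding $O$, $\hat\beta_{XE}$ and $\hat\beta_{EO}$ fixed. The p-value is

$$p = \frac{1 + \#\{b : t_b \ge t^*\}}{1 + B}.$$

Under the null of no causal effect, offspring and twins are exchangeable
conditional on the family data, so $p$ is (super-)uniform on the grid
$\{k/(B+1)\}$ regardless of how confounded the external estimates are. The
external weights may be arbitrarily biased: bias shifts true offspring and
twins identically and cancels. This also makes the test immune to weak
instrument bias — instrument filtering is supported
(`select_instruments()`, Bonferroni $p < \alpha/M$ and an $F \ge 10$
screen) but not needed for validity.

Ties count toward the null ($t_b \ge t^*$), the conservative randomization
convention; consequently a degenerate statistic (e.g. $\hat\beta_{EO} = 0$,
which makes $t$ identical for everyone) returns $p = 1$ rather than an
artifact. The smallest attainable p-value is $1/(B+1)$; with the
recommended $B = 1000$ for one-off analyses this is $9.99\times10^{-4}$.
$B = 100$ keeps replicate studies cheap at the cost of p-value granularity
($\{k/101\}$). Twin replicates are drawn from a single RNG stream in a
fixed order, so results are a deterministic function of (data, $B$, seed)
and independent of internal chunking.

A two-sided variant ($2\min(P(t_b \ge t^*), P(t_b \le t^*))$, capped at 1)
is available but off by default: a causal effect makes the true offspring's
genetic prediction *better* than their twins', so the one-sided test is the
scientifically motivated one.

## Twin generation by design

*Trio* (both parents genotyped): $D_j \sim \mathrm{Bern}(P1_j/2) +
\mathrm{Bern}(P2_j/2)$ per SNP. This is exact, and trio mode inherits the
full validity guarantee.

*Duo* (one parent): the allele contributed by the unobserved parent cannot
be resampled, so it is fixed at its value in the true offspring; only the
observed parent's transmission is redrawn. If the observed parent is
homozygous the twin equals the offspring at that SNP; if heterozygous,
$D_j \sim \mathrm{Bern}(1/2) + \mathrm{Bern}(X_j/2)$.

*Sibling* (two or more siblings, no parents): the twin's two alleles are
drawn independently and uniformly from the $2S$ pooled alleles of the $S$
siblings at that SNP ($D_j \sim \mathrm{Binomial}(2, s_j/2S)$). This
"shuffling" rule is an approximation to resampling from the unobserved
parents; an alternative that draws one allele from each of two distinct
siblings is available via `sibling_method = "pairs"`.

Duo and sibling twins only approximate the conditional law of the offspring
genotype, so those modes reduce, but do not fully control, confounding at
high stratification strength. That is expected behavior, not a defect, and
is reproducible with `run_fpr_experiment()` on duo/sibling designs.

Instrument SNPs are assumed (approximately) independent, as is standard for
pruned MR instruments; per-SNP allele draws then stand in for
haplotype-level inheritance and no phasing is required. Correlated
instruments would require haplotype-aware (e.g. HMM-based) twin
generation, which this package does not implement.

## The simulator

`simulate_mr_data()` generates the two-population study design used
throughout the tests. Genotypes follow the Balding-Nichols model: per SNP
an ancestral frequency $p \sim U(0.05, 0.95)$ (bounded away from 0/1 to
avoid near-monomorphic SNPs; the bounds are configurable), population
frequencies $p_k \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with
fixation index $F$ (at $F = 0$ both populations collapse onto $p$ exactly),
and genotypes $\mathrm{Binomial}(2, p_k)$. External samples and trio
parents share the same frequency realizations, matching the recommendation
that external and family cohorts be drawn from similar populations.

Phenotypes follow a confounded linear model with a binary population label
$z$:

$$E = X\beta_{XE} + \gamma z + \varepsilon_E, \qquad
  O = \beta_{EO} E + \gamma z + \varepsilon_O.$$

Per-SNP causal effects are i.i.d. Gaussian on the `m_causal` SNPs, rescaled
against the realized genotypes so the genetic component explains `h2` of
exposure variance; noise is scaled so each phenotype has unit variance at
$\gamma = 0$. This standardization makes $\gamma$ and $\beta_{EO}$
comparable across runs; it also means $|\beta_{EO}| \le 1$ (larger values
would need negative outcome-noise variance and are rejected). The same
$\gamma$ applies to both traits by default, with independent overrides
(`gamma_exposure`, `gamma_outcome`). Defaults mirror the reference design:
50,000 external samples, 1,000 trios evenly split between two populations,
$F_{ST} = 0.01$, 100 SNPs with 50 causal, $h^2 = 0.2$.

What the simulator does *not* emulate: linkage disequilibrium, genotyping
error, missingness, assortative mating or dynastic generative mechanisms,
and binary outcomes. Passing tests therefore demonstrate calibration and
power under independent-SNP stratification confounding; robustness to
familial confounding rests on the conditioning argument, not on these
simulations.

## Numerical and design choices

- **Marginal GWAS** is closed-form simple OLS per SNP (slope, SE, t-test
  p). Monomorphic SNPs are excluded with a warning, never silently.
  Residual sums of squares are floored at zero to absorb cancellation in
  the perfect-fit limit.
- **IVW** is fixed-effect (weights $1/\mathrm{se}_{XO}^2$ on a
  through-origin weighted regression). The twin statistic needs only a
  point estimate of $\beta_{EO}$, and the fixed-effect form reduces
  *exactly* to the ratio estimator at one instrument, which the tests
  assert. **Egger** orients instruments to $\beta_{XE} \ge 0$, fits WLS
  with intercept, and reports the fixed-effect covariance
  $(X'WX)^{-1}$, consistent with the IVW convention. The ratio estimator
  uses the first-order delta-method SE, $\mathrm{se}_{XO}/|\beta_{XE}|$.
- **$\hat\beta_{EO}$ is estimated once** from external summary statistics
  and never re-fit per twin replicate: conditional on the family data the
  external estimates are constants, and re-fitting would break
  exchangeability.
- **Mendelian inconsistencies** between offspring and recorded parents are
  a hard construction error; `allow_mendel_errors = TRUE` downgrades them
  to per-SNP family-wise exclusion with a logged count. Missing data are
  not imputed.
- **Replicate seeds** in `run_fpr_experiment()`/`run_power_experiment()`
  are drawn up front from the master seed, so tables replicate exactly and
  cells are independent.
- **Sibling pooling** samples alleles with replacement from all siblings —
  the simplest faithful reading of drawing haplotypes from the observed
  sibling pool; the distinct-pair variant is behind a flag rather than a
  default because the pooled rule has the simpler exchangeable-allele
  interpretation.

## Scale choices in the shipped tests

The packaged test-suite experiments run at a reduced scale chosen to keep a
full run in minutes on one CPU while leaving Monte-Carlo error well below
the effect sizes being asserted: 500-replicate null studies at 2,000
external samples / 200 trios / 50 SNPs with $B = 100$; power grids at 200
replicates with 4,000 external samples (power studies double the external
cohort relative to null studies, mirroring the reference design's ratio);
and a weak-instrument study at 200 SNPs of which 10 are causal. The
full-scale design (1,000 replicates, 50,000-100,000 external samples,
1,000 trios) is supported by the same functions and is used where the
assertion genuinely requires it — notably the p-value-floor check, since
the conditional-randomization z-score grows like $\sqrt{N h^2/2}$ and at
200 trios a causal effect of 0.5 yields power well short of 1 against the
$1/(B+1)$ floor, whereas at 1,000 trios the floor is reached reliably.
That scaling is worth remembering when planning real analyses: with a few
hundred trios the test is valid but conservative in resolution, and
p-values near the floor should not be expected.

## Known limitations

- Trio mode carries the full conditional-independence guarantee; duo and
  sibling modes are approximations and lose calibration under strong
  stratification.
- The statistic assumes a continuous outcome with an additive model;
  binary outcomes would need a different loss and a different treatment of
  external effect sizes.
- Instruments are treated as independent; no LD-aware twin generation or
  correlation-matrix-aware estimators are provided.
- The test yields a p-value, not an effect estimate with confidence
  interval — it is a test of the causal null, with effect sizes left to
  the summary-statistic estimators it wraps.
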