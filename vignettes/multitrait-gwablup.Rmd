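---
title: "Multitrait genomic prediction with GWAS-weighted SNP priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitrait genomic prediction with GWAS-weighted SNP priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwablup)
```

## The model

Standard multitrait SNP-BLUP assumes every SNP contributes equally to the
genetic (co)variance. **gwablup** implements GWAS-weighted BLUP (GWABLUP):
association evidence collected on the training data re-weights each SNP's
prior (co)variance, concentrating prior variance on regions that plausibly
harbour QTL, while everything else about the linear mixed model is unchanged.

For $T$ traits and $N$ SNPs the model for the training records (yield
deviations, ordered traits within animals) is

$$
\mathbf{y} = \mathbf{X}\boldsymbol{\mu} + \mathbf{Z}\mathbf{b} + \mathbf{e},
\qquad
\mathbf{e} \sim N\!\big(\mathbf{0},\, \mathbf{W} \otimes \mathbf{R}\big),
$$

with $\mathbf{X} = \mathbf{1}_{n_a} \otimes \mathbf{I}_T$,
$\mathbf{Z} = \mathbf{M} \otimes \mathbf{I}_T$ for the $n_a \times N$ matrix
$\mathbf{M}$ of centred allele counts, and $\mathbf{W}$ diagonal with the
*inverses* of the record weights, so animal $i$'s residual covariance is
$\mathbf{R}/w_i$. The multitrait SNP effects are a priori independent across
SNPs with per-SNP $T \times T$ covariance blocks
$\mathbf{b}_j \sim N(\mathbf{0}, \mathbf{V}_{\mathrm{SNP}_j})$, collected in
the block-diagonal $\boldsymbol{\Theta} = \bigoplus_j \mathbf{V}_{\mathrm{SNP}_j}$.
Breeding values $\mathbf{u} = \mathbf{Z}\mathbf{b}$ are carried explicitly,
with the joint covariance of $(\mathbf{u}, \mathbf{b})$ regularized by a small
$\varepsilon\,\mathbf{I}_{n_a}$ term so that it is non-singular. This yields a
three-block system of mixed-model equations in
$(\hat{\boldsymbol\mu}, \hat{\mathbf{u}}, \hat{\mathbf{b}})$ whose coupling
blocks are $-\mathbf{Z}/\varepsilon$ and
$\mathbf{Z}'\mathbf{Z}/\varepsilon + \boldsymbol{\Theta}^{-1}$; as
$\varepsilon \to 0$, $\hat{\mathbf{u}} \to \mathbf{Z}\hat{\mathbf{b}}$
(asserted as a test property). With every block equal to
$\mathbf{V}_{\mathrm{SNP}} = \mathbf{G} / \sum_j 2p_j(1-p_j)$ the model is the
familiar unweighted multitrait SNP-BLUP, equivalent to GBLUP with genomic
relationship $\mathbf{M}\mathbf{M}'/\sum_j 2p_j(1-p_j)$ (also asserted
against a dense GBLUP construction).

## From GWAS to SNP weights

The correlated traits are first mapped to *canonical* traits that are
genetically and environmentally independent: `canonical_transform()` solves
the generalized eigenproblem of $(\mathbf{G}, \mathbf{R})$, returning
$\mathbf{Q}$ with $\mathbf{Q}\mathbf{R}\mathbf{Q}' = \mathbf{I}$ and
$\mathbf{Q}\mathbf{G}\mathbf{Q}' = \mathrm{diag}(\boldsymbol\lambda)$. The
canonical traits can be scanned one at a time because their residuals are
uncorrelated with unit variance; the scan itself
(`single_snp_scan()`) is a per-SNP weighted least-squares regression with an
intercept and the record weights as regression weights.

Per trait $t$ and SNP $j$ the evidence is summarized as a log-likelihood
ratio

$$
LR_{tj} = \tfrac12\, \hat{b}_{tj}^2 / se_{tj}^2 ,
$$

computed from *original-scale* effects — canonical estimates are
back-transformed through $\mathbf{Q}^{-1}$, with standard errors propagated
through $\mathbf{Q}^{-1}\mathrm{diag}(se^2)\mathbf{Q}^{-\top}$. To mimic the
model averaging of MCMC variable-selection methods, the $LR$ track is
smoothed by a moving average over the SNP and its `half_window = 2`
neighbours on each side, and mapped to the posterior probability of a
non-zero effect under a point-mass mixture prior,

$$
PP_{tj} = \frac{\pi\, e^{\overline{LR}_{tj}}}
               {\pi\, e^{\overline{LR}_{tj}} + (1-\pi)},
\qquad \pi = 0.001 .
$$

Three weighting schemes build the prior blocks (`build_prior()`):

* **unweighted** — $\mathbf{V}_{\mathrm{SNP}_j} = \mathbf{V}_{\mathrm{SNP}}$;
* **equal weights** — one weight per SNP shared by all traits,
  $\mathbf{V}_{\mathrm{SNP}}\, PP_j / \overline{PP}$, where $PP_j$ comes from
  the *sum* of the smoothed canonical-trait $LR$s;
* **trait specific** —
  $\mathbf{V}_{\mathrm{SNP}_j} = \mathbf{S}_j \mathbf{V}_{\mathrm{SNP}} \mathbf{S}_j$
  with $S_{j,tt} = \sqrt{PP_{tj} / \overline{PP}_{t}}$: per-trait variances
  are re-weighted, prior correlations between traits are left untouched.

Dividing by the mean posterior probability keeps the total prior genetic
variance per trait equal to the diagonal of $\mathbf{G}$ under every scheme.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pi` | 0.001 | prior probability that a SNP has a non-zero effect; the posterior equals `pi` at zero evidence |
| `half_window` | 2 | moving-average half width in SNPs (a 5-SNP window), a linkage proxy |
| `epsilon` | 0.01 | regularization coupling `u` to `Zb`; smaller values tighten the identity `u = Zb` at the cost of conditioning |
| `tolerance` | 1e-9 | PCG stop rule: residual norm relative to the right-hand-side norm |
| `record weights` | 1 | per-animal precision of the yield deviation; residual covariance is `R / w` |

## Numerical choices

* **Bending.** Published correlation tables are rounded and often not jointly
  positive definite (the three-trait dairy residual correlations
  0.96 / −0.17 / 0.16 are an example). `bend_to_positive_definite()` clips
  eigenvalues at a floor of $10^{-6} \times$ the mean eigenvalue and
  reconstructs — a minimal repair applied to G and R at `trait_model()`
  construction.
* **Log-space posteriors.** $e^{LR}$ overflows for $LR$ in the hundreds
  (routine on strong QTL); `posterior_probability()` evaluates the logistic
  of $LR + \log(\pi/(1-\pi))$ and stays strictly inside $(0, 1)$.
* **Smoothing at boundaries.** Windows never cross chromosomes — adjacent-SNP
  smoothing is an LD proxy and LD does not cross chromosomes — and are
  truncated at chromosome ends, dividing by the number of SNPs actually in
  the window.
* **Degenerate SNPs.** A SNP whose single-SNP fit is exact (zero residual
  variance) or has no genotype variance is excluded from the scan, contributes
  zero evidence to the smoothing, and keeps the prior `pi` as its weight
  rather than being dropped from the prediction model.
* **Allele frequencies.** Computed from training animals only; validation
  genotypes are centred with training frequencies, avoiding any leakage.
  Missing genotypes are mean-imputed; SNPs monomorphic in training are
  removed.
* **Solver.** The mixed-model equations are never materialized:
  `apply_mme()` is matrix-free (two dense genotype products per iteration)
  and $\boldsymbol\Theta^{-1}$ is applied through the per-SNP diagonal scale
  factors and one $T \times T$ inverse. The preconditioner inverts the
  $T \times T$ diagonal block of every effect level (block-Jacobi). The
  published analyses used a doubly preconditioned conjugate gradient; the
  preconditioner affects the iteration count only, not the solution, so
  block-Jacobi reproduces the same estimates. The true residual is recomputed
  every 50 iterations (and at convergence) to guard against drift of the
  recursive residual; the start vector is zero, making runs bit-identical.
* **Bootstrap ties.** Method comparisons resample animals jointly across
  methods; a comparison is significant when the strict-win (or strict-loss)
  fraction exceeds 0.975. Ties count toward neither side, so a method is
  never significantly different from itself.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` provides the study conditions for all method-level
checks: genotypes with first-order linkage between adjacent SNPs (a latent
Gaussian autoregression with parameter `ld_decay`, preserving marginal allele
frequencies exactly), sparse trait-specific QTL sets with configurable
pairwise overlap, effects drawn so that shared QTL generate the target
genetic correlations, per-trait genetic variances scaled to hit the diagonal
of $\mathbf{G}$ exactly, and residuals drawn from $\mathbf{R}/w_i$.

The `"table1"` preset emulates a three-trait dairy setting under unit
phenotypic variances: heritabilities 0.26 / 0.20 / 0.16, two yield-like
traits sharing 80% of their 50 QTL, and a near-independent somatic-cell-count
trait sharing 10%; residual correlations 0.96 / −0.17 / 0.16. Because shared
QTL are the only source of genetic correlation, a pair sharing 80% of its
QTL cannot exceed a genetic correlation of 0.80; the preset therefore sets
the yield-pair correlation to 0.80 (real dairy estimates are slightly
higher). The canonical genetic variances are invariant to per-trait
rescaling (a tested property), so the unit-variance convention loses no
generality.

The generator deliberately omits several features of real dairy data:
long-range LD and population structure, selection and pedigree, genotyping
or imputation error, and mis-specified variance components — phenotypes are
drawn from the exact SNP-BLUP generative model with the correct total
genetic variance. Two consequences for interpreting the test suite: first,
passing the method-ordering checks shows the weighting machinery works when
its assumptions hold, not that the same margins appear in real cattle data;
second, unweighted BLUP is dispersion-unbiased by construction here (the
validation regression slope sits at 1), so the deflation that weighting
repairs in real data has no analogue in these conditions — data-driven
weights can only add mild over-dispersion through reuse of the training
data, which the validation checks report.

Problem sizes used by the checks: the simulation study runs 10 replicates of
3,000 training plus 500 validation animals, 2,000 SNPs and 50 QTL per trait,
with the solver at a relative tolerance of $10^{-6}$ — prediction metrics
are insensitive beyond that point, while the default $10^{-9}$ remains the
recommendation for production estimates. Solver-equivalence checks run
against dense assemblies at up to 20 animals and 30 SNPs, where direct
solves are exact.

## A worked run

```{r, eval = FALSE}
cfg <- preset_config("table1", seed = 1)
sim <- simulate_dataset(cfg)
run <- run_gwablup(sim$panel, sim$phenotypes, sim$traits,
                   n_boot = 10000, seed = 1)
tidy(run)          # reliability and slope per scheme and trait
glance(run)        # PCG iterations and residuals per scheme
autoplot(run$weights)   # Manhattan plot of posterior probabilities
```

## Known limitations and open choices

* The single-SNP scan models no genomic relationship among training animals;
  with strong structure the likelihood ratios are miscalibrated and the
  weights absorb some of that. Canonical traits and yield deviations make
  this mild in the intended setting, but it is a stated assumption.
* Smoothing is applied per canonical trait *before* summing the likelihood
  ratios for the across-trait weight; the alternative order (sum first, then
  smooth) differs only at chromosome ends but is a genuine interpretation
  choice.
* Back-transformed standard errors treat canonical estimates as independent
  across canonical traits — exact for the model under which the canonical
  decomposition is built, approximate otherwise.
* Record weights are taken as given inputs; how they derive from phenotype
  reliabilities is outside the package's scope.
* Single-step extensions (non-genotyped animals), pedigree-regularized
  covariances, and per-SNP prior *correlations* are not implemented.
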