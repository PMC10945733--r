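---
title: "Phylogenetic mixed models for chemosensory panel data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic mixed models for chemosensory panel data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phylotaste)
```

## The scientific problem

Botanical drugs — specific plant parts used therapeutically — carry
chemosensory signatures (tastes, flavours, chemesthetic sensations) that
may have guided how people assigned them to therapeutic uses. Testing
that idea quantitatively requires relating tasting-panel assessments of
drugs to binary records of therapeutic use while accounting for the fact
that drugs from related plant species share both chemistry and uses:
observations on a phylogeny are not independent. `phylotaste` implements
the full analysis chain for this problem:

1. **Panel data**: readers/validators for a drug table, a sensory-trial
   table (each trial is one panellist scoring one drug sample on 22
   chemosensory qualities, each 0 = absent, 1 = weak, 2 = medium,
   3 = strong), and a binary drug x use matrix with a use -> category map.
2. **Chemosensory metrics**: per-trial *intensity* (sum of the 22 scores,
   0-66) and *complexity* (number of non-zero qualities, 0-22); per-drug
   *therapeutic versatility* (number of distinct broader categories of
   use the drug is recommended for).
3. **Phylogeny preparation**: grafting analysis taxa missing from a
   published ultrametric supertree onto the most recent common ancestor
   of their genus (family as fallback) with pendant lengths preserving
   ultrametricity, and the phylogenetic correlation matrix `A` (shared
   root-to-ancestor path length divided by tree height).
4. **A Bayesian PGLMM engine** written from scratch (no external MCMC
   dependency), with gaussian, binary-probit and zero-truncated Poisson
   families, random effects with arbitrary positive-definite covariance,
   parameter-expanded variance priors, and the summaries used in this
   literature: the sign-crossing significance `p_x` and the phylogenetic
   heritability `h^2`.
5. **A model battery**: versatility as a zero-truncated Poisson response
   (one model with all 22 qualities as covariates, one with intensity +
   complexity), and per therapeutic use a pair of probit models with the
   same two fixed-effect sets — 94 models for a 46-use dataset — plus the
   22 x uses effect map and per-quality "magnitude of effect" (sum of
   significant betas across uses).
6. **A synthetic-data generator** with complete known truth, which is the
   package's test surface.

## The model

For trial $i$ of drug $d(i)$ on taxon $t(i)$, the linear predictor is

$$\eta_i = \mathbf{x}_i'\boldsymbol\beta + u_{\mathrm{phylo},t(i)}
  + u_{\mathrm{part},p(i)} + u_{\mathrm{panellist},j(i)}$$

with $\mathbf{u}_{\mathrm{phylo}} \sim N(0, \sigma^2_{\mathrm{phylo}} A)$
and identity covariance for plant part and panellist. Fixed effects are
either the 22 ordinal quality scores treated as numeric covariates (one
coefficient per quality) or intensity and complexity, always plus the
mean-centred days-between-collection-and-tasting covariate. The response
is drug-level and repeated across the drug's trials (a deliberate
pseudo-replication: the panellist effect is only estimable at trial
level; see *Known limitations*). Families:

* **gaussian** — identity link, conjugate throughout.
* **probit** — $y_{d}=1$ iff a latent liability
  $\ell_i = \eta_i + e_i$ is positive; data augmentation with
  truncated-normal draws, all remaining updates conjugate.
* **zero-truncated Poisson** — versatility $y_d \ge 1$ with
  $y \sim \mathrm{ZTP}(\exp(w_i))$, $w_i = \eta_i + e_i$; the latent
  log-rates $w_i$ get per-observation random-walk Metropolis updates
  whose global step size adapts during burn-in toward an acceptance rate
  near 0.3 (adaptation stops at the end of burn-in, keeping the
  post-burn-in kernel valid).

### Priors

* Fixed effects: independent $N(0, 10^{10})$ — effectively flat.
* Residual variance: inverse-gamma with $(V = 1, \nu = 0.002)$.
* Random-effect variances: parameter expansion. Each effect vector is
  $\xi_k \mathbf{u}_k$ with $\mathbf{u}_k \sim N(0, \sigma^2_{u,k} K_k)$
  (inverse-gamma base, $V = 1, \nu = 1$) and a scalar expansion factor
  $\xi_k \sim N(0, 25)$ updated jointly with $\boldsymbol\beta$ as a
  regression coefficient on the column $Z_k\mathbf{u}_k$. The effective
  variance component is $\xi_k^2\sigma^2_{u,k}$ and the implied prior on
  the effective standard deviation is approximately half-Cauchy with
  scale 5: flat ("roughly uniform") across the plausible range of
  probit-liability and log-rate scales, without the enormous tail mass
  that a much larger scale would put on degenerate near-separation
  regimes of binary responses (see *Known limitations*). Parameter
  expansion also breaks the classic random-walk dependence between a
  variance component and its effect vector, improving mixing when a
  variance is near zero.

### Posterior summaries

* $p_x$: the proportion of retained samples of a coefficient on the
  opposite side of zero from its posterior mean (zeros count as
  crossing); significance is declared at $p_x < 0.05$. With $N$ retained
  samples the smallest resolvable value is $1/N$; when no sample crosses,
  the value 0 is reported with the floor recorded alongside. Under the
  reference profile (500,000 iterations thinned every 5,000) only 100
  samples are retained, so the floor is 0.01 — reported values such as
  "< 0.001" are not resolvable at that thinning; the engine surfaces
  the floor rather than extrapolating. A doubled (two-sided) variant is
  available: under a true null effect the doubled variant flags at level
  $\alpha$ with probability $\alpha$, whereas the one-sided $p_x$ flags
  at about $2\alpha$ — the doubled variant is therefore what a
  calibration experiment should target.
* $h^2$: per retained sample,
  $\sigma^2_{\mathrm{phylo}} / (\sigma^2_{\mathrm{phylo}} +
  \sigma^2_{\mathrm{part}} + \sigma^2_{\mathrm{panellist}} +
  \sigma^2_{e})$, summarised by its kernel-density mode on $[0,1]$.
  Because `A` is scaled to unit diagonal, $h^2$ is a proportion with the
  same reading as Pagel's lambda.
* Coefficients are summarised by posterior mean *and* kernel-density
  mode; the effect map uses the mode by default (configurable), matching
  the modal reporting convention of this literature.

## MCMC profiles and problem sizes

Two built-in profiles: the reference profile (500,000 post-burn-in
iterations, thin 5,000, 100 retained samples) and the default desk
profile (20,000 / 20, 1,000 retained) used for routine work and the test
suite. Burn-in defaults to 10% of post-burn-in iterations. The package's
own validation experiments (see `tests/testthat/test-acceptance.R`) use
the default synthetic scenario — 80 taxa, 100 drugs, 5 panellists,
about 570 trials, 6 uses — with 20,000-50,000 iteration chains; at these
sizes a versatility model fits in roughly a minute. Thinning must divide
the iteration count; chains are bit-reproducible from the seed, and the
battery derives per-model seeds deterministically from one master seed
so any subset of models reruns identically.

## The synthetic-data generator

The generator emulates the structure the analysis assumes, with every
parameter recorded in a truth bundle:

* A pure-birth tree scaled to height 1; tips are labelled
  `Genus<g>_species<i>` where genera are clades younger than 30% of tree
  height and families clades younger than 80%, so grafting by rank is
  exercised naturally.
* Latent quality traits per trial: baseline + phylogenetic effect
  (covariance $\sigma^2 A$) + plant-part + panellist + trial residual,
  thresholded at cut-points (0.8, 1.8, 2.8) into scores 0-3. Defaults
  (phylo 0.6, part 0.12, panellist 0.005, residual 0.01) describe a
  trained consensus panel whose trial scores are a reliable proxy of the
  drug's profile; this matters because the fitted covariate is the trial
  score while drug-level responses are driven by drug-mean scores, and
  low panel reliability would attenuate recovered coefficients
  (classical measurement error). The per-quality phylogenetic effects
  are centred across taxa: a real panel vocabulary only retains
  descriptors that discriminate among drugs, and the common component is
  absorbed by the intercept in any case.
* Versatility: drug-level zero-truncated Poisson with log rate =
  intercept + quality effects on drug-mean scores + phylogenetic +
  plant-part effects (defaults: share
  $1.5 / (1.5 + 0.15) \approx 0.91$ phylogenetic, mirroring the strong
  signal reported for real drug-use data). Default non-zero effects
  follow the qualities found predictive in the field: bitter, starchy,
  musky, sweet, soapy positive; sour negative. The response-level
  random effects are centred across their levels: the realised common
  component of a phylogenetic or plant-part effect is confounded with
  the intercept in any fitted model, so leaving it in would make the
  recorded intercept truth untestable. The rate is used exactly as
  drawn — no truncation — so the recorded truth *is* the process the
  engine fits, at the cost of occasional large synthetic counts under
  the high phylogenetic variance.
* Uses: drug-level probit liabilities with unit residual plus the same
  random-effect structure, and a sparse 22 x uses matrix of true effects
  (8 non-zero by default over 6 uses).
* Days since collection: gamma-distributed, rounded; no true degradation
  effect, so the days coefficient is a built-in null.

What the generator does **not** emulate: empirical score frequencies of
any real panel, correlations between quality effects and use categories,
panellist-specific scale usage, or drifts over tasting sessions. Passing
recovery tests on this generator therefore demonstrates correctness of
the machinery under the stated model, not robustness to those
real-data features.

## Numerical choices

* Truncated-normal liabilities are drawn by inverse-CDF with the uniform
  clamped to $[10^{-15}, 1-10^{-15}]$ and the result clamped to
  $\mu \pm 8\sigma$, which keeps extreme-mean draws finite.
* The zero-truncated Poisson log-mass uses
  $\log(1-e^{-\lambda})$ computed via `log1p`/`expm1` branches and a
  series fallback for $\lambda < 10^{-8}$, so the $\lambda \to 0$ limit
  (all mass on $k=1$) is exact.
* Random-effect vectors are drawn from their full conditionals via
  Cholesky factors of the precision; identity-covariance terms use the
  diagonal fast path.
* The phylogenetic correlation matrix is symmetrised and its diagonal
  pinned to 1 after construction; non-positive-definite covariances
  raise a decomposition error rather than being silently repaired.
* Ultrametricity tolerance is $10^{-8}$ relative; violations are only
  repaired when `repair_ultrametric()` is called explicitly.
* Grafting attaches to the genus (or family) MRCA; a single-tip genus
  has no MRCA, so the new tip is attached at the midpoint of the
  existing tip's pendant edge.
* Ties/order: battery seeds derive as
  `(master + 7919 * model_index) mod 2147483629`, so results are
  independent of execution order.

## Design choices on open points

* **Trials are never excluded**: the loaders keep repeated samples to
  the same panellist; the panellist random effect absorbs rater bias.
* **Per-quality percentages** divide by the number of trials; strength-
  level percentages divide by the number of perception reports — the
  only reading consistent with published descriptive counts of this
  kind. Report rounding: percentages at or above 10 print as integers,
  below 10 with one decimal.
* **Pooled vs per-trial qualities**: "qualities per drug" pools
  non-zero qualities across a drug's trials; per-trial complexity is the
  modelling covariate. Both are exposed.
* **Pruning before grafting**: when preparing a large supertree the
  package grafts onto the tree as given; pruning to the analysis taxa
  happens in `phylo_correlation()` via subsetting, which is equivalent
  to pruning first because correlations depend only on shared path
  lengths.
* **Probit residual variance** is estimated by default (inverse-gamma
  prior, as specified for all models in the reference analysis) with an
  option to fix it at 1. Location effects of a probit model are only
  identified relative to the residual standard deviation; $p_x$ and
  $h^2$ are scale-free and unaffected, and validation experiments that
  compare coefficients against a known truth fix the residual.

## Known limitations

* **Pseudo-replication and quasi-separation in the binary models.** The
  per-use probit models repeat one drug-level 0/1 response across the
  drug's ~5.7 trials while including taxon- and part-level random
  effects. With about as many taxa as drugs, those random effects can
  reproduce nearly every drug's response sign, and each drug contributes
  several consistent sign observations, so the likelihood rewards
  drifting into a near-separation regime: variance components grow
  almost without bound, $h^2$ tends to 1 regardless of the generating
  share, and finite chains are far from stationarity. The 22
  quality covariates under near-flat priors contribute to the same
  separation when the number of distinct drugs is of the same order as
  the number of predictors plus random-effect levels. This is the known
  behaviour of binary "animal model" GLMMs with cluster-level random
  effects — and it is consistent with uniformly very high heritability
  reported for real analyses of this design. Consequences inside this
  package: (i) coefficient-recovery and calibration validation are
  performed on the zero-truncated Poisson versatility models, whose
  count likelihood anchors the latent scale (the probit sampler itself
  is validated against conjugate/symmetry oracles and, with
  phylogenetic random effects, in a low-dimensional identified design
  where it recovers slope, variance component and $h^2$);
  (ii) every use-model summary carries
  quasi-complete-separation flags (a quality never observed among
  positive-response drugs, or only there); (iii) probit effect-map
  entries should be read as directions and relative magnitudes, not
  absolute liability-scale effects.
* **Partial confounding of quality effects with the phylogenetic random
  effect.** The quality covariates are themselves phylogenetically
  structured, so a free phylogenetic random effect can absorb part of a
  quality's signal and redistribute credit among correlated
  coefficients. In the package's own recovery experiment (five replicate
  default scenarios, 50,000-iteration chains) the realised central-95%
  interval coverage of the true non-zero quality effects is 26/30
  (~87%), slightly below nominal, and the pattern (one coefficient low
  while a correlated one runs high within the same replicate) persists
  at 300,000 iterations — it is a property of the design, not of chain
  length. Interval statements about single quality coefficients should
  be read with this in mind.
* **Intercept identification under parameter expansion.** The expansion
  column $Z_k\mathbf{u}_k$ is nearly collinear with the intercept
  whenever the realised mean of a random-effect vector is non-zero, so
  the intercept is only identified jointly with the random-effect
  location; its marginal interval is wide and slowly mixing. Quality
  coefficients and contrasts are unaffected.
* **$p_x$ resolution** is limited to $1/N$ retained samples (0.01 under
  the reference profile).
* The versatility response enters at drug level but is fitted on trial
  rows; uncertainty for drug-level contrasts is accordingly somewhat
  optimistic. This mirrors the published design and is flagged rather
  than corrected.
* No multivariate responses, no model comparison (DIC/WAIC), no
  families beyond the three listed.

## Validation summary

The test suite validates, among other things: loader round trips;
metric definitions and the printed-percentage rounding rule;
ultrametricity preservation over random graft sets; exactness of the
3-taxon correlation matrix; the zero-truncated Poisson mass function
against a renormalised `dpois` oracle and brute-force summation;
gaussian-family equivalence with the conjugate closed form; probit
symmetry and its asymptotic intercept standard error; rate recovery for
the zero-truncated Poisson; bit-level chain reproducibility; coverage of
true non-zero effects and modal-$h^2$ recovery on the default synthetic
scenario; null calibration of the (doubled) $p_x$ flag rate; and battery
determinism, skip rules and effect-map aggregation against brute-force
recomputation. Every number asserted in the tests is either derived from
an independent oracle inside the test itself or is a property with an
explicit tolerance.
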