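---
title: "Threshold-trait quantitative genetics of developmental-mode plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-trait quantitative genetics of developmental-mode plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alderia)
```

## The biological problem

Poecilogonous sea slugs lay two kinds of egg mass: clutches of many small
eggs that develop into plankton-feeding (planktotrophic) larvae, and
clutches of few large, yolk-provisioned eggs whose larvae can complete
metamorphosis without feeding (lecithotrophic). Egg capsule diameter is
bimodal (modes near 113 and 182 µm) and tracks egg size closely, so a
clutch is scored lecithotrophic when its capsules reach 150 µm. The
propensity to lay one clutch type or the other is environmentally
modulated — low salinity, typical of the winter rainy season, shifts
animals toward planktotrophy — and varies among maternal families reared
in a split-brood design across salinities. `alderia` implements the
quantitative-genetic machinery for this situation: liability-scale
("threshold") animal models, latent/observed-scale heritability
conversion, realized heritability from truncation selection with
self-fertilization, family reaction norms and the cross-environment
genetic correlation, together with a forward simulator of the whole
design.

## The liability model

Developmental mode is modelled as a threshold trait. Individual $i$
carries an unobserved liability

$$\ell_i = \mu + \beta\,\mathrm{salinity}_i + a_i + m_{f(i)} + d_{k(i)}
          + \mathrm{id}_i + e_i,$$

with additive genetic value $a \sim N(0, \sigma^2_A A)$ over the
relationship matrix $A$, maternal-family, culture-dish and
permanent-environment effects, and a residual with variance fixed at 1
(the probit link variance). A clutch (or individual) is lecithotrophic
when $\ell > 0$, so $P(y=1) = \Phi(\eta)$. Heritability on the latent
scale is $h^2_\ell = \sigma^2_A / (\sigma^2_A + \sum_k \sigma^2_k + 1)$;
the observed (0/1) scale version follows from the average inverse-link
derivative, $h^2_{\mathrm{obs}} = \Psi^2 \sigma^2_A / \bar p(1-\bar p)$
with $\bar p = E[\Phi(\eta)]$ and $\Psi = E[\phi(\eta)]$, evaluated by
Gauss–Hermite quadrature (48 nodes by default; the Monte-Carlo cross-check
is part of the test suite).

Egg capsule diameter itself is analysed with the same machinery under an
identity link (`response = "gaussian"`), and the three-way classification
(planktotrophic / lecithotrophic / mixed) with a baseline-category
multinomial probit with two latent dimensions and identity residual
covariance (`response = "categorical"`).

## Relationship matrices with selfing

`relationship_matrix()` runs the tabular method over a topologically
ordered pedigree; selfing is just `dam == sire`, so the diagonal $1+F$
accumulates as $F_{g+1} = (1+F_g)/2$ along selfing chains. Because the
founding maternal families come from field-collected egg masses with
unknown sires, within-clutch relatedness is an assumption rather than an
observation; the `assumption` argument rebuilds the founder generation
through phantom parents so that clutch-mates are maternal half sibs
($a = 0.25$, the conservative default), outcrossed full sibs ($0.5$),
offspring of a single selfing parent ($a = 1$, diagonal $1.5$), or a
per-clutch random mixture. All later generations inherit their recorded
(selfed) pedigree links on top of that assumption.

## The Gibbs sampler and its numerical choices

`animal_model()` is a single-site conjugate Gibbs sampler with data
augmentation for the threshold models (the latent liability is redrawn
from its truncated normal each sweep; far tails use Robert's exponential
rejection sampler, the body the inverse CDF). Three choices matter and
are worth spelling out.

**Marginalized genetic remainder.** With one binary record per
individual, the individual-specific part of the breeding value is
perfectly confounded with the unit residual: a naive sampler leaves
$\sigma^2_A$ effectively frozen (or drifting) because every residual can
be absorbed by the animal effect. The sampler therefore splits
$a = Gz + w$ along the eigenstructure of $A$, with
$G = U\,\mathrm{diag}(\sqrt{\lambda_j - c})$, $c = \lambda_{\min}(A)$,
and integrates the isotropic remainder $w \sim N(0, c\,\sigma^2_A I)$
into the residual, whose variance becomes $1 + c\,\sigma^2_A$ (or
$\sigma^2_E + c\,\sigma^2_A$ for Gaussian responses). This is an exact
reparameterization of the same model; it exposes the structured,
identified directions (for half-sib families, one dimension per family)
to the sampler and removes the pathological ridge. Reported draws are
always on the original scale: `Va` is the full additive variance and `Vr`
the link (or environmental) residual.

**Variance priors.** Each variance component is updated by slice sampling
on the log scale under one of three priors: a half-normal prior on the
standard deviation (default; scale 1 on the unit liability scale,
`sd(y)` for Gaussian responses), a half-Cauchy, or the classical
inverse-gamma. In a design with ~20 families, the likelihood for
$\sigma^2_A$ of a threshold trait saturates at large values (the
between-family intraclass correlation is bounded), so heavy-tailed priors
— the half-Cauchy, and catastrophically the near-improper
IG(0.001, 0.001) — leave appreciable posterior mass at scientifically
absurd variances (breeding-value standard deviations several times the
residual). The half-normal keeps the prior proper and honest on the scale
where the link variance is 1 while remaining flat over the plausible
range ($h^2_\ell$ up to $\approx 0.9$); the other two priors are retained
as explicit sensitivity options, and posterior summaries of weakly
identified components should always be read as prior-sensitive.

**Interweaving.** Each variance component is updated twice per sweep: in
the usual (sufficient) parameterization given the effects, and again in
the ancillary parameterization (effects rescaled by the new standard
deviation, a slice move whose target involves only three running sums).
This ancillarity–sufficiency interweaving is what makes the variance
components of the augmented probit models mix at usable rates; effective
sample sizes per 1 000 retained draws move from single digits to the
hundreds.

Fixed effects keep independent normal priors, $N(0, 1)$ for Gaussian and
$N(0, 1000)$ for threshold/categorical responses, and `pMCMC` is twice
the smaller tail proportion with a $1/n_{\mathrm{draws}}$ floor. Default
chain settings are 603 000 iterations, burn-in 10 000, thinning 10 —
appropriate for a real analysis; the package's own tests run at
20 000/2 000/10 and state so below. `dic()` computes
$\mathrm{DIC} = 2\bar D - D(\hat\theta)$ with the deviance focused on the
retained (structured) effects; for categorical fits the per-observation
probabilities use the per-dimension standardized utilities, an
approximation that is exact when the two latent dimensions carry equal
variance. `ess()` is the initial-positive-sequence autocorrelation
estimator with a noise cutoff, and parameters below the conventional
ESS 1000 are flagged, not refused (small categorical analyses are
routinely accepted at a few hundred).

## Realized heritability under truncation selection

For the selection experiment, the proportion $q_g$ of lecithotrophic egg
masses in generation $g$ maps to a liability mean $u_g = \Phi^{-1}(q_g)$
(unit-variance liability, threshold at zero). Selecting exactly the
above-threshold fraction gives the selection differential
$S_g = \phi(\Phi^{-1}(q_g))/q_g$, the response is
$R_g = u_{g+1} - u_g$, and `realized_heritability()` reports per-step
$h^2 = R/S$ plus the summed form $\sum R / \sum S$ over the available
consecutive steps (a lost line simply truncates the sum). The
continuous-trait version uses plain mean differences; capsule-size
selection differentials and responses are reported in both µm and mm —
the printed convention for this trait is mm while means are quoted in µm,
and the only consistent reading of a response of 0.02 following means of
124 and 144 µm is 20 µm = 0.02 mm.

Two boundary policies are deliberate: a capsule of exactly 150 µm counts
as large, and an individual mean of exactly 150 µm is scored
lecithotrophic (the egg-mass rule is quoted as $\ge$; the individual rule
is quoted with strict inequalities that leave 150 unassigned, and we
resolve it the same way for consistency). Frequencies of 0 or 1 are a
hard error for the probit transform rather than being clamped.

## The synthetic-data generator

`simulate_base_population()` and `simulate_selection_experiment()` draw
from exactly the liability model the estimators assume, so parameter
recovery is meaningful. Defaults describe the split-brood design: 17
maternal families, 15 individuals per family per salinity, capsule modes
113/182 µm with within-mode SD 9.7 µm applied to both modes (a single
pooled value; the mode-specific spread is not separately known), egg
sizes 68 ± 4 and 105 ± 5 µm, survival to laying 0.63 (16 ppt) and 0.81
(32 ppt), clutches per layer $1 + \mathrm{Pois}(3.5)$ (mean 4.5), and a
mixed-clutch probability of 0.065 under which a clutch interleaves both
capsule modes regardless of its liability.

The liability parameters were derived once from the observed
first-generation proportions: with variance defaults
$V_A = 1.3, V_M = 0.2, V_{dish} = 0.1, V_{id} = 0.4, V_E = 1$ (total
$\sigma_T^2 = 3$, latent $h^2 = 0.433$, close to the published estimate
for this trait), the marginal proportion of lecithotrophic clutches is
$(1 - p_{mixed})\,\Phi(\eta/\sigma_T)$, so
$\mu = \sqrt{3}\,\Phi^{-1}(0.176/0.935) = -1.533$ and
$\mu + \beta = \sqrt{3}\,\Phi^{-1}(0.257/0.935)$, giving
$\beta = 0.497$. These are fixed defaults, not fitted quantities.

Selection proceeds by truncation: the parents of each new generation are
exactly the lecithotrophic layers (capped at a rearing capacity of 12 per
salinity line), each contributing selfed offspring with
$a_{child} = a_{parent} + \text{Mendelian deviation}$, Mendelian variance
$\tfrac12 V_A (1 - F_{parent})$, and $F_{child} = (1 + F_{parent})/2$. A
line with no lecithotrophic layers terminates with a logged message, as
happens in practice. Repeated clutches of one individual share $a$, $m$
and the permanent-environment effect and redraw only the clutch residual,
so egg-mass-type lability emerges from residual noise; an optional
per-clutch Markov flip (`switch_rate`) adds environment-dependent
switching on top.

What the generator does *not* emulate: temperature and photoperiod
effects, incomplete fertilization of selfed clutches, measurement error
in capsule diameters beyond the within-mode spread, and any genetic
architecture beyond the additive infinitesimal model. Passing recovery
tests on these data therefore demonstrates internal consistency of the
estimators, not robustness to real-data violations.

## Problem sizes used in the test suite

Sampler tests run at chain length 20 000 (burn-in 2 000, thin 10).
Threshold-model recovery uses 20 half-sib families × 30 individuals with
latent $h^2 = 0.45$ over 20 replicates; with so few independent genetic
units the posterior is wide and noticeably prior-influenced, which is
exactly what the matching field design implies, and the tests assert
recovery of the replicate-averaged posterior mean to ±0.15 with ≥85%
interval coverage. Gaussian recovery uses 100 outcrossed full-sib
families of 6 (a configuration where $V_A$ is well identified), and the
no-random-effect Gaussian model is checked against the exact posterior
obtained by numerical integration. Scale conversions are verified against
closed probit forms and a $10^6$-draw Monte-Carlo oracle on a 25-point
grid. The end-to-end test simulates the full design, checks the
first-generation proportions and survival against their generative
expectations, and verifies that truncation selection raises the
proportion lecithotrophic when $V_A > 0$ and not when $V_A = 0$.

## Known limitations

* With single binary records and family-structured relatedness, the
  additive variance of the threshold model is only weakly identified;
  credible intervals are honest but wide, and the posterior mean is
  pulled toward the prior. Designs with repeated records or deeper
  pedigrees identify it far better.
* The categorical model's residual covariance is fixed to identity, and
  its DIC/prediction use a per-dimension standardization that is
  approximate when the two latent dimensions differ strongly in variance.
* The cross-environment genetic correlation uses the family-mean method
  (low-salinity proportions regressed on high-salinity ones — the
  direction matching the interpretation of a correlated response in low
  salinity per unit of direct response in high — with the direction-free
  Pearson correlation reported alongside); no bivariate animal model is
  fitted.
* Realized heritability has no control-line correction, mirroring the
  experimental design it serves, and proportions enter untransformed.
* The selection differential assumes the selected fraction is exactly the
  upper liability tail; partial selection within the tail would need an
  explicit selected-parent mean instead.
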