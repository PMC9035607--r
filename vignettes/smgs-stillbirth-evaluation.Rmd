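---
title: "Sire-MGS threshold-model genetic evaluation of stillbirth"
author: "stillbirthSMGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sire-MGS threshold-model genetic evaluation of stillbirth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillbirthSMGS)
```

## The problem

Stillbirth in dairy cattle — a calf born dead or dying within 48 hours —
is recorded nationally on a 3-point livability scale alongside calving
ease. Because the outcome is binary after recoding, and because the calf's
own genes (the *direct* effect, transmitted by the service sire) and the
dam's genes (the *maternal* effect, proxied by the maternal grandsire,
MGS) both matter and are antagonistically correlated, the field's standard
tool is a **sire-maternal-grandsire (S-MGS) threshold model**. This
package implements that evaluation end to end: editing raw calving
records, estimating liability-scale (co)variance components by Gibbs
sampling, transforming them to direct/maternal genetic parameters,
expressing bull merit as observed-scale predicted transmitting abilities
(PTA), approximating reliabilities, and estimating phenotypic and genetic
trends. A generative simulator built from exactly the model's assumptions
makes the whole pipeline testable without access to any national database.

## The model

For calving record $r$, a latent liability follows

$$
\ell_r = hy_i + YS_j + PS_k + sB_l + mB_m + sPSB_n + mPSB_o
        + s_p + m_q + e_r,
$$

with herd-year $hy_i \sim N(0, \sigma^2_{hy})$ random; fixed year-season
($YS$, seasons starting in October and May), parity-sex ($PS$, parity
classes 1, 2, 3-and-later by calf sex), sire and MGS birth-year groups
($sB$, $mB$, carrying genetic-group means and trend), and the two
parity-sex-by-birth-year interactions ($sPSB$, $mPSB$) that absorb the
sexed-semen shift in heifer calf sex ratios; and random sire and MGS
effects jointly

$$
\begin{pmatrix} \mathbf{s} \\ \mathbf{m} \end{pmatrix}
  \sim \mathrm{MVN}\!\left(\mathbf{0},\; G_0 \otimes A\right),
\qquad
G_0 = \begin{pmatrix} \sigma^2_s & \sigma_{s,mgs} \\
                      \sigma_{s,mgs} & \sigma^2_{mgs} \end{pmatrix},
$$

where $A$ is the pedigree additive relationship matrix over bulls. The
residual is $e_r \sim N(0, 1)$: with a single threshold and a binary
response, the liability scale is identified only up to the residual SD, so
the residual variance is fixed at 1 and never updated. The stillbirth
code is $2$ (dead) when $\ell_r$ exceeds the threshold, which we fix at 0
and carry the overall level in an explicit intercept; only differences
matter on the liability scale, and the reporting scale is re-anchored
downstream by the genetic base.

Transformation to direct/maternal parameters, per retained draw:
$\sigma^2_D = 4\sigma^2_s$;
$\sigma^2_M = 4\sigma^2_{mgs} - 4\sigma_{s,mgs} + \sigma^2_s$;
$\sigma_{D,M} = 4\sigma_{s,mgs} - 2\sigma^2_s$;
$r_{D,M} = \sigma_{D,M}/\sqrt{\sigma^2_D \sigma^2_M}$;
$\sigma^2_P = \sigma^2_s + \sigma^2_{mgs} + 1$;
$h^2_D = \sigma^2_D / \sigma^2_P$; $h^2_M = \sigma^2_M / \sigma^2_P$.
Summaries are means and 95% highest-posterior-density intervals of the
per-draw transforms — *transform first, summarize second* — which is why
a table's printed heritabilities need not equal transforms of its printed
(rounded) variance components. Draws implying a non-positive maternal
variance are excluded from the correlation summary and counted.

## Data editing

`applyEdits()` applies the national edit rules in a fixed order: dam birth
year inside the extraction window; purebred only (service-sire breed equal
to dam breed); livability 2/3 recoded to binary stillbirth; parities 3+
collapsed to class 3; unknown-MGS records dropped; herds that never
reported a stillbirth dropped (herds reporting only live calves bias the
incidence); herd-year contemporary groups under 5 records dropped. The
last two rules interact — removing an undersized group can strip a herd's
only stillbirth — so they are iterated to a fixed point, which keeps the
advertised post-conditions true on the final dataset and makes the whole
edit idempotent. The per-rule removal counts are returned in the edit
log and always sum, with the retained count, to the input count.

Season convention: May-September is season A of the calving year,
October-December season B, and January-April season B of the *previous*
year (the October season spans the year boundary). The year-season labels
say exactly this, e.g. `"2010-B"` for February 2011.

## Pedigree machinery

`buildAInverse()` assembles the sparse A-inverse directly from sire-MGS
rules: each bull contributes the outer product of $(1, -\tfrac12,
-\tfrac14)$ over (bull, sire, MGS), scaled by the inverse
Mendelian-sampling variance $d^{-1}$ with $d = 11/16$, $3/4$, $15/16$, or
$1$ as both, only the sire, only the MGS, or neither ancestor is known.
Inbreeding is not tracked — the classic closed-form practice for S-MGS
evaluations — and unknown ancestors are absorbed into $d$, with
genetic-group means carried by the fixed birth-year effects instead of
phantom-parent groups. The dense tabular oracle
(`relationshipMatrix()`) builds $A$ from the same recursion, so the two
routes are exact inverses of each other on every pedigree; its diagonal
equals 1 exactly whenever a bull's sire and MGS are unrelated.

## The Gibbs sampler

`runGibbs()` is a single-site Gibbs sampler with truncated-normal data
augmentation, written in C++ for the chain lengths the method requires:

1. each record's liability is drawn from $N(\eta_r, 1)$ truncated to
   $(-\infty, 0]$ or $(0, \infty)$ by its stillbirth code (means are
   clamped at $|\eta| = 8$ purely to keep the inverse-CDF draw away from
   tail underflow);
2. every location effect is drawn from its full conditional, with each
   bull's (sire, MGS) pair updated jointly as a 2-vector so the
   $G_0 \otimes A$ coupling is handled exactly;
3. $\sigma^2_{hy}$ is drawn from its scaled inverse-chi-square full
   conditional and $G_0$ from its inverse-Wishart full conditional using
   the bull-effect quadratic form with $A^{-1}$.

Priors are weakly informative and centred on the start values (the role
the national-evaluation initial values play): inverse-Wishart with 4
degrees of freedom and scale $4 \times G_{0,\text{start}}$, and a scaled
inverse-chi-square with 4 df for the herd-year variance. Fixed effects
additionally carry a very diffuse proper normal prior (variance $10^6$),
which guarantees a proper posterior and well-defined updates under any
incidence pattern; its shrinkage is far below the Monte Carlo noise.

Identification of the fixed part uses first-level-zero constraints per
factor, margin constraints for the interaction cells, and a pivoted-QR
rank check of the remaining incidence columns that clamps any residually
aliased cells (sparsely populated interactions can alias a margin level).
The deterministic mode of the same sweeps (`solveLocations()`, stochastic
terms off, liabilities fixed) converges to the mixed-model-equation
solution and is verified in the tests against a dense solve at $10^{-6}$.

Chain defaults are desk-scale — 20,000 iterations, 5,000 burn-in,
thinning 10, i.e. 1,500 retained draws — which recovers Jersey-scale
parameters on ~25,000 simulated records in a few minutes on one core;
the national-scale schedule (500,000 / 100,000 / 100) is a configuration
away. Convergence is checked with Geweke z scores and effective sample
sizes (via coda, the field's standard diagnostic toolkit).

## PTA, reliabilities, trends

On the underlying scale a bull's solution $\varepsilon$ is its random
solution plus its birth-year-group solution. The observed scale is
anchored to a genetic base — service sires born 2011-2015, MGS born
2006-2010 by convention, five-year windows smoothing year-to-year
noise — and a phenotypic base $\%SB^*$, the record-weighted heifer
stillbirth percentage over the base years:

$$
\%SB(\text{bull}) = 100\left[1 - F\!\left(-\varepsilon +
  \overline{F^{-1}(1 - \%SB^*) + \varepsilon^*}\right)\right],
$$

with the bar averaging over base bulls on the liability scale. The
conversion is strictly increasing in $\varepsilon$, invariant to common
shifts, and maps the base-mean bull to $\%SB^*$ exactly. Reliabilities
use only the diagonal of a bull's own mixed-model equation,
$rel_i = 1 - d_i^{-1}/\sigma^2_a$ floored at zero, with $\sigma^2_a$ the
sire variance for service-sire reliabilities and the MGS variance for
maternal ones; ignoring relationships can only inflate these values,
which the tests document against a dense prediction-error-variance
oracle. Phenotypic and genetic trends are ordinary least-squares
regressions of yearly means on birth year with two-sided t tests; the
cubic smoothing spline (`splineSmooth()`, roughness by generalized
cross-validation) is for plotting only and never enters a slope test.

## The simulator and what passing tests mean

`simConfig()` / `generatePedigree()` / `simulateCalvingRecords()` generate
data from exactly the estimator's assumptions: bull (sire, MGS) effect
pairs drawn down the pedigree by $u = \tfrac12 u_{sire} + \tfrac14
u_{MGS} + \phi$ with Mendelian variance $d \cdot G_0$ (the exact inverse
of the A-inverse rules), normal herd-years, fixed parity-sex and
year-season shifts, unit residual, one threshold. Dams are identity links
carrying the MGS and have no genetic effect of their own, mirroring the
model. Calving ease is a monotone 5-bin discretization of the same
liability — enough to exercise the ease-by-stillbirth summary, not a
fitted trait. A configurable fraction of stillbirths is relabelled
died-within-48h, of MGS ids masked unknown, of dam breeds crossed, and of
dam birth years displaced, so every edit rule has real work.

Default study conditions emulate a mid-size Jersey-like population:
about 300 service sires and 300 MGS (40% of the smaller pool serving in
both roles, which is what identifies $\sigma_{s,mgs}$), 140 herds over
calving years 2010-2018 at ~20 records per herd-year (~25,000 records),
$G_0 = [[0.016, 0.005], [0.005, 0.014]]$, threshold set for ~5% incidence,
parity mix (0.366, 0.265, 0.369) and female-calf probabilities (0.75,
0.64, 0.59) by parity class following national parity-sex record
distributions. The herd-year variance is not published for any breed; the
default 0.05 is this package's choice of a plausible, modest herd-year
share (~5% of liability variance) and nothing downstream is tuned to it.

What the simulator does *not* emulate: non-random mating, herd-by-sire
confounding, selective reporting beyond the all-alive-herd mechanism,
twins, crossbreeding structure, or genomic information. Parameter
recovery on these data therefore demonstrates the estimator's internal
correctness under its own assumptions — not robustness to the ways real
national data violate them.

## Numerical choices and limitations

* Retained-sample bookkeeping: draws are kept at burn-in, burn-in + thin,
  …, giving $\lceil (n_{iter} - n_{burn}) / thin \rceil$ samples.
* HPD intervals use the shortest sorted window containing
  $\lceil 0.95 n \rceil$ draws (first window on ties); cross-checked
  against an independent implementation in the tests.
* Birth-year groups default to single years, with years holding fewer
  than 5 bulls pooled into 5-year blocks — a configuration choice
  (`yearGroupMinBulls`) rather than a published rule.
* The mean of the truncated-normal draw is clamped at $|\eta| = 8$;
  beyond that the truncated distribution is numerically degenerate
  anyway, and the sampler reports a divergence error on non-finite means.
* Reliabilities assume parent information is exact and ignore
  relationships; they are upper bounds in exactly the sense the tests
  verify.
* Exact reproduction of any breed's published posterior means, trend
  slopes, or reliability distributions requires the national database and
  is out of scope; simulation-scale recovery targets the published
  Jersey-scale parameter region instead.

## A worked desk-scale run

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1)            # Jersey-like study conditions
ped <- generatePedigree(cfg)
sim <- simulateCalvingRecords(cfg, ped)
edited <- applyEdits(sim$records)
design <- buildDesign(edited, ped)
fit <- runGibbs(design, buildAInverse(ped),
                mcmcConfig(n_iter = 20000, burn_in = 5000, thin = 10,
                           seed = 2))
geneticParameters(fit)                # Table-2-shaped posterior summary

eps <- underlyingSolutions(fit, "sire")
base <- phenotypicBasePct(edited, ped, "sire", c(2011, 2015))
pta <- observedScalePTA(eps, c(2011, 2015), base)
rel <- reliabilityApprox(mmeDiagonals(fit, "sire"),
                         colMeans(varianceSamples(fit))["sigma_s2"])
geneticTrend(pta[pta$n_records > 0, ])
```

The README shows the numbers this run prints.
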