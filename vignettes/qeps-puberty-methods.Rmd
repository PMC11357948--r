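---
title: "Modelling pubertal growth and menarche timing with qepsgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pubertal growth and menarche timing with qepsgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qepsgrowth)
```

## The problem

Menarche — a girl's first menstrual period — is a late landmark of pubertal
maturation, and clinicians are routinely asked how much a girl will still
grow after it. Answering that question from longitudinal height data
requires (i) a growth model that separates the *specific* pubertal growth
spurt from the *basic* growth that continues through puberty, (ii) rules to
turn heterogeneous questionnaire recollections of menarche into a usable
decimal age, and (iii) a regression framework that respects what is
knowable at each clinical milestone (birth, age 7, pubertal onset,
midpuberty). `qepsgrowth` implements all three stages and a calibrated
synthetic cohort generator, so the whole pipeline can be exercised and
tested without access to restricted registry data.

## The QEPS growth model

Total height is decomposed as

$$T(a) = \underbrace{E(a) + Q_S(a)}_{QES(a)} + P(a),$$

where $a$ is age in decimal years since birth and the model clock starts at
$t_0$, about six weeks after conception ($c_0 = 0.65$ y before birth):

* **E** (infancy): a saturating exponential
  $E(a) = E_{max}\,[1 - e^{-(a+c_0)/(\theta_E\,Etsc)}]$ that plateaus around
  age 2;
* **Q** (basic): velocity declining linearly from $t_0$ to zero at age
  $t_Q$, so the un-stopped height is quadratic in age; heights are
  normalised so the un-stopped plateau equals $Q_{max}$;
* **S** (stop): a unit logistic brake of width $s_S = 0.5$ y that
  multiplies the Q velocity by $1 - S(a)$, ending growth;
* **P** (pubertal): a Richards-type sigmoid
  $P(a) = P_{max}\,(1 + e^{-x(a)})^{-\nu}$ with
  $x(a) = k\,(a - AgeP50)/Ptsc + x_{50}$, normalised by
  $x_{50} = -\log(2^{1/\nu}-1)$ so that exactly half of $P_{max}$ is
  achieved at $AgeP50$.

Six per-subject parameters modify these shapes: three height scales
($E_{max}, Q_{max}, P_{max}$, cm), two time scales ($Etsc, Ptsc$) and
$AgeP50$. Everything else is a shared shape constant (`qeps_shape()`).

Milestones are defined on the normalised P sigmoid: pubertal onset at 5%
(`AgeP5`), midpuberty at 50%, end of pubertal growth at 95/99/99.9%
(`AgeP95`, `AgeP99`, and the operational `AgeP100 = age at pEnd = 0.999`,
since an asymptotic sigmoid has no literal 100% age). The sigmoid has a
closed-form inverse, so milestone ages are exact rather than root-found;
the test suite still checks them against a dense-grid oracle. The age of
peak P-velocity is also closed-form, $AgeP50 + Ptsc(\log\nu - x_{50})/k$;
with $\nu > 1$ it falls slightly before $AgeP50$, matching the ordering
observed in cohort data. The stopped Q height — the integral of a linear
velocity times a logistic brake — is expressed with softplus and
dilogarithm terms, keeping curve evaluation exact and fast inside the
fitting loop.

### Choice of the shape constants

The component equations above are this package's own concrete forms; they
reproduce the qualitative behaviour of the published model family (E
plateau by age 2, Q through end of growth, P adding onto QES during
puberty, S concluding growth) and every milestone definition. The defaults
were calibrated once against published cohort summary tables for ~793
healthy term-born Swedish girls and then frozen:

| constant | default | why |
|---|---|---|
| `c0` | 0.65 y | prenatal offset of the model clock |
| `thetaE` | 0.6 y | E reaches >95% of its plateau by age 2 |
| `tQ` | 19.55 y | basic growth between age 7 and adulthood matches the cohort means |
| `nu` | 1.3 | peak P-velocity 0.07–0.08 y before `AgeP50`, as observed |
| `sS` | 0.5 y | smooth stop over about a year |
| `pEnd` | 0.999 | makes `Ppubgain` within 5% of `Pmax` |
| `p5_gap` | 2.22 y | cohort-mean `AgeP50 - AgeP5` at unit time scale |

The P steepness $k$ is derived from `nu` and `p5_gap`. The S brake is
centred at `AgeP95`, the age at 95% of P: with `Qmax` defined as the
*un-stopped* plateau, this centring simultaneously reproduces the cohort's
mean height at 7 years, mean adult height, and the split of the pubertal
gain between its specific and basic parts — centring at `AgeP100` would
make the stop nearly inert (S-loss under 0.5 cm, adult height ~6 cm too
tall). It also matches the view that growth diminishes after 95% of the
pubertal spurt. One caveat is documented rather than forced: the published
per-component adult-height contributions sum to ~174 cm while mean adult
height is ~168 cm, so no parameterisation can match every printed gain
simultaneously; with this package's attribution the S brake absorbs the
~6 cm difference, and the basic pubertal gain comes out ~1 cm above the
printed mean.

```{r shape}
qeps_shape()
qeps_milestones(qeps_params(Emax = 62.76, Qmax = 98.51, Pmax = 12.92,
                            Etsc = 1, Ptsc = 1, AgeP50 = 11.98))
```

## Fitting individual curves

`fit_qeps()` minimises the unweighted sum of squared height residuals in
cm — the simplest defensible criterion for measurements whose error is
roughly age-constant. The model is linear in the three height scales given
the nonlinear triple (`Etsc`, `Ptsc`, `AgeP50`), so the height scales are
profiled out by a small non-negative linear solve at every evaluation and
only three parameters are searched: a coarse grid over `AgeP50` × `Ptsc`
seeds bounded `L-BFGS-B` refinement (time scales in [0.5, 2], `AgeP50` in
[7, 17]) from the best candidates plus seeded jittered copies (default
seed 1990), and the best-loss start wins. The fit is deterministic and
invariant to measurement order.

Preconditions guard against unidentifiable series: at least 8 points,
starting by age 2, reaching age 15, with at least 2 points after age 13.
Exact duplicate rows are dropped; an apparent shrink of more than 1 cm
between consecutive visits is flagged (`negative_growth`) but never
auto-corrected. With annual visits and 0.3 cm noise the information limit
of the design puts the per-subject standard error of `AgeP50` near
0.065 y; the cohort-mean bias is an order of magnitude smaller, which is
what the cohort-level analyses rely on.

## Menarcheal age imputation

Questionnaires ask for the first period as year and/or month and/or age.
The four reporting patterns are imputed as:

* **year + month** — date arithmetic from birth date to day 15 of the
  month ("middle of the recorded month");
* **year only** — to July 2, the middle of the year (symmetric midpoint,
  mirroring the month rule);
* **year + age** — midpoint of the overlap between the year of life at the
  stated age and the stated calendar year (the most literal reading of
  "the remaining part of the written year at the stated age");
* **age only** — reported age + 0.193 years, the correction estimated
  among dual reporters in the source cohort. The constant itself is not
  re-derivable without the raw data and is treated as given.

Decimal ages use a 365.25-day year. Imputed ages outside [6, 20] or years
preceding birth raise errors rather than propagate silently.

## Derived variables and milestone grouping

Per subject the package derives: milestone ages and heights, model adult
height `Tmax` (replaced by the largest measured height when that is
taller), pubertal gains over `AgeP5`–`AgeP100` (with
`Tpubgain = Ppubgain + QESpubgain` holding to machine precision by
construction), the achieved pubertal fraction at menarche (`P%`), height
at menarche, postmenarcheal gain (floored at 0 with a warning — a model
artifact only, observed minima are positive), midparental height
(`MPH = (mother SDS + father SDS)/2`, missing parents propagate), height
minus MPH at each milestone, and the childhood BMI maximum over the
inclusive window [3.5, 7] years. SDS transforms accept pluggable
age–mean–SD reference grids (linear interpolation, no extrapolation);
the shipped default is cohort-internal standardization because national
reference tables are not redistributable here.

Variables are grouped by the clinical milestone at which they become
available (`milestone_groups()`): birth (parental heights, birth size),
childhood at 7 years (E/Q scales, BMI, height at 7), pubertal onset
(`AgeP5` and height there), midpuberty (`AgeP50`, PHV ages, heights).
Candidate sets for the regressions are cumulative across this order.

## The regression layer

All association and outcome variables are standardized by their own
cohort SD so betas are comparable. Univariable scans use simple linear
regression per variable (complete cases per pair; the standardized beta
equals the Pearson correlation and R² its square) with Bonferroni–Holm
adjustment across the scanned set. Multivariable models per milestone use
p-value-based stepwise forward/backward selection (entry and removal at
0.05, the same convention as the significance level; ties broken by |t|
then name; aliased candidates dropped with a warning), reporting
standardized betas with normal-theory 95% CIs, model R² and partial R²
(`(SSE_without − SSE_with)/SSE_without`). For the postmenarcheal-gain
outcome the multivariable step is run only when more than one variable is
Holm-significant, mirroring how that outcome behaves in practice. Base
`stats::step()` is AIC-based and therefore not used; Holm adjustment is
delegated to `stats::p.adjust(method = "holm")` and tested against a
hand-computed step-down.

## The synthetic cohort generator

`simulate_cohort()` draws the six parameters from a truncated multivariate
normal with means/SDs set to the published cohort summaries (`AgeP50`
11.98 (1.00) y, `Emax` 62.76 (2.83) cm, `Qmax` 98.51 (7.83) cm, `Pmax`
12.92 (3.58) cm, `Etsc` 0.99 (0.09)). `Ptsc` is not tabulated in the
source; its SD (0.15) was chosen so that the implied `AgeP5` SD is ~0.95 y
against the published 1.00 y. The true between-parameter covariance is
unpublished; defaults assume independence except corr(`AgeP50`, `Ptsc`)
= 0.3 and corr(`Qmax`, `Emax`) = 0.2, and are configurable. Measurement
series follow a well-baby + school schedule (seven visits before age 2,
annual 3–18 y, jittered) with i.i.d. Gaussian noise (0.3 cm default).
Weights come from a childhood BMI trajectory with a per-subject level
shift, giving realistic `BMI_max` spread.

Menarche is, by default, tied to growth: each girl's menarche occurs when
her achieved P-fraction reaches an individual draw from a truncated
Normal(0.716, 0.188) — building in the central coupling between pubertal
progression and menarche — with an alternative age-linked null mode for
testing. Note the truncation to (0.02, 0.995) pulls the realized mean
fraction to ~0.68; the generator states the latent distribution, not the
realized moments. Report modes are assigned in the observed 285:38:103:367
proportions and degraded from the true date (e.g. age-only reports floor
the age, which makes the +0.193 round trip biased by about −0.3 y by
construction — a deliberate property of the degradation model, not a bug
in the rule).

What the generator does *not* emulate: secular trends, measurement error
that grows with age or differs between well-baby and school settings,
informative missingness, recall error in the year/month fields, and any
real covariance of BMI or parental height with pubertal timing beyond the
built-in P-fraction link. Passing tests therefore show the pipeline is
correct and well-calibrated under these idealised conditions, not that the
published regression coefficients would be reproduced on real registry
data.

## Numerical choices

* Dilogarithm via series + inversion (tested against the integral
  representation at 1e-10).
* Non-negative height scales enforced by a tiny active-set around
  `lm.fit`.
* `L-BFGS-B` with `factr = 1e7`, max 100 iterations, 5 starts; a fit is
  `converged` only if the winning start reports clean convergence, and
  non-converged subjects are excluded from cohort summaries rather than
  silently kept.
* Problem sizes in the test suite: the cohort recovery experiment uses the
  full 793 subjects (one fit takes ~0.2 s); replicate-based property
  tests use 10–100 replicates at n = 500–793; the pipeline smoke test uses
  50 subjects.

## Worked example

```{r example, eval = FALSE}
coh <- simulate_cohort(cohort_config(n_subjects = 100, seed = 1))
fits <- fit_cohort(coh$measurements)
derived <- derive_cohort(fits, coh$measurements, coh$metadata)
milestone_models(derived, "age_menarche")
```

## Known limitations

* The concrete component equations are this package's own; per-subject
  parameter values are not interchangeable with other implementations of
  the model family.
* Stepwise p-value selection inherits the usual caveats (post-selection
  inference is optimistic); it is implemented because it is the procedure
  under study, not because it is recommended practice.
* Girls only; weight is simulated for `BMI_max` but not modelled inside
  the growth curve; no hierarchical pooling across subjects.
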