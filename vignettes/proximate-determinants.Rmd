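---
title: "Modelling fertility and pregnancy outcomes from their proximate determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fertility and pregnancy outcomes from their proximate determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famplanr)
```

## The model

`famplanr` rests on the proximate-determinants view of fertility: whatever
affects how many children women bear — education, income, programmes,
norms — must act through a small set of direct mechanisms: exposure to
pregnancy (marriage or union), contraception, postpartum insusceptibility
from breastfeeding and abstinence, induced abortion, and sterility. Each
mechanism contributes a multiplicative index, and the product scales total
fecundity TF down to the observed total fertility rate:

$$\mathrm{TFR} = C_m \, C_i \, C_a \, C_s \, C_c \, \mathrm{TF}.$$

The indices and the inputs they take are:

| index | formula | input, units |
|---|---|---|
| marriage $C_m$ | proportion married/in union | proportion of women 15–49 |
| postpartum $C_i$ | $20/(18.5+\mathrm{PPI})$ | median insusceptibility, months |
| sterility $C_s$ | $(7.63-0.11\,s)/7.3$ | % childless at 45–49 |
| abortion $C_a$ | $\mathrm{TFR}/(\mathrm{TFR}+0.4(1+\mathrm{CPR})\mathrm{TAR})$ | lifetime abortions/woman |
| contraception $C_c$ | $1-1.08\cdot\mathrm{CPR}\cdot e$ | prevalence and effectiveness, proportions |

The constants (20, 18.5, 7.63, 0.11, 7.3, 0.4, 1.08) are the standard
Bongaarts regression constants and are deliberately not configurable:
revising them would be a different model, and cross-study comparability
depends on everyone using the same ones.

The framework stops at the fertility rate, so the package adds an
accounting layer that closes the books on pregnancies. Unintended
pregnancies come from two pools — users whose method fails,
$CU\,(1-e)$, and women with unmet need who become pregnant, $UN\,\rho$ —
and a constant calibrated fraction $\alpha$ of them ends in induced
abortion. Stillbirths are proportional to live births
($S = B\,\sigma/1000$) and miscarriages close the identity
$M = (B+A+S)\,\mu/(1-\mu)$, which makes the miscarriage share of all
pregnancies exactly $\mu$ — an algebraic property the test-suite verifies
over randomised inputs.

## Parameters and defaults

* **$\mu$ = 0.13** — miscarriage proportion of pregnancies. Measured
  losses depend heavily on how early gestation is observed; 0.13 is the
  standard demographic estimate for recognised pregnancies.
* **$\sigma$ = 19 per 1000 live births** — the global-average stillbirth
  rate, used when no country value is supplied; the bundled presets carry
  country-specific rates (12–44).
* **$\rho$ = 0.31 per year** — pregnancy rate among women with unmet need,
  with an inter-quartile plausibility range of roughly 0.23–0.38. This
  parameter drives most unintended pregnancies in low-use settings.
* **$\alpha$** — abortion share of unintended pregnancies. Not a default
  but a calibration: expressing abortion this way (rather than as an
  exogenous rate) lets the abortion count respond to changing
  contraceptive use while the behavioural propensity stays fixed.
* **Failure rates** — the bundled nine-method table (sterilisation to
  traditional methods, annual failure 0.05%–78%) feeds the mix-weighted
  average effectiveness $e = 1 - \sum_m w_m f_m$. A two-column CSV
  overrides it.
* **Reproductive span = 35 years** (ages 15–49). Used to convert an
  annual abortion rate per 1000 women into the lifetime TAR
  ($\mathrm{TAR} = \text{rate} \times 35/1000$) and, in the crude birth
  conversion, to spread a TFR over the span ($B = \mathrm{TFR}\cdot W/35$).
  Both are admitted simplifications of age structure; callers with real
  birth estimates should supply them directly.

## Calibration conventions

Three conventions had to be fixed where the framework itself is silent.

**The abortion-index circularity.** $C_a$ contains the TFR it helps
produce. Projections resolve this with a one-year lag — year-$t$ $C_a$
uses year-$(t{-}1)$ fertility *and prevalence* — and the baseline
calibration closes the loop as a fixed point, evaluating $C_a$ at the
observed baseline TFR. The payoff is exactness: recomposing the TFR from
the calibrated TF reproduces the observation to machine precision
(`glance(calibrate_baseline(...))` shows both), and a constant-input
scenario is a true fixed point, with bit-identical outcome rows every
year. Treating prevalence as lagged alongside fertility keeps the lag
semantics clean: perturbing this year's prevalence affects this year's
$C_c$ immediately but reaches $C_a$ only next year.

**Which prevalence enters the indices.** Surveys report modern and
traditional prevalence separately. The package uses all-method prevalence
(modern + traditional) in both $C_c$ and $C_a$, with traditional methods
carrying their standard 78% failure rate in the effectiveness table. A
supplied scalar effectiveness (as in the bundled presets, which quote the
published country values) overrides a mix-derived one. Published
total-fecundity values for reference countries are reproduced only loosely
under this — or any — convention, because the published inputs are rounded
and the original software's internal convention is not documented; the
bundled Ukraine preset is the extreme case, where the published TF of 6.5
is below what the other four indices alone would permit. Calibration
therefore warns (rather than errors) when TF leaves the plausible 13–18
band, and the tests hold TF reproduction to a loose tolerance while
checking everything downstream of it tightly.

**Where $\alpha$ comes from.** `calibrate_baseline()` prefers, in order:
explicitly supplied abortion and unintended-pregnancy counts; the preset's
published counts; and finally the abortion rate per 1000 women converted
to a count with the population scaffold, paired with the model's own
unintended-pregnancy estimate. An observed abortion count exceeding
unintended pregnancies is an inconsistency error, since in this model
every induced abortion terminates an unintended pregnancy.

## Scenarios and the unmet-need default

Scenarios move inputs along per-year trajectories: constant, linear ramp
(in percentage points per year, the unit survey trends are reported in),
or an explicit interpolated series. Ramps are capped — default 85% — both
to keep $C_c$ positive and because prevalence saturates in practice.
Ramp arithmetic is done on the percent scale so that integer-point ramps
land on exact endpoint values.

One default required a modelling judgement. If unmet need were held at its
baseline level while prevalence ramps up, the model would predict *rising*
abortions under contraceptive scale-up: the method-failure pool
$CU\,(1-e)$ grows with $CU$ while the unmet-need term never shrinks. That
contradicts both observed dynamics and the arithmetic of the model itself:
a woman who starts using contraception leaves the unmet-need pool, and her
annual pregnancy risk drops from $\rho \approx 0.31$ to
$1-e \approx 0.05$. The package therefore couples the default unmet-need
path to prevalence growth, $u_t = \max(0,\, u_0 - (\mathrm{cpr}_t -
\mathrm{cpr}_0))$, drawing each additional user from the unmet-need pool
until it empties. Under this default, scale-up reduces abortions in every
bundled preset, as it should. The coupling is only a default: an explicit
`unmet_need = traj_constant()` (or any trajectory, e.g. one encoding an
empirical prevalence–unmet-need curve) overrides it.

Women of reproductive age are held constant unless a trajectory is given;
the cohort-component projection that would supply them is out of scope, so
multi-year population growth must be passed in by the user.

## The synthetic-population generator

`synth_population(seed)` draws one population uniformly from ranges that
span the bundled presets: TFR 1.2–7, prevalence 2–80%, effectiveness
85–99%, insusceptibility 1.5–18 months, abortion rates 0–60 per 1000,
unmet need 3–30%, populations of 1–50 million. The box is chosen so the
contraception-index domain constraint $1.08\cdot\mathrm{CPR}\cdot e < 1$
holds everywhere in it, making every draw feasible by construction; the
generator still validates each draw against the full invariant set, and
its reference outcomes are computed from the model itself so that, for
example, abortions never exceed unintended pregnancies.

What the generator emulates is the *static* variety of national survey
indicators; what it does not emulate is anything dynamic or correlated —
real co-movement of prevalence and unmet need, survey measurement error,
age structure, or heterogeneity within a population. Property tests passing
over these draws therefore demonstrate algebraic correctness and domain
safety across the realistic input space, not predictive validity for any
actual country.

## Numerical choices

* All prevalences are proportions in $[0,1]$ internally; percent values in
  configuration files and presets are converted once, at the boundary.
* Outcome counts are real-valued throughout; rounding (default: nearest
  100, the granularity of published country tables) happens only in the
  report writer.
* Calibration identities (TF round-trip, $\alpha$ round-trip) are exact
  algebra and tested at 1e-9 relative; accounting identities
  ($P = B+A+M+S$, $M/P=\mu$) at 1e-6.
* Domain violations are typed errors: invalid inputs
  (`fp_error_invalid_input`), model-domain breakdowns such as
  $C_c \le 0$ — which names the offending inputs, and the offending year
  in a projection — (`fp_error_domain`), unknown methods or presets
  (`fp_error_lookup`), and configuration faults (`fp_error_config`).
  Out-of-band TF is the one soft case (a classed warning), because real
  applications legitimately produce it.
* Degenerate cases: a zero index makes TF calibration impossible and is an
  error; `pct_childless` ≥ 69.36 would make $C_s$ non-positive and is
  rejected; TAR of 0 gives $C_a = 1$ exactly.

The test-suite and the acceptance script size their property loops at 1000
seeded synthetic populations for the calibration round-trip and outcome
conservation, and 200–300 draws for the per-index range checks; all
complete in seconds since each evaluation is closed-form.

## Limitations

The model estimates period fertility and aggregate annual counts; it has
no age structure, no parity or birth-interval effects, and no dynamics of
contraceptive adoption — future prevalence is an assumption the user
supplies, not something the model predicts. Abortion for sex selection is
outside the accounting (it does not arise from an unintended pregnancy).
The crude birth conversion is a placeholder for a demographic projection;
the women-of-reproductive-age scaffolds bundled with the presets are
synthetic back-solves, labelled as such, not census data. Finally,
$\alpha$, $\rho$, and $\mu$ are assumed constant over a projection, which
legal, medical, or measurement changes can violate.
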