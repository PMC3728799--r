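---
title: "Models and methods: dissolution chemistry, the 7-compartment PBPK model, and the calibrate-once-predict-twice workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpkivivc)
```

pbpkivivc connects three layers of oral-drug development that are usually
handled by separate tools: the chemistry of dissolution testing, empirical
release-kinetics fitting, and physiologically based pharmacokinetic (PBPK)
prediction. This vignette is the package's own account of the models it
implements, the assumptions behind them, and the choices made where the
design was genuinely open.

## 1. Dissolution-medium chemistry

### The charge-balance solver

Everything the simulated dissolution vessel does reduces to one question:
given the total (analytical) composition of the medium, what is its pH?
The package answers it by solving the full charge balance over all
dissolved forms. For the media the protocols need — strong acid (HCl),
strong base (NaOH), and sodium phosphate salts — the unknown is the
hydrogen-ion concentration $h$ and the balance reads

$$h + [\mathrm{Na^+}] - [\mathrm{Cl^-}] - \frac{K_w}{\gamma_1^2 h}
 - P_T\,\bar z(h) = 0,$$

where $P_T$ is total phosphate and $\bar z$ the mean phosphate charge from
the stepwise dissociation constants (pKa 2.148, 7.198, 12.35 at 25 °C,
stored in the auditable registry file `extdata/species.yaml`). Water
autoionization ($K_w = 10^{-14}$) is always included. The root is
bracketed in $h \in (10^{-14}, 10)$ mol/L, located with Brent's method on
$\log_{10} h$, and polished with a few Newton steps so the charge residual
of every reported speciation sits at machine noise (the package contracts
it to $\le 10^{-10}$ mol/L). A consequence worth knowing: the ideal-mode
pH of $c$ mol/L strong acid is the exact
$-\log_{10}\!\big((c + \sqrt{c^2 + 4K_w})/2\big)$, which differs from the
nominal $-\log_{10} c$ by up to $\sim 4\times10^{-7}$ pH units at
$10^{-4}$ mol/L — the solver does not neglect water.

### Two pH conventions, both exposed

The two printed landmarks of the two-stage enteric test are mutually
inconsistent under a single convention. 0.1 M HCl is "pH 1.0" only if pH
means $-\log_{10}$ of the H⁺ *concentration* with unit activity
coefficients (ideal mode). But mixing 750 mL of it with 250 mL of 0.2 M
Na₃PO₄ gives a solution whose concentration-based pH is 7.20 — phosphate's
pKa₂ — while a glass electrode reads about 6.8, because at the mixture's
ionic strength ($I \approx 0.18$ mol/L) activity coefficients are far from
unity. The package therefore exposes both conventions and never defaults:

* **ideal** — $\mathrm{pH} = -\log_{10} [\mathrm{H^+}]$;
* **davies** — activity coefficients for every charged form from the
  Davies equation, $\log_{10}\gamma_z = -0.509\,z^2\big(\sqrt I/(1+\sqrt I)
  - 0.3 I\big)$, with $I$ solved self-consistently by fixed-point
  iteration; $\mathrm{pH} = -\log_{10} a_{\mathrm{H^+}}$.

```{r}
usp_buffer <- mix_media(medium(0.750, HCl = 0.1),
                        medium(0.250, Na3PO4 = 0.2))
compute_ph(usp_buffer, mode = "ideal")$pH
compute_ph(usp_buffer, mode = "davies")$pH
```

The Davies form is adequate to $I \approx 0.5$ mol/L, which covers every
medium these protocols produce; the package makes no claim beyond that.
Temperature is carried on media for reporting but the constants are 25 °C
reference values — the protocols run isothermally at 37 °C and no
temperature dependence is modeled.

### The simulated pH-stat

`run_ph_program()` reproduces a feedback-controlled vessel: every control
interval (default 30 s) the pH is computed in Davies mode, compared with
the program setpoint, and a discrete PI controller doses 2 M HCl or 2 M
NaOH, clipped to the pump capacity (default 0.12 L/h). Two standard
embellishments keep the loop sane: integral action freezes while the pump
saturates (anti-windup), and the integrator resets when the error crosses
zero, which suppresses post-step ringing. The defaults
($k_p = 3\times10^{-4}$ L/pH, $k_i = 10^{-2}$ L/(pH·h)) were tuned on the
step-response benchmark (4.8 → 6.8 step settles within ±0.05 in well
under ten intervals) and stored in `ph_controller()`.

The starting medium deserves a flag. The physical protocol specifies only
"500 mL of a buffer at pH 4.8"; its composition is unstated. The package
assumes 0.05 M sodium dihydrogen phosphate titrated to pH 4.8
(`make_buffer_at_ph()`). The concentration matters more than it may seem:
phosphate has a buffer-capacity *minimum* near pH 4.7, and a much more
dilute medium makes any discrete-dosing feedback loop limit-cycle — a real
phenomenon pH-stat operators know. A meal-conditioned stomach is
moderately buffered, so 0.05 M is a defensible stand-in; it is an
assumption, not a measured recipe. Likewise the "fed-stomach" pH program
(`fed_stomach_program()`, and the CSV fixture
`extdata/fed_stomach_ph_synthetic.csv`) is a synthetic piecewise-linear
emulation of published postprandial recordings — pH starting at 4.8,
declining to about 2 over two hours, then rising to 6.8 at gastric
emptying — not digitized subject data.

### Enteric tablets as pH-gated release

Inside a protocol, a `tablet()` couples a release model to the vessel
through an optional threshold: the release clock only advances while the
pH is at or above it. This is deliberately the simplest mechanism that
reproduces the qualitative enteric-coating contrast — zero release in the
acid stage of the two-stage test, substantial release under a fed-stomach
program once the pH spends time above the threshold. It does not model
coat erosion, osmotic rupture, or pH-dependent release *rates*; if a
formulation needs those, fit separate per-stage release models instead.

## 2. Release kinetics

Dissolution profiles are fitted on cumulative *mass* (mg), not fraction,
so that the PBPK mass balances stay in one unit system. The primary form
is the Weibull,

$$M(t) = M_\infty\Big(1 - e^{-((t - t_{lag})/\tau)^\beta}\Big),$$

chosen because it nests first-order release ($\beta = 1$), bends into the
sigmoid shapes enteric-coated products show ($\beta > 1$), and has an
analytic derivative — the ODE forcing term — everywhere. A capped
zero-order form covers constant-rate products. Fitting is bounded
nonlinear least squares ($M_\infty \le 1.2\times$ content,
$\beta \in (0.2, 5]$) from five deterministic starts seeded by the
profile's half-release time; there is no randomness anywhere in the
fitting path. `select_release_model()` compares candidate forms by AICc
with near-ties going to fewer parameters, keeping the choice of "a
suitable expression" auditable rather than implicit. The lag time exists
for enteric coats but stays fixed at zero unless explicitly freed.

Degenerate inputs fail loudly: an all-zero profile or one that decreases
by more than 5% of the labeled content raises a fit error instead of
returning a meaningless model.

## 3. The 7-compartment PBPK model

The body is reduced to seven perfectly mixed compartments — the continuous
stirred-tank assumption — each carrying one mass-balance ODE: three
gastrointestinal lumens (stomach, small intestine, large intestine), the
gut-wall circulation ("gics", splanchnic blood), the liver, plasma
(blood plus richly perfused organs), and scarcely perfused tissues. All
membrane transport is passive diffusion, flux = PA · ΔC. The circulation
is the physiological portal loop: plasma → gut circulation → liver →
plasma, with equal flows in and out of the two interior nodes enforced at
construction so their volumes stay constant. Elimination is first-order
and split into hepatic metabolic and renal pathways, either of which may
be zeroed. Saturable metabolism, transporters, and enterohepatic
recirculation are deliberately out of scope.

Dissolved drug moves down the lumen chain by first-order transit
constants, with the large-intestine outflow counted as fecal excretion.
The *intact dosage form* moves differently: a monolithic tablet is
carried between segments at discrete times (default: gastric emptying at
2 h — matching the two-stage protocol's acid-stage duration — then 3 h
small-intestinal and 24 h colonic residence), and the release source term
feeds whichever lumen the form currently occupies. This dual
representation exists because a tablet is not a well-mixed solute; its
location is an event, not a concentration.

The parameterization is exactly 22 scalars (`physiology_parameter_names`),
and the schema is strict in both directions — a 21- or 23-entry set is
rejected. Twenty of them are the volumes, flows, transit constants,
permeability–area products, clearances and the tissue partition factor
listed in `?physiology_spec`; the remaining two are the gastric and
small-intestinal residence times of the intact form, which are genuine
subject/formulation properties on the same footing as the transit
constants. The colonic residence is an argument of `simulate_pbpk()`
(default 24 h) rather than a 23rd parameter.

Numerics: lsoda with rtol 1e-8 / atol 1e-10 mg, with the integration
split into smooth segments at dose start, infusion end, and form-transit
times so no discontinuity crosses a solver step. The bookkeeping states
(unreleased drug, cumulative metabolic/renal/fecal sinks, undelivered
infusion) are integrated alongside, which turns mass conservation into a
checkable identity: the flux laws sum to zero algebraically, and along
any simulated trajectory the total recovered mass stays within 1e-6
(relative) of the dose — in practice at machine precision. The solver
uses a position-indexed copy of the right-hand side for speed; the
readable `pbpk_rhs()` is the reference, and the test suite asserts the
two agree flux for flux.

One emergent property is worth documenting because it looks like a bug
and is not: plasma AUC is *not* globally monotone in the intestinal
permeability PA_si. In the absorption-limited regime (up to the default
2.5 L/h) more permeability means more exposure, but far beyond it the
same passive-diffusion term lets drug secrete back into the lumen and
make extra passes through hepatic extraction, producing a weak
(~0.1%) AUC decline. The monotonicity test therefore covers the
absorption-limited grid.

## 4. Calibration and zero-refit prediction

The workflow that motivates the package has three steps:

1. **Fit** the in-vitro release profile of each formulation
   (`fit_release()`).
2. **Calibrate** the PBPK model once, against the plasma curve of a
   *single* reference formulation (`calibrate_pbpk()`).
3. **Predict** every other formulation with the calibrated parameters
   frozen — only the release model changes (`predict_formulation()`).

Step 3 is the scientific claim: if a physiologically structured model,
anchored by one in-vivo study, predicts the plasma curves of modified
formulations from their dissolution data alone, it does the regulatory
job of a Level A in-vitro/in-vivo correlation while retaining physical
meaning. The package enforces the "no further optimization" clause
mechanically: calibrations carry a fingerprint of their parameter set,
and `predict_formulation()` refuses to run if anything was mutated in
between.

Calibration details, each a deliberate choice:

* **Free set.** Which of the 22 parameters to fit is an explicit input.
  The default four — PA_si, CL_hepatic, Q_tissues, F_unbound_factor —
  are the absorption/disposition parameters least constrained by prior
  physiology. Q_portal and Q_hepatic_out may never be freed directly;
  they follow Q_gics through the flow balance.
* **Weighting.** Residuals are weighted by $1/\max(C_{obs},
  0.01\,C_{max})$: plasma curves span an order of magnitude, so relative
  weighting is appropriate, and the floor keeps near-zero samples from
  dominating.
* **Multi-start.** Five log-spaced candidate starts per free dimension
  (full factorial, thinned deterministically to at most 32), every
  candidate screened by its initial objective, and the best eight
  refined by Levenberg–Marquardt in log-parameter space within
  ×/÷10 bounds around the template. Screening-then-refining keeps a
  four-parameter calibration around a minute on one CPU without
  surrendering the global search; the procedure contains no random
  numbers, so a calibration is exactly reproducible.
* **Identifiability guard.** More free parameters than observations is
  refused up front.

Non-compartmental metrics (`nca_metrics()`) follow standard practice:
linear-up/log-down trapezoids, terminal slope from a log-linear fit on
the final run of at least three descending positive points, and a refusal
flag when the extrapolated tail exceeds 20% of AUC₀–∞.

## 5. The synthetic study: what it does and does not show

No machine-readable experimental datasets exist for the study this
package emulates, so `synthetic_study()` generates the whole design with
known ground truth: three 100 mg formulations ("fast", τ = 1.5 h;
"medium", τ = 3 h; "slow", τ = 6 h; all Weibull with β = 1.6, strictly
ordered by time-to-50%-release), plasma curves produced by the default
physiology — a realistic adult with high first-pass extraction, emulating
a calcium-channel-blocker-like oral drug — and multiplicative log-normal
noise (σ = 0.05, about 5% relative error, the conventional figure for
both dissolution and bioanalytical assays; multiplicative because both
measurements are positive with roughly constant CV). Every draw comes
from the mandatory seed through one task-keyed generator, so fixtures are
bit-reproducible and generation does not disturb the caller's RNG stream.

Problem sizes used by the standing tests: 12-point dissolution grids over
12 h, 15-point plasma grids over 24 h, 50-replicate round-trip checks for
release-parameter recovery (median |relative error| of τ and β within
10%), and the full workflow replay — calibrate four parameters on noisy
"medium", then predict "fast" and "slow" with no refit — achieving
parameter recovery within 15% and Cmax/AUC prediction errors well inside
±15%, the working accuracy band of Level A correlation practice.

What passing these tests does **not** show: that the model predicts real
humans. The generator draws from the same model family the calibrator
fits, so the exercise demonstrates identifiability, numerical
correctness, and workflow integrity — not structural adequacy. Real data
bring inter-subject variability, absorption windows, saturable
first-pass, and release mechanisms the pH-gate does not capture; all are
out of scope here and the package makes no claim about them.

## 6. Known limitations

* Chemistry is limited to strong acids/bases plus one polyprotic buffer
  family; no CO₂ absorption, no ionic-strength-dependent solubility, no
  general geochemical speciation.
* The pH-gated tablet is a threshold mechanism, not a coat-dissolution
  model.
* The PBPK model has no enterohepatic recirculation, no saturable
  metabolism, no active transport, and no population variability; it is
  a single-subject, mean-behavior model.
* Calibration is least squares with box bounds — no posterior, no
  uncertainty intervals beyond the fit diagnostics.
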