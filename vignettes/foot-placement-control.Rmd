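---
title: "Inferring feedforward-feedback foot placement control from locomotor variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring feedforward-feedback foot placement control from locomotor variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Legged animals walk stably despite continuous sensorimotor noise. Two
control structures could explain this. A *feedforward-only* controller
maps locomotor speed (and heading) onto a stereotyped, velocity-dependent
gait pattern, and relies on the body's passive mechanics to absorb
perturbations. A *feedforward-feedback* controller additionally monitors
deviations of the body state from the velocity-conditioned nominal
pattern and corrects them by adjusting where the next foot lands.
`stablegait` implements a data-driven pipeline that discriminates between
the two from nothing but planar marker trajectories of the body and feet
during natural walking, and a stochastic walker simulator that generates
such trajectories from a *known* control structure, so every stage of the
inference can be validated against ground truth.

## The model

For each leg, a gait cycle runs between two successive contact
initiations of that leg; the gait fraction $\phi \in [0,1]$ is elapsed
time over cycle duration. With $\hat v$ the mean fore-aft body velocity
over the cycle, the observed placement decomposes as

$$P = f(\hat v) + g(\Delta Q(\phi)),$$

where the feedforward part $f$ comprises a linear step length law
$f^x(\hat v)=\beta_0^x+\beta_1^x\hat v$, a linear (in practice flat)
step width law, and an exponential cycle-duration law
$f^t(\hat v)=\beta_0^t e^{-\beta_1^t(\hat v-\beta_2^t)}+\beta_3^t$; and
the feedback part is a linear map from the phase-resolved body-state
error $\Delta Q(\phi) = Q(\phi) - Q^*_{\hat v}(\phi)$ (positions *and*
velocities of the body markers, both planar coordinates) to the
placement deviation $\Delta P = P - f(\hat v)$:

$$\Delta P \approx \gamma_0 + \sum_{i=1}^{N} \gamma_i \,\Delta Q_i(\phi).$$

The nominal pattern $Q^*_{\hat v}(\phi)$ is fitted per animal, per leg,
per phase by regressing each state channel on $\hat v$ with an
intercept, so errors are deviations from the *velocity-conditioned*
pattern, not from average behavior. A baseline model with the swinging
foot's own kinematic deviations $\Delta\tilde Q(\phi)$ as predictors
controls for information already contained in the foot trajectory: as
$\phi \to 1$ the foot *is* at its placement, so the baseline explained
variance tends to 1 by geometry, and any body-state advantage must
appear earlier, before swing onset, to count as evidence of feedback.

Downstream of the fits, the pipeline quantifies:

* **control magnitude** — per animal, the maximum over phases of
  $R^2_{\text{body}} - R^2_{\text{baseline}}$;
* **stability** — a Poincaré return map $K$ fitted between body-state
  deviations of consecutive cycles sampled at $\phi_0 = 0.75$; spectral
  radius $\rho < 1$ indicates orbital stability;
* **error reduction** — the regression of (mean absolute lateral body
  error in the half-cycle before a contact minus that after it) on the
  magnitude of the lateral placement deviation at that contact; a
  positive slope links placements to subsequent error decay;
* **control timescale** — Pearson correlations between a leg's lateral
  placement deviations $N$ cycles apart decay exponentially; the decay
  constant $\tau$ (in cycles) is fitted by nonlinear least squares with
  a bootstrap CI (resampling bouts, keeping a bout's legs together);
* **modularity** — medial vs lateral errors (toward/away from the
  stance reference foot) are fitted separately, and lag-1 correlations
  are compared across anterior-posterior limb pairs.

All of this is orchestrated by `run_pipeline()`; each stage is also an
exported function.

## The synthetic walker

`simulate_walker()` renders a stochastic walker with two support groups
in antiphase (contralateral feet for a biped, diagonal pairs for a trot,
tripods for a hexapod). Its discrete skeleton is the closed loop

$$\Delta P_n = G\, e_n + \varepsilon_n,\qquad
  e_{n+1} = a\, e_n - G\, e_n + \eta_n,$$

so the cycle-to-cycle coefficient is $\lambda = a - G$: the fitted gain
at swing onset should recover $G$, the return map $\rho \approx
|\lambda|$, and the placement correlations $r(N) \propto \lambda^N$,
i.e. $\tau \approx -1/\ln|\lambda|$. Execution scatter $\varepsilon$
(SD `sigma_foot`) perturbs where the foot lands but not the body
dynamics; body-level noise is $\eta$ (SD `sigma_body`). This separation
is what makes the feedforward-only null ($G=0$) genuinely null: placement
noise then carries no information about, and has no effect on, the body
state.

Two kinematic constraints shaped the generator:

* **Step geometry and timing are linked.** In a world-frame walker with
  alternating support, the same-leg stride must equal the body's advance
  per cycle, $2L(\hat v) = \hat v\, T(\hat v)$. One law is therefore
  primary: by default the linear length law is commanded and duration
  derived (`timing = "from_length"`); `"from_duration"` commands the
  exponential duration law and derives length. Recovery of the
  respective primary law's parameters is part of the test suite.
* **The landing lead is constant.** Feet touch down ahead of the body by
  `duty` times the step length at the *mean* commanded speed. A
  per-cycle lead would leak cycle-to-cycle jumps of the length law into
  the step length measured relative to the opposite group's front limb
  and bias its velocity slope.

The rendered body error is held constant across each gait cycle (eased
over `ramp_frac` of each half-cycle window, default 0.08, so it has
settled well before swing onset), feet are constant during stance and
follow a cosine ease during swing, and i.i.d. Gaussian observation noise
`sigma_obs` is added per frame and marker.

### Defaults as study conditions

The three built-in embodiments define the conditions used throughout the
tests and the acceptance script (species-native units):

| parameter | biped (m) | quadruped (mm) | hexapod (mm) |
|---|---|---|---|
| speed mean / SD | 1.2 / 0.15 | 100 / 15 | 20 / 3.5 |
| length law (b0, b1) | 0.2, 0.4 | 10, 0.3 | 1, 0.08 |
| step width | 0.12 | 25 | 2.5 |
| `sigma_body` | 0.012 | 1.2 | 0.12 |
| `sigma_foot` | 0.003 | 0.3 | 0.03 |
| `sigma_obs` | 0.002 | 0.25 | 0.02 |
| frame rate (Hz) | 100 | 80 | 150 |

Body noise is roughly 10% of step width; execution scatter a quarter of
body noise (placement scatter in real walkers is small relative to
step-to-step body motion, and the placement autocorrelation signature
would otherwise drown); observation noise is at the scale of modern
marker/pose tracking. Speed follows a stationary AR(1) across cycles
with autocorrelation `v_persistence = 0.5`: natural locomotor speed
varies smoothly within a bout rather than jumping independently every
cycle, and the asynchrony between a leg's own cycle and the command
cycle makes independent draws leak into the step-length slope measured
for the half-cycle-shifted support group. Stance fraction `duty = 0.62`
and feedback defaults $a = 0.9$, $G = 0.4$ give the closed-loop
$\lambda = 0.5$ used by the recovery checks. Simulations in the test
suite use 10 individuals of 300 cycles per embodiment (the analysis
scripts use 5 x 150), sizes at which every recovered quantity except the
decay timescale has a relative sampling error of a few percent; the
timescale is intrinsically noisier because it is driven by the tail of
the correlation profile.

## Numerical and statistical choices

* **Contact detection.** The extrema detector works on the *signed*
  fore-aft foot-minus-body displacement (an unsigned distance would make
  touchdown and liftoff the same kind of extremum): touchdown at maxima,
  liftoff at minima, with peak prominence at 10% of the displacement
  range and a minimum spacing of half the running median cycle. Because
  the foot decelerates below body speed before landing, the displacement
  extremum systematically leads touchdown (and lags liftoff); each event
  is therefore snapped to the nearest crossing of a low foot-speed
  threshold (10% of the local swing peak). A velocity-threshold detector
  is provided as an independent method; both agree on clean input.
* **Mean cycle velocity** is net displacement over duration, not an
  average of frame-differenced velocities: frame differentiation at the
  cycle edges smears adjacent cycles' speeds into $\hat v$ and, with
  autocorrelated speed, inflates fitted velocity slopes.
* **The exponential duration law is degenerate** as written
  ($\beta_0$ and $\beta_2$ trade off through $\beta_0 e^{\beta_1\beta_2}$),
  so the identifiable three-parameter reduced form is fitted (multi-start
  Levenberg-Marquardt) and re-expressed with $\beta_2$ anchored at the
  median velocity; the amplitude at the median velocity is reported as
  the identifiable summary. Non-convergence falls back to a smoothing
  spline for deviation computation, flagged.
* **Explained variance is in-sample** (the closed-form normal-equations
  estimator), matching how the feedback map is defined; zero-variance
  predictors are dropped and residual rank deficiency triggers a tiny
  ridge penalty, flagged. When the body-state and baseline models have
  different predictor counts, the per-phase Kolmogorov-Smirnov
  comparison uses dimension-adjusted explained variance so the larger
  model's in-sample optimism cannot masquerade as a feedback signature;
  the reported $R^2$ profiles and the control magnitude keep the raw
  in-sample definition.
* **The return map is fitted forward in time** (next cycle's deviation
  regressed on the current one's) so that eigenvalue moduli below 1 mean
  stability; a backward-direction fit exists behind a flag, and its
  eigenvalues are *not* reciprocals of the forward ones under noise,
  which is why the direction is an explicit choice.
* **Error reduction** uses absolute lateral body error (a reduction must
  be sign-free to regress on $|\Delta P_y|$), computed from consecutive
  same-leg cycle pairs: the half-cycle before the shared contact in the
  first cycle's normalization, the half-cycle after it in the next
  cycle's.
* **The decay fit carries a non-positive additive offset** by default.
  Placement deviations are centered per individual in-sample (the
  intercept and velocity term of the placement law are fitted on the
  same few hundred cycles), which depresses all pooled lagged
  correlations by $O(1/n)$; at 300 cycles per individual this is enough
  to bias the two-parameter fit's timescale visibly downward (verified
  against generator ground truth). The offset can only absorb a
  depression, so it is constrained non-positive, and `offset = FALSE`
  restores the pure two-parameter fit.
* **Chatterjee's xi** is computed with the mid-count tie convention and
  a seeded random tie-break among equal predictor values (restoring the
  caller's RNG state), with the asymptotic right-tailed normal test
  ($\sqrt n\,\xi \to \mathcal N(0, 2/5)$); a seeded permutation option
  exists for small samples or heavy ties. Calibration of the asymptotic
  test at the 5% level is part of the acceptance suite.
* **Delegated tests** (Shapiro-Wilk gate, t/ANOVA vs Wilcoxon /
  Kruskal-Wallis with a hand-rolled Dunn post hoc under FDR correction)
  run through one gateway that records the choice, statistic, p and
  effect size.

## What passing tests do and do not show

The generator emulates the statistical structure the analyses assume:
alternating support groups, linear velocity dependence of step length,
flat width, duration falling with speed, per-step lateral noise with a
linear error-to-placement feedback law, smooth within-bout speed
variation, and tracker-like observation noise. It deliberately omits:
continuous-time body dynamics (the error updates once per cycle),
mechanics (no forces or inertia), nonlinearity of the feedback law,
within-cycle error fluctuation beyond the rendering ramp, curved
locomotion (a curvature option exists only to exercise straightness
selection), and behavioral heterogeneity across individuals. Recovery of
$G$, $\lambda$ and $\tau$ on this generator therefore validates the
*inference machinery* — detection, segmentation, normalization,
regression bookkeeping — not the biological adequacy of the linear
model. Two desk-scale artifacts are worth knowing: before the stance
reference contact (gait fraction < 0.5) the normalized body error mixes
in the previous anchor's deviation, so the body-state advantage is fully
expressed only between the reference contact and swing onset; and the
in-sample velocity-law projection slightly whitens placement deviations,
which is what the offset term in the decay fit compensates.

## Reproducing the study conditions

```{r example}
library(stablegait)

params <- walker_params("hexapod", a = 0.9, gain = 0.4)
sim <- simulate_walker(params, n_cycles = 300, seed = 1)
bout <- align_heading(select_straight_bouts(list(sim$bout))[[1]])
cycles <- build_cycles(list(bout), params$profile, animal = "fly01")
ff <- fit_feedforward(cycles)
dev <- compute_deviations(cycles, ff)

sw <- median(dev$meta$phi_swing)
fit_error_map(dev, sw, "lateral", leg = c("front_left", "front_right"))
fit_return_map(dev, 0.75, leg = "front_left")
fit_decay_timescale(lag_correlation_profile(dev, leg = "front_left"),
                    n_boot = 1000)
```

The numbered scripts under `analysis/` run the full narrative (simulate,
process, feedforward, feedback, stability/timescale, modularity) and
write their tables under `results/`; `scripts/acceptance.R` recomputes
the headline quantities from scratch at the full study size.
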