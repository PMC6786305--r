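---
title: "Reward-driven synaptic sampling in a closed visuomotor loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-driven synaptic sampling in a closed visuomotor loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporenet)
```

## The model

`sporenet` simulates *synaptic sampling with online reinforcement
learning*: instead of converging to a point estimate of the synaptic
parameter vector $\theta$, the network continuously samples from a target
distribution proportional to a prior $p(\theta)$ times the expected
discounted reward $V(\theta)$. Each plastic synapse $i$ carries five state
variables:

* $y_i$ — the pre-synaptic spike train filtered with a
  post-synaptic-potential kernel,
* $e_i$ — an eligibility trace holding a short history of pre/post
  coincidence,
* $g_i$ — a slowly integrated estimate of the reward gradient,
* $\theta_i$ — the sampled synaptic parameter,
* $w_i$ — the synaptic weight actually used by the network.

The fast dynamics are

$$\dot e_i = -\frac{e_i}{\tau_e} + w_i\, y_i\,(z_i^{post} - \rho_i^{post}),
\qquad
\dot g_i = -\frac{g_i}{\tau_g} + r(t)\, e_i,$$

where $z_i^{post}$ is the post-synaptic spike train (unit-area pulses),
$\rho_i^{post}$ the neuron's instantaneous rate, and $r(t) \ge 0$ the one
global reward signal streamed to every synapse. The slow dynamics are the
Euler–Maruyama discretization of

$$d\theta_i = \beta\left(c_p(\mu - \theta_i) + c_g\, g_i\right) dt
 + \sqrt{2 T \beta}\; dW_i,$$

with prior strength $c_p$ (0 = flat prior), prior mean $\mu$, gradient
gain $c_g$, and temperature $T$ controlling exploration. Weights follow
the projection $w_i = w_0 e^{\theta_i - \theta_0}$ for $\theta_i > 0$ and
$w_i = 0$ otherwise, so parameters that drift non-positive correspond to
retracted synapses. With the reward term switched off the slow dynamics
reduce to an Ornstein–Uhlenbeck process with mean $\mu$ and stationary
variance $T/c_p$ — the package's test suite uses exactly this reduction to
verify that the sampler reproduces its target prior.

Integration uses two time grids: the traces advance by forward Euler every
`dt_fast` = 1 ms; parameters and weights advance only every `dt_slow` =
100 ms and weights are strictly constant in between. The learning rate can
be annealed, $\beta(t) = \beta_0 e^{-\lambda \Delta \lfloor t/\Delta
\rfloor}$ with $\Delta$ = 600 s, which shrinks both the drift and the
diffusion and thereby lets sampled policy improvements persist.

## Key parameters

| parameter | meaning | default | unit |
|---|---|---|---|
| `tau_psp` | PSP kernel time constant | 0.02 | s |
| `tau_e` | eligibility time constant | 2 | s |
| `tau_g` | reward-gradient integration time | 50 | s |
| `temperature` | SDE diffusion coefficient | 0.1 | – |
| `beta0` | initial learning rate | 1e-7 | – |
| `lambda_decay` | annealing rate | 8.5e-5 | 1/s |
| `theta_min`, `theta_max` | parameter clip | −2, 5 | – |
| `dtheta_max` | gradient clip at read time | 1 | – |
| `w0`, `theta0` | weight projection | 1, 0 | – |
| `theta_init_mean`, `theta_init_var` | initial parameter Gaussian | 0.8, 0.6 | – |
| `rho0`, `du`, `rho_max` | neuron intensity curve | 10, 20, 500 | Hz, –, Hz |
| `tau_a` | motor activity low-pass | 0.1 | s |
| `tau_r` | reward smoothing | 0.1 | s |

`tau_g` = 50 s is the published integration time of the gradient
estimate; `tau_e` defaults to 2 s, on the order of the tasks' episode
lengths, so that eligibility spans the sensor-to-reward delay without
blurring distinct maneuvers. `c_g`, `dtheta_max`, `w0` and `theta0` are
not published; the defaults ($c_g = 1$, $\Delta\theta_{max} = 1$, $w =
e^\theta$ for $\theta > 0$) keep the reward term and the prior term on
comparable scales and make the weak-weight threshold $w < 0.07$ include
exactly the retracted synapses plus nothing else at initialization.

**Initial parameter distribution.** The published initializer is a
Gaussian "N(0.8, 0.6) clipped at 0". The package reads 0.6 as the
*variance* ($\sigma = \sqrt{0.6} \approx 0.775$). The reading was fixed by
an observable: with $w = e^\theta$, initially weak synapses are exactly
the clipped draws, so the full 23,040-synapse reaching network starts with
$\Phi(-0.8/\sigma) \times 23040$ weak weights — about 3,475 under the
variance reading, within a few percent of the reported initial count,
whereas the standard-deviation reading predicts about 2,100.

## The closed loop

Every millisecond the runner executes: render the scene → event-camera
differencing → spike encoding → network step → fast plasticity traces
(driven by the smoothed global reward) → motor decoding from 100 ms
low-passed activities → environment step → reward. Resets (ball reaching
the target; vehicle leaving the lane) are silent: nothing marks an episode
boundary to the learner.

Neurons are stochastic point processes with intensity $\rho(u) = \rho_0
e^{u/\Delta u}$ capped at $\rho_{max}$, where $u$ sums afferent PSP traces
times weights. $\Delta u$ matters: with the published static weights
(exploration→motor 10.0 acting on a PSP trace of mean ≈ 10) the potentials
reach tens of units, and a small $\Delta u$ parks every motor neuron at
the rate cap, where the decoded command no longer depends on the synaptic
weights and no policy — learned or random — can be expressed. The default
$\Delta u = 20$ was chosen by open-loop operating-point analysis so that
typical potentials sit in the sensitive part of the intensity curve:
motor rates then range over roughly 10–300 Hz in closed loop, and a
frozen-weight network behaves as a genuine random policy that reaches the
target a few times per 250 s.

**Reaching.** A ball (radius 2 m) on a walled 20 m × 20 m plane must move
to the 2 m target disc at the center, observed top-down by a 16 × 16
event camera. Each event spikes its pixel neuron plus one row-axis and one
column-axis neuron. Eight motor neurons sit on a circle; the command is
the population vector of their low-passed activities, scaled by
`velocity_gain` (default 0.5, giving speeds of order 1 m/s on the 20 m
plane — the command scale is not published) and capped at `v_max`. The
reward $r = \tfrac35 r_v (r_\beta + 1)^5$ multiplies a speed term by a
direction term; the printed form is typographically ambiguous and the
package exposes the coefficient and exponent as configuration. The
heading tolerance $\beta_{lim}$ defaults to $\pi/4$ radians and the speed
threshold to 0.1 m/s (both unpublished). An exploration neuron — excited
at 35 Hz, inhibited by pixels (weights drawn from N(−500, 50²)), exciting
every motor neuron with weight 10 — kicks the agent whenever the event
camera falls silent, since a motionless scene produces no input at all.

**Lane following.** A vehicle drives at constant 1 m/s on the right lane
of a closed stadium circuit (two 8 m straights, two semicircles of radius
3 m, lane half-width 0.4 m — the track itself is not published and is
chosen so the reward's 0.1 m halving scale is meaningful), steered through
a kinematic bicycle model (wheelbase 0.3 m) by five discrete angles {−30,
−15, 0, 15, 30}°. The 128 × 32 forward view is pooled into 16 × 4 visual
neurons, one per 8 × 8 window, firing at `rate_gain` (10 Hz) per event in
the window. Steering is decoded from the left/right population ratio
$(a_L - a_R)/(a_L + a_R)$; since the published decision boundaries
{−10, −2.5, 2.5, 10} exceed the raw ratio's range, the ratio is expressed
on a ×100 (percent) scale before the boundary lookup. Boundaries map
half-open from the left (a ratio exactly on a boundary takes the milder
command); a silent motor layer steers straight. The sign convention
(dominant left population → left turn) is configurable and behaviorally
immaterial, because the two populations are unlabeled at initialization.
The reward $e^{-0.03\beta_{err}^2} e^{-70 d_{err}^2}$ uses the angular
error in *degrees* — that is the only unit under which the published
constants halve the score per 5° or 0.1 m.

## Numerical choices

* PSP filtering is a single exponential ($\tau_{psp}$ = 20 ms) with a unit
  jump per spike, integrated by forward Euler to match the synapse
  model's discretization; the motor-activity and reward filters use exact
  exponential decay factors, as their time constants are the decoders'
  definition rather than part of the SDE scheme.
* A spike inside a 1 ms step contributes area 1 to the eligibility
  update (an indicator, not indicator/dt), making the spike term and the
  rate term $\rho\,dt$ commensurate.
* The gradient estimate is clipped to $\pm\Delta\theta_{max}$ when read by
  a parameter update; the stored trace is untouched.
* The event camera thresholds linear intensity differences (default 0.1)
  against a per-pixel reference that resets only where an event fired, and
  emits at most one event per pixel per frame.
* Nearest-centerline queries warm-start from the previous match with a
  ±80-point window, which also serves as the arc-length tie-break between
  track branches.
* Every stochastic draw flows through R's global RNG in one documented
  order per step (noise source, exploration neuron, motor neurons;
  parameter noise in column-major synapse order), so runs are exactly
  reproducible from one seed, and the compiled engine reproduces the
  pure-R reference loop to floating-point noise. The pure-R loop is
  composed from the exported per-operation functions and acts as the
  oracle for the compiled path in the test suite.

## What the synthetic environments do and do not show

The environments emulate the *structure* of the original robotic setup —
event-driven vision that only senses change, silent resets, continuous
reward, population decoding — with procedural rendering and first-order
kinematics. They deliberately omit: sensor noise and refractory pixels of
a real event camera, vehicle and ball inertia, collision dynamics beyond
wall clamping, rendering artifacts, and transport delays between
simulator processes. Passing tests therefore show that the plasticity
rule's dynamics (prior sampling, gradient following, annealing,
sparsification) behave correctly in a faithful closed loop at desk scale;
they do not certify performance numbers on physical robots or full-scale
multi-hour experiments.

Problem sizes were scaled for a single CPU: the learning studies use an
8 × 8 sensor, 4 motor neurons and multiplicity 2 (640 plastic synapses)
with the learning rate raised to $10^{-3}$, 1800 simulated seconds and
seven seeds per condition, against a frozen-weight ($\beta_0 = 0$)
baseline; the stationary-distribution check uses 100 synapses over $10^6$
slow steps; the integration-accuracy check compares 10 s of the 1 ms
scheme against a 0.01 ms reference. The full-size networks (23,040 and
512 plastic synapses) are built and checked structurally, and the runner
supports full-scale simulations; multi-hour learning curves are outside
the test suite by design.

## Known limitations

* The reward-gradient estimate is high-variance and heavy-tailed (it is a
  50 s average of reward × eligibility products; roughly half of the
  synapses in a learning run sit beyond the ±1 gradient clip at any
  moment), and no baseline subtraction is implemented (matching the
  modeled rule). Desk-scale learning effects are therefore small relative
  to seed-to-seed noise: over 30 simulated minutes, learning first
  *degrades* the dense random policy (parameter diffusion retracts
  synapses faster than the gradient rebuilds them) and the reach-rate gain
  appears only in the final windows, at about one standard error over ten
  seeds. The direction of the gradient was validated separately with a
  controlled reward tied to a single motor neuron, which reliably
  strengthens exactly that neuron's afferent synapses.
* Temperature is annealed only implicitly through $\beta$; a separate
  temperature schedule is not implemented.
* Only the discrete steering variant of the lane task is provided.
* Annealing retention is verified mechanistically at desk scale: at a
  matched mean exploration budget the annealed run's late weight drift is
  roughly half the constant-rate run's, but the downstream reduction in
  late *reward* dispersion is smaller than seed-to-seed noise in 30-minute
  runs (measured medians were equal over five seeds); resolving the
  behavioral effect needs full-scale multi-hour runs.
* The point-process neuron has no refractory period; at the rate cap the
  Bernoulli-per-step approximation saturates at one spike per
  millisecond.

## A short run

```{r, eval = FALSE}
setup <- reduced_reaching_setup()
run <- run_experiment("reaching", duration = 60, seed = 1,
                      spore = setup$spore, net = setup$net,
                      env = setup$env, record_dt = 0.1)
summary(run)
plot(run)
policy <- policy_map(run)
head(policy)
```
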