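---
title: "Adaptation versus learning in a simulated BCI center-out task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptation versus learning in a simulated BCI center-out task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcimanifold)
```

## The question

When a motor task is perturbed — here, by rotating the mapping between
neural activity and a cursor — proficiency can be recovered by two very
different mechanisms. An *adapting* controller re-purposes its existing
activity repertoire: to counter a rotation by $\theta$ it simply produces
the activity that previously drove movement at $-\theta$ relative to the
goal. A *learning* controller changes its internal connectivity and
generates genuinely new activity patterns. Both strategies can yield nearly
identical cursor trajectories, so behaviour alone cannot distinguish them.
Population activity can: under adaptation, the low-dimensional manifold
that captures most activity variance is preserved, and activity merely
rotates within it; under learning, the manifold itself (its mean and
principal axes) moves.

This package builds both kinds of controller over the same center-out
task and provides the manifold statistics that tell them apart.

## The closed-loop BCI simulator

### Population model

Real motor-cortical recordings are replaced by a cosine-tuned Poisson
population (`make_tuning()`): unit $i$ fires at

$$r_i = b_i + m_i\, g\, s\, \cos(\phi - \mathrm{pd}_i)$$

where $\phi$ and $s$ are the intended movement direction and speed. This
is the minimal population model compatible with the decoder's linear
observation equation: the rate is exactly linear in the intended velocity,
$r_i = b_i + m_i g\, (v \cdot u_i)$ with $u_i$ the unit vector along the
preferred direction. Defaults: 40 units (a realistic array yield),
baselines uniform on 5–25 Hz, modulation depths on 5–15 Hz, speed gain
$g = 0.1$ with intended speed 6 units/s, counts in 100 ms bins. Baselines
are raised where needed so rates are non-negative at all intents up to the
maximum speed. These choices give enough signal-to-noise for proficient
baseline control (~2 s reaches) without being unrealistically clean.
What this generator deliberately omits: spike-train temporal structure
(refractoriness, bursting), unit instability across sessions, and any
heterogeneity beyond cosine tuning. Passing tests therefore demonstrate
properties of the analysis pipeline under an idealized encoder, not
conclusions about any particular recorded dataset.

### Decoder

The cursor state $x = (p_x, p_y, v_x, v_y, 1)$ follows a steady-state
Kalman filter: a kinematics prior $\tilde A$ (position integrates velocity
over the bin; velocity persists with damping $\alpha = 0.8$; the constant
carries through), an observation model $y = Cx + q$ fit by least squares
on passive-observation data (straight prescribed reaches to each target),
process noise $W$ on the velocity components only, and the steady-state
gain $K$ from the discrete Riccati recursion (initialized at $\Sigma_0 = W$,
Frobenius tolerance $10^{-10}$, capped at $10^5$ iterations; non-convergence
is an error, never silently accepted). The closed-loop update is
$x_{t+1} = A x_t + K y_t$ with $A = (I - KC)\tilde A$, and a visuomotor
rotation multiplies the gain by a block-diagonal rotation of the position
and velocity blocks: $x_{t+1} = A x_t + R_5(\theta) K y_t$.

One numerical choice matters enough to call out. The gain is applied to
**mean-centered** counts ($y - y_0$, with $y_0$ the mean calibration
count, stored in the fitted model). With raw counts, the unrotated filter
is self-consistent — the constant column of $A$ exactly cancels the gain's
response $K c_0$ to the baseline pattern — but rotating the full gain
output rotates that baseline term too, leaving a constant velocity bias
$(R(\theta) - I) K c_0$ that no directional strategy can compensate.
Centering makes the rotation act on the movement-coding part of the
activity, which is what the perturbation is meant to do, and is standard
practice in closed-loop Kalman decoders. (`fit_kalman_decoder(...,
center_observations = FALSE)` restores the raw-count behaviour for
study.)

### Task and adapting agent

Eight targets at 45° separation, distance 10, acceptance radius 1.5, a
2-bin hold, and a 100-bin (10 s) timeout; these values are not dictated by
the model and were chosen once so baseline reaches take roughly 1–3 s.
The agent is a feedback controller: each bin it aims from the current
cursor position toward the target at constant speed, re-aimed by
$-f\theta$ where $f$ is the compensation fraction (`adaptation_policy()`).
With $f = 1$ the rotated decoder output lands back on the target
direction; with $f = 0$ the rotation is uncompensated, reaches curl by
$\approx \theta$, and for $|\theta| \ge 90°$ the radial velocity component
vanishes or reverses and control collapses — the simulator reproduces both
regimes. No inter-trial interval or gradual trial-by-trial learning curve
is modelled: sessions represent the post-compensation steady state that
the analysis operates on.

## The reinforcement-learning agent

The virtual center-out environment uses dimensionless steps:
$v_{t+1} = 0.1\,v_t + a_t$, $x_{t+1} = x_t + \Delta t\, v_{t+1}$ with
$\Delta t = 1$, and reward $-0.5\,\Delta d - |a|^2$ per step plus $+20$ on
reaching the target. The position update uses the *post-action* velocity,
so an action affects the same step's distance change — the convention the
reward definition implies; a config flag switches to the pre-action
velocity. Rotated environments multiply the executed action by
$R(\theta)$. The observation vector is (position, velocity, target −
position), with position-like entries scaled by the target distance;
actions are clipped to magnitude 5. Episode cap is 100 steps.

The agent is trained with proximal policy optimization implemented
directly in the package (clipped surrogate, GAE($\lambda = 0.95$),
discount 0.99, rollouts of 2048, 10 epochs of minibatch 64, Adam at
3e-4, gradient-norm clip 0.5) with separate policy and value networks of
two 128-unit tanh layers. Training to a ≥95 % deterministic success rate
takes well under 100k environment steps. Retraining in a rotated
environment restores the policy's exploration standard deviation to its
initial value first: by the end of baseline training the Gaussian
policy's noise has annealed to $\sigma \approx e^{-2.8}$, and a
near-deterministic policy cannot discover an action mapping whose
required corrections point the other way (at $\theta = 110°$, retraining
without the reset fails outright). The manifold analysis consumes the
post-nonlinearity activations of the *second hidden layer of the policy
network*, recorded during deterministic rollouts of successful episodes.

## Manifold statistics

All analyses run on a units × observations matrix (spike counts per bin,
or 128 activations per step), by default movement-epoch bins of
successful trials. PCA is a mean-centered SVD; two components are kept
because the task is two-dimensional. Component signs follow the
largest-loading-positive rule.

* **Centroid geometry.** Per-target means of PC1–PC2 scores; angles via
  `atan2`. Gaps between angularly adjacent centroids sum to 360° by
  construction, so their pooled mean is 45° whenever all eight centroids
  are distinct — the informative quantities are the spread and the
  preservation of cyclic order (the task isomorphism).
* **Angular displacement.** Before/after centroids share one PCA basis.
  Because an SVD plane has arbitrary handedness, a reflected basis would
  flip every displacement's sign; the plane is therefore oriented so the
  *baseline* centroids run counter-clockwise in target order before
  displacement is measured. Displacements are circular differences in
  (−180°, 180°], averaged with the circular mean (an arithmetic mean
  would be corrupted near ±180°). The per-rotation means are regressed
  on $\theta$ by ordinary least squares; exact compensation gives slope
  −1.
* **Manifold preservation.** PCA fit separately before and after the
  perturbation; the absolute cosine similarity compares the mean-activity
  vectors and the first two principal components scaled by their singular
  values (the scaling is recorded for completeness — it cannot change a
  cosine). Normalized per-unit differences
  $d_i = (\bar f_{b,i} - \bar f_{r,i}) / \bigl(\tfrac1N \sum_j \bar f_{b,j}\bigr)$
  summarize mean-activity change; both mean $|d_i|$ and mean $d_i$ are
  reported (the default summary is mean $|d_i|$), and the same formula is
  applied elementwise to the absolute loadings of the scaled components,
  an extension flagged in the output rather than silently mixed in.
  Group differences are assessed by one-way ANOVA.

## Orchestration and reproducibility

`validate_config()` normalizes a flat config (rotations given as 0–360°
are folded to signed degrees, e.g. 310° → −50°), checks ranges, and
derives per-stage seeds from one master seed. `run_experiment()` executes
the three stages (baseline gap distribution, adapting-agent rotation
series, RL rotation series), writes results JSON, tidy CSVs, and an
md5-checksummed manifest, and skips stages whose outputs already exist
under the same config hash. All randomness flows through explicit seeds;
two runs from the same config are identical.

Default problem sizes used by the shipped analyses: 10 baseline sessions
and 3 sessions per rotation at 20 trials per target for the adapting
agent; 100k baseline and 50k per-rotation retraining steps with 20
episodes per target for the RL agent in the packaged checks (the
`run_experiment()` defaults are higher, 300k/150k). These sizes give
stable statistics — the displacement regression's $R^2$ exceeds 0.999 —
while keeping a full run in minutes on one CPU.

## Known limitations

* The synthetic population is stationary and perfectly cosine-tuned; real
  recordings drift, and their tuning is neither perfectly cosine nor
  noise-free in the Poisson sense.
* The adapting agent implements pure re-aiming with a fixed speed; it
  cannot model partial, gradual, or speed-dependent compensation dynamics
  (a compensation fraction below 1 is supported, but its time course is
  not).
* The RL agent's displacement slope and similarity values depend on the
  training trajectory (seed, budgets); only their qualitative contrast
  with the adapting agent is stable.
* Shared-basis mode makes principal-component similarities trivially 1;
  it exists for the displacement analysis, not for manifold-preservation
  claims.
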