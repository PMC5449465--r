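---
title: "State-dependent decoding for a bidirectional brain-machine interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-dependent decoding for a bidirectional brain-machine interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdbmi)
```

## The problem

A bidirectional brain-machine interface (BMI) encodes the position of a
simulated point mass as one of four intracortical microstimulation (ICMS)
patterns delivered to somatosensory cortex, records the evoked response in
motor cortex, decodes from it which pattern was delivered, and converts the
decoded posterior into a force that drives the mass toward a central
target. The decoding step is the bottleneck: cortical responses to
identical stimulation vary strongly from trial to trial, and a large share
of that variability is not sensor noise but *state dependence* — the
response rides on endogenous, stimulus-independent fluctuations of network
excitability ("cortical state"). A decoder that estimates the current state
from ongoing activity recorded *before* the stimulus can discount the
state-induced component of the response and recover stimulus information
that a state-blind decoder cannot.

`sdbmi` implements this complete loop as tested, reproducible code: a
synthetic spike-session generator with an explicit latent state, an
adaptive spike-binning layer, the PCA + multiclass-LDA decoder with
winner-take-all (WTA) posterior thresholding under leave-one-out (LOO)
cross-validation, confusion-matrix mutual information with shuffle bias
correction, and the closed-loop point-mass simulator with its trajectory
metric suite.

## The decoder

For each trial $m$ with stimulus $s_m \in \{1,\dots,4\}$, spikes of the
$N$ units are binned into a pre-stimulus count matrix
$\Theta^m \in \mathbb{N}^{N \times T_\theta}$ and a post-stimulus response
matrix $R^m \in \mathbb{N}^{N \times T_r}$. Three feature variants are
built by flattening these matrices unit by unit:

* **SI** (state-independent): the response only, $a^m = \mathrm{vec}(R^m)$,
  $F = N T_r$ features;
* **SD-TA** (state-dependent, time-averaged): one time-averaged
  pre-stimulus activity value per unit prepended to the response,
  $F = N(1 + T_r)$;
* **SD-TD** (state-dependent, time-dependent): the full pre-stimulus time
  course prepended, $F = N(T_\theta + T_r)$.

The $M \times F$ trial-by-feature matrix is centered and reduced to its
first $k$ principal components; a multiclass linear discriminant with a
pooled, lightly regularized covariance is fit on the scores, and Bayes'
rule yields a posterior $P(s_d \mid a^m)$ over the four stimuli. If the
largest posterior exceeds a threshold $P_{thr}$ the vector is replaced by
a one-hot vector at its argmax (WTA); otherwise it is left soft. The
decoded force is the posterior-weighted sum of the four region forces,
$F_{dec} = \sum_d \tilde P(s_d \mid a^m) F_d$, so it always lies in their
convex hull.

Performance is the mutual information of the soft confusion matrix
$Q(s_d \mid s_i)$ (mean thresholded posterior over the trials of each
presented stimulus), $I(S;D) = \sum_{d,i} P(s_i) Q(s_d|s_i)
\log_2 [Q(s_d|s_i) / Q(s_d)]$, between 0 and 2 bits for four equiprobable
patterns. Because $Q$ is estimated from finitely many trials this
information is biased upward; the bias is estimated by rerunning the whole
LOO pipeline on label-permuted data and subtracting the mean shuffled
information. Negative corrected values are reported as-is, since clipping
would bias averages across sessions.

Everything is cross-validated leave-one-out: the PCA and the LDA are refit
on the other $M-1$ trials for every decoded trial, so no information leaks
from the test trial. The hyperparameters ($P_{thr}$, $k$, feature variant,
SUA/MUA signal, $T_\theta$, $T_r$) can in turn be optimized by a nested
LOO over the training trials (`optimize_parameters()`), with deterministic
tie-breaking.

### Numerical choices

* **Leave-one-out cost.** Per fold the PCA is solved exactly in whichever
  space is cheaper — the $F \times F$ scatter or the $(M-1) \times (M-1)$
  Gram matrix; both give identical posteriors because LDA with an isotropic
  regularization target is invariant to orthonormal rotations of score
  space. The per-fold scores do not depend on the labels, so the shuffle
  bias correction computes them once and refits only the (cheap)
  discriminant stage per permutation; this is exactly equivalent to
  rerunning the full pipeline per shuffle and is verified by a test.
* **Covariance regularization.** The pooled covariance on $k$ scores is
  shrunk toward the scaled identity with a *small fixed* coefficient
  ($\gamma = 0.01$). The pooled covariance carries the decoder's
  state-discounting ability — the pre/post correlations are what allow the
  discriminant to subtract state-induced variability — so data-driven
  shrinkage coefficients are unsuitable here: in PCA score space their
  estimated intensity saturates at 1 (the eigenvalue dispersion is
  comparable to its own sampling noise), which collapses the discriminant
  to a nearest-mean rule and silently disables state discounting. A 1%
  shrinkage keeps the estimate invertible at full PCA rank while changing
  well-determined directions negligibly.
* **Time-averaged state feature.** The SD-TA pre-stimulus feature is the
  total spike count over the pre-stimulus window (the duration-weighted
  mean rate times the window length). This is invariant to the bin
  partition and, importantly, lives on the same count scale as the
  response features: a per-bin average over 39 bins would be ~40 times
  smaller, carry ~1600 times less variance, and be discarded by the
  variance-ranked PCA step for any realistic $k$ — silently reducing SD-TA
  to SI.
* **Ties and degeneracies.** WTA argmax ties break toward the lowest
  stimulus index; a LOO fold whose training set loses a class entirely
  falls back to the empirical priors with a warning; $k$ larger than a
  fold's rank is capped at that rank; $0 \log 0 = 0$ in the information
  sum.

## The synthetic sessions

No recordings ship with the package; the generator produces sessions with
the statistical structure the method assumes, and its defaults are the
study conditions used by the tests and the acceptance script.

* **Latent state.** One scalar excitability trace $x(t)$ per trial: an
  Ornstein-Uhlenbeck process (decorrelation time 0.85 s, exact
  discretization) carrying 85% of the variance plus a random-phase
  sinusoid at a frequency drawn uniformly in 1-4 Hz carrying 15%, giving a
  zero-mean, unit-variance stationary trace. The timescale sits at the
  slow end of "a few hundred milliseconds" deliberately: what a *linear*
  decoder can exploit is bounded by the correlation between the
  pre-stimulus trace and the state during the response window, a gap of
  roughly 100 ms; a much shorter timescale makes the pre-stimulus window
  uninformative about the response-window state, and a fast oscillation
  with random per-trial frequency behaves, for linear prediction, like an
  extra fast-decorrelating component — which is why the oscillatory share
  is kept small.
* **Stimulation patterns.** Each unit has a preferred pattern (cycling
  across units) with a mild tuning falloff (0.85 per step of circular
  pattern distance), and the four patterns differ in overall stimulation
  efficacy (total-drive factors 0.4 / 0.75 / 1.2 / 1.8). Responses decay
  exponentially (40 ms constant) from the end of the 30 ms artifact blank.
  Class information therefore lives substantially in the *overall response
  amplitude*, as well as in the milder per-unit pattern differences.
* **State coupling.** The state acts additively on rates in two ways:
  (i) on ongoing activity, $g\,x(t)\,s_n$, with per-unit scales $s_n$
  drawn log-normally (median = baseline rate) — this is what makes the
  pre-stimulus window informative about the state; and (ii) on the evoked
  response, where excitability additively gates each unit's overall evoked
  drive (its mean template across patterns) with the same post-stimulus
  time course as the response. The second term is the scientifically
  load-bearing one: it makes a high-excitability trial look like a
  stronger stimulation and a low-excitability trial like a weaker one,
  exactly confounding the state with the class-informative amplitude axis
  *within* the response window, while the pre-stimulus window — which sees
  the state directly — disambiguates. Both couplings scale with
  `state_coupling`, so `state_coupling = 0` is a completely state-free
  session.
* **Why this structure and not a plain flat additive term.** A
  window-constant additive offset with state-independent unit weights is
  *self-correcting* for an optimal linear decoder: the response window
  itself estimates the offset (through the noise correlations it induces)
  at least as well as the pre-stimulus window can predict it across the
  ~100 ms gap, so pre-stimulus features add nothing and the three variants
  tie. Conversely, purely multiplicative gain modulation is invisible to a
  pooled-covariance LDA, whose regression slopes are class-independent.
  The additive evoked-gate used here is the regime in which state
  knowledge genuinely helps a linear decoder: it is large (no conflict
  with the non-negativity of rates, because it rides on the response
  rather than the baseline), aligned with a class-informative axis, and
  linear in $x$.
* **Slow drift.** Evoked amplitudes grow linearly by +20.5% from the first
  to the last trial of a session, a realistic source of slow
  non-stationarity. The closed-loop oracle emits at the session-average
  drift factor by default.
* **Calibration.** With 10 units and 50 trials per pattern, the defaults
  put the state-independent decoder at roughly 0.85-0.95 corrected bits
  (mid-range), with SD-TA above it and SD-TD above both; they were
  calibrated once to that operating point and then frozen.
* **What the generator does not emulate.** Spike sorting errors,
  refractoriness and spike-history dependence, inter-unit correlations
  beyond the single shared state, multi-dimensional states,
  stimulation-evoked oscillatory reverberation, and any stimulus-to-state
  coupling (habituation). Passing tests therefore show that the pipeline
  recovers state-dependent structure *of the assumed form*; they do not
  certify performance on real recordings.

## The closed loop

The workspace is a 36 x 36 cm plane split into four quadrant regions
(1 = upper-right, counterclockwise), with a force vector of magnitude
0.008 N at each quadrant centroid pointing at the central target disc, and
eight symmetric start positions at 14 cm (axes) and 10 cm (diagonals).
The point mass (20 g) moves in a viscous medium (b = 0.4 N s/m) with the
exact exponential solution of $m\dot v = F - b v$ over each 0.5 s step —
an overdamped regime in which a step at terminal velocity covers ~1 cm, so
an ideal decoder needs ~20-40 of the 100 allowed steps from any start.
These constants are package choices (the loop's calibration invariant —
ideal-decoder convergence from every start for any target radius
$\geq$ 0.5 cm — is enforced by a test) and all of them are
config-overridable.

Per step: the encoder maps the position to a stimulus (half-open axis
convention, origin to region 1), a stateful oracle emits one synthetic
trial — its latent state evolves *continuously* across steps, with no
reset, so state-dependent decoders can exploit it inside the loop — the
trial is binned and decoded, the thresholded posterior weights the region
forces, and the dynamics advance. Walls clamp the position and zero the
inward velocity component. Non-converging trajectories stop at exactly
100 steps.

Metrics: convergence rate (%), mean steps of converging trajectories,
closest approach to the target per trajectory (mm), directive force
(signed component of the decoded force toward the target), and the
within-trajectory variance $wtv = \sqrt{C_x^2 + C_y^2}$, where $C_x$ and
$C_y$ are the variances of the per-step displacement components pooled
over the trajectories of one start position. The $wtv$ formula is
typographically ambiguous in its source; the root-sum-of-squares reading
is used, isolated in `within_trajectory_variance()`, and any monotone
variant preserves ordering claims.

A known limitation, documented rather than hidden: $wtv$ rewards *soft*
force readouts. A decoder whose posteriors are nearly one-hot emits forces
from the discrete set $\{F_1,\dots,F_4\}$ and zigzags at region
boundaries, while a decoder with softer posteriors blends adjacent forces
and moves more smoothly. High-dimensional discriminants are systematically
sharper (their Mahalanobis contrasts grow with $k$), so the SD-TD decoder
can show a *larger* $wtv$ than the SI decoder even when it decodes more
information and reaches the target in fewer steps. The within-loop
comparisons in the acceptance suite should be read with this in mind.

## Problem sizes

The shipped tests and the acceptance script use sessions of 10 units with
50 trials per pattern (offline information) and
100 trials per pattern for closed-loop decoder training; 20 replicate
seeds for offline orderings and null calibration (50 label shuffles), 20
shuffles per corrected-information estimate elsewhere; and closed-loop
protocols of 8 starts with 10-20 repetitions at a 1 cm target radius.
These sizes were chosen as the smallest at which the orderings of interest
are stable across seeds.

## A minimal session

```{r example, eval = FALSE}
params <- sim_params(n_trials_per_stimulus = 50, seed = 1)
session <- generate_session(params)
schedule <- make_default_schedule(0.75, 0.1, 0.03)

datasets <- lapply(c(SI = "SI", `SD-TA` = "SD-TA", `SD-TD` = "SD-TD"),
                   function(v) assemble_dataset(session, schedule, v))
ks <- c(SI = 48, `SD-TA` = 58, `SD-TD` = 150)
for (v in names(datasets)) {
  print(shuffle_bias_correct(datasets[[v]], k = ks[[v]], n_shuffles = 20,
                             seed = 1))
}

decoder <- sd_decoder(datasets[["SD-TD"]], k = 150, p_thr = 0.7)
ws <- bmi_workspace(r_target = 1)
protocol <- run_session_protocol(ws, decoder, schedule, params,
                                 reps_per_start = 10, seed = 1,
                                 scales = session$meta$scales)
print(protocol$metrics)
```
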