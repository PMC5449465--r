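# sdbmi — state-dependent decoding for a bidirectional brain-machine interface

Cortical responses to identical stimulation vary strongly from trial to
trial, and much of that variability is *state dependence*: the evoked
response rides on endogenous fluctuations of network excitability that are
visible in the ongoing activity recorded just before the stimulus. `sdbmi`
implements and evaluates decoders that exploit this: alongside a standard
state-independent decoder (SI) it fits state-dependent decoders that add
either the time-averaged pre-stimulus activity (SD-TA) or its full time
course (SD-TD) to the feature set, and measures how much stimulus
information and closed-loop control performance the state knowledge buys.

The package is aimed at computational neuroscientists studying
state-dependent neural coding and closed-loop bidirectional BMIs. It
provides, as tested R code:

* a **synthetic spike-session generator** with an explicit latent
  excitability process (Ornstein–Uhlenbeck plus a 1–4 Hz oscillatory
  component) that additively modulates ongoing rates and evoked responses,
  four ICMS-like stimulation patterns, a 30 ms artifact blank, and a slow
  (+20.5%) within-session drift of evoked rates;
* the **binning layer**: a 39-bin adaptive pre-stimulus schedule
  (coarse-to-fine toward onset, 9×50 ms + 10×20 ms + 20×5 ms over 0.75 s),
  uniform 5 ms post-stimulus bins, single-unit or pooled multi-unit
  counts, and the SI / SD-TA / SD-TD feature variants;
* the **decoder**: PCA to `k` components, multiclass LDA with a pooled
  regularized covariance, winner-take-all posterior thresholding at
  `P_thr`, leave-one-out cross-validation with per-fold refits, and nested
  hyperparameter optimization;
* the **evaluation**: soft confusion matrices `Q(decoded | presented)`,
  mutual information `I(S;D) = Σ P(s_i) Q(s_d|s_i) log2 Q(s_d|s_i)/Q(s_d)`
  in bits with shuffle-based bias correction, a state-only-information
  control, and the angular error of the decoded force;
* the **closed loop**: a 36 × 36 cm workspace with four quadrant force
  fields pointing at a central target, exact exponential point-mass
  dynamics in a viscous medium, a stateful neural oracle whose latent
  state evolves continuously across steps, and the trajectory metric suite
  (convergence rate, steps to target, closest approach, directive force,
  within-trajectory variance).

The methods vignette (`vignettes/state-dependent-decoding.Rmd`) describes
the model, every tunable constant, and the design decisions in detail.

## Worked example

Generate a synthetic session at the package's study conditions, decode it
with the state-independent and the full state-dependent decoder, and run
the closed loop:

```r
library(sdbmi)

params   <- sim_params(n_trials_per_stimulus = 50, seed = 1)
session  <- generate_session(params)
schedule <- make_default_schedule(0.75, 0.1, 0.03)

si <- assemble_dataset(session, schedule, "SI")
td <- assemble_dataset(session, schedule, "SD-TD")
shuffle_bias_correct(si, k = 48,  n_shuffles = 20, seed = 1)
shuffle_bias_correct(td, k = 150, n_shuffles = 20, seed = 1)

decoder  <- sd_decoder(td, k = 150, p_thr = 1)
ws       <- bmi_workspace(r_target = 1)
protocol <- run_session_protocol(ws, decoder, schedule, params,
                                 reps_per_start = 10, seed = 1,
                                 scales = session$meta$scales)
protocol$metrics
```

which prints:

```
Decoding information (SI, SUA): 0.7900 bits (raw 0.7966 - bias 0.0066, 20 shuffles, sem 0.0008)
Decoding information (SD-TD, SUA): 1.0723 bits (raw 1.0980 - bias 0.0258, 20 shuffles, sem 0.0033)
Trajectory metrics over 80 runs (target radius 1.00 cm):
  convergence rate: 100.0%, mean steps (converging): 27.6
  mean closest distance: 6.2 mm, mean F_dir: 0.00425 N, mean wtv: 0.380
```

Reading this: on this session the state-independent decoder extracts
0.79 bits of the 2 bits available about which of the four stimulation
patterns was delivered (after subtracting the finite-sampling bias
estimated from 20 label shuffles), while the state-dependent time-course
decoder extracts 1.07 bits — pre-stimulus ongoing activity lets it
discount excitability-driven response variability. Driving the point mass
with the SD-TD decoder, every one of the 80 trajectories reaches the 1 cm
target, in about 28 half-second steps, passing within ~6 mm of the target
center.

The `simulate-session`, `fit-decode`, `run-bmi` and `report` pipeline
commands are also available from the shell via the thin wrapper
`inst/cli/sdbmi.R` (see `--help`), configured by a single JSON file whose
keys are validated against `default_config()`.

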