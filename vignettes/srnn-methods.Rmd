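---
title: "Spiking recurrent networks for rule-dependent choice: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking recurrent networks for rule-dependent choice: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ruleSRNN)
```

## The task and the model

The package simulates a rule-dependent two-alternative forced-choice (2AFC)
task of the kind used to probe working memory and cognitive control in
rodent prefrontal cortex. Each trial consists of a 200-ms fixation period
(white-noise input only), a 100-ms rule cue (attend vision, rule 1, vs.
attend audition, rule 2), a 400-ms delay during which only white noise is
supplied and the rule must be held in working memory, and a 100-ms
presentation of simultaneous visual and auditory targets on possibly
conflicting sides. The correct choice is the side of the cued modality, so
only incongruent trials (half of them, by construction) reveal whether the
network actually uses the rule.

Three components are chained:

1. **Input encoder** — five leaky integrate-and-fire (LIF) neurons (one
   cue channel, four sensory channels: Vision/Left, Vision/Right,
   Audition/Left, Audition/Right) convert continuous currents into spikes.
   Encoder constants: `v_rest = 0`, `v_th = 1`, `tau_m = 5` ms, `R = 1`.
2. **Recurrent network (SRNN)** — `n_rec` LIF units (80% excitatory)
   with exponential-Euler dynamics at `dt = 2` ms,

   `I(t) = exp(-dt/tau_syn) I(t-dt) + W_in X(t) + W_rec S(t-dt) + I_base(t)`

   `V(t) = v_rest + exp(-dt/tau_m) (V(t-dt) - v_rest) + (1 - exp(-dt/tau_m)) R I(t) + xi_m`

   with `v_rest = -65` mV, `v_th = -50` mV, `tau_m = 20` ms, postsynaptic
   `tau_syn` of 35 ms (E) / 40 ms (I), a 6-ms absolute refractory period
   (potential clamped at rest), and Gaussian voltage noise treated as a
   diffusion (`sigma_m = 4` mV per sqrt-second, i.e. ~0.18 mV per 2-ms
   step by Euler-Maruyama; the stationary membrane noise SD is then
   ~0.4 mV). The baseline current follows a random walk
   (`sigma_base = 0.002` nA per sqrt-second) from a truncated-normal
   start, `0.041 x N(2, 0.01)` truncated to `[1.8, 2.4]` nA, fixed across
   trials. Treating these variances as per-step values instead
   makes the stationary membrane noise ~9 mV — well over half the
   rest-to-threshold gap — under which working memory across the delay is
   unsustainable at this scale; the diffusion reading is also the
   standard discretization of white noise and matches the stated intent
   of scaling the noise with the integration step.
3. **Decoder** — one non-resetting LIF readout per choice port
   (`tau_m = 5` ms, `tau_syn = 20` ms) integrating the excitatory spikes
   through `W_out`; the final decoder voltages are compared with the
   targets `[0, 1]` (left) / `[1, 0]` (right) and the decision is their
   argmax (softmax over four ports for the 4AFC variant).

**Units.** Voltages are carried in mV, currents in nA, and `R = 1e-2` GOhm
enters as 10 mV/nA. These choices make the standard constants mutually
consistent: the baseline current (~0.08 nA) accumulates in the synaptic
trace to ~1.5 nA, producing a steady-state depolarization of ~15 mV — just
at the rest-to-threshold gap — so baseline firing is driven by the voltage
noise, as intended. The discrete membrane update above is the proper
exponential-Euler integrator with the resting state as its fixed point; a
literal transcription that re-adds `v_rest` every step would diverge.

**Dale's principle.** The recurrent matrix is stored as nonnegative
magnitudes `M` and materialized as `W_rec = M * D`, where the mask `D`
carries each presynaptic unit's constraint item: `d_exc = 1` for
excitatory columns, `d_inh = -phi_exc / (1 - phi_exc) = -4` for inhibitory
ones (so excitation and inhibition balance exactly), normalized by
`d_norm = sqrt(sum d^2)` and with a zero diagonal. Magnitudes are
initialized as the absolute values of a Glorot-uniform draw rescaled to
spectral radius `g = 1.5` *before* masking; because `d_norm ~ 45` at full
scale, the effective recurrence is weak at initialization and functional
recurrent structure is produced by training.

**Spike-frequency adaptation (SFA).** A random 25% of units (excitatory
and inhibitory alike) carry an adaptation variable
`A(t) = phi A(t-dt) + (1 - phi) S(t-dt)`, `phi = exp(-dt/tau_a)`,
`tau_a = 400` ms, which raises their effective threshold by `psi A` with
`psi = 1.6` mV. Dynamically this is a small modulation, but during
backpropagation the `A` recurrence is a gradient pathway whose decay
(`phi^k ~ e^{-k dt/400}`) spans the delay period, which is why training
without SFA reliably stalls at the one-rule solution.

## Training

Training minimizes a mean-squared error on the decoder voltages over the
final five steps of the stimulus window,

`L = 1/(2 * 5 * N_batch) * sum (y - V_dec)^2 + lambda * L_fr`,

where `L_fr` sums, over 10-ms bins (80 bins for the default 800-ms trial),
the squared population-and-batch mean instantaneous firing rate (Hz),
weighted by `lambda`. Gradients flow by backpropagation through time through
the full discrete dynamics; the derivative of the spike threshold is
replaced by the SuperSpike fast-sigmoid surrogate
`1 / (1 + beta |V - V_th_eff|)^2` (the forward pass keeps the hard
threshold). `beta = 1000` follows the SuperSpike convention of acting on
volts, so the surrogate's half-width is about 1 mV. The hard reset and the
refractory clamp are treated as non-differentiable and detached; gradients
flow through `V`, `I` and `A` across steps. Adam updates `M`, `W_in`
(cue + sensory) and `W_out` jointly; after every update `M` is clipped at
zero elementwise, so the Dale sign pattern is preserved exactly
(the projection is idempotent).

The backward pass is hand-derived and implemented in C++ alongside the
forward dynamics. Its correctness is established against the standard
surrogate-gradient oracle: on a smoothed forward model in which the
threshold is replaced by the fast sigmoid `g(x) = x / (1 + beta |x|)`
(whose exact derivative is the surrogate) and reset/refractory mechanisms
are absent, the implemented backward pass agrees with central finite
differences to ~1e-9 relative error (the test suite requires 1e-4) for
all three weight matrices.

## Scaled-down preset and optimizer settings

Full-scale experiments use 400E + 100I units, 64-trial batches and 200
batches per epoch. For desk-scale work (and the package's own tests) the
`srnn_preset_small()` preset uses 128E + 32I units with 32-trial batches
and 50 batches per epoch, keeping every neuron constant at its full-scale
value. Several optimizer settings differ from the full-scale defaults, as
design choices for the reduced problem:

* **Learning rate.** The full-scale learning rate is `eta = 3e-4`. At
  reduced scale this converges very slowly (thousands of updates without
  reaching criterion within a desk-scale session); the preset raises
  `eta` to 3e-3 and anneals it geometrically (factor 0.93 per epoch,
  floored at `eta / 10`) within a curriculum stage once that stage's best
  validation accuracy has stagnated for 6 epochs or reached 0.95, resetting
  to the full rate whenever the curriculum advances. The optimizer thus
  explores at the higher rate and consolidates near solutions at rates
  approaching the full-scale value. With Adam the step size is
  per-parameter, so this is a time-rescaling of optimization rather than
  a change in the model.
* **Delay curriculum.** Training batches start with a 50-ms delay and
  advance in 50-ms steps to the nominal 400 ms, each stage ending when
  validation accuracy at that stage reaches 0.95; the Adam moment
  estimates are reset at each transition (the gradient scale shifts by
  orders of magnitude across stages and stale second moments destabilize
  the first post-transition updates). Direct training at 400 ms reliably
  stalls at the rule-ignoring "hedging" solution at this scale (the
  readout outputs 0.5/0.5 on incongruent trials; the mean-squared error
  then sits at its analytic plateau of 0.125): the gradient toward using
  the rule must travel across the whole delay, and with the weak initial
  recurrence that signal is too small to escape the plateau in a
  desk-scale budget. With short delays the rule signal first bridges the
  gap through passive synaptic traces, and the curriculum then extends
  the learned maintenance to longer gaps. All validation at the final
  stage, all early stopping, and every held-out evaluation use the full
  400-ms task.
* **Gradient scale.** Backpropagated gradient norms grow enormously once
  the trained recurrent gain exceeds one (norms of 1e30+ over 400 steps
  are routine); Adam's per-parameter normalization absorbs this dynamic
  range, and global norm clipping — although available via `grad_clip` —
  measurably slowed learning here and is off by default.
* **Firing-rate regularizer.** The full-scale coefficient is
  `lambda = 1e-9`. Under every unit reading of the instantaneous rate the
  resulting penalty is orders of magnitude below the readout loss, i.e.
  functionally inert — yet the regularizer's stated purpose is to
  prevent excessive firing. Desk-scale training with the inert value
  converges to a very-high-rate persistent regime (~30 Hz excitatory)
  with no late-delay slow point. The preset therefore calibrates
  `lambda = 1e-4`, which makes the penalty roughly a third of the readout
  loss at the observed 20-Hz population scale; with it the trained
  network recovers the reported qualitative dynamics (kinetic energy
  decaying to near zero late in the delay, a beta-rhythmic inhibitory
  subpopulation, task sequentiality above both chance-level controls)
  while still reaching 100% held-out accuracy. The full-scale default
  keeps `1e-9`.
* **Restarts and model selection.** Spiking-network training at this
  scale has visible attempt-to-attempt variability (some initializations
  escape the hedging plateau and consolidate within ~20 epochs, others
  grind at intermediate delays), so the fit runs up to 3 independent
  attempts from derived seeds — the analogue of training independent
  network realizations — returns the weights with the best nominal-delay
  validation accuracy, and stops as soon as one attempt holds validation
  accuracy at or above 0.99 for 3 consecutive epochs. Typical converged
  attempts reach 100% held-out accuracy; occasional seeds end near the
  75-85% plateau within the desk-scale budget.

The problem sizes used by the test suite and the acceptance script — a
160-unit network, 200-trial held-out evaluations, 10 seed replicates for
rank-sum comparisons, 25–100 simulated trials for the population analyses
— were chosen so that a complete run is comfortable on a single CPU while
keeping every statistical check meaningfully powered.

## What the task generator emulates, and what it does not

Trial inputs are synthesized, not recorded: cue waveforms are constant
currents (2.0 for rule 1, 1.2 for rule 2, both suprathreshold for the
encoder at distinct rates), active sensory channels carry a constant 2.0,
and fixation/delay background is zero-mean Gaussian white noise with
SD 0.05 entering through the encoder (the encoder stays essentially
silent under noise alone). Stimulus sides are sampled independently, so
congruent and incongruent trials are equally frequent; rule-cue ambiguity
is modeled as the convex mixture `q * cue1 + (1 - q) * cue2`. Real
sensory statistics, reward dynamics, impulsive behavior and thalamocortical
input are outside the model, so passing tests demonstrate properties of
the network model under these idealized conditions, not claims about
biological recordings.

## Analysis suite: definitions and numerical choices

* **PSTH z-scoring** (`psth_zscore`): spikes are binned at 8 ms, averaged
  over trials, converted to Hz, and smoothed with a Gaussian kernel of
  SD 4 bins (32 ms; the kernel is renormalized where truncated at the
  edges). The z-score subtracts the delay-period mean of the smoothed
  series pooled over both rules (zero delay mean holds exactly) and
  divides by the pooled delay SD of the *unsmoothed* PSTH. Normalizing by
  the raw-rate variability calibrates the `z >= 2` peak criterion — on
  homogeneous Poisson nulls fewer than 5% of units are flagged — whereas
  dividing by the smoothed series' own SD would flag roughly a third of
  untuned units purely through max-statistics.
* **Tuning classification** (`find_tuned_units`): a unit is tuned to a
  rule if its pooled delay rate is at least 2 Hz and its z-series has a
  local peak with `z >= 2` under that rule; units passing under both rules
  are labelled "both".
* **Peak-to-noise ratio** (`pnr`): the delay-period maximum of the
  z-series divided by the SD of the series excluding ±2 kernel SDs around
  the peak, with a small floor guarding degenerate near-flat series. The
  PNR is invariant to the z-normalization choice above.
* **Sequentiality index** (`sequentiality_index`): entropy of the
  distribution of per-unit peak times plus the mean log ridge-to-background
  ratio, the ridge window spanning 50 ms around each unit's peak and a
  0.1-Hz floor guarding the log. The entropy term is 0 when all units
  peak together and `log B` when peaks tile the delay uniformly.
* **Trajectories and kinetic energy** (`pca_trajectory`): PCA is fitted on
  the binned delay rates of the excitatory population only (bins of all
  trials as observations), rule trajectories are the projections of
  trial-averaged rates, and the kinetic energy is
  `K(t) = 0.5 ||dx/dt||^2` by first differences in per-bin time units.
* **Correlograms** (`correlogram`): per-trigger normalized lag histograms
  on a ±50-ms window with 2-ms bins (half-open bins, so total mass is
  conserved under binning changes); auto-correlograms exclude self-pairs.
* **Beta detection** (`detect_beta`): per-trial delay spike-count series
  are mean-removed and their periodograms averaged (Bartlett), and a unit
  is flagged rhythmic when the 15–30 Hz band peak reaches twice the median
  power below 100 Hz. Trial averaging is what makes the 2x-median
  threshold calibrated: a single raw periodogram is exponentially
  distributed and its band maximum exceeds twice the median for most
  unstructured inputs. A 400-ms delay gives 2.5-Hz frequency resolution,
  which is sufficient for a 15–30 Hz band decision.
* **LFP proxy** (`lfp_proxy`): the per-step linear sum of all units'
  synaptic currents, with a short-time Fourier spectrogram (Hann window)
  for visualization.
* **Population decoding** (`decode_population`): delay spike counts
  (20- or 50-ms bins) of the excitatory units are projected onto the
  leading 15 PCs and classified by a compact two-layer recurrent (tanh)
  sequence network trained by BPTT with dropout 0.2 and L2 1e-3, under
  repeated 90/10 splits. A recurrent readout is used because no
  deep-learning framework is assumed; the published readout of this kind
  is insensitive to the classifier's exact architecture, and accuracy is
  reported cumulatively over delay time from the per-step readout.

## Perturbation experiments

All perturbations act on a trained network at test time and are pure
functions of `(weights, specification, seed)`:

* `sweep_mixture`: psychometric curve over cue ambiguity `q`; accuracy is
  chance at `q = 0.5` by symmetry and non-increasing toward ambiguity.
* `sweep_delay`: test-time delay elongation (no retraining), with an
  optional report of units whose tuning peaks persist vs. newly appear in
  the extended window.
* `sparsify`: zeroes an exact fraction of the nonzero recurrent
  magnitudes, chosen uniformly among nonzero entries so the nominal
  fraction is unbiased; survivors are untouched, so Dale signs are
  preserved by construction.
* `scale_block`: multiplies one of the EE/EI/IE/II magnitude blocks
  (post x pre) by a factor; applied to magnitudes rather than signed
  weights — equivalent under the sign mask, and it keeps the Dale
  projection trivially valid.
* `sweep_noise_distractor`: varies the input white-noise SD and injects a
  50-ms cue-channel pulse in chosen delay windows. The distractor is
  placed on the cue channel because the prediction concerns rule
  maintenance; its amplitude is a sweep parameter.

## Degenerate inputs and tie-breaking

Exact decoder-voltage ties resolve to the first output and are flagged.
Units with zero delay-period rate variance are excluded from tuning
analysis rather than producing NaN z-scores. The PNR of a nearly flat
series is reported against a 1e-6 noise floor and should be treated as
qualitative. `sequentiality_index` requires at least two units with
nonzero delay activity and floors both ridge and background rates at
0.1 Hz. `spectral_rescale` refuses a zero matrix. Period durations must
be multiples of `dt`, and `tau_ref` must be a multiple of `dt`.

## The adaptation-strength ambiguity

The model's standard constants mix voltage scales: thresholds are in mV while the
surrogate sharpness `beta = 1000` presumes volts (this package follows
that convention for the surrogate). The same ambiguity applies to the
adaptation scale `psi = 1.6`. Read in mV (this package's default), SFA
shifts thresholds by at most a few tenths of a millivolt at realistic
rates — dynamically almost silent, though its slow variable still
provides the non-vanishing gradient pathway across the delay that makes
training converge where the no-SFA control does not. Read in volts
(1.6 V, matching the surrogate's convention), a single spike raises the
threshold by ~8 mV with a 400-ms decay: adaptation then self-limits
adapted units near 4-5 Hz and reproduces the reported low delay rates
(we measure ~2.4 Hz excitatory / 8.9 Hz inhibitory under that reading)
— but the task then could not be trained to criterion at desk scale
within any practical budget, because persistent-activity solutions are
suppressed. The package ships the trainable mV reading and exposes `psi`
so either regime can be studied; the volt reading is plausibly the
full-scale regime behind the reported sparse, sequential phenomenology.

## What the desk-scale model does and does not reproduce

With the scaled preset, converged networks reproduce: training to ~100%
choice accuracy with early stopping; failure of the no-SFA control near
the 75% one-rule mark; chance performance at maximal cue ambiguity with
a monotone psychometric over `q` (evaluated on incongruent trials, since
congruent trials are solved without the rule); accuracy degradation
under weight sparsification, delay elongation and extreme E/I-block
scaling; a beta-rhythmic inhibitory subpopulation; late-delay kinetic
energy near zero; rule-separated principal-component trajectories; and
task sequentiality exceeding both the noise-input and weight-shuffled
controls. It does **not** reproduce the transiently peaked rule-tuned
units (the peak-based tuning detector finds essentially none: the
desk-scale solution codes the rule as persistent selective activity, and
pooled-rule z-scoring saturates near z = 1 for sustained two-level
selectivity), the inhibitory-above-excitatory delay rates (we measure
near parity), or reduced late-delay distractor sensitivity. All three
are expected to require either the full 500-unit scale or the
strong-adaptation (volt-scale `psi`) regime described above.

## Known limitations

* Neurons are point LIF units; no conductances, no bursting, no
  cell-type diversity beyond the E/I split and the SFA subset.
* The reported phenomena at reduced scale (tuned fractions, rhythmic
  unit counts, rate statistics) are directional analogues of the
  full-scale ensemble statistics, not quantitative reproductions; the
  full-scale runs (500 units, 10 network realizations) are outside a
  desk-scale session.
* The unit system reconciles the standard constants as described above;
  other reconciliations are conceivable and would rescale noise and
  currents together.
* Training uses supervised BPTT with a surrogate gradient; no claim is
  made that biological circuits implement this learning rule.
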