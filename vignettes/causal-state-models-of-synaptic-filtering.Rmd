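---
title: "Causal-state models of short-term synaptic filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal-state models of short-term synaptic filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdmachine)
```

# The model and what the package computes

A chemical synapse driven by a spike train transforms the train into a
sequence of postsynaptic response amplitudes.  With repetitive activation
the amplitude can decay (depression, through depletion of the readily
releasable vesicle pool) or grow (facilitation, through presynaptic calcium
accumulation raising the probability of release).  `fdmachine` implements a
minimal facilitation–depression (FD) model of this transformation, drives
it with Poisson spike trains, and then asks a computational-mechanics
question of the output alone: *what is the minimal unifilar hidden Markov
model — the epsilon machine — of the binarized response sequence, and how
does its statistical complexity change with the input firing rate?*

## The FD map

Three per-pulse variables evolve across each inter-spike interval (ISI)
$T$: rescaled presynaptic calcium $C$, release probability $P$, and the
readily releasable fraction $R$.  Writing primes for the values at the next
pulse,

$$C' = C\,e^{-T/\tau_{ca}} + \Delta,$$
$$P' = P_{max}\frac{C'^4}{C'^4 + K^4},$$
$$R' = 1 - \bigl(1 - (1-P)R\bigr)
      \Bigl(\frac{C e^{-T/\tau_{ca}} + K_r}{K_r + C}\Bigr)^{\Delta k}
      e^{-k_{min}T}.$$

Calcium decays exponentially with time constant $\tau_{ca}$ (ms) and jumps
by $\Delta$ at each pulse; release follows calcium through a Hill function
of coefficient 4 (half-height $K$), reflecting the cooperative calcium
binding of the release sensor; the pool recovers toward 1 at a
calcium-dependent rate between $k_{min}$ and $k_{max}$ (Hill coefficient 1,
half-height $K_r$), and is depleted by release: after a pulse with
pre-release pool $R$ the pool restarts from $(1-P)R$.  The per-pulse
response proxy is $Pr = P'R'$, proportional to the peak postsynaptic
current.

Four presets ship with the package (`synapse_preset()`): a fitted
*depressing* (control) hippocampal basket-cell synapse and its *muscarine*
neuromodulation variant ($\Delta = 0.17$, $P_{max} = 0.27$: reduced
calcium influx and release), plus two mock synapses, *facilitating* and
*mixed*, obtained by lengthening $\tau_{ca}$ to 30 ms and retuning $K$ so
that calcium accumulation matters.  The mock presets do not print a value
for $\Delta$ anywhere we could adopt it from, so they reuse the control
value $\Delta = 1$.

### A note on the recovery exponent

Dimensional bookkeeping would suggest scaling the recovery Hill exponent by
$\tau_{ca}$ (the exact solution of $dR/dt = k_{recov}(C(t))(1-R)$ under
exponentially decaying calcium carries the exponent $\Delta k\,\tau_{ca}$).
We deliberately implement the exponent as the bare $\Delta k$, exactly as
the map is conventionally written.  The reason is empirical, and we treat
it as a property of the model rather than a nuisance: with the scaled
exponent the mock parameter sets ($k_{max} = 6$/ms, $\tau_{ca} = 30$ ms)
drive the recovery factor to zero, the pool never depletes, and the mixed
synapse loses its defining band-pass resonance.  With the bare exponent the
model produces the three canonical frequency responses — monotone
depression from $P_{max}$, facilitation rising through the physiological
range, and a mixed response with a single interior maximum near 50–60 Hz —
which is the behavior the presets were tuned to produce (see
`fixed_point_spectrum()` and the tests).  The trade-off is documented
below under *Known limitations*: the bare exponent keeps a constant
calcium-dependent recovery offset even when $\tau_{ca}$ is negligible, so
the closed-form small-$\tau_{ca}$ response distribution matches the
simulated map only approximately at short mean ISIs.

## Deterministic fixed points

Under periodic stimulation at interval $T$ the map contracts onto a unique
fixed point, available in closed form: calcium sums a geometric series,
$\bar C = \Delta/(1 - e^{-T/\tau_{ca}})$; $\bar P$ evaluates the release
Hill function at $\bar C$; and $\bar R = (1-\gamma)/(1-(1-\bar P)\gamma)$
with $\gamma$ the recovery decay factor at $\bar C$.  `fd_fixed_point()`
returns these and `fixed_point_spectrum()` tabulates
$(\bar P, \bar R, \bar P \bar R)$ against rate, the decomposition that
explains which presets can generate complex output: only where both $\bar
P$ and $\bar R$ vary appreciably over the same frequency band does the
response train carry rich temporal structure.

```{r spectrum}
fixed_point_spectrum(synapse_preset("mixed"), c(1, 10, 25, 50, 100, 250))
```

## The stochastic fixed point

For the depressing synapse, $\tau_{ca}$ (1.5 ms) is far below typical
ISIs, so calcium relaxes between pulses, $\bar P \to P_{max}$, and the pool
fixed point depends on the preceding interval only through
$$\bar R(T) = \frac{1 - e^{-k_{min}T}}{1 - (1-P_{max})e^{-k_{min}T}}.$$
Feeding an exponential ISI (rate $\lambda$, in 1/ms throughout, so the
mean ISI is $1/\lambda$ ms) through this curve defines the *stochastic
fixed point*, whose density follows by the change of variables
$u = e^{-k_{min}T}$:
$$f(x) = \frac{\lambda(1-c)}{k_{min}}
  (1-x)^{-(1-\lambda/k_{min})}(1-cx)^{-(1+\lambda/k_{min})},
  \qquad c = 1 - P_{max},$$
supported on $(0,1)$, with the response version supported on
$(0, P_{max})$ via $y = P_{max}x$ (`dsfp_rbar()`, `dsfp_pr()`).  Useful
internal checks are exact: the density integrates to one, reduces to a
Beta$(1, \lambda/k_{min})$ law at $c = 0$, and the inverse-transform
sampler `rsfp_pr()` (draw $T$, evaluate $P_{max}\bar R(T)$) reproduces the
closed-form CDF `psfp_pr()` to KS distance below $10^{-2}$ at $10^5$
draws.

## Symbolization and threshold choice

Machine reconstruction operates on a binary partition of the response
train: symbol 1 where $Pr \ge \theta$ ("large response"), else 0; the
boundary maps to 1 by convention.  The threshold is the one genuinely free
knob in the pipeline, and `select_threshold()` fixes it by maximizing the
statistical complexity of the reconstructed machine — the partition that
exposes the most structure — over 41 evenly spaced candidates between the
5th and 95th percentile of the sample, with two guards:

* **Robustness.** A topology that appears at a single grid point and
  vanishes at its neighbors is the significance test resolving sampling
  noise, not structure; at $2^{15}$ symbols such single-point artifacts
  occur regularly.  The maximization is therefore restricted to candidates
  whose machine topology persists over at least three adjacent grid points
  (machines on a plateau of the sweep); if no plateau exists the plain
  maximum is used.  `threshold_sweep()` exposes the underlying sweep so the
  plateau structure can be inspected directly.
* **Narrow support.** When the central 99% of the sample spans less than
  0.2, thresholding mostly resolves noise around a single mode; the
  selection then falls back to the midpoint of that central support.  The
  central-99% interval, rather than the raw range, defines "support"
  because a $2^{15}$-pulse Poisson train always contains a handful of
  extreme intervals that stretch the raw range without carrying histogram
  mass.  The same fallback applies when every candidate yields a
  zero-complexity machine.  A constant train is rejected with an error.

Ties in complexity are broken toward the candidate nearest the sample
median, the most nearly equiprobable partition.

## CSSR

`cssr()` is a from-scratch Causal State Splitting Reconstruction for
binary sequences.  Histories (suffixes of the past) are grown from the
empty history to length `lmax`; each history's next-symbol distribution is
compared to its state's pooled distribution with a two-sample test at
significance `alpha`, and significantly different histories move to the
best-matching other state (largest p-value) or found a new one.  The
partition is then determinized — states are split until each (state,
symbol) pair has a unique successor, which is what makes the model
unifilar — and transient states are dropped, keeping the recurrent
strongly connected component carrying the largest share of the data.
Transition probabilities are maximum-likelihood ratios of the pooled
full-length suffix counts (full-length suffixes partition the sample, so
no observation is double counted), zero-count transitions are omitted, and
the stationary distribution is the left fixed vector of the symbol-summed
transition matrix.  State 0 is always the most visited state.

Numerical and procedural choices that matter:

* The default test is the two-sample Kolmogorov–Smirnov test, which for a
  binary alphabet reduces to $D = |\hat p_1 - \hat p_2|$ with the
  asymptotic Kolmogorov tail; $\chi^2$ is available by flag.  The
  alternating series for the Kolmogorov tail is summed only for
  $\lambda \ge 0.2$ — below that it fails to converge in any reasonable
  number of terms while the true tail equals 1 to within $10^{-12}$.
  Getting this wrong is not cosmetic: a truncated series at tiny $\lambda$
  returns spuriously small p-values and fabricates causal states.
* `alpha = 0.01` and `lmax = 3` are the pipeline defaults.  The
  data-size heuristic `lmax_heuristic()` (largest $L$ with
  $|A|^L/(N-L) \le \alpha$) is advisory; at $N = 2^{15}$ it admits longer
  histories, but 3 is the length at which the reference machines of this
  model family are resolved, and machines that fail validation trigger an
  automatic decrement (below).
* During determinization, a history whose extension was never observed
  imposes no successor constraint (it acts as a wildcard) rather than
  forcing a split.
* `validate_machine()` enforces the standard acceptance rule: every state
  must contain at least one history of full length `lmax` (otherwise the
  history length outruns the data), the machine must be unifilar, and
  transition rows must be stochastic.  `run_experiment()` responds to a
  validation failure by decrementing `lmax` and reconstructing again.

`simulate_machine()` generates from any hand-built machine
(`epsilon_machine()`), which is how the reconstruction is tested against
analytic ground truth: an i.i.d. process must give one state, strict
alternation the two-state period-2 machine with $C_\mu = 1$ bit, and the
golden-mean process its two-state generator with transition probabilities
recovered to $\pm 0.02$ at $n = 10^5$.

## The experiment driver

`run_experiment()` chains the stages for each rate in an
`experiment_config()`: seeded Poisson ISIs, map simulation with the first
100 pulses discarded (the collapse onto the attractor takes only a few
pulses; 100 is a safety margin), $2^{15}$ retained samples, threshold
selection, reconstruction, validation, and bookkeeping into a
`complexity_spectrum`.  Per-rate seeds are a fixed function of the master
seed and the rate value alone, so rate grids can be extended or reordered
without perturbing existing draws.  Everything is deterministic given the
configuration; repeated runs are byte-identical.

The reference protocol (the default configuration) uses $2^{15}$ samples
per rate, the preset rate grids of `default_rates()`, and — in the
acceptance material — five seeds per condition with majority voting on
state counts, since threshold selection near a plateau boundary can tip
individual seeds between adjacent topologies.

# What the generator emulates, and what it does not

The FD simulator *is* the data generator of this analysis: no external
data enter anywhere.  It emulates per-pulse peak response amplitudes of a
synapse with calcium-dependent facilitation and recovery under Poisson
stimulation, which is the regime the reconstruction pipeline is designed
for.  It does not emulate: postsynaptic conductance waveforms or their
kinetics (only per-pulse peaks), measurement noise (responses are exact
functions of the state; real amplitude estimates carry quantal and
recording noise that would thicken every morph), non-Poisson natural spike
statistics, or slower processes (augmentation, post-tetanic potentiation)
absent from the model.  Passing tests therefore certify the pipeline on
clean model output; on experimental amplitude sequences the significance
level and the narrow-support guard would both need recalibration against
the noise floor.

# Known limitations

* The bare-$\Delta k$ recovery exponent keeps the factor
  $\bigl(K_r/(K_r + C)\bigr)^{\Delta k} \approx 0.89$ (control values) in
  the recovery decay even for negligible $\tau_{ca}$.  The closed-form
  stochastic fixed point, which drops that factor, consequently
  underestimates the simulated pool at short mean ISIs: at a 10 ms mean
  ISI the simulated responses concentrate near $0.1$–$0.2$ while the
  analytic law concentrates near $0.02$, and the KS distance between them
  is large; at long mean ISIs (hundreds of ms and beyond) the two agree
  closely.  The analytic module is exact for its own law — the
  discrepancy is a statement about the map, not about Eq-level algebra —
  and the tests report it rather than hiding it.
* CSSR's state counts at a fixed `alpha` depend on test power, hence on
  sample size: with $2^{15}$ symbols the KS test resolves genuinely weak
  second-order structure (e.g. calcium-memory correlations in the
  facilitating preset at low rates) that a smaller sample or a different
  test implementation would merge into fewer states.  Comparisons of
  state counts across studies are only meaningful under matched sample
  sizes and tests.
* The two-symbol partition is deliberately coarse; machines are
  comparable only within a partition family, and no claim is made that
  the partition is generating.
* `topologically_equal()` uses backtracking over state bijections, which
  is exact and fast for the machine sizes that arise here (up to ~10
  states) but is not intended for large machines.
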