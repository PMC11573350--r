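---
title: "Directed information flow in iEEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed information flow in iEEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptenet)
```

ptenet quantifies *directed* interactions between intracranial EEG (iEEG)
network nodes — in the motivating application, between the anterior insula
(AI) of the salience network and nodes of the default-mode network
(PCC/precuneus, mPFC) and frontoparietal network (dPPC, MFG) during episodic
memory encoding and recall. This vignette explains the models and
procedures the package implements, the parameters that matter, the choices
we made where the design was genuinely open, and what the synthetic
benchmark does and does not demonstrate.

## The measures

### Phase transfer entropy

Given two signals, instantaneous phases $\phi_x(t), \phi_y(t)$ are extracted
via the analytic signal $z(t) = x(t) + i\tilde{x}(t)$, where $\tilde{x}$ is
the Hilbert transform. The phase transfer entropy from driver $x$ to target
$y$ is the conditional mutual information

$$\mathrm{PTE}_{x \to y} \;=\; I\big(\phi_y(t+\tau)\,;\,\phi_x(t)\,\big|\,\phi_y(t)\big)
 \;=\; \sum p(\phi_y^{t+\tau}, \phi_y^{t}, \phi_x^{t})
 \log \frac{p(\phi_y^{t+\tau} \mid \phi_y^{t}, \phi_x^{t})}
           {p(\phi_y^{t+\tau} \mid \phi_y^{t})},$$

estimated by plug-in from a three-dimensional histogram of the phase
triplets. PTE is asymmetric — $\mathrm{PTE}_{x \to y} > \mathrm{PTE}_{y \to x}$
indicates net information flow from $x$ to $y$ — and, being phase-based and
model-free, it tolerates the nonstationarity that rules out parametric
Granger causality for iEEG (`ar_spectral_radius()` lets you check this:
iEEG-like series have AR spectral radii very close to one).

Two data-driven hyper-parameters follow the analyzed series themselves
(computed per trial and per pair):

* **Delay** $\tau = \mathrm{round}(2M / M_\pm)$, where $M$ is the series
  length and $M_\pm$ counts sign changes of the phase across consecutive
  samples, summed over the two channels. A phase sawtooth contributes two
  sign changes per oscillatory cycle (one zero-crossing, one $\pm\pi$ wrap),
  so $\tau$ is roughly half a period of the dominant rhythm. We interpret
  "across channels" as the two channels of the analyzed pair, not the whole
  montage — the definition is stated in terms of the pair's series.
* **Bin count** from the Scott bin-width rule
  $h = 3.49\,\sigma\,M^{-1/3}$, with $\sigma$ the mean of the two phase
  standard deviations, giving $n_{\mathrm{bins}} = \lceil 2\pi/h \rceil$
  over the circle $[-\pi,\pi)$. The expression is dimensionally a bin
  *width*; read literally as a bin *count* it returns < 1 bin for any
  realistic $M$ (e.g. $3.49 \times 1.81 \times 1000^{-1/3} \approx 0.63$),
  which is degenerate. Both readings are implemented
  (`default_bins(mode = "as_printed")` clamps to the 2-bin floor); Scott is
  the default.

Numerical conventions: bin edges are fixed to $[-\pi, \pi)$ equal-width per
axis, because phases live on a known circle and fixed edges keep histograms
comparable across trials. Empty cells contribute zero ($0 \log 0 := 0$),
and all conditionals are derived from the *same* joint table, which
guarantees non-negativity of the plug-in estimate up to floating-point
rounding. Logarithms are natural (nats); every comparison in the analysis
is a difference or ordering of PTE values, so the base cancels.

### Net outflow

For a node $v$ in a set of analyzed regions,
$\mathrm{net}(v) = \mathrm{PTE(out)} - \mathrm{PTE(in)}$, aggregated over
$v$'s outgoing and incoming directed pairs. The default aggregation is the
*mean* over pairs so that regions with many electrodes are not declared
hubs by degree alone; a *sum* mode exists, under which a closed node set is
exactly conservative ($\sum_v \mathrm{net}(v) = 0$), which the tests
exploit.

### Phase-locking value

$\mathrm{PLV} = \left| \mathbb{E}_t\, e^{i(\phi_x(t) - \phi_y(t))} \right|
\in [0, 1]$: 1 for perfectly (possibly constant-lag) locked phases, about
$\sqrt{\pi}/(2\sqrt{M})$ in expectation for independent phases (the mean
resultant of a Rayleigh walk). PLV is symmetric; it complements PTE by
measuring undirected synchronization per narrowband.

### High-gamma power

High-gamma (80–160 Hz) amplitude is a proxy for local population activity.
The range is decomposed into eight 10 Hz sub-bands to counteract the
$1/f$ decay of power; each sub-band is band-passed (zero-phase Butterworth),
its Hilbert envelope normalized to that band's own mean and expressed in
percent, and the sub-bands averaged. The series is then smoothed with 0.2 s
windows at 90% overlap and baseline-corrected by subtracting the 0.2 s
pre-stimulus mean.

Two numerical choices deserve note:

* *Edge handling.* The first and last 50 ms of every epoch carry filter and
  Hilbert edge transients. These samples are excluded both from statistics
  and from each band's normalizing mean. Normalizing by the full-epoch mean
  would let edge transients dominate in bands with little steady-state
  signal, biasing the normalized interior far below 100%.
* *Stopband-floor guard.* A sub-band whose interior median envelope is
  below $10^{-3} \times$ the epoch RMS contains no appreciable signal —
  it is at the band-pass filter's stopband floor (about $-80$ dB for the
  two-pass design). Such bands are excluded from the across-band mean:
  normalizing them would amplify pure filter artefacts. Genuine broadband
  recordings sit two to three orders of magnitude above this threshold in
  every sub-band, so the guard only triggers on synthetic narrowband
  inputs.

The recall baseline is an open point: pre-vocal recall windows have no
pre-stimulus period. We use the matched rest-period mean as the recall
baseline (flagged `baseline = "rest"` in the output attributes), which
preserves comparability with the task-versus-rest contrasts.

## Preprocessing

The conditioning pipeline runs in a fixed order, enforced by
`preprocess_session()`: resample to 500 Hz → bipolar montage → band-stop
filters at 57–63, 117–123, 177–183 Hz → per-channel z-normalization →
band-pass (broadband 0.5–80 Hz for connectivity; the power branch takes the
unfiltered z-scored montage because its sub-band filters live above 80 Hz).
All filtering is forward–backward ("two-way") 4th-order Butterworth —
"4th order" names the one-pass design; the two passes double the effective
order and cancel the phase response.

Resampling uses a zero-phase 8th-order Butterworth low-pass at 0.9× the
target Nyquist followed by spline evaluation at the new sample times
(passband error below $10^{-4}$, alias rejection below $10^{-8}$ in the
tests). Epochs are half-open `[start, end)` windows with 0-based sample
indexing and onset sample `floor(onset_s * fs)`; encoding epochs are cut
from the stimulus onset for the task-specific duration (1.6 s verbal free
recall, 4 s paired associates, 5 s water maze), recall epochs are the 1.6 s
*preceding* each vocal onset (5 s post-onset for the water maze), and rest
epochs are consecutive non-overlapping windows cut from the pre-task rest
span, matched in length and count to the task epochs. Epochs are cut after
filtering, so epoch interiors are steady-state.

## Group statistics

PTE and power values are right-skewed, so before modelling they pass
through a rank-based ordered-quantile transform,
$x \mapsto \Phi^{-1}((\mathrm{rank}(x) - 0.5)/n)$ — the deterministic
default of the ordered-quantile family of normalizing transforms. Condition
contrasts (direction A→B vs B→A; task vs rest) are fitted as
`value ~ condition + (1 | subject)` with REML and Satterthwaite denominator
degrees of freedom, after averaging across trials within each channel pair
(trials are the measurement replicates, pairs the observational units).
Cohen's $d$ uses the $d = 2t/\sqrt{\mathrm{df}}$ convention
($t = \sqrt{F}$ for the 1-df condition effect). Families of p-values are
corrected by Benjamini–Hochberg FDR. Tables with a single subject fall back
to fixed-effects ANOVA with a warning, as do singular random-effect fits.

Replication strength across tasks is quantified by the replication Bayes
factor ratio $\mathrm{BF}_{10}(\text{joint}) / \mathrm{BF}_{10}(\text{original})$,
with verdicts *replicated* at ratio ≥ 3 and *decisive* at ≥ 100. Individual
Bayes factors use the BIC approximation
$\mathrm{BF}_{10} \approx \exp((\mathrm{BIC}_0 - \mathrm{BIC}_1)/2)$ from
maximum-likelihood mixed-model fits (both models keep the subject
intercept). This implies a unit-information prior: ratios are internally
consistent and monotone in evidence, but not numerically comparable to
Bayes factors computed under other default priors — use them to compare
conditions within this implementation.

## The synthetic benchmark

`make_session()` generates ground-truth-known sessions so the whole chain is
testable without patient recordings. It emulates the statistical structure
the analysis assumes, not the biophysics of iEEG:

* **Background**: per-channel Gaussian $1/f^{\alpha}$ noise, $\alpha = 1$ by
  default — matches the broadband decay of field-potential spectra without
  claiming a generative model of cortex.
* **Directed coupling**: a band-limited (8–12 Hz by default) driver shared
  by the source region; target channels receive
  $s \cdot u(t - \mathrm{lag}) + (1 - s) \cdot v(t)$ with independent $v$.
  The delayed-copy construction gives an unambiguous ground-truth lag in
  samples. Couplings are attenuated by `rest_factor` (default 0.5) inside
  the pre-task rest span so task-versus-rest contrasts are testable; the
  generative claim is ours, not empirical.
* **Contact gains**: contacts along a probe carry a deterministic falloff
  (1, 0.5, 0.25, …) of their region's coupled component. A perfectly
  common component would cancel exactly under the downstream bipolar
  montage; the falloff emulates the spatial decay of a local field along a
  probe and leaves each virtual bipolar channel a defined fraction of the
  coupling.
* **Amplitudes**: background SD 1, coupled-component SD 2 at unit gain.
  After bipolar differencing (noise SD $\sqrt{2}$, coupling gain 0.5) this
  puts the in-band SNR near 1 — strong enough for single-session direction
  recovery with a dozen trials, weak enough that the coupling is invisible
  in the raw traces.
* **Task structure**: `n_trials` encoding events with task-specific
  durations and inter-stimulus intervals, `n_trials` recall (vocal-onset)
  events, and a pre-task rest span at least as long as the summed task
  epochs, placed immediately before the task. The 12-item default matches
  a verbal free-recall word list.
* **High-gamma responses**: `gamma_response_spec()` scales the 80–160 Hz
  component of a region's channels by $1 \pm m$ inside event-locked
  windows, emulating task-locked activation or suppression (e.g. the
  PCC/precuneus suppression during encoding).

In `coupled_phase_pair()` — the minimal two-channel version used for
calibration experiments — white measurement noise is added to *both*
channels. With noise on the target only, the two series differ in phase
jitter and the plug-in PTE asymmetry is biased positive even at zero
coupling (we measured 68% positive signs over 200 uncoupled replicates);
symmetric noise restores exchangeability, and the uncoupled asymmetry sign
is a fair coin (measured 47.5%).

What passing the synthetic benchmark shows: the estimator chain —
preprocessing, phase extraction, the $(\tau, \mathrm{bins})$ heuristics,
the histogram CMI, trial averaging, net-outflow ranking, and the
mixed-model inference on top — recovers the direction, ordering and
approximate monotonicity of planted couplings at realistic epoch lengths
and SNR, with calibrated false-positive behavior at zero coupling. What it
does not show: that real iEEG satisfies the generator's assumptions
(Gaussian $1/f$ background, stationary band-limited coupling at a fixed
lag, linear mixing). Conclusions about real recordings rest on the
robustness arguments for phase-based transfer entropy, not on these
simulations.

## Problem sizes and determinism

The shipped tests and the acceptance script use 20 simulated sessions of 12
trials for direction recovery, 1000 simulated observation tables for type-I
calibration, 150 coupled pairs of 5000 samples for monotonicity, and
100 + 200 replication-Bayes-factor simulations — sizes at which every Monte
Carlo margin in the checks is wide relative to its standard error while the
whole suite stays comfortably interactive. All randomness flows from
explicit integer seeds; `make_session()` and `coupled_phase_pair()` seed a
local RNG scope and restore the caller's stream, so identical configs are
bit-reproducible regardless of ambient RNG state.

## Known limitations

* PTE here is the raw plug-in histogram estimate: no surrogate correction,
  no directionality normalization (dPTE), no time-resolved variant. The
  analyses compare raw PTE between directions and conditions, where the
  shared plug-in bias largely cancels; absolute PTE values retain
  estimator bias and should not be interpreted in isolation.
* The BIC Bayes factors inherit the unit-information prior; see above.
* Session I/O supports 16-bit EDF plus TSV metadata. EDF quantizes to the
  per-channel full-scale range (relative error ≤ $3 \times 10^{-5}$).
* Electrode localization is out of scope: region labels are taken as given
  in the channel table, and a bipolar channel inherits the region of its
  first contact.
```
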