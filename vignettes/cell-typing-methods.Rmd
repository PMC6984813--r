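---
title: "Trace-to-cell-type methods: detection, membrane properties, classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trace-to-cell-type methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phystype)
```

`phystype` turns whole-cell patch-clamp sweeps into postsynaptic-current
event tables, 15-property membrane feature vectors, and interneuron class
labels. This vignette documents the measurement definitions, the
conventions the package had to fix where the procedure leaves latitude, the
synthetic world used for testing, and the numerical choices. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Data model and conventions

A sweep is a uniformly sampled trace (nominally 10 kHz): current in pA under
voltage clamp, voltage in mV under current clamp. Time is in seconds with
t = 0 at the first sample; all windows are half-open `[start, end)`. Sweeps
carry stimulus times and artifact windows; a sweep set shares sampling rate,
signal kind and protocol metadata. On disk the package uses a neutral
interchange pair — a CSV sample matrix (one column per sweep, 17 significant
digits so doubles round-trip exactly) and a JSON sidecar. ABF is not parsed:
it is a closed vendor binary format, and the adapter boundary keeps the
analysis core acquisition-agnostic.

Stimulus artifacts are blanked by linear interpolation across the artifact
window (default 2 ms from stimulus onset) before any detection. The
interpolation anchors are 0.5 ms means, not single samples: a single noisy
anchor sample next to the search window otherwise leaks spurious
suprathreshold deflections into the detector.

Current sweeps are smoothed with a 3rd-order Savitzky–Golay filter, window
±0.5 ms (11 samples at 10 kHz). Voltage sweeps are never filtered: AP
threshold detection differentiates the raw trace, and smoothing would bias
dV/dt. The filter reproduces cubic polynomials exactly (this is tested), and
edges are handled by evaluating the edge-window polynomial fit rather than
shortening the output.

## Noise floor: raw MAD of the unfiltered baseline

Every detector thresholds deflections at a multiple of the median absolute
deviation of a baseline: 6 × MAD for evoked and unitary events, 5 × MAD
(rolling, 50 ms pre-peak) for spontaneous events. Two conventions matter:

* **The MAD is raw** — `median(|x − median(x)|)` with no 1.4826
  normal-consistency factor. The multipliers are calibrated against the raw
  value; a scale factor is exposed (`mad_scale`) but defaults to 1.
* **The MAD is computed on the unfiltered baseline**, while peak search and
  kinetics run on the filtered trace. This is a deliberate asymmetry: if
  the MAD were taken on the filtered trace, the threshold would be
  ~4 standard deviations of the *filtered* noise at every noise scale
  (MAD is proportional to σ), and a ±5 ms search window over hundreds of
  sweeps then guarantees occasional false successes whose latencies wreck
  the jitter statistic (jitter is an SD, so a single outlier dominates).
  Measuring the noise floor pre-filter keeps the threshold at the
  physical noise level of the recording while detection still benefits
  from smoothing.

## Evoked EPSC/IPSC detection

EPSCs (holding −70 mV) are negative deflections, IPSCs (holding 0 mV)
positive. The procedure is two-pass. First, 25% of sweeps (or 5 when the
experiment has fewer than 20) are subsampled — with a seeded RNG, since the
original subsample policy is unstated — and the maximal correct-polarity
deflection within 20 ms after the artifact end is located in each; the
detection window is centred at the median of those peak times with half-width
5 ms (EPSC) or 7.5 ms (IPSC). Second, every sweep is classified: a success
strictly exceeds mean baseline (500 ms pre-stimulus) by 6 × MAD inside the
window. Strict comparison means a zero-noise flat trace (MAD 0) never
produces spurious successes.

Amplitude is peak minus the sweep's baseline mean; the cell amplitude
averages successes only. Failures record the extremal correct-polarity
deflection within ±5 ms of the cell's mean success peak time; if every sweep
fails, the cell amplitude falls back to the extremum of the mean trace
within 20 ms of the artifact end. Rise time is the 20→80% crossing interval
(linear interpolation between samples); latency runs from the artifact end
(or the presynaptic AP peak, for paired recordings) to the 20% crossing;
jitter is the SD of latencies. Decay τ is fitted on the cell's mean success
trace, aligned by point of maximal rise: single exponential for EPSCs,
weighted double exponential τ_w = (τ₁A₁ + τ₂A₂)/(A₁ + A₂) for IPSCs.

## Spontaneous EPSC detection

Candidates are local negative minima of the smoothed trace (2 ms refractory,
deeper peak wins) exceeding 5 × the rolling MAD of the 50 ms before the
peak. The rolling baseline excludes samples already assigned to detected
events. A candidate inside the decay span of an accepted event must
additionally clear the threshold against the immediately local (2 ms) level;
without this, noise minima riding on decays triple the candidate count.

The template is the aligned mean of a 10% candidate subsample, truncated
from its 20% rise point to one decay constant past the peak (the fitted τ;
"end of the decay time constant" is read as t = peak + τ). For scoring, the
template is scaled to each candidate's peak amplitude and the candidate's
negative-going charge is divided by the scaled template's charge; candidates
below the cutoff (default 0.5) are rejected. Peak scaling, rather than a
least-squares fit of the template to the segment, is what makes the cutoff
meaningful for its stated purpose: a one-sample artifact spike has nearly no
charge relative to a template scaled to the same peak, while a least-squares
scale of a template onto a spike is near zero and the ratio degenerates.
Event frequency is the inverse of inter-event intervals; cell statistics are
medians.

## Action potentials and the 15 membrane properties

AP threshold is the voltage at the first upward crossing of dV/dt = 20 V/s
(centred finite differences on the unfiltered voltage, linear interpolation
between samples). The peak is the *first* downturn after the crossing, not
the window maximum — in a fast-spiking train at 150 Hz, a windowed maximum
jumps to the next spike and silently halves the spike count. A minimum
peak-above-threshold excursion (default 20 mV) rejects spikelets and noise.
Halfwidth is the interval between the half-amplitude crossings on the up-
and downslopes. The AHP trough is searched within 100 ms of threshold,
bounded by the next AP's threshold and, when analysing current steps, by the
step offset — otherwise the post-step relaxation masquerades as a deep,
late AHP for the last spike of a train.

The 15 properties and their sources:

| property | protocol | definition |
|---|---|---|
| membrane_resistance (MΩ) | 10 pA series, sub-rheobase steps | I–V slope; ΔV = mean(50–150 ms post-onset) − mean(100 ms pre-onset) |
| membrane_decay_tau (ms) | −100 pA step | single-exponential fit of the onset relaxation |
| sag (%) | −200 pA step | (V_min − V_ss)/(V_min − V_bl) × 100 |
| rebound_spikes | −200 pA step | APs within 500 ms after offset |
| max_firing_rate (Hz) | 25 pA series | 1/min ISI in the first 200 ms of the last step before attenuation |
| ap_threshold, ap_amplitude, ap_halfwidth, ahp_magnitude, ahp_latency | rheobase sweep | per-AP means |
| delta_ahp, fr_adaptation, ap_broadening, ap_amplitude_adaptation | rheobase + 50 pA | last-vs-first train ratios/differences |
| latency_first_ap (ms) | rheobase sweep | onset to first AP peak |

Decisions worth stating: "the inter-spike interval during the first 200 ms"
is read as the *minimum* ISI (instantaneous maximum rate); a mean-ISI
variant is a config option. "Before attenuation of AP firing" is made
operational as the first step whose AP count drops below the previous
step's, or where any AP amplitude falls under 40 mV; the step before that
is used. ISIs are peak-to-peak. The two step series are taken as defined by
the protocol (−100…+100 at 10 pA, −200…+400 at 25 pA) where later
subsection texts contradict it. Missing inputs (e.g. no −200 pA sweep)
yield `NA` entries, never imputation.

## Classification

Features are z-scored per column (sample SD), so megaohm-scale properties
cannot dominate millisecond-scale ones. Ward clustering is implemented
directly with merge cost equal to the increase in within-cluster error sum
of squares, updated by the exact Lance–Williams recurrence; heights are the
ESS increments themselves and are checked verbatim against brute-force
enumeration on all small instances. The Thorndike criterion places the cut
at the stage with the largest jump in merge height (k = n − s + 1 when the
jump enters stage s). Cluster 1 is the larger cluster by convention.

Note a structural fact the tests make visible: z-scoring the *pooled*
two-class table shrinks the effective class separation, because the mixture
SD is √(1 + p(1−p)Δ²). A planted 4-SD contrast on three salient features is
therefore ~1.8 SD per feature after scaling, and single-realization
agreement with planted labels (ARI) at 105 neurons ranges roughly 0.8–1.0;
stochastic checks therefore average over a fixed seed sweep.

The decision tree is CART: Gini-grown (min node size 5), weakest-link
cost-complexity pruning, 10-fold cross-validation over the nested subtree
sequence evaluated at the geometric means of consecutive critical α values,
final tree at the minimum-CV-error complexity (ties resolved toward the
smaller tree). Validation is 500 stratified 80/20 train/test splits without
replacement. The random forest grows trees to purity on bootstrap samples
with ⌊√p⌋ = 3 features per split; OOB error comes from out-of-bag majority
votes, importance is the per-feature mean decrease in Gini impurity,
proximity is the fraction of trees in which two neurons share a terminal
node (unit diagonal, symmetric), and the embedding is the first two
principal components of the proximity matrix. "The modal tree" of the
original description is operationalized as standard majority voting.
Forest cross-validation bootstraps the 80% training split (with
replacement) and scores the untouched 20%, 20 runs. All stochastic
procedures take explicit seeds and are reproducible bit-for-bit.

## Statistics

Normality is assessed per group with the Anderson–Darling test (case with
estimated mean and variance; statistic modified by 1 + 0.75/n + 2.25/n²,
p-value by the D'Agostino–Stephens piecewise approximation; Shapiro–Wilk
fallback below n = 8 where that approximation is unreliable). Data are
"normal" only if every group passes at 0.05. Normal designs use the t
family and one-way ANOVA with Tukey HSD (family-wise 0.05); non-normal use
Wilcoxon signed-rank / Mann–Whitney / Kruskal–Wallis with Mann–Whitney post
hocs corrected by Benjamini–Hochberg step-up (not BY), reporting
α_FDR = (i*/m)·α. Two-sample distribution comparisons use Kolmogorov–
Smirnov. Everything is two-tailed. Summaries follow normality: mean ± sem
or median with IQR.

## The synthetic world

The generators are pure functions of (spec, seed) and restore the caller's
RNG state.

**Current steps** (`sim_step_protocol`): a leaky integrator
(V = V_rest + IR(1 − e^(−t/τ))) plus three phenomenological elements.
*Sag* is a slow relaxation (τ_sag = 100 ms) from a transient minimum toward
steady state, applied only to steps at or below −150 pA — sag is measured
at −200 pA only, and HCN-like sag on the small 10 pA-series steps would
contaminate the I–V window that defines membrane resistance. The transient
amplitude is calibrated numerically (uniroot) so the *measured* sag equals
the requested percentage despite the overlap of charging and sag
exponentials. *APs* are parametric: a 1.2 ms sub-threshold foot, cosine
upstroke and downstroke (halfwidth exactly (t_up + t_down)/2 by
construction), and an alpha-function AHP whose recovery targets the
inter-spike base level — targeting the previous spike's tail instead makes
the AHP drift spuriously across a train. *Trains* realize the requested
maximum rate as constant ISIs at the last pre-attenuation step and the
adaptation ratios at rheobase + 50 pA (first ISI = ratio × later ISIs, so
counts still rise monotonically across steps and the attenuation rule is
not falsely triggered). Ground-truth vectors use peak-referenced timing to
match the measurement definitions.

The FS/nFS default parameter sets (e.g. FS: 150 MΩ, 150 Hz, 0.6 ms
halfwidth, 4% sag; nFS: 250 MΩ, 60 Hz, 1.1 ms, 22%, 2 rebound spikes)
encode the qualitative fast-spiking/non-fast-spiking contrast; they are
explicitly non-canonical, as population means are not printed in the source
material.

**Evoked sweeps** (`sim_evoked`): Gaussian baseline noise (default σ = 3 pA,
i.e. raw MAD ≈ 2 pA — the stated acceptance world), a biphasic artifact
inside the 2 ms blanking window, Bernoulli(p) all-or-none events of fixed
amplitude with N(latency, jitter²) onsets and a biexponential kernel.
**Spontaneous traces** (`sim_spontaneous`): Poisson times, lognormal
amplitudes, fixed kernel. **Feature tables** (`sim_feature_table`): 60/45
Gaussian rows with the class contrast concentrated in max firing rate, sag
and AP halfwidth (4 SD default) plus a 1 SD minor set; response status
assigns 14/2 responders and 2/17 non-responders to the two classes, so
responder concordance is a computed, not asserted, quantity.

What the generators do **not** emulate — and hence what a green test does
not establish: conductance-based spike dynamics (no Hodgkin–Huxley
channels, no depolarization block shape), electrode/access-resistance
artifacts and drift, correlated or 1/f noise, overlapping evoked
polysynaptic responses, and any within-class correlation structure among
the 15 features. Parameter-recovery results certify the measurement code
against its own definitions, not biological realism.

## Numerical choices and degenerate inputs

* Exponential fits use L-BFGS-B on the sum of squares, log-linear
  initialization for τ, the double fit initialized from the single fit
  (τ₂ = 10τ₁, amplitudes 80/20, bounds τ > 0, A ≥ 0). A line-search
  warning at an already-converged optimum (residual < 10⁻⁶ of signal
  energy) is accepted.
* Tree CV ties go to the smaller tree; forest votes break ties toward the
  first class; Thorndike's largest gap at the final stage simply yields
  k = 2 (k = 1 is never forced).
* Z-scoring a constant column, clustering with missing values, paired
  designs with unequal lengths, empty baselines after artifact exclusion,
  and single-class labels all raise errors naming the offender.
* The Bayes-rate benchmark for the tree validator uses two Gaussian classes
  of 200 points *each*: the criterion treats the closed-form Bayes accuracy
  Φ(1) ≈ 84.1% as an asymptote, and at 200 points total the CART cutpoint
  noise alone costs ~3 points, which is a property of sample size, not of
  the implementation.

## Limitations

ABF ingestion requires prior export. The sEPSC charge-integral cutoff
(default 0.5) is a free parameter chosen to exclude narrow transients;
sensitivity to it should be checked on real data. The Thorndike gap uses
absolute height increments, which favours well-separated, comparably sized
clusters. Forest proximity is accumulated over all samples (in-bag and
out-of-bag alike). Importance values are mean Gini decreases per tree and
are not bias-corrected for correlated features.
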