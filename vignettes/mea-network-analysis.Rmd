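---
title: "Network-burst and irregularity analysis of developing MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-burst and irregularity analysis of developing MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

## The problem

Dissociated cortical neurons cultured on micro-electrode arrays (MEAs)
develop, over roughly the second and third week in vitro, from sparse,
uncorrelated "background" firing into a stereotyped regime of periodic,
network-wide synchronized bursts.  Comparing how this maturation unfolds in
two experimental conditions (here: control cultures vs cultures in which
EHMT1, the histone methyltransferase mutated in Kleefstra syndrome, has
been knocked down) requires a pipeline that turns raw extracellular voltage
into a per-recording vector of activity, synchrony and regularity
statistics, and then tests those statistics per developmental age
(days in vitro, DIV) with appropriate multiple-comparison control.

`meaburst` implements that pipeline end to end, together with a synthetic
generator that produces spike-train sets (and raw voltage) with planted
ground truth, so that every stage is testable without access to any
recording.

## Spike detection

Raw traces (10 kHz) are high-pass filtered (300 Hz, 6th-order Butterworth)
and offset-corrected per channel.  Filtering is applied forward-backward:
the effective magnitude response is squared, and, more importantly, the
phase is exactly zero, so detected spike times are not shifted by the
filter group delay.  Offset correction subtracts the per-channel *median*
of the signal, which centers it at zero; the alternative convention of
subtracting the median of the absolute value (which cannot center a
symmetric signal, and is kept only behind the `offset_operand` switch)
enters the pipeline solely through the threshold formula.

The detection threshold per channel is

$$\Theta_{ap} = f \cdot M(|signal|) \cdot 1.5,$$

with gain factor $f = 8$ and $M(|signal|)$ the median of the absolute
signal.  For Gaussian noise $M(|x|) = 0.6745\,\sigma$, so the default
threshold sits near $8.1\,\sigma$ of the noise floor.  A spike is
registered where the peak-to-peak excursion within a sliding window
exceeds $\Theta_{ap}$; its time is the time of the negative peak.  The
formula does not determine the window or the refractory handling, so both
are explicit parameters: `peak_window` defaults to 1 ms and `dead_time` to
2 ms, typical extracellular spike widths.  The threshold is computed on
the whole recording (not in blocks).  Electrodes are *active* when their
firing rate is strictly above 0.1 Hz; rates above `max_rate` (default
100 Hz, exposed because the original exclusion rule for noisy channels is
not quantified anywhere) mark a channel as noise.

## Network bursts

All spikes of the active electrodes are convolved with a unit-amplitude
Gaussian ($A = 1$, $\sigma = 50$ ms), evaluated on a 1 ms grid (50 times
finer than the kernel, so threshold crossings are effectively continuous;
the kernel is truncated at $5\sigma$, a relative mass error below
$10^{-6}$).  A network burst runs from the upward crossing of the density
threshold to the next downward crossing.  The nominal threshold of 10 is
referenced to a 60-electrode array; by default it is scaled by
`n_active / 60` so that per-electrode sensitivity stays constant while
cultures recruit electrodes during development (`scaling = "fixed"`
disables this).  Burst *size* is the area under the density inside the
burst window divided by the kernel area $A\sigma\sqrt{2\pi}$, i.e. a count
in spike equivalents; on well-separated bursts the sizes sum to the total
spike count within 5%.  Bursts in progress at either end of the recording
are discarded.  Interburst intervals are, by default, the quiescent gaps
(offset to next onset); onset-to-onset intervals are available via
`ibi_convention = "onset"` and are the right choice when recovering
renewal-process parameters, whose intervals are defined onset to onset.

Independently of burst detection, each spike is labeled background or
burst-candidate by the two-step isolation rule: (1) per electrode,
background if both neighbouring ISIs exceed $\theta_1 = 100$ ms; (2) the
remaining spikes, pooled across electrodes, are background if both pooled
ISIs exceed $\theta_2 = 5$ ms.  Both the window-based and the label-based
burst-spike percentages are reported (`pct_spikes_in_bursts`,
`pct_burst_labeled`), since either convention is defensible and the two
disagree by a few percent in practice.

A note on onset localization: the crossing time of a smoothed density has
an intrinsic bias of order $\sigma \cdot \Phi^{-1}(\theta_{eff}/D_{peak})$
(the kernel anticipates a sharp rate step when the threshold is far below
the plateau, and lags a slow envelope when it is close to it).  With
$\sigma = 50$ ms, onsets are localized to a few tens of milliseconds when
the burst plateau density is a moderate multiple (about 1.2-6x) of the
effective threshold; the burst-recovery validation uses such a fixture.
For very dense bursts the onset is systematically early, for slowly
igniting ones systematically late — by up to ~0.1 s either way.  All
downstream statistics are contrasts between conditions analysed with the
same kernel, so this bias cancels in the comparisons.

## Irregularity statistics

* `cv_isi`: per-electrode coefficient of variation of the interspike
  intervals (sample SD over mean), averaged over active electrodes.  The
  sample (n-1) standard deviation is used everywhere; with the small
  interval counts of a 20-minute recording the bias of the population
  estimator would not be negligible, and fixing the convention makes the
  tests deterministic.
* `fano_factor`: variance-to-mean ratio of spike counts in 5 s windows
  slid by 1 s, per electrode, averaged over active electrodes.  1 for
  Poisson firing, 0 for perfectly periodic firing, increasing with
  renewal-interval CV in between.  The overlapping windows correlate
  neighbouring counts; this leaves the expectation untouched but inflates
  the sampling variability of the estimate, which is why the validation
  tolerance for the Poisson identity is $\pm 0.15$ rather than the
  $\pm 0.03$ a naive independent-window calculation would suggest.
* `cv_ibi`: CV of the interburst intervals; needs at least 3 bursts.
* `ir`: rate-independent burst irregularity, the mean absolute natural-log
  ratio of consecutive IBIs, $\frac{1}{N-1}\sum_{i=1}^{N-1}
  |\ln(IBI_{i+1}/IBI_i)|$.  Multiplying all IBIs by a constant leaves it
  exactly unchanged, so it separates "slower bursting" from "less regular
  bursting".  The natural log is used; any other base would scale all
  values by a constant and leave every between-condition comparison
  unchanged.  For i.i.d. exponential IBIs the log ratio is standard
  logistic and IR converges to $2\ln 2 \approx 1.386$, a closed form the
  tests exploit.

## Autocovariance

Per active electrode, the spike train is binned at 1 ms and the
autocovariance $C_{xx}(\tau) = \sum_n (x_n - \mu_x)(x_{n+\tau} - \mu_x)$
is accumulated for lags $0 < |\tau| < 2$ s and normalized by $T - |\tau|$.
The zero-lag bin is excluded.  The implementation never materializes the
dense count vector: the raw product sum at lag $k$ equals the number of
spike pairs exactly $k$ bins apart (a pairwise-lag histogram, computed in
compiled code), and the mean-correction terms follow from cumulative spike
counts; the dense definition is retained in the test suite as an
independent oracle.  Binning at 1 ms rather than the native 10 kHz keeps
the computation tractable and is well inside the 5 ms moving-average
smoothing applied next.  The smoothed per-electrode curves are averaged,
the average is normalized to peak 1 per recording, and the *half-width* —
the full width at half maximum around the global peak, with linear
interpolation at the crossings — summarizes the timescale of spike-time
coherence.  ("Width at half max" is ambiguous between the full and the
half width; the full width is used, and since only relative comparisons
enter the statistics the choice is inconsequential.)  A curve that never
falls below half maximum within the lag range returns the full range with
a saturation flag.

## Group statistics

Culture metrics are rarely normal (they are rates, percentages and CVs of
small counts); a Jarque-Bera screen documents this per group, and the
condition comparison uses the Mann-Whitney rank-sum test throughout
(exact for small tie-free samples, normal approximation with tie and
continuity corrections otherwise).  Within each DIV, the p-values of the
metric family are adjusted by the Benjamini-Yekutieli step-up procedure,
which controls the FDR under arbitrary dependence — the metrics of one
recording are strongly dependent (burst rate and mean IBI are nearly
reciprocal).  The original analysis used a q-value estimator with a
polynomial lambda selector; that estimator needs hundreds of p-values to
stabilize and is erratic on families of ~10, so the dependency-robust
step-up is the default here (Benjamini-Hochberg remains available).  The
adjusted values are explicitly capped from below by the raw p-values
("correction never increases significance"), and significance is declared
at adjusted $p < 0.05$, two-sided.  Families are partitioned strictly by
DIV: adjusting one age can never change another's results.

## The synthetic generator

`simulate_culture()` draws from a doubly stochastic model chosen as the
simplest process with the statistical structure the analysis assumes:

* network-burst onsets are a **gamma renewal process** (shape $1/CV^2$,
  scale $mean \cdot CV^2$), giving independent control of the burst rate
  and of `cv_ibi` — the two axes along which the conditions differ;
* each burst recruits each electrode with probability
  `participation_prob`; recruited electrodes contribute Poisson spike
  counts placed by a within-burst envelope (gamma-decay latencies by
  default, reproducing the rise-and-fall firing profile of real network
  bursts; uniform as an option);
* background firing is homogeneous Poisson per electrode;
* bursts reaching past the recording end are truncated and flagged.

Every per-culture, per-DIV simulation gets a child seed derived from the
master seed by a counter scheme, so any single recording can be reproduced
in isolation.  `simulate_study()` re-simulates the same culture at each
DIV (a longitudinal design) and gives each culture a persistent lognormal
activity multiplier (`heterogeneity_sd = 0.2`, applied to background and
burst rates).  Without it, between-culture variation would be mere
sampling noise and any group test would be degenerately powerful;
20% between-well variability is typical of culture batches.

The condition presets encode the developmental fingerprint the analysis
is meant to resolve, at 20 minutes and 60 electrodes per recording:
controls mature from sparse weakly-synchronized firing at DIV 10 to
stationary regular bursting by DIV 15-17; the deficient condition has a
40% lower burst rate, 18% lower background rate and 24% longer bursts at
DIV 13, partial catch-up at DIV 15, and fully recovered rates but a
markedly higher IBI CV (0.45 vs 0.30) at DIV 17.  Where the underlying
study reports only percentage contrasts and significance, not absolute
rates, the baselines (0.15-0.3 Hz background per electrode, 10-45 s mean
IBIs) were fixed once at values typical for dissociated cortical cultures;
in particular the resting network density
(rate x electrodes x kernel area) must sit well below the 10 Hz burst
threshold, which bounds realistic background rates by about 0.5 Hz.  Two
reported contrasts — the 40% burst-rate reduction and the 39% longer
IBIs at DIV 13 — cannot both hold exactly for a renewal process (a 0.6
rate multiplier implies 67% longer intervals); the presets follow the
burst-rate multiplier, and the simulated IBI contrast accordingly comes
out larger than 39%.  Similarly, the total MFR contrast at DIV 13 emerges
from both the background reduction and the missing burst spikes and
exceeds the 18% background multiplier alone.

What the generator does *not* emulate: electrode geometry and propagation
delays, burst-internal structure beyond the latency envelope (no
avalanches, no leader electrodes), firing-rate drift within a session,
electrode dropout, or non-Poisson background statistics.  Passing the
planted-ground-truth validations therefore demonstrates that the pipeline
measures what it claims on data with the assumed structure — not that the
assumed structure exhausts real MEA recordings.

## Numerical choices and degenerate inputs

* Density grid `dt` = 1 ms; kernel truncation $5\sigma$; crossings and
  half-widths linearly interpolated between grid points.
* A recording whose density never crosses the threshold yields an empty
  burst train; burst metrics are then `NA` (missing), never zero.
* Fewer than 2 intervals make CV/IR missing; nonpositive IBIs are an
  error (they cannot arise from the detector, whose windows are disjoint).
* All-zero channels get threshold 0 and a dead-channel flag; an
  all-inactive recording is an error carrying the per-electrode rates.
* MFR is normalized by the active-electrode count at the culture's final
  recorded DIV; when unknown, the current count is used with a warning.
* Validation problem sizes: 20-minute, 60-electrode simulations for the
  burst-recovery and parameter-recovery checks; 60 s, 8-channel, 10 kHz
  traces for raw-voltage detection; 200 reduced-scale replicate studies
  (300 s, 12 electrodes, 8 vs 8 cultures) for the null false-positive
  rate; 100 full-scale replicate studies at DIV 13 (25 vs 19 cultures)
  for the power of the burst-rate comparison.

## Known limitations

* No spike sorting: threshold crossings per electrode are treated as
  multi-unit activity, as in the original analysis.
* Burst onset localization carries the kernel-scale bias described above;
  absolute onset times should not be interpreted below ~0.1 s.
* The Jarque-Bera chi-squared reference is anti-conservative for n < 50;
  it is used only as a descriptive screen, never for inference.
* The Fano factor estimate from overlapping windows has a wide sampling
  distribution on 20-minute recordings; condition contrasts in FF need
  group sizes of the order used here (~20) to be detectable.
* `simulate_study()` treats DIVs independently given the culture
  multiplier; real longitudinal recordings have richer within-culture
  correlation across ages, and the per-DIV test families do not model it
  (matching the original per-DIV analysis).
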