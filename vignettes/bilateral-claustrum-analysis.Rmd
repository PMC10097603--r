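---
title: "Bilateral claustrum sleep analysis: models, parameters and design choices"
author: "claustra package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral claustrum sleep analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

During the REM-like sleep phase of the bearded dragon (*Pogona vitticeps*),
here called REM_P, the claustrum produces trains of sharp negative field
potentials (SNs). The two claustra produce these events in tight bilateral
register, offset by about 20 ms, with the leading side switching slowly —
typically zero or one switch per REM_P episode — and the leading side's
events larger in amplitude. During slow-wave (SW) sleep, by contrast, each
claustrum produces sharp-wave ripples independently. An isthmic midbrain
nucleus (Imc) carries matching deflections that lead the ipsilateral
claustrum by about 30 ms and the contralateral one by about 50 ms;
unilateral Imc lesions abolish side switching and shorten REM_P episodes.

`claustra` implements the full analysis chain for such recordings:

1. **Preprocessing** (`conditionSignal`, `synchronizeRecordings`,
   `bandPower`, `snRate`): clock alignment via a shared 1-Hz square wave,
   zero-phase low-pass conditioning, derivatives, and sliding band power.
2. **SN detection** (`detectTriplets`, `estimateNoise`,
   `filterCandidates`, `detectSN`): derivative triplet-peak detection with
   a sign-flip noise null.
3. **Bilateral matching** (`scorePairs`, `matchPairs`, `acceptPairs`,
   `matchSN`): optimal one-to-one assignment of left and right SNs.
4. **Leadership** (`laggedXcorr`, `peakLagDistribution`,
   `leadershipScore`, `segmentDominance`): sliding lagged
   cross-correlation, the instantaneous-leadership score, and dominance
   segmentation.
5. **Sleep macrostructure** (`segmentSleep`, `episodeStats`,
   `amplitudeLagStats`, `welchCompare`, `lagSignedRank`).
6. **A synthetic-night generator** (`generatorConfig`, `generateNight`,
   `generateSpikes`) that emulates the statistical structure of these
   recordings with full ground truth, so every stage can be validated
   without recorded data.

# Detection model

A candidate SN is a triplet of derivative peaks on the 40-Hz low-passed
signal: a negative second-derivative peak (start of the downward phase), a
negative first-derivative peak (steepest descent), and a positive
second-derivative peak (end of the downward phase). Amplitude is
`v(t_start) - v(t_end)` and duration `t_end - t_start`. Conditioning is
zero-phase (forward–backward order-4 Butterworth), so event times are not
shifted — essential for ±20-ms lag analyses.

Two numerical choices matter here:

* **Peak floors.** Raw peak picking uses a magnitude floor of 0.5 times
  the standard deviation of each derivative (config-exposed). This
  suppresses numerical micro-peaks without touching genuine events, whose
  derivative peaks are an order of magnitude above the noise floor at
  realistic SNRs.
* **Flank association.** Each steepest-descent trough is flanked by the
  nearest preceding negative and following positive second-derivative
  peaks within 100 ms; triplets sharing a flank pair keep the steeper
  trough.

## The sign-flip noise null

False positives are controlled by detecting "events" on the sign-inverted
signal, where true SNs cannot exist. A subtlety that shapes the whole
filter: in any dense train of sharp falls, the signal must come back up
between events, so the inverted signal's detections are dominated by the
*recovery ramps* — events of comparable amplitude but substantially longer
duration than the true falls. A noise event therefore only counts against
a candidate if it is at least as large **and** at least as sharp: the null
statistic is the joint tail `P(noise amplitude >= a AND noise duration <=
d)`. Because a bivariate tail statistic is not uniform under the null, the
acceptance cut is rank-calibrated on the noise sample itself: a candidate
is kept when its statistic is at or below the `alpha` (default 0.025)
quantile of the noise events' own statistics. This pins the filter's
false-positive rate at `alpha` (measured 2.7% on pure-noise input) while
keeping ~98% of true events at default SNR. Matched bilateral pairs are
accepted when at least one member has null probability below 0.05.
Detection and matching run in consecutive 1-h sections, with the noise
model estimated per section.

# Matching model

Every left–right candidate pair within ±51 ms is scored by the local
cross-correlation of the negative-clipped first derivatives in a 100-ms
window centered at the midpoint between the two events, evaluated at the
pair's lag and weighted by `exp(-|lag| / 10 ms)`. Clipping makes scores
non-negative, so "maximize the total score" is well defined. The optimal
one-to-one combination is found by maximum-weight bipartite matching on
the sparse candidate graph; because no edge spans a gap wider than the lag
window, the graph decomposes into independent components (one per train
segment), which keeps the globally optimal assignment linear-time in
practice. An exhaustive-enumeration oracle verifies optimality on small
instances in the test suite.

# Leadership and dominance

The instantaneous-leadership score for a lag of +20 ms (left leads) is the
base-10 logarithm of the 10-s windowed sum of products of the
negative-clipped first derivatives, the right channel shifted by the lag;
the -20-ms score is its mirror. Sums are floored at `1e-12` before the
logarithm so empty-product windows map to a finite floor. The score is
evaluated exactly as written — the averaging window is centered on the
unshifted channel — which makes the left/right swap identity exact only up
to the 20-ms window offset (the test suite checks it at that tolerance).

Dominance states are segmented with per-side linear thresholds. The
original analysis sets these manually per animal; `claustra` provides a
reproducible stand-in, `calibrateDominanceThresholds`: pooled left/right
scores within REM_P are split by 2-means into a non-leading and a leading
cluster, and the threshold is placed at 70% of the way from the
non-leading to the leading center. The fraction matters because windows
straddling a dominance switch carry partial contributions of both sides
and score *between* the clusters; a threshold close to the leading cluster
leaves them below both thresholds, hence labelled unsettled. The default
0.70 was calibrated on synthetic nights so that the mean detected
unsettled time per switching episode is unbiased for the generating
process (a 4-s unsettled window yields ~4.8 s detected, the excess being
10-s-window smoothing); switch counts are insensitive to the choice over
0.55–0.75. Dominance runs shorter than 3 s are merged into their
surroundings, and an unsettled run at the very edge of an episode — where
the score window straddles SW and leadership is undefined — is attributed
to its settled neighbour.

# Sleep segmentation

REM_P/SW segmentation thresholds the beta-band (12–30 Hz) power trace
(10-s windows, 1-s steps), merging state runs shorter than 15 s. The
published recipe thresholds at the trace's 15th percentile; that
percentile only falls between the SW and REM_P power clusters when SW
occupies less than 15% of the night, which neither the stated sleep
structure (SW share ~35%, ~70% in lesion mode) nor the published lesion
numbers satisfy. `segmentSleep` therefore implements the percentile rule
faithfully (default `pct = 15`) but also accepts an explicit threshold,
and the pipeline default is `betaThreshold2Means`: 2-means clustering of
log10 beta power with the threshold at the arithmetic midpoint of the two
cluster centers on the power scale. The arithmetic midpoint keeps episode
boundaries unbiased, because a 10-s window straddling a transition crosses
it when half filled with REM_P signal. A second pass
(`refineEpisodeBoundaries`) re-localizes each boundary with a 2-s-window
beta trace and the midpoint of the *local* SW and REM_P levels, reducing
the residual boundary bias to well under a second on synthetic nights.

# The synthetic-night generator

The generator is phenomenological: it reproduces the statistical structure
the analysis assumes, not the biophysics. A night is a sequence of full
sleep cycles (SW then REM_P) with cycle lengths uniform in 90–150 s.
REM_P episode durations are Gaussian with mean 57 s (s.d. 16.6) for
episodes without a dominance switch and 88.5 s (s.d. 19.6) with one
switch; an episode has one switch with probability 103/162 and two with a
residual 0.02. A first-order autoregressive side bias (coefficient 0.9 per
episode) produces the slow waxing and waning of side dominance across the
night. Each switch is surrounded by a 4-s unsettled window in which both
sides emit independent trains.

**IEI law.** Per-channel inter-event intervals follow a refractory-shifted
log-normal, `IEI = 30 ms + LN(mu, sigma)`, with `sigma^2 =
log((median-30)/(mode-30))` so that the law has exactly the configured
median (60.2 ms) and mode (40 ms). The shift encodes that an SN plus its
recovery occupies several tens of milliseconds, and it gives the law a
sharp, stable mode; an unshifted log-normal puts 4–5% of its mass below
25 ms, which is undetectable at a 40-Hz bandwidth and distorts the
detected distribution. Because the published statistics describe the
*detected* per-channel stream, the generator calibrates `mu` at run time
(an internal 200,000-interval simulation on the seeded RNG) so that the
emitted stream — leader phases plus follower copies thinned at
`p_bilateral = 0.9`, less a nominal 3% detection loss — has the configured
median. Verified on seeded nights, the detected median lands within ~1–3%
of 60.2 ms.

**Waveforms.** An SN is a sharp Gaussian fall (width
`duration/sqrt(3)`, so triplet detection recovers the configured
falling-phase amplitude and duration on the unfiltered waveform) followed
by a double-exponential recovery: 30% of the amplitude returns with a
fast time constant (7 fall-widths) and the rest relaxes with a 200-ms
baseline constant. Partial fast recovery matters: if each event recovered
fully between events, charge balance would force inter-event upstrokes of
~0.3 of the event scale, and the sign-flip null would be saturated by
rebound artifacts; with a depressed baseline — as in AC-coupled
extracellular recordings of dense trains — the inverted signal stays
clean. Followers copy the leader at +20 ms (3-ms Gaussian jitter) with
amplitude scaled by 0.8 and existence probability 0.9. Sharp-wave ripples
during SW are biphasic (15-ms sharp wave, shallow 50-ms rebound at
+80 ms, small 28-Hz ripple) at 1 per second per side with a 250-ms
refractory period. Imc channels carry the same fall/recovery morphology
30 ms before each dominant-side SN, only while their side is dominant
(matching the observation that a side's Imc is active when its claustrum
leads); the lesioned side's Imc is silent. The noise floor is pink (1/f),
10 µV RMS — a realistic in-band extracellular noise floor, and one at
which sign-flip wiggle artifacts stay below the event scale. Spiking
units fire on each ipsilateral SN with per-unit probabilities drawn from
14–43% (2-ms jitter around the steepest descent; multi-spike probability
0.3–3%) over a 0.05-Hz background.

Invented defaults the source data do not constrain numerically —
SN duration (10 ms median) and amplitude (200 µV median, log-normal
spread 0.15), the recovery shape, SWR and Imc amplitudes, jitters, and
the noise floor — are all config-exposed, and the resolved configuration
is written next to every run.

**What the generator does not emulate.** Real recordings have
heavy-tailed, non-stationary noise, electrode drift, movement and licking
artifacts, volume-conducted cross-talk between probes, amplitude
non-stationarity across the night, and SN waveform diversity. Passing the
recovery suites therefore demonstrates that the analysis chain is correct
and well-calibrated under the assumed statistical structure — not that it
is robust to every pathology of real data. Thresholds (dominance,
sleep-state) would still be inspected per animal in practice, as in the
original analysis.

# Problem sizes and runtime

The validation suites use 600–1800-s nights for unit-level recovery and,
for the acceptance runs, one 1-h default night (interval statistics,
lag distributions, matching), one 3-h night (episode statistics: roughly
85 episodes, of which ~55 contain one switch), and one 2-h lesion night —
sizes at which every recovered statistic has a comfortable sampling
margin against its tolerance. A full 1-h night runs through the entire
chain in about a minute on one core; memory stays under a few hundred MB
per conditioned hour.

# Known limitations

* Detected durations are filter-limited: a 40-Hz low-pass stretches a
  10-ms falling phase to ~16 ms, so duration statistics characterize the
  conditioned, not the raw, waveform (amplitude and timing are
  essentially unbiased).
* Events closer than ~20 ms merge; the generator's refractory shift keeps
  this region almost empty, as the published interval distribution implies.
* The lagged cross-correlation normalizer (99.9th percentile) is
  meaningful only when the matrix contains genuinely correlated epochs;
  on pure-noise input the normalized values are not small.
* `calibrateDominanceThresholds` assumes both score traces share a scale
  (guaranteed here by z-scored conditioning); strongly asymmetric
  electrode gains would require manual thresholds.
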