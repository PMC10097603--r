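# claustra

Analysis of bilateral claustrum sleep electrophysiology in reptiles.

During the REM-like sleep phase (REM_P) of the bearded dragon, the
claustrum emits trains of **sharp negative field potentials (SNs)** —
brief downward deflections recurring every few tens of milliseconds. The
two claustra produce these events in tight bilateral register but offset
by about 20 ms, with the *leading* side switching slowly (typically zero
or one switch per REM_P episode) and carrying the larger events; during
slow-wave (SW) sleep the two sides instead produce sharp-wave ripples
independently. An isthmic midbrain nucleus (Imc) leads the ipsilateral
claustrum by ~30 ms and the contralateral one by ~50 ms, and unilateral
Imc lesions abolish the switching. `claustra` provides the complete
pipeline for quantifying this structure, for electrophysiologists working
with multichannel sleep recordings:

* **Preprocessing** — sync-pulse clock alignment, zero-phase 40-Hz
  conditioning with derivatives, sliding beta-band (12–30 Hz) power.
* **SN detection** — a candidate SN is a triplet of derivative peaks
  (negative `v''`, negative `v'`, positive `v''` = start, steepest
  descent, end of the falling phase); false positives are filtered
  against a *sign-flip null* (the same detector run on `-v`, where true
  SNs cannot exist) at null probability `P < 0.025`.
* **Bilateral matching** — candidate left–right pairs within ±51 ms are
  scored by the local 100-ms cross-correlation of negative-clipped
  derivatives times an `exp(-|lag|/10 ms)` kernel, and the one-to-one
  assignment maximizing total score is found by maximum-weight bipartite
  matching; pairs are accepted if either member has `P < 0.05`.
* **Leadership** — sliding lagged cross-correlation (10-s windows, 100-ms
  steps, ±51-ms lags, 99.9th-percentile normalization), peak-lag
  distributions, and the instantaneous-leadership score
  `s±20(t) = log10[ Σ_τ [c0(t+τ)]⁻ [c1(t+τ±20)]⁻ ]`
  computed on clipped first derivatives, from which each REM_P instant is
  labelled left-leading, right-leading or unsettled (3-s defragmentation).
* **Sleep macrostructure** — REM_P/SW segmentation from the beta-power
  trace (15-s defragmentation), per-episode switch counts and state
  times, amplitude-versus-lag statistics (Mann–Whitney), and
  lesion-versus-control comparisons (Welch's t, signed-rank).
* **A synthetic-night generator** — `generateNight()` produces
  multichannel nights (claustrum-L/R, imc-L/R, 1-Hz sync) with full
  ground truth that reproduce the statistical structure above: a
  refractory-shifted log-normal inter-event-interval law (median 60.2 ms,
  mode 40 ms per channel), ±20-ms bilateral pairs with the leader 1.25×
  larger, 0–1 dominance switches per episode, episode-duration laws
  (57 s without a switch, 88.5 s with one), Imc leads of 30/50 ms, and a
  unilateral-lesion mode (33-s episodes, all dominance on the intact
  side). Every stage of the pipeline is validated by recovering these
  parameters from generated nights.

## Worked example

```r
library(claustra)

night <- generateNight(generatorConfig(duration_s = 600, seed = 7))
rec  <- night$recording
sigL <- conditionSignal(rec, "claustrum-L")
sigR <- conditionSignal(rec, "claustrum-R")

detL <- detectSN(sigL); detR <- detectSN(sigR)
st <- ieiStats(detL$events, episodes = episodes(night$truth))

pairs <- matchSN(detL, detR, sigL, sigR)
pl <- peakLagDistribution(laggedXcorr(sigL, sigR))

beta <- bandPower(sigL)
segs <- refineEpisodeBoundaries(
  segmentSleep(beta, threshold = betaThreshold2Means(beta)), sigL)
trace <- leadershipScore(sigL, sigR)
trace <- segmentDominance(trace,
  calibrateDominanceThresholds(trace, segs), segs)
episodeStats(segs, attr(trace, "segments"))
```

which prints, summarized:

```
left-channel SNs: 4967; IEI median 60.0 ms, mode 37.5 ms
accepted bilateral pairs: 4409; median |lag| 20.0 ms
peak-lag modes: -20 / +20 ms (bimodal: TRUE)
REM_P episodes: 5; switch counts: 0x1, 1x3, 2x1
```

Read: on this 10-minute synthetic night the detector recovered ~5,000 SNs
per channel whose interval statistics match the generating law (median
60 ms, mode in the 35–40 ms bin); 4,409 left–right pairs were accepted at
the expected ±20-ms offset; the lag distribution is bimodal at ±20 ms
(both sides led at some point); and the five REM_P episodes contained
one, three and one episodes with zero, one and two dominance switches.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/claustra-cli.R` (subcommands `simulate`, `preprocess`,
`detect`, `match`, `leadership`, `segment`, `run-all`), and `runAll()`
executes the whole chain into a run directory with stamped CSV/JSON
artifacts and the resolved YAML configuration.

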