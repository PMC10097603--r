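shiftSignal <- function(sig, lagSamples) {
  ## sig delayed by lagSamples: y(t) = x(t - lag)
  n <- length(sig@v)
  idx <- pmax(seq_len(n) - lagSamples, 1L)
  new("ConditionedSignal", v = sig@v[idx], c = sig@c[idx], c2 = sig@c2[idx],
      rateHz = sig@rateHz, role = "claustrum-R", t0 = sig@t0,
      filterDesc = sig@filterDesc)
}

snTrainSignal <- function(dur = 40, rate = 1000, seed = 41) {
  ## sparse train: events at least 60 ms apart, so +/-20 ms misalignment
  ## leaves no product overlap
  set.seed(seed)
  tt <- (seq_len(dur * rate) - 1) / rate
  v <- claustra:::pinkNoise(length(tt), 5)
  times <- cumsum(0.06 + rlnorm(1000, log(0.04), 0.5))
  for (t0 in times[times < dur - 0.5])
    v <- v - 200 * exp(-(tt - t0)^2 / (2 * 0.005^2))
  analyticConditioned(v, rate, "claustrum-L")
}

test_that("lagged cross-correlation localizes a constructed shift", {
  sig <- snTrainSignal()
  same <- laggedXcorr(sig, sig, windowS = 10, stepS = 0.5)
  pl <- peakLagDistribution(same, keepQuantile = 0.5)
  expect_true(all(pl$lags_ms == 0))

  lag20 <- shiftSignal(sig, 20)
  xc <- laggedXcorr(sig, lag20, windowS = 10, stepS = 0.5)
  pl20 <- peakLagDistribution(xc, keepQuantile = 0.5)
  ## positive lag = channel 0 leads
  expect_true(all(abs(pl20$lags_ms - 20) <= 1))
  expect_equal(pl20$modes_ms[2], 20)

  expect_error(laggedXcorr(sig, snTrainSignal(dur = 20)), "equal length")
})

test_that("normalization sets the 99.9th percentile to one, idempotently", {
  sig <- snTrainSignal()
  xc <- laggedXcorr(sig, shiftSignal(sig, 20), windowS = 10, stepS = 0.5)
  expect_equal(quantile(xc@m, 0.999, names = FALSE), 1, tolerance = 1e-9)
  again <- quantile(xc@m / quantile(xc@m, 0.999, names = FALSE), 0.999,
                    names = FALSE)
  expect_equal(again, 1, tolerance = 1e-9)
})

test_that("uncorrelated stretches have low correlation relative to the
           norm set by correlated epochs", {
  ## the 99.9th-percentile normalizer is meaningful when the matrix
  ## contains genuinely correlated epochs (as in a night with SN trains):
  ## windows over independent noise then normalize to small values
  set.seed(42)
  sig <- snTrainSignal(dur = 20)
  noiseA <- claustra:::pinkNoise(20000, 5)
  noiseB <- claustra:::pinkNoise(20000, 5)
  a <- analyticConditioned(c(sig@v, noiseA))
  b <- analyticConditioned(c(sig@v, noiseB))
  xc <- laggedXcorr(a, b, windowS = 10, stepS = 0.5)
  noiseRows <- xc@t > 25 & xc@t < 35
  pk <- apply(abs(xc@m[noiseRows, ]), 1, max)
  expect_gt(mean(pk < 0.2), 0.95)
})

test_that("the leadership score equals a literal loop evaluation", {
  set.seed(43)
  rate <- 1000
  for (rep in 1:5) {
    n <- 2000
    s0 <- analyticConditioned(rnorm(n, sd = 30), rate)
    s1 <- analyticConditioned(rnorm(n, sd = 30), rate)
    tr <- leadershipScore(s0, s1, lagMs = 20, windowS = 1, stepS = 0.25)
    half <- round(0.5 * rate)
    for (k in seq(1, length(tr@t), by = 3)) {
      ctr <- round(tr@t[k] * rate) + 1L
      want <- leadershipLoopOracle(s0@c, s1@c, ctr, 20, half)
      expect_equal(tr@sPlus[k], want, tolerance = 1e-9)
      wantM <- leadershipLoopOracle(s0@c, s1@c, ctr, -20, half)
      expect_equal(tr@sMinus[k], wantM, tolerance = 1e-9)
    }
  }
})

test_that("leadership score floors at log10(eps) and swaps symmetrically", {
  rate <- 1000
  flat <- analyticConditioned(rep(0, 15000), rate)
  tr <- leadershipScore(flat, flat, floorEps = 1e-12)
  expect_true(all(tr@sPlus == log10(1e-12)))
  expect_true(all(tr@sMinus == log10(1e-12)))

  sig <- snTrainSignal()
  lag20 <- shiftSignal(sig, 20)
  tr1 <- leadershipScore(sig, lag20)
  tr2 <- leadershipScore(lag20, sig)
  ## swapping the channels exchanges the two scores; the equality is
  ## exact up to the 20-ms offset of the (unshifted) averaging window
  expect_lt(max(abs(tr1@sPlus - tr2@sMinus)), 0.02)
  expect_lt(max(abs(tr1@sMinus - tr2@sPlus)), 0.02)

  ## products align only at the +20 lag: clear margin over the whole overlap
  interior <- tr1@t > 6 & tr1@t < max(tr1@t) - 6
  expect_true(all((tr1@sPlus - tr1@sMinus)[interior] > 1))
})

test_that("dominance segmentation defragments and labels states", {
  t <- seq(0, 100, by = 0.1)
  sPlus <- rep(-1, length(t)); sMinus <- rep(-1, length(t))
  ## left-dominant for 30-60 s with a 2-s sub-threshold blip at 45 s
  sPlus[t >= 30 & t < 60] <- 1
  sPlus[t >= 45 & t < 47] <- -1
  tr <- new("LeadershipTrace", t = t, sPlus = sPlus, sMinus = sMinus,
            state = character(0),
            params = list(lagMs = 20, windowS = 10, stepS = 0.1))
  ep <- data.frame(state = c("SW", "REM_P", "SW"),
                   start_s = c(0, 30, 60), end_s = c(30, 60, 100))
  out <- segmentDominance(tr, c(left = 0, right = 0), ep, minDurS = 3)
  segs <- attr(out, "segments")
  expect_identical(segs$side, "left")        # blip absorbed, one segment
  expect_equal(segs$start_s, 30)
  expect_equal(segs$end_s, 60)
  expect_true(all(out@state[t < 30 | t >= 60] == "SW"))

  ## both scores below threshold -> single unsettled segment
  tr2 <- new("LeadershipTrace", t = t, sPlus = rep(-1, length(t)),
             sMinus = rep(-1, length(t)), state = character(0),
             params = list(lagMs = 20, windowS = 10, stepS = 0.1))
  out2 <- segmentDominance(tr2, c(left = 0, right = 0), ep, minDurS = 3)
  segs2 <- attr(out2, "segments")
  expect_identical(segs2$side, "unsettled")

  expect_error(segmentDominance(tr, NULL, ep), "thresholds")
})

test_that("seeded synthetic dominance switches are recovered within 2 s", {
  night <- sharedNight(1800, seed = 13)
  sigL <- conditionSignal(night$recording, "claustrum-L")
  sigR <- conditionSignal(night$recording, "claustrum-R")
  trace <- leadershipScore(sigL, sigR)
  ep <- episodes(night$truth)
  thr <- calibrateDominanceThresholds(trace, ep)
  trace <- segmentDominance(trace, thr, ep)
  segs <- attr(trace, "segments")

  ## true switch times: boundaries between left and right truth segments
  tdom <- dominanceSegments(night$truth)
  r <- tdom[tdom$side != "unsettled", ]
  swTrue <- (r$start_s[-1] + head(r$end_s, -1)) / 2
  swTrue <- swTrue[r$side[-1] != head(r$side, -1)]
  d <- segs[segs$side != "unsettled", ]
  swDet <- (d$start_s[-1] + head(d$end_s, -1)) / 2
  swDet <- swDet[d$side[-1] != head(d$side, -1)]
  expect_gte(fractionMatched(swTrue, swDet, tol = 2), 0.9)
})
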