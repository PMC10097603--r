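test_that("flat signals produce no candidates", {
  s <- analyticConditioned(rep(2.5, 3000))
  expect_identical(nrow(detectTriplets(s)), 0L)
})

test_that("a Gaussian trough yields the analytic triplet geometry", {
  ## v(t) = -A exp(-(t-t0)^2 / (2 sigma^2)), A = 300 uV, sigma = 5 ms:
  ## second-derivative peaks at t0 - sigma*sqrt(3) and t0, first-derivative
  ## trough at t0 - sigma, so duration = sigma*sqrt(3) ~ 8.66 ms and
  ## amplitude = A (1 - e^-1.5) ~ 233 uV
  rate <- 1000
  tt <- (seq_len(2000) - 1) / rate
  t0 <- 1.0; A <- 300; sigma <- 0.005
  v <- -A * exp(-(tt - t0)^2 / (2 * sigma^2))
  s <- analyticConditioned(v, rate)
  cand <- detectTriplets(s, prominenceFloor = c(1, 0.1))
  expect_identical(nrow(cand), 1L)
  expect_equal(cand$t_start_s, t0 - sigma * sqrt(3), tolerance = 2e-3)
  expect_equal(cand$t_steep_s, t0 - sigma, tolerance = 2e-3)
  expect_equal(cand$t_end_s, t0, tolerance = 2e-3)
  expect_equal(cand$duration_ms, sigma * sqrt(3) * 1000, tolerance = 0.15)
  expect_equal(cand$amplitude, A * (1 - exp(-1.5)), tolerance = 1)
})

test_that("detection is deterministic and covariant under scaling", {
  night <- sharedNight(120, seed = 9)
  s <- conditionSignal(night$recording, "claustrum-L", zscore = FALSE)
  c1 <- detectTriplets(s)
  c2 <- detectTriplets(s)
  expect_identical(c1, c2)

  k <- 3.7
  sk <- new("ConditionedSignal", v = k * s@v, c = k * s@c, c2 = k * s@c2,
            rateHz = s@rateHz, role = s@role, t0 = s@t0,
            filterDesc = s@filterDesc)
  ck <- detectTriplets(sk)
  expect_identical(nrow(ck), nrow(c1))
  expect_equal(ck$t_steep_s, c1$t_steep_s)
  expect_equal(ck$duration_ms, c1$duration_ms)
  expect_equal(ck$amplitude, k * c1$amplitude, tolerance = 1e-9)
})

test_that("the sign-flip null is symmetric on symmetric noise", {
  set.seed(11)
  rate <- 1000
  v <- claustra:::pinkNoise(120 * rate, 20)
  s <- conditionSignal(vectorRecording(v, rate), "claustrum-L")
  up <- detectTriplets(s)
  nm <- estimateNoise(s)
  n <- nrow(up)
  expect_lt(abs(nm@nNoiseEvents - n), 3 * sqrt(n))
})

test_that("a noiseless negative template yields no sign-flip noise events", {
  ## sharp fall, slow partial recovery: the inverted signal has no
  ## deflection steep enough to clear the peak floors
  rate <- 1000
  tt <- (seq_len(5000) - 1) / rate
  event <- function(t0, A) {
    fall <- -A * exp(-(tt - t0)^2 / (2 * 0.005^2)) * (tt <= t0)
    rec <- -A * 0.3 * exp(-(tt - t0) / 0.08) * (tt > t0)
    fall + rec
  }
  v <- event(1, 200) + event(3, 150)
  s <- analyticConditioned(v, rate)
  fl <- c(5, 0.5)
  expect_warning(nm <- estimateNoise(s, prominenceFloor = fl),
                 "degenerate")
  expect_identical(nm@nNoiseEvents, 0L)
  ## degenerate model keeps all candidates at p_null = 0
  kept <- filterCandidates(detectTriplets(s, prominenceFloor = fl), nm)
  expect_identical(nrow(kept), 2L)
  expect_true(all(kept$p_null == 0))
})

test_that("null filtering keeps extreme candidates and rejects typical noise", {
  nm <- new("NoiseModel", amplitude = runif(400, 1, 2),
            duration = runif(400, 10, 40), nNoiseEvents = 400L,
            degenerate = FALSE)
  cand <- data.frame(t_start_s = c(1, 2), t_steep_s = c(1.005, 2.005),
                     t_end_s = c(1.01, 2.01),
                     amplitude = c(5, 1.5),      # far above / at the median
                     duration_ms = c(50, 25),    # beyond all / at the median
                     c_peak = c(-1, -1), channel = "claustrum-L",
                     stringsAsFactors = FALSE)
  kept <- filterCandidates(cand, nm, alpha = 0.025)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$amplitude, 5)
  expect_identical(kept$p_null, 0)
  ann <- attr(kept, "annotated")
  expect_gt(ann$p_null[2], 0.025)   # median-of-noise candidate rejected
  expect_error(filterCandidates(cand, nm, alpha = 1.2), "alpha")
})

test_that("on pure noise, accepted events are at most a few percent", {
  set.seed(12)
  rate <- 1000
  v <- claustra:::pinkNoise(300 * rate, 20)
  s <- conditionSignal(vectorRecording(v, rate), "claustrum-L")
  det <- detectSN(s)
  expect_lt(nrow(det$events) / max(nrow(det$candidates), 1), 0.05)
})

test_that("chunked detection equals whole-signal detection away from seams", {
  night <- sharedNight(600, seed = 7)
  s <- conditionSignal(night$recording, "claustrum-L")
  whole <- detectSN(s, chunkHours = 1)          # single chunk (10 min)
  parts <- detectSN(s, chunkHours = 300 / 3600) # two 5-min sections
  seam <- 300
  ## candidates: identical away from the seam (times agree to rounding)
  wc <- whole$candidates$t_steep_s
  pc <- parts$candidates$t_steep_s
  expect_equal(wc[abs(wc - seam) > 1], pc[abs(pc - seam) > 1],
               tolerance = 1e-9)
  ## filtered events: per-section noise models shift the cut only at the
  ## margin, so the kept sets agree almost everywhere
  wKeep <- whole$events[abs(whole$events$t_steep_s - seam) > 1, ]
  pKeep <- parts$events[abs(parts$events$t_steep_s - seam) > 1, ]
  expect_gt(fractionMatched(wKeep$t_steep_s, pKeep$t_steep_s, tol = 1e-6),
            0.95)
})

test_that("interval statistics behave on constructed trains", {
  reg <- data.frame(t_steep_s = seq(0, 5, by = 0.05))  # 50-ms train
  st <- ieiStats(reg)
  expect_equal(st$median_ms, 50)
  expect_equal(st$mode_ms, 47.5)   # 50 falls in the right-closed (45, 50] bin
  expect_equal(st$q75_ms - st$q25_ms, 0)

  two <- data.frame(t_steep_s = c(1, 1.08))
  st2 <- ieiStats(two)
  expect_equal(st2$median_ms, 80)
  expect_identical(st2$n, 1L)
  expect_error(ieiStats(two[1, , drop = FALSE]), "at least 2")
})

test_that("spike alignment attributes spikes to their SN", {
  ev <- data.frame(t_steep_s = seq(1, 10, by = 0.5))
  sp <- data.frame(unit = "u1", t_s = ev$t_steep_s)
  al <- spikeSnAlignment(sp, ev)
  expect_equal(al$u1$p_spike, 1)
  expect_equal(al$u1$p_multi, 0)
  h <- al$u1$histogram
  expect_equal(sum(h$count[abs(h$mid_ms) <= 1]), nrow(ev))

  alEmpty <- spikeSnAlignment(sp[0, ], ev)
  expect_identical(length(alEmpty), 0L)
})

test_that("synthetic spiking recovers the configured firing probabilities", {
  night <- sharedNight(1200, seed = 5)
  sp <- trueSpikes(night$truth)
  ev <- trueEvents(night$truth)
  for (side in c("L", "R")) {
    evS <- ev[ev$channel == paste0("claustrum-", side), ]
    al <- spikeSnAlignment(sp[sp$side == side, ],
                           data.frame(t_steep_s = evS$t_steep_s))
    nSN <- nrow(evS)
    for (u in names(al)) {
      ## allowance: binomial sampling error plus the 0.05 Hz background
      ## falling inside the attribution window (0.1 s -> +0.005)
      tol1 <- 3 * sqrt(0.43 * 0.57 / nSN) + 0.005
      tol2 <- 3 * sqrt(0.03 * 0.97 / nSN) + 0.005 * 0.43
      expect_gte(al[[u]]$p_spike, 0.14 - tol1)
      expect_lte(al[[u]]$p_spike, 0.43 + tol1)
      expect_gte(al[[u]]$p_multi, 0.003 - tol2)
      expect_lte(al[[u]]$p_multi, 0.03 + tol2)
    }
  }
})
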