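mkTrainSignals <- function(tL, tR, dur = 3, rate = 1000) {
  tt <- (seq_len(dur * rate) - 1) / rate
  mk <- function(times) {
    v <- numeric(length(tt))
    for (t0 in times) v <- v - 200 * exp(-(tt - t0)^2 / (2 * 0.005^2))
    v
  }
  list(L = analyticConditioned(mk(tL), rate, "claustrum-L"),
       R = analyticConditioned(mk(tR), rate, "claustrum-R"))
}

eventsAt <- function(times, p_null = 0) {
  n <- length(times)
  data.frame(t_steep_s = times, amplitude = rep(200, n),
             duration_ms = rep(9, n), p_null = rep(p_null, length.out = n))
}

test_that("pair scores follow the exponential lag kernel", {
  sig <- mkTrainSignals(1.000, numeric(0))
  ## same waveform against itself: lag 0 vs lag 20 ms differ only by the
  ## kernel factor exp(-20/10) = e^-2 (up to window-edge effects)
  sc0 <- scorePairs(eventsAt(1.000), eventsAt(1.000), sig$L, sig$L)
  expect_identical(nrow(sc0), 1L)
  expect_equal(sc0$lag_ms, 0)

  sig2 <- mkTrainSignals(1.000, 1.020)
  scL <- scorePairs(eventsAt(0.995), eventsAt(1.015), sig2$L, sig2$R)
  expect_equal(scL$lag_ms, 20, tolerance = 1e-9)
  ## remove the kernel: raw window correlation at the matching lag is
  ## close to the lag-0 self correlation
  raw <- scL$score / exp(-abs(scL$lag_ms) / 10)
  expect_gt(raw, 0.5 * sc0$score)

  ## unrelated band-limited noise stretches: the clipped-product baseline
  ## is far below an aligned-event score
  set.seed(21)
  nz <- conditionSignal(vectorRecording(claustra:::pinkNoise(3000, 20)),
                        "claustrum-L", zscore = FALSE)
  nz2 <- conditionSignal(vectorRecording(claustra:::pinkNoise(3000, 20),
                                         role = "claustrum-R"),
                         "claustrum-R", zscore = FALSE)
  scN <- scorePairs(eventsAt(1.5), eventsAt(1.5), nz, nz2)
  expect_lt(abs(scN$score), 0.05 * sc0$score)
})

test_that("optimal assignment picks aligned over crossed pairings", {
  sig <- mkTrainSignals(c(1.000, 1.100), c(1.020, 1.120))
  sc <- scorePairs(eventsAt(c(0.995, 1.095)), eventsAt(c(1.015, 1.115)),
                   sig$L, sig$R)
  mp <- matchPairs(sc)
  expect_identical(nrow(mp), 2L)
  expect_identical(mp$left, 1:2)
  expect_identical(mp$right, 1:2)   # not the crossed assignment
  expect_equal(mp$lag_ms, c(20, 20), tolerance = 1e-9)

  empty <- scorePairs(eventsAt(numeric(0)), eventsAt(1), sig$L, sig$R)
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(matchPairs(empty)), 0L)
})

test_that("assignment matches exhaustive enumeration on random instances", {
  set.seed(31)
  for (rep in 1:200) {
    nL <- sample(1:8, 1); nR <- sample(1:8, 1)
    edges <- expand.grid(left = seq_len(nL), right = seq_len(nR))
    keep <- runif(nrow(edges)) < 0.6
    edges <- edges[keep, , drop = FALSE]
    if (!nrow(edges)) next
    edges$lag_ms <- runif(nrow(edges), -50, 50)
    edges$score <- runif(nrow(edges), 0, 1) *
      sample(c(1, 0), nrow(edges), replace = TRUE, prob = c(0.9, 0.1))
    got <- sum(matchPairs(edges)$score)
    want <- bruteForceAssignment(edges)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("matching is symmetric and stable to removing unmatched events", {
  set.seed(32)
  tL <- sort(runif(6, 0, 2)); tR <- sort(runif(6, 0, 2))
  sig <- mkTrainSignals(tL, tR)
  sc <- scorePairs(eventsAt(tL - 0.005), eventsAt(tR - 0.005), sig$L, sig$R)
  mp <- matchPairs(sc)

  ## swap: lags negate, same pairing
  scSwap <- scorePairs(eventsAt(tR - 0.005), eventsAt(tL - 0.005),
                       sig$R, sig$L)
  mpSwap <- matchPairs(scSwap)
  key <- paste(mp$left, mp$right)
  keySwap <- paste(mpSwap$right, mpSwap$left)
  expect_setequal(key, keySwap)
  m <- match(keySwap, key)
  expect_equal(mpSwap$lag_ms, -mp$lag_ms[m], tolerance = 1e-9)

  ## removing an unmatched left event leaves the assignment unchanged
  unmatched <- setdiff(seq_along(tL), mp$left)
  if (length(unmatched)) {
    drop <- unmatched[1]
    tL2 <- tL[-drop]
    sc2 <- scorePairs(eventsAt(tL2 - 0.005), eventsAt(tR - 0.005),
                      sig$L, sig$R)
    mp2 <- matchPairs(sc2)
    remap <- ifelse(mp$left > drop, mp$left - 1L, mp$left)
    expect_setequal(paste(mp2$left, mp2$right), paste(remap, mp$right))
  }
})

test_that("pair acceptance needs one low null probability", {
  pairs <- data.frame(left = 1:2, right = 1:2, lag_ms = c(20, 20),
                      score = c(1, 1))
  le <- eventsAt(c(1, 2), p_null = c(0.001, 0.5))
  re <- eventsAt(c(1.02, 2.02), p_null = c(0.5, 0.5))
  acc <- acceptPairs(pairs, le, re)
  expect_identical(acc$accepted, c(TRUE, FALSE))
  le$p_null <- NULL
  expect_error(acceptPairs(pairs, le, re), "p_null")
})
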