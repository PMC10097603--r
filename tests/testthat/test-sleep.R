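mkBeta <- function(p, stepS = 1, windowS = 10) {
  new("BandPowerTrace", t = windowS / 2 + (seq_along(p) - 1) * stepS,
      p = p, bandHz = c(12, 30), windowS = windowS, stepS = stepS)
}

test_that("sleep segmentation thresholds and defragments", {
  ## alternating 60 s high / 60 s low
  p <- rep(rep(c(10, 1), 5), each = 60)
  segs <- segmentSleep(mkBeta(p), pct = 50)
  expect_identical(segs$state, rep(c("REM_P", "SW"), 5))
  durs <- segs$end_s - segs$start_s
  expect_true(all(abs(durs[2:(length(durs) - 1)] - 60) <= 1))
  ## conservation: exact tiling of the span
  expect_equal(sum(durs), max(segs$end_s) - min(segs$start_s))
  expect_equal(segs$start_s[-1], head(segs$end_s, -1))

  ## a 10-s dip inside a high block is absorbed
  p2 <- c(rep(10, 60), rep(1, 10), rep(10, 60))
  segs2 <- segmentSleep(mkBeta(p2), threshold = 5)
  expect_identical(segs2$state, "REM_P")

  expect_error(segmentSleep(mkBeta(rep(5, 100))), "degenerate")
})

test_that("raising the percentile never increases REM_P time", {
  set.seed(51)
  p <- abs(rlnorm(600, 0, 1))
  remp <- function(pct) {
    s <- segmentSleep(mkBeta(p), pct = pct)
    sum((s$end_s - s$start_s)[s$state == "REM_P"])
  }
  tot <- vapply(c(10, 30, 50, 70, 90), remp, numeric(1))
  expect_true(all(diff(tot) <= 1e-9))
})

test_that("episode statistics count switches and partition time", {
  ep <- data.frame(state = c("SW", "REM_P", "SW", "REM_P"),
                   start_s = c(0, 40, 104, 150), end_s = c(40, 104, 150, 210))
  dom <- data.frame(side = c("left", "unsettled", "right", "left"),
                    start_s = c(40, 70, 74, 150), end_s = c(70, 74, 104, 210))
  st <- episodeStats(ep, dom)
  e <- st$episodes
  expect_identical(e$n_switches, c(1L, 0L))
  expect_equal(e$time_left_s, c(30, 60))
  expect_equal(e$time_right_s, c(30, 0))
  expect_equal(e$time_unsettled_s, c(4, 0))
  expect_identical(e$leading_side_majority, c("left", "left"))
  expect_equal(e$time_left_s + e$time_right_s + e$time_unsettled_s,
               e$end_s - e$start_s)
  expect_equal(st$summary$mean_dur_0switch_s, 60)
  expect_equal(st$summary$mean_dur_1switch_s, 64)
  expect_equal(st$summary$mean_unsettled_switching_s, 4)

  ## left -> unsettled -> left is zero switches
  dom2 <- data.frame(side = c("left", "unsettled", "left"),
                     start_s = c(40, 70, 74), end_s = c(70, 74, 104))
  st2 <- episodeStats(ep[1:3, ], dom2)
  expect_identical(st2$episodes$n_switches, 0L)

  expect_error(episodeStats(ep, dom[0, ]), "missing")
})

test_that("amplitude-lag statistics split by lag sign", {
  ## equal normalized amplitudes: delta identically 0
  pairs0 <- data.frame(amp_left = rep(2, 40), amp_right = rep(3, 40),
                       lag_ms = rep(c(-20, 20), 20))
  s0 <- amplitudeLagStats(pairs0)
  expect_true(all(s0$delta == 0))

  ## leader strictly larger: delta sign predicts lag sign
  set.seed(52)
  n <- 200
  lead <- rlnorm(n, log(2), 0.1)
  lag <- sample(c(-20, 20), n, replace = TRUE)
  pairs <- data.frame(amp_left = ifelse(lag > 0, lead, 0.8 * lead),
                      amp_right = ifelse(lag > 0, 0.8 * lead, lead),
                      lag_ms = lag)
  s <- amplitudeLagStats(pairs)
  expect_true(all(s$delta[pairs$lag_ms > 0] >
                  max(s$delta[pairs$lag_ms < 0])))
  expect_gt(s$mean_delta_left_leads, 0)
  expect_lt(s$mean_delta_right_leads, 0)
  expect_lt(s$test$p.value, 1e-10)

  expect_error(amplitudeLagStats(pairs[pairs$lag_ms > 0, ][1:3, ]),
               "per lag-sign group")
})

test_that("group comparisons report the standard statistics", {
  a <- c(30, 35, 40, 28, 33)
  expect_equal(unname(welchCompare(a, a)$statistic), 0)
  w <- welchCompare(c(1, 2, 3), c(11, 12, 13))
  expect_lt(unname(w$statistic), -5)   # sign: mean(a) - mean(b)
  expect_error(welchCompare(1, a), "at least 2")

  sr <- lagSignedRank(c(18, 22, 19, 21, 20.5), alternative = "greater")
  expect_lt(sr$p.value, 0.05)
  expect_error(lagSignedRank(5), "at least 2")
})

test_that("lesion-vs-control comparison flags shorter lesioned episodes", {
  ctrl <- sharedNight(1200, seed = 61)
  les <- sharedNightEnv[["les61"]]
  if (is.null(les)) {
    les <- suppressWarnings(generateNight(
      generatorConfig(duration_s = 1200, seed = 62, lesion_side = "left")))
    sharedNightEnv[["les61"]] <- les
  }
  dur <- function(n) {
    ep <- episodes(n$truth)
    (ep$end_s - ep$start_s)[ep$state == "REM_P"]
  }
  a <- dur(les); b <- dur(ctrl)
  w <- welchCompare(a[1:8], b[1:8], alternative = "less")
  expect_lt(w$p.value, 0.01)
})
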