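test_that("conditioning passes the band and rejects above-cutoff content", {
  rate <- 1000
  t <- seq(0, 10, by = 1 / rate)
  rec5 <- vectorRecording(100 * sin(2 * pi * 5 * t), rate)
  s5 <- conditionSignal(rec5, "claustrum-L", zscore = FALSE)
  expect_gt(max(s5@v) / 100, 0.95)            # 5 Hz preserved

  rec80 <- vectorRecording(100 * sin(2 * pi * 80 * t), rate)
  s80 <- conditionSignal(rec80, "claustrum-L", zscore = FALSE)
  mid <- s80@v[1000:9000]
  expect_lt(max(abs(mid)) / 100, 10^(-40 / 20))  # >= 40 dB down

  expect_error(conditionSignal(rec5, "missing-channel"), "not present")
  lowRate <- vectorRecording(rnorm(100), 60)
  expect_error(conditionSignal(lowRate, "claustrum-L"), "too low")
})

test_that("derivatives follow the analytic values on simple signals", {
  rate <- 1000
  const <- vectorRecording(rep(3, 2000), rate)
  sc <- conditionSignal(const, "claustrum-L", zscore = FALSE)
  interior <- 300:1700   # zero-phase filtering leaves edge transients
  expect_true(all(abs(sc@c[interior]) < 1e-6))
  expect_true(all(abs(sc@c2[interior]) < 1e-6))

  k <- 4  # microvolt per ms ramp
  ramp <- vectorRecording(k * (seq_len(4000) - 1), rate)  # k uV per sample = k uV/ms
  sr <- conditionSignal(ramp, "claustrum-L", zscore = FALSE)
  interior <- 500:3500
  expect_lt(max(abs(sr@c[interior] - k)), 0.05 * k)
  expect_lt(max(abs(sr@c2[interior])), 0.05 * k)
})

test_that("zero-phase contract: a pulse keeps its extremum time", {
  rate <- 1000
  v <- numeric(4000)
  t0 <- 2000
  tt <- seq_along(v)
  v <- -300 * exp(-(tt - t0)^2 / (2 * 8^2))   # 8-ms-wide trough
  s <- conditionSignal(vectorRecording(v, rate), "claustrum-L",
                       zscore = FALSE)
  expect_lte(abs(which.min(s@v) - t0), 1)
})

test_that("z-scoring is global: unit variance and zero mean", {
  night <- sharedNight(120, seed = 9)
  s <- conditionSignal(night$recording, "claustrum-L")
  expect_equal(mean(s@v), 0, tolerance = 1e-8)
  expect_equal(sd(s@v), 1, tolerance = 1e-8)
})

test_that("synchronization aligns drifting clocks onto the reference", {
  rate <- 1000
  dur <- 60
  t1 <- seq(0, dur, by = 1 / rate)
  sync1 <- ifelse(t1 %% 1 < 0.5, 500, 0)
  sig1 <- 50 * sin(2 * pi * 3 * t1)
  r1 <- new("Recording",
            samples = cbind(`claustrum-L` = sig1, sync = sync1),
            rateHz = rate, channelRoles = c("claustrum-L", "sync"), t0 = 0)

  ## identity: two copies -> zero residual
  out <- synchronizeRecordings(list(r1, r1))
  expect_equal(out$diagnostics$residual_s[2], 0, tolerance = 1e-9)

  ## drifting clock: true rate 1000.5 Hz labelled as 1000 Hz
  t2true <- seq(0, dur, by = 1 / 1000.5)
  r2 <- new("Recording",
            samples = cbind(`claustrum-R` = 50 * sin(2 * pi * 3 * t2true),
                            sync = ifelse(t2true %% 1 < 0.5, 500, 0)),
            rateHz = rate, channelRoles = c("claustrum-R", "sync"), t0 = 0)
  out2 <- synchronizeRecordings(list(r1, r2))
  expect_lt(out2$diagnostics$residual_s[2], 1 / rate)  # within one sample
  ## the mapped signal matches the reference signal away from the edges
  mid <- 5000:55000
  expect_lt(max(abs(out2$recordings[[2]]@samples[mid, 1] - sig1[mid])), 2)

  ## single edge -> sync failure
  rBad <- new("Recording",
              samples = cbind(`claustrum-L` = sig1,
                              sync = c(rep(0, 100), rep(500,
                                length(sig1) - 100))),
              rateHz = rate, channelRoles = c("claustrum-L", "sync"), t0 = 0)
  expect_error(synchronizeRecordings(list(r1, rBad)), "sync failure")
})

test_that("band power separates band-limited content", {
  rate <- 1000
  t <- seq(0, 60, by = 1 / rate)
  s20 <- conditionSignal(vectorRecording(100 * sin(2 * pi * 20 * t), rate),
                         "claustrum-L", zscore = FALSE)
  s5 <- conditionSignal(vectorRecording(100 * sin(2 * pi * 5 * t), rate),
                        "claustrum-L", zscore = FALSE)
  b20 <- bandPower(s20)
  b5 <- bandPower(s5)
  expect_gt(median(b20@p), 10 * median(b5@p))

  z <- conditionSignal(vectorRecording(numeric(30001), rate),
                       "claustrum-L", zscore = FALSE)
  bz <- bandPower(z)
  expect_true(all(bz@p < 1e-12))
  expect_error(bandPower(conditionSignal(vectorRecording(rnorm(3000), rate),
                                         "claustrum-L")),
               "shorter")
})

test_that("beta power is higher during REM_P than SW on a synthetic night", {
  night <- sharedNight(600, seed = 7)
  s <- conditionSignal(night$recording, "claustrum-L")
  b <- bandPower(s)
  ep <- episodes(night$truth)
  inRemp <- inEpisodes(b@t, ep, "REM_P")
  inSw <- inEpisodes(b@t, ep, "SW")
  expect_gt(median(b@p[inRemp]), 3 * median(b@p[inSw]))
})

test_that("SN rate trace tracks event density and correlates with beta", {
  ev <- data.frame(t_steep_s = seq(0.05, 100, by = 0.1))  # 10 Hz train
  r <- snRate(ev, spanS = 100)
  interior <- r$t > 10 & r$t < 90
  expect_true(all(abs(r$rate_hz[interior] - 10) <= 0.1))

  r0 <- snRate(data.frame(t_steep_s = numeric(0)), spanS = 50)
  expect_true(all(r0$rate_hz == 0))

  night <- sharedNight(600, seed = 7)
  s <- conditionSignal(night$recording, "claustrum-L")
  det <- detectSN(s)
  rate <- snRate(det$events, spanS = 600)
  beta <- bandPower(s)
  n <- min(nrow(rate), length(beta@t))
  expect_gt(cor(rate$rate_hz[seq_len(n)], beta@p[seq_len(n)]), 0.5)
})

test_that("binary recording IO round-trips within quantization error", {
  night <- sharedNight(120, seed = 9)
  dir <- withr::local_tempdir()
  side <- writeRecording(night$recording, file.path(dir, "rec"))
  back <- readRecording(file.path(dir, "rec"))
  expect_identical(back@channelRoles, night$recording@channelRoles)
  expect_equal(back@rateHz, night$recording@rateHz)
  expect_lt(max(abs(back@samples - night$recording@samples)),
            side$uv_per_bit)
})
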