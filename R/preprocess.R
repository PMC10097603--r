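#' Condition a channel: resample, zero-phase low-pass, z-score, derivatives
#'
#' Resamples one channel to the working rate (with an anti-alias low-pass
#' when downsampling), applies a zero-phase (forward-backward) order-4
#' Butterworth low-pass at \code{lpHz}, optionally z-scores over the full
#' span, and computes first and second derivatives by central differences.
#' Zero-phase filtering keeps event times unshifted, which matters for the
#' +/- 20 ms lag analyses downstream.
#'
#' @param rec a \code{\linkS4class{Recording}}.
#' @param role channel role to condition.
#' @param workingRateHz target rate (samples/s), default 1000.
#' @param lpHz low-pass cutoff (Hz), default 40.
#' @param zscore z-score the filtered trace over the full span (default
#'   TRUE). Statistics are global, not per window.
#' @return a \code{\linkS4class{ConditionedSignal}} with \code{v} (filtered
#'   voltage), \code{c} (first derivative per ms) and \code{c2} (second
#'   derivative per ms^2).
#' @export
conditionSignal <- function(rec, role, workingRateHz = 1000, lpHz = 40,
                            zscore = TRUE) {
  stopifnot(is(rec, "Recording"))
  stopifnot_scalar(workingRateHz, "workingRateHz")
  stopifnot_scalar(lpHz, "lpHz")
  if (rec@rateHz < 2 * lpHz)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz low-pass",
                 rec@rateHz, lpHz), call. = FALSE)
  v <- getChannel(rec, role)
  if (abs(rec@rateHz - workingRateHz) > 1e-9) {
    if (workingRateHz < rec@rateHz) {
      ## anti-alias before resampling down
      aa <- signal::butter(4, min(0.45 * workingRateHz, lpHz * 1.2) /
                              (rec@rateHz / 2), type = "low")
      v <- signal::filtfilt(aa, v)
    }
    told <- (seq_along(v) - 1L) / rec@rateHz
    nNew <- floor(tail(told, 1L) * workingRateHz) + 1L
    tnew <- (seq_len(nNew) - 1L) / workingRateHz
    v <- approx(told, v, xout = tnew)$y
  }
  bf <- signal::butter(4, lpHz / (workingRateHz / 2), type = "low")
  v <- signal::filtfilt(bf, v)
  if (zscore) {
    s <- stats::sd(v)
    if (s == 0) s <- 1
    v <- (v - mean(v)) / s
  }
  dtms <- 1000 / workingRateHz
  n <- length(v)
  cc <- numeric(n); c2 <- numeric(n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    cc[i] <- (v[i + 1L] - v[i - 1L]) / (2 * dtms)
    c2[i] <- (v[i + 1L] - 2 * v[i] + v[i - 1L]) / dtms^2
    cc[1L] <- cc[2L]; cc[n] <- cc[n - 1L]
    c2[1L] <- c2[2L]; c2[n] <- c2[n - 1L]
  }
  new("ConditionedSignal", v = v, c = cc, c2 = c2, rateHz = workingRateHz,
      role = role, t0 = rec@t0,
      filterDesc = list(lpHz = lpHz, order = 4, zscore = zscore,
                        design = "butterworth zero-phase (filtfilt)"))
}

detectSyncEdges <- function(sync, rateHz, t0 = 0) {
  thr <- (max(sync) + min(sync)) / 2
  above <- sync > thr
  idx <- which(!above[-length(above)] & above[-1L]) + 1L
  if (length(idx) < 2L) return(t0 + (idx - 1L) / rateHz)
  ## refine by linear interpolation across the crossing
  frac <- (thr - sync[idx - 1L]) / (sync[idx] - sync[idx - 1L])
  t0 + (idx - 2L + frac) / rateHz
}

#' Synchronize recordings onto a common clock via a shared square wave
#'
#' Aligns every recording to the first one by piecewise-linear
#' interpolation of time, using the rising edges of a common 1-Hz
#' square-wave sync channel as anchors. Handles small constant or drifting
#' differences between nominal and true sampling rates.
#'
#' @param recordings list of \code{\linkS4class{Recording}} objects, each
#'   containing a channel with role \code{syncRole}.
#' @param syncRole role of the sync channel (default \code{"sync"}).
#' @return list with \code{recordings} (all resampled onto the reference
#'   clock) and \code{diagnostics} (per-recording residual edge
#'   misalignment in seconds after mapping).
#' @export
synchronizeRecordings <- function(recordings, syncRole = "sync") {
  stopifnot(length(recordings) >= 1L)
  edges <- lapply(recordings, function(r)
    detectSyncEdges(getChannel(r, syncRole), r@rateHz, r@t0))
  for (e in edges)
    if (length(e) < 2L)
      stop("sync failure: fewer than 2 rising edges on the sync channel",
           call. = FALSE)
  ref <- edges[[1L]]
  out <- vector("list", length(recordings))
  resid <- numeric(length(recordings))
  out[[1L]] <- recordings[[1L]]
  for (i in seq_along(recordings)[-1L]) {
    e <- edges[[i]]
    m <- min(length(e), length(ref))
    e <- e[seq_len(m)]; r <- ref[seq_len(m)]
    if (any(diff(e) <= 0))
      stop("corrupted sync: non-monotonic edge mapping", call. = FALSE)
    rec <- recordings[[i]]
    told <- timesS(rec)
    ## map this recording's clock onto the reference clock; piecewise
    ## linear between anchors, linear extrapolation beyond them (constant
    ## padding would fold the ends onto one instant)
    tmapped <- approx(e, r, xout = told)$y
    ne <- length(e)
    s0 <- (r[2L] - r[1L]) / (e[2L] - e[1L])
    s1 <- (r[ne] - r[ne - 1L]) / (e[ne] - e[ne - 1L])
    pre <- told < e[1L]; post <- told > e[ne]
    tmapped[pre] <- r[1L] + (told[pre] - e[1L]) * s0
    tmapped[post] <- r[ne] + (told[post] - e[ne]) * s1
    tref <- timesS(recordings[[1L]])
    samples <- apply(rec@samples, 2L, function(col)
      approx(tmapped, col, xout = tref, rule = 2)$y)
    out[[i]] <- new("Recording", samples = samples,
                    rateHz = recordings[[1L]]@rateHz,
                    channelRoles = rec@channelRoles,
                    t0 = recordings[[1L]]@t0)
    e2 <- detectSyncEdges(getChannel(out[[i]], syncRole),
                          out[[i]]@rateHz, out[[i]]@t0)
    m2 <- min(length(e2), length(ref))
    resid[i] <- if (m2) max(abs(e2[seq_len(m2)] - ref[seq_len(m2)])) else NA
  }
  list(recordings = out, diagnostics = data.frame(
    recording = seq_along(recordings), residual_s = resid))
}

#' Sliding band-power trace
#'
#' Band-passes the conditioned voltage (zero-phase) and reports the mean
#' squared amplitude per sliding window at window centers. The default
#' band, window and step target the beta band (12-30 Hz) with 10-s windows
#' at 1-s steps, the trace used for REM_P/SW segmentation.
#'
#' @param sig a \code{\linkS4class{ConditionedSignal}}.
#' @param bandHz numeric length 2, band edges (Hz).
#' @param windowS window length (s).
#' @param stepS step between window centers (s).
#' @return a \code{\linkS4class{BandPowerTrace}}.
#' @export
bandPower <- function(sig, bandHz = c(12, 30), windowS = 10, stepS = 1) {
  stopifnot(is(sig, "ConditionedSignal"))
  n <- length(sig@v)
  if (n / sig@rateHz <= windowS)
    stop("signal shorter than the analysis window", call. = FALSE)
  bf <- signal::butter(4, bandHz / (sig@rateHz / 2), type = "pass")
  bp <- signal::filtfilt(bf, sig@v)
  inst <- bp^2
  half <- round(windowS / 2 * sig@rateHz)
  tc <- seq(windowS / 2, n / sig@rateHz - windowS / 2, by = stepS)
  centers <- round(tc * sig@rateHz) + 1L
  p <- windowedMean(inst, half, centers)
  new("BandPowerTrace", t = sig@t0 + tc, p = pmax(p, 0), bandHz = bandHz,
      windowS = windowS, stepS = stepS)
}

#' Scrolling SN rate trace
#'
#' Events per second in a scrolling window, on the same grid as
#' \code{\link{bandPower}} so that the two traces can be correlated.
#'
#' @param events SN event data.frame (uses \code{t_steep_s}), time-sorted.
#' @param windowS,stepS window and step (s).
#' @param spanS total span covered (s); defaults to the last event time.
#' @return data.frame(t, rate_hz).
#' @export
snRate <- function(events, windowS = 10, stepS = 1, spanS = NULL) {
  tt <- if (nrow(events)) sort(events$t_steep_s) else numeric(0)
  if (is.null(spanS)) spanS <- if (length(tt)) max(tt) else windowS
  tc <- seq(windowS / 2, max(spanS - windowS / 2, windowS / 2), by = stepS)
  lo <- findInterval(tc - windowS / 2, tt)
  hi <- findInterval(tc + windowS / 2, tt)
  data.frame(t = tc, rate_hz = (hi - lo) / windowS)
}
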