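#' Detect SN candidates as derivative triplet peaks
#'
#' A potential sharp negative event (SN) is a triplet of peaks: a negative
#' second-derivative peak, followed by a negative first-derivative peak
#' (the steepest descent), followed by a positive second-derivative peak.
#' The outer pair marks the beginning and end of the downward phase and
#' yields amplitude (\code{v(t_start) - v(t_end)}, positive for a downward
#' event) and duration (\code{t_end - t_start}, ms). Peaks must exceed a
#' minimal magnitude floor (default half the standard deviation of the
#' corresponding derivative) to suppress numerical micro-peaks; each
#' first-derivative trough is associated with the nearest flanking
#' second-derivative extrema within \code{assocMs}. When two triplets share
#' the same flanking pair, the one with the larger |first derivative| is
#' kept.
#'
#' @param sig a \code{\linkS4class{ConditionedSignal}}.
#' @param prominenceFloor length-2 numeric: magnitude floors for peaks of
#'   \code{c} and \code{c2}; \code{NULL} (default) uses 0.5 x the standard
#'   deviation of each derivative.
#' @param assocMs maximal distance (ms) between the steepest-descent peak
#'   and its flanking second-derivative peaks.
#' @return data.frame of time-sorted candidates: \code{t_start_s},
#'   \code{t_steep_s}, \code{t_end_s}, \code{amplitude}, \code{duration_ms},
#'   \code{c_peak}, \code{channel}. Amplitude is in the units of
#'   \code{sig@v} (z-units for the default conditioning).
#' @export
detectTriplets <- function(sig, prominenceFloor = NULL, assocMs = 100) {
  stopifnot(is(sig, "ConditionedSignal"))
  if (is.null(prominenceFloor))
    prominenceFloor <- 0.5 * c(stats::sd(sig@c), stats::sd(sig@c2))
  emptyCand <- data.frame(t_start_s = numeric(0), t_steep_s = numeric(0),
                          t_end_s = numeric(0), amplitude = numeric(0),
                          duration_ms = numeric(0), c_peak = numeric(0),
                          channel = character(0), stringsAsFactors = FALSE)
  if (all(prominenceFloor == 0) || length(sig@v) < 5L) return(emptyCand)
  iC <- localMinima(sig@c, floor = prominenceFloor[1])
  iN <- localMinima(sig@c2, floor = prominenceFloor[2])
  iP <- localMaxima(sig@c2, floor = prominenceFloor[2])
  if (!length(iC) || !length(iN) || !length(iP)) return(emptyCand)
  assoc <- round(assocMs / 1000 * sig@rateHz)
  ## nearest preceding negative c2 peak and nearest following positive one
  jN <- findInterval(iC, iN)                     # last iN <= iC
  jP <- findInterval(iC - 1L, iP) + 1L           # first iP > iC - 1
  ok <- jN >= 1L & jP <= length(iP)
  iC <- iC[ok]; jN <- jN[ok]; jP <- jP[ok]
  s <- iN[jN]; e <- iP[jP]
  ok <- (iC - s) <= assoc & (e - iC) <= assoc & s < iC & e > iC
  iC <- iC[ok]; s <- s[ok]; e <- e[ok]
  if (!length(iC)) return(emptyCand)
  amp <- sig@v[s] - sig@v[e]
  dur <- (e - s) * 1000 / sig@rateHz
  cand <- data.frame(iStart = s, iSteep = iC, iEnd = e, amplitude = amp,
                     duration_ms = dur, c_peak = sig@c[iC])
  cand <- cand[cand$amplitude > 0 & cand$duration_ms > 0, , drop = FALSE]
  if (!nrow(cand)) return(emptyCand)
  ## overlapping triplets sharing flanks: keep the steeper candidate
  key <- paste(cand$iStart, cand$iEnd)
  if (anyDuplicated(key)) {
    o <- order(key, cand$c_peak)   # most negative c_peak first per key
    cand <- cand[o, , drop = FALSE]
    cand <- cand[!duplicated(key[o]), , drop = FALSE]
  }
  cand <- cand[order(cand$iSteep), , drop = FALSE]
  dt <- 1 / sig@rateHz
  out <- data.frame(
    t_start_s = sig@t0 + (cand$iStart - 1L) * dt,
    t_steep_s = sig@t0 + (cand$iSteep - 1L) * dt,
    t_end_s = sig@t0 + (cand$iEnd - 1L) * dt,
    amplitude = cand$amplitude, duration_ms = cand$duration_ms,
    c_peak = cand$c_peak,
    channel = rep(sig@role, nrow(cand)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate the noise null by sign inversion
#'
#' Runs the same triplet detection on the sign-inverted signal, where true
#' SNs cannot exist: anything detected there is LFP noise. The joint
#' (amplitude, duration) sample of those false events is the null model
#' used by \code{\link{filterCandidates}}.
#'
#' @inheritParams detectTriplets
#' @return a \code{\linkS4class{NoiseModel}}.
#' @export
estimateNoise <- function(sig, prominenceFloor = NULL, assocMs = 100) {
  stopifnot(is(sig, "ConditionedSignal"))
  if (is.null(prominenceFloor))
    prominenceFloor <- 0.5 * c(stats::sd(sig@c), stats::sd(sig@c2))
  inv <- new("ConditionedSignal", v = -sig@v, c = -sig@c, c2 = -sig@c2,
             rateHz = sig@rateHz, role = sig@role, t0 = sig@t0,
             filterDesc = sig@filterDesc)
  ev <- detectTriplets(inv, prominenceFloor = prominenceFloor,
                       assocMs = assocMs)
  if (!nrow(ev)) {
    warning("no noise events detected; degenerate noise model ",
            "(thresholds fall back to global minima)", call. = FALSE)
    return(new("NoiseModel", amplitude = numeric(0), duration = numeric(0),
               nNoiseEvents = 0L, degenerate = TRUE))
  }
  new("NoiseModel", amplitude = ev$amplitude, duration = ev$duration_ms,
      nNoiseEvents = nrow(ev), degenerate = FALSE)
}

#' Filter SN candidates against the sign-flip noise null
#'
#' For each candidate the null probability is the joint empirical tail of
#' the noise model: the fraction of sign-flip noise events that look at
#' least as SN-like, i.e. have amplitude >= the candidate's amplitude AND
#' duration <= the candidate's duration. (In a dense SN train the
#' inverted-signal detections are dominated by the slow recovery ramps,
#' which are necessarily longer than the sharp falls; sharpness therefore
#' counts in favour of a candidate, while a large amplitude must be rarer
#' than \code{alpha} under the null.) Because a bivariate tail statistic
#' does not have a uniform null distribution, the acceptance cut is
#' rank-calibrated on the null itself: a candidate is kept when its tail
#' statistic is at or below the \code{alpha} quantile of the noise
#' events' own tail statistics, which pins the false-positive rate of the
#' filter at \code{alpha}. Kept events always satisfy \code{p_null <
#' alpha}. With a degenerate (empty) noise model all candidates are kept
#' with \code{p_null = 0}.
#'
#' @param candidates data.frame from \code{\link{detectTriplets}}.
#' @param noise a \code{\linkS4class{NoiseModel}}.
#' @param alpha null-probability level (default 0.025).
#' @return the kept events with a \code{p_null} column; the full annotated
#'   candidate set is attached as attribute \code{"annotated"} (used by
#'   pair acceptance, which works on unfiltered candidates).
#' @export
filterCandidates <- function(candidates, noise, alpha = 0.025) {
  stopifnot(is(noise, "NoiseModel"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!nrow(candidates)) {
    candidates$p_null <- numeric(0)
    attr(candidates, "annotated") <- candidates
    return(candidates)
  }
  if (noise@degenerate || noise@nNoiseEvents == 0L) {
    candidates$p_null <- 0
    attr(candidates, "annotated") <- candidates
    return(candidates)
  }
  candidates$p_null <- jointNullProb(noise@amplitude, noise@duration,
                                     candidates$amplitude,
                                     candidates$duration_ms)
  selfStat <- jointNullProb(noise@amplitude, noise@duration,
                            noise@amplitude, noise@duration)
  cut <- quantile(selfStat, alpha, type = 1, names = FALSE)
  kept <- candidates[candidates$p_null <= cut, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "annotated") <- candidates
  kept
}

#' Detect and filter SNs in consecutive one-hour sections
#'
#' Full detection for one channel: conditioning is assumed done; the
#' signal is processed in consecutive sections of \code{chunkHours} (noise
#' model estimated per section, mirroring the chunked processing of long
#' nights) and the per-section results are concatenated.
#'
#' @param sig a \code{\linkS4class{ConditionedSignal}}.
#' @param alpha null-probability level for \code{\link{filterCandidates}}.
#' @param chunkHours section length in hours (default 1).
#' @param prominenceFloor see \code{\link{detectTriplets}}.
#' @return list with \code{events} (kept SNs, with \code{p_null}),
#'   \code{candidates} (all annotated candidates) and \code{noise} (list of
#'   per-section \code{NoiseModel}s).
#' @export
detectSN <- function(sig, alpha = 0.025, chunkHours = 1,
                     prominenceFloor = NULL) {
  stopifnot(is(sig, "ConditionedSignal"))
  n <- length(sig@v)
  chunk <- round(chunkHours * 3600 * sig@rateHz)
  starts <- seq(1L, n, by = chunk)
  evs <- list(); cands <- list(); noises <- list()
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- min(i0 + chunk - 1L, n)
    sub <- new("ConditionedSignal", v = sig@v[i0:i1], c = sig@c[i0:i1],
               c2 = sig@c2[i0:i1], rateHz = sig@rateHz, role = sig@role,
               t0 = sig@t0 + (i0 - 1L) / sig@rateHz,
               filterDesc = sig@filterDesc)
    nm <- estimateNoise(sub, prominenceFloor = prominenceFloor)
    kept <- filterCandidates(
      detectTriplets(sub, prominenceFloor = prominenceFloor), nm,
      alpha = alpha)
    evs[[k]] <- kept
    cands[[k]] <- attr(kept, "annotated")
    noises[[k]] <- nm
  }
  events <- do.call(rbind, evs)
  rownames(events) <- NULL
  candidates <- do.call(rbind, cands)
  rownames(candidates) <- NULL
  list(events = events, candidates = candidates, noise = noises)
}

#' Inter-event-interval statistics of an SN stream
#'
#' Intervals between consecutive events on one channel, optionally
#' restricted to REM_P episodes (intervals straddling an episode boundary
#' are dropped). The histogram is truncated at \code{truncMs} and the mode
#' is the center of the fullest bin.
#'
#' @param events SN event data.frame with \code{t_steep_s} (one channel).
#' @param episodes optional episode table (\code{state}, \code{start_s},
#'   \code{end_s}); only intervals inside REM_P episodes are kept.
#' @param binMs histogram bin width (ms).
#' @param truncMs histogram truncation (ms).
#' @return list: \code{median_ms}, \code{mode_ms}, \code{q25_ms},
#'   \code{q75_ms}, \code{n}, \code{histogram} (data.frame mid, count).
#' @export
ieiStats <- function(events, episodes = NULL, binMs = 5, truncMs = 150) {
  if (nrow(events) < 2L)
    stop("need at least 2 events for interval statistics", call. = FALSE)
  tt <- sort(events$t_steep_s)
  if (!is.null(episodes)) {
    remp <- episodes[episodes$state == "REM_P", , drop = FALSE]
    epi <- rep(NA_integer_, length(tt))
    for (i in seq_len(nrow(remp)))
      epi[tt >= remp$start_s[i] & tt < remp$end_s[i]] <- i
    a <- epi[-length(epi)]; b <- epi[-1L]
    ok <- !is.na(a) & !is.na(b) & a == b
    iei <- diff(tt)[ok] * 1000
  } else {
    iei <- diff(tt) * 1000
  }
  if (!length(iei))
    stop("no intervals left after episode restriction", call. = FALSE)
  breaks <- seq(0, truncMs, by = binMs)
  h <- graphics::hist(iei[iei <= truncMs], breaks = breaks, plot = FALSE)
  list(median_ms = median(iei),
       mode_ms = h$mids[which.max(h$counts)],
       q25_ms = unname(quantile(iei, 0.25)),
       q75_ms = unname(quantile(iei, 0.75)),
       n = length(iei),
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Align spikes to SN steepest-descent times
#'
#' Per-unit histogram of spike lags relative to the SN steepest-descent
#' time within +/- \code{windowMs}, and per-SN firing probabilities.
#'
#' @param spikes data.frame(unit, t_s) of spike times (common clock with
#'   the events).
#' @param events SN event data.frame with \code{t_steep_s} (the channel
#'   ipsilateral to the units).
#' @param windowMs half-window (ms).
#' @param binMs histogram bin (ms).
#' @details The histogram counts every spike within the +/- window of
#'   every SN (the usual peri-event histogram, which also shows flanking
#'   events of the train). The firing probabilities attribute each spike
#'   to its \emph{nearest} SN only -- with inter-event intervals of a few
#'   tens of ms, window occupancy alone would double-count spikes fired
#'   for neighbouring events.
#' @return list per unit: \code{histogram} (mid_ms, count),
#'   \code{p_spike} = P(>= 1 spike per SN), \code{p_multi} = P(> 1 spike).
#'   Empty inputs give empty output.
#' @export
spikeSnAlignment <- function(spikes, events, windowMs = 50, binMs = 2) {
  out <- list()
  if (!nrow(spikes) || !nrow(events)) return(out)
  steep <- sort(events$t_steep_s)
  w <- windowMs / 1000
  for (u in unique(spikes$unit)) {
    st <- sort(spikes$t_s[spikes$unit == u])
    lo <- findInterval(steep - w, st)
    hi <- findInterval(steep + w, st)
    nIn <- hi - lo
    lags <- unlist(lapply(which(nIn > 0), function(i)
      st[(lo[i] + 1L):hi[i]] - steep[i]), use.names = FALSE) * 1000
    breaks <- seq(-windowMs, windowMs, by = binMs)
    h <- graphics::hist(lags[lags >= -windowMs & lags <= windowMs],
                        breaks = breaks, plot = FALSE)
    ## nearest-SN attribution for the per-SN firing probabilities
    iN <- findInterval(st, steep)
    loI <- pmax(iN, 1L); hiI <- pmin(iN + 1L, length(steep))
    nearest <- ifelse(abs(st - steep[loI]) <= abs(st - steep[hiI]),
                      loI, hiI)
    nearest <- nearest[abs(st - steep[nearest]) <= w]
    cnt <- tabulate(nearest, nbins = length(steep))
    out[[u]] <- list(histogram = data.frame(mid_ms = h$mids,
                                            count = h$counts),
                     p_spike = mean(cnt >= 1L),
                     p_multi = mean(cnt > 1L))
  }
  out
}
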