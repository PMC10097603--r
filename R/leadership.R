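#' Sliding lagged cross-correlation of two first-derivative signals
#'
#' Computes, for every 10-s window scrolled in 100-ms steps and every lag
#' on a symmetric millisecond grid, the mean product of the two first
#' derivatives, and normalizes the matrix to its 99.9th percentile. The
#' sign convention is: positive lag means channel 0 (first signal) leads.
#'
#' @param sig0,sig1 equal-length \code{\linkS4class{ConditionedSignal}}s on
#'   a common clock (channel 0 conventionally the left side).
#' @param windowS sliding window (s).
#' @param stepS window step (s).
#' @param lagWindowMs maximal |lag| (ms).
#' @param normPct normalization percentile (default 99.9).
#' @return a \code{\linkS4class{LaggedXCorr}}.
#' @export
laggedXcorr <- function(sig0, sig1, windowS = 10, stepS = 0.1,
                        lagWindowMs = 51, normPct = 99.9) {
  stopifnot(is(sig0, "ConditionedSignal"), is(sig1, "ConditionedSignal"))
  if (length(sig0@c) != length(sig1@c))
    stop("signals must have equal length", call. = FALSE)
  rate <- sig0@rateHz
  n <- length(sig0@c)
  if (n / rate < windowS)
    stop("signals shorter than the analysis window", call. = FALSE)
  lagSamp <- round(-lagWindowMs / 1000 * rate):round(lagWindowMs / 1000 * rate)
  lags <- lagSamp * 1000 / rate
  half <- round(windowS / 2 * rate)
  tc <- seq(windowS / 2, n / rate - windowS / 2, by = stepS)
  centers <- round(tc * rate) + 1L
  m <- matrix(0, length(tc), length(lags))
  c0 <- sig0@c; c1 <- sig1@c
  for (j in seq_along(lagSamp)) {
    L <- lagSamp[j]
    ## m(t, L) = mean_tau c0(t+tau) * c1(t+tau+L)
    if (L >= 0) {
      prod <- c0[seq_len(n - L)] * c1[(1L + L):n]
    } else {
      prod <- c0[(1L - L):n] * c1[seq_len(n + L)]
    }
    ctr <- if (L >= 0) centers else centers + L
    ctr <- pmin(pmax(ctr, 1L), length(prod))
    m[, j] <- windowedMean(prod, half, ctr)
  }
  nv <- quantile(m, normPct / 100, names = FALSE)
  if (!is.finite(nv) || nv <= 0) nv <- 1
  new("LaggedXCorr", t = sig0@t0 + tc, lags = lags, m = m / nv,
      normValue = nv, windowS = windowS, stepS = stepS)
}

#' Peak-lag distribution of a lagged cross-correlation
#'
#' Takes each window's argmax lag, keeps only windows whose peak
#' correlation value is at or above the \code{keepQuantile} quantile of
#' peak values (isolating periods of high correlation), drops lags at the
#' extremes of the grid, and summarizes the resulting lag distribution.
#'
#' @param xc a \code{\linkS4class{LaggedXCorr}}.
#' @param keepQuantile keep windows with peak value >= this quantile
#'   (default 0.75, i.e. the top 25 percent).
#' @param minorModeFrac a side's mode is reported only if it holds at
#'   least this fraction of kept windows; used for the bimodal flag.
#' @return list: \code{lags_ms} (kept per-window peak lags),
#'   \code{histogram} (lag_ms, count), \code{modes_ms} (negative-side and
#'   positive-side modes, NA when that side is below
#'   \code{minorModeFrac}), \code{bimodal}, \code{median_lag_ms},
#'   \code{median_abs_lag_ms}.
#' @export
peakLagDistribution <- function(xc, keepQuantile = 0.75,
                                minorModeFrac = 0.15) {
  stopifnot(is(xc, "LaggedXCorr"))
  pv <- apply(xc@m, 1L, max)
  pl <- xc@lags[max.col(xc@m, ties.method = "first")]
  thr <- quantile(pv, keepQuantile, names = FALSE)
  lagMax <- max(abs(xc@lags))
  keep <- pv >= thr & abs(pl) < lagMax
  kept <- pl[keep]
  if (!length(kept)) {
    warning("no windows left after filtering; empty lag distribution",
            call. = FALSE)
    return(list(lags_ms = numeric(0),
                histogram = data.frame(lag_ms = numeric(0),
                                       count = integer(0)),
                modes_ms = c(NA_real_, NA_real_), bimodal = FALSE,
                median_lag_ms = NA_real_, median_abs_lag_ms = NA_real_))
  }
  tab <- table(factor(kept, levels = sort(unique(xc@lags))))
  hist <- data.frame(lag_ms = as.numeric(names(tab)),
                     count = as.integer(tab))
  sideMode <- function(sel) {
    h <- hist[sel, , drop = FALSE]
    if (!nrow(h) || sum(h$count) < minorModeFrac * length(kept))
      return(NA_real_)
    h$lag_ms[which.max(h$count)]
  }
  modes <- c(sideMode(hist$lag_ms < 0), sideMode(hist$lag_ms > 0))
  list(lags_ms = kept, histogram = hist, modes_ms = modes,
       bimodal = all(!is.na(modes)),
       median_lag_ms = median(kept),
       median_abs_lag_ms = median(abs(kept)))
}

#' Instantaneous-leadership score traces
#'
#' For each 100-ms step, the score for channel 0 leading by \code{lagMs}
#' (\code{sPlus}) and for channel 1 leading (\code{sMinus}):
#' the base-10 logarithm of the windowed sum of products of the
#' negative-clipped first derivatives, one channel shifted by the lag.
#' With derivatives clipped to be <= 0, every product is >= 0; the sum is
#' floored at \code{floorEps} before the logarithm so empty-product
#' windows map to \code{log10(floorEps)}.
#'
#' @param sig0,sig1 conditioned signals on a common clock (0 = left).
#' @param lagMs leadership lag (ms), normally the modal inter-channel lag
#'   from \code{\link{peakLagDistribution}}.
#' @param windowS sliding window (s).
#' @param stepS trace step (s).
#' @param floorEps floor applied to the windowed sum (default 1e-12).
#' @return a \code{\linkS4class{LeadershipTrace}} (states unset).
#' @export
leadershipScore <- function(sig0, sig1, lagMs = 20, windowS = 10,
                            stepS = 0.1, floorEps = 1e-12) {
  stopifnot(is(sig0, "ConditionedSignal"), is(sig1, "ConditionedSignal"))
  if (length(sig0@c) != length(sig1@c))
    stop("signals must have equal length", call. = FALSE)
  rate <- sig0@rateHz
  n <- length(sig0@c)
  c0 <- pmin(sig0@c, 0); c1 <- pmin(sig1@c, 0)
  L <- round(lagMs / 1000 * rate)
  half <- round(windowS / 2 * rate)
  tc <- seq(windowS / 2, n / rate - windowS / 2, by = stepS)
  centers <- round(tc * rate) + 1L
  sumAt <- function(lagSamp) {
    if (lagSamp >= 0) {
      prod <- c0[seq_len(n - lagSamp)] * c1[(1L + lagSamp):n]
      ctr <- centers
    } else {
      prod <- c0[(1L - lagSamp):n] * c1[seq_len(n + lagSamp)]
      ctr <- centers + lagSamp
    }
    ctr <- pmin(pmax(ctr, 1L), length(prod))
    windowedSum(prod, half, ctr)
  }
  ## sPlus: channel 0 leads -> channel 1 repeats later -> product of
  ## c0(t) with c1(t + lag)
  sPlus <- log10(pmax(sumAt(L), floorEps))
  sMinus <- log10(pmax(sumAt(-L), floorEps))
  new("LeadershipTrace", t = sig0@t0 + tc, sPlus = sPlus, sMinus = sMinus,
      state = character(0),
      params = list(lagMs = lagMs, windowS = windowS, stepS = stepS,
                    floorEps = floorEps))
}

#' Calibrate linear dominance thresholds from the score distributions
#'
#' Within REM_P, the pooled leadership scores are bimodal: a low cluster
#' (the score of the non-leading lag) and a high cluster (the leading
#' lag). The threshold is the midpoint between the two cluster centers of
#' a 2-means split of the pooled (sPlus, sMinus) values inside REM_P
#' episodes -- a reproducible stand-in for the per-animal manual threshold
#' selection the analysis otherwise requires. Pooling the two scores makes
#' the calibration work also when one side never leads (lesion mode),
#' where each score alone is unimodal. The same threshold is returned for
#' both sides (the conditioning z-scores both channels, so the score
#' scales are comparable).
#'
#' @param trace a \code{\linkS4class{LeadershipTrace}}.
#' @param episodeTable optional episode table; when given, only points
#'   inside REM_P episodes enter the calibration (recommended: slow-wave
#'   points otherwise drag the low cluster away from the REM_P structure).
#' @param leadFraction where the threshold sits between the non-leading
#'   and leading cluster centers (default 0.70). Windows around a
#'   dominance switch carry partial contributions of both sides and score
#'   between the clusters; a threshold close to the leading cluster keeps
#'   them below both thresholds, hence labelled unsettled. The default is
#'   calibrated on synthetic nights so that the mean detected unsettled
#'   time per switching episode is unbiased for the generating process;
#'   switch counts are insensitive to the choice over a wide range.
#' @return named numeric: \code{left} (threshold on sPlus), \code{right}
#'   (threshold on sMinus).
#' @export
calibrateDominanceThresholds <- function(trace, episodeTable = NULL,
                                         leadFraction = 0.70) {
  stopifnot(is(trace, "LeadershipTrace"))
  sel <- rep(TRUE, length(trace@t))
  if (!is.null(episodeTable)) {
    sel <- rep(FALSE, length(trace@t))
    remp <- episodeTable[episodeTable$state == "REM_P", , drop = FALSE]
    for (i in seq_len(nrow(remp)))
      sel[trace@t >= remp$start_s[i] & trace@t < remp$end_s[i]] <- TRUE
    if (!any(sel)) sel <- rep(TRUE, length(trace@t))
  }
  s <- c(trace@sPlus[sel], trace@sMinus[sel])
  cn <- matrix(quantile(s, c(0.25, 0.9), names = FALSE), ncol = 1)
  if (abs(diff(cn)) < 1e-9)
    return(c(left = cn[1], right = cn[1]))
  km <- kmeans(matrix(s, ncol = 1), centers = cn)
  lo <- min(km$centers); hi <- max(km$centers)
  thr <- lo + leadFraction * (hi - lo)
  c(left = thr, right = thr)
}

#' Segment dominance states from leadership scores
#'
#' Labels every trace point \code{left} (only the left-leads score above
#' its threshold), \code{right} (only the right-leads score above its
#' threshold), \code{unsettled} (both or neither above) or \code{SW}
#' (outside REM_P episodes). Within each REM_P episode, state runs shorter
#' than \code{minDurS} are merged into their surroundings (short detours
#' that leave and re-enter a state are ignored).
#'
#' @param trace a \code{\linkS4class{LeadershipTrace}}.
#' @param thresholds named numeric with elements \code{left} and
#'   \code{right}, e.g. from \code{\link{calibrateDominanceThresholds}}.
#' @param episodeTable episode data.frame (\code{state}, \code{start_s},
#'   \code{end_s}); points outside REM_P rows are labelled \code{SW}.
#' @param minDurS minimal dominance-state run (s), default 3.
#' @return the trace with \code{state} filled in; dominance segments as a
#'   data.frame in attribute \code{"segments"} (side, start_s, end_s,
#'   clipped to REM_P episodes).
#' @export
segmentDominance <- function(trace, thresholds, episodeTable,
                             minDurS = 3) {
  stopifnot(is(trace, "LeadershipTrace"))
  if (is.null(thresholds) ||
      !all(c("left", "right") %in% names(thresholds)))
    stop("thresholds must be a named vector with 'left' and 'right'",
         call. = FALSE)
  lAbove <- trace@sPlus >= thresholds[["left"]]
  rAbove <- trace@sMinus >= thresholds[["right"]]
  state <- ifelse(lAbove & !rAbove, "left",
                  ifelse(rAbove & !lAbove, "right", "unsettled"))
  inRemp <- rep(FALSE, length(trace@t))
  remp <- episodeTable[episodeTable$state == "REM_P", , drop = FALSE]
  for (i in seq_len(nrow(remp)))
    inRemp[trace@t >= remp$start_s[i] & trace@t < remp$end_s[i]] <- TRUE
  state[!inRemp] <- "SW"
  step <- trace@params$stepS %||% diff(trace@t[1:2])
  minLen <- max(1L, round(minDurS / step))
  ## defragment within each REM_P episode independently
  for (i in seq_len(nrow(remp))) {
    sel <- which(trace@t >= remp$start_s[i] & trace@t < remp$end_s[i])
    if (length(sel) > 1L)
      state[sel] <- mergeShortRuns(state[sel], minLen)
  }
  ## leadership windows overlapping an episode boundary straddle SW, where
  ## the score is undefined; an unsettled run at the very edge of an
  ## episode is therefore attributed to its settled neighbour
  for (i in seq_len(nrow(remp))) {
    sel <- which(trace@t >= remp$start_s[i] & trace@t < remp$end_s[i])
    if (length(sel) < 2L) next
    r <- rle(state[sel])
    if (length(r$values) >= 2L && r$values[1L] == "unsettled")
      r$values[1L] <- r$values[2L]
    nr <- length(r$values)
    if (nr >= 2L && r$values[nr] == "unsettled")
      r$values[nr] <- r$values[nr - 1L]
    state[sel] <- mergeShortRuns(inverse.rle(r), minLen)
  }
  trace@state <- state
  segs <- list()
  for (i in seq_len(nrow(remp))) {
    sel <- which(trace@t >= remp$start_s[i] & trace@t < remp$end_s[i])
    if (!length(sel)) next
    s <- runsToSegments(state[sel], step, t0 = trace@t[sel[1L]])
    ## clip segment boundaries to the episode
    s$start_s[1L] <- remp$start_s[i]
    s$end_s[nrow(s)] <- remp$end_s[i]
    names(s)[1L] <- "side"
    s$episode <- i
    segs[[length(segs) + 1L]] <- s
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(side = character(0), start_s = numeric(0),
               end_s = numeric(0), episode = integer(0))
  rownames(segments) <- NULL
  trace@params$thresholds <- thresholds
  attr(trace, "segments") <- segments
  trace
}
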