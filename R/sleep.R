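#' Cluster-based beta-power threshold
#'
#' Splits the beta-power values into two clusters by 2-means on log10
#' power (the low cluster is slow-wave sleep, the high cluster REM_P) and
#' returns the arithmetic midpoint of the two cluster centers on the
#' power scale. Clustering in log space separates the modes robustly;
#' thresholding at the arithmetic midpoint keeps episode boundaries
#' unbiased, because a sliding window straddling a transition crosses the
#' midpoint when it is half filled with REM_P signal. A fixed percentile
#' cannot guarantee a threshold in the inter-cluster gap when state
#' occupancies vary.
#'
#' @param beta a \code{\linkS4class{BandPowerTrace}}.
#' @return threshold on the power scale of \code{beta@p}.
#' @export
betaThreshold2Means <- function(beta) {
  stopifnot(is(beta, "BandPowerTrace"))
  lp <- log10(pmax(beta@p, .Machine$double.xmin))
  cn <- matrix(quantile(lp, c(0.1, 0.9), names = FALSE), ncol = 1)
  if (abs(diff(cn)) < 1e-9) return(10^cn[1])
  km <- kmeans(matrix(lp, ncol = 1), centers = cn)
  hi <- km$cluster == which.max(km$centers)
  ## arithmetic cluster means on the power scale: a window straddling a
  ## transition crosses their midpoint when half filled with REM_P signal
  (mean(beta@p[hi]) + mean(beta@p[!hi])) / 2
}

#' Segment REM_P and SW sleep from a beta-power trace
#'
#' Thresholds the beta-band power trace (above = REM_P, below = SW) and
#' merges state runs shorter than \code{minDurS} into their surroundings,
#' ignoring short detours that leave and re-enter a state. Episodes tile
#' the analyzed span.
#'
#' By default the threshold is the \code{pct}-th percentile of the trace
#' (the published recipe). When the SW share of the night exceeds that
#' percentile the percentile falls inside the SW power cluster rather than
#' between the clusters; pass \code{threshold = betaThreshold2Means(beta)}
#' (what \code{\link{runAll}} does) for a threshold that adapts to the
#' actual state occupancy.
#'
#' @param beta a \code{\linkS4class{BandPowerTrace}}.
#' @param pct percentile (0-100) defining the threshold (default 15).
#' @param minDurS minimal episode duration (s), default 15.
#' @param threshold explicit power threshold; overrides \code{pct}.
#' @return data.frame(state, start_s, end_s) tiling the span, with the
#'   threshold in attribute \code{"threshold"}.
#' @export
segmentSleep <- function(beta, pct = 15, minDurS = 15, threshold = NULL) {
  stopifnot(is(beta, "BandPowerTrace"))
  if (diff(range(beta@p)) < 1e-12 * max(abs(beta@p), 1))
    stop("degenerate beta trace: constant power, no threshold exists",
         call. = FALSE)
  if (is.null(threshold))
    threshold <- quantile(beta@p, pct / 100, names = FALSE)
  state <- ifelse(beta@p > threshold, "REM_P", "SW")
  step <- beta@stepS
  minLen <- max(1L, round(minDurS / step))
  state <- mergeShortRuns(state, minLen)
  segs <- runsToSegments(state, step, t0 = beta@t[1L])
  ## extend the outer boundaries to the full recorded span
  segs$start_s[1L] <- beta@t[1L] - beta@windowS / 2
  segs$end_s[nrow(segs)] <- beta@t[length(beta@t)] + beta@windowS / 2
  attr(segs, "threshold") <- threshold
  segs
}

#' Refine episode boundaries with a fine-resolution beta trace
#'
#' The 10-s beta window localizes state transitions only to within a few
#' seconds, and a global threshold is biased where local power levels
#' deviate from the cluster centers. This second pass recomputes band
#' power with a short window and moves every interior episode boundary to
#' the nearest crossing of the midpoint between the \emph{local} SW and
#' REM_P power levels.
#'
#' @param episodeTable coarse table from \code{\link{segmentSleep}}.
#' @param sig the \code{\linkS4class{ConditionedSignal}} the beta trace
#'   came from.
#' @param windowS,stepS fine band-power resolution (default 2 s / 0.25 s).
#' @param searchS how far a boundary may move (s).
#' @return the episode table with refined boundaries (still tiling the
#'   span).
#' @export
refineEpisodeBoundaries <- function(episodeTable, sig, windowS = 2,
                                    stepS = 0.25, searchS = 6) {
  if (nrow(episodeTable) < 2L) return(episodeTable)
  fine <- bandPower(sig, windowS = windowS, stepS = stepS)
  tf <- fine@t; pf <- fine@p
  segs <- episodeTable
  for (k in seq_len(nrow(segs) - 1L)) {
    b <- segs$end_s[k]
    up <- segs$state[k] == "SW"   # upward power crossing at SW -> REM_P
    level <- function(lo, hi) {
      sel <- tf >= lo & tf <= hi
      if (!any(sel)) NA_real_ else median(pf[sel])
    }
    lLow <- level(b - 14, b - 4); lHigh <- level(b + 4, b + 14)
    if (!up) { tmp <- lLow; lLow <- lHigh; lHigh <- tmp }
    if (!is.finite(lLow) || !is.finite(lHigh) || lHigh <= lLow) next
    thr <- (lLow + lHigh) / 2
    sel <- which(tf >= b - searchS & tf <= b + searchS)
    if (length(sel) < 2L) next
    above <- pf[sel] > thr
    cross <- if (up) which(!above[-length(above)] & above[-1L])
             else which(above[-length(above)] & !above[-1L])
    if (!length(cross)) next
    tCross <- (tf[sel[cross]] + tf[sel[cross + 1L]]) / 2
    bNew <- tCross[which.min(abs(tCross - b))]
    segs$end_s[k] <- bNew
    segs$start_s[k + 1L] <- bNew
  }
  attr(segs, "threshold") <- attr(episodeTable, "threshold")
  segs
}

#' Episode-level dominance statistics
#'
#' Combines the sleep episode table with dominance segments: per REM_P
#' episode, the number of left/right dominance switches (unsettled
#' interludes between same-side periods do not count as switches), time
#' spent in each state, and the majority leading side; plus night-level
#' aggregates (mean durations of 0-switch and 1-switch episodes, mean
#' unsettled time of switching episodes, the switch-count distribution,
#' and the per-episode left-leading fraction series).
#'
#' @param episodeTable data.frame(state, start_s, end_s) from
#'   \code{\link{segmentSleep}} (or generator truth).
#' @param domSegments data.frame(side, start_s, end_s) from
#'   \code{\link{segmentDominance}} (attribute \code{"segments"}) or
#'   generator truth.
#' @return list with \code{episodes} (the REM_P rows extended with
#'   \code{n_switches}, \code{time_left_s}, \code{time_right_s},
#'   \code{time_unsettled_s}, \code{leading_side_majority}) and
#'   \code{summary}.
#' @export
episodeStats <- function(episodeTable, domSegments) {
  remp <- episodeTable[episodeTable$state == "REM_P", , drop = FALSE]
  if (nrow(remp) && !nrow(domSegments))
    stop("dominance segments missing for REM_P episodes", call. = FALSE)
  rownames(remp) <- NULL
  res <- remp
  res$n_switches <- 0L
  res$time_left_s <- 0; res$time_right_s <- 0; res$time_unsettled_s <- 0
  res$leading_side_majority <- NA_character_
  for (i in seq_len(nrow(remp))) {
    a <- remp$start_s[i]; b <- remp$end_s[i]
    ov <- domSegments[domSegments$end_s > a & domSegments$start_s < b, ,
                      drop = FALSE]
    ov <- ov[!ov$side %in% "SW", , drop = FALSE]
    if (!nrow(ov)) next
    ov <- ov[order(ov$start_s), , drop = FALSE]
    dur <- pmin(ov$end_s, b) - pmax(ov$start_s, a)
    res$time_left_s[i] <- sum(dur[ov$side == "left"])
    res$time_right_s[i] <- sum(dur[ov$side == "right"])
    res$time_unsettled_s[i] <- sum(dur[ov$side == "unsettled"])
    sides <- ov$side[ov$side %in% c("left", "right")]
    if (length(sides)) {
      collapsed <- rle(sides)$values
      res$n_switches[i] <- length(collapsed) - 1L
    }
    tl <- res$time_left_s[i]; tr <- res$time_right_s[i]
    res$leading_side_majority[i] <-
      if (tl == 0 && tr == 0) "none" else if (tl >= tr) "left" else "right"
  }
  d <- res$end_s - res$start_s
  switching <- res$n_switches >= 1L
  summary <- list(
    n_remp_episodes = nrow(res),
    mean_dur_0switch_s = if (any(res$n_switches == 0L))
      mean(d[res$n_switches == 0L]) else NA_real_,
    mean_dur_1switch_s = if (any(res$n_switches == 1L))
      mean(d[res$n_switches == 1L]) else NA_real_,
    mean_remp_dur_s = if (nrow(res)) mean(d) else NA_real_,
    mean_unsettled_switching_s = if (any(switching))
      mean(res$time_unsettled_s[switching]) else NA_real_,
    total_remp_s = sum(d),
    switch_distribution = if (nrow(res))
      as.list(table(res$n_switches)) else list(),
    left_fraction_per_episode = if (nrow(res))
      res$time_left_s / pmax(res$time_left_s + res$time_right_s, 1e-12)
      else numeric(0))
  list(episodes = res, summary = summary)
}

#' Amplitude difference versus lag sign for matched SN pairs
#'
#' Normalizes each side's amplitudes by that side's night median, takes
#' the per-pair difference (left minus right), splits by lag sign
#' (positive lag = left leads) and compares the two groups with a
#' two-sample rank-sum (Mann-Whitney) test. When the leading side carries
#' the larger event, the difference is positive for left-leading pairs
#' and negative for right-leading ones.
#'
#' @param pairs accepted pair data.frame (needs \code{amp_left},
#'   \code{amp_right}, \code{lag_ms}); typically
#'   \code{subset(matchSN(...), accepted)}.
#' @param normalize \code{"median"} (divide by night median) or
#'   \code{"zscore"}.
#' @return list: \code{delta} (normalized differences), \code{lag_ms},
#'   \code{mean_delta_left_leads}, \code{mean_delta_right_leads},
#'   \code{test} (the \code{htest}).
#' @export
amplitudeLagStats <- function(pairs, normalize = c("median", "zscore")) {
  normalize <- match.arg(normalize)
  if (normalize == "median") {
    nl <- pairs$amp_left / median(pairs$amp_left)
    nr <- pairs$amp_right / median(pairs$amp_right)
  } else {
    nl <- as.vector(scale(pairs$amp_left))
    nr <- as.vector(scale(pairs$amp_right))
  }
  delta <- nl - nr
  pos <- delta[pairs$lag_ms > 0]
  neg <- delta[pairs$lag_ms < 0]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need at least 2 pairs per lag-sign group", call. = FALSE)
  list(delta = delta, lag_ms = pairs$lag_ms,
       mean_delta_left_leads = mean(pos),
       mean_delta_right_leads = mean(neg),
       test = wilcox.test(pos, neg))
}

#' Welch's two-sided t comparison of episode-duration groups
#'
#' @param a,b numeric duration samples (s), e.g. lesioned vs control REM_P
#'   episode durations. The statistic has the sign of \code{mean(a) -
#'   mean(b)}.
#' @param alternative passed to \code{t.test} (default two-sided).
#' @return the \code{htest} object.
#' @export
welchCompare <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  t.test(a, b, var.equal = FALSE, alternative = alternative)
}

#' One-sided Wilcoxon signed-rank test on per-night median lags
#'
#' @param lags numeric vector (one median lag per night, ms).
#' @param alternative direction of the one-sided test (default
#'   \code{"greater"}: lags exceed zero).
#' @return the \code{htest} object.
#' @export
lagSignedRank <- function(lags, alternative = "greater") {
  if (length(lags) < 2L)
    stop("need at least 2 nights", call. = FALSE)
  wilcox.test(lags, mu = 0, alternative = alternative)
}
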