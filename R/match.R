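#' Matching parameters for bilateral SN pairing
#'
#' @param xcorr_window_ms local cross-correlation window (ms).
#' @param kernel_tau_ms time constant of the exponential lag kernel (ms).
#' @param lag_window_ms maximal |lag| of a candidate pair (ms).
#' @param chunk_hours section length for chunked matching (hours).
#' @return a validated list of class \code{"MatchParams"}.
#' @export
matchParams <- function(xcorr_window_ms = 100, kernel_tau_ms = 10,
                        lag_window_ms = 51, chunk_hours = 1) {
  p <- list(xcorr_window_ms = xcorr_window_ms,
            kernel_tau_ms = kernel_tau_ms,
            lag_window_ms = lag_window_ms, chunk_hours = chunk_hours)
  for (f in names(p)) stopifnot_scalar(p[[f]], f)
  class(p) <- "MatchParams"
  p
}

#' Score candidate left-right SN pairs
#'
#' Every (left, right) pair of candidate SNs within \code{lag_window_ms}
#' is scored by the local cross-correlation of the negative-clipped first
#' derivatives in a \code{xcorr_window_ms} window centered at the midpoint
#' between the two events, evaluated at the pair's lag, and multiplied by
#' an exponential lag kernel \code{exp(-|lag| / kernel_tau_ms)}. Clipping
#' both derivatives to be <= 0 makes all scores non-negative. Lags are
#' \code{t_right - t_left} in ms: positive lag means the left side leads.
#'
#' @param leftEvents,rightEvents candidate data.frames (need
#'   \code{t_steep_s}).
#' @param sigL,sigR the conditioned signals the candidates came from.
#' @param params a \code{\link{matchParams}} list.
#' @return data.frame with \code{left}, \code{right} (row indices into the
#'   input tables), \code{lag_ms} and \code{score}.
#' @export
scorePairs <- function(leftEvents, rightEvents, sigL, sigR,
                       params = matchParams()) {
  stopifnot(is(sigL, "ConditionedSignal"), is(sigR, "ConditionedSignal"))
  empty <- data.frame(left = integer(0), right = integer(0),
                      lag_ms = numeric(0), score = numeric(0))
  nL <- nrow(leftEvents); nR <- nrow(rightEvents)
  if (!nL || !nR) return(empty)
  rate <- sigL@rateHz
  tL <- leftEvents$t_steep_s; tR <- rightEvents$t_steep_s
  ord <- order(tR)
  tRs <- tR[ord]
  wLag <- params$lag_window_ms / 1000
  lo <- findInterval(tL - wLag, tRs)
  hi <- findInterval(tL + wLag, tRs)
  nPer <- hi - lo
  if (!sum(nPer)) return(empty)
  li <- rep.int(seq_len(nL), nPer)
  ri <- ord[unlist(mapply(function(a, b) if (b > a) (a + 1L):b else integer(0),
                          lo, hi, SIMPLIFY = FALSE), use.names = FALSE)]
  lagS <- tR[ri] - tL[li]
  cLm <- pmin(sigL@c, 0)
  cRm <- pmin(sigR@c, 0)
  n <- length(cLm)
  half <- round(params$xcorr_window_ms / 2000 * rate)
  lagSamp <- round(lagS * rate)
  center <- round(((tL[li] + tR[ri]) / 2 - sigL@t0) * rate) + 1L
  score <- numeric(length(li))
  for (k in seq_along(li)) {
    i0 <- max(1L, center[k] - half)
    i1 <- min(n, center[k] + half)
    j0 <- i0 + lagSamp[k]; j1 <- i1 + lagSamp[k]
    if (j0 < 1L) { i0 <- i0 + (1L - j0); j0 <- 1L }
    if (j1 > n) { i1 <- i1 - (j1 - n); j1 <- n }
    if (i1 < i0) next
    score[k] <- sum(cLm[i0:i1] * cRm[j0:j1]) / (i1 - i0 + 1L)
  }
  score <- score * exp(-abs(lagS) * 1000 / params$kernel_tau_ms)
  data.frame(left = li, right = ri, lag_ms = lagS * 1000, score = score)
}

#' Optimal one-to-one assignment of scored pairs
#'
#' Finds the combination of candidate pairs maximizing the total score,
#' with each event used at most once and events allowed to remain
#' unmatched, by maximum-weight bipartite matching on the sparse candidate
#' graph.
#'
#' @param scored data.frame from \code{\link{scorePairs}}.
#' @return the subset of rows forming the optimal assignment, ordered by
#'   \code{left}.
#' @export
matchPairs <- function(scored) {
  if (!nrow(scored)) return(scored[0, , drop = FALSE])
  pos <- scored[scored$score > 0, , drop = FALSE]
  if (!nrow(pos)) return(scored[0, , drop = FALSE])
  lIds <- sort(unique(pos$left)); rIds <- sort(unique(pos$right))
  nL <- length(lIds)
  li <- match(pos$left, lIds)
  ri <- nL + match(pos$right, rIds)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nL), rep(TRUE, length(rIds))),
    edges = as.vector(rbind(li, ri)))
  ## the candidate graph splits into independent components at every gap
  ## wider than the lag window; solving per component keeps the (globally
  ## optimal) weighted matching fast on long nights
  comp <- igraph::components(g)$membership
  edgeComp <- comp[li]
  keep <- logical(nrow(pos))
  for (cid in unique(edgeComp)) {
    eIdx <- which(edgeComp == cid)
    sub <- pos[eIdx, , drop = FALSE]
    sL <- sort(unique(sub$left)); sR <- sort(unique(sub$right))
    nsL <- length(sL)
    gs <- igraph::make_bipartite_graph(
      types = c(rep(FALSE, nsL), rep(TRUE, length(sR))),
      edges = as.vector(rbind(match(sub$left, sL),
                              nsL + match(sub$right, sR))))
    m <- igraph::max_bipartite_match(gs, weights = sub$score)$matching
    sel <- which(!is.na(m[seq_len(nsL)]))
    if (!length(sel)) next
    key <- paste(sL[sel], sR[m[sel] - nsL])
    keep[eIdx[match(key, paste(sub$left, sub$right))]] <- TRUE
  }
  out <- pos[keep, , drop = FALSE]
  out <- out[order(out$left), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Accept matched pairs against the noise null
#'
#' A matched pair is accepted when at least one of its two SNs has a low
#' null probability: \code{min(p_null_left, p_null_right) < alpha}.
#' Rejected pairs are retained with \code{accepted = FALSE} for audit.
#'
#' @param pairs data.frame from \code{\link{matchPairs}}.
#' @param leftEvents,rightEvents the candidate tables the pair indices
#'   refer to; both must carry a \code{p_null} column (from
#'   \code{\link{filterCandidates}}'s annotated set).
#' @param alpha acceptance level (default 0.05).
#' @return \code{pairs} with columns \code{p_null_left}, \code{p_null_right},
#'   \code{amp_left}, \code{amp_right}, \code{t_left_s}, \code{t_right_s}
#'   and \code{accepted}.
#' @export
acceptPairs <- function(pairs, leftEvents, rightEvents, alpha = 0.05) {
  if (is.null(leftEvents$p_null) || is.null(rightEvents$p_null))
    stop("events must carry p_null (run filterCandidates first)",
         call. = FALSE)
  pairs$p_null_left <- leftEvents$p_null[pairs$left]
  pairs$p_null_right <- rightEvents$p_null[pairs$right]
  pairs$amp_left <- leftEvents$amplitude[pairs$left]
  pairs$amp_right <- rightEvents$amplitude[pairs$right]
  pairs$t_left_s <- leftEvents$t_steep_s[pairs$left]
  pairs$t_right_s <- rightEvents$t_steep_s[pairs$right]
  pairs$accepted <- pmin(pairs$p_null_left, pairs$p_null_right) < alpha
  pairs
}

#' Detect-and-match pipeline for one pair of channels
#'
#' Convenience wrapper: candidate pairing on the annotated (unfiltered)
#' candidate sets, per 1-h section, then optimal assignment and
#' acceptance.
#'
#' @param detL,detR results of \code{\link{detectSN}} for the left and
#'   right channel.
#' @param sigL,sigR the conditioned signals.
#' @param params \code{\link{matchParams}}.
#' @param alpha pair acceptance level (default 0.05).
#' @return data.frame of matched pairs with acceptance flags.
#' @export
matchSN <- function(detL, detR, sigL, sigR, params = matchParams(),
                    alpha = 0.05) {
  candL <- detL$candidates; candR <- detR$candidates
  chunkS <- params$chunk_hours * 3600
  t1 <- max(candL$t_steep_s, candR$t_steep_s, 0)
  out <- list()
  for (a in seq(0, max(t1 - 1e-9, 0), by = chunkS)) {
    b <- a + chunkS
    selL <- which(candL$t_steep_s >= a & candL$t_steep_s < b)
    selR <- which(candR$t_steep_s >= a & candR$t_steep_s < b)
    if (!length(selL) || !length(selR)) next
    sc <- scorePairs(candL[selL, , drop = FALSE],
                     candR[selR, , drop = FALSE], sigL, sigR, params)
    mp <- matchPairs(sc)
    if (!nrow(mp)) next
    mp <- acceptPairs(mp, candL[selL, , drop = FALSE],
                      candR[selR, , drop = FALSE], alpha = alpha)
    mp$left <- selL[mp$left]
    mp$right <- selR[mp$right]
    out[[length(out) + 1L]] <- mp
  }
  if (!length(out))
    return(data.frame(left = integer(0), right = integer(0),
                      lag_ms = numeric(0), score = numeric(0),
                      p_null_left = numeric(0), p_null_right = numeric(0),
                      amp_left = numeric(0), amp_right = numeric(0),
                      t_left_s = numeric(0), t_right_s = numeric(0),
                      accepted = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score recovery of ground-truth bilateral pairs by the matching stage
#'
#' Among detected SNs whose amplitude lies in the top \code{1 -
#' topQuantile} of the pooled amplitude distribution and that correspond
#' (within \code{tolMs}) to a ground-truth event with a bilateral partner,
#' computes the fraction that the matcher placed in an accepted pair at
#' the correct lag.
#'
#' @param truth a \code{\linkS4class{NightTruth}}.
#' @param detL,detR \code{\link{detectSN}} results for the two claustrum
#'   channels.
#' @param pairs accepted-pair table from \code{\link{matchSN}}.
#' @param topQuantile amplitude quantile defining "clearly detectable"
#'   events (default 0.95: the top 5 percent).
#' @param tolMs tolerance for event identification and lag agreement (ms).
#' @return list: \code{fraction} (recovered share), \code{n} (number of
#'   top-amplitude detected SNs with a truth partner).
#' @export
pairRecovery <- function(truth, detL, detR, pairs, topQuantile = 0.95,
                         tolMs = 5) {
  stopifnot(is(truth, "NightTruth"))
  acc <- pairs[pairs$accepted, , drop = FALSE]
  tp <- truth@pairs
  ev <- truth@events
  evP <- ev[!is.na(ev$pair_id), , drop = FALSE]
  tol <- tolMs / 1000
  thr <- quantile(c(detL$events$amplitude, detR$events$amplitude),
                  topQuantile, names = FALSE)
  ok <- logical(0)
  for (side in c("L", "R")) {
    det <- if (side == "L") detL else detR
    big <- det$events[det$events$amplitude >= thr, , drop = FALSE]
    evC <- evP[evP$channel == paste0("claustrum-", side), , drop = FALSE]
    evC <- evC[order(evC$t_steep_s), , drop = FALSE]
    if (!nrow(big) || !nrow(evC)) next
    i <- findInterval(big$t_steep_s, evC$t_steep_s)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, nrow(evC))
    nearest <- ifelse(abs(big$t_steep_s - evC$t_steep_s[lo]) <=
                        abs(big$t_steep_s - evC$t_steep_s[hi]), lo, hi)
    matched <- abs(big$t_steep_s - evC$t_steep_s[nearest]) < tol
    big <- big[matched, , drop = FALSE]
    pid <- evC$pair_id[nearest[matched]]
    trueLag <- tp$lag_ms[match(pid, tp$pair_id)]
    tKey <- if (side == "L") acc$t_left_s else acc$t_right_s
    for (j in seq_len(nrow(big))) {
      cand <- which(abs(tKey - big$t_steep_s[j]) < tol)
      ok <- c(ok, length(cand) > 0 &&
                any(abs(acc$lag_ms[cand] - trueLag[j]) < tolMs))
    }
  }
  list(fraction = if (length(ok)) mean(ok) else NA_real_, n = length(ok))
}
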