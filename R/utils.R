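#' @import methods
#' @importFrom stats approx quantile median rnorm runif rexp rbinom rlnorm
#'   plogis kmeans sd t.test wilcox.test setNames fft rpois
#' @importFrom utils head tail write.csv read.csv
NULL

## Vectorized local-extrema finder.
## Returns indices i with x[i-1] < x[i] >= x[i+1] (maxima) whose height
## exceeds `floor`. Plateaus keep their first sample. pracma::findpeaks is
## too slow on multi-million-sample traces, hence this primitive.
localMaxima <- function(x, floor = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  ## resolve zero slopes by propagating the previous sign (plateau start wins)
  z <- which(s == 0)
  if (length(z)) {
    for (i in z) s[i] <- if (i == 1L) 1 else s[i - 1L]
  }
  idx <- which(s[-length(s)] > 0 & s[-1L] < 0) + 1L
  idx[x[idx] > floor]
}

localMinima <- function(x, floor = -Inf) {
  localMaxima(-x, floor = floor)
}

## Running mean over a centered window, sampled at arbitrary center indices.
## x: numeric; half: half-window in samples; centers: integer indices.
windowedMean <- function(x, half, centers) {
  cs <- cumsum(c(0, x))
  lo <- pmax(centers - half, 1L)
  hi <- pmin(centers + half, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

windowedSum <- function(x, half, centers) {
  cs <- cumsum(c(0, x))
  lo <- pmax(centers - half, 1L)
  hi <- pmin(centers + half, length(x))
  cs[hi + 1L] - cs[lo]
}

## 1/f ("pink") noise with a given RMS, via spectral shaping of white
## Gaussian noise. Deterministic given the RNG state.
pinkNoise <- function(n, rms) {
  if (n < 2L) return(rnorm(n) * rms)
  nf <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(nf)
  W <- fft(w)
  f <- c(seq_len(nf %/% 2 + 1L) - 1L, rev(seq_len(nf - nf %/% 2 - 1L)))
  shape <- 1 / sqrt(pmax(f, 1))
  x <- Re(fft(W * shape, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x * (rms / stats::sd(x))
}

## Merge runs shorter than minLen into their surroundings. labels is a
## character/integer vector on a uniform grid. A short run flanked by a
## single state on both sides is relabelled to that state; otherwise it is
## absorbed into the longer neighbouring run. Applied iteratively,
## shortest runs first, until every run is >= minLen (or one run remains).
mergeShortRuns <- function(labels, minLen) {
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < minLen)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    if (i == 1L) {
      r$values[i] <- r$values[i + 1L]
    } else if (i == length(r$values)) {
      r$values[i] <- r$values[i - 1L]
    } else if (identical(r$values[i - 1L], r$values[i + 1L])) {
      r$values[i] <- r$values[i - 1L]
    } else if (r$lengths[i - 1L] >= r$lengths[i + 1L]) {
      r$values[i] <- r$values[i - 1L]
    } else {
      r$values[i] <- r$values[i + 1L]
    }
    labels <- inverse.rle(r)
  }
  labels
}

## Run-length segments of a label vector on a uniform grid with step `step`
## starting at `t0`: data.frame(state, start_s, end_s) with half-open
## [start, end) intervals.
runsToSegments <- function(labels, step, t0 = 0) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(0, head(ends, -1L))
  data.frame(state = r$values,
             start_s = t0 + starts * step,
             end_s = t0 + ends * step,
             stringsAsFactors = FALSE)
}

## Empirical upper-tail probability P(sample >= x), evaluated for each x.
upperTailProb <- function(sample, x) {
  if (!length(sample)) return(rep(0, length(x)))
  n <- length(sample)
  s <- sort(sample)
  (n - findInterval(x, s, left.open = TRUE)) / n
}

## Joint null tail: for each candidate (a_i, d_i), the fraction of noise
## events with amplitude >= a_i and duration <= d_i. Durations are
## quantized (sample-grid multiples), so noise events are bucketed by
## duration and each query is one binary search over the cumulative
## sorted-amplitude vector of its bucket.
jointNullProb <- function(noiseAmp, noiseDur, a, d) {
  nn <- length(noiseAmp)
  if (!nn) return(rep(0, length(a)))
  if (!length(a)) return(numeric(0))
  durGrid <- sort(unique(noiseDur))
  ord <- order(noiseDur)
  bucket <- findInterval(noiseDur[ord], durGrid)
  ampsByBucket <- split(noiseAmp[ord], bucket)
  cumAmps <- vector("list", length(durGrid))
  acc <- numeric(0)
  for (b in seq_along(durGrid)) {
    key <- as.character(b)
    if (!is.null(ampsByBucket[[key]]))
      acc <- c(acc, ampsByBucket[[key]])
    cumAmps[[b]] <- sort(acc)
  }
  qb <- findInterval(d, durGrid)   # last grid value <= d
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    b <- qb[i]
    if (b < 1L) next
    s <- cumAmps[[b]]
    out[i] <- (length(s) - findInterval(a[i], s, left.open = TRUE)) / nn
  }
  out
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
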