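# Independent oracles and fixture builders used across the suite.

# Exhaustive-enumeration oracle for the one-to-one assignment: maximal total
# score over all matchings of the candidate edge list (events may stay
# unmatched). Recursive branch over edges; independent of the package's
# bipartite-matching route.
bruteForceAssignment <- function(edges) {
  best <- 0
  n <- nrow(edges)
  recurse <- function(i, usedL, usedR, total) {
    if (total > best) best <<- total
    if (i > n) return()
    # upper bound: remaining positive scores
    rem <- sum(pmax(edges$score[i:n], 0))
    if (total + rem <= best) return()
    recurse(i + 1L, usedL, usedR, total)               # skip edge i
    if (!(edges$left[i] %in% usedL) && !(edges$right[i] %in% usedR))
      recurse(i + 1L, c(usedL, edges$left[i]), c(usedR, edges$right[i]),
              total + edges$score[i])
  }
  recurse(1L, integer(0), integer(0), 0)
  best
}

# Literal loop evaluation of the leadership sum for one window center:
# sum over tau of [c0(t+tau)]^- * [c1(t+tau+lag)]^-, log10 with floor.
leadershipLoopOracle <- function(c0, c1, centerIdx, lagSamp, halfSamp,
                                 floorEps = 1e-12) {
  s <- 0
  n <- length(c0)
  for (tau in -halfSamp:halfSamp) {
    i <- centerIdx + tau
    j <- i + lagSamp
    if (i < 1 || i > n || j < 1 || j > n) next
    a <- min(c0[i], 0)
    b <- min(c1[j], 0)
    s <- s + a * b
  }
  log10(max(s, floorEps))
}

# Conditioned signal constructed directly from an analytic voltage trace
# (derivatives by the same central differences the package uses), without
# filtering -- for tests of detection geometry on exact waveforms.
analyticConditioned <- function(v, rateHz = 1000, role = "claustrum-L") {
  dtms <- 1000 / rateHz
  n <- length(v)
  cc <- numeric(n); c2 <- numeric(n)
  i <- 2:(n - 1L)
  cc[i] <- (v[i + 1L] - v[i - 1L]) / (2 * dtms)
  c2[i] <- (v[i + 1L] - 2 * v[i] + v[i - 1L]) / dtms^2
  cc[1] <- cc[2]; cc[n] <- cc[n - 1L]
  c2[1] <- c2[2]; c2[n] <- c2[n - 1L]
  new("ConditionedSignal", v = v, c = cc, c2 = c2, rateHz = rateHz,
      role = role, t0 = 0, filterDesc = list())
}

# Single-channel recording from a plain vector.
vectorRecording <- function(v, rateHz = 1000, role = "claustrum-L") {
  m <- matrix(v, ncol = 1)
  colnames(m) <- role
  new("Recording", samples = m, rateHz = rateHz, channelRoles = role, t0 = 0)
}

# Fraction of times in `a` that have a counterpart in `b` within tol (s).
fractionMatched <- function(a, b, tol = 0.005) {
  if (!length(a)) return(NA_real_)
  if (!length(b)) return(0)
  b <- sort(b)
  i <- findInterval(a, b)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(b))
  mean(pmin(abs(a - b[lo]), abs(a - b[hi])) < tol)
}

inEpisodes <- function(t, episodes, state = "REM_P") {
  sel <- episodes[episodes$state == state, , drop = FALSE]
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(sel)))
    out <- out | (t >= sel$start_s[i] & t < sel$end_s[i])
  out
}

# Cached small synthetic night shared by several test files (generation is
# deterministic, so caching only saves time).
sharedNightEnv <- new.env(parent = emptyenv())
sharedNight <- function(duration_s = 600, seed = 7L, ...) {
  key <- paste(duration_s, seed, ...)
  if (is.null(sharedNightEnv[[key]]))
    sharedNightEnv[[key]] <- generateNight(
      generatorConfig(duration_s = duration_s, seed = seed, ...))
  sharedNightEnv[[key]]
}
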