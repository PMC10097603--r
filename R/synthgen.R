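#' Synthetic-night generator configuration
#'
#' Builds a validated \code{\linkS4class{GeneratorConfig}}. Defaults encode
#' the statistical structure of bilateral claustrum sleep recordings in
#' \emph{Pogona}: alternating slow-wave (SW) and REM-like (REM_P) episodes,
#' SN trains with a skewed-right inter-event-interval (IEI) law
#' (mode 40 ms, per-channel median 60.2 ms), bilateral SN pairs offset by
#' 20 ms with the leading side larger in amplitude, dominance switching 0-1
#' times per episode, isthmic (Imc) channels leading the claustra by 30 ms
#' (ipsilateral) / 50 ms (contralateral), per-side independent sharp-wave
#' ripples during SW, and a unilateral-lesion mode with shortened REM_P
#' episodes and all dominance on the intact side.
#'
#' @param duration_s night duration (s).
#' @param rate_hz sampling rate (samples/s).
#' @param noise_rms_uv RMS of the pink (1/f) noise floor, microvolts.
#' @param sleep_cycle_s length-2 range of full sleep-cycle durations (s).
#' @param remp_nosw_mean_s,remp_nosw_sd_s REM_P episode duration law for
#'   episodes with no dominance switch (s).
#' @param remp_onesw_mean_s,remp_onesw_sd_s duration law for episodes with
#'   one (or two) switches (s).
#' @param p_switch probability that an episode contains exactly one
#'   dominance switch; a residual 0.02 produces two switches.
#' @param unsettled_s unsettled (no-dominance) time around each switch (s).
#' @param sn_iei_median_ms,sn_iei_mode_ms target median and mode of the
#'   per-channel SN IEI distribution (ms). The base log-normal is
#'   recalibrated at generation time so the emitted per-channel stream
#'   (leader phases plus follower copies thinned at \code{p_bilateral})
#'   matches the median.
#' @param sn_iei_min_ms refractory shift of the IEI law (ms): intervals
#'   are this shift plus a log-normal, so successive SNs on one channel
#'   cannot be closer than this (an SN plus its recovery occupies several
#'   tens of ms). Must be smaller than the mode.
#' @param sn_duration_median_ms median falling-phase duration of SNs (ms).
#' @param sn_amp_median_uv median falling-phase amplitude of SNs
#'   (microvolts).
#' @param follower_amp_factor amplitude scaling of the lagging (follower)
#'   SN relative to its leader, < 1.
#' @param interclaustral_lag_ms lag of follower behind leader SNs (ms).
#' @param lag_jitter_sd_ms Gaussian jitter of the pair lag (ms).
#' @param p_bilateral probability that a leader SN has a contralateral
#'   partner.
#' @param imc_ipsi_lead_ms,imc_contra_lead_ms lead of Imc deflections over
#'   the ipsi-/contralateral claustrum SN (ms); their difference must equal
#'   \code{interclaustral_lag_ms}.
#' @param swr_rate_hz sharp-wave-ripple rate per side during SW (events/s).
#' @param n_units spiking units per claustrum.
#' @param p_spike_range per-unit range for P(>= 1 spike per ipsilateral SN).
#' @param p_multispike_range per-unit range for P(> 1 spike per SN).
#' @param spike_jitter_sd_ms spike-time jitter around the SN
#'   steepest-descent time (ms).
#' @param lesion_side \code{"none"}, \code{"left"} or \code{"right"}: side
#'   of a unilateral Imc lesion. Dominance is then fixed on the intact
#'   (contralateral) side and switches are suppressed.
#' @param lesioned_remp_mean_s mean REM_P episode duration in lesion mode (s).
#' @param lesioned_remp_sd_s sd of lesion-mode REM_P durations (s).
#' @param sn_amp_sdlog,sn_duration_sdlog log-normal spread of SN amplitudes
#'   and durations.
#' @param sn_recovery_factor time constant of the fast recovery phase,
#'   as a multiple of the falling-phase width; gives the sharp-down /
#'   slow-up morphology of real SNs.
#' @param sn_recovery_frac fraction of the falling-phase amplitude
#'   recovered on the fast timescale; the remainder relaxes with
#'   \code{baseline_tau_s}. Partial fast recovery keeps inter-event
#'   upstrokes shallow, as in AC-coupled extracellular recordings where
#'   dense event trains ride on a depressed baseline.
#' @param baseline_tau_s slow baseline relaxation time constant (s).
#' @param swr_amp_median_uv median sharp-wave amplitude (microvolts).
#' @param imc_amp_median_uv median Imc deflection amplitude (microvolts).
#' @param background_rate_hz background firing rate of units away from SNs
#'   (spikes/s).
#' @param seed integer RNG seed.
#' @return a \code{GeneratorConfig}.
#' @seealso \code{\link{generateNight}}, \code{\link{generateSpikes}}
#' @export
generatorConfig <- function(duration_s = 3600,
                            rate_hz = 1000,
                            noise_rms_uv = 10,
                            sleep_cycle_s = c(90, 150),
                            remp_nosw_mean_s = 57,
                            remp_nosw_sd_s = 16.6,
                            remp_onesw_mean_s = 88.5,
                            remp_onesw_sd_s = 19.6,
                            p_switch = 103 / 162,
                            unsettled_s = 4,
                            sn_iei_median_ms = 60.2,
                            sn_iei_mode_ms = 40,
                            sn_iei_min_ms = 30,
                            sn_duration_median_ms = 10,
                            sn_amp_median_uv = 200,
                            follower_amp_factor = 0.8,
                            interclaustral_lag_ms = 20,
                            lag_jitter_sd_ms = 3,
                            p_bilateral = 0.9,
                            imc_ipsi_lead_ms = 30,
                            imc_contra_lead_ms = 50,
                            swr_rate_hz = 1.0,
                            n_units = 4,
                            p_spike_range = c(0.14, 0.43),
                            p_multispike_range = c(0.003, 0.03),
                            spike_jitter_sd_ms = 2,
                            lesion_side = "none",
                            lesioned_remp_mean_s = 33,
                            lesioned_remp_sd_s = 10,
                            sn_amp_sdlog = 0.15,
                            sn_recovery_factor = 7,
                            sn_recovery_frac = 0.3,
                            baseline_tau_s = 0.2,
                            sn_duration_sdlog = 0.2,
                            swr_amp_median_uv = 300,
                            imc_amp_median_uv = 150,
                            background_rate_hz = 0.05,
                            seed = 1L) {
  params <- as.list(environment())
  new("GeneratorConfig", params = params)
}

## IEI law: refractory-shifted log-normal, IEI = shift + LN(mu, sigma),
## with shift = sn_iei_min_ms. Solving median = shift + e^mu and
## mode = shift + e^(mu - sigma^2) gives sigma^2 = log((median - shift) /
## (mode - shift)); the sharp mode of the shifted law survives detection.
## calibrateIeiLaw adjusts mu so that the per-channel emitted stream
## (50/50 leader phases and follower copies thinned at p_bilateral) has
## the configured median. Uses the current RNG stream; deterministic
## given the generator seed.
ieiLaw <- function(medianMs, modeMs, shiftMs) {
  list(meanlog = log(medianMs - shiftMs),
       sdlog = sqrt(log((medianMs - shiftMs) / (modeMs - shiftMs))),
       shiftMs = shiftMs)
}

calibrateIeiLaw <- function(medianMs, modeMs, shiftMs, pBilateral,
                            n = 200000L, detectLoss = 0.03) {
  law <- ieiLaw(medianMs, modeMs, shiftMs)
  ## the configured median/mode are statistics of the *observed* (detected)
  ## per-channel stream: the follower channel is the leader train thinned
  ## at p_bilateral, and null filtering at the 2.5% level loses a few
  ## percent of true events; both thin the stream and stretch its
  ## intervals, so the base law is adjusted to the fixed point
  for (it in 1:3) {
    iei <- shiftMs + rlnorm(n, law$meanlog, law$sdlog)
    t0 <- cumsum(iei)
    lead <- t0[runif(n) < 1 - detectLoss]
    foll <- t0[runif(n) < pBilateral * (1 - detectLoss)]
    nh <- n %/% 2L
    mix <- c(diff(lead)[seq_len(min(nh, length(lead) - 1L))],
             diff(foll)[seq_len(min(nh, max(length(foll) - 1L, 0L)))])
    mixMed <- median(mix, na.rm = TRUE)
    law$meanlog <- law$meanlog +
      log(max(medianMs - shiftMs, 1e-6) / max(mixMed - shiftMs, 1e-6))
  }
  law
}

drawTrain <- function(from, to, law) {
  span <- to - from
  if (span <= 0) return(numeric(0))
  meanIei <- (law$shiftMs + exp(law$meanlog + law$sdlog^2 / 2)) / 1000
  nGuess <- ceiling(span / meanIei * 1.4) + 10L
  draw <- function(k) (law$shiftMs + rlnorm(k, law$meanlog, law$sdlog)) / 1000
  tt <- from + cumsum(draw(nGuess))
  while (length(tt) && tail(tt, 1L) < to)
    tt <- c(tt, tail(tt, 1L) + cumsum(draw(nGuess)))
  tt[tt < to]
}

truncNorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

otherSide <- function(s) ifelse(s == "left", "right", "left")

#' Generate a synthetic bilateral sleep night
#'
#' Produces a five-channel recording (claustrum-L/R, imc-L/R and a 1-Hz
#' square-wave sync channel) plus a full ground-truth registry. REM_P
#' segments carry bilateral SN trains driven by a dominance process: the
#' leading side emits SNs from the IEI law, the follower copies each event
#' after \code{interclaustral_lag_ms} (with jitter, amplitude scaled by
#' \code{follower_amp_factor}, with probability \code{p_bilateral});
#' unsettled segments around dominance switches carry independent trains on
#' both sides. SW segments carry per-side independent sharp-wave ripples.
#' Imc channels carry negative deflections leading the dominant-side
#' claustrum SNs by \code{imc_ipsi_lead_ms}. Identical seeds give identical
#' outputs.
#'
#' The SN waveform is a negative Gaussian trough of peak amplitude
#' \eqn{A / (1 - e^{-3/2})} and width \eqn{\sigma =
#' duration/\sqrt{3}}, chosen so that derivative triplet detection recovers
#' the configured falling-phase amplitude \eqn{A} and duration exactly
#' (the second-derivative peaks of a Gaussian trough sit at
#' \eqn{-\sigma\sqrt{3}} and 0 relative to the trough).
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return a list with elements \code{recording}
#'   (\code{\linkS4class{Recording}}) and \code{truth}
#'   (\code{\linkS4class{NightTruth}}).
#' @examples
#' night <- generateNight(generatorConfig(duration_s = 120, seed = 1))
#' night$recording
#' head(episodes(night$truth))
#' @export
generateNight <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  p <- config@params
  if (p$duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (p$rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  lesion <- p$lesion_side != "none"
  pSwitch <- p$p_switch
  if (lesion && pSwitch > 0) {
    warning("lesion_side is set: dominance switches are suppressed",
            call. = FALSE)
    pSwitch <- 0
  }
  set.seed(p$seed)

  law <- calibrateIeiLaw(p$sn_iei_median_ms, p$sn_iei_mode_ms,
                         p$sn_iei_min_ms, p$p_bilateral)
  ## base (uncalibrated) law for independent trains in unsettled segments
  baseLaw <- ieiLaw(p$sn_iei_median_ms, p$sn_iei_mode_ms, p$sn_iei_min_ms)

  ## ---- episode skeleton: SW then REM_P per cycle, tiling [0, duration) ----
  epState <- character(0); epStart <- numeric(0); epEnd <- numeric(0)
  epSwitches <- integer(0)
  t <- 0
  pTwo <- min(0.02, max(0, 1 - pSwitch))
  while (t < p$duration_s) {
    u <- runif(1)
    nsw <- if (lesion) 0L else if (u < pTwo) 2L
           else if (u < pTwo + pSwitch) 1L else 0L
    if (lesion) {
      remp <- truncNorm(1, p$lesioned_remp_mean_s, p$lesioned_remp_sd_s,
                        15, p$sleep_cycle_s[2] - 16)
    } else if (nsw == 0L) {
      remp <- truncNorm(1, p$remp_nosw_mean_s, p$remp_nosw_sd_s,
                        20, p$sleep_cycle_s[2] - 16)
    } else {
      remp <- truncNorm(1, p$remp_onesw_mean_s, p$remp_onesw_sd_s,
                        20, p$sleep_cycle_s[2] - 16)
    }
    swLo <- max(15, p$sleep_cycle_s[1] - remp)
    swHi <- max(swLo + 0.1, p$sleep_cycle_s[2] - remp)
    sw <- runif(1, swLo, swHi)
    epState <- c(epState, "SW", "REM_P")
    epStart <- c(epStart, t, t + sw)
    epEnd <- c(epEnd, t + sw, t + sw + remp)
    epSwitches <- c(epSwitches, NA_integer_, nsw)
    t <- t + sw + remp
  }
  keep <- epStart < p$duration_s
  epState <- epState[keep]; epStart <- epStart[keep]
  epEnd <- pmin(epEnd[keep], p$duration_s)
  epSwitches <- epSwitches[keep]
  episodes <- data.frame(state = epState, start_s = epStart, end_s = epEnd,
                         n_switches = epSwitches, stringsAsFactors = FALSE)

  ## ---- dominance segments inside REM_P episodes ----
  domSide <- character(0); domStart <- numeric(0); domEnd <- numeric(0)
  bias <- 0
  intact <- if (lesion) otherSide(p$lesion_side) else NA_character_
  rempIdx <- which(episodes$state == "REM_P")
  for (i in rempIdx) {
    a <- episodes$start_s[i]; b <- episodes$end_s[i]
    len <- b - a
    bias <- 0.9 * bias + rnorm(1, 0, 0.35)
    startSide <- if (lesion) intact
                 else if (runif(1) < plogis(2.5 * bias)) "left" else "right"
    nsw <- episodes$n_switches[i]
    fr <- switch(as.character(nsw),
                 "0" = numeric(0),
                 "1" = runif(1, 0.35, 0.65),
                 "2" = c(runif(1, 0.28, 0.45), runif(1, 0.55, 0.72)))
    swTimes <- a + fr * len
    half <- p$unsettled_s / 2
    bounds <- c(a, as.vector(rbind(pmax(swTimes - half, a),
                                   pmin(swTimes + half, b))), b)
    ## sides alternates settled/unsettled: s0, u, s1, u, s2 ...
    sides <- startSide
    cur <- startSide
    if (nsw > 0) for (k in seq_len(nsw)) {
      cur <- otherSide(cur)
      sides <- c(sides, "unsettled", cur)
    }
    segS <- bounds[-length(bounds)]
    segE <- bounds[-1L]
    ok <- segE > segS + 1e-9
    domSide <- c(domSide, sides[ok])
    domStart <- c(domStart, segS[ok])
    domEnd <- c(domEnd, segE[ok])
  }
  dominance <- data.frame(side = domSide, start_s = domStart,
                          end_s = domEnd, stringsAsFactors = FALSE)

  ## ---- SN trains ----
  chL <- "claustrum-L"; chR <- "claustrum-R"
  evChannel <- character(0); evT <- numeric(0); evAmp <- numeric(0)
  evDur <- numeric(0); evRole <- character(0); evPair <- integer(0)
  prChannelLead <- character(0)
  prTL <- numeric(0); prTR <- numeric(0)
  prAmpL <- numeric(0); prAmpR <- numeric(0)
  pairId <- 0L
  lagS <- p$interclaustral_lag_ms / 1000
  for (k in seq_len(nrow(dominance))) {
    a <- dominance$start_s[k]; b <- dominance$end_s[k]
    side <- dominance$side[k]
    if (side == "unsettled") {
      for (s in c("left", "right")) {
        tt <- drawTrain(a, b, baseLaw)
        n <- length(tt)
        if (!n) next
        evChannel <- c(evChannel, rep(if (s == "left") chL else chR, n))
        evT <- c(evT, tt)
        evAmp <- c(evAmp, rlnorm(n, log(p$sn_amp_median_uv), p$sn_amp_sdlog))
        evDur <- c(evDur, rlnorm(n, log(p$sn_duration_median_ms),
                                 p$sn_duration_sdlog))
        evRole <- c(evRole, rep("solo", n))
        evPair <- c(evPair, rep(NA_integer_, n))
      }
    } else {
      tt <- drawTrain(a, b, law)
      n <- length(tt)
      if (!n) next
      amp <- rlnorm(n, log(p$sn_amp_median_uv), p$sn_amp_sdlog)
      dur <- rlnorm(n, log(p$sn_duration_median_ms), p$sn_duration_sdlog)
      lead <- if (side == "left") chL else chR
      foll <- if (side == "left") chR else chL
      hasF <- runif(n) < p$p_bilateral
      ids <- ifelse(hasF, pairId + cumsum(hasF), NA_integer_)
      pairId <- pairId + sum(hasF)
      evChannel <- c(evChannel, rep(lead, n))
      evT <- c(evT, tt)
      evAmp <- c(evAmp, amp)
      evDur <- c(evDur, dur)
      evRole <- c(evRole, rep("leader", n))
      evPair <- c(evPair, ids)
      if (any(hasF)) {
        tf <- tt[hasF] + lagS + rnorm(sum(hasF), 0, p$lag_jitter_sd_ms / 1000)
        af <- amp[hasF] * p$follower_amp_factor
        evChannel <- c(evChannel, rep(foll, sum(hasF)))
        evT <- c(evT, tf)
        evAmp <- c(evAmp, af)
        evDur <- c(evDur, dur[hasF])
        evRole <- c(evRole, rep("follower", sum(hasF)))
        evPair <- c(evPair, ids[hasF])
        if (side == "left") {
          prTL <- c(prTL, tt[hasF]); prTR <- c(prTR, tf)
          prAmpL <- c(prAmpL, amp[hasF]); prAmpR <- c(prAmpR, af)
        } else {
          prTL <- c(prTL, tf); prTR <- c(prTR, tt[hasF])
          prAmpL <- c(prAmpL, af); prAmpR <- c(prAmpR, amp[hasF])
        }
        prChannelLead <- c(prChannelLead, rep(side, sum(hasF)))
      }
    }
  }
  sigmaS <- evDur / sqrt(3) / 1000
  events <- data.frame(channel = evChannel, t_s = evT,
                       t_steep_s = evT - sigmaS, amplitude_uv = evAmp,
                       duration_ms = evDur, role = evRole,
                       pair_id = evPair, stringsAsFactors = FALSE)
  events <- events[order(events$channel, events$t_s), , drop = FALSE]
  rownames(events) <- NULL
  pairs <- data.frame(pair_id = seq_along(prTL), t_left_s = prTL,
                      t_right_s = prTR,
                      lag_ms = (prTR - prTL) * 1000,
                      amp_left_uv = prAmpL, amp_right_uv = prAmpR,
                      leader = prChannelLead, stringsAsFactors = FALSE)

  ## ---- sharp-wave ripples during SW ----
  swrChannel <- character(0); swrT <- numeric(0); swrAmp <- numeric(0)
  refrac <- 0.25
  rateEff <- 1 / max(1 / max(p$swr_rate_hz, 1e-6) - refrac, 0.05)
  for (i in which(episodes$state == "SW")) {
    a <- episodes$start_s[i]; b <- episodes$end_s[i]
    for (ch in c(chL, chR)) {
      tt <- numeric(0); tcur <- a + runif(1, 0, 1 / p$swr_rate_hz)
      while (tcur < b) {
        tt <- c(tt, tcur)
        tcur <- tcur + refrac + rexp(1, rateEff)
      }
      if (length(tt)) {
        swrChannel <- c(swrChannel, rep(ch, length(tt)))
        swrT <- c(swrT, tt)
        swrAmp <- c(swrAmp, rlnorm(length(tt), log(p$swr_amp_median_uv), 0.3))
      }
    }
  }

  ## ---- Imc deflections: tied to dominant-side (leader/solo) SNs ----
  drive <- events[events$role %in% c("leader", "solo"), , drop = FALSE]
  imcCh <- ifelse(drive$channel == chL, "imc-L", "imc-R")
  if (lesion) {
    lesionCh <- if (p$lesion_side == "left") "imc-L" else "imc-R"
    keepImc <- imcCh != lesionCh
    drive <- drive[keepImc, , drop = FALSE]
    imcCh <- imcCh[keepImc]
  }
  imc <- data.frame(channel = imcCh,
                    t_s = drive$t_s - p$imc_ipsi_lead_ms / 1000,
                    amplitude_uv = rlnorm(nrow(drive),
                                          log(p$imc_amp_median_uv), 0.3),
                    duration_ms = drive$duration_ms,
                    stringsAsFactors = FALSE)

  ## ---- signal assembly ----
  n <- round(p$duration_s * p$rate_hz)
  rate <- p$rate_hz
  ## SN/Imc deposition: sharp Gaussian fall (sigma_f = duration/sqrt(3),
  ## so the falling-phase amplitude A corresponds to template peak
  ## A/(1-e^-1.5)); recovery is double-exponential -- a fraction
  ## sn_recovery_frac returns with the fast time constant
  ## sn_recovery_factor * sigma_f, the rest with baseline_tau_s. The
  ## recoveries are superposed with two recursive filters (O(n)).
  tauFastS <- p$sn_recovery_factor *
    (p$sn_duration_median_ms / sqrt(3) / 1000)
  addEvents <- function(v, tc, ampDetected, durMs) {
    sigF <- durMs / sqrt(3) / 1000
    peak <- ampDetected / (1 - exp(-1.5))
    impFast <- numeric(n); impSlow <- numeric(n)
    for (j in seq_along(tc)) {
      i0 <- round(tc[j] * rate) + 1L
      half <- ceiling(4 * sigF[j] * rate)
      idx <- max(1L, i0 - half):min(n, i0)
      if (length(idx)) {
        trel <- (idx - 1L) / rate - tc[j]
        v[idx] <- v[idx] - peak[j] * exp(-trel^2 / (2 * sigF[j]^2))
      }
      i1 <- i0 + 1L
      if (i1 >= 1L && i1 <= n) {
        impFast[i1] <- impFast[i1] - peak[j] * p$sn_recovery_frac
        impSlow[i1] <- impSlow[i1] - peak[j] * (1 - p$sn_recovery_frac)
      }
    }
    dFast <- exp(-1 / (tauFastS * rate))
    dSlow <- exp(-1 / (p$baseline_tau_s * rate))
    v <- v + as.numeric(stats::filter(impFast, dFast, "recursive")) +
      as.numeric(stats::filter(impSlow, dSlow, "recursive"))
    v
  }
  addSwr <- function(v, tc, amp) {
    for (j in seq_along(tc)) {
      i0 <- round(tc[j] * rate) + 1L
      idx <- max(1L, i0 - ceiling(0.08 * rate)):
        min(n, i0 + ceiling(0.25 * rate))
      if (!length(idx)) next
      trel <- (idx - 1L) / rate - tc[j]
      env <- exp(-trel^2 / (2 * 0.015^2))
      ## sharp wave with a slow, shallow rebound and a modest ripple; the
      ## return to baseline must stay gentle so sign-flip noise estimation
      ## is not polluted by steep upstrokes
      v[idx] <- v[idx] + amp[j] *
        (-env + 0.25 * exp(-(trel - 0.08)^2 / (2 * 0.05^2)) +
          0.12 * sin(2 * pi * 28 * trel) * env)
    }
    v
  }
  chans <- list()
  for (ch in c(chL, chR)) {
    v <- pinkNoise(n, p$noise_rms_uv)
    sel <- events$channel == ch
    v <- addEvents(v, events$t_s[sel], events$amplitude_uv[sel],
                   events$duration_ms[sel])
    sel <- swrChannel == ch
    v <- addSwr(v, swrT[sel], swrAmp[sel])
    chans[[ch]] <- v
  }
  for (ch in c("imc-L", "imc-R")) {
    v <- pinkNoise(n, p$noise_rms_uv)
    sel <- imc$channel == ch
    v <- addEvents(v, imc$t_s[sel], imc$amplitude_uv[sel],
                   imc$duration_ms[sel])
    chans[[ch]] <- v
  }
  tGrid <- (seq_len(n) - 1L) / rate
  chans[["sync"]] <- ifelse(tGrid %% 1 < 0.5, 500, 0)
  samples <- do.call(cbind, chans)
  colnames(samples) <- names(chans)
  rec <- new("Recording", samples = samples, rateHz = rate,
             channelRoles = names(chans), t0 = 0)

  truth <- new("NightTruth", episodes = episodes, dominance = dominance,
               events = events, pairs = pairs,
               imc = imc[, c("channel", "t_s")],
               spikes = data.frame(unit = character(0), side = character(0),
                                   t_s = numeric(0)),
               config = config)
  truth@spikes <- generateSpikes(truth, config)
  list(recording = rec, truth = truth)
}

#' Generate per-unit spike trains locked to SN events
#'
#' Each spiking unit belongs to one claustrum and fires, for every
#' ipsilateral SN, at least one spike with its unit-specific probability
#' (drawn uniformly from \code{p_spike_range}), jittered around the SN
#' steepest-descent time; a second spike follows with probability drawn
#' from \code{p_multispike_range}. A sparse Poisson background
#' (\code{background_rate_hz}) is added across the whole night.
#'
#' @param truth a \code{\linkS4class{NightTruth}} (SN times are read from
#'   its event registry).
#' @param config the \code{\link{generatorConfig}} used (supplies unit
#'   counts, probabilities, jitter and the seed; spike generation uses a
#'   seed offset so it is reproducible independently of the night signal).
#' @return data.frame(unit, side, t_s), time-sorted within unit.
#' @export
generateSpikes <- function(truth, config) {
  stopifnot(is(truth, "NightTruth"), is(config, "GeneratorConfig"))
  p <- config@params
  set.seed((p$seed + 1000003L) %% .Machine$integer.max)
  ev <- truth@events
  out <- list()
  for (side in c("L", "R")) {
    ch <- paste0("claustrum-", side)
    steep <- ev$t_steep_s[ev$channel == ch]
    nu <- max(0L, as.integer(p$n_units))
    for (u in seq_len(nu)) {
      p1 <- runif(1, p$p_spike_range[1], p$p_spike_range[2])
      p2 <- runif(1, p$p_multispike_range[1], p$p_multispike_range[2])
      tt <- numeric(0)
      if (length(steep)) {
        fire <- runif(length(steep)) < p1
        tt <- steep[fire] + rnorm(sum(fire), 0, p$spike_jitter_sd_ms / 1000)
        burst <- runif(sum(fire)) < (p2 / max(p1, 1e-12))
        tt <- c(tt, tt[burst] + 0.003 +
                  abs(rnorm(sum(burst), 0, p$spike_jitter_sd_ms / 1000)))
      }
      if (p$background_rate_hz > 0 && p$duration_s > 0) {
        nb <- rpois(1, p$background_rate_hz * p$duration_s)
        tt <- c(tt, runif(nb, 0, p$duration_s))
      }
      tt <- sort(tt[tt >= 0 & tt < p$duration_s])
      if (length(tt))
        out[[paste0(side, u)]] <- data.frame(
          unit = paste0(side, u), side = side, t_s = tt,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(unit = character(0), side = character(0),
                      t_s = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
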