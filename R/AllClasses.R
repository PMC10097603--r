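#' Multichannel extracellular recording
#'
#' Container for a multichannel voltage time series on a uniform clock.
#' Samples are stored in microvolts, one column per channel; channel roles
#' (\code{"claustrum-L"}, \code{"claustrum-R"}, \code{"imc-L"},
#' \code{"imc-R"}, \code{"sync"}) are carried as column names.
#'
#' @slot samples numeric matrix, one column per channel, in microvolts.
#' @slot rateHz sampling rate in samples per second.
#' @slot channelRoles character vector of channel roles (same order as
#'   columns).
#' @slot t0 time of the first sample, in seconds.
#' @exportClass Recording
setClass("Recording",
  representation(samples = "matrix", rateHz = "numeric",
                 channelRoles = "character", t0 = "numeric"),
  prototype(t0 = 0))

setValidity("Recording", function(object) {
  msg <- character(0)
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (ncol(object@samples) != length(object@channelRoles))
    msg <- c(msg, "one role per channel column is required")
  if (anyDuplicated(object@channelRoles))
    msg <- c(msg, "channel roles must be unique")
  if (length(msg)) msg else TRUE
})

#' Conditioned (filtered, derived) single-channel signal
#'
#' A low-pass-filtered single channel at the working rate, together with
#' its first and second derivatives by central differences. The filter is
#' applied forward-backward (zero phase) so that event times are not
#' shifted.
#'
#' @slot v filtered voltage (z-units when z-scored, else microvolts).
#' @slot c first derivative of \code{v} per millisecond.
#' @slot c2 second derivative of \code{v} per millisecond squared.
#' @slot rateHz working sampling rate (samples/s).
#' @slot role channel role the signal came from.
#' @slot t0 time of the first sample (s).
#' @slot filterDesc list describing the conditioning (cutoff, order,
#'   z-scoring).
#' @exportClass ConditionedSignal
setClass("ConditionedSignal",
  representation(v = "numeric", c = "numeric", c2 = "numeric",
                 rateHz = "numeric", role = "character", t0 = "numeric",
                 filterDesc = "list"),
  prototype(t0 = 0, filterDesc = list()))

setValidity("ConditionedSignal", function(object) {
  if (length(object@v) != length(object@c) ||
      length(object@v) != length(object@c2))
    return("v, c and c2 must have equal length")
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    return("rateHz must be a single positive number")
  TRUE
})

#' Sliding band-power trace
#'
#' Mean squared amplitude of a band-passed signal in a sliding window,
#' reported at window centers.
#'
#' @slot t window-center times (s), strictly increasing.
#' @slot p band power (signal units squared), non-negative.
#' @slot bandHz numeric length-2, band edges in Hz.
#' @slot windowS window length (s).
#' @slot stepS step between window centers (s).
#' @exportClass BandPowerTrace
setClass("BandPowerTrace",
  representation(t = "numeric", p = "numeric", bandHz = "numeric",
                 windowS = "numeric", stepS = "numeric"))

setValidity("BandPowerTrace", function(object) {
  if (length(object@t) != length(object@p))
    return("t and p must have equal length")
  if (any(object@p < 0)) return("band power must be non-negative")
  if (length(object@t) > 1L && any(diff(object@t) <= 0))
    return("t must be strictly increasing")
  TRUE
})

#' Sign-flip noise model for SN filtering
#'
#' Joint empirical sample of (amplitude, duration) of triplet detections on
#' the sign-inverted signal, where true sharp negative events cannot exist.
#' Provides the null distribution against which SN candidates are filtered.
#'
#' @slot amplitude noise-event amplitudes (signal units).
#' @slot duration noise-event durations (ms).
#' @slot nNoiseEvents number of noise events.
#' @slot degenerate TRUE when no noise events were found (thresholds fall
#'   back to global minima).
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(amplitude = "numeric", duration = "numeric",
                 nNoiseEvents = "integer", degenerate = "logical"),
  prototype(degenerate = FALSE))

setValidity("NoiseModel", function(object) {
  if (length(object@amplitude) != length(object@duration))
    return("amplitude and duration samples must have equal length")
  if (object@nNoiseEvents != length(object@amplitude))
    return("nNoiseEvents must match the sample size")
  TRUE
})

#' Sliding lagged cross-correlation matrix
#'
#' Cross-correlation of two first-derivative signals per (window, lag),
#' windows of \code{windowS} seconds scrolled in \code{stepS} steps, lags on
#' a symmetric millisecond grid, normalized to the 99.9th percentile of the
#' matrix.
#'
#' @slot t window-center times (s).
#' @slot lags lag grid (ms), symmetric about 0; positive lag means channel
#'   0 leads.
#' @slot m matrix of correlation values, \code{length(t)} rows by
#'   \code{length(lags)} columns.
#' @slot normValue the normalizer (pre-normalization 99.9th percentile).
#' @slot windowS,stepS window and step (s).
#' @exportClass LaggedXCorr
setClass("LaggedXCorr",
  representation(t = "numeric", lags = "numeric", m = "matrix",
                 normValue = "numeric", windowS = "numeric",
                 stepS = "numeric"))

setValidity("LaggedXCorr", function(object) {
  if (nrow(object@m) != length(object@t) ||
      ncol(object@m) != length(object@lags))
    return("m must be length(t) x length(lags)")
  if (max(abs(object@lags + rev(object@lags))) > 1e-9)
    return("lag grid must be symmetric about 0")
  TRUE
})

#' Instantaneous-leadership score traces and dominance states
#'
#' The two leadership scores s+ and s- (channel 0 leading and channel 1
#' leading, at the modal inter-channel lag), on a uniform time grid, with
#' the dominance state labels once segmented.
#'
#' @slot t trace times (s).
#' @slot sPlus score for channel 0 (left) leading, log10 units.
#' @slot sMinus score for channel 1 (right) leading, log10 units.
#' @slot state character: "SW", "left", "right" or "unsettled" ("" before
#'   segmentation).
#' @slot params list: window (s), lag (ms), floorEps, thresholds.
#' @exportClass LeadershipTrace
setClass("LeadershipTrace",
  representation(t = "numeric", sPlus = "numeric", sMinus = "numeric",
                 state = "character", params = "list"),
  prototype(state = character(0), params = list()))

setValidity("LeadershipTrace", function(object) {
  if (length(object@t) != length(object@sPlus) ||
      length(object@t) != length(object@sMinus))
    return("t, sPlus and sMinus must have equal length")
  if (length(object@state) &&
      length(object@state) != length(object@t))
    return("state must be empty or match t")
  TRUE
})

#' Synthetic-night generator configuration
#'
#' Validated parameter set for \code{\link{generateNight}}. Parameters are
#' stored in a named list; access with \code{$}. See
#' \code{\link{generatorConfig}} for the fields, units and defaults.
#'
#' @slot params named list of generator parameters.
#' @exportClass GeneratorConfig
setClass("GeneratorConfig", representation(params = "list"))

#' @export
setMethod("$", "GeneratorConfig", function(x, name) x@params[[name]])

setValidity("GeneratorConfig", function(object) {
  p <- object@params
  msg <- character(0)
  nonneg <- c("duration_s", "rate_hz", "noise_rms_uv", "remp_nosw_mean_s",
              "remp_nosw_sd_s", "remp_onesw_mean_s", "remp_onesw_sd_s",
              "p_switch", "unsettled_s", "sn_iei_median_ms",
              "sn_iei_mode_ms", "sn_duration_median_ms", "sn_amp_median_uv",
              "follower_amp_factor", "interclaustral_lag_ms",
              "lag_jitter_sd_ms", "p_bilateral", "imc_ipsi_lead_ms",
              "imc_contra_lead_ms", "swr_rate_hz", "n_units",
              "spike_jitter_sd_ms", "lesioned_remp_mean_s")
  for (f in nonneg)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] < 0)
      msg <- c(msg, sprintf("%s must be a non-negative scalar", f))
  for (f in c("p_switch", "p_bilateral"))
    if (is.numeric(p[[f]]) && p[[f]] > 1)
      msg <- c(msg, sprintf("%s must be <= 1", f))
  if (!length(msg)) {
    if (p$sn_iei_mode_ms >= p$sn_iei_median_ms)
      msg <- c(msg, "sn_iei_mode_ms must be < sn_iei_median_ms (skewed-right IEI)")
    if (!is.null(p$sn_iei_min_ms) && p$sn_iei_min_ms >= p$sn_iei_mode_ms)
      msg <- c(msg, "sn_iei_min_ms (refractory shift) must be < sn_iei_mode_ms")
    if (abs((p$imc_contra_lead_ms - p$imc_ipsi_lead_ms) -
            p$interclaustral_lag_ms) > 1e-9)
      msg <- c(msg,
        "imc_contra_lead_ms - imc_ipsi_lead_ms must equal interclaustral_lag_ms")
    if (length(p$sleep_cycle_s) != 2L || any(p$sleep_cycle_s <= 0) ||
        p$sleep_cycle_s[1] > p$sleep_cycle_s[2])
      msg <- c(msg, "sleep_cycle_s must be an increasing positive range")
    if (!p$lesion_side %in% c("none", "left", "right"))
      msg <- c(msg, "lesion_side must be one of none/left/right")
    rng <- function(r) length(r) == 2L && all(r >= 0) && all(r <= 1) &&
      r[1] <= r[2]
    if (!rng(p$p_spike_range)) msg <- c(msg, "invalid p_spike_range")
    if (!rng(p$p_multispike_range)) msg <- c(msg, "invalid p_multispike_range")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth for a synthetic night
#'
#' Generator-side truth registry used for recovery tests: sleep episodes,
#' dominance segments, per-side true SN events, the bilateral pair
#' registry, isthmic (Imc) deflection times, and per-unit spike times.
#'
#' @slot episodes data.frame(state, start_s, end_s) tiling [0, duration).
#' @slot dominance data.frame(side, start_s, end_s) inside REM_P episodes.
#' @slot events data.frame of true SN events: channel, t_s (template
#'   center), t_steep_s, amplitude_uv (falling-phase amplitude),
#'   duration_ms, role ("leader"/"follower"/"solo"), pair_id.
#' @slot pairs data.frame of bilateral pairs: pair_id, t_left_s, t_right_s,
#'   lag_ms (right minus left; positive = left leads), amp_left_uv,
#'   amp_right_uv, leader.
#' @slot imc data.frame(channel, t_s) of Imc deflection centers.
#' @slot spikes data.frame(unit, side, t_s) of spike times.
#' @slot config the \code{GeneratorConfig} used.
#' @exportClass NightTruth
setClass("NightTruth",
  representation(episodes = "data.frame", dominance = "data.frame",
                 events = "data.frame", pairs = "data.frame",
                 imc = "data.frame", spikes = "data.frame",
                 config = "GeneratorConfig"))

setValidity("NightTruth", function(object) {
  ep <- object@episodes
  msg <- character(0)
  if (nrow(ep)) {
    if (any(abs(ep$start_s[-1L] - ep$end_s[-nrow(ep)]) > 1e-9))
      msg <- c(msg, "episodes must tile the night without gaps or overlap")
    if (!all(ep$state %in% c("SW", "REM_P")))
      msg <- c(msg, "episode states must be SW or REM_P")
  }
  dm <- object@dominance
  if (nrow(dm) && !all(dm$side %in% c("left", "right", "unsettled")))
    msg <- c(msg, "dominance sides must be left/right/unsettled")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(object@samples), nrow(object@samples), object@rateHz,
              nrow(object@samples) / object@rateHz))
  cat("  roles:", paste(object@channelRoles, collapse = ", "), "\n")
})

setMethod("show", "ConditionedSignal", function(object) {
  cat(sprintf(
    "ConditionedSignal [%s]: %d samples @ %g Hz, low-pass %s Hz%s\n",
    object@role, length(object@v), object@rateHz,
    format(object@filterDesc$lpHz %||% NA),
    if (isTRUE(object@filterDesc$zscore)) ", z-scored" else ""))
})

setMethod("show", "BandPowerTrace", function(object) {
  cat(sprintf(
    "BandPowerTrace: band [%g, %g] Hz, %d windows (%g s window, %g s step)\n",
    object@bandHz[1], object@bandHz[2], length(object@t), object@windowS,
    object@stepS))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: %d sign-flip noise events%s\n",
              object@nNoiseEvents,
              if (object@degenerate) " (degenerate)" else ""))
})

setMethod("show", "LaggedXCorr", function(object) {
  cat(sprintf(
    "LaggedXCorr: %d windows x %d lags (%g s window, %g s step), norm %.4g\n",
    length(object@t), length(object@lags), object@windowS, object@stepS,
    object@normValue))
})

setMethod("show", "LeadershipTrace", function(object) {
  cat(sprintf("LeadershipTrace: %d points, lag %g ms, window %g s\n",
              length(object@t), object@params$lagMs %||% NA,
              object@params$windowS %||% NA))
  if (length(object@state))
    print(table(object@state))
})

setMethod("show", "GeneratorConfig", function(object) {
  p <- object@params
  cat(sprintf(
    "GeneratorConfig: %.0f s @ %g Hz, lesion: %s, seed: %s\n",
    p$duration_s, p$rate_hz, p$lesion_side, format(p$seed)))
})

setMethod("show", "NightTruth", function(object) {
  cat(sprintf(
    "NightTruth: %d episodes, %d dominance segments, %d SNs, %d pairs\n",
    nrow(object@episodes), nrow(object@dominance), nrow(object@events),
    nrow(object@pairs)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
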