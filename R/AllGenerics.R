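#' @rdname Recording-class
#' @param object,x a \code{Recording} (or other claustra object).
#' @export
setGeneric("rateHz", function(x) standardGeneric("rateHz"))

#' @rdname Recording-class
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname Recording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname Recording-class
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))

#' Extract one channel's samples
#' @param x a \code{Recording}.
#' @param role channel role, e.g. \code{"claustrum-L"}.
#' @return numeric vector of samples (microvolts).
#' @export
setGeneric("getChannel", function(x, role) standardGeneric("getChannel"))

#' Sample/trace times
#' @param x a claustra signal object.
#' @return numeric vector of times in seconds.
#' @export
setGeneric("timesS", function(x) standardGeneric("timesS"))

#' @rdname NightTruth-class
#' @export
setGeneric("episodes", function(x) standardGeneric("episodes"))

#' @rdname NightTruth-class
#' @export
setGeneric("dominanceSegments", function(x) standardGeneric("dominanceSegments"))

#' @rdname NightTruth-class
#' @export
setGeneric("trueEvents", function(x) standardGeneric("trueEvents"))

#' @rdname NightTruth-class
#' @export
setGeneric("truePairs", function(x) standardGeneric("truePairs"))

#' @rdname NightTruth-class
#' @export
setGeneric("trueSpikes", function(x) standardGeneric("trueSpikes"))

setMethod("rateHz", "Recording", function(x) x@rateHz)
setMethod("rateHz", "ConditionedSignal", function(x) x@rateHz)
setMethod("channelRoles", "Recording", function(x) x@channelRoles)
setMethod("nSamples", "Recording", function(x) nrow(x@samples))
setMethod("nSamples", "ConditionedSignal", function(x) length(x@v))
setMethod("durationS", "Recording", function(x) nrow(x@samples) / x@rateHz)
setMethod("durationS", "ConditionedSignal",
          function(x) length(x@v) / x@rateHz)

setMethod("getChannel", "Recording", function(x, role) {
  j <- match(role, x@channelRoles)
  if (is.na(j))
    stop(sprintf("channel role '%s' not present (have: %s)", role,
                 paste(x@channelRoles, collapse = ", ")), call. = FALSE)
  x@samples[, j]
})

setMethod("timesS", "Recording", function(x)
  x@t0 + (seq_len(nrow(x@samples)) - 1L) / x@rateHz)
setMethod("timesS", "ConditionedSignal", function(x)
  x@t0 + (seq_along(x@v) - 1L) / x@rateHz)
setMethod("timesS", "BandPowerTrace", function(x) x@t)
setMethod("timesS", "LeadershipTrace", function(x) x@t)
setMethod("timesS", "LaggedXCorr", function(x) x@t)

setMethod("episodes", "NightTruth", function(x) x@episodes)
setMethod("dominanceSegments", "NightTruth", function(x) x@dominance)
setMethod("trueEvents", "NightTruth", function(x) x@events)
setMethod("truePairs", "NightTruth", function(x) x@pairs)
setMethod("trueSpikes", "NightTruth", function(x) x@spikes)
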