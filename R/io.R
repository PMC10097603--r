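#' Write a recording as flat binary int16 plus JSON sidecar
#'
#' Samples are written channel-interleaved as little-endian int16 with a
#' single microvolt-per-bit scale chosen to cover the signal range; the
#' sidecar (\code{<name>.json}) records rate, channel roles, scale and time
#' origin.
#'
#' @param rec a \code{\linkS4class{Recording}}.
#' @param path output path without extension; writes \code{<path>.bin} and
#'   \code{<path>.json}.
#' @return invisibly, the sidecar list.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  rng <- max(abs(range(rec@samples)), 1e-9)
  uvPerBit <- rng / 32000
  q <- t(round(rec@samples / uvPerBit))   # channel-interleaved
  storage.mode(q) <- "integer"
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(q), con, size = 2L, endian = "little")
  sidecar <- list(rate_hz = rec@rateHz, n_channels = ncol(rec@samples),
                  channel_roles = rec@channelRoles,
                  uv_per_bit = uvPerBit, t0 = rec@t0,
                  n_samples = nrow(rec@samples))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(sidecar)
}

#' Read a recording written by \code{\link{writeRecording}}
#'
#' Applies the microvolt scaling on read, so no raw integers leak
#' downstream.
#'
#' @param path path without extension (expects \code{<path>.bin} and
#'   \code{<path>.json}).
#' @return a \code{\linkS4class{Recording}}.
#' @export
readRecording <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "integer", size = 2L, signed = TRUE,
                 n = side$n_samples * side$n_channels, endian = "little")
  m <- matrix(raw * side$uv_per_bit, ncol = side$n_channels, byrow = TRUE)
  colnames(m) <- side$channel_roles
  new("Recording", samples = m, rateHz = side$rate_hz,
      channelRoles = side$channel_roles, t0 = side$t0)
}

#' Write ground-truth tables as CSV
#'
#' Emits \code{episodes.csv}, \code{dominance.csv}, \code{sn_truth.csv},
#' \code{pairs_truth.csv} and \code{spikes.csv} into \code{dir}, times in
#' seconds at 6-decimal precision.
#'
#' @param truth a \code{\linkS4class{NightTruth}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
writeTruth <- function(truth, dir) {
  stopifnot(is(truth, "NightTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  round6 <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = 6)
    df
  }
  files <- c(episodes = "episodes.csv", dominance = "dominance.csv",
             events = "sn_truth.csv", pairs = "pairs_truth.csv",
             spikes = "spikes.csv")
  tabs <- list(episodes = truth@episodes, dominance = truth@dominance,
               events = truth@events, pairs = truth@pairs,
               spikes = truth@spikes)
  paths <- file.path(dir, files)
  for (i in seq_along(tabs))
    write.csv(round6(tabs[[i]]), paths[i], row.names = FALSE)
  invisible(paths)
}

#' Read ground-truth tables written by \code{\link{writeTruth}}
#' @param dir directory containing the CSV tables.
#' @param config optional \code{GeneratorConfig} to attach.
#' @return a \code{\linkS4class{NightTruth}}.
#' @export
readTruth <- function(dir, config = generatorConfig()) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  new("NightTruth", episodes = rd("episodes.csv"),
      dominance = rd("dominance.csv"), events = rd("sn_truth.csv"),
      pairs = rd("pairs_truth.csv"), imc = data.frame(
        channel = character(0), t_s = numeric(0)),
      spikes = rd("spikes.csv"), config = config)
}
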