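#' Build a full-run configuration
#'
#' Bundles the generator configuration, matching parameters and all
#' analysis percentiles/thresholds into one serializable object. Every run
#' writes the resolved configuration (and its hash) beside its outputs, so
#' a run is reproducible from its output directory alone.
#'
#' @param gen a \code{\link{generatorConfig}}.
#' @param match a \code{\link{matchParams}}.
#' @param alpha_detect SN null-probability level (default 0.025).
#' @param alpha_pair pair acceptance level (default 0.05).
#' @param beta_pct percentile for the sleep threshold, or \code{"auto"}
#'   (default) for \code{\link{betaThreshold2Means}}.
#' @param keep_quantile window filter for \code{\link{peakLagDistribution}}.
#' @param xcorr_norm_pct normalization percentile for
#'   \code{\link{laggedXcorr}}.
#' @param lag_ms leadership lag (ms).
#' @param min_dominance_s,min_episode_s defragmentation minima (s).
#' @param seed overrides the generator seed when not \code{NULL}.
#' @return a list of class \code{"RunConfig"}.
#' @export
runConfig <- function(gen = generatorConfig(), match = matchParams(),
                      alpha_detect = 0.025, alpha_pair = 0.05,
                      beta_pct = "auto", keep_quantile = 0.75,
                      xcorr_norm_pct = 99.9, lag_ms = 20,
                      min_dominance_s = 3, min_episode_s = 15,
                      seed = NULL) {
  if (!is.null(seed)) gen@params$seed <- seed
  cfg <- list(gen = gen@params, match = unclass(match),
              alpha_detect = alpha_detect, alpha_pair = alpha_pair,
              beta_pct = beta_pct, keep_quantile = keep_quantile,
              xcorr_norm_pct = xcorr_norm_pct, lag_ms = lag_ms,
              min_dominance_s = min_dominance_s,
              min_episode_s = min_episode_s)
  class(cfg) <- "RunConfig"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless for all configuration fields.
#'
#' @param config a \code{\link{runConfig}}.
#' @param path YAML file path.
#' @return \code{writeRunConfig}: invisibly, the path;
#'   \code{readRunConfig}: the \code{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  gen <- do.call(generatorConfig, raw$gen)
  match <- do.call(matchParams, raw$match)
  do.call(runConfig, c(list(gen = gen, match = match),
                       raw[setdiff(names(raw), c("gen", "match"))]))
}

writeStamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", hash), con)
  write.csv(df, con, row.names = FALSE)
}

readStamped <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full pipeline on one synthetic night
#'
#' Executes simulate, preprocess, detect, match, leadership, segmentation
#' and statistics with one configuration and one seed, writing all
#' artifacts (binary recording + sidecar, ground-truth tables, event and
#' pair tables, leadership and dominance traces, episode table, night
#' summary JSON, resolved config + hash) into \code{outDir}. Rerunning
#' with the same configuration reproduces identical event tables.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory (created).
#' @return invisibly, a list with the main in-memory results
#'   (\code{events}, \code{pairs}, \code{episodes}, \code{stats},
#'   \code{lagDist}, \code{trace}, \code{paths}).
#' @export
runAll <- function(config, outDir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  gen <- do.call(generatorConfig, config$gen)
  stage <- "simulate"
  res <- tryCatch({
    night <- generateNight(gen)
    writeRecording(night$recording, file.path(outDir, "recording"))
    writeTruth(night$truth, file.path(outDir, "truth"))
    cfgPath <- file.path(outDir, "run_config.yaml")
    writeRunConfig(config, cfgPath)
    hash <- unname(tools::md5sum(cfgPath))

    stage <- "preprocess"
    rec <- readRecording(file.path(outDir, "recording"))
    sigL <- conditionSignal(rec, "claustrum-L")
    sigR <- conditionSignal(rec, "claustrum-R")

    stage <- "detect"
    detL <- detectSN(sigL, alpha = config$alpha_detect,
                     chunkHours = config$match$chunk_hours)
    detR <- detectSN(sigR, alpha = config$alpha_detect,
                     chunkHours = config$match$chunk_hours)
    events <- rbind(detL$events, detR$events)
    writeStamped(events, file.path(outDir, "sn_events.csv"), hash)

    stage <- "match"
    match <- do.call(matchParams, config$match)
    pairs <- matchSN(detL, detR, sigL, sigR, params = match,
                     alpha = config$alpha_pair)
    writeStamped(pairs, file.path(outDir, "sn_pairs.csv"), hash)

    stage <- "leadership"
    xc <- laggedXcorr(sigL, sigR, lagWindowMs = match$lag_window_ms,
                      normPct = config$xcorr_norm_pct)
    lagDist <- peakLagDistribution(xc, keepQuantile = config$keep_quantile)
    trace <- leadershipScore(sigL, sigR, lagMs = config$lag_ms)

    stage <- "segment"
    beta <- bandPower(sigL)
    thr <- if (identical(config$beta_pct, "auto"))
      betaThreshold2Means(beta) else NULL
    episodeTable <- segmentSleep(beta,
      pct = if (is.null(thr)) config$beta_pct else 15,
      minDurS = config$min_episode_s, threshold = thr)
    episodeTable <- refineEpisodeBoundaries(episodeTable, sigL)
    thresholds <- calibrateDominanceThresholds(trace, episodeTable)
    trace <- segmentDominance(trace, thresholds, episodeTable,
                              minDurS = config$min_dominance_s)
    dom <- attr(trace, "segments")
    writeStamped(data.frame(t = trace@t, s_plus = trace@sPlus,
                            s_minus = trace@sMinus, state = trace@state),
                 file.path(outDir, "leadership.csv"), hash)
    writeStamped(dom, file.path(outDir, "dominance_segments.csv"), hash)
    writeStamped(episodeTable, file.path(outDir, "episodes.csv"), hash)

    stage <- "stats"
    st <- episodeStats(episodeTable, dom)
    ampLag <- tryCatch(
      amplitudeLagStats(pairs[pairs$accepted, , drop = FALSE]),
      error = function(e) NULL)
    summary <- list(
      config_hash = hash,
      n_sn_events = nrow(events),
      n_pairs_accepted = sum(pairs$accepted),
      lag_modes_ms = lagDist$modes_ms,
      lag_bimodal = lagDist$bimodal,
      median_abs_lag_ms = lagDist$median_abs_lag_ms,
      episode_summary = st$summary[setdiff(names(st$summary),
                                           "left_fraction_per_episode")],
      amp_lag = if (is.null(ampLag)) NULL else list(
        mean_delta_left_leads = ampLag$mean_delta_left_leads,
        mean_delta_right_leads = ampLag$mean_delta_right_leads,
        rank_sum_p = ampLag$test$p.value),
      dominance_thresholds = as.list(thresholds),
      beta_threshold = attr(episodeTable, "threshold"))
    jsonlite::write_json(summary, file.path(outDir, "night_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    list(events = events, pairs = pairs, episodes = episodeTable,
         stats = st, lagDist = lagDist, trace = trace,
         paths = list(dir = outDir, hash = hash))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed (out=%s): %s", stage, outDir,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
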