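#' Default pipeline configuration
#'
#' All detector parameters default to the values documented in the
#' detection functions; a YAML file with any subset of these keys can
#' override them. Unknown keys are rejected.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    input = list(eeg = NULL, hypnogram = NULL, mask = NULL),
    simulate = NULL,                 # simulation_spec() arguments
    mastoids = NULL,                 # e.g. c("M1", "M2")
    filter = list(highpass = NULL, notch = list()),
    screen_bad_channels = FALSE,
    bands = "night",
    sso = list(neg_thresh = -80, np_thresh = 140,
               dur_range = c(0.3, 1.0), completion_neg = -30,
               completion_np = 50, cluster_tol_s = 0.2,
               condition_band = c(0.1, 6)),
    spindles = list(multiplier = 2, merge_gap_s = 0.25,
                    dur_range = c(0.3, 3)),
    seed = 1L,
    out_dir = "sleepod-out")
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, config)
  sp <- merged$spindles
  if (any(unlist(sp$dur_range) < 0) || diff(unlist(sp$dur_range)) < 0)
    stop("config: spindle duration bounds must be non-negative and ordered")
  if (any(unlist(merged$sso$dur_range) < 0))
    stop("config: SSO duration bounds must be non-negative")
  merged
}

#' Run the full analysis pipeline
#'
#' Stages: input (read files or simulate), preprocessing (optional
#' mastoid re-reference, filtering, bad-channel screening), NREM
#' selection, band power, slow-oscillation detection/clustering/
#' characterization with the pre-event sigma precursor, spindle detection
#' and metrics, sleep macrostructure, and a run manifest. Re-running with
#' an identical config and inputs reproduces identical tables.
#'
#' @param config path to a YAML config, or a config list (see
#'   [default_config()]).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(if (is.character(config)) yaml::read_yaml(config)
                     else config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(cfg$simulate)) {
      spec <- do.call(simulation_spec,
                      c(cfg$simulate, list(seed = cfg$seed)))
      sim <- generate_nrem_eeg(spec)
      rec <- sim$rec; hyp <- sim$hyp; mask <- sim$mask
      write_ground_truth(sim$truth, file.path(out, "ground_truth.json"))
    } else {
      if (is.null(cfg$input$eeg)) stop("config: neither input$eeg nor simulate given")
      rec <- read_eeg(cfg$input$eeg)
      hyp <- read_hypnogram(cfg$input$hypnogram)
      mask <- if (!is.null(cfg$input$mask)) read_artifact_mask(cfg$input$mask)
      else artifact_mask()
    }

    stage <- "preproc"
    if (!is.null(cfg$mastoids))
      rec <- rereference_mastoids(rec, unlist(cfg$mastoids))
    if (!is.null(cfg$filter$highpass) || length(cfg$filter$notch))
      rec <- filter_recording(rec, highpass = cfg$filter$highpass,
                              notch = unlist(cfg$filter$notch))
    bad <- character()
    if (isTRUE(cfg$screen_bad_channels)) {
      bad <- detect_bad_channels(rec)
      if (length(bad)) {
        keep <- !(rec$labels %in% bad)
        rec <- eeg_recording(rec$signal[keep, , drop = FALSE],
                             rec$labels[keep], rec$fs, rec$reference,
                             rec$start_s)
      }
    }

    stage <- "nrem-selection"
    segs <- select_nrem(rec, hyp, mask)
    nrem_min <- attr(segs, "total_s") / 60
    utils::write.csv(segs, file.path(out, "nrem_segments.csv"),
                     row.names = FALSE)

    stage <- "band-power"
    bp <- band_power(rec, segs, band_defs(cfg$bands))
    utils::write.csv(bp, file.path(out, "band_power.csv"), row.names = FALSE)

    stage <- "sso"
    sso_cfg <- cfg$sso
    waves <- detect_sso_recording(
      rec, segs, condition = TRUE,
      neg_thresh = sso_cfg$neg_thresh, np_thresh = sso_cfg$np_thresh,
      dur_range = unlist(sso_cfg$dur_range),
      completion_neg = sso_cfg$completion_neg,
      completion_np = sso_cfg$completion_np)
    events <- cluster_sso_events(waves, tol_s = sso_cfg$cluster_tol_s)
    utils::write.csv(events, file.path(out, "sso_waves.csv"),
                     row.names = FALSE)
    sso_feat <- characterize_sso(events, nrem_min, channels = rec$labels)
    sigma_pre <- pre_sso_sigma(rec, events)
    sso_feat <- merge(sso_feat, sigma_pre, by = "channel", all.x = TRUE)
    utils::write.csv(sso_feat, file.path(out, "sso_features.csv"),
                     row.names = FALSE)

    stage <- "spindles"
    spi <- detect_spindles_recording(
      rec, segs, multiplier = cfg$spindles$multiplier,
      merge_gap_s = cfg$spindles$merge_gap_s,
      dur_range = unlist(cfg$spindles$dur_range))
    utils::write.csv(spi$events, file.path(out, "spindle_events.csv"),
                     row.names = FALSE)
    utils::write.csv(spi$thresholds, file.path(out, "spindle_thresholds.csv"),
                     row.names = FALSE)
    spi_feat <- spindle_metrics(spi$events, nrem_min, channels = rec$labels)
    utils::write.csv(spi_feat, file.path(out, "spindle_features.csv"),
                     row.names = FALSE)

    stage <- "macrostructure"
    macro <- macrostructure(hyp)
    utils::write.csv(macro, file.path(out, "macrostructure.csv"),
                     row.names = FALSE)

    stage <- "manifest"
    cfg_path <- file.path(out, "config_resolved.yaml")
    yaml::write_yaml(cfg, cfg_path)
    inputs <- unlist(cfg$input)
    manifest <- list(
      package = "sleepod",
      version = as.character(utils::packageVersion("sleepod")),
      seed = cfg$seed,
      config_hash = unname(tools::md5sum(cfg_path)),
      input_checksums = if (length(inputs))
        as.list(tools::md5sum(inputs[file.exists(inputs)])) else list(),
      bad_channels = bad,
      nrem_minutes = nrem_min,
      tables = c("nrem_segments.csv", "band_power.csv", "sso_waves.csv",
                 "sso_features.csv", "spindle_events.csv",
                 "spindle_thresholds.csv", "spindle_features.csv",
                 "macrostructure.csv"))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Default 128-channel geodesic-net ROI layout
#'
#' Approximate electrode lists for the occipital, prefrontal, and
#' sensorimotor regions of a 128-channel geodesic sensor net (sensors
#' around O1/Oz/O2/POz, Fp1/Fpz/Fp2/AFz, and C3/Cz/C4 equivalents). The
#' layout is data, not code: ship your own YAML (ROI name -> label list)
#' and load it with [read_roi_layout()] to replace it.
#'
#' @return An [roi_layout()].
#' @export
default_roi_layout <- function() {
  read_roi_layout(system.file("extdata", "roi_geodesic128.yaml",
                              package = "sleepod"))
}

#' Read an ROI layout from YAML
#' @param path YAML file mapping ROI names to electrode-label lists.
#' @return An [roi_layout()].
#' @export
read_roi_layout <- function(path) {
  roi_layout(lapply(yaml::read_yaml(path), as.character))
}
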