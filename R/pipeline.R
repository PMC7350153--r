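#' Pipeline run configuration
#'
#' A validated, JSON-serializable description of one analysis run: which
#' network state to analyze, where the input comes from (a synthetic
#' generator spec or CSV paths), the analysis bands and detector parameters,
#' and the oxygen model template. Every parameter has a default, and a
#' config round-trips losslessly through JSON.
#'
#' @param mode one of `"gam"`, `"thegam"`, `"spwr"`, `"bursts"`, `"oxygen"`.
#' @param recording_csv optional path to an input recording CSV (header
#'   `time_s` + channel columns); if `NULL`, a synthetic recording is
#'   generated from `generator`.
#' @param oxygen_csv optional path to an oxygen depth-profile CSV
#'   (`depth_um, o2`); if `NULL` (oxygen mode), a synthetic profile is
#'   generated from the template with `oxygen_true_vmax` and
#'   `oxygen_noise_sd`.
#' @param generator named list of [synth_spec()] overrides.
#' @param band spectral analysis band name or `c(low, high)`.
#' @param switch_time,k_sd_burst,refractory burst-detector parameters.
#' @param k_sd_spw,k_sd_spw_peak,ripple_k_sd SPW-R detector parameters.
#' @param max_lag_ms cross-region lag search window.
#' @param oxygen_model_args named list of [oxygen_model()] overrides for the
#'   fitting template.
#' @param oxygen_true_vmax,oxygen_noise_sd generator settings for synthetic
#'   oxygen profiles.
#' @param seed integer seed controlling every stochastic step.
#' @param out_dir output directory for reports (`NULL` = no files written).
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `run_config`.
#' @seealso [run_pipeline()]
#' @export
run_config <- function(mode = c("gam", "thegam", "spwr", "bursts", "oxygen"),
                       recording_csv = NULL, oxygen_csv = NULL,
                       generator = list(), band = "gamma",
                       switch_time = 120, k_sd_burst = 5, refractory = 0.5,
                       k_sd_spw = 3, k_sd_spw_peak = 5, ripple_k_sd = 2,
                       max_lag_ms = 25,
                       oxygen_model_args = list(),
                       oxygen_true_vmax = 0.05, oxygen_noise_sd = 0.02,
                       seed = 1L, out_dir = NULL, log_level = c("info", "quiet")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  cfg <- list(mode = mode, recording_csv = recording_csv, oxygen_csv = oxygen_csv,
              generator = generator, band = band, switch_time = switch_time,
              k_sd_burst = k_sd_burst, refractory = refractory,
              k_sd_spw = k_sd_spw, k_sd_spw_peak = k_sd_spw_peak,
              ripple_k_sd = ripple_k_sd, max_lag_ms = max_lag_ms,
              oxygen_model_args = oxygen_model_args,
              oxygen_true_vmax = oxygen_true_vmax,
              oxygen_noise_sd = oxygen_noise_sd,
              seed = as.integer(seed), out_dir = out_dir, log_level = log_level)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: mode %s, seed %d, input %s\n", x$mode, x$seed,
              if (!is.null(x$recording_csv)) x$recording_csv
              else if (x$mode == "oxygen" && !is.null(x$oxygen_csv)) x$oxygen_csv
              else "synthetic"))
  invisible(x)
}

#' Read and write run configurations as JSON
#'
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @export
write_config_json <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  raw$generator <- as.list(raw$generator)
  raw$oxygen_model_args <- as.list(raw$oxygen_model_args)
  do.call(run_config, raw)
}

# deterministic md5 of the canonical JSON serialization of a config;
# output location and verbosity do not affect the analysis, so they are
# excluded and reruns into different directories hash identically
config_hash <- function(cfg) {
  core <- unclass(cfg)
  core$out_dir <- NULL
  core$log_level <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

pipe_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info"))
    message(sprintf(paste0("[slicemetrics] ", fmt), ...))
  invisible(NULL)
}

#' Run the analysis pipeline
#'
#' Executes generate (or load) -> analyze -> summarize for one configuration
#' and returns a flat, reproducible report. For LFP modes the report carries
#' the spectral summary (peak frequency `f`, `Power`, `AuC`, `FWHM`), the
#' autocorrelation `TAU`, event metrics (burst or SPW-R) where applicable,
#' and the cross-region similarity/lag for two-channel recordings. For
#' oxygen mode it carries the fitted CMRO2 and lowest O2. Identical
#' config + seed yields a byte-identical report payload; provenance (config
#' hash, package version, seed) is embedded.
#'
#' @param cfg a [run_config()].
#' @return A list of class `pipeline_report`. If `cfg$out_dir` is set, the
#'   report JSON (`report.json`), the event table (`events.csv`) and, for
#'   synthetic inputs, the recording/profile CSVs are written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  report <- list(provenance = list(
    package = "slicemetrics",
    version = as.character(utils::packageVersion("slicemetrics")),
    mode = cfg$mode, seed = cfg$seed, config_hash = config_hash(cfg)))

  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)

  events_df <- NULL
  if (cfg$mode == "oxygen") {
    template <- do.call(oxygen_model, cfg$oxygen_model_args)
    if (!is.null(cfg$oxygen_csv)) {
      pipe_log(cfg, "reading oxygen profile %s", cfg$oxygen_csv)
      prof <- read_oxygen_csv(cfg$oxygen_csv)
    } else {
      pipe_log(cfg, "generating synthetic oxygen profile (Vmax = %g)",
               cfg$oxygen_true_vmax)
      truth <- template
      truth$Vmax <- cfg$oxygen_true_vmax
      prof <- gen_oxygen_profile(truth, seq(0, template$L, length.out = 81L),
                                 noise_sd = cfg$oxygen_noise_sd, seed = cfg$seed)
      if (!is.null(cfg$out_dir))
        write_oxygen_csv(prof, file.path(cfg$out_dir, "profile.csv"))
      report$generator <- list(true_vmax = cfg$oxygen_true_vmax,
                               noise_sd = cfg$oxygen_noise_sd)
    }
    fit <- fit_cmro2(prof, template)
    report$oxygen <- list(CMRO2_hat = fit$CMRO2_hat,
                          residual_rms = fit$residual_rms,
                          lowest_O2_fit = fit$lowest_O2,
                          lowest_O2_measured = lowest_o2(prof),
                          converged = fit$converged)
  } else {
    if (!is.null(cfg$recording_csv)) {
      pipe_log(cfg, "reading recording %s", cfg$recording_csv)
      rec <- read_recording_csv(cfg$recording_csv)
      truth <- NULL
    } else {
      gen_state <- if (cfg$mode == "bursts") "gam" else cfg$mode
      gen_args <- utils::modifyList(list(state = gen_state, seed = cfg$seed),
                                    cfg$generator)
      if (cfg$mode == "bursts" && is.null(gen_args$burst_rate))
        gen_args$burst_rate <- 0.3
      if (cfg$mode == "bursts" && is.null(gen_args$burst_start))
        gen_args$burst_start <- cfg$switch_time
      spec <- do.call(synth_spec, gen_args)
      pipe_log(cfg, "generating synthetic %s recording (%g s at %g Hz)",
               spec$state, spec$duration, spec$sampling_rate)
      g <- gen_recording(spec)
      rec <- g$recording
      truth <- g$truth
      if (!is.null(cfg$out_dir)) {
        write_recording_csv(rec, file.path(cfg$out_dir, "recording.csv"))
        jsonlite::write_json(truth$events, file.path(cfg$out_dir, "truth.json"),
                             digits = NA, dataframe = "rows")
      }
    }

    pipe_log(cfg, "spectral analysis (%s band)", paste(cfg$band, collapse = "-"))
    psd <- compute_psd(rec)
    ss <- summarize_spectrum(psd, band = cfg$band)
    report$spectrum <- list(f = ss$f, Power = ss$Power, AuC = ss$AuC,
                            FWHM = ss$FWHM, flagged = ss$flagged)
    ac <- tryCatch(autocorr_tau(rec, band = cfg$band), error = function(e) NULL)
    report$autocorr <- if (is.null(ac)) list(TAU = NA, non_decaying = NA)
      else list(TAU = if (is.finite(ac$TAU)) ac$TAU else NA,
                fit_quality = ac$fit_quality, non_decaying = ac$non_decaying)

    if (cfg$mode == "bursts") {
      pipe_log(cfg, "burst detection (switch at %g s)", cfg$switch_time)
      b <- detect_bursts(rec, switch_time = cfg$switch_time,
                         k_sd = cfg$k_sd_burst, refractory = cfg$refractory)
      report$bursts <- list(n = nrow(b$events), incidence_per_s = b$incidence,
                            onset_min = b$onset_min, has_bursts = b$has_bursts,
                            amp_median_uV = if (b$has_bursts)
                              stats::median(b$events$amp_uV) else NA,
                            interval_median_s = if (length(b$intervals))
                              stats::median(b$intervals) else NA)
      events_df <- b$events
    }
    if (cfg$mode == "spwr") {
      pipe_log(cfg, "SPW-R detection")
      sp <- detect_spwr(rec, k_sd = cfg$k_sd_spw, k_sd_peak = cfg$k_sd_spw_peak,
                        ripple_k_sd = cfg$ripple_k_sd)
      report$spwr <- list(n = nrow(sp$events), incidence_per_min = sp$incidence,
                          amp_median_uV = if (nrow(sp$events))
                            stats::median(sp$events$amp_uV) else NA,
                          duration_median_ms = if (nrow(sp$events))
                            stats::median(sp$events$duration_ms) else NA,
                          ripples_per_event_median = if (nrow(sp$events))
                            stats::median(sp$events$ripples) else NA)
      events_df <- sp$events
    }
    if (ncol(rec$data) == 2L) {
      pipe_log(cfg, "cross-region similarity and lag")
      cr <- similarity_and_lag(rec, band = cfg$band, max_lag_ms = cfg$max_lag_ms)
      report$crossregion <- list(Similarity = cr$Similarity, lag_ms = cr$lag_ms)
    }
    if (!is.null(truth))
      report$generator <- list(state = truth$spec$state,
                               n_truth_events = nrow(truth$events))
  }

  report <- structure(report, class = "pipeline_report")
  if (!is.null(cfg$out_dir)) {
    write_report_json(report, file.path(cfg$out_dir, "report.json"))
    if (!is.null(events_df))
      data.table::fwrite(events_df, file.path(cfg$out_dir, "events.csv"))
    pipe_log(cfg, "report written to %s", cfg$out_dir)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (mode %s, seed %d, config %s)\n",
              x$provenance$mode, x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  flat <- report_flat(x)
  for (nm in names(flat)) cat(sprintf("  %-28s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}

# flatten the report (minus provenance) to name = scalar pairs
report_flat <- function(report) {
  out <- list()
  for (sec in setdiff(names(report), "provenance")) {
    for (nm in names(report[[sec]]))
      out[[paste(sec, nm, sep = ".")]] <- report[[sec]][[nm]]
  }
  out
}

#' Write a pipeline report as JSON
#'
#' The serialization is deterministic (no timestamps), so identical
#' config + seed produce byte-identical files.
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
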