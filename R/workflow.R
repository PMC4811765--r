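## End-to-end runs: simulate (or load) -> ensemble MSD -> K/alpha fits ->
## per-condition report, with a manifest recording the seed, a config hash
## and per-file checksums for reproducibility audits.

md5_of_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$conditions) || length(config$conditions) == 0L)
    stop("config validation failed: no conditions/stages declared")
  labels <- vapply(config$conditions, function(cc) cc$label %||% "",
                   character(1))
  if (any(labels == "")) stop("every condition needs a label")
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  for (cc in config$conditions) {
    if (is.null(cc$tracks_csv) && is.null(cc$model))
      stop(sprintf("condition '%s': need either a simulation model or tracks_csv",
                   cc$label))
    if (!is.null(cc$tracks_csv) && !file.exists(cc$tracks_csv))
      stop(sprintf("condition '%s': input path %s does not exist",
                   cc$label, cc$tracks_csv))
  }
  config$seed <- config$seed %||% 1L
  config$output_dir <- config$output_dir %||% "sptcrowd_run"
  config$fit <- config$fit %||% list()
  config$fit$k_window <- config$fit$k_window %||% c(1L, 10L)
  config$fit$alpha_lags <- config$fit$alpha_lags %||% 40L
  config$fit$through_origin <- isTRUE(config$fit$through_origin)
  config$reference <- config$reference %||% labels[1]
  if (!config$reference %in% labels)
    stop("reference condition not among the declared labels")
  config$figure <- config$figure %||% TRUE
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simulate_condition <- function(cc, seed) {
  model <- cc$model %||% "csv"
  n_traj <- cc$n_traj %||% 200L
  n_frames <- cc$n_frames %||% 121L
  dt <- cc$dt %||% 0.5
  tracks <- switch(model,
    csv = read_tracks(cc$tracks_csv, condition_label = cc$label),
    brownian = simulate_brownian(n_traj, n_frames, dt,
                                 msd_slope = cc$msd_slope, seed = seed),
    fbm = simulate_fbm(n_traj, n_frames, dt, alpha = cc$alpha,
                       gamma = cc$gamma, seed = seed),
    confined = simulate_confined(n_traj, n_frames, dt, D = cc$D,
                                 tau_c = cc$tau_c, seed = seed),
    stop(sprintf("unknown model '%s' in condition '%s'", model, cc$label)))
  tracks$condition_label <- cc$label
  if (!is.null(cc$sigma_loc) && cc$sigma_loc > 0)
    tracks <- add_localization_noise(tracks, cc$sigma_loc, seed = seed + 1L)
  tracks
}

#' Run the simulate -> MSD -> fit -> report pipeline
#'
#' Executes each configured condition (simulation model or trajectory CSV),
#' computes the ensemble MSD, fits K (lags 1-10, free intercept by default)
#' and alpha (first 40 lags), writes per-condition MSD CSVs and fit JSONs, a
#' condition-comparison table with fold-changes relative to the declared
#' reference, an optional log-log overlay figure, and a run manifest with the
#' config hash and per-file checksums.
#'
#' @param config A list or a YAML file path. Required: `conditions`, a list
#'   of blocks each with `label` and either a simulation `model`
#'   (`"brownian"`, `"fbm"`, `"confined"` plus its parameters) or a
#'   `tracks_csv` path. Optional: `seed` (default 1), `output_dir`,
#'   `reference` (default: first label), `fit$k_window`, `fit$alpha_lags`,
#'   `fit$through_origin`, `figure`.
#' @return A `run_manifest` list (also written as `manifest.json`), with the
#'   comparison table attached as `$comparison` and fits as `$fits`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "output_dir")],
                               auto_unbox = TRUE, digits = NA)
  stage_times <- c()
  fits <- list()
  curves <- list()
  outputs <- character(0)
  for (i in seq_along(config$conditions)) {
    cc <- config$conditions[[i]]
    t0 <- proc.time()[["elapsed"]]
    tracks <- simulate_condition(cc, seed = config$seed + 1000L * i)
    slug <- sprintf("%02d_%s", i, gsub("[^A-Za-z0-9]+", "_", cc$label))
    tpath <- file.path(config$output_dir, paste0("tracks_", slug, ".csv"))
    write_tracks(tracks, tpath)
    msd <- ensemble_msd(tracks)
    mpath <- file.path(config$output_dir, paste0("msd_", slug, ".csv"))
    write_msd(msd, mpath)
    kw <- config$fit$k_window
    fit <- fit_diffusion(msd, window = kw[1]:kw[2],
                         n_lags = config$fit$alpha_lags,
                         through_origin = config$fit$through_origin)
    fpath <- file.path(config$output_dir, paste0("fit_", slug, ".json"))
    jsonlite::write_json(unclass(fit), fpath, auto_unbox = TRUE, digits = NA)
    fits[[cc$label]] <- fit
    curves[[cc$label]] <- msd
    outputs <- c(outputs, tpath, mpath, fpath)
    stage_times[cc$label] <- proc.time()[["elapsed"]] - t0
    message(sprintf("[stage] condition '%s': %d trajectories, K = %.4g, alpha = %.3f",
                    cc$label, length(tracks), fit$K, fit$alpha))
  }
  comparison <- compare_conditions(fits, reference = config$reference)
  cpath <- file.path(config$output_dir, "comparison.csv")
  utils::write.csv(comparison, cpath, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, cpath)
  if (isTRUE(config$figure)) {
    fig <- file.path(config$output_dir, "msd_loglog.png")
    plot_msd_loglog(curves, path = fig)
  }
  manifest <- list(
    artifact = paste0("sptcrowd ", as.character(utils::packageVersion("sptcrowd"))),
    seed = config$seed,
    config_hash = md5_of_string(as.character(cfg_json)),
    checksums = as.list(tools::md5sum(outputs)),
    stage_seconds = as.list(stage_times))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$comparison <- comparison
  manifest$fits <- fits
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' Compare diffusion fits across conditions
#'
#' Tabulates K and alpha per condition with fold-decreases relative to a
#' reference condition: `fold_K = K_reference / K_condition` (so a mobility
#' loss reads as a fold-change > 1, e.g. 4.2e-2 -> 1.31e-2 gives 3.21).
#'
#' @param fits Named list of `diffusion_fit` objects (unique labels).
#' @param reference Label of the reference condition; default: first.
#' @return Data frame `condition,K,alpha,fold_K,fold_alpha`.
#' @export
compare_conditions <- function(fits, reference = names(fits)[1]) {
  if (length(fits) < 1L) stop("need at least one labelled fit")
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("fits must be a named list")
  if (anyDuplicated(names(fits))) stop("duplicate condition labels")
  if (!reference %in% names(fits)) stop("unknown reference condition")
  ref <- fits[[reference]]
  data.frame(
    condition = names(fits),
    K = vapply(fits, function(f) f$K, numeric(1)),
    alpha = vapply(fits, function(f) f$alpha, numeric(1)),
    fold_K = vapply(fits, function(f) ref$K / f$K, numeric(1)),
    fold_alpha = vapply(fits, function(f) ref$alpha / f$alpha, numeric(1)),
    row.names = NULL)
}
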