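## End-to-end orchestration: one config object drives
## register -> displace -> tfm -> dynamics on a bead image stack, with
## stage-granular logging and deterministic, provenance-stamped outputs.

#' Default pipeline configuration
#'
#' A single nested list drives every stage; all the parameters the
#' underlying methods leave unstated (window sizes, regularization policy,
#' thresholds) are surfaced here so runs are reproducible.
#'
#' @param ... Name-value overrides of the defaults (nested lists are
#'   merged shallowly per stage).
#' @return A list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    gel = list(youngs_modulus = 1000, poisson_ratio = 0.5, thickness = 150),
    pixel_size = 0.5,
    frame_interval_min = 5,
    registration = list(reference_frame = 1, score_floor = 0.2),
    displacement = list(window = 32, overlap = 0.5, min_quality = 0.2,
                        outlier_threshold = 5),
    traction = list(lambda = "noise", filter_mode = "tikhonov",
                    pad = 2, taper_frac = 0.1),
    dynamics = list(prominence = NULL, min_separation = 0,
                    expected_period_min = 10),
    seed = 1
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline config as YAML
#'
#' Configs round-trip through serialization unchanged.
#'
#' @param path YAML file path.
#' @param config A `run_config` (for writing).
#' @return For `read_config`, a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Reports out-of-range parameters and sampling-design warnings (an
#' expected force-peak period below three frame intervals cannot be
#' resolved reliably) without mutating the config.
#'
#' @param config A `run_config`.
#' @return List of class `config_report`: character vectors `errors` and
#'   `warnings`; empty vectors mean a clean config.
#' @export
validate_config <- function(config) {
  errors <- character(0); warnings <- character(0)
  g <- config$gel
  if (g$youngs_modulus <= 0)
    errors <- c(errors, "gel.youngs_modulus must be > 0")
  if (g$poisson_ratio < 0 || g$poisson_ratio > 0.5)
    errors <- c(errors, "gel.poisson_ratio out of range [0, 0.5]")
  if (config$pixel_size <= 0)
    errors <- c(errors, "pixel_size must be > 0")
  d <- config$displacement
  if (d$window < 16) errors <- c(errors, "displacement.window must be >= 16")
  if (d$overlap < 0 || d$overlap >= 1)
    errors <- c(errors, "displacement.overlap out of range [0, 1)")
  if (!is.null(config$dynamics$expected_period_min) &&
      config$dynamics$expected_period_min <
        3 * config$frame_interval_min)
    warnings <- c(warnings, sprintf(
      "expected peak period (%g min) < 3 frame intervals (%g min): interval statistics at the Nyquist limit",
      config$dynamics$expected_period_min, 3 * config$frame_interval_min))
  structure(list(errors = errors, warnings = warnings),
            class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  if (!length(x$errors) && !length(x$warnings)) cat("config OK\n")
  for (e in x$errors) cat("error:", e, "\n")
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  # small stable polynomial hash in double arithmetic (exact below 2^53);
  # avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Run the TFM pipeline on a bead image stack
#'
#' Executes register -> displace (vs the relaxed reference) -> traction
#' reconstruction -> per-frame force metrics -> peak statistics, writing
#' CSV outputs stamped with the config hash. Identical config and seed
#' give identical outputs.
#'
#' @param stack List of loaded-frame image matrices (in time order).
#' @param reference Relaxed-state reference image (post embryo removal);
#'   required — displacements are measured against the unloaded gel.
#' @param config A `run_config`.
#' @param contact_mask Optional logical matrix (displacement-grid shape)
#'   of embryo contact nodes; when absent, a mask is derived per frame by
#'   thresholding |T| at the noise floor of the border region.
#' @param out_dir Optional output directory for CSV results.
#' @return List of class `tfm_run`: `metrics` (per-frame data.frame),
#'   `tractions` (list of `traction_field`), `displacements`, `drift`,
#'   `peaks`, `log` (stage messages), `config_hash`.
#' @export
run_pipeline <- function(stack, reference, config = default_config(),
                         contact_mask = NULL, out_dir = NULL) {
  if (is.null(reference))
    stop("a relaxed-state reference image (acquired after embryo removal) ",
         "is required to measure gel displacement")
  rep_err <- validate_config(config)
  if (length(rep_err$errors))
    stop("invalid config: ", paste(rep_err$errors, collapse = "; "))
  set.seed(config$seed)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  gel <- gel_properties(config$gel$youngs_modulus,
                        config$gel$poisson_ratio, config$gel$thickness)

  # -- register: drift relative to the reference image ------------------
  drift <- tryCatch(
    estimate_drift(c(list(reference), stack), reference_frame = 1,
                   score_floor = config$registration$score_floor),
    error = function(e) stop("stage register failed: ", conditionMessage(e)))
  drift <- drift[-1, , drop = FALSE]
  drift$frame <- seq_len(nrow(drift))
  note("register: max |drift| %.2f px, %d frame(s) flagged",
       max(abs(c(drift$dx_px, drift$dy_px))), sum(drift$flagged))

  # -- displace + invert per frame --------------------------------------
  dcfg <- config$displacement
  displacements <- vector("list", length(stack))
  tractions <- vector("list", length(stack))
  metrics <- vector("list", length(stack))
  lambda_val <- NULL
  for (f in seq_along(stack)) {
    img <- apply_shift(stack[[f]], c(drift$dx_px[f], drift$dy_px[f]))
    fld <- tryCatch(
      compute_displacement_field(img, reference, dcfg$window, dcfg$overlap,
                                 config$pixel_size, dcfg$min_quality),
      error = function(e) stop("stage displace failed on frame ", f, ": ",
                               conditionMessage(e)))
    fld <- filter_outliers(fld, threshold = dcfg$outlier_threshold)
    note("displace frame %d: %d/%d nodes valid, %d outlier(s) replaced",
         f, sum(fld$mask), length(fld$mask), attr(fld, "n_replaced"))
    displacements[[f]] <- fld

    tcfg <- config$traction
    if (is.null(lambda_val)) {
      if (identical(tcfg$lambda, "noise")) {
        border <- border_mask(dim(fld$u), frac = 0.12)
        lambda_val <- select_lambda(fld, gel, "noise",
                                    noise_region = border,
                                    pad = tcfg$pad,
                                    taper_frac = tcfg$taper_frac)$lambda
        note("tfm: noise-matched lambda = %.3g", lambda_val)
      } else if (identical(tcfg$lambda, "lcurve")) {
        lambda_val <- select_lambda(fld, gel, "lcurve", pad = tcfg$pad,
                                    taper_frac = tcfg$taper_frac)$lambda
        note("tfm: L-curve lambda = %.3g", lambda_val)
      } else lambda_val <- as.numeric(tcfg$lambda)
    }
    tr <- tryCatch(
      fttc_inverse(fld, gel, lambda = lambda_val,
                   filter_mode = tcfg$filter_mode, pad = tcfg$pad,
                   taper_frac = tcfg$taper_frac),
      error = function(e) stop("stage tfm failed on frame ", f, ": ",
                               conditionMessage(e)))
    tractions[[f]] <- tr

    cm <- contact_mask
    if (is.null(cm)) {
      floor_pa <- noise_floor(tr, border_mask(dim(tr$magnitude), 0.12))
      cm <- tr$magnitude > floor_pa
      if (!any(cm)) cm <- tr$magnitude >= max(tr$magnitude)
      note("tfm frame %d: contact mask from noise floor %.3g Pa (%d nodes)",
           f, floor_pa, sum(cm))
    }
    metrics[[f]] <- traction_metrics(
      tr, cm, time = (f - 1) * config$frame_interval_min)
  }
  metrics <- do.call(rbind, metrics)

  # -- dynamics ----------------------------------------------------------
  peaks <- NULL
  if (nrow(metrics) >= 3) {
    ser <- force_series(metrics$t_min, metrics$max_Pa, "max traction (Pa)")
    peaks <- suppressWarnings(
      detect_peaks(ser, prominence = config$dynamics$prominence,
                   min_separation = config$dynamics$min_separation))
    note("dynamics: %d peak(s) detected", peaks$n)
  }

  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    mo <- metrics; mo$config_hash <- hash
    utils::write.csv(mo, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    do <- drift; do$config_hash <- hash
    utils::write.csv(do, file.path(out_dir, "drift.csv"), row.names = FALSE)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  structure(list(metrics = metrics, tractions = tractions,
                 displacements = displacements, drift = drift,
                 peaks = peaks, log = log, config_hash = hash),
            class = "tfm_run")
}

#' @export
print.tfm_run <- function(x, ...) {
  cat(sprintf("TFM run [%s]: %d frame(s), max traction %.4g Pa, total force %.4g nN\n",
              x$config_hash, nrow(x$metrics), max(x$metrics$max_Pa),
              x$metrics$total_nN[nrow(x$metrics)]))
  invisible(x)
}

# Logical mask of the outer border band of a matrix (embryo-free margin).
border_mask <- function(dims, frac = 0.1) {
  ny <- dims[1]; nx <- dims[2]
  by <- max(1, round(frac * ny)); bx <- max(1, round(frac * nx))
  m <- matrix(FALSE, ny, nx)
  m[c(seq_len(by), ny - seq_len(by) + 1), ] <- TRUE
  m[, c(seq_len(bx), nx - seq_len(bx) + 1)] <- TRUE
  m
}
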