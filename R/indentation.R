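## Young's modulus extraction from nanoindentation force-indentation
## curves with the Hertz spherical-contact model, plus the quality-control
## screen that excludes curves with improper tip-sample contact.

#' Fit the Hertz spherical-contact model to a force-indentation curve
#'
#' Model: `F = (4/3) E / (1 - nu^2) sqrt(R) max(delta - delta0, 0)^(3/2)`
#' with E (Pa) and the contact offset `delta0` (um) fitted jointly. For a
#' given offset E enters linearly, so the fit is a 1-D golden-section
#' search over the offset with the closed-form least-squares E inside —
#' robust on soft gels where contact is gradual. A threshold-based contact
#' pre-detector is available via `contact = "threshold"`.
#'
#' @param curve An `indentation_curve` (or data.frame with `delta_um`,
#'   `force_nN`), >= 10 samples spanning past contact.
#' @param R Tip radius (um, > 0).
#' @param nu Poisson's ratio in \[0, 0.5\] (0.5 for hydrated gels).
#' @param contact `"joint"` (default) or `"threshold"` (offset at the
#'   first force exceeding 3 baseline SD, then E-only fit).
#' @param max_indent_frac When `thickness` is given, only samples with
#'   effective indentation below this fraction of it are fitted
#'   (thin-sample validity; default 0.1).
#' @param thickness Optional sample thickness (um).
#' @return List of class `hertz_fit`: `E_Pa`, `contact_offset_um`,
#'   `rmse_nN`, `r_squared`, `qc_pass`, `qc_reasons`.
#' @export
fit_hertz <- function(curve, R = 3, nu = 0.5,
                      contact = c("joint", "threshold"),
                      max_indent_frac = 0.1, thickness = NULL) {
  contact <- match.arg(contact)
  if (R <= 0) stop("R must be > 0")
  if (nu < 0 || nu > 0.5) stop("nu must be in [0, 0.5]")
  d <- curve$delta_um; f <- curve$force_nN
  if (length(d) < 10) stop("need >= 10 samples")
  if (is.unsorted(d)) stop("samples must be ordered by indentation depth")
  fail <- function(reason) structure(
    list(E_Pa = NA_real_, contact_offset_um = NA_real_, rmse_nN = NA_real_,
         r_squared = NA_real_, qc_pass = FALSE, qc_reasons = reason),
    class = "hertz_fit")

  e_given_offset <- function(d0) {
    m <- (4 / 3) / (1 - nu^2) * sqrt(R) * pmax(d - d0, 0)^1.5 * 1e-3
    if (!is.null(thickness))
      m[pmax(d - d0, 0) > max_indent_frac * thickness] <- NA
    ok <- is.finite(m)
    mm <- m[ok]; ff <- f[ok]
    if (sum(mm^2) == 0) return(list(E = NA_real_, sse = Inf))
    E <- sum(ff * mm) / sum(mm^2)
    list(E = E, sse = sum((ff - E * mm)^2))
  }

  if (contact == "threshold") {
    base <- f[seq_len(max(3, floor(length(f) / 10)))]
    thr <- mean(base) + 3 * stats::sd(base)
    i0 <- which(f > thr)
    if (!length(i0)) return(fail("no contact detected"))
    d0 <- d[min(i0)]
  } else {
    obj <- function(d0) e_given_offset(d0)$sse
    opt <- stats::optimize(obj, range(d))
    d0 <- opt$minimum
    # refine near the boundary in case contact is at the very start
    if (obj(d[1]) <= opt$objective) d0 <- d[1]
  }
  eo <- e_given_offset(d0)
  if (!is.finite(eo$E) || eo$E <= 0) return(fail("non-positive modulus"))
  pred <- eo$E * (4 / 3) / (1 - nu^2) * sqrt(R) * pmax(d - d0, 0)^1.5 * 1e-3
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - sum((f - pred)^2) / ss_tot else NA_real_
  structure(list(E_Pa = eo$E, contact_offset_um = d0,
                 rmse_nN = sqrt(mean((f - pred)^2)), r_squared = r2,
                 qc_pass = TRUE, qc_reasons = character(0)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$qc_pass)
    cat(sprintf("Hertz fit: E = %.4g Pa, contact at %.3g um, R2 = %.4f\n",
                x$E_Pa, x$contact_offset_um, x$r_squared))
  else cat("Hertz fit failed QC:", paste(x$qc_reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Quality-control screen for indentation curves
#'
#' Flags signatures of improper tip-sample contact: adhesion dips
#' (negative force excursions beyond the noise band), non-monotone
#' post-contact force, baseline drift, and non-contact (flat) curves.
#' Any flag carries an exclusion recommendation.
#'
#' @param curve An `indentation_curve` or compatible data.frame.
#' @param noise_mult Noise band as a multiple of the baseline SD
#'   (default 3).
#' @return List: logical flags `adhesion`, `non_monotone`,
#'   `baseline_drift`, `non_contact`; `exclude` is their union.
#' @export
qc_curve <- function(curve, noise_mult = 3) {
  d <- curve$delta_um; f <- curve$force_nN
  nb <- max(3, floor(length(f) / 10))
  base <- f[seq_len(nb)]
  # noise level from the detrended baseline, so drift itself does not
  # widen the band used to detect it
  sd0 <- stats::sd(stats::lm.fit(cbind(1, seq_len(nb)), base)$residuals)
  band <- noise_mult * max(sd0, 1e-12)
  non_contact <- max(f) - mean(base) <= band
  adhesion <- any(f < mean(base) - band)
  # post-contact region: beyond the point the force first clears the band
  i0 <- which(f > mean(base) + band)
  non_monotone <- FALSE
  if (length(i0) && !non_contact) {
    post <- f[min(i0):length(f)]
    non_monotone <- any(diff(post) < -band)
  }
  half <- floor(length(base) / 2)
  baseline_drift <- FALSE
  if (half >= 2)
    baseline_drift <- abs(mean(base[seq_len(half)]) -
                            mean(base[(half + 1):length(base)])) > band
  flags <- list(adhesion = adhesion, non_monotone = non_monotone,
                baseline_drift = baseline_drift, non_contact = non_contact)
  c(flags, list(exclude = Reduce(`|`, flags)))
}

#' Summarize Young's modulus over a set of fitted curves
#'
#' Mean and SEM of E over the QC-passing fits; excluded curves are
#' counted, matching the practice of averaging >= 10 measurement points
#' per sample after discarding irregular curves.
#'
#' @param fits List of `hertz_fit` objects.
#' @return List: `mean_E_Pa`, `sem_E_Pa`, `n_used`, `n_excluded`.
#' @export
summarize_points <- function(fits) {
  pass <- vapply(fits, function(f) isTRUE(f$qc_pass), logical(1))
  if (!any(pass)) stop("no passing fits to summarize")
  e <- vapply(fits[pass], function(f) f$E_Pa, numeric(1))
  list(mean_E_Pa = mean(e),
       sem_E_Pa = if (length(e) > 1) stats::sd(e) / sqrt(length(e))
                  else NA_real_,
       n_used = length(e), n_excluded = sum(!pass))
}
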