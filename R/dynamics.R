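## Time-series analysis of per-frame force metrics: peak statistics,
## peak-to-movement association, intensity/traction correlation, and
## pre/post inhibitor comparison.

#' Construct a labelled time series
#'
#' @param times Sample times (min), strictly increasing.
#' @param values Sample values (Pa or nN).
#' @param label Optional label.
#' @return A data.frame of class `force_series`.
#' @export
force_series <- function(times, values, label = "") {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(data.frame(t_min = times, value = values),
            class = c("force_series", "data.frame"), label = label)
}

as_force_series <- function(x) {
  if (inherits(x, "force_series")) return(x)
  if (inherits(x, "peak_series")) return(force_series(x$times, x$values))
  stop("cannot coerce to force_series")
}

#' Detect peaks and inter-peak intervals
#'
#' Local maxima with a prominence and minimum-separation criterion.
#' Prominence is the height of a peak above the higher of the two deepest
#' valleys separating it from taller terrain (the standard topographic
#' definition). When two candidate samples tie, the earlier one is kept.
#'
#' @param series A `force_series` (or [gen_peak_series()] output).
#' @param prominence Minimum prominence; default 20% of the series
#'   interquartile range.
#' @param min_separation Minimum time between accepted peaks (min).
#' @return List of class `peak_stats`: `peak_times`, `peak_heights`,
#'   `intervals`, `interval_mean`, `interval_sd`, `n`.
#' @details With sampling this coarse relative to the period the interval
#'   statistics sit near the Nyquist limit; a warning is issued when the
#'   mean interval is below 3 sampling intervals.
#' @export
detect_peaks <- function(series, prominence = NULL, min_separation = 0) {
  s <- as_force_series(series)
  t <- s$t_min; v <- s$value
  n <- length(v)
  if (n < 3) stop("need at least 3 samples")
  if (is.null(prominence)) prominence <- 0.2 * stats::IQR(v)
  # strict local maxima; plateaus resolved to their earliest sample
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  if (length(cand)) {
    prom <- vapply(cand, function(i) {
      h <- v[i]
      left <- v[seq_len(i - 1)]
      higher_l <- which(left >= h)
      lmin <- min(left[seq.int(if (length(higher_l)) max(higher_l) else 1,
                               i - 1)])
      right <- v[seq.int(i + 1, n)]
      higher_r <- which(right >= h)
      rmin <- min(right[seq_len(if (length(higher_r)) min(higher_r)
                                else length(right))])
      h - max(lmin, rmin)
    }, numeric(1))
    cand <- cand[prom >= prominence]
  }
  # enforce separation: accept in decreasing height, earliest first on ties
  if (length(cand) && min_separation > 0) {
    ord <- cand[order(-v[cand], t[cand])]
    kept <- integer(0)
    for (i in ord)
      if (!length(kept) || all(abs(t[i] - t[kept]) >= min_separation))
        kept <- c(kept, i)
    cand <- sort(kept)
  }
  pt <- t[cand]; ph <- v[cand]
  iv <- diff(pt)
  if (length(iv) && mean(iv) < 3 * stats::median(diff(t)))
    warning("mean inter-peak interval < 3 sampling intervals: ",
            "interval statistics are at the Nyquist limit")
  structure(list(peak_times = pt, peak_heights = ph, intervals = iv,
                 interval_mean = if (length(iv)) mean(iv) else NA_real_,
                 interval_sd = if (length(iv) > 1) stats::sd(iv) else NA_real_,
                 n = length(pt)),
            class = "peak_stats")
}

#' @export
print.peak_stats <- function(x, ...) {
  cat(sprintf("%d peaks; interval mean %.3g min, sd %.3g min\n",
              x$n, x$interval_mean, x$interval_sd))
  invisible(x)
}

#' Fraction of force peaks followed by embryo displacement
#'
#' For each detected peak, tests whether the embryo moved more than
#' `threshold` um within `(t_peak, t_peak + window]`; movement is the
#' largest distance from the position at the peak to any sample in the
#' window.
#'
#' @param peaks A `peak_stats` object.
#' @param trajectory A `trajectory` data.frame (`t_min`, `x_um`, `y_um`)
#'   covering the peak time range.
#' @param window Look-ahead window (min, default 5).
#' @param threshold Displacement threshold (um); default twice the median
#'   per-interval step of the trajectory.
#' @return List: `fraction`, per-peak data.frame `table`
#'   (`peak_time`, `displacement_um`, `moved`), and the `threshold` used.
#' @export
peak_displacement_association <- function(peaks, trajectory, window = 5,
                                          threshold = NULL) {
  stopifnot(inherits(peaks, "peak_stats"))
  t <- trajectory$t_min
  if (window > diff(range(t)))
    stop("window larger than the trajectory sampling span")
  steps <- sqrt(diff(trajectory$x_um)^2 + diff(trajectory$y_um)^2)
  if (is.null(threshold)) threshold <- 2 * stats::median(steps)
  disp <- vapply(peaks$peak_times, function(tp) {
    i0 <- max(which(t <= tp))
    sel <- which(t > tp & t <= tp + window)
    if (!length(sel)) return(0)
    max(sqrt((trajectory$x_um[sel] - trajectory$x_um[i0])^2 +
               (trajectory$y_um[sel] - trajectory$y_um[i0])^2))
  }, numeric(1))
  moved <- disp > threshold
  list(fraction = if (length(disp)) mean(moved) else NA_real_,
       table = data.frame(peak_time = peaks$peak_times,
                          displacement_um = disp, moved = moved),
       threshold = threshold)
}

#' Linear correlation between matched ROI measurements
#'
#' Least-squares line and Pearson correlation between, e.g., F-actin mean
#' fluorescence intensities and matched traction strengths — either across
#' ROIs at one time or one ROI across time.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), finite.
#' @return List of class `roi_correlation`: `slope`, `intercept`, `r`,
#'   `p_value`, `n`, `degenerate` (TRUE when either variable has zero
#'   variance, leaving `r` undefined).
#' @export
roi_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, p_value = NA_real_, n = length(x),
                          degenerate = TRUE), class = "roi_correlation"))
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), degenerate = FALSE),
            class = "roi_correlation")
}

#' @export
print.roi_correlation <- function(x, ...) {
  if (x$degenerate) cat("correlation undefined (zero variance)\n")
  else cat(sprintf("r = %.3f (n = %d), y = %.3g + %.3g x\n",
                   x$r, x$n, x$intercept, x$slope))
  invisible(x)
}

#' Pre/post treatment comparison of a force series
#'
#' Segment means around a treatment time, their ratio, and the time after
#' treatment at which the series first falls below half the pre-treatment
#' mean (the inhibitor-response half-decline).
#'
#' @param series A `force_series`.
#' @param treatment_time Treatment time (min), strictly inside the series
#'   span with >= 2 samples on each side.
#' @return List: `pre_mean`, `post_mean`, `ratio`, `half_decline_time`
#'   (min after treatment; `NA` with `declined = FALSE` if never reached).
#' @export
pre_post_compare <- function(series, treatment_time) {
  s <- as_force_series(series)
  pre <- s$value[s$t_min < treatment_time]
  post_i <- which(s$t_min >= treatment_time)
  if (length(pre) < 2 || length(post_i) < 2)
    stop("treatment_time must lie inside the span with >= 2 samples each side")
  pre_mean <- mean(pre)
  post <- s$value[post_i]
  hit <- which(post < pre_mean / 2)
  list(pre_mean = pre_mean, post_mean = mean(post),
       ratio = mean(post) / pre_mean,
       half_decline_time = if (length(hit))
         s$t_min[post_i[min(hit)]] - treatment_time else NA_real_,
       declined = length(hit) > 0)
}
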