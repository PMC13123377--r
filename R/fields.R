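#' Gel material properties
#'
#' Linear-elastic substrate parameters used by the forward model and the
#' traction reconstruction. The gel is treated as an incompressible (or
#' near-incompressible) elastic half-space; `thickness` is carried for
#' bookkeeping only and does not enter the Boussinesq kernel.
#'
#' @param youngs_modulus Young's modulus E in Pa (> 0). Hydrogels in the
#'   implantation-window range are ~1--10 kPa.
#' @param poisson_ratio Poisson's ratio in \[0, 0.5\]; 0.5 is the
#'   incompressibility convention for hydrated gels.
#' @param thickness Gel thickness in micrometres (informational; default 150).
#' @return An object of class `gel_properties`.
#' @export
gel_properties <- function(youngs_modulus = 1000, poisson_ratio = 0.5,
                           thickness = 150) {
  if (!is.numeric(youngs_modulus) || length(youngs_modulus) != 1 ||
      !is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("youngs_modulus must be a single finite value > 0 (Pa)")
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1 ||
      poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("poisson_ratio must lie in [0, 0.5]")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 thickness = thickness),
            class = "gel_properties")
}

#' @export
print.gel_properties <- function(x, ...) {
  cat(sprintf("Gel: E = %g Pa, nu = %g, thickness = %g um\n",
              x$youngs_modulus, x$poisson_ratio, x$thickness))
  invisible(x)
}

# Internal constructor shared by displacement and traction fields.
# Matrices are stored image-style: rows index y, columns index x.
new_vector_field <- function(x, y, fx, fy, spacing, class, extra = list()) {
  fx <- as.matrix(fx); fy <- as.matrix(fy)
  if (!all(dim(fx) == dim(fy))) stop("component matrices must match in shape")
  if (length(x) != ncol(fx) || length(y) != nrow(fx))
    stop("coordinate vectors must match matrix dimensions (y rows, x cols)")
  if (spacing <= 0) stop("grid spacing must be > 0")
  obj <- c(list(x = as.numeric(x), y = as.numeric(y),
                spacing = as.numeric(spacing)),
           stats::setNames(list(fx, fy), c("c1", "c2")), extra)
  structure(obj, class = class)
}

#' Displacement field container
#'
#' A gel-surface displacement field on a uniform grid. Coordinates and
#' components are in micrometres; `u` points along +x (image columns) and
#' `v` along +y (image rows, downward).
#'
#' @param x,y Node coordinate vectors (um), uniformly spaced.
#' @param u,v Component matrices (um), `length(y)` rows by `length(x)` cols.
#' @param mask Logical validity matrix (default all `TRUE`).
#' @param quality Optional per-node quality score matrix (e.g. correlation
#'   peak height from PIV).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(x, y, u, v, mask = NULL, quality = NULL) {
  check_uniform(x); check_uniform(y)
  sp <- if (length(x) > 1) diff(x)[1] else if (length(y) > 1) diff(y)[1] else 1
  u <- as.matrix(u)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(u), ncol(u))
  if (is.null(quality)) quality <- matrix(NA_real_, nrow(u), ncol(u))
  f <- new_vector_field(x, y, u, v, sp, "displacement_field",
                        list(mask = mask, quality = quality))
  names(f)[names(f) == "c1"] <- "u"
  names(f)[names(f) == "c2"] <- "v"
  if (any(!is.finite(f$u[f$mask])) || any(!is.finite(f$v[f$mask])))
    stop("u, v must be finite wherever mask is TRUE")
  f
}

#' Traction field container
#'
#' Reconstructed (or simulated) traction stresses on a uniform grid.
#' Components in Pa; `magnitude` is derived as `sqrt(tx^2 + ty^2)`.
#'
#' @param x,y Node coordinate vectors (um), uniformly spaced.
#' @param tx,ty Traction components (Pa).
#' @param lambda Regularization parameter used in the reconstruction
#'   (`NA` for simulated ground truth).
#' @return An object of class `traction_field` with a `magnitude` matrix.
#' @export
traction_field <- function(x, y, tx, ty, lambda = NA_real_) {
  check_uniform(x); check_uniform(y)
  sp <- if (length(x) > 1) diff(x)[1] else if (length(y) > 1) diff(y)[1] else 1
  f <- new_vector_field(x, y, tx, ty, sp, "traction_field",
                        list(lambda = as.numeric(lambda)))
  names(f)[names(f) == "c1"] <- "tx"
  names(f)[names(f) == "c2"] <- "ty"
  f$magnitude <- sqrt(f$tx^2 + f$ty^2)
  f
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- sqrt(x$u^2 + x$v^2)
  cat(sprintf(
    "Displacement field: %d x %d nodes, spacing %.3g um, |u| max %.3g um, %d/%d valid\n",
    length(x$y), length(x$x), x$spacing, max(m[x$mask], 0),
    sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf(
    "Traction field: %d x %d nodes, spacing %.3g um, |T| max %.4g Pa, lambda %.3g\n",
    length(x$y), length(x$x), x$spacing, max(x$magnitude), x$lambda))
  invisible(x)
}

#' @export
plot.traction_field <- function(x, ...) {
  graphics::image(x$x, x$y, t(x$magnitude), ylim = rev(range(x$y)),
                  xlab = "x (um)", ylab = "y (um)",
                  main = "|T| (Pa)", useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.displacement_field <- function(x, subsample = 2, scale = 5, ...) {
  m <- sqrt(x$u^2 + x$v^2)
  graphics::image(x$x, x$y, t(m), ylim = rev(range(x$y)),
                  xlab = "x (um)", ylab = "y (um)",
                  main = "|u| (um)", useRaster = TRUE, ...)
  ix <- seq(1, length(x$x), by = subsample)
  iy <- seq(1, length(x$y), by = subsample)
  g <- expand.grid(y = iy, x = ix)
  ok <- x$mask[cbind(g$y, g$x)]
  graphics::arrows(x$x[g$x[ok]], x$y[g$y[ok]],
                   x$x[g$x[ok]] + scale * x$u[cbind(g$y, g$x)][ok],
                   x$y[g$y[ok]] + scale * x$v[cbind(g$y, g$x)][ok],
                   length = 0.02)
  invisible(x)
}

#' @describeIn traction_field Net force vector (nN) integrated over the grid.
#' @param field A `traction_field`.
#' @export
net_force <- function(field) {
  da <- field$spacing^2                      # um^2 per node
  c(fx = sum(field$tx) * da * PA_UM2_TO_NN,
    fy = sum(field$ty) * da * PA_UM2_TO_NN)
}

# 1 Pa * um^2 = 1e-12 N = 1e-3 nN; fixed by unit algebra.
PA_UM2_TO_NN <- 1e-3

check_uniform <- function(g, tol = 1e-8) {
  if (length(g) > 1) {
    d <- diff(g)
    if (any(abs(d - d[1]) > tol * max(abs(d[1]), 1)) || d[1] <= 0)
      stop("grid coordinates must be uniformly increasing")
  }
  invisible(TRUE)
}

#' Write a vector field to CSV
#'
#' Long-format export (`x_um`, `y_um`, components, and for displacement
#' fields the validity mask and quality score).
#'
#' @param field A `displacement_field` or `traction_field`.
#' @param path Output CSV path.
#' @export
write_field_csv <- function(field, path) {
  g <- expand.grid(y_um = field$y, x_um = field$x)
  if (inherits(field, "displacement_field")) {
    df <- data.frame(x_um = g$x_um, y_um = g$y_um,
                     u_um = as.vector(field$u), v_um = as.vector(field$v),
                     valid = as.vector(field$mask),
                     quality = as.vector(field$quality))
  } else {
    df <- data.frame(x_um = g$x_um, y_um = g$y_um,
                     tx_Pa = as.vector(field$tx), ty_Pa = as.vector(field$ty),
                     t_Pa = as.vector(field$magnitude))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
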