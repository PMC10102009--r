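# Axial orientation utilities shared by the phantom generator and the
# fiber-orientation estimators.  Fibers are axes, not vectors: u and -u are
# the same orientation.  Canonical angles: theta = azimuth in the imaging
# (x, y) plane measured from +x, degrees in [0, 180); phi = polar angle from
# the optical +z axis, degrees in [0, 90].

#' Fold direction vectors to canonical axial form
#'
#' Flips each row so the z component is non-negative; rows with z == 0 are
#' flipped so the in-plane azimuth lies in `[0, 180)`.
#'
#' @param axes numeric matrix `n x 3`, columns `(x, y, z)`.
#' @return matrix of unit axes with `z >= 0`.
#' @export
fold_axes <- function(axes) {
  axes <- axes / sqrt(rowSums(axes^2))
  flip <- axes[, 3] < 0 |
    (axes[, 3] == 0 & (axes[, 2] < 0 | (axes[, 2] == 0 & axes[, 1] < 0)))
  axes[flip, ] <- -axes[flip, , drop = FALSE]
  axes
}

#' Convert unit axes to canonical (theta, phi) display angles
#'
#' `theta` is the in-plane azimuth folded to `[0, 180)` and `phi` the
#' axis-to-axis angle with the optical axis, `acos(|u_z|)` in `[0, 90]`.
#' This is the conventional pair for orientation maps but is *not*
#' injective on the hemisphere of axes (the sign pairing of the in-plane
#' and axial components is lost), so quantitative axial statistics must use
#' the unit axes themselves, never angles reconstructed from these values.
#'
#' @param axes matrix `n x 3` of unit axes, columns `(x, y, z)`.
#' @return list with `theta` (deg, `[0, 180)`) and `phi` (deg, `[0, 90]`).
#' @export
axes_to_angles <- function(axes) {
  axes <- fold_axes(axes)
  theta <- atan2(axes[, 2], axes[, 1]) * 180 / pi
  theta <- theta %% 180
  phi <- acos(pmin(1, abs(axes[, 3]))) * 180 / pi
  list(theta = theta, phi = phi)
}

#' Convert canonical display angles to unit axes
#'
#' Inverse of [axes_to_angles()] under the convention that the axial
#' component is non-negative; exact for in-plane (`phi = 90`) and
#' z-aligned (`phi = 0`) axes, ambiguous in between (see
#' [axes_to_angles()]).
#'
#' @param theta azimuth, degrees.
#' @param phi polar angle from +z, degrees.
#' @return matrix `n x 3`, columns `(x, y, z)`.
#' @export
angles_to_axes <- function(theta, phi) {
  t <- theta * pi / 180; p <- phi * pi / 180
  cbind(x = sin(p) * cos(t), y = sin(p) * sin(t), z = cos(p))
}

rotation_from_z <- function(mu) {
  # rotation matrix carrying (0,0,1) onto unit vector mu
  mu <- mu / sqrt(sum(mu^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * mu[3] - z[3] * mu[2],
         z[3] * mu[1] - z[1] * mu[3],
         z[1] * mu[2] - z[2] * mu[1])
  c_ <- sum(z * mu)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))  # antipodal
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Sample axial orientations from a von Mises-Fisher distribution
#'
#' Directions are drawn from vMF(`mean_axis`, `kappa`) on the sphere and
#' folded to axial form; `kappa = 0` gives uniform axes on the hemisphere and
#' `kappa = Inf` returns the mean axis exactly.
#'
#' @param n number of axes.
#' @param mean_axis length-3 mean direction (normalized internally).
#' @param kappa concentration, `>= 0`.
#' @return matrix `n x 3` of folded unit axes, columns `(x, y, z)`.
#' @export
sample_axes <- function(n, mean_axis = c(1, 0, 0), kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  mu <- mean_axis / sqrt(sum(mean_axis^2))
  if (is.infinite(kappa)) {
    return(fold_axes(matrix(mu, n, 3, byrow = TRUE)))
  }
  u <- stats::runif(n)
  if (kappa == 0) {
    w <- 2 * u - 1
  } else {
    # Wood (1994) inverse-CDF for the vMF polar cosine
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  }
  a <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  dirs <- cbind(s * cos(a), s * sin(a), w)
  fold_axes(dirs %*% t(rotation_from_z(mu)))
}

#' 3D directional variance of a set of axes
#'
#' `V = (3/2) * (1 - lambda_max(T))` where `T` is the mean dyadic tensor
#' `mean(u_i u_i')`. V is 0 for perfectly parallel axes and 1 for axes drawn
#' uniformly at random on the hemisphere, and is clipped to `[0, 1]`.
#'
#' @param axes matrix `n x 3` of unit axes.
#' @return scalar variance in `[0, 1]`.
#' @export
directional_variance_axes <- function(axes) {
  stopifnot(nrow(axes) >= 1)
  axes <- axes / sqrt(rowSums(axes^2))
  T <- crossprod(axes) / nrow(axes)
  lmax <- max(eigen(T, symmetric = TRUE, only.values = TRUE)$values)
  min(1, max(0, 1.5 * (1 - lmax)))
}
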