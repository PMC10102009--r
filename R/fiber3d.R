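# 3D fiber orientation by weighted vector summation and windowed 3D
# directional variance of the resulting axial orientation field.

window_voxels <- function(window_um, voxel_size) {
  if (any(window_um <= 2 * voxel_size))
    stop("window must exceed twice the voxel size on every axis")
  n <- round(window_um / voxel_size)
  n <- ifelse(n %% 2 == 0, n + 1, n)            # odd window
  if (any(n < 3)) stop("window smaller than 3 voxels on some axis")
  as.integer(n)
}

#' Per-voxel axial orientation field
#'
#' Carries both the unit axis components (`ax`, `ay`, `az`, the quantities
#' all axial statistics are computed from) and the conventional display
#' angles `theta`/`phi`, which are lossy (see [axes_to_angles()]). When
#' constructed from angles alone the axes are reconstructed under the
#' non-negative-z convention.
#'
#' @param theta,phi canonical display angle arrays (deg), `NA` invalid.
#' @param valid logical array.
#' @param voxel_size um per axis `(z, y, x)`.
#' @param axes optional `n_valid x 3` matrix of unit axes for the valid
#'   voxels in column-major order of `which(valid)`.
#' @return object of class `orientation_field`.
#' @export
orientation_field <- function(theta, phi, valid, voxel_size, axes = NULL) {
  stopifnot(identical(dim(theta), dim(phi)), identical(dim(theta), dim(valid)))
  d <- dim(theta)
  ax <- array(NA_real_, d); ay <- array(NA_real_, d); az <- array(NA_real_, d)
  if (is.null(axes)) axes <- angles_to_axes(theta[valid], phi[valid])
  stopifnot(nrow(axes) == sum(valid))
  ax[valid] <- axes[, 1]; ay[valid] <- axes[, 2]; az[valid] <- axes[, 3]
  structure(list(theta = theta, phi = phi, valid = valid,
                 ax = ax, ay = ay, az = az,
                 voxel_size = voxel_size),
            class = "orientation_field")
}

#' Unit axes of the valid voxels of an orientation field
#'
#' @param orient an [orientation_field()].
#' @return matrix `n_valid x 3`, columns `(x, y, z)`.
#' @export
field_axes <- function(orient) {
  stopifnot(inherits(orient, "orientation_field"))
  cbind(orient$ax[orient$valid], orient$ay[orient$valid],
        orient$az[orient$valid])
}

#' Estimate per-voxel 3D fiber orientation by weighted vector summation
#'
#' For each voxel `c` inside the evaluation mask, unit displacement vectors
#' `v_p = (p - c)/|p - c|` (physical, micrometer coordinates) to every other
#' voxel `p` of an approximately cubic window are accumulated into the
#' intensity-weighted second-moment tensor `M = sum_p I(p) v_p v_p'`; the
#' fiber axis is the principal eigenvector of `M`, reported as canonical
#' `(theta, phi)`.
#'
#' @param shg SHG [volumetric_image()].
#' @param window_um window size in um `(z, y, x)`; default 5 x 5.3 x 5.3,
#'   converted to odd voxel counts.
#' @param mask logical array of voxels to evaluate (default: voxels with
#'   positive intensity; pass the matrix mask in practice).
#' @param min_coherence minimum linear (prolate) tensor shape measure
#'   `(lambda_1 - lambda_2)/trace(M)` for a voxel to stay valid; voxels
#'   whose tensor is planar (`lambda_1 ~ lambda_2`, no single fiber
#'   direction, e.g. inside merged uniform-intensity regions) are also
#'   rejected whenever the planar measure exceeds the linear one.
#'   Default 0.01.
#' @return an [orientation_field()] (with a `coherence` array).
#' @export
local_orientation <- function(shg, window_um = c(5, 5.3, 5.3), mask = NULL,
                              min_coherence = 0.01) {
  stopifnot(inherits(shg, "volumetric_image"))
  arr <- shg$intensities
  d <- dim(arr)
  if (is.null(mask)) mask <- arr > 0
  stopifnot(identical(dim(mask), d))
  n <- window_voxels(window_um, shg$voxel_size)
  half <- (n - 1L) %/% 2L
  res <- cpp_local_orientation(as.numeric(arr), as.integer(d),
                               as.numeric(shg$voxel_size), half,
                               as.logical(mask))
  tr <- res$l1 + res$l2 + res$l3
  linear <- (res$l1 - res$l2) / tr      # Westin prolate measure
  planar <- (res$l2 - res$l3) / tr      # Westin oblate measure
  keep <- res$valid & is.finite(linear) & linear >= min_coherence &
    linear >= planar
  valid <- array(keep, d)
  theta <- array(NA_real_, d); phi <- array(NA_real_, d)
  axes <- cbind(res$ux[valid], res$uy[valid], res$uz[valid])
  if (any(valid)) {
    axes <- fold_axes(axes)
    ang <- axes_to_angles(axes)
    theta[valid] <- ang$theta
    phi[valid] <- ang$phi
  }
  out <- orientation_field(theta, phi, valid, shg$voxel_size, axes = axes)
  out$coherence <- array(linear, d)
  out
}

#' Windowed 3D directional variance of an orientation field
#'
#' Over the valid orientations `u_i` inside each window, the mean dyadic
#' `T = mean(u_i u_i')` is formed and `V = (3/2)(1 - lambda_max(T))`,
#' clipped to `[0, 1]`: 0 for perfectly parallel fibers, 1 for completely
#' random organization. Windows are truncated at stack borders; voxels with
#' fewer than `min_count` valid orientations in the window are invalid.
#'
#' @param orient an [orientation_field()].
#' @param window_um window in um `(z, y, x)`, default 5 x 5.3 x 5.3.
#' @param min_count minimum valid orientations per window (default 4).
#' @return list of class `variance_map`: `V` array, `valid`, `window_um`.
#' @export
directional_variance <- function(orient, window_um = c(5, 5.3, 5.3),
                                 min_count = 4L) {
  stopifnot(inherits(orient, "orientation_field"))
  if (!any(orient$valid)) stop("orientation field has no valid voxels")
  d <- dim(orient$theta)
  n <- window_voxels(window_um, orient$voxel_size)
  half <- (n - 1L) %/% 2L
  ax <- ifelse(is.na(orient$ax), 0, orient$ax)
  ay <- ifelse(is.na(orient$ay), 0, orient$ay)
  az <- ifelse(is.na(orient$az), 0, orient$az)
  res <- cpp_directional_variance(as.vector(ax), as.vector(ay),
                                  as.vector(az),
                                  as.logical(orient$valid), as.integer(d),
                                  half, as.integer(min_count))
  structure(list(V = array(res$V, d), valid = array(res$valid, d),
                 window_um = window_um),
            class = "variance_map")
}

#' Mean directional variance per cartilage zone
#'
#' @param vmap a `variance_map` from [directional_variance()].
#' @param zones zone label array (integer codes with a `levels` attribute, as
#'   returned by [generate_cartilage_phantom()] or [segment_zones()]).
#' @return data.frame with `zone`, `mean_variance`, `n_voxels`; zones with no
#'   valid voxel carry `NA` and are flagged in the `missing` column.
#' @export
zone_mean_variance <- function(vmap, zones) {
  stopifnot(inherits(vmap, "variance_map"),
            identical(dim(zones), dim(vmap$V)))
  levels <- attr(zones, "levels")
  if (is.null(levels)) levels <- ZONE_LEVELS
  codes <- sort(unique(as.vector(zones)))
  codes <- codes[codes > 0]
  out <- data.frame(zone = levels[codes + 1L], mean_variance = NA_real_,
                    n_voxels = 0L, missing = TRUE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(codes)) {
    sel <- zones == codes[i] & vmap$valid
    out$n_voxels[i] <- sum(sel)
    if (out$n_voxels[i] > 0) {
      out$mean_variance[i] <- mean(vmap$V[sel])
      out$missing[i] <- FALSE
    }
  }
  out
}
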