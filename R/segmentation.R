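# Surface alignment, zonal segmentation along depth, and matrix / cell /
# cytoplasm compartment masks.

#' Otsu threshold of a set of intensities
#'
#' Histogram-based between-class variance maximization; used for the
#' SHG matrix/cell split so masks are invariant to positive rescaling up to
#' binning.
#'
#' @param x numeric vector.
#' @param nbins histogram bins.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = nbins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

rotate_plane <- function(mat, angle_deg, vy = 1, vx = 1, fill = 0) {
  # rotate image content by angle_deg (positive tilts a horizontal line to
  # slope +tan(angle) in (x, y-down) pixel coordinates); bilinear sampling
  a <- angle_deg * pi / 180
  ny <- nrow(mat); nx <- ncol(mat)
  cy <- (ny + 1) / 2 * vy; cx <- (nx + 1) / 2 * vx
  yo <- ((seq_len(ny)) * vy - cy)
  xo <- ((seq_len(nx)) * vx - cx)
  Y <- matrix(yo, ny, nx); X <- matrix(xo, ny, nx, byrow = TRUE)
  # inverse map: source = R(-a) . target
  xs <- (cos(a) * X + sin(a) * Y + cx) / vx
  ys <- (-sin(a) * X + cos(a) * Y + cy) / vy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  get <- function(yy, xx) {
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    v <- matrix(fill, ny, nx)
    v[ok] <- mat[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- get(y0, x0); v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0); v11 <- get(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Rotate a stack in the imaging plane
#'
#' Each z slice is rotated by `angle_deg` about the field center (bilinear
#' interpolation, zero fill); positive angles tilt a horizontal surface line
#' to positive slope in (x, depth) coordinates.
#'
#' @param img a [volumetric_image()].
#' @param angle_deg rotation angle, degrees.
#' @return rotated `volumetric_image`.
#' @export
rotate_stack <- function(img, angle_deg) {
  stopifnot(inherits(img, "volumetric_image"))
  arr <- img$intensities
  for (z in seq_len(dim(arr)[1]))
    arr[z, , ] <- rotate_plane(img$intensities[z, , ],
                               angle_deg, img$voxel_size[2], img$voxel_size[3])
  img$intensities <- array(pmax(arr, 0), dim(arr))
  img
}

#' Align the articular surface horizontally
#'
#' The shallow boundary of the SHG-positive region is located per image
#' column on the z-mean projection, a line is fitted to the boundary, and the
#' stack is rotated so the surface is horizontal.
#'
#' @param shg SHG [volumetric_image()].
#' @param min_contrast required foreground/background mean-intensity ratio;
#'   below it the stack is declared to have no SHG-positive region.
#' @return list with `img` (aligned stack) and `angle` (the correction
#'   rotation applied, degrees).
#' @export
align_surface <- function(shg, min_contrast = 2) {
  stopifnot(inherits(shg, "volumetric_image"))
  proj <- apply(shg$intensities, c(2, 3), mean)
  thr <- otsu_threshold(as.vector(proj))
  fg <- proj > thr
  if (!any(fg) || all(fg))
    stop("no SHG-positive region found")
  contrast <- mean(proj[fg]) / max(mean(proj[!fg]), .Machine$double.eps)
  if (contrast < min_contrast)
    stop("no SHG-positive region found (insufficient contrast)")
  surf <- apply(fg, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  ok <- !is.na(surf)
  if (mean(ok) < 0.5) stop("articular surface not traceable across the field")
  # central columns only (the rotated surface distorts near the frame), with
  # a Theil-Sen slope so sparse-fiber detection noise does not bias the fit
  nx <- length(surf)
  trim <- ok & seq_along(surf) > 0.1 * nx & seq_along(surf) <= 0.9 * nx
  x <- which(trim); y <- surf[trim]
  n <- length(x)
  idx <- utils::combn(min(n, n), 2)
  slopes <- (y[idx[2, ]] - y[idx[1, ]]) / (x[idx[2, ]] - x[idx[1, ]])
  slope <- stats::median(slopes)
  slope_phys <- slope * shg$voxel_size[2] / shg$voxel_size[3]
  angle <- atan(slope_phys) * 180 / pi
  aligned <- rotate_stack(shg, -angle)
  list(img = aligned, angle = as.numeric(-angle))
}

axial_dist <- function(theta, ref) {
  d <- abs(theta - ref) %% 180
  pmin(d, 180 - d)
}

#' Segment cartilage into depth zones from fiber alignment and the endplate
#'
#' On a surface-aligned stack, the per-row circular median of the in-plane
#' fiber angle classifies depth rows: superficial where the angle is within
#' `angle_tol_deg` of the surface direction (0/180 deg), radial where within
#' tolerance of 90 deg, transitional in between; the calcified zone starts at
#' the deepest contiguous dark row band (row mean SHG `< endplate_factor x`
#' cartilage median), the endplate. Labels are per depth row, yielding
#' depth-ordered bands.
#'
#' @param shg surface-aligned SHG [volumetric_image()].
#' @param orient matching [orientation_field()].
#' @param overrides optional zone label array replacing the automatic result.
#' @param angle_tol_deg angular tolerance (default 25 deg).
#' @param endplate_factor endplate darkness factor (default 0.2).
#' @return integer zone array (codes 0-4, `levels` attribute) with attribute
#'   `flags` listing absent zones.
#' @export
segment_zones <- function(shg, orient, overrides = NULL,
                          angle_tol_deg = 25, endplate_factor = 0.2) {
  d <- dim(shg$intensities)
  if (!is.null(overrides)) {
    stopifnot(identical(dim(overrides), d))
    return(structure(overrides, levels = ZONE_LEVELS, flags = character()))
  }
  stopifnot(inherits(orient, "orientation_field"),
            identical(dim(orient$theta), d))
  row_mean <- apply(shg$intensities, 2, mean)
  cart <- which(row_mean > 0.02 * max(row_mean))
  if (!length(cart)) stop("no cartilage rows found")
  y_first <- cart[1]; y_last <- cart[length(cart)]
  rows <- y_first:y_last
  med <- stats::median(row_mean[rows])
  dark <- row_mean[rows] < endplate_factor * med
  # the endplate is an interior dark line: require SHG-positive rows below
  # it, so dim rows touching the stack borders are not mistaken for it
  calc_start <- NA_integer_
  runs <- rle(dark)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & ends < length(rows) & starts > 1L)
  if (length(cand)) calc_start <- rows[starts[cand[length(cand)]]]
  upper_rows <- if (is.na(calc_start)) rows else rows[rows < calc_start]
  # exclude stack-edge voxels from the row medians: windowed estimates are
  # truncated there and unreliable (same margin as the phantom core truth)
  inner <- array(FALSE, d)
  zi <- pmin(d[1], 3L):max(1L, d[1] - 2L)
  xi <- pmin(d[3], 5L):max(1L, d[3] - 4L)
  inner[zi, , xi] <- TRUE
  cls <- rep(NA_character_, length(upper_rows))
  for (i in seq_along(upper_rows)) {
    y <- upper_rows[i]
    sel <- orient$valid[, y, ] & inner[, y, ]
    if (sum(sel) < 5) next                       # too sparse to classify
    u <- cbind(orient$ax[, y, ][sel], orient$ay[, y, ][sel],
               orient$az[, y, ][sel])
    # axial average of the row: principal eigenvector of the mean dyadic
    # (robust where a scalar median of the folded angle is not)
    e <- eigen(crossprod(u) / nrow(u), symmetric = TRUE)
    m <- atan2(abs(e$vectors[2, 1]), abs(e$vectors[1, 1])) * 180 / pi
    cls[i] <- if (axial_dist(m, 0) <= angle_tol_deg) "superficial"
      else if (axial_dist(m, 90) <= angle_tol_deg) "radial"
      else "transitional"
  }
  # sparse rows inherit the nearest classified row's label
  if (anyNA(cls) && !all(is.na(cls))) {
    known <- which(!is.na(cls))
    for (i in which(is.na(cls)))
      cls[i] <- cls[known[which.min(abs(known - i))]]
  } else if (all(is.na(cls))) cls <- rep("transitional", length(cls))
  flags <- character()
  # enforce depth-ordered bands: leading superficial run, trailing radial
  # run, transitional between
  sup_end <- 0L
  if (length(cls) && cls[1] == "superficial")
    sup_end <- rle(cls)$lengths[1]
  else flags <- c(flags, "superficial zone absent")
  rad_start <- length(cls) + 1L
  if (length(cls) && cls[length(cls)] == "radial") {
    r <- rle(cls)
    rad_start <- length(cls) - r$lengths[length(r$lengths)] + 1L
  } else if (!is.na(calc_start) || length(cls)) {
    if (!any(cls == "radial")) flags <- c(flags, "radial zone absent")
    rad_start <- if (any(cls == "radial")) max(which(cls == "radial")) + 1L else length(cls) + 1L
  }
  zones <- array(0L, d)
  code <- stats::setNames(seq_along(ZONE_LEVELS[-1]), ZONE_LEVELS[-1])
  for (i in seq_along(upper_rows)) {
    lab <- if (i <= sup_end) "superficial"
      else if (i >= rad_start) "radial" else "transitional"
    zones[, upper_rows[i], ] <- code[[lab]]
  }
  if (!any(zones == code[["transitional"]]))
    flags <- c(flags, "transitional zone absent")
  if (!is.na(calc_start)) {
    zones[, calc_start:y_last, ] <- code[["calcified"]]
  } else flags <- c(flags, "calcified zone absent (no endplate)")
  structure(zones, levels = ZONE_LEVELS, flags = flags)
}

#' Matrix, cell and cytoplasm compartment masks
#'
#' Matrix is the SHG-bright compartment (Otsu threshold within the cartilage
#' region); cells are the remaining cartilage voxels; the cytoplasm-only mask
#' keeps cell voxels whose NAD(P)H intensity lies strictly between the
#' nucleus-rejection percentile (dark nuclei) and the lipofuscin-rejection
#' percentile (bright granules) of the cell NAD(P)H distribution.
#'
#' @param shg SHG [volumetric_image()] or `NULL` when the whole field is
#'   cellular (no matrix compartment, e.g. sections cut parallel to the
#'   surface).
#' @param nadh NAD(P)H [volumetric_image()].
#' @param zones optional zone label array restricting the cartilage region.
#' @param nucleus_percentile,lipofuscin_percentile percentile cuts (defaults
#'   20 and 98).
#' @return list of class `compartment_masks`: `matrix_mask`, `cell_mask`,
#'   `cytoplasm_mask` logical arrays.
#' @export
compartment_masks <- function(shg, nadh, zones = NULL,
                              nucleus_percentile = 20,
                              lipofuscin_percentile = 98) {
  stopifnot(inherits(nadh, "volumetric_image"))
  d <- dim(nadh$intensities)
  cartilage <- if (is.null(zones)) array(TRUE, d) else zones > 0
  if (is.null(shg)) {
    matrix_mask <- array(FALSE, d)
  } else {
    stopifnot(identical(dim(shg$intensities), d))
    thr <- otsu_threshold(shg$intensities[cartilage])
    matrix_mask <- cartilage & shg$intensities >= thr
  }
  cell_mask <- cartilage & !matrix_mask
  if (!any(cell_mask)) stop("empty cell region")
  cell_nadh <- nadh$intensities[cell_mask]
  q <- stats::quantile(cell_nadh,
                       c(nucleus_percentile, lipofuscin_percentile) / 100)
  cytoplasm_mask <- cell_mask & nadh$intensities > q[1] &
    nadh$intensities < q[2]
  structure(list(matrix_mask = matrix_mask, cell_mask = cell_mask,
                 cytoplasm_mask = cytoplasm_mask),
            class = "compartment_masks")
}
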