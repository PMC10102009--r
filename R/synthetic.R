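# Phantom generators with known ground truth for every pipeline stage:
# fibrous SHG volumes, zoned cartilage stacks, bi-exponential TCSPC cubes,
# and two-channel metabolic cell fields.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

# separable convolution of a 3D array along one axis, zero-padded edges
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  p <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, p)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  h <- (length(kernel) - 1L) / 2L
  mp <- rbind(matrix(0, h, ncol(m)), m, matrix(0, h, ncol(m)))
  f <- stats::filter(mp, kernel, sides = 2)
  f <- f[(h + 1L):(h + da[1]), , drop = FALSE]
  aperm(array(as.numeric(f), da), order(p))
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Blur a 3D array with an anisotropic Gaussian
#'
#' @param arr array `(z, y, x)`.
#' @param sigma_vox standard deviations in voxels, `(z, y, x)`; zero skips an
#'   axis.
#' @return blurred array, zero-padded boundaries.
#' @export
gaussian_blur3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0)
      arr <- conv_axis(arr, gaussian_kernel(sigma_vox[ax]), ax)
  }
  arr
}

#' Specification of a synthetic fibrous SHG volume
#'
#' Straight cylindrical fibers with axes drawn from a von Mises-Fisher
#' distribution (folded to axial form), rasterized on the voxel grid, blurred
#' by an anisotropic Gaussian PSF and optionally Poisson-sampled.
#'
#' @param volume_shape voxels `(z, y, x)`.
#' @param voxel_size micrometers per axis `(z, y, x)`; default mirrors
#'   512 px / 386 um lateral sampling with a 1 um axial step.
#' @param n_fibers number of fibers.
#' @param fiber_radius fiber radius, um; the default 1 um diameter-2 um fiber
#'   sits at the top of the typical 1-2 um collagen fiber diameter range.
#' @param mean_axis mean fiber axis `(x, y, z)`.
#' @param kappa orientation concentration (`>= 0`; 0 = uniform axes, `Inf` =
#'   single fixed axis).
#' @param psf_sigma Gaussian PSF sigma in um, `(z, y, x)`.
#' @param photon_scale expected peak photon count of a fiber core.
#' @param poisson Poisson-sample the blurred expectation.
#' @param seed RNG seed.
#' @return list of class `fiber_spec`.
#' @export
fiber_spec <- function(volume_shape = c(16L, 64L, 64L),
                       voxel_size = c(1, 0.754, 0.754),
                       n_fibers = 30L, fiber_radius = 1.0,
                       mean_axis = c(1, 0, 0), kappa = 20,
                       psf_sigma = c(1.0, 0.4, 0.4),
                       photon_scale = 100, poisson = TRUE, seed = 1L) {
  stopifnot(all(volume_shape > 0), all(voxel_size > 0), n_fibers >= 1,
            fiber_radius > 0, photon_scale > 0)
  if (kappa < 0) stop("kappa must be >= 0")
  if (fiber_radius < max(voxel_size[2:3]))
    stop("fiber radius smaller than one lateral voxel: unresolvable")
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size = voxel_size, n_fibers = as.integer(n_fibers),
                 fiber_radius = fiber_radius, mean_axis = mean_axis,
                 kappa = kappa, psf_sigma = psf_sigma,
                 photon_scale = photon_scale, poisson = poisson, seed = seed),
            class = "fiber_spec")
}

rasterize_fibers <- function(shape, voxel_size, centers, axes, radius,
                             photon_scale) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  zc <- (seq_len(nz) - 0.5) * voxel_size[1]
  yc <- (seq_len(ny) - 0.5) * voxel_size[2]
  xc <- (seq_len(nx) - 0.5) * voxel_size[3]
  # voxel center coordinates in (x, y, z), array index order (z, y, x)
  X <- rep(xc, each = nz * ny)
  Y <- rep(rep(yc, each = nz), times = nx)
  Z <- rep(zc, times = ny * nx)
  inten <- numeric(nz * ny * nx)
  dmin <- rep(Inf, nz * ny * nx)
  owner <- integer(nz * ny * nx)
  r2 <- radius^2
  for (i in seq_len(nrow(centers))) {
    u <- axes[i, ]
    wx <- X - centers[i, 1]; wy <- Y - centers[i, 2]; wz <- Z - centers[i, 3]
    t <- wx * u[1] + wy * u[2] + wz * u[3]
    d2 <- pmax(0, wx^2 + wy^2 + wz^2 - t^2)
    inside <- d2 <= r2
    inten[inside] <- inten[inside] + photon_scale
    upd <- inside & d2 < dmin
    dmin[upd] <- d2[upd]
    owner[upd] <- i
  }
  list(intensity = array(inten, shape), owner = array(owner, shape),
       dmin = array(sqrt(dmin), shape))
}

#' Generate a synthetic fibrous SHG stack with orientation ground truth
#'
#' @param spec a [fiber_spec()].
#' @return list with `shg` (a [volumetric_image()]) and `truth`, an
#'   [orientation_field()] holding the generating fiber's axis per fiber
#'   voxel (background invalid) plus `core` (voxels within half the fiber
#'   radius of an axis, away from the volume faces) and `axes` (the sampled
#'   fiber axes, `n_fibers x 3`).
#' @export
generate_fiber_stack <- function(spec) {
  stopifnot(inherits(spec, "fiber_spec"))
  with_seed(spec$seed, {
    shape <- spec$volume_shape
    ext <- shape * spec$voxel_size          # (z, y, x) extent in um
    axes <- sample_axes(spec$n_fibers, spec$mean_axis, spec$kappa)
    centers <- cbind(stats::runif(spec$n_fibers, 0, ext[3]),
                     stats::runif(spec$n_fibers, 0, ext[2]),
                     stats::runif(spec$n_fibers, 0, ext[1]))  # (x, y, z)
    ras <- rasterize_fibers(shape, spec$voxel_size, centers, axes,
                            spec$fiber_radius, spec$photon_scale)
    expected <- gaussian_blur3d(ras$intensity, spec$psf_sigma / spec$voxel_size)
    counts <- if (spec$poisson) {
      array(stats::rpois(length(expected), pmax(expected, 0)), shape)
    } else array(pmax(expected, 0), shape)
    valid <- ras$owner > 0L
    theta <- array(NA_real_, shape); phi <- array(NA_real_, shape)
    vox_axes <- axes[ras$owner[valid], , drop = FALSE]
    if (any(valid)) {
      ang <- axes_to_angles(vox_axes)
      theta[valid] <- ang$theta
      phi[valid] <- ang$phi
    }
    shg <- volumetric_image(counts, spec$voxel_size, channel = "SHG")
    # core ground truth: voxels within half a radius of a fiber axis, away
    # from the volume faces where any windowed estimator has truncated
    # support (edge effects are not part of the stated truth)
    margin <- c(2L, 4L, 4L)
    interior <- array(FALSE, shape)
    interior[pmin(shape[1], margin[1] + 1L):max(1L, shape[1] - margin[1]),
             pmin(shape[2], margin[2] + 1L):max(1L, shape[2] - margin[2]),
             pmin(shape[3], margin[3] + 1L):max(1L, shape[3] - margin[3])] <- TRUE
    truth <- orientation_field(theta, phi, valid, spec$voxel_size,
                               axes = vox_axes)
    # core radius: half the fiber radius, but never below ~the half-diagonal
    # of a lateral voxel, so the nearest voxel column to every axis counts
    core_r <- max(spec$fiber_radius / 2, 0.71 * max(spec$voxel_size[2:3]))
    truth$core <- valid & ras$dmin <= core_r & interior
    truth$axes <- axes
    list(shg = shg, truth = truth)
  })
}

ZONE_LEVELS <- c("background", "superficial", "transitional", "radial",
                 "calcified")

#' Specification of a zoned cartilage phantom
#'
#' Depth bands along y mimic the zonal anatomy: superficial fibers parallel
#' to the articular surface (+x), transitional broadly dispersed, radial and
#' calcified fibers perpendicular to the surface (+y), with a dark endplate
#' band at the top of the calcified zone.
#'
#' @param volume_shape voxels `(z, y, x)`.
#' @param voxel_size um per axis.
#' @param zone_fractions named depth fractions (must sum to 1) of the
#'   cartilage region for superficial/transitional/radial/calcified.
#' @param surface_margin_rows empty rows above the articular surface.
#' @param surface_lamina_rows rows of dense SHG at the articular surface
#'   (the bright continuous boundary real cartilage presents).
#' @param endplate_rows rows of the dark endplate band.
#' @param endplate_attenuation SHG attenuation factor within the endplate.
#' @param kappas per-zone orientation concentration.
#' @param fiber_density fibers per 1000 voxels of a zone band.
#' @param fiber_radius,photon_scale,psf_sigma,poisson,seed as [fiber_spec()].
#' @return list of class `cartilage_spec`.
#' @export
cartilage_spec <- function(volume_shape = c(12L, 96L, 64L),
                           voxel_size = c(1, 0.754, 0.754),
                           zone_fractions = c(superficial = 0.15,
                                              transitional = 0.25,
                                              radial = 0.45,
                                              calcified = 0.15),
                           surface_margin_rows = 6L,
                           surface_lamina_rows = 2L,
                           endplate_rows = 3L,
                           endplate_attenuation = 0.05,
                           kappas = c(superficial = 40, transitional = 1,
                                      radial = 40, calcified = 40),
                           fiber_density = 0.6,
                           fiber_radius = 1.0, photon_scale = 100,
                           psf_sigma = c(1.0, 0.4, 0.4),
                           poisson = TRUE, seed = 1L) {
  if (abs(sum(zone_fractions) - 1) > 1e-8)
    stop("zone depth fractions must sum to 1")
  stopifnot(setequal(names(zone_fractions), ZONE_LEVELS[-1]),
            surface_margin_rows >= 0, endplate_rows >= 1)
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size = voxel_size, zone_fractions = zone_fractions,
                 surface_margin_rows = as.integer(surface_margin_rows),
                 surface_lamina_rows = as.integer(surface_lamina_rows),
                 endplate_rows = as.integer(endplate_rows),
                 endplate_attenuation = endplate_attenuation,
                 kappas = kappas, fiber_density = fiber_density,
                 fiber_radius = fiber_radius, photon_scale = photon_scale,
                 psf_sigma = psf_sigma, poisson = poisson, seed = seed),
            class = "cartilage_spec")
}

#' Generate a zoned cartilage SHG phantom with a zone-label ground truth
#'
#' @param spec a [cartilage_spec()].
#' @return list with `shg` ([volumetric_image()]), `zones` (integer array of
#'   zone codes 0-4, `levels` attribute giving the zone names), and
#'   `meta` (band row ranges, `thin_zone_warning` flag).
#' @export
generate_cartilage_phantom <- function(spec) {
  stopifnot(inherits(spec, "cartilage_spec"))
  with_seed(spec$seed, {
    shape <- spec$volume_shape
    nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
    cart_rows <- ny - spec$surface_margin_rows
    fr <- spec$zone_fractions[ZONE_LEVELS[-1]]
    rows <- floor(cart_rows * fr)
    rows[length(rows)] <- cart_rows - sum(rows[-length(rows)])
    mean_axes <- list(superficial = c(1, 0, 0), transitional = c(0, 1, 0),
                      radial = c(0, 1, 0), calcified = c(0, 1, 0))
    inten <- array(0, shape)
    zones <- array(0L, shape)
    y0 <- spec$surface_margin_rows
    bands <- list()
    for (zi in seq_along(rows)) {
      zname <- names(rows)[zi]
      band_ny <- rows[[zi]]
      if (band_ny < 1L) next
      band_shape <- c(nz, band_ny, nx)
      n_fib <- max(2L, round(spec$fiber_density * prod(band_shape) / 1000))
      fs <- fiber_spec(volume_shape = band_shape,
                       voxel_size = spec$voxel_size,
                       n_fibers = n_fib, fiber_radius = spec$fiber_radius,
                       mean_axis = mean_axes[[zname]],
                       kappa = spec$kappas[[zname]],
                       psf_sigma = spec$psf_sigma,
                       photon_scale = spec$photon_scale,
                       poisson = FALSE,
                       seed = NULL)     # inherit the outer RNG stream
      sub <- generate_fiber_stack(fs)
      yr <- (y0 + 1L):(y0 + band_ny)
      inten[, yr, ] <- sub$shg$intensities
      zones[, yr, ] <- zi
      bands[[zname]] <- c(first = y0 + 1L, last = y0 + band_ny)
      y0 <- y0 + band_ny
    }
    # dense articular surface lamina at the top of the superficial band
    if (spec$surface_lamina_rows > 0L) {
      lam <- (spec$surface_margin_rows + 1L):
        (spec$surface_margin_rows + spec$surface_lamina_rows)
      inten[, lam, ] <- spec$photon_scale
    }
    # dark endplate: top rows of the calcified band
    cb <- bands[["calcified"]]
    ep <- cb["first"]:min(cb["last"], cb["first"] + spec$endplate_rows - 1L)
    inten[, ep, ] <- inten[, ep, ] * spec$endplate_attenuation
    if (spec$poisson)
      inten <- array(stats::rpois(length(inten), pmax(0, inten)), shape)
    win_rows <- ceiling(5.3 / spec$voxel_size[2])
    thin <- any(rows < win_rows)
    if (thin) warning("zone thinner than one analysis window")
    shg <- volumetric_image(inten, spec$voxel_size, channel = "SHG")
    zones <- structure(zones, levels = ZONE_LEVELS)
    list(shg = shg, zones = zones,
         meta = list(bands = bands, endplate_rows = ep,
                     thin_zone_warning = thin))
  })
}

#' Specification of a bi-exponential TCSPC decay cube
#'
#' @param image_shape pixels `(y, x)`.
#' @param tau_short,tau_long component lifetimes, ns (`0 < short < long <
#'   rep_period`).
#' @param f_long_map per-pixel long-component intensity fraction in `[0, 1]`
#'   (scalar recycled).
#' @param n_bins number of time bins (`>= 8`).
#' @param rep_period repetition period, ns.
#' @param total_counts expected photons per pixel.
#' @param poisson Poisson-sample the expected decays.
#' @param seed RNG seed.
#' @return list of class `decay_spec`.
#' @export
decay_spec <- function(image_shape = c(32L, 32L), tau_short = 0.4,
                       tau_long = 3.0, f_long_map = 0.5, n_bins = 256L,
                       rep_period = 12.5, total_counts = 1e4,
                       poisson = TRUE, seed = 1L) {
  if (!(tau_short > 0 && tau_short < tau_long && tau_long < rep_period))
    stop("need 0 < tau_short < tau_long < rep_period")
  if (n_bins < 8L) stop("n_bins < 8: phasor ill-conditioned")
  if (is.matrix(f_long_map)) {
    stopifnot(all(dim(f_long_map) == image_shape))
  } else {
    f_long_map <- matrix(f_long_map, image_shape[1], image_shape[2])
  }
  if (any(f_long_map < 0 | f_long_map > 1)) stop("f_long_map outside [0, 1]")
  structure(list(image_shape = as.integer(image_shape),
                 tau_short = tau_short, tau_long = tau_long,
                 f_long_map = f_long_map, n_bins = as.integer(n_bins),
                 rep_period = rep_period, total_counts = total_counts,
                 poisson = poisson, seed = seed),
            class = "decay_spec")
}

bin_probs <- function(tau, n_bins, bin_width) {
  edges <- (0:n_bins) * bin_width
  p <- exp(-edges[-length(edges)] / tau) - exp(-edges[-1] / tau)
  p / sum(p)
}

#' Generate a bi-exponential decay cube with a known fraction map
#'
#' Per-pixel expected decay `A[f exp(-t/tau_long) + (1-f) exp(-t/tau_short)]`
#' integrated over bins (so expected total photons equal `total_counts`),
#' optionally Poisson-sampled.
#'
#' @param spec a [decay_spec()].
#' @return list with `cube` ([decay_cube()]) and `truth` (`f_long_map`).
#' @export
generate_decay_cube <- function(spec) {
  stopifnot(inherits(spec, "decay_spec"))
  with_seed(spec$seed, {
    ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
    bw <- spec$rep_period / spec$n_bins
    pl <- bin_probs(spec$tau_long, spec$n_bins, bw)
    ps <- bin_probs(spec$tau_short, spec$n_bins, bw)
    f <- as.vector(spec$f_long_map)               # length ny*nx
    # expected counts: n_bins x (ny*nx)
    exp_counts <- spec$total_counts *
      (outer(pl, f) + outer(ps, 1 - f))
    counts <- if (spec$poisson) {
      matrix(stats::rpois(length(exp_counts), exp_counts), nrow = spec$n_bins)
    } else exp_counts
    cube <- decay_cube(array(counts, c(spec$n_bins, ny, nx)), bw,
                       spec$rep_period, poisson = spec$poisson)
    list(cube = cube, truth = spec$f_long_map)
  })
}

#' Synthesize a texture with a prescribed inverse-power-law PSD
#'
#' White Gaussian noise is shaped in the frequency domain by the amplitude
#' filter `k^(-beta/2)` (DC zeroed), so the expected power spectral density
#' is proportional to `k^-beta`; the result is standardized to zero mean,
#' unit variance.
#'
#' @param shape `(ny, nx)` pixels.
#' @param beta power-law exponent (`0` = white noise).
#' @return numeric matrix `ny x nx`.
#' @export
synthesize_psd_texture <- function(shape, beta) {
  ny <- shape[1]; nx <- shape[2]
  w <- matrix(stats::rnorm(ny * nx), ny, nx)
  ky <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  kx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  k <- sqrt(outer(ky^2, kx^2, "+"))
  amp <- ifelse(k > 0, k^(-beta / 2), 0)
  f <- stats::fft(w) * amp
  tex <- Re(stats::fft(f, inverse = TRUE)) / (ny * nx)
  (tex - mean(tex)) / stats::sd(tex)
}

#' Specification of a two-channel metabolic cell field
#'
#' @param image_shape pixels `(y, x)`.
#' @param pixel_size um per pixel.
#' @param n_cells number of cells.
#' @param cell_radius,nucleus_radius radii, um (`nucleus < cell`).
#' @param rr_per_cell target per-cell redox ratio in `(0, 1)`; scalar or
#'   length `n_cells`.
#' @param beta_true PSD power-law exponent of the cytoplasmic texture.
#' @param lipofuscin_density fraction of cell pixels carrying a bright
#'   lipofuscin speckle.
#' @param cytoplasm_mean,cytoplasm_sd NAD(P)H cytoplasm intensity moments.
#' @param seed RNG seed.
#' @return list of class `cell_field_spec`.
#' @export
cell_field_spec <- function(image_shape = c(128L, 128L), pixel_size = 0.754,
                            n_cells = 8L, cell_radius = 10, nucleus_radius = 3,
                            rr_per_cell = 0.4, beta_true = 1.5,
                            lipofuscin_density = 0.005,
                            cytoplasm_mean = 100, cytoplasm_sd = 20,
                            seed = 1L) {
  if (nucleus_radius >= cell_radius)
    stop("nucleus_radius must be smaller than cell_radius")
  rr <- rep_len(rr_per_cell, n_cells)
  if (any(rr <= 0 | rr >= 1))
    stop("rr_per_cell must lie strictly inside (0, 1)")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, n_cells = as.integer(n_cells),
                 cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 rr_per_cell = rr, beta_true = beta_true,
                 lipofuscin_density = lipofuscin_density,
                 cytoplasm_mean = cytoplasm_mean, cytoplasm_sd = cytoplasm_sd,
                 seed = seed),
            class = "cell_field_spec")
}

#' Generate a two-channel metabolic cell field with ground-truth masks
#'
#' NAD(P)H cytoplasm carries a texture with PSD exponent `beta_true`; nuclei
#' are dark, lipofuscin speckles are >= 10x the cytoplasm median, and the
#' FAD channel is constructed per cell as `NADH * rr / (1 - rr)` so that the
#' pixelwise redox ratio FAD/(NADH+FAD) equals `rr` on noise-free cytoplasm
#' pixels.
#'
#' @param spec a [cell_field_spec()].
#' @return list with `nadh`, `fad` ([volumetric_image()], z = 1), `masks`
#'   (`cell`, `nucleus`, `lipofuscin`, `cytoplasm` logical matrices) and
#'   `truth` (`rr` per cell, `rr_map`, `beta`).
#' @export
generate_metabolic_field <- function(spec) {
  stopifnot(inherits(spec, "cell_field_spec"))
  with_seed(spec$seed, {
    ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
    px <- spec$pixel_size
    tex <- synthesize_psd_texture(c(ny, nx), spec$beta_true)
    cyto_int <- pmax(1, spec$cytoplasm_mean + spec$cytoplasm_sd * tex)
    yy <- matrix((seq_len(ny) - 0.5) * px, ny, nx)
    xx <- matrix((seq_len(nx) - 0.5) * px, ny, nx, byrow = TRUE)
    cell_mask <- matrix(FALSE, ny, nx)
    nucleus_mask <- matrix(FALSE, ny, nx)
    cell_id <- matrix(0L, ny, nx)
    ext <- c(ny, nx) * px
    r <- spec$cell_radius
    centers <- matrix(NA_real_, spec$n_cells, 2)
    for (i in seq_len(spec$n_cells)) {
      for (try in 1:200) {
        cy <- stats::runif(1, r, ext[1] - r)
        cx <- stats::runif(1, r, ext[2] - r)
        if (i == 1 || all((centers[seq_len(i - 1), 1] - cy)^2 +
                          (centers[seq_len(i - 1), 2] - cx)^2 > (2 * r)^2))
          break
      }
      centers[i, ] <- c(cy, cx)
      d2 <- (yy - cy)^2 + (xx - cx)^2
      inside <- d2 <= r^2
      cell_mask <- cell_mask | inside
      cell_id[inside] <- i
      nucleus_mask <- nucleus_mask | (d2 <= spec$nucleus_radius^2)
    }
    nadh <- matrix(spec$cytoplasm_mean * 0.1, ny, nx)     # dim intercellular
    nadh[cell_mask] <- cyto_int[cell_mask]
    nadh[nucleus_mask] <- spec$cytoplasm_mean * 0.05      # dark nuclei
    cyto_truth <- cell_mask & !nucleus_mask
    lip_mask <- matrix(FALSE, ny, nx)
    n_lip <- round(spec$lipofuscin_density * sum(cell_mask))
    if (n_lip > 0) {
      cand <- which(cyto_truth)
      lip_px <- sample(cand, min(n_lip, length(cand)))
      lip_mask[lip_px] <- TRUE
      nadh[lip_mask] <- 12 * stats::median(nadh[cyto_truth])
    }
    rr_map <- matrix(0.5, ny, nx)                         # background filler
    for (i in seq_len(spec$n_cells))
      rr_map[cell_id == i] <- spec$rr_per_cell[i]
    fad <- nadh * rr_map / (1 - rr_map)
    vs <- c(1, px, px)
    list(nadh = volumetric_image(nadh, vs, channel = "NADH"),
         fad = volumetric_image(fad, vs, channel = "FAD"),
         masks = list(cell = cell_mask, nucleus = nucleus_mask,
                      lipofuscin = lip_mask,
                      cytoplasm = cyto_truth & !lip_mask),
         truth = list(rr = spec$rr_per_cell, rr_map = rr_map,
                      beta = spec$beta_true))
  })
}
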