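# Cellular metabolic metrics: optical redox ratio FAD/(NAD(P)H+FAD) and the
# mitochondrial clustering exponent beta from the radially averaged power
# spectral density of clone-stamped NAD(P)H images.

#' Optical redox ratio map
#'
#' Per-pixel `RR = FAD / (NADH + FAD)` over the cytoplasm mask; pixels with
#' zero channel sum are excluded and counted. The summary is the mean over
#' the mask.
#'
#' @param nadh,fad co-registered, consistently power-normalized
#'   [volumetric_image()]s.
#' @param cytoplasm_mask logical array.
#' @return list of class `redox_result`: `rr_map` (NA off-mask), `mean_rr`,
#'   `n_excluded`.
#' @export
redox_map <- function(nadh, fad, cytoplasm_mask) {
  stopifnot(inherits(nadh, "volumetric_image"),
            inherits(fad, "volumetric_image"),
            identical(dim(nadh$intensities), dim(fad$intensities)),
            identical(dim(nadh$intensities), dim(cytoplasm_mask)))
  if (!any(cytoplasm_mask)) stop("empty cytoplasm mask")
  total <- nadh$intensities + fad$intensities
  ok <- cytoplasm_mask & total > 0
  rr <- array(NA_real_, dim(total))
  rr[ok] <- fad$intensities[ok] / total[ok]
  if (!any(ok)) stop("all masked pixels have zero NADH+FAD")
  structure(list(rr_map = rr, mean_rr = mean(rr[ok]),
                 n_excluded = sum(cytoplasm_mask) - sum(ok)),
            class = "redox_result")
}

tile_grid <- function(n, tile) {
  starts <- seq(1L, n, by = tile)
  cbind(start = starts, end = pmin(starts + tile - 1L, n))
}

#' Clone-stamp cytoplasm texture over nuclei and intercellular regions
#'
#' Fully-cytoplasmic square tiles are sampled at random and pasted over the
#' non-cytoplasm pixels of a 2D plane, leaving cytoplasm pixels untouched,
#' so the result carries only mitochondrial (cytoplasmic) intensity patterns
#' without cell or nuclear borders.
#'
#' @param plane numeric matrix (one NAD(P)H z-plane).
#' @param cytoplasm_mask logical matrix.
#' @param tile_px tile side in pixels (default 16).
#' @return stamped matrix.
#' @export
clone_stamp <- function(plane, cytoplasm_mask, tile_px = 16L) {
  stopifnot(is.matrix(plane), identical(dim(plane), dim(cytoplasm_mask)))
  if (mean(cytoplasm_mask) < 0.05)
    stop("cytoplasm mask covers less than 5% of the plane")
  if (all(cytoplasm_mask)) return(plane)
  ny <- nrow(plane); nx <- ncol(plane)
  # summed-area table locates top-left corners of all-cytoplasm tiles
  sat <- apply(apply(cytoplasm_mask, 2, cumsum), 1, cumsum)  # nx x ny (t)
  sat <- t(sat)
  satv <- function(y, x) {
    v <- numeric(length(y))
    ok <- y >= 1L & x >= 1L
    v[ok] <- sat[cbind(y[ok], x[ok])]
    v
  }
  area <- function(y0, x0, y1, x1)
    satv(y1, x1) - satv(y0 - 1L, x1) - satv(y1, x0 - 1L) +
      satv(y0 - 1L, x0 - 1L)
  ys <- seq_len(ny - tile_px + 1L)
  xs <- seq_len(nx - tile_px + 1L)
  grid <- expand.grid(y = ys, x = xs)
  full <- area(grid$y, grid$x, grid$y + tile_px - 1L, grid$x + tile_px - 1L) ==
    tile_px^2
  src <- grid[full, , drop = FALSE]
  if (!nrow(src))
    stop("no fully-cytoplasmic source tile of size ", tile_px,
         "; use a smaller tile_px")
  out <- plane
  gy <- tile_grid(ny, tile_px); gx <- tile_grid(nx, tile_px)
  for (iy in seq_len(nrow(gy))) {
    for (ix in seq_len(nrow(gx))) {
      yr <- gy[iy, 1]:gy[iy, 2]; xr <- gx[ix, 1]:gx[ix, 2]
      target <- !cytoplasm_mask[yr, xr, drop = FALSE]
      if (!any(target)) next
      k <- src[sample.int(nrow(src), 1L), ]
      tile <- plane[k$y:(k$y + tile_px - 1L), k$x:(k$x + tile_px - 1L)]
      tile <- tile[seq_along(yr), seq_along(xr), drop = FALSE]
      block <- out[yr, xr, drop = FALSE]
      block[target] <- tile[target]
      out[yr, xr] <- block
    }
  }
  out
}

#' Inverse power-law fit to the radially averaged power spectral density
#'
#' The mean-subtracted 2D Fourier power spectrum is averaged over annuli one
#' frequency sample wide; the high-frequency cutoff is the smallest spatial
#' frequency at which the cumulative radial PSD (DC excluded) reaches 98% of
#' the total (the top 2% is attributed to noise), and an unweighted
#' least-squares line on `log10 R(k)` vs `log10 k` over
#' `[k_lo, k_hi]` gives the exponent `beta` as minus the slope.
#'
#' @param img numeric matrix.
#' @param pixel_size_um pixel size, um.
#' @param k_lo lower fit bound, 1/um (default 0.1).
#' @param energy_cut cumulative-energy fraction defining the cutoff
#'   (default 0.98).
#' @return list of class `psd_fit`: `A`, `beta`, `k_lo`, `k_hi`, `r2`,
#'   `k`, `R` (the fitted radial profile).
#' @export
psd_power_law <- function(img, pixel_size_um, k_lo = 0.1, energy_cut = 0.98) {
  stopifnot(is.matrix(img), pixel_size_um > 0)
  ny <- nrow(img); nx <- ncol(img)
  f <- stats::fft(img - mean(img))
  psd <- Mod(f)^2
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / (ny * pixel_size_um)
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / (nx * pixel_size_um)
  k <- sqrt(outer(fy^2, fx^2, "+"))
  dk <- 1 / (max(ny, nx) * pixel_size_um)
  bin <- round(k / dk)
  sel <- bin > 0
  ann_sum <- tapply(psd[sel], bin[sel], sum)
  ann_n <- tapply(psd[sel], bin[sel], length)
  kb <- as.numeric(names(ann_sum)) * dk
  R <- ann_sum / ann_n
  ord <- order(kb)
  kb <- kb[ord]; R <- R[ord]; ann_sum <- ann_sum[ord]
  cum <- cumsum(ann_sum) / sum(ann_sum)
  k_hi <- kb[which(cum >= energy_cut)[1]]
  fit_sel <- kb >= k_lo & kb <= k_hi & R > 0
  if (sum(fit_sel) < 5)
    stop("fewer than 5 annuli in fit range [", k_lo, ", ",
         format(k_hi, digits = 3), "] 1/um: image too small or pixels too coarse")
  lx <- log10(kb[fit_sel]); ly <- log10(R[fit_sel])
  fit <- stats::lm(ly ~ lx)
  structure(list(A = 10^stats::coef(fit)[[1]],
                 beta = -stats::coef(fit)[[2]],
                 k_lo = k_lo, k_hi = k_hi,
                 r2 = summary(fit)$r.squared,
                 k = kb[fit_sel], R = as.numeric(R[fit_sel])),
            class = "psd_fit")
}

#' Mitochondrial clustering exponent from repeated clone-stamping
#'
#' Clone-stamping is repeated `repeats` times (independent random tile
#' placements); the PSD power-law exponent is fitted to each stamped image
#' and the mean over repeats (and z-planes for stacks) is the clustering
#' metric.
#'
#' @param nadh NAD(P)H [volumetric_image()].
#' @param cytoplasm_mask logical array matching `nadh`.
#' @param repeats number of stamping repeats (default 20).
#' @param tile_px tile side, pixels (default 16).
#' @param k_lo,energy_cut passed to [psd_power_law()].
#' @return list of class `clustering_result`: `beta`, `beta_per_repeat`,
#'   `A`, `k_lo`, `k_hi`, `r2` (means over repeats).
#' @export
mitochondrial_clustering <- function(nadh, cytoplasm_mask, repeats = 20L,
                                     tile_px = 16L, k_lo = 0.1,
                                     energy_cut = 0.98) {
  stopifnot(inherits(nadh, "volumetric_image"),
            identical(dim(nadh$intensities), dim(cytoplasm_mask)),
            repeats >= 1)
  nz <- dim(nadh$intensities)[1]
  px <- nadh$voxel_size[3]
  per_repeat <- numeric(repeats)
  A <- khi <- r2 <- numeric(repeats)
  for (r in seq_len(repeats)) {
    betas <- numeric(nz)
    for (z in seq_len(nz)) {
      stamped <- clone_stamp(nadh$intensities[z, , ],
                             cytoplasm_mask[z, , ], tile_px)
      fit <- psd_power_law(stamped, px, k_lo, energy_cut)
      betas[z] <- fit$beta
      if (z == 1L) { A[r] <- fit$A; khi[r] <- fit$k_hi; r2[r] <- fit$r2 }
    }
    per_repeat[r] <- mean(betas)
  }
  structure(list(beta = mean(per_repeat), beta_per_repeat = per_repeat,
                 A = mean(A), k_lo = k_lo, k_hi = mean(khi), r2 = mean(r2)),
            class = "clustering_result")
}
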