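# Collagen cross-link content: TPEF (755 ex / 525 em) within SHG-positive
# matrix, normalized pixelwise by SHG.

#' Collagen cross-link density from cross-link TPEF and SHG channels
#'
#' Within the matrix mask, the per-pixel density is `xlink/shg`; the summary
#' is the mean of the pixelwise ratios over the mask (not the ratio of
#' sums). Pixels with zero SHG are excluded and counted, never imputed; the
#' raw mean cross-link TPEF intensity over the mask is reported alongside.
#'
#' @param xlink cross-link TPEF [volumetric_image()] (755/525 channel).
#' @param shg SHG [volumetric_image()], co-registered and power-normalized
#'   consistently with `xlink`.
#' @param matrix_mask logical array of SHG-positive matrix voxels.
#' @return list of class `crosslink_result`: `raw_intensity`, `density_map`
#'   (NA off-mask and at excluded pixels), `mean_density`, `n_excluded`,
#'   `warning` (TRUE when >10% of masked pixels were excluded).
#' @export
crosslink_density <- function(xlink, shg, matrix_mask) {
  stopifnot(inherits(xlink, "volumetric_image"),
            inherits(shg, "volumetric_image"),
            identical(dim(xlink$intensities), dim(shg$intensities)),
            identical(dim(xlink$intensities), dim(matrix_mask)))
  if (!any(matrix_mask)) stop("matrix mask is empty")
  d <- dim(xlink$intensities)
  density <- array(NA_real_, d)
  ok <- matrix_mask & shg$intensities > 0
  density[ok] <- xlink$intensities[ok] / shg$intensities[ok]
  n_excluded <- sum(matrix_mask) - sum(ok)
  warn <- n_excluded > 0.1 * sum(matrix_mask)
  if (warn)
    warning(sprintf("%d/%d masked pixels excluded (zero SHG)",
                    n_excluded, sum(matrix_mask)))
  if (!any(ok)) stop("all masked pixels have zero SHG")
  structure(list(raw_intensity = mean(xlink$intensities[matrix_mask]),
                 density_map = density,
                 mean_density = mean(density[ok]),
                 n_excluded = n_excluded, warning = warn),
            class = "crosslink_result")
}
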