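# Independent oracles and small fixture builders shared across the suite.

# Structure-tensor orientation oracle: smoothed outer product of intensity
# gradients; the fiber axis is the eigenvector of the *smallest* eigenvalue.
# Independent of the weighted-vector-summation implementation.
st_orientation_axes <- function(arr, voxel_size, at, sigma_vox = c(1, 2, 2)) {
  d <- dim(arr)
  grad <- function(axis) {
    g <- array(0, d)
    idx_hi <- idx_lo <- rep(list(quote(expr = )), 3)
    n <- d[axis]
    hi <- lo <- vector("list", 3)
    for (i in 1:3) hi[[i]] <- lo[[i]] <- seq_len(d[i])
    hi[[axis]] <- c(2:n, n); lo[[axis]] <- c(1, 1:(n - 1))
    (arr[hi[[1]], hi[[2]], hi[[3]]] - arr[lo[[1]], lo[[2]], lo[[3]]]) /
      (2 * voxel_size[axis])
  }
  gz <- grad(1); gy <- grad(2); gx <- grad(3)
  sm <- function(a) gaussian_blur3d(a, sigma_vox)
  Jxx <- sm(gx * gx); Jyy <- sm(gy * gy); Jzz <- sm(gz * gz)
  Jxy <- sm(gx * gy); Jxz <- sm(gx * gz); Jyz <- sm(gy * gz)
  out <- matrix(NA_real_, length(at), 3)
  for (i in seq_along(at)) {
    p <- at[i]
    J <- matrix(c(Jxx[p], Jxy[p], Jxz[p],
                  Jxy[p], Jyy[p], Jyz[p],
                  Jxz[p], Jyz[p], Jzz[p]), 3, 3)
    e <- eigen(J, symmetric = TRUE)
    out[i, ] <- e$vectors[, 3]          # smallest eigenvalue -> fiber axis
  }
  out
}

axis_angle_deg <- function(a, b) {
  acos(pmin(1, abs(rowSums(a * b)))) * 180 / pi
}

# small valid metric table
make_metric_table <- function(n = 6, group = rep(c("DMM", "sham"), length.out = n),
                              seed = 1) {
  set.seed(seed)
  metric_table(data.frame(
    specimen = paste0("m", seq_len(n)), group = group,
    time_point = "wk1", zone = "superficial",
    field_id = paste0("f", seq_len(n)),
    variance = runif(n, 0.2, 0.8), xlink_density = runif(n, 0.5, 2),
    xlink_llif = runif(n, 0.2, 0.8), redox = runif(n, 0.2, 0.8),
    nadh_llif = runif(n, 0.2, 0.8), beta = runif(n, 1, 2.5)))
}
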