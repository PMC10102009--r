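# Multivariate layer: control normalization, Pearson collinearity screening,
# canonical LDA with resubstitution (OCA) and leave-one-out (CVCA)
# accuracies, and metabolic relative-change triplets mapped against a
# reference perturbation table.

METABOLIC_COLS <- c("redox", "nadh_llif", "beta")

#' Normalize metrics to control means
#'
#' Each metric column is divided by the mean of the matching control rows,
#' optionally stratified by time point (e.g. DMM normalized to the sham mean
#' at each time point).
#'
#' @param table a [metric_table()] (or compatible data.frame).
#' @param control_group value of `group` identifying control rows.
#' @param by_time_point stratify the control means by `time_point`.
#' @return the table with metric columns rescaled; control rows then average
#'   to 1 per metric (per stratum).
#' @export
normalize_to_control <- function(table, control_group,
                                 by_time_point = FALSE) {
  df <- as.data.frame(table)
  if (!any(df$group == control_group))
    stop("no control rows with group == '", control_group, "'")
  strata <- if (by_time_point) unique(df$time_point) else NA
  for (st in strata) {
    in_st <- if (by_time_point) df$time_point == st else rep(TRUE, nrow(df))
    ctrl <- in_st & df$group == control_group
    if (!any(ctrl))
      stop("no control rows in stratum time_point = ", st)
    for (m in METRIC_COLS) {
      cm <- mean(df[[m]][ctrl])
      if (!is.finite(cm) || cm == 0)
        stop("zero or undefined control mean for metric '", m,
             "' in stratum time_point = ", st)
      df[[m]][in_st] <- df[[m]][in_st] / cm
    }
  }
  df
}

#' Pearson collinearity screen
#'
#' Full pairwise Pearson correlation matrix of the numeric metric columns;
#' pairs at or above the threshold are flagged as offending, and constant
#' columns (undefined r) are reported.
#'
#' @param table metric table or data.frame; non-numeric columns ignored.
#' @param threshold flag threshold on `|r|` (default 0.7).
#' @return list: `r` (matrix), `offending` (data.frame of flagged pairs),
#'   `constant` (names of constant columns).
#' @export
collinearity_screen <- function(table, threshold = 0.7) {
  df <- as.data.frame(table)
  num <- df[vapply(df, is.numeric, TRUE)]
  if (nrow(num) < 3) stop("need at least 3 rows")
  sds <- vapply(num, stats::sd, 0)
  constant <- names(num)[sds == 0 | !is.finite(sds)]
  r <- suppressWarnings(stats::cor(num))
  pairs <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  offending <- data.frame(var1 = rownames(r)[pairs[, 1]],
                          var2 = colnames(r)[pairs[, 2]],
                          r = r[pairs], stringsAsFactors = FALSE)
  list(r = r, offending = offending, constant = constant)
}

fit_lda <- function(X, y, ridge = 1e-6) {
  classes <- sort(unique(y))
  K <- length(classes); p <- ncol(X); n <- nrow(X)
  means <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                    numeric(p)))
  S <- matrix(0, p, p)
  for (k in seq_len(K)) {
    Xi <- X[y == classes[k], , drop = FALSE]
    Xi <- sweep(Xi, 2, means[k, ])
    S <- S + crossprod(Xi)
  }
  S <- S / (n - K)
  ridged <- FALSE
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * sum(diag(S))) {
    S <- S + diag(ridge * sum(diag(S)), p)
    ridged <- TRUE
  }
  Sinv <- solve(S)
  list(classes = classes, means = means, Sinv = Sinv, ridged = ridged)
}

predict_lda <- function(model, X) {
  # equal priors: argmax_k x' Sinv mu_k - mu_k' Sinv mu_k / 2
  W <- model$Sinv %*% t(model$means)                # p x K
  b <- -0.5 * colSums(t(model$means) * W)
  scores <- X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
  model$classes[max.col(scores, ties.method = "first")]
}

#' Linear discriminant classification with OCA and CVCA
#'
#' Canonical LDA with equal class priors and pooled within-class covariance
#' (ridge `1e-6 x trace` applied and flagged when singular). OCA is the
#' resubstitution accuracy of discriminants fitted on the full data set;
#' CVCA is leave-one-out accuracy with the model refitted on every fold.
#'
#' @param x numeric matrix / data.frame of features (e.g. the six metrics).
#' @param labels class labels, length `nrow(x)`.
#' @return list of class `lda_result`: `oca`, `cvca` (fractions in
#'   `[0, 1]`), `per_class` (per-class resubstitution accuracy), `ridged`,
#'   `model`.
#' @export
lda_classify <- function(x, labels) {
  X <- as.matrix(as.data.frame(x)[vapply(as.data.frame(x), is.numeric, TRUE)])
  y <- as.character(labels)
  stopifnot(nrow(X) == length(y))
  tab <- table(y)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < ncol(X) + 2))
    stop("every class needs at least n_features + 2 rows")
  model <- fit_lda(X, y)
  pred <- predict_lda(model, X)
  oca <- mean(pred == y)
  per_class <- vapply(model$classes,
                      function(k) mean(pred[y == k] == k), 0)
  cv_pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    m <- fit_lda(X[-i, , drop = FALSE], y[-i])
    cv_pred[i] <- predict_lda(m, X[i, , drop = FALSE])
  }
  cvca <- mean(cv_pred == y)
  structure(list(oca = oca, cvca = cvca,
                 per_class = stats::setNames(per_class, model$classes),
                 ridged = model$ridged, model = model),
            class = "lda_result")
}

#' Build a metabolic perturbation reference
#'
#' A labeled table of reference samples in the 3-metric relative-change
#' space (`delta_redox`, `delta_nadh_llif`, `delta_beta`); per-class
#' centroids and covariances define coverage ellipsoids at the chi-square
#' quantile with 3 degrees of freedom.
#'
#' @param df data.frame with columns `class`, `delta_redox`,
#'   `delta_nadh_llif`, `delta_beta`.
#' @param coverage ellipsoid coverage quantile (default 0.75).
#' @return list of class `perturbation_reference`: per-class `centroid`,
#'   `cov`, `radius2` (= `qchisq(coverage, 3)`), `skipped` classes (<4
#'   samples).
#' @export
perturbation_reference <- function(df, coverage = 0.75) {
  cols <- c("delta_redox", "delta_nadh_llif", "delta_beta")
  stopifnot(all(c("class", cols) %in% names(df)))
  classes <- unique(df$class)
  out <- list(); skipped <- character()
  for (k in classes) {
    Xi <- as.matrix(df[df$class == k, cols])
    if (nrow(Xi) < 4) { skipped <- c(skipped, k); next }
    out[[k]] <- list(centroid = colMeans(Xi), cov = stats::cov(Xi))
  }
  if (length(skipped))
    warning("reference classes skipped (<4 samples): ",
            paste(skipped, collapse = ", "))
  structure(list(classes = out, radius2 = stats::qchisq(coverage, df = 3),
                 coverage = coverage, skipped = skipped),
            class = "perturbation_reference")
}

#' Metabolic relative-change triplets and nearest reference perturbation
#'
#' For each row the fractional change `(x - c_bar)/c_bar` of the three
#' metabolic metrics (redox ratio, NAD(P)H LLIF, clustering beta) relative
#' to the matched control means; with a [perturbation_reference()] supplied,
#' the Mahalanobis distance to each reference class (its own covariance) and
#' the nearest class are reported, along with whether the sample falls
#' inside each class's coverage ellipsoid.
#'
#' @param table metric table.
#' @param control_group control `group` value.
#' @param reference optional [perturbation_reference()].
#' @param by_time_point stratify control means by time point.
#' @param style `"fractional"` for `(x - c)/c` or `"ratio"` for `x/c`.
#' @return data.frame of key columns plus `delta_redox`, `delta_nadh_llif`,
#'   `delta_beta` (and `nearest_class`, `nearest_distance` with a
#'   reference); attribute `style` records the change convention.
#' @export
metabolic_delta <- function(table, control_group, reference = NULL,
                            by_time_point = FALSE,
                            style = c("fractional", "ratio")) {
  style <- match.arg(style)
  df <- as.data.frame(table)
  strata <- if (by_time_point) unique(df$time_point) else NA
  out <- df[, intersect(KEY_COLS, names(df)), drop = FALSE]
  for (m in METABOLIC_COLS) out[[paste0("delta_", sub("^redox$", "redox", m))]] <- NA_real_
  names(out)[(ncol(out) - 2):ncol(out)] <-
    c("delta_redox", "delta_nadh_llif", "delta_beta")
  dn <- c(redox = "delta_redox", nadh_llif = "delta_nadh_llif",
          beta = "delta_beta")
  for (st in strata) {
    in_st <- if (by_time_point) df$time_point == st else rep(TRUE, nrow(df))
    ctrl <- in_st & df$group == control_group
    if (!any(ctrl)) stop("no control rows in stratum time_point = ", st)
    for (m in METABOLIC_COLS) {
      cm <- mean(df[[m]][ctrl])
      if (!is.finite(cm) || cm == 0)
        stop("zero control mean for '", m, "'")
      out[[dn[[m]]]][in_st] <- if (style == "fractional")
        (df[[m]][in_st] - cm) / cm else df[[m]][in_st] / cm
    }
  }
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "perturbation_reference"))
    D <- as.matrix(out[, c("delta_redox", "delta_nadh_llif", "delta_beta")])
    cls <- names(reference$classes)
    dist <- vapply(cls, function(k) {
      ref <- reference$classes[[k]]
      stats::mahalanobis(D, ref$centroid, ref$cov)
    }, numeric(nrow(D)))
    dist <- matrix(dist, nrow = nrow(D),
                   dimnames = list(NULL, cls))
    nearest <- cls[apply(dist, 1, which.min)]
    out$nearest_class <- nearest
    out$nearest_distance <- sqrt(dist[cbind(seq_len(nrow(D)),
                                            match(nearest, cls))])
    out$inside_ellipsoid <- dist[cbind(seq_len(nrow(D)),
                                       match(nearest, cls))] <=
      reference$radius2
  }
  attr(out, "style") <- style
  out
}

#' Export normalized metrics for external embedding (viSNE-style)
#'
#' Writes the six control-normalized metrics plus key columns as a tidy CSV
#' consumed by external t-SNE/viSNE tools; no embedding is computed here.
#'
#' @param table metric table.
#' @param control_group control group for normalization.
#' @param path output CSV.
#' @return `path` invisibly.
#' @export
export_for_embedding <- function(table, control_group, path) {
  norm <- normalize_to_control(table, control_group)
  utils::write.csv(norm, path, row.names = FALSE)
  invisible(path)
}
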