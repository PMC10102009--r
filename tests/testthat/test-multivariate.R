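test_that("control normalization maps control means to 1 and scales rows", {
  tab <- make_metric_table(8, group = rep(c("DMM", "sham"), each = 4))
  norm <- normalize_to_control(tab, "sham")
  for (m in c("variance", "redox", "beta"))
    expect_equal(mean(norm[[m]][norm$group == "sham"]), 1)
  # explicit scaling: value 0.8 against control mean 0.4 gives 2.0
  df <- as.data.frame(tab)
  df$redox <- c(rep(0.8, 4), rep(0.4, 4))
  norm2 <- normalize_to_control(df, "sham")
  expect_equal(norm2$redox[1], 2)
  # missing control stratum errors
  df2 <- as.data.frame(tab); df2$time_point <- rep(c("wk1", "wk2"), 4)
  df2$group[df2$time_point == "wk2"] <- "DMM"
  expect_error(normalize_to_control(df2, "sham", by_time_point = TRUE),
               "stratum")
})

test_that("collinearity screen flags duplicates, passes independent nulls", {
  set.seed(50)
  df <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
  scr <- collinearity_screen(df)
  expect_true(all(abs(scr$r[upper.tri(scr$r)]) < 0.2))
  expect_equal(nrow(scr$offending), 0L)
  expect_equal(diag(scr$r), c(a = 1, b = 1, c = 1))
  expect_equal(scr$r, t(scr$r))
  df$dup <- df$a
  scr2 <- collinearity_screen(df)
  expect_true(any(scr2$offending$r == 1))
  df$k <- 1
  scr3 <- collinearity_screen(df)
  expect_true("k" %in% scr3$constant)
})

test_that("LDA separates separated classes and matches the MASS oracle", {
  set.seed(51)
  X <- rbind(matrix(rnorm(300), 100, 3), matrix(rnorm(300, mean = 10), 100, 3))
  y <- rep(c("a", "b"), each = 100)
  res <- lda_classify(X, y)
  expect_equal(res$oca, 1)
  expect_equal(res$cvca, 1)
  expect_equal(unname(res$per_class), c(1, 1))
  # oracle: overlapping classes, decisions agree with MASS::lda
  skip_if_not_installed("MASS")
  set.seed(52)
  X2 <- rbind(matrix(rnorm(150), 50, 3),
              matrix(rnorm(150, mean = 1), 50, 3))
  y2 <- rep(c("a", "b"), each = 50)
  ours <- lda_classify(X2, y2)
  m <- MASS::lda(X2, grouping = y2, prior = c(0.5, 0.5))
  oracle_oca <- mean(predict(m, X2)$class == y2)
  expect_equal(ours$oca, oracle_oca)
  mcv <- MASS::lda(X2, grouping = y2, prior = c(0.5, 0.5), CV = TRUE)
  expect_equal(ours$cvca, mean(mcv$class == y2))
})

test_that("LDA null accuracy sits at chance and CVCA rarely beats OCA", {
  set.seed(53)
  X <- matrix(rnorm(120 * 3), 120, 3)
  y <- rep(c("a", "b"), 60)
  null <- lda_classify(X, y)
  # within 3 binomial sigma of chance
  expect_lt(abs(null$cvca - 0.5), 3 * sqrt(0.25 / 120))
  # optimism: CVCA <= OCA on >= 95% of 200 simulated datasets
  set.seed(54)
  cmp <- replicate(200, {
    Xs <- matrix(rnorm(24 * 3), 24, 3)
    ys <- rep(c("a", "b"), 12)
    r <- lda_classify(Xs, ys)
    r$cvca <= r$oca
  })
  expect_gte(mean(cmp), 0.95)
})

test_that("LDA input contracts and the singular-covariance ridge", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(lda_classify(X, rep("a", 20)), "2 classes")
  expect_error(lda_classify(X, rep(c("a", "b"), c(18, 2))), "n_features")
  # duplicated column makes the pooled covariance singular -> ridged flag
  set.seed(55)
  Z <- matrix(rnorm(60), 30, 2); Z <- cbind(Z, Z[, 1])
  r <- lda_classify(Z, rep(c("a", "b"), 15))
  expect_true(r$ridged)
})

test_that("metabolic deltas, nearest reference class and ellipsoid coverage", {
  tab <- make_metric_table(8, group = rep(c("DMM", "sham"), each = 4))
  df <- as.data.frame(tab)
  # a sample equal to the control means maps to (0, 0, 0)
  for (m in c("redox", "nadh_llif", "beta"))
    df[[m]][1] <- mean(df[[m]][df$group == "sham"])
  d <- metabolic_delta(df, "sham")
  expect_equal(unlist(d[1, c("delta_redox", "delta_nadh_llif", "delta_beta")]),
               c(delta_redox = 0, delta_nadh_llif = 0, delta_beta = 0))
  # reference: a sample at a class centroid is nearest to it at distance 0
  set.seed(56)
  ref <- data.frame(
    class = rep(c("glycolysis", "fao"), each = 10),
    delta_redox = c(rnorm(10, -0.3, 0.05), rnorm(10, 0.4, 0.05)),
    delta_nadh_llif = c(rnorm(10, 0.2, 0.05), rnorm(10, -0.1, 0.05)),
    delta_beta = c(rnorm(10, 0.1, 0.05), rnorm(10, -0.2, 0.05)))
  pref <- perturbation_reference(ref)
  ctr <- pref$classes$glycolysis$centroid
  df2 <- df
  cm <- vapply(c("redox", "nadh_llif", "beta"),
               function(m) mean(df[[m]][df$group == "sham"]), 0)
  df2$redox[2] <- cm[1] * (1 + ctr[1])
  df2$nadh_llif[2] <- cm[2] * (1 + ctr[2])
  df2$beta[2] <- cm[3] * (1 + ctr[3])
  d2 <- metabolic_delta(df2, "sham", reference = pref)
  expect_equal(d2$nearest_class[2], "glycolysis")
  expect_lt(d2$nearest_distance[2], 1e-8)
  # classes with < 4 samples are skipped with a warning
  small <- ref[c(1:10, 11:13), ]
  expect_warning(p2 <- perturbation_reference(small), "skipped")
  expect_false("fao" %in% names(p2$classes))
  # chi-square 75% ellipsoid contains ~75% of draws from the class law
  set.seed(57)
  S <- matrix(c(1, 0.3, 0, 0.3, 1, -0.2, 0, -0.2, 1), 3, 3) * 0.04
  draws <- matrix(rnorm(4000 * 3), 4000, 3) %*% chol(S)
  d2m <- stats::mahalanobis(draws, c(0, 0, 0), S)
  expect_equal(mean(d2m <= pref$radius2), 0.75, tolerance = 0.03)
})
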