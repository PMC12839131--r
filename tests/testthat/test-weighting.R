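tiny_table <- function() {
  tibble::tibble(
    cell_line = "CL", compound = "CP",
    concentration = rep(c(0, 10, 100), each = 2),
    replicate = rep(1:2, 3),
    fa = c(200, 200, 100, 120, 60, 70),
    fb = c(2, 2, 3, 3.2, 4, 4.4))
}

test_that("control normalisation divides by the zero-dose mean per feature", {
  m <- normalize_to_control(tiny_table())
  expect_equal(m$fa, c(200, 200, 100, 120, 60, 70) / 200)
  expect_equal(m$fb, c(2, 2, 3, 3.2, 4, 4.4) / 2)
  expect_equal(mean(m$fa[m$concentration == 0]), 1)
  ref <- control_reference(m)
  expect_equal(ref$control_mean[ref$feature == "fa"], 200)

  no_ctrl <- dplyr::filter(tiny_table(), concentration > 0)
  expect_error(normalize_to_control(no_ctrl), "no control")
  bad <- tiny_table(); bad$fa[3] <- -1
  expect_error(normalize_to_control(bad), "non-positive")
})

test_that("normalisation is computed per cell line independently", {
  t1 <- tiny_table()
  t2 <- tiny_table(); t2$cell_line <- "CL2"; t2$fa <- t2$fa * 10
  m <- normalize_to_control(dplyr::bind_rows(t1, t2))
  expect_equal(m$fa[m$cell_line == "CL"], m$fa[m$cell_line == "CL2"])
})

test_that("conditional inversion fires only on rising features with a real trend", {
  mk <- function(vals) {
    tbl <- tibble::tibble(cell_line = "CL", compound = "CP",
                          concentration = c(0, 1, 2, 3), replicate = 1L,
                          f = c(1, vals))
    new <- normalize_to_control(tbl)
    conditional_invert(new)
  }
  # mean 2.0 > 1 and mean of inverses 0.5222 < 2.0: inverted
  inv <- mk(c(1.5, 2.0, 2.5))
  expect_equal(inv$f[-1], 1 / c(1.5, 2.0, 2.5))
  expect_true(inversion_log(inv)$inverted)

  # boundary: all exactly 1 stays (strict inequality)
  expect_equal(mk(c(1, 1, 1))$f, rep(1, 4))

  # falling feature untouched
  expect_equal(mk(c(0.2, 0.5, 0.8))$f[-1], c(0.2, 0.5, 0.8))
})

test_that("the re-check reverts inversions that no longer lower the mean", {
  tbl <- tibble::tibble(cell_line = "CL", compound = "CP",
                        concentration = c(0, 1, 2, 3), replicate = 1L,
                        f = c(1, 1.5, 2.0, 2.5))
  m <- conditional_invert(normalize_to_control(tbl))
  # edits between inversion and re-check (e.g. QC replacement) can raise the
  # inverted column's mean above the recorded pre-inversion mean
  m$f[m$concentration > 0] <- c(2.5, 3.0, 3.5)
  out <- recheck_revert(m)
  log <- inversion_log(out)
  expect_true(log$reverted)
  expect_false(log$inverted)
  expect_equal(out$f[out$concentration > 0], 1 / c(2.5, 3.0, 3.5))

  # a cleanly inverted column is untouched
  m2 <- conditional_invert(normalize_to_control(tbl))
  out2 <- recheck_revert(m2)
  expect_false(inversion_log(out2)$reverted)
  expect_equal(out2$f, m2$f)

  # with no inversions the re-check is the identity
  flat <- normalize_to_control(tibble::tibble(
    cell_line = "CL", compound = "CP", concentration = c(0, 1, 2),
    replicate = 1L, f = c(1, 0.8, 0.6)))
  expect_equal(recheck_revert(flat)$f, flat$f)
})

test_that("PCA weights match the full-eigendecomposition oracle", {
  set.seed(11)
  for (i in 1:10) {
    X <- matrix(rnorm(12 * 5, mean = 5), 12, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    w <- pca_feature_weights(X, 0.90)
    expect_equal(unname(w$weights), oracle_pca_weights(X, 0.90),
                 tolerance = 1e-10)
    expect_equal(sum(w$weights), 1, tolerance = 1e-12)
    expect_true(all(w$weights >= 0))
  }
})

test_that("degenerate weighting cases behave analytically", {
  X1 <- matrix(rnorm(10, 3), 10, 1, dimnames = list(NULL, "only"))
  expect_equal(unname(pca_feature_weights(X1)$weights), 1)

  set.seed(2)
  v <- rnorm(20, 10)
  X2 <- cbind(a = v, b = v)
  expect_equal(unname(pca_feature_weights(X2)$weights), c(0.5, 0.5),
               tolerance = 1e-12)

  expect_error(pca_feature_weights(matrix(1, 5, 2)), "zero-variance")
  expect_error(pca_feature_weights(matrix(rnorm(10), 5, 2),
                                   cum_var_threshold = 1.2), "0, 1")
})

test_that("higher cumulative-variance thresholds never select fewer components", {
  set.seed(3)
  X <- matrix(rnorm(30 * 6), 30, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
  colnames(X) <- paste0("f", 1:6)
  k90 <- pca_feature_weights(X, 0.90)$k
  k95 <- pca_feature_weights(X, 0.95)$k
  expect_gte(k95, k90)
})

test_that("weights are invariant to component sign flips", {
  # |c_ij| makes the weight formula sign-blind; verify through the oracle
  set.seed(4)
  X <- matrix(rnorm(15 * 4, 2), 15, 4, dimnames = list(NULL, paste0("f", 1:4)))
  Xs <- scale(X)
  e <- eigen(crossprod(Xs) / (nrow(Xs) - 1), symmetric = TRUE)
  a <- e$values / sum(e$values)
  k <- which(cumsum(a) >= 0.9)[1]
  flip <- e$vectors %*% diag(c(-1, 1, -1, 1))
  w1 <- abs(e$vectors[, 1:k, drop = FALSE]) %*% a[1:k]
  w2 <- abs(flip[, 1:k, drop = FALSE]) %*% a[1:k]
  expect_equal(w1 / sum(w1), w2 / sum(w2))
  expect_equal(as.numeric(w1 / sum(w1)),
               unname(pca_feature_weights(X, 0.90)$weights), tolerance = 1e-10)
})

test_that("the composite metric is the weighted feature sum", {
  w <- structure(list(weights = c(a = 0.5, b = 0.5), features = c("a", "b")),
                 class = "pca_weighting")
  tbl <- tibble::tibble(cell_line = "CL", compound = "CP", concentration = 1,
                        replicate = 1L, a = 0.4, b = 0.6)
  expect_equal(composite_metric(tbl, w)$sigma, 0.5)

  wrong <- dplyr::rename(tbl, c = b)
  expect_error(composite_metric(wrong, w), "feature sets")

  # brute-force dot product on a larger fixture
  set.seed(5)
  big <- tibble::tibble(cell_line = "CL", compound = "CP",
                        concentration = rep(c(0, 1, 10, 100), each = 5),
                        replicate = rep(1:5, 4))
  for (f in paste0("f", 1:4)) big[[f]] <- runif(20, 0.5, 2)
  ww <- pca_feature_weights(big)
  sig <- composite_metric(big, ww)$sigma
  manual <- as.matrix(big[paste0("f", 1:4)]) %*% ww$weights
  expect_equal(sig, as.numeric(manual), tolerance = 1e-12)
})

test_that("clean control wells score exactly 1", {
  scn <- dose_scenario(noise_cv = 0, seed = 8)
  tbl <- make_dose_tables(scn)$features
  mt <- compute_composite_metric(tbl, qc = FALSE)
  expect_equal(mt$sigma[mt$concentration == 0],
               rep(1, sum(mt$concentration == 0)), tolerance = 1e-12)
})

test_that("the composite metric falls monotonically with dose", {
  # noiseless: strictly non-increasing per-concentration means
  scn <- dose_scenario(noise_cv = 0, seed = 10)
  mt <- compute_composite_metric(make_dose_tables(scn)$features, qc = FALSE)
  means <- mt |>
    dplyr::filter(concentration > 0) |>
    dplyr::group_by(concentration) |>
    dplyr::summarise(m = mean(sigma)) |>
    dplyr::arrange(concentration)
  expect_true(all(diff(means$m) <= 1e-9))

  # at 10% noise the dose trend stays strongly monotone across seeds
  rhos <- vapply(1:5, function(s) {
    mt <- compute_composite_metric(
      make_dose_tables(dose_scenario(noise_cv = 10, seed = 100 + s))$features)
    sub <- dplyr::filter(mt, concentration > 0)
    cor(sub$sigma, sub$concentration, method = "spearman")
  }, numeric(1))
  expect_lte(median(rhos), -0.9)
})
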