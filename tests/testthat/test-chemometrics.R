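test_that("PCA matches the covariance-eigendecomposition oracle", {
  set.seed(41)
  X <- matrix(stats::rnorm(24), 6, 4)
  m <- pca_fit(X, ncomp = 3)
  o <- pca_eigen_oracle(X, 3)
  expect_lt(max_abs_diff_signflip(m$scores, o$scores), 1e-9)
  expect_lt(max_abs_diff_signflip(m$loadings, o$loadings), 1e-9)
  expect_equal(m$pct_variance, o$pct[1:3], tolerance = 1e-9)
  # orthonormal loadings, non-increasing percent variance
  expect_lt(max(abs(crossprod(m$loadings) - diag(3))), 1e-8)
  expect_true(all(diff(m$pct_variance) <= 1e-9))
  expect_lte(sum(m$pct_variance), 100 + 1e-6)
  # rank-1 data put 100% on PC1
  r1 <- outer(1:5, c(1, -2, 0.5))
  m1 <- pca_fit(r1 + 0, 2)
  expect_equal(m1$pct_variance[1], 100, tolerance = 1e-9)
  expect_error(pca_fit(X, 10), "ncomp")
  expect_error(pca_fit(matrix(1, 4, 3), 2), "constant")
})

test_that("PCA reconstruction error decreases with the component count", {
  set.seed(42)
  X <- matrix(stats::rnorm(20 * 8), 20, 8) %*% diag(c(4, 3, 2, 1.5, 1, 1, 0.5, 0.2))
  errs <- vapply(1:5, function(k) {
    m <- pca_fit(X, k)
    rec <- m$scores %*% t(m$loadings)
    sum((sweep(X, 2, m$mean) - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("consensus PCA degenerates to PCA for a single block", {
  set.seed(43)
  X <- matrix(stats::rnorm(60), 10, 6)
  cm <- cpca_fit(list(b = X), ncomp = 3)
  Xs <- sweep(X, 2, colMeans(X))
  Xs <- Xs / sqrt(sum(Xs^2))
  pm <- pca_fit(X, 3)
  # same scores up to the block scaling constant
  sc <- pm$scores / sqrt(sum(sweep(X, 2, colMeans(X))^2))
  expect_lt(max_abs_diff_signflip(cm$global_scores, sc), 1e-10)
  expect_equal(cm$pct_variance_global, pm$pct_variance, tolerance = 1e-10)
})

test_that("consensus PCA matches the concatenated-super-matrix SVD oracle", {
  set.seed(44)
  A <- matrix(stats::rnorm(10 * 7), 10, 7)
  B <- matrix(stats::rnorm(10 * 5), 10, 5)
  cm <- cpca_fit(list(ftir = A, raman = B), ncomp = 4)
  # oracle: centre, Frobenius-scale, concatenate, SVD
  cf <- function(X) { Xc <- sweep(X, 2, colMeans(X)); Xc / sqrt(sum(Xc^2)) }
  super <- cbind(cf(A), cf(B))
  sv <- svd(super)
  oscores <- sv$u[, 1:4] %*% diag(sv$d[1:4])
  expect_lt(max_abs_diff_signflip(cm$global_scores, oscores), 1e-9)
  expect_equal(cm$pct_variance_global, 100 * sv$d[1:4]^2 / sum(sv$d^2),
               tolerance = 1e-9)
  # two identical copies of one block: equal block scores and variances
  cm2 <- cpca_fit(list(x = A, y = A), ncomp = 3)
  expect_equal(cm2$block_scores$x, cm2$block_scores$y, tolerance = 1e-10)
  expect_equal(cm2$pct_variance_per_block[1, ], cm2$pct_variance_per_block[2, ],
               tolerance = 1e-10)
  expect_true(all(cm2$pct_variance_per_block >= 0 &
                  cm2$pct_variance_per_block <= 100 + 1e-9))
  expect_error(cpca_fit(list(a = A, b = B[1:5, ])), "sample count")
})

test_that("block-weight scaling makes CPCA invariant to block rescaling", {
  set.seed(45)
  A <- matrix(stats::rnorm(80), 10, 8)
  B <- matrix(stats::rnorm(60), 10, 6)
  m1 <- cpca_fit(list(a = A, b = B), ncomp = 3)
  m2 <- cpca_fit(list(a = 1000 * A, b = 0.01 * B), ncomp = 3)
  expect_lt(max_abs_diff_signflip(m1$global_scores, m2$global_scores), 1e-9)
})

test_that("correlation loadings are bounded correlations with flagged dead variables", {
  set.seed(46)
  X <- matrix(stats::rnorm(30 * 5), 30, 5)
  m <- pca_fit(X, 3)
  # a variable equal to score 1 correlates perfectly
  X2 <- cbind(X, m$scores[, 1], 0)
  cl <- correlation_loadings(m, X2)
  expect_true(all(abs(cl$r) <= 1 + 1e-12))
  expect_equal(cl$r[6, 1], 1, tolerance = 1e-9)
  expect_true(cl$flagged[7])
  expect_equal(cl$r[7, ], rep(0, 3))
  expect_equal(unname(cl$circle_radii), c(sqrt(0.5), 1))
})

test_that("CPCA on the synthetic design separates isotopes and timepoints", {
  sim <- simulate_design_dataset(default_design(), seed = 17)
  blocks <- list(
    HTSFTIR = average_replicates(apply_recipe(sim$HTSFTIR, "htsftir_mva")),
    FTRaman = average_replicates(apply_recipe(sim$FTRaman, "ftraman_mva")))
  meta <- blocks$HTSFTIR$meta
  cm <- cpca_fit(lapply(blocks, function(b) b$intensity), ncomp = 5)
  S <- cm$global_scores
  # pure glucose media: 12C vs 13C biomass separates in the leading scores
  glu <- meta$medium %in% c("nGlu", "iGlu")
  lab13 <- meta$medium == "iGlu"
  sep <- vapply(1:5, function(k) {
    abs(mean(S[glu & lab13, k]) - mean(S[glu & !lab13, k])) /
      (stats::sd(S[glu, k]) + 1e-12)
  }, numeric(1))
  expect_gt(max(sep[1:3]), 1)
  # timepoints order along some leading component (rank correlation)
  tcor <- vapply(1:3, function(k)
    abs(stats::cor(S[glu, k], meta$timepoint_h[glu], method = "spearman")),
    numeric(1))
  expect_gt(max(tcor), 0.6)
  # ester C=O variables: 12C and 13C columns load with opposite signs on
  # the isotope-separating component
  k_iso <- which.max(sep)
  cl <- correlation_loadings(cm, lapply(blocks, function(b) b$intensity))
  nu <- blocks$HTSFTIR$wavenumber
  j12 <- which.min(abs(nu - 1745)); j13 <- which.min(abs(nu - 1701))
  expect_lt(cl$r[j12, k_iso] * cl$r[j13, k_iso], 0)
})

test_that("PLS1 fits exactly at full rank and flags out-of-model spectra", {
  set.seed(47)
  X <- matrix(stats::rnorm(40 * 6), 40, 6)
  b <- stats::rnorm(6)
  y <- drop(X %*% b)
  m <- plsr_fit(X, y, n_lv = 6)
  pr <- plsr_predict(m, X)
  expect_equal(pr$y_hat, y, tolerance = 1e-9)
  expect_gt(1 - sum((pr$y_hat - y)^2) / sum((y - mean(y))^2), 1 - 1e-9)
  # spectra in the span of the training loadings have ~zero Q residual
  inspan <- matrix(m$x_mean, 5, 6, byrow = TRUE) +
    m$scores[1:5, ] %*% t(m$loadings)
  expect_lt(max(plsr_predict(m, inspan)$q_residual), 1e-9)
  expect_error(plsr_fit(X, rep(1, 40), 2), "zero-variance")
  expect_error(plsr_fit(X, y, 20), "rank")
})

test_that("PLSR recovers lipid content within 3x of the OLS oracle; outliers flagged", {
  # synthetic calibration: 60 samples, known TAG weights, preprocessed
  # Raman spectra
  set.seed(48)
  n <- 60
  w <- stats::runif(n, 0.2, 2.5)
  axis <- default_axis("FTRaman")
  specs <- t(vapply(seq_len(n), function(i) {
    cmp <- composition(c(TAG = w[i], protein = 1,
                         carbohydrate = stats::runif(1, 0.5, 1)),
                       c(TAG = 0))
    simulate_bulk_spectrum(cmp, "FTRaman",
                           baseline = baseline_params("FTRaman", 0.01),
                           pathlength = stats::rlnorm(1, 0, 0.15),
                           noise_sd = 1e-4, seed = 5000 + i)$intensity
  }, numeric(length(axis))))
  ds <- spectral_dataset(axis, specs, modality = "FTRaman")
  pp <- apply_recipe(ds, "ftraman_plsr")
  tr <- 1:40; te <- 41:60
  m <- plsr_fit(pp$intensity[tr, ], w[tr], n_lv = 5)
  pred <- plsr_predict(m, pp$intensity[te, ])
  rmse_pls <- sqrt(mean((pred$y_hat - w[te])^2))
  # OLS oracle: regress y on projections onto the true component spectra
  comps <- t(vapply(c("TAG", "protein", "carbohydrate"), function(mb)
    component_spectrum(mb, pp$wavenumber, 0, "FTRaman")$intensity,
    numeric(length(pp$wavenumber))))
  Zn <- pp$intensity %*% t(comps)
  ols <- stats::lm.fit(cbind(1, Zn[tr, ]), w[tr])
  yhat_ols <- drop(cbind(1, Zn[te, ]) %*% ols$coefficients)
  rmse_ols <- sqrt(mean((yhat_ols - w[te])^2))
  expect_lte(rmse_pls, 3 * rmse_ols)
  # spectra containing a component absent from training are flagged
  out_specs <- t(vapply(1:20, function(i) {
    cmp <- composition(c(TAG = stats::runif(1, 0.2, 2.5), protein = 1,
                         polyphosphate = 1.5), c(TAG = 0))
    simulate_bulk_spectrum(cmp, "FTRaman",
                           baseline = baseline_params("FTRaman", 0.01),
                           noise_sd = 1e-4, seed = 6000 + i)$intensity
  }, numeric(length(axis))))
  po <- apply_recipe(spectral_dataset(axis, out_specs, modality = "FTRaman"),
                     "ftraman_plsr")
  fl <- plsr_predict(m, po$intensity)
  expect_gte(mean(fl$flagged), 0.95)
})
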