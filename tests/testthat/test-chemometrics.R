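test_that("PCA matches a brute-force eigendecomposition on a toy matrix", {
  set.seed(4)
  X <- matrix(rnorm(50), 5, 10)
  res <- fit_pca(X, n_components = 3)
  # independent oracle: eigenvectors of the covariance matrix
  ev <- eigen(cov(X), symmetric = TRUE)
  for (j in 1:3) {
    v <- ev$vectors[, j]
    expect_lt(min(sum((res$loadings[j, ] - v)^2),
                  sum((res$loadings[j, ] + v)^2)), 1e-16)
  }
  expect_equal(res$explained_variance_fraction,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-10)
  # loadings orthonormal; scores are the centred projections
  G <- res$loadings %*% t(res$loadings)
  expect_equal(G, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  ctr <- sweep(X, 2, colMeans(X))
  expect_equal(res$scores, ctr %*% t(res$loadings), tolerance = 1e-10,
               ignore_attr = TRUE)
  # deterministic sign convention
  for (j in 1:3)
    expect_gt(res$loadings[j, which.max(abs(res$loadings[j, ]))], 0)
})

test_that("PCA handles rank-1 data and the isotropic limit", {
  d <- rnorm(8)
  X <- outer(seq(-2, 2, length.out = 9), d)     # varies along one direction
  res <- fit_pca(X, n_components = 2)
  expect_equal(res$explained_variance_fraction[1], 1, tolerance = 1e-10)
  set.seed(11)
  iso <- matrix(rnorm(3000 * 3), 3000, 3)
  ri <- fit_pca(iso, n_components = 3)
  expect_equal(ri$explained_variance_fraction, rep(1 / 3, 3),
               tolerance = 0.05)
  expect_error(fit_pca(matrix(rnorm(20), 2, 10), n_components = 3),
               "at least")
})

test_that("projection through the loadings reconstructs the kept variance", {
  set.seed(5)
  X <- matrix(rnorm(80), 8, 10)
  res <- fit_pca(X, n_components = 3)
  recon <- res$scores %*% res$loadings +
    matrix(res$center, 8, 10, byrow = TRUE)
  err <- sum((X - recon)^2)
  tot <- sum(sweep(X, 2, colMeans(X))^2)
  discarded <- 1 - sum(res$explained_variance_fraction)
  expect_equal(err / tot, discarded, tolerance = 1e-10)
})

test_that("3-PC scores separate the synthetic dose groups", {
  ds <- make_group_spectra(seed = 6)
  res <- fit_pca(preprocess_spectra(ds))
  sep <- score_scatter_3d(res, file = tempfile(fileext = ".png"))
  expect_gt(sep$silhouette, 0.5)
  expect_equal(nrow(sep$centroids), 4)
  # degenerate separation: identical spectra per group -> silhouette ~ 1
  tpl <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  X <- tpl[rep(1:3, each = 4), ] + matrix(rnorm(48, sd = 1e-6), 12, 4)
  r2 <- fit_pca(X, 3)
  s2 <- score_scatter_3d(r2, labels = rep(c("a", "b", "c"), each = 4))
  expect_gt(s2$silhouette, 0.99)
  expect_error(score_scatter_3d(r2, labels = rep("a", 12)), "single group")
})

test_that("welch test reproduces the closed-form statistic", {
  a <- c(10, 12, 14); b <- c(20, 22, 24)
  w <- welch_test(a, b)
  # independent oracle: textbook Welch formulas evaluated inline
  se2 <- var(a) / 3 + var(b) / 3
  t_manual <- (mean(a) - mean(b)) / sqrt(se2)
  df_manual <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  expect_equal(w$t_statistic, t_manual, tolerance = 1e-12)
  expect_equal(w$degrees_of_freedom, df_manual, tolerance = 1e-12)
  expect_equal(w$p_value, p_manual, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t_statistic, 0)
  expect_equal(w0$p_value, 1)
  # large shift at equal variance: decisive rejection
  wl <- welch_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(wl$p_value, 1e-4)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("welch p-values rank like a permutation test", {
  set.seed(12)
  perm_p <- function(a, b, B = 2000) {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    hits <- replicate(B, {
      i <- sample(length(pool), length(a))
      abs(mean(pool[i]) - mean(pool[-i])) >= obs - 1e-12
    })
    mean(hits)
  }
  a <- rnorm(8)
  shifts <- c(0.2, 1, 3)
  wp <- vapply(shifts, function(s) welch_test(a, rnorm(8) + s)$p_value,
               numeric(1))
  set.seed(12)
  a <- rnorm(8)
  pp <- vapply(shifts, function(s) perm_p(a, rnorm(8) + s), numeric(1))
  expect_equal(order(wp), order(pp))
})

test_that("viability correction subtracts the blank background", {
  tab <- data.frame(well_type = c("sample", "blank"),
                    group = c("control", "blank"),
                    exposure_min = c(0, NA), replicate = c(1, 1),
                    a570 = c(0.8, NA), a600 = c(NA, 0.1))
  out <- viability_correct(tab)
  expect_equal(out$corrected_mean, 0.7)
  tab$a570[1] <- 0.1
  expect_equal(viability_correct(tab)$corrected_mean, 0)
  expect_error(viability_correct(tab[tab$well_type == "sample", ]),
               "blank")
  # synthetic monotone configuration stays monotone after correction
  corr <- viability_correct(make_viability_table(noise_sd = 0.005,
                                                 seed = 2))
  expect_true(all(diff(corr$corrected_mean) < 0))
})

test_that("fluence converts irradiance and minutes to J/cm^2", {
  expect_equal(fluence(1.02, c(50, 100, 200), round_to = 1),
               c(0.3, 0.6, 1.2))
  expect_equal(fluence(1.02, 50), 1.02 * 50 * 60 / 1e4)
  expect_equal(fluence(5, 0), 0)
  expect_equal(fluence(1, 1e4 / 60), 1.0)   # unit identity: 1 W/m^2, 1e4 s
  # linear in both arguments
  expect_equal(fluence(2 * 1.3, 7), 2 * fluence(1.3, 7))
  expect_equal(fluence(1.3, 2 * 7), 2 * fluence(1.3, 7))
  expect_error(fluence(-1, 10), "non-negative")
})
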