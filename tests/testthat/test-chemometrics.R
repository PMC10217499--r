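test_that("rank-1 data yields a loading collinear with the generating direction", {
  set.seed(1)
  p <- 40
  dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
  X <- 5 + outer(rnorm(30), dir)
  s <- mk_set(X)
  m <- fit_pca(s, 1)
  expect_gt(abs(sum(m$loadings[, 1] * dir)), 1 - 1e-8)
  # deterministic sign: largest-magnitude element positive
  expect_gt(m$loadings[which.max(abs(m$loadings[, 1])), 1], 0)
})

test_that("full-rank PCA reconstructs centred data and orders variance", {
  set.seed(2)
  X <- matrix(rnorm(20 * 12), 20)
  s <- mk_set(X)
  m <- fit_pca(s, 12)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_lt(max(abs(crossprod(m$loadings) - diag(12))), 1e-8)
  sc <- pca_scores(m, s)
  recon <- sc %*% t(m$loadings)
  expect_lt(max(abs(recon - sweep(X, 2, colMeans(X)))), 1e-8)
  expect_error(fit_pca(s, 20), class = "freshir_rank_error")
})

test_that("two-group canonical axis matches the closed-form whitened mean difference", {
  set.seed(3)
  n <- 120; p <- 30
  X <- matrix(rnorm(n * p, sd = 0.3), n)
  day <- rep(c(0L, 7L), each = n / 2)
  shift <- rnorm(p, sd = 1); X[day == 0, ] <- X[day == 0, ] + rep(shift, each = n / 2)
  s <- mk_set(X, day = day)
  m <- fit_pcda(s, c(0, 7), K = 5, ridge = 0)
  delta <- m$group_means_pc[1, ] - m$group_means_pc[2, ]
  w_ref <- solve(m$pooled_cov_pc, delta)
  cosang <- sum(w_ref * m$canonical_weights[, 1]) /
    sqrt(sum(w_ref^2) * sum(m$canonical_weights[, 1]^2))
  expect_gt(abs(cosang), 0.999999)
  # sign convention: first declared group has positive mean canonical score
  cs <- canonical_scores(m, s)
  expect_gt(mean(cs[day == 0, 1]), 0)
  expect_lt(mean(cs[day == 7, 1]), 0)
})

test_that("identical group means give chance-level membership", {
  set.seed(4)
  X <- matrix(rnorm(80 * 10), 80)
  s <- mk_set(X, day = rep(c(0L, 7L), 40))
  m <- fit_pcda(s, c(0, 7), K = 3)
  mem <- membership(m, s)
  expect_equal(rowSums(mem$probabilities), rep(1, 80), tolerance = 1e-12)
  expect_lt(abs(mean(mem$probabilities[, 1]) - 0.5), 0.1)
})

test_that("membership matches a brute-force nearest-Mahalanobis-mean oracle", {
  cfg <- tiny_scenario(n_fibres = 10, sigma_fibre = 0.1, sigma_noise = 0.01)
  s <- generate_spectra(cfg)
  m <- fit_pcda(s, c(0, 7), K = 4)
  mem <- membership(m, s)
  Tm <- pca_scores(m$pca, s)
  Sinv <- solve(m$pooled_cov_pc)
  oracle <- apply(Tm, 1, function(t) {
    d2 <- sapply(seq_along(m$groups), function(j) {
      d <- t - m$group_means_pc[j, ]
      drop(t(d) %*% Sinv %*% d)
    })
    m$groups[which.min(d2)]
  })
  expect_equal(mem$predicted, oracle)
  # probabilities sum to one per observation
  expect_equal(rowSums(mem$probabilities), rep(1, n_spectra(s)),
               tolerance = 1e-12)
})

test_that("back-projection identity: canonical score equals F1 dot centred spectrum", {
  cfg <- tiny_scenario(n_fibres = 8, sigma_fibre = 0.1, sigma_noise = 0.01)
  s <- generate_spectra(cfg)
  m <- fit_pcda(s, c(0, 7), K = 3)
  f1 <- f1_vector(m)
  cs <- canonical_scores(m, s)
  offset <- sum(m$grand_mean_pc * m$canonical_weights[, 1])
  ip <- sweep(s$intensities, 2, m$pca$mean_spectrum) %*% f1$scores - offset
  expect_lt(max(abs(cs[, 1] - ip)), 1e-8)
})

test_that("with K = 1 the contribution vector is the scaled first loading", {
  set.seed(6)
  X <- matrix(rnorm(40 * 15), 40)
  X[1:20, ] <- X[1:20, ] + 2
  s <- mk_set(X, day = rep(c(0L, 7L), each = 20))
  m <- fit_pcda(s, c(0, 7), K = 1)
  f1 <- f1_vector(m)
  expect_equal(f1$scores,
               as.vector(m$pca$loadings * m$canonical_weights[1, 1]),
               tolerance = 1e-12)
})

test_that("a single differential band is located by the top F1 extremum", {
  bands <- list(mk_band(1100, 14, 0.4, c(`0` = 1, `7` = 1), "neutral"),
                mk_band(1250, 14, 0.4, c(`0` = 1, `7` = 0.5), "freshness"),
                mk_band(1350, 14, 0.4, c(`0` = 1, `7` = 1), "neutral"))
  cfg <- tiny_scenario(bands = bands, n_fibres = 10, sigma_fibre = 0.05,
                       sigma_noise = 0.002)
  s <- generate_spectra(cfg)
  m <- fit_pcda(s, c(0, 7))
  f1 <- f1_vector(m)
  top <- f1$wavenumbers[which.max(abs(f1$scores))]
  expect_lte(abs(top - 1250), 2)
  expect_gt(f1$scores[which.max(abs(f1$scores))], 0)  # fresher group positive
})

test_that("biomarker extraction ranks extrema and handles degenerate vectors", {
  f1 <- structure(list(wavenumbers = seq(1000, 1100, 2),
                       scores = dnorm(seq(1000, 1100, 2), 1050, 8),
                       sign_convention = "positive -> D0", groups = c(0L, 7L)),
                  class = "F1Vector")
  bm <- extract_biomarkers(f1, 1)
  expect_equal(bm$wavenumber[1], 1050)
  expect_equal(bm$associated_group[1], 0L)
  f1$scores <- rep(0, length(f1$scores))
  expect_equal(nrow(extract_biomarkers(f1, 1)), 0)
  expect_error(extract_biomarkers(f1, 0), class = "freshir_validation_error")
})

test_that("PC-DA model survives a JSON round-trip", {
  cfg <- tiny_scenario(n_fibres = 6, sigma_fibre = 0.1, sigma_noise = 0.01)
  s <- generate_spectra(cfg)
  m <- fit_pcda(s, c(0, 7), K = 3)
  f <- tempfile(fileext = ".json")
  write_pcda(m, f)
  m2 <- read_pcda(f)
  expect_equal(canonical_scores(m2, s), canonical_scores(m, s),
               tolerance = 1e-10)
  expect_equal(f1_vector(m2)$scores, f1_vector(m)$scores, tolerance = 1e-10)
})

test_that("ridge guards against a singular pooled covariance", {
  set.seed(8)
  X <- matrix(rnorm(12 * 30), 12)
  s <- mk_set(X, day = rep(c(0L, 7L), each = 6))
  expect_error(fit_pcda(s, c(0, 7), K = 8, ridge = 0),
               class = "freshir_singularity_error")
  m <- fit_pcda(s, c(0, 7), K = 8, ridge = 1e-3)
  expect_equal(m$pca$K, 8)
})
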