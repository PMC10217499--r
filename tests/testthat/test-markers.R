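test_that("the shipped band table carries the 14 fingerprint biomarkers", {
  bt <- band_table()
  expect_equal(nrow(bt), 14)
  expect_true(all(bt$wavenumber >= 900 & bt$wavenumber <= 1780))
  expect_setequal(bt$biomarker_for, c("D0", "D7"))
  expect_equal(sort(bt$wavenumber[bt$biomarker_for == "D7"]),
               c(1002, 1186, 1205, 1490, 1670))
})

test_that("peak intensity recovers noise-free band heights and interpolates linearly", {
  bands <- list(mk_band(1176, 10, 0.5, c(`0` = 1, `7` = 0.5), "freshness"))
  cfg <- tiny_scenario(bands = bands, n_fish = 1, n_fibres = 2)
  s <- generate_spectra(cfg)
  pk <- peak_intensity(s, 1176, 5, "max")
  expect_equal(pk$intensity[s$meta$day == 0], rep(0.5, 2))
  expect_equal(pk$intensity[s$meta$day == 7], rep(0.25, 2))
  expect_equal(pk$wavenumber_found, rep(1176, 4))
  expect_true(all(abs(pk$wavenumber_found - pk$wavenumber_nominal) <=
                    pk$window_halfwidth))
  # interp on a linear ramp gives the exact interpolated value
  ramp <- mk_set(matrix(seq(0, 10, length.out = 11), 1),
                 grid = seq(1000, 1020, 2))
  pi_ <- peak_intensity(ramp, 1007, 5, "interp")
  expect_equal(pi_$intensity, 3.5)
  expect_error(peak_intensity(s, 3000, 5), class = "freshir_empty_crop_error")
})

test_that("band ratios are scale invariant and flag dead denominators", {
  bands <- list(mk_band(1176, 10, 0.5, c(`0` = 1, `7` = 0.5), "freshness"),
                mk_band(1186, 10, 0.5, c(`0` = 1, `7` = 1), "neutral"))
  cfg <- tiny_scenario(bands = bands, n_fish = 1, n_fibres = 2)
  s <- generate_spectra(cfg)
  bt <- data.frame(wavenumber = 1176)
  r1 <- band_ratios(s, bt, denominator = 1186)
  # equal heights at day 0 -> ratio close to 1 (overlapping tails shared)
  expect_equal(r1$ratio[s$meta$day == 0][1], 1, tolerance = 0.05)
  s2 <- s; s2$intensities <- s2$intensities * 7.3
  r2 <- band_ratios(s2, bt, denominator = 1186)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  # zero denominator: per-spectrum error record, not a failure
  z <- mk_set(matrix(0, 2, 201), grid = seq(1000, 1400, 2))
  rz <- band_ratios(z, bt, denominator = 1186)
  expect_true(all(is.na(rz$ratio)))
  expect_true(all(!is.na(rz$error)))
})

test_that("mean 1176/1186 ratio is higher at day 0 than day 7 under default effects", {
  cfg <- default_scenario("paper_effects")
  cfg$n_fibres_per_fish_day <- 10
  pre <- preprocess(generate_spectra(cfg),
                    preprocess_config(normalise = FALSE))
  r <- band_ratios(pre, data.frame(wavenumber = 1176), denominator = 1186)
  m <- tapply(r$ratio, r$day, mean)
  expect_gt(m[["0"]], m[["7"]])
})

test_that("group comparison finds strong effects and handles degenerate input", {
  set.seed(1)
  g <- rep(c("a", "b"), each = 50)
  v <- c(rnorm(50, 0), rnorm(50, 5))
  res <- group_compare(v, g)
  expect_lt(res$p, 1e-3)
  expect_equal(nrow(res$tukey), 1)
  expect_true(res$letters[["a"]] != res$letters[["b"]])
  # all-identical values: documented F = 0 / p = 1 path
  res0 <- group_compare(rep(2, 20), rep(c("a", "b"), each = 10))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_equal(unname(res0$letters), c("a", "a"))
  expect_error(group_compare(1:3, c("a", "a", "b")),
               class = "freshir_validation_error")
})

test_that("Tukey adjusted p is at least the unadjusted pairwise p", {
  set.seed(2)
  g <- rep(c("a", "b", "c"), each = 15)
  v <- rnorm(45) + rep(c(0, 0.4, 0.8), each = 15)
  res <- group_compare(v, g)
  for (r in seq_len(nrow(res$tukey))) {
    sel <- g %in% c(res$tukey$group1[r], res$tukey$group2[r])
    p_t <- stats::t.test(v[sel] ~ g[sel], var.equal = TRUE)$p.value
    expect_gte(res$tukey$p_adj[r] + 1e-10, p_t)
  }
})

test_that("spectra/physchem correlation: exact match, null, and documented coupling", {
  cfg <- default_scenario("paper_effects")
  cfg$n_fibres_per_fish_day <- 9
  s <- generate_spectra(cfg)
  bt <- data.frame(wavenumber = 1247)
  pc <- generate_physchem(cfg)
  # construct a variable exactly equal to the 1247 block means -> r == 1
  seed <- 5
  tab <- correlate_physchem(s, bt, pc, seed = seed)
  expect_true(all(c("band", "variable", "r", "p") %in% names(tab)))
  # solubility couples negatively to the freshness band by design
  expect_lt(tab$r[tab$variable == "solubility"], 0)
  expect_lt(tab$p[tab$variable == "solubility"], 0.05)
  # same seed -> same partition -> identical result
  tab2 <- correlate_physchem(s, bt, pc, seed = seed)
  expect_identical(tab, tab2)
  # mismatched fish/day keys raise an alignment error
  pc_bad <- pc[pc$day != 15, ]
  expect_error(correlate_physchem(s, bt, pc_bad, seed = 1),
               class = "freshir_alignment_error")
})

test_that("an exactly coupled variable attains r == 1", {
  cfg <- tiny_scenario(n_fibres = 9, sigma_fibre = 0.2, sigma_noise = 0.01)
  s <- generate_spectra(cfg)
  bt <- data.frame(wavenumber = 1176)
  # physchem table whose 'solubility' IS the seeded block-mean intensity
  pc <- expand.grid(replicate = 1:3, day = c(0L, 7L),
                    fish_id = c("fish1", "fish2"), KEEP.OUT.ATTRS = FALSE)
  pc <- pc[, c("fish_id", "day", "replicate")]
  pc$pH <- 6.5; pc$proteolysis <- 5; pc$L <- 45; pc$a <- 2; pc$b <- 8
  seed <- 9
  cell <- paste(s$meta$fish_id, s$meta$day)
  block <- integer(n_spectra(s))
  set.seed(seed)
  for (k in unique(cell)) {
    idx <- which(cell == k)
    block[idx] <- sample(rep_len(1:3, length(idx)))
  }
  pk <- peak_intensity(s, 1176, 5, "max")
  bm <- tapply(pk$intensity, paste(cell, block), mean)
  pc$solubility <- as.vector(bm[match(paste(pc$fish_id, pc$day, pc$replicate),
                                      names(bm))])
  tab <- correlate_physchem(s, bt, pc, seed = seed)
  expect_equal(tab$r[tab$variable == "solubility"], 1, tolerance = 1e-10)
})

test_that("the seeded tripartition is a true partition of each fish/day cell", {
  cfg <- tiny_scenario(n_fibres = 7)
  s <- generate_spectra(cfg)
  cell <- paste(s$meta$fish_id, s$meta$day)
  set.seed(3)
  block <- integer(n_spectra(s))
  for (k in unique(cell)) {
    idx <- which(cell == k)
    block[idx] <- sample(rep_len(1:3, length(idx)))
  }
  for (k in unique(cell)) {
    b <- block[cell == k]
    expect_setequal(unique(b), 1:3)
    expect_equal(length(b), 7)
  }
})
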