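# compact scenario builders used across test files

mk_band <- function(center, fwhm = 12, amp = 0.2,
                    factors = c(`0` = 1, `7` = 1), role = "neutral") {
  band_definition(center, fwhm, amp, factors, role)
}

# small two-day scenario: narrow grid, few spectra, configurable noise
tiny_scenario <- function(days = c(0L, 7L), n_fish = 2, n_fibres = 6,
                          bands = NULL, sigma_fish = 0, sigma_fibre = 0,
                          sigma_noise = 0, baseline_coeff_scale = 0,
                          global_scale_range = c(1, 1), seed = 1L,
                          grid_min = 1000, grid_max = 1400) {
  if (is.null(bands))
    bands <- list(mk_band(1176, 10, 0.5,
                          stats::setNames(seq(1, 0.5, length.out = length(days)),
                                          days),
                          if (length(days) > 1) "freshness" else "neutral"))
  scenario_config(grid_min = grid_min, grid_max = grid_max, grid_step = 2,
                  days = days, n_fish = n_fish,
                  n_fibres_per_fish_day = n_fibres, bands = bands,
                  baseline_coeff_scale = baseline_coeff_scale,
                  sigma_fish = sigma_fish, sigma_fibre = sigma_fibre,
                  sigma_noise = sigma_noise,
                  global_scale_range = global_scale_range, seed = seed)
}

# a bare SpectraSet from a matrix, for tests that bypass the generator
mk_set <- function(mat, grid = NULL, day = NULL) {
  n <- nrow(mat)
  if (is.null(grid)) grid <- seq(1000, by = 2, length.out = ncol(mat))
  if (is.null(day)) day <- rep(0L, n)
  spectra_set(grid, mat,
              data.frame(spectrum_id = sprintf("s%03d", seq_len(n)),
                         fish_id = "f1", day = day,
                         fibre_id = sprintf("c%03d", seq_len(n))))
}
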