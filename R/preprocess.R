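#' Pre-processing configuration
#'
#' Parameters of the spectral pre-processing chain: iterative polynomial
#' baseline correction on the full acquired grid, cropping to the analysis
#' (fingerprint) region, and vector normalisation over the cropped region.
#'
#' @param poly_order baseline polynomial order (default 5).
#' @param max_iterations iteration cap of the baseline scheme (default 200).
#' @param convergence_tol early-stop threshold on the relative change of the
#'   baseline estimate, `max|dp| / max|p|` (default 1e-6).
#' @param crop_min,crop_max analysis region bounds, cm\eqn{^{-1}}
#'   (defaults 900 and 1780).
#' @param normalise scale each cropped spectrum to unit Euclidean norm
#'   (default `TRUE`).
#' @param normalise_before_crop sensitivity switch: normalise on the full
#'   baseline-corrected grid before cropping instead (default `FALSE`).
#' @return a `PreprocessConfig` list.
#' @export
preprocess_config <- function(poly_order = 5, max_iterations = 200,
                              convergence_tol = 1e-6,
                              crop_min = 900, crop_max = 1780,
                              normalise = TRUE,
                              normalise_before_crop = FALSE) {
  if (poly_order < 0) abort("poly_order must be >= 0", "freshir_validation_error")
  if (max_iterations < 1) abort("max_iterations must be >= 1", "freshir_validation_error")
  if (crop_min >= crop_max) abort("crop_min must be < crop_max", "freshir_validation_error")
  structure(list(poly_order = poly_order, max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 crop_min = crop_min, crop_max = crop_max,
                 normalise = normalise,
                 normalise_before_crop = normalise_before_crop),
            class = "PreprocessConfig")
}

# Iterative-minimum polynomial baseline (ModPoly) on a p x n column matrix.
# Each iteration fits a least-squares polynomial to the working vector and
# clips the working vector to the fit; converged columns are frozen so a
# 1-column call and a batched call give identical results.
modpoly_matrix <- function(grid, W, order, max_iterations, tol) {
  p <- nrow(W)
  if (p < order + 2)
    abort(sprintf("baseline fit under-determined: %d points for order %d (need >= %d)",
                  p, order, order + 2), "freshir_underdetermined_error")
  xs <- rescale_axis(grid)
  basis <- cbind(1, stats::poly(xs, degree = order))
  Q <- qr.Q(qr(basis))                       # orthonormal, p x (order+1)
  project <- function(M) Q %*% crossprod(Q, M)
  P <- project(W)
  active <- rep(TRUE, ncol(W))
  for (it in seq_len(max_iterations)) {
    if (!any(active)) break
    Wa <- pmin(W[, active, drop = FALSE], P[, active, drop = FALSE])
    Pn <- project(Wa)
    dmax <- apply(abs(Pn - P[, active, drop = FALSE]), 2, max)
    pmax_ <- apply(abs(Pn), 2, max)
    rel <- ifelse(pmax_ > 0, dmax / pmax_, 0)
    W[, active] <- Wa
    P[, active] <- Pn
    active[active] <- rel >= tol
  }
  P
}

#' Iterative polynomial (ModPoly) baseline correction
#'
#' Repeatedly fits a least-squares polynomial of the given order to a
#' working copy of the spectrum and clips the working copy to the
#' elementwise minimum of itself and the fit. The fit converges to a curve
#' lying under the peaks; iteration stops at `max_iterations` or when the
#' relative change of the baseline estimate drops below `tol`. The
#' polynomial is fitted in an orthogonal basis on a wavenumber axis rescaled
#' to \[-1, 1\], so order-5 fits over wide grids stay well conditioned.
#'
#' @param spectrum a `Spectrum` (see [get_spectrum()]).
#' @param order polynomial order (default 5).
#' @param max_iterations iteration cap (default 200).
#' @param tol relative-change early-stop threshold (default 1e-6).
#' @return list with `baseline` (numeric vector on the grid) and `corrected`
#'   (a `Spectrum`, original minus baseline, same grid and metadata).
#' @export
modpoly_baseline <- function(spectrum, order = 5, max_iterations = 200,
                             tol = 1e-6) {
  if (!all(is.finite(spectrum$intensities)))
    abort("spectrum contains non-finite intensities", "freshir_validation_error")
  P <- modpoly_matrix(spectrum$wavenumbers,
                      matrix(spectrum$intensities, ncol = 1),
                      order, max_iterations, tol)
  baseline <- as.vector(P)
  corrected <- spectrum
  corrected$intensities <- spectrum$intensities - baseline
  list(baseline = baseline, corrected = corrected)
}

# same scheme applied to every spectrum of a set (shared grid)
modpoly_correct_set <- function(set, order = 5, max_iterations = 200, tol = 1e-6) {
  P <- modpoly_matrix(set$grid, t(set$intensities), order, max_iterations, tol)
  out <- set
  out$intensities <- set$intensities - t(P)
  out
}

#' Scale a spectrum to unit Euclidean norm
#'
#' Removes global intensity effects (section thickness, aperture coupling):
#' two spectra identical up to a positive scalar map to the same output.
#'
#' @param spectrum a `Spectrum`.
#' @return the normalised `Spectrum`.
#' @export
vector_normalise <- function(spectrum) {
  nrm <- sqrt(sum(spectrum$intensities^2))
  if (nrm == 0)
    abort(paste0("cannot normalise zero spectrum",
                 if (!is.null(spectrum$meta$spectrum_id))
                   paste0(" '", spectrum$meta$spectrum_id, "'") else ""),
          "freshir_normalisation_error")
  spectrum$intensities <- spectrum$intensities / nrm
  spectrum
}

normalise_set <- function(set) {
  nrm <- sqrt(rowSums(set$intensities^2))
  if (any(nrm == 0))
    abort(paste0("cannot normalise zero spectrum: ",
                 paste(set$meta$spectrum_id[nrm == 0], collapse = ", ")),
          "freshir_normalisation_error")
  set$intensities <- set$intensities / nrm
  set
}

#' Crop a spectrum or set to a wavenumber interval
#'
#' Closed-interval selection: points with `wmin <= w <= wmax` are retained;
#' metadata are preserved.
#'
#' @param x a `Spectrum` or `SpectraSet`.
#' @param wmin,wmax interval bounds, cm\eqn{^{-1}}.
#' @return object of the same class on the cropped grid.
#' @export
crop <- function(x, wmin, wmax) UseMethod("crop")

#' @export
crop.Spectrum <- function(x, wmin, wmax) {
  keep <- crop_index(x$wavenumbers, wmin, wmax)
  x$wavenumbers <- x$wavenumbers[keep]
  x$intensities <- x$intensities[keep]
  x
}

#' @export
crop.SpectraSet <- function(x, wmin, wmax) {
  keep <- crop_index(x$grid, wmin, wmax)
  spectra_set(x$grid[keep], x$intensities[, keep, drop = FALSE], x$meta)
}

crop_index <- function(grid, wmin, wmax) {
  eps <- 1e-9 * max(1, abs(wmax))
  keep <- which(grid >= wmin - eps & grid <= wmax + eps)
  if (!length(keep))
    abort(sprintf("crop [%g, %g] does not overlap the grid [%g, %g]",
                  wmin, wmax, min(grid), max(grid)), "freshir_empty_crop_error")
  keep
}

#' Run the full pre-processing chain on a set
#'
#' Applies, per spectrum and in this fixed order:
#' 1. subtraction of `reference` (e.g. a substrate background), if given;
#' 2. ModPoly baseline correction on the full acquired grid;
#' 3. cropping to `[crop_min, crop_max]`;
#' 4. vector normalisation over the cropped region (when enabled).
#'
#' The baseline is estimated before cropping so the polynomial is anchored
#' outside the analysis region; the unit-norm constraint applies to the
#' analysed fingerprint only (set `normalise_before_crop = TRUE` to
#' normalise on the full corrected grid instead).
#'
#' @param set a `SpectraSet`.
#' @param config a [preprocess_config()].
#' @param reference optional `Spectrum` on the same grid, subtracted first.
#' @return the pre-processed `SpectraSet` (same spectra, cropped grid).
#' @examples
#' cfg <- default_scenario("paper_effects"); cfg$n_fibres_per_fish_day <- 2
#' pre <- preprocess(generate_spectra(cfg), preprocess_config())
#' range(sqrt(rowSums(pre$intensities^2)))  # all 1
#' @export
preprocess <- function(set, config = preprocess_config(), reference = NULL) {
  stopifnot(inherits(set, "SpectraSet"), inherits(config, "PreprocessConfig"))
  if (!is.null(reference)) {
    if (!identical(reference$wavenumbers, set$grid))
      abort("reference spectrum is not on the set's grid", "freshir_grid_error")
    set$intensities <- sweep(set$intensities, 2, reference$intensities)
  }
  out <- modpoly_correct_set(set, config$poly_order, config$max_iterations,
                             config$convergence_tol)
  if (config$normalise && config$normalise_before_crop) out <- normalise_set(out)
  out <- crop(out, config$crop_min, config$crop_max)
  if (config$normalise && !config$normalise_before_crop) out <- normalise_set(out)
  out
}
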