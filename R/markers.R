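#' The packaged biomarker band table
#'
#' Fourteen fingerprint-region bands with their freshness association
#' (`D0` = fresh, `D7` = aged), molecular bond and compound assignment.
#' Ranges quoted in the literature (1172–1176, 1204–1206 cm\eqn{^{-1}}) are
#' represented by single centres at 1176 and 1205 cm\eqn{^{-1}}.
#'
#' @return data.frame with columns `wavenumber`, `biomarker_for`,
#'   `molecular_bond`, `biological_compounds`.
#' @export
band_table <- function() {
  path <- system.file("extdata", "band_table.csv", package = "freshir",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Peak intensity at a nominal wavenumber
#'
#' For each spectrum, either the maximum intensity within a closed window
#' around the nominal wavenumber (`mode = "max"`, with the location of the
#' maximum reported) or the linear interpolation exactly at the nominal
#' wavenumber (`mode = "interp"`).
#'
#' @param set a `SpectraSet`.
#' @param wavenumber nominal band position, cm\eqn{^{-1}}.
#' @param window half-width of the search window, cm\eqn{^{-1}} (default 5).
#' @param mode `"max"` or `"interp"`.
#' @return data.frame with `spectrum_id`, `wavenumber_nominal`,
#'   `wavenumber_found`, `intensity`, `window_halfwidth`.
#' @export
peak_intensity <- function(set, wavenumber, window = 5.0,
                           mode = c("max", "interp")) {
  mode <- match.arg(mode)
  eps <- 1e-9 * max(1, abs(wavenumber))
  idx <- which(abs(set$grid - wavenumber) <= window + eps)
  if (!length(idx))
    abort(sprintf("window %g +/- %g does not overlap the grid", wavenumber, window),
          "freshir_empty_crop_error")
  if (mode == "max") {
    sub <- set$intensities[, idx, drop = FALSE]
    j <- apply(sub, 1, which.max)
    found <- set$grid[idx[j]]
    val <- sub[cbind(seq_len(nrow(sub)), j)]
  } else {
    found <- rep(wavenumber, n_spectra(set))
    val <- apply(set$intensities, 1, function(y)
      stats::approx(set$grid, y, xout = wavenumber, rule = 2)$y)
  }
  data.frame(spectrum_id = set$meta$spectrum_id,
             wavenumber_nominal = wavenumber, wavenumber_found = found,
             intensity = val, window_halfwidth = window)
}

#' Ratiometric band analysis against a reference band
#'
#' Computes, per spectrum, the ratio of each band's peak intensity to the
#' reference (denominator) band's peak intensity. Ratios are invariant to
#' global multiplicative rescaling of a spectrum. A zero or negative
#' denominator yields an `NA` ratio flagged in the `error` column rather
#' than a global failure.
#'
#' @param set a `SpectraSet`.
#' @param bands a [band_table()]-shaped data.frame (column `wavenumber`).
#' @param denominator reference band position, cm\eqn{^{-1}} (default 1186,
#'   the amide III reference).
#' @param window,mode passed to [peak_intensity()].
#' @return long data.frame with `spectrum_id`, `day`, `band`, `ratio`,
#'   `error`.
#' @export
band_ratios <- function(set, bands = band_table(), denominator = 1186,
                        window = 5.0, mode = "max") {
  den <- peak_intensity(set, denominator, window, mode)
  bad <- den$intensity <= 0
  out <- lapply(bands$wavenumber, function(b) {
    num <- peak_intensity(set, b, window, mode)
    data.frame(spectrum_id = set$meta$spectrum_id, day = set$meta$day,
               band = b,
               ratio = ifelse(bad, NA_real_, num$intensity / den$intensity),
               error = ifelse(bad, "non-positive denominator intensity",
                              NA_character_))
  })
  do.call(rbind, out)
}

#' One-way ANOVA with Tukey HSD post hoc comparison
#'
#' Standard one-way ANOVA of a per-spectrum scalar against day groups,
#' followed by Tukey honest-significant-difference pairwise comparisons and
#' compact significance letters at the 0.05 level. Degenerate input with
#' zero variance everywhere is reported as `F = 0`, `p = 1` (no evidence of
#' group differences) rather than an error.
#'
#' @param values numeric vector of per-spectrum scalars.
#' @param labels group label per value (e.g. postmortem day).
#' @param alpha significance level for the letters (default 0.05).
#' @return list with `F`, `p`, `tukey` (pairwise table with adjusted p) and
#'   `letters` (named group letters; groups sharing a letter are not
#'   significantly different).
#' @export
group_compare <- function(values, labels, alpha = 0.05) {
  g <- factor(labels)
  if (nlevels(g) < 2) abort("need at least 2 groups", "freshir_validation_error")
  if (any(table(g) < 2))
    abort("every group needs at least 2 values", "freshir_validation_error")
  if (stats::var(values) == 0) {
    lv <- levels(g)
    pairs <- t(utils::combn(lv, 2))
    return(list(F = 0, p = 1,
                tukey = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                                   diff = 0, lwr = 0, upr = 0, p_adj = 1),
                letters = stats::setNames(rep("a", length(lv)), lv)))
  }
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(group1 = vapply(cmp, `[`, "", 2),
                      group2 = vapply(cmp, `[`, "", 1),
                      diff = -tk[, "diff"], lwr = -tk[, "upr"],
                      upr = -tk[, "lwr"], p_adj = tk[, "p adj"],
                      row.names = NULL)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], tukey = tukey,
       letters = cld_letters(tukey, levels(g),
                             tapply(values, g, mean), alpha))
}

# compact letter display: groups sharing a letter are not significantly
# different (insert-and-absorb on the pairwise adjusted p matrix)
cld_letters <- function(tukey, groups, means, alpha) {
  G <- length(groups)
  sig <- matrix(FALSE, G, G, dimnames = list(groups, groups))
  for (r in seq_len(nrow(tukey))) {
    s <- tukey$p_adj[r] < alpha
    sig[tukey$group1[r], tukey$group2[r]] <- s
    sig[tukey$group2[r], tukey$group1[r]] <- s
  }
  ord <- order(means, decreasing = TRUE)
  cols <- list()
  for (gi in ord) {
    placed <- FALSE
    for (ci in seq_along(cols)) {
      if (!any(sig[gi, cols[[ci]]])) {
        cols[[ci]] <- c(cols[[ci]], gi); placed <- TRUE
      }
    }
    if (!placed) cols[[length(cols) + 1]] <- gi
  }
  lab <- stats::setNames(rep("", G), groups)
  for (ci in seq_along(cols))
    for (gi in cols[[ci]])
      lab[gi] <- paste0(lab[gi], letters[ci])
  lab
}

#' Correlate band intensities with physicochemical measurements
#'
#' Within each fish/day cell, the spectra are randomly partitioned
#' (seeded) into three blocks to match the three physicochemical
#' replicates; the block-mean peak intensity of each band is paired with
#' the corresponding replicate, and Pearson correlation is computed per
#' band and variable across all fish/day/replicate pairs.
#'
#' @param set a `SpectraSet`.
#' @param bands a [band_table()]-shaped data.frame.
#' @param physchem a [generate_physchem()]-shaped data.frame (3 replicates
#'   per fish/day).
#' @param seed integer seed making the random tripartition reproducible.
#' @param window,mode passed to [peak_intensity()].
#' @return data.frame with `band`, `variable`, `r`, `p`, `n`.
#' @export
correlate_physchem <- function(set, bands = band_table(), physchem,
                               seed = 1, window = 5.0, mode = "max") {
  key_s <- unique(paste(set$meta$fish_id, set$meta$day))
  key_p <- unique(paste(physchem$fish_id, physchem$day))
  if (!setequal(key_s, key_p))
    abort(paste0("fish/day mismatch between spectra and physchem: ",
                 paste(union(setdiff(key_s, key_p), setdiff(key_p, key_s)),
                       collapse = ", ")), "freshir_alignment_error")
  cell <- paste(set$meta$fish_id, set$meta$day)
  block <- integer(n_spectra(set))
  with_seed(seed, {
    for (k in unique(cell)) {
      idx <- which(cell == k)
      block[idx] <- sample(rep_len(1:3, length(idx)))
    }
  })
  pvars <- c("pH", "solubility", "proteolysis", "L", "a", "b")
  pkey <- paste(physchem$fish_id, physchem$day, physchem$replicate)
  out <- list()
  for (b in bands$wavenumber) {
    pk <- peak_intensity(set, b, window, mode)
    bm <- tapply(pk$intensity, paste(cell, block), mean)
    m <- match(pkey, names(bm))
    if (anyNA(m))
      abort("physicochemical replicates without matching spectral block",
            "freshir_alignment_error")
    x <- as.vector(bm[m])
    for (v in pvars) {
      y <- physchem[[v]]
      ct <- if (stats::sd(y) == 0 || stats::sd(x) == 0) NULL else
        tryCatch(stats::cor.test(x, y, method = "pearson"),
                 error = function(e) NULL)
      out[[length(out) + 1]] <- data.frame(
        band = b, variable = v,
        r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
        p = if (is.null(ct)) NA_real_ else ct$p.value, n = length(x))
    }
  }
  do.call(rbind, out)
}
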