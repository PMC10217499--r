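#' Principal component analysis of a spectra set
#'
#' Mean-centred (no variance scaling) decomposition of the intensity matrix.
#' Loadings carry a deterministic sign: the largest-magnitude element of
#' each loading is positive.
#'
#' @param set a `SpectraSet` on a common grid.
#' @param K number of components to retain; `1 <= K <= min(n - 1, n_points)`.
#' @return a `PCAModel`: list with `grid`, `mean_spectrum`, `loadings`
#'   (`n_points x K`, orthonormal columns), `explained_variance`
#'   (non-increasing component variances) and `K`.
#' @export
fit_pca <- function(set, K) {
  n <- n_spectra(set)
  p <- length(set$grid)
  if (K < 1 || K > min(n - 1, p))
    abort(sprintf("K = %d outside valid range [1, %d] for %d spectra x %d points",
                  K, min(n - 1, p), n, p), "freshir_rank_error")
  pr <- stats::prcomp(set$intensities, center = TRUE, scale. = FALSE, rank. = K)
  L <- pr$rotation[, seq_len(K), drop = FALSE]
  flip <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
  L <- sweep(L, 2, flip, `*`)
  dimnames(L) <- NULL
  structure(list(grid = set$grid, mean_spectrum = as.vector(pr$center),
                 loadings = L, explained_variance = pr$sdev[seq_len(K)]^2,
                 K = K),
            class = "PCAModel")
}

#' PC scores of spectra under a fitted PCA model
#'
#' @param model a `PCAModel`.
#' @param set a `SpectraSet` on the model's grid.
#' @return `n x K` score matrix.
#' @export
pca_scores <- function(model, set) {
  if (!identical(set$grid, model$grid))
    abort("set is not on the model's wavenumber grid", "freshir_grid_error")
  sweep(set$intensities, 2, model$mean_spectrum) %*% model$loadings
}

# smallest K explaining >= frac of the variance, capped
choose_K <- function(set, frac = 0.95, cap = 15) {
  n <- n_spectra(set); p <- length(set$grid)
  kmax <- min(n - 1, p, 50)
  sdev <- stats::prcomp(set$intensities, center = TRUE, scale. = FALSE,
                        rank. = kmax)$sdev
  v <- sdev^2
  cum <- cumsum(v) / sum(v)
  min(which(cum >= frac)[1], cap, kmax)
}

#' Discriminant analysis on principal-component scores (PC-DA)
#'
#' Fits PCA to the spectra of the requested day groups, then a linear
#' discriminant model in PC-score space: for two groups the canonical axis
#' is the classical direction `pooled_cov^-1 (mean1 - mean2)`; for more
#' groups, the leading eigenvectors of `pooled_cov^-1 B` with `B` the
#' between-group scatter. The pooled covariance is regularised as
#' `cov + ridge * trace(cov)/K * I`. Each canonical axis is oriented so the
#' first declared group (by convention the fresher day) has a positive mean
#' canonical score.
#'
#' @param set a `SpectraSet`.
#' @param groups two or more day labels, in the order defining the sign
#'   convention (first group scores positive).
#' @param K number of PCs; `NULL` selects the smallest K explaining
#'   `var_frac` of the variance, capped at 15.
#' @param ridge covariance regularisation strength (default `1e-6`; `0`
#'   allowed when the pooled covariance is non-singular).
#' @param var_frac variance fraction used by the automatic K rule.
#' @return a `PCDAModel`: list with `pca`, `groups`, `canonical_weights`
#'   (`K x n_axes`), `group_means_pc`, `pooled_cov_pc`, `grand_mean_pc`,
#'   `n_axes` and per-group sizes.
#' @export
fit_pcda <- function(set, groups, K = NULL, ridge = 1e-6, var_frac = 0.95) {
  groups <- as.integer(groups)
  if (length(groups) < 2) abort("need at least two groups", "freshir_validation_error")
  sub <- subset_days(set, groups)
  counts <- table(factor(sub$meta$day, levels = groups))
  if (any(counts < 2))
    abort(paste0("group(s) with fewer than 2 spectra: ",
                 paste(groups[counts < 2], collapse = ", ")),
          "freshir_validation_error")
  if (is.null(K)) K <- choose_K(sub, var_frac)
  if (any(counts < K + 2) && ridge <= 0)
    abort("a group has fewer than K + 2 members; use ridge > 0",
          "freshir_singularity_error")
  pca <- fit_pca(sub, K)
  Tm <- pca_scores(pca, sub)
  g <- factor(sub$meta$day, levels = groups)
  G <- length(groups)
  n <- nrow(Tm)
  means <- t(sapply(levels(g), function(l) colMeans(Tm[g == l, , drop = FALSE])))
  if (K == 1) means <- matrix(means, ncol = 1, dimnames = list(levels(g), NULL))
  Sw <- matrix(0, K, K)
  for (l in levels(g)) {
    Tl <- Tm[g == l, , drop = FALSE]
    Sw <- Sw + crossprod(sweep(Tl, 2, colMeans(Tl)))
  }
  Sw <- Sw / (n - G)
  covR <- Sw + ridge * sum(diag(Sw)) / K * diag(K)
  solve_cov <- function(b) tryCatch(solve(covR, b), error = function(e)
    abort("pooled covariance is singular; refit with ridge > 0",
          "freshir_singularity_error"))
  n_axes <- min(K, G - 1)
  if (G == 2) {
    W <- matrix(solve_cov(means[1, ] - means[2, ]), ncol = 1)
  } else {
    grand <- colMeans(Tm)
    B <- matrix(0, K, K)
    for (l in levels(g)) {
      d <- means[l, ] - grand
      B <- B + sum(g == l) * tcrossprod(d)
    }
    ev <- eigen(solve_cov(B))
    W <- Re(ev$vectors[, seq_len(n_axes), drop = FALSE])
  }
  W <- sweep(W, 2, sqrt(colSums(W^2)), `/`)   # unit-length axes
  grand_mean_pc <- colMeans(Tm)
  # sign convention: first group positive on every axis
  sc1 <- (means[1, , drop = FALSE] - matrix(grand_mean_pc, 1)) %*% W
  flip <- ifelse(as.vector(sc1) >= 0, 1, -1)
  W <- sweep(W, 2, flip, `*`)
  structure(list(pca = pca, groups = groups, canonical_weights = W,
                 group_means_pc = means, pooled_cov_pc = covR,
                 grand_mean_pc = grand_mean_pc, n_axes = n_axes,
                 group_sizes = as.vector(counts), ridge = ridge),
            class = "PCDAModel")
}

#' @export
print.PCDAModel <- function(x, ...) {
  cat(sprintf("<PCDAModel> groups D%s | K = %d PCs | %d canonical axis(es) | n = %s\n",
              paste(x$groups, collapse = "/D"), x$pca$K, x$n_axes,
              paste(x$group_sizes, collapse = "+")))
  invisible(x)
}

#' Canonical scores of spectra under a PC-DA model
#'
#' Projection of each spectrum's centred PC scores onto the canonical
#' axis/axes.
#'
#' @param model a `PCDAModel`.
#' @param set a `SpectraSet` on the model's grid.
#' @return `n x n_axes` matrix of canonical scores.
#' @export
canonical_scores <- function(model, set) {
  Tm <- pca_scores(model$pca, set)
  sweep(Tm, 2, model$grand_mean_pc) %*% model$canonical_weights
}

#' Mahalanobis group-membership probabilities
#'
#' Squared Mahalanobis distance of each spectrum's PC scores to each group
#' mean under the pooled (regularised) covariance; membership probability
#' is proportional to `exp(-D^2/2)`, normalised over groups. The predicted
#' group is the argmax (ties resolve to the first declared group).
#'
#' @param model a `PCDAModel`.
#' @param set a `SpectraSet` on the model's grid.
#' @return list with `probabilities` (`n x G` matrix, rows summing to 1)
#'   and `predicted` (integer day labels).
#' @export
membership <- function(model, set) {
  Tm <- pca_scores(model$pca, set)
  Sinv <- solve(model$pooled_cov_pc)
  D2 <- sapply(seq_along(model$groups), function(j) {
    d <- sweep(Tm, 2, model$group_means_pc[j, ])
    rowSums((d %*% Sinv) * d)
  })
  if (is.null(dim(D2))) D2 <- matrix(D2, nrow = 1)
  logw <- -D2 / 2
  logw <- logw - apply(logw, 1, max)
  P <- exp(logw)
  P <- P / rowSums(P)
  colnames(P) <- paste0("D", model$groups)
  pred <- model$groups[apply(P, 1, which.max)]
  list(probabilities = P, predicted = pred)
}

#' Discriminant contribution vector back-projected to wavenumbers
#'
#' Sums, over the retained PCs, the product of the canonical (discriminant)
#' weight of each PC with that PC's loading, yielding a wavenumber-indexed
#' contribution vector: positive values are associated with the first
#' declared group, negative with the second. Its extrema mark the bands
#' driving the group separation (the biomarker-identification device).
#'
#' For every spectrum `x`, the canonical score equals
#' `sum(contribution * (x - mean_spectrum))` up to the (near-zero) grand
#' mean offset — the back-projection identity used as this module's oracle.
#'
#' @param model a `PCDAModel`.
#' @param axis canonical axis index (default 1).
#' @return an `F1Vector`: list with `wavenumbers`, `scores`,
#'   `sign_convention` and `groups`.
#' @export
f1_vector <- function(model, axis = 1) {
  if (axis < 1 || axis > model$n_axes)
    abort(sprintf("axis %d out of range (model has %d)", axis, model$n_axes),
          "freshir_validation_error")
  scores <- as.vector(model$pca$loadings %*% model$canonical_weights[, axis])
  structure(list(wavenumbers = model$pca$grid, scores = scores,
                 sign_convention = sprintf("positive -> D%d", model$groups[1]),
                 groups = model$groups),
            class = "F1Vector")
}

#' @export
print.F1Vector <- function(x, ...) {
  cat(sprintf("<F1Vector> %d points [%g-%g cm-1], %s\n", length(x$scores),
              min(x$wavenumbers), max(x$wavenumbers), x$sign_convention))
  invisible(x)
}

#' Rank contribution-vector extrema as candidate biomarkers
#'
#' Finds local extrema of the absolute contribution score, ranks them by
#' magnitude and returns the top fraction, each attributed to a group by
#' the sign convention (positive = first group).
#'
#' @param f1 an `F1Vector`.
#' @param top_fraction fraction of extrema to return, in (0, 1\].
#' @return data.frame with `wavenumber`, `score`, `associated_group`
#'   (day label), ordered by decreasing `|score|`; empty for a flat vector.
#' @export
extract_biomarkers <- function(f1, top_fraction = 0.25) {
  if (top_fraction <= 0 || top_fraction > 1)
    abort("top_fraction must be in (0, 1]", "freshir_validation_error")
  s <- f1$scores
  a <- abs(s)
  empty <- data.frame(wavenumber = numeric(), score = numeric(),
                      associated_group = integer())
  if (all(a < .Machine$double.eps * 100)) return(empty)
  n <- length(a)
  if (n < 3) return(empty)
  i <- 2:(n - 1)
  ext <- i[a[i] >= a[i - 1] & a[i] >= a[i + 1] & a[i] > 0]
  # collapse plateaus to their first point
  if (length(ext) > 1) ext <- ext[c(TRUE, diff(ext) > 1 | diff(a[ext]) != 0)]
  if (!length(ext)) return(empty)
  o <- ext[order(a[ext], decreasing = TRUE)]
  keep <- o[seq_len(ceiling(top_fraction * length(o)))]
  data.frame(wavenumber = f1$wavenumbers[keep], score = s[keep],
             associated_group = ifelse(s[keep] > 0, f1$groups[1], f1$groups[2]))
}

#' Export / import a PC-DA model as JSON
#'
#' Serialises grid, mean spectrum, loadings, canonical weights and group
#' statistics at full precision for reproducible re-scoring.
#'
#' @param model a `PCDAModel`.
#' @param path JSON file path.
#' @export
write_pcda <- function(model, path) {
  obj <- list(grid = model$pca$grid, mean_spectrum = model$pca$mean_spectrum,
              loadings = model$pca$loadings,
              explained_variance = model$pca$explained_variance,
              K = model$pca$K, groups = model$groups,
              canonical_weights = model$canonical_weights,
              group_means_pc = model$group_means_pc,
              pooled_cov_pc = model$pooled_cov_pc,
              grand_mean_pc = model$grand_mean_pc, n_axes = model$n_axes,
              group_sizes = model$group_sizes, ridge = model$ridge)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pcda
#' @export
read_pcda <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_mat <- function(m, ...) {
    m <- matrix(as.numeric(m), ...)
    m
  }
  pca <- structure(list(grid = as.numeric(o$grid),
                        mean_spectrum = as.numeric(o$mean_spectrum),
                        loadings = num_mat(o$loadings, ncol = o$K),
                        explained_variance = as.numeric(o$explained_variance),
                        K = o$K),
                   class = "PCAModel")
  structure(list(pca = pca, groups = as.integer(o$groups),
                 canonical_weights = num_mat(o$canonical_weights, ncol = o$n_axes),
                 group_means_pc = num_mat(o$group_means_pc, nrow = length(o$groups)),
                 pooled_cov_pc = num_mat(o$pooled_cov_pc, nrow = o$K),
                 grand_mean_pc = as.numeric(o$grand_mean_pc), n_axes = o$n_axes,
                 group_sizes = as.numeric(o$group_sizes), ridge = o$ridge),
            class = "PCDAModel")
}
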