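#' Cross-validated support-vector classification of postmortem day
#'
#' Stratified, seeded k-fold cross-validation of an RBF-kernel support
#' vector classifier predicting the day label from the (pre-processed)
#' intensity matrix. Every spectrum is predicted exactly once by a model
#' not trained on it; the confusion matrix is pooled over folds.
#'
#' `gamma = "scale"` resolves to `1 / (n_features * var)` with `var` the
#' population variance of the whole feature matrix — the conventional
#' data-driven default. Features are not re-scaled.
#'
#' @param set a `SpectraSet` (typically the output of [preprocess()]).
#' @param folds number of folds (default 10); every class needs at least
#'   `folds` members.
#' @param seed integer seed driving the fold assignment.
#' @param C soft-margin cost (default 1).
#' @param gamma `"scale"` or a positive real RBF width parameter.
#' @return a `CVReport`: list with `confusion` (rows = true day, columns =
#'   predicted), `per_class_accuracy` (%), `overall_accuracy` (%), `folds`,
#'   `seed` and `hyperparams`.
#' @examples
#' cfg <- default_scenario("paper_effects"); cfg$n_fibres_per_fish_day <- 5
#' pre <- preprocess(generate_spectra(cfg))
#' rep <- svm_cv(pre, folds = 3, seed = 1)
#' rep$overall_accuracy
#' @export
svm_cv <- function(set, folds = 10, seed = 1, C = 1, gamma = "scale") {
  y <- factor(set$meta$day, levels = sort(unique(set$meta$day)))
  counts <- table(y)
  if (any(counts < folds))
    abort(paste0("class(es) with fewer members than folds: day ",
                 paste(names(counts)[counts < folds], collapse = ", ")),
          "freshir_fold_error")
  X <- set$intensities
  g <- if (identical(gamma, "scale")) {
    v <- mean((X - mean(X))^2)
    1 / (ncol(X) * v)
  } else as.numeric(gamma)
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    te <- fold_id == f
    fit <- e1071::svm(x = X[!te, , drop = FALSE], y = y[!te],
                      type = "C-classification", kernel = "radial",
                      cost = C, gamma = g, scale = FALSE)
    pred[te] <- stats::predict(fit, X[te, , drop = FALSE])
  }
  confusion <- table(true = y, predicted = pred)
  confusion <- matrix(confusion, nrow = nlevels(y),
                      dimnames = list(true = levels(y), predicted = levels(y)))
  per_class <- 100 * diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion,
                 per_class_accuracy = per_class,
                 overall_accuracy = 100 * sum(diag(confusion)) / sum(confusion),
                 folds = folds, seed = seed,
                 hyperparams = list(C = C, gamma = if (identical(gamma, "scale")) "scale" else g,
                                    gamma_value = g)),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("<CVReport> %d-fold CV | overall accuracy %.1f%%\n",
              x$folds, x$overall_accuracy))
  cat("per-class accuracy (%):\n")
  print(round(x$per_class_accuracy, 1))
  invisible(x)
}

#' Convert a confusion matrix of counts to row percentages
#'
#' @param report a `CVReport`.
#' @return matrix of row percentages (each row sums to 100).
#' @export
confusion_to_percent <- function(report) {
  cm <- report$confusion
  rs <- rowSums(cm)
  if (any(rs == 0))
    abort(paste0("confusion matrix has empty true-class row(s): ",
                 paste(rownames(cm)[rs == 0], collapse = ", ")),
          "freshir_validation_error")
  100 * cm / rs
}

#' 2-D t-SNE embedding of a spectra set
#'
#' Reduces the spectra to `n_pcs` principal components, then runs exact
#' (quadratic-cost) t-distributed stochastic neighbour embedding with
#' per-point bandwidths calibrated to the requested perplexity, early
#' exaggeration and momentum gradient descent. Intended for visualisation
#' only; no quantitative claim should rest on the embedding geometry.
#'
#' @param set a `SpectraSet`.
#' @param n_pcs number of PCs fed to the embedding (default 5).
#' @param perplexity neighbourhood size parameter (default 50); must be
#'   below the number of spectra, and `n > 3 * perplexity` is recommended.
#' @param seed integer seed for the embedding initialisation.
#' @param max_iter gradient-descent iterations (default 500).
#' @return an `EmbeddingResult`: list with `coordinates` (`n x 2`),
#'   `perplexity`, `n_pcs_input`, `seed`.
#' @export
tsne_embed <- function(set, n_pcs = 5, perplexity = 50, seed = 1,
                       max_iter = 500) {
  n <- n_spectra(set)
  if (perplexity >= n)
    abort(sprintf("perplexity (%g) must be below the number of spectra (%d)",
                  perplexity, n), "freshir_parameter_error")
  if (n <= 3 * perplexity)
    warning("n_spectra <= 3 * perplexity; embedding may be unstable")
  K <- min(n_pcs, n - 1, length(set$grid))
  pca <- fit_pca(set, K)
  Xp <- pca_scores(pca, set)
  P <- tsne_affinities(Xp, perplexity)
  Y <- with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), ncol = 2)
    tsne_descent(P, Y, max_iter)
  })
  structure(list(coordinates = Y, perplexity = perplexity,
                 n_pcs_input = K, seed = seed),
            class = "EmbeddingResult")
}

# symmetrised affinities with per-point precision matched to perplexity
tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    d <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0 } else {
        H <- log(sw) + beta * sum(d * w) / sw
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / max(sum(w), .Machine$double.xmin)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_descent <- function(P, Y, max_iter, lr = 200) {
  n <- nrow(Y)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exag_until <- min(100, max_iter %/% 4)
  Pe <- P * 12
  for (iter in seq_len(max_iter)) {
    if (iter == exag_until + 1) Pe <- P
    momentum <- if (iter <= 250) 0.5 else 0.8
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    M <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(M)) %*% Y - M %*% Y)
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - lr * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
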