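#' Count preprocessing for classification
#'
#' Adds a pseudocount of 1 to the raw counts, normalizes samples by DESeq
#' median-ratio size factors (reference: per-gene geometric mean over
#' samples, genes with any zero count excluded), and log-transforms:
#' `log2(normalized + 0.5)`. Optional voom-style precision weights from a
#' lowess fit of per-gene `sqrt(sd)` versus mean of the log-counts are
#' attached as a `weights` attribute; they are off by default and do not
#' enter the centroid computation unless requested at training time.
#'
#' @param counts Raw count matrix (genes x samples, unit `"counts"`).
#' @param weights Compute voom-style precision weights (default `FALSE`).
#' @return Transformed matrix (unit `"log2"`) with attributes
#'   `size_factors` and (optionally) `weights`.
#' @export
prepare_counts <- function(counts, weights = FALSE) {
  check_unit(counts, "counts", "prepare_counts()")
  if (any(colSums(counts) == 0)) {
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(colnames(counts)[colSums(counts) == 0], collapse = ", ")))
  }
  x <- unclass(counts) + 1
  sf <- median_ratio_size_factors(x)
  norm <- sweep(x, 2, sf, "/")
  out <- expr_matrix(log2(norm + 0.5), "log2")
  attr(out, "size_factors") <- sf
  if (weights) {
    mu <- rowMeans(out)
    sq_sd <- sqrt(apply(unclass(out), 1, sd))
    fit <- lowess(mu, sq_sd, f = 0.5)
    pred <- approx(fit$x, fit$y, xout = as.vector(unclass(out)), rule = 2)$y
    w <- matrix(1 / pmax(pred, 1e-4)^4, nrow = nrow(out),
                dimnames = dimnames(out))
    attr(out, "weights") <- w
  }
  out
}

#' DESeq median-ratio size factors
#'
#' Per-sample scaling factor: the median over reference genes of the ratio
#' of the sample's count to the gene's geometric mean across samples. Genes
#' with a zero count in any sample are excluded from the reference.
#'
#' @param x Count matrix (strictly positive after any pseudocount).
#' @return Named numeric vector of size factors.
#' @export
median_ratio_size_factors <- function(x) {
  x <- unclass(x)
  ok <- rowSums(x == 0) == 0
  if (!any(ok)) abort("no gene is zero-free; cannot form the median-ratio reference")
  logx <- log(x[ok, , drop = FALSE])
  ref <- rowMeans(logx)
  apply(logx, 2, function(col) exp(median(col - ref)))
}

#' Stratified train/test split
#'
#' Splits samples into a training and a test partition, preserving class
#' proportions per label (training size per class = `round(fraction_train *
#' n_class)`). Deterministic for a given seed.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param labels Class label per sample.
#' @param fraction_train Fraction used for training (default 0.6).
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `label`, `partition` (`"train"`/`"test"`).
#' @export
split_train_test <- function(sample_ids, labels, fraction_train = 0.6, seed = 1) {
  if (length(sample_ids) != length(labels)) abort("sample_ids and labels differ in length")
  tab <- table(labels)
  if (any(tab < 2)) {
    abort(paste0("class(es) with < 2 samples: ", paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (fraction_train >= 1) warn("fraction_train >= 1: test partition is empty")
  set.seed(seed)
  part <- rep("test", length(sample_ids))
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    n_train <- min(length(idx), max(1, round(fraction_train * length(idx))))
    part[sample(idx, n_train)] <- "train"
  }
  tibble(sample_id = sample_ids, label = labels, partition = part)
}

# Per-gene NSC statistics for one training set.
# Returns centroids, pooled sd, s0, m_k, priors and the raw d_ik matrix.
nsc_stats <- function(X, labels, weights = NULL) {
  classes <- sort(unique(labels))
  K <- length(classes)
  n <- ncol(X)
  if (K < 2) abort("need >= 2 classes")
  wmean <- function(M, w) {
    if (is.null(w)) rowMeans(M) else rowSums(M * w) / rowSums(w)
  }
  overall <- wmean(X, weights)
  cent <- vapply(classes, function(cl) {
    idx <- labels == cl
    wmean(X[, idx, drop = FALSE],
          if (is.null(weights)) NULL else weights[, idx, drop = FALSE])
  }, numeric(nrow(X)))
  cent <- matrix(cent, nrow = nrow(X), dimnames = list(rownames(X), classes))
  nk <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  # pooled within-class sd, df = n - K
  ss <- rowSums(matrix(vapply(classes, function(cl) {
    idx <- labels == cl
    rowSums((X[, idx, drop = FALSE] - cent[, cl])^2)
  }, numeric(nrow(X))), nrow = nrow(X)))
  s_i <- sqrt(ss / (n - K))
  s0 <- median(s_i)
  m_k <- sqrt(1 / nk - 1 / n)
  d_ik <- sweep(cent - overall, 2, m_k, "/") / (s_i + s0)
  list(classes = classes, overall = overall, centroids = cent, nk = nk,
       priors = nk / n, s_i = s_i, s0 = s0, m_k = m_k, d_ik = d_ik)
}

shrink_d <- function(d_ik, delta) {
  sign(d_ik) * pmax(abs(d_ik) - delta, 0)
}

nsc_fit_delta <- function(stats, delta) {
  d_shr <- shrink_d(stats$d_ik, delta)
  cent_shr <- stats$overall +
    sweep(d_shr, 2, stats$m_k, "*") * (stats$s_i + stats$s0)
  selected <- rowSums(d_shr != 0) > 0
  list(delta = delta, d_shrunk = d_shr, centroids_shrunk = cent_shr,
       selected = selected)
}

nsc_predict_scores <- function(stats, fit, Xnew) {
  scale2 <- (stats$s_i + stats$s0)^2
  scores <- sapply(seq_along(stats$classes), function(k) {
    colSums((Xnew - fit$centroids_shrunk[, k])^2 / scale2) -
      2 * log(stats$priors[k])
  })
  matrix(scores, ncol = length(stats$classes),
         dimnames = list(colnames(Xnew), stats$classes))
}

#' Train a nearest shrunken centroids classifier
#'
#' Standard NSC: per-gene standardized class-centroid contrasts
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` are soft-thresholded at
#' `delta`, giving shrunken centroids
#' `xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik`; prediction minimizes the
#' standardized squared distance to the shrunken centroids minus
#' `2 log(prior)`. `s0` is the median of the pooled within-class standard
#' deviations, `m_k = sqrt(1/n_k - 1/n)`. The shrinkage threshold is chosen
#' from `delta_grid` by repeated stratified k-fold cross-validation on the
#' training data, maximizing mean CV accuracy with ties broken toward the
#' largest threshold (fewest genes).
#'
#' @param X Transformed expression matrix (genes x samples), e.g. from
#'   [prepare_counts()].
#' @param labels Class label per training sample.
#' @param delta_grid Candidate thresholds; default 30 points from 0 to
#'   `max |d_ik|`.
#' @param folds Cross-validation folds (default 5).
#' @param repeats CV repetitions (default 2).
#' @param seed Integer seed for fold assignment.
#' @param use_weights Use voom-style precision weights (from
#'   `attr(X, "weights")`) in the centroid means.
#' @return An object of class `"nsc_model"`.
#' @export
train_nsc <- function(X, labels, delta_grid = NULL, folds = 5, repeats = 2,
                      seed = 1, use_weights = FALSE) {
  Xm <- unclass(X)
  weights <- if (use_weights) attr(X, "weights") else NULL
  if (use_weights && is.null(weights)) {
    abort("use_weights = TRUE but X carries no weights attribute; run prepare_counts(weights = TRUE)")
  }
  stats <- nsc_stats(Xm, labels, weights)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(stats$d_ik)), length.out = 30)
  }
  if (length(delta_grid) == 0) abort("empty delta grid")

  set.seed(seed)
  acc <- matrix(NA_real_, nrow = repeats * folds, ncol = length(delta_grid))
  row <- 0
  for (r in seq_len(repeats)) {
    fold_id <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    for (f in seq_len(folds)) {
      row <- row + 1
      test <- fold_id == f
      if (all(test) || !all(sort(unique(labels[!test])) == stats$classes)) next
      st <- nsc_stats(Xm[, !test, drop = FALSE], labels[!test],
                      if (is.null(weights)) NULL else weights[, !test, drop = FALSE])
      for (j in seq_along(delta_grid)) {
        fit <- nsc_fit_delta(st, delta_grid[j])
        sc <- nsc_predict_scores(st, fit, Xm[, test, drop = FALSE])
        pred <- st$classes[apply(sc, 1, which.min)]
        acc[row, j] <- mean(pred == labels[test])
      }
    }
  }
  cv_acc <- colMeans(acc, na.rm = TRUE)
  best <- which(cv_acc == max(cv_acc))
  delta <- delta_grid[max(best)]  # ties -> largest delta, sparsest model

  fit <- nsc_fit_delta(stats, delta)
  structure(
    list(
      classes = stats$classes, priors = stats$priors,
      overall_centroid = stats$overall, centroids = stats$centroids,
      s_i = stats$s_i, s0 = stats$s0, m_k = stats$m_k,
      d_ik = stats$d_ik, delta = delta,
      d_shrunk = fit$d_shrunk, centroids_shrunk = fit$centroids_shrunk,
      selected = rownames(Xm)[fit$selected],
      cv = tibble(delta = delta_grid, accuracy = cv_acc,
                  n_genes = vapply(delta_grid, function(d)
                    sum(rowSums(shrink_d(stats$d_ik, d) != 0) > 0), numeric(1))),
      gene_ids = rownames(Xm)
    ),
    class = "nsc_model"
  )
}

#' @export
print.nsc_model <- function(x, ...) {
  cat("Nearest shrunken centroids model\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  threshold delta = %.4g; %d / %d genes selected\n",
              x$delta, length(x$selected), length(x$gene_ids)))
  invisible(x)
}

#' Predict class labels with an NSC model
#'
#' @param object An `"nsc_model"`.
#' @param newdata Transformed matrix (genes x samples) on the same genes.
#' @param ... Unused.
#' @return Character vector of predicted labels, named by sample.
#' @export
predict.nsc_model <- function(object, newdata, ...) {
  Xm <- unclass(newdata)[object$gene_ids, , drop = FALSE]
  stats <- list(classes = object$classes, priors = object$priors,
                s_i = object$s_i, s0 = object$s0)
  sc <- nsc_predict_scores(stats, list(centroids_shrunk = object$centroids_shrunk), Xm)
  setNames(object$classes[apply(sc, 1, which.min)], colnames(Xm))
}

#' Classification metrics against a reference class
#'
#' The reference class is treated as the negative class; sensitivity is the
#' true-positive rate on the non-reference class, specificity the
#' true-negative rate on the reference class.
#'
#' @param model Trained `"nsc_model"`.
#' @param X_test Transformed test matrix (genes x samples).
#' @param labels_test True labels.
#' @param reference Reference (negative) class label.
#' @return List: `accuracy`, `sensitivity`, `specificity`, `confusion`
#'   (table), `predictions`.
#' @export
evaluate_nsc <- function(model, X_test, labels_test, reference) {
  bad <- setdiff(unique(labels_test), model$classes)
  if (length(bad) > 0) {
    abort(paste0("label(s) absent from model: ", paste(bad, collapse = ", ")))
  }
  if (!reference %in% model$classes) abort("reference class not in model")
  pred <- predict(model, X_test)
  lv <- c(setdiff(model$classes, reference), reference)
  confusion <- table(
    predicted = factor(pred, levels = lv),
    truth = factor(labels_test, levels = lv)
  )
  pos <- labels_test != reference
  list(
    accuracy = mean(pred == labels_test),
    sensitivity = if (any(pos)) mean(pred[pos] == labels_test[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(pred[!pos] == reference) else NA_real_,
    confusion = confusion,
    predictions = pred
  )
}

#' Selected biomarker genes, ranked
#'
#' Genes whose shrunken contrast is nonzero in at least one class, ranked by
#' the largest absolute shrunken contrast.
#'
#' @param model Trained `"nsc_model"`.
#' @return Tibble `gene_id`, `max_abs_shrunken`, `rank`.
#' @export
selected_features <- function(model) {
  score <- apply(abs(model$d_shrunk), 1, max)
  keep <- score > 0
  tibble(gene_id = model$gene_ids[keep], max_abs_shrunken = unname(score[keep])) |>
    arrange(dplyr::desc(.data$max_abs_shrunken)) |>
    mutate(rank = dplyr::row_number())
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an NSC model
#'
#' One row per gene and class with the raw and shrunken standardized
#' contrasts.
#'
#' @param x An `"nsc_model"`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `class`, `d`, `d_shrunken`, `selected`.
#' @method tidy nsc_model
#' @export
tidy.nsc_model <- function(x, ...) {
  tidyr::expand_grid(gene_id = x$gene_ids, class = x$classes) |>
    mutate(
      d = as.vector(t(x$d_ik)),
      d_shrunken = as.vector(t(x$d_shrunk)),
      selected = .data$gene_id %in% x$selected
    )
}

#' One-row summary of an NSC model
#'
#' @param x An `"nsc_model"`.
#' @param ... Unused.
#' @return Tibble `delta`, `n_selected`, `n_genes`, `cv_accuracy`.
#' @method glance nsc_model
#' @export
glance.nsc_model <- function(x, ...) {
  tibble(
    delta = x$delta,
    n_selected = length(x$selected),
    n_genes = length(x$gene_ids),
    cv_accuracy = x$cv$accuracy[which(x$cv$delta == x$delta)[1]]
  )
}
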