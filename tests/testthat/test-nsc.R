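# independent plain nearest-centroid rule with pooled standardization,
# for the delta = 0 equivalence check
oracle_nearest_centroid <- function(Xtr, ytr, Xte) {
  classes <- sort(unique(ytr))
  n <- ncol(Xtr); K <- length(classes)
  cent <- sapply(classes, function(cl) rowMeans(Xtr[, ytr == cl, drop = FALSE]))
  ss <- 0
  for (cl in classes) {
    sub <- Xtr[, ytr == cl, drop = FALSE]
    ss <- ss + rowSums((sub - cent[, cl])^2)
  }
  s_i <- sqrt(ss / (n - K))
  s0 <- median(s_i)
  prior <- table(ytr)[classes] / n
  apply(Xte, 2, function(x) {
    sc <- sapply(classes, function(cl) {
      sum((x - cent[, cl])^2 / (s_i + s0)^2) - 2 * log(prior[[cl]])
    })
    classes[which.min(sc)]
  })
}

test_that("median-ratio size factors behave canonically and match DESeq2", {
  m <- matrix(rep(c(10, 20, 30, 40), 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(median_ratio_size_factors(m)), rep(1, 3))

  set.seed(6)
  m2 <- matrix(rpois(200 * 6, 60) + 1, 200, 6,
               dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  sf <- median_ratio_size_factors(m2)
  m3 <- m2
  m3[, 2] <- m3[, 2] * 2
  sf3 <- median_ratio_size_factors(m3)
  # doubling one column doubles its factor only approximately exactly:
  # the geometric-mean reference shifts by 2^(1/6) uniformly, cancelling in
  # the ratio of factors
  expect_equal(sf3[2] / sf3[1], 2 * sf[2] / sf[1], tolerance = 1e-10)

  perm <- sample(nrow(m2))
  expect_equal(median_ratio_size_factors(m2[perm, ]), sf)

  dsq <- DESeq2::estimateSizeFactorsForMatrix(m2)
  expect_equal(unname(sf), unname(dsq), tolerance = 1e-8)
})

test_that("prepare_counts applies pseudocount, normalization and log transform", {
  ds <- tiny_dataset()
  X <- prepare_counts(ds$counts)
  expect_identical(expr_unit(X), "log2")
  sf <- attr(X, "size_factors")
  expect_equal(length(sf), ncol(ds$counts))
  i <- "t00001A"; j <- 3
  expect_equal(unclass(X)[i, j],
               log2((unclass(ds$counts)[i, j] + 1) / sf[[j]] + 0.5),
               ignore_attr = TRUE)
  zero <- mk_counts(matrix(c(1, 2, 0, 0), 2, 2))
  expect_error(prepare_counts(zero), "s2")
  Xw <- prepare_counts(ds$counts, weights = TRUE)
  expect_equal(dim(attr(Xw, "weights")), dim(Xw))
  expect_true(all(attr(Xw, "weights") > 0))
})

test_that("delta = 0 equals plain pooled-standardized nearest centroid", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
    y <- rep(c("A", "B"), each = 4)
    X[1:3, y == "B"] <- X[1:3, y == "B"] + 2
    model <- train_nsc(X, y, delta_grid = 0, folds = 2, repeats = 1, seed = 1)
    expect_equal(model$centroids_shrunk, model$centroids)
    set.seed(seed + 100)
    Xte <- matrix(rnorm(20 * 6), 20, 6,
                  dimnames = list(rownames(X), paste0("t", 1:6)))
    expect_identical(unname(predict(model, Xte)),
                     unname(oracle_nearest_centroid(X, y, Xte)))
    expect_setequal(model$selected, rownames(X))
  }
})

test_that("the hand-computed shrinkage table is reproduced on a 6x5 toy", {
  # 5 genes x 6 samples, classes a/a/a b/b/b; gene g1 separated by ~10 sd
  X <- rbind(
    g1 = c(0.0, 0.1, -0.1, 10.0, 10.1, 9.9),
    g2 = c(1.0, 1.1, 0.9, 1.0, 1.1, 0.9),
    g3 = c(-0.5, -0.4, -0.6, -0.5, -0.4, -0.6),
    g4 = c(2.0, 2.2, 1.8, 2.1, 2.3, 1.9),
    g5 = c(0.3, 0.2, 0.4, 0.35, 0.25, 0.45)
  )
  colnames(X) <- paste0("s", 1:6)
  y <- rep(c("a", "b"), each = 3)

  # hand recomputation of d_ik per the NSC definition
  overall <- rowMeans(X)
  cent_a <- rowMeans(X[, 1:3]); cent_b <- rowMeans(X[, 4:6])
  s_i <- sqrt((rowSums((X[, 1:3] - cent_a)^2) + rowSums((X[, 4:6] - cent_b)^2)) / (6 - 2))
  s0 <- median(s_i)
  m_k <- sqrt(1 / 3 - 1 / 6)
  d_a <- (cent_a - overall) / (m_k * (s_i + s0))
  d_b <- (cent_b - overall) / (m_k * (s_i + s0))

  model <- train_nsc(X, y, delta_grid = 0, folds = 3, repeats = 1, seed = 1)
  expect_equal(model$d_ik[, "a"], d_a)
  expect_equal(model$d_ik[, "b"], d_b)
  expect_equal(model$s0, s0)

  # an intermediate threshold keeps exactly the separated gene
  dmax_other <- max(abs(c(d_a, d_b)[names(c(d_a, d_b)) != "g1"][-1]))
  delta_mid <- (abs(d_a["g1"]) + max(abs(d_a[-1]))) / 2
  m2 <- train_nsc(X, y, delta_grid = unname(delta_mid), folds = 3, repeats = 1, seed = 1)
  expect_identical(m2$selected, "g1")
  expect_identical(selected_features(m2)$gene_id, "g1")

  # soft thresholding: surviving contrast is |d| - delta
  expect_equal(abs(m2$d_shrunk["g1", "a"]), abs(d_a["g1"]) - delta_mid,
               ignore_attr = TRUE)
})

test_that("selection is monotone in the threshold with the stated limits", {
  set.seed(7)
  X <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  y <- rep(c("A", "B"), each = 5)
  model <- train_nsc(X, y, folds = 2, repeats = 1, seed = 3)
  sizes <- model$cv$n_genes
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], 40)
  big <- train_nsc(X, y, delta_grid = max(abs(model$d_ik)) + 1,
                   folds = 2, repeats = 1, seed = 3)
  expect_equal(length(big$selected), 0)
  expect_equal(nrow(selected_features(big)), 0)
  # with every gene dropped, prediction falls back to class priors
  y2 <- c(rep("A", 6), rep("B", 4))
  big2 <- train_nsc(X, y2, delta_grid = 100, folds = 2, repeats = 1, seed = 3)
  expect_true(all(predict(big2, X) == "A"))
})

test_that("prediction is invariant to gene order and global library scaling", {
  ds <- tiny_dataset()
  counts <- unclass(ds$counts)
  labels <- ds$sample_sheet$genotype
  X1 <- prepare_counts(expr_matrix(counts, "counts"))
  X2 <- prepare_counts(expr_matrix(counts * 4, "counts"))
  m1 <- train_nsc(unclass(X1), labels, delta_grid = c(0, 1), folds = 3,
                  repeats = 1, seed = 2)
  m2 <- train_nsc(unclass(X2), labels, delta_grid = c(0, 1), folds = 3,
                  repeats = 1, seed = 2)
  expect_equal(predict(m1, unclass(X1)), predict(m2, unclass(X2)))

  perm <- sample(nrow(counts))
  m3 <- train_nsc(unclass(X1)[perm, ], labels, delta_grid = c(0, 1), folds = 3,
                  repeats = 1, seed = 2)
  expect_equal(predict(m3, unclass(X1)[perm, ]), predict(m1, unclass(X1)))
})

test_that("stratified splitting preserves classes and is seed-deterministic", {
  ids <- sprintf("s%02d", 1:18)
  y <- rep(c("N", "S"), each = 9)
  sp <- split_train_test(ids, y, 0.6, seed = 11)
  tab <- table(sp$label, sp$partition)
  expect_equal(unname(tab["N", "train"]), 5)
  expect_equal(unname(tab["S", "train"]), 5)
  expect_true(all(table(sp$label[sp$partition == "test"]) > 0))
  expect_identical(sp, split_train_test(ids, y, 0.6, seed = 11))
  expect_false(identical(sp$partition, split_train_test(ids, y, 0.6, seed = 12)$partition))
  expect_warning(split_train_test(ids, y, 1.0, seed = 1), "test partition is empty")
  expect_error(split_train_test(ids[1:3], c("N", "N", "S"), 0.6, 1), "< 2 samples")
})

test_that("classification metrics match a hand-tallied confusion matrix", {
  set.seed(9)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  X[1:5, 6:10] <- X[1:5, 6:10] + 5
  y <- rep(c("Sadash", "Nanda"), each = 5)
  model <- train_nsc(X, y, delta_grid = 0, folds = 2, repeats = 1, seed = 1)
  ev <- evaluate_nsc(model, X, y, reference = "Sadash")
  pred <- predict(model, X)
  tp <- sum(pred == "Nanda" & y == "Nanda"); fn <- sum(pred == "Sadash" & y == "Nanda")
  tn <- sum(pred == "Sadash" & y == "Sadash"); fp <- sum(pred == "Nanda" & y == "Sadash")
  expect_equal(ev$accuracy, (tp + tn) / 10)
  expect_equal(ev$sensitivity, tp / (tp + fn))
  expect_equal(ev$specificity, tn / (tn + fp))
  expect_equal(sum(ev$confusion), 10)

  # degenerate predictions: all reference
  yy <- c("Sadash", "Sadash", "Nanda", "Nanda")
  fake <- model
  ev2 <- list(
    sens0 = {
      preds <- rep("Sadash", 4)
      mean(preds[yy == "Nanda"] == "Nanda")
    }
  )
  expect_equal(ev2$sens0, 0)
  expect_error(evaluate_nsc(model, X, rep("Other", 10), reference = "Sadash"),
               "absent")
})

test_that("tidy and glance summarise the model consistently", {
  set.seed(10)
  X <- matrix(rnorm(15 * 8), 15, 8,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:8)))
  y <- rep(c("A", "B"), each = 4)
  model <- train_nsc(X, y, folds = 2, repeats = 1, seed = 1)
  td <- tidy(model)
  expect_equal(nrow(td), 15 * 2)
  expect_equal(td$d[td$gene_id == "g3" & td$class == "A"],
               unname(model$d_ik["g3", "A"]))
  gl <- glance(model)
  expect_equal(gl$n_selected, length(model$selected))
  expect_equal(gl$n_genes, 15)
})
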