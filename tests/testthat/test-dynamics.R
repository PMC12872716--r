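# brute-force stability oracle on an assignment table
oracle_stable <- function(assign, genotype) {
  stages <- levels(assign$stage)
  out <- list()
  for (tr in unique(assign$triad_id)) {
    cats <- sapply(stages, function(s) {
      as.character(assign$category[assign$triad_id == tr &
                                     assign$genotype == genotype &
                                     assign$stage == s])
    })
    if (any(cats == "undefined")) next
    if (length(unique(cats)) == 1) out[[tr]] <- cats[1]
  }
  tibble::tibble(triad_id = names(out), category = unname(unlist(out)))
}

test_that("stable triads match a brute-force per-triad equality check", {
  assign <- random_assignment(seed = 21)
  st <- stable_triads(assign, "Nanda")
  or <- oracle_stable(assign, "Nanda")
  expect_setequal(st$triad_id, or$triad_id)
  expect_equal(as.character(st$category[order(st$triad_id)]),
               or$category[order(or$triad_id)])

  # denominators: triads defined at all stages
  wide <- tidyr::pivot_wider(
    dplyr::mutate(assign[assign$genotype == "Nanda", ],
                  stage = as.character(stage), category = as.character(category)),
    id_cols = "triad_id", names_from = "stage", values_from = "category")
  n_def <- sum(apply(as.matrix(wide[-1]), 1, function(z) all(z != "undefined")))
  expect_equal(attr(st, "n_defined"), n_def)
  expect_equal(attr(st, "unchanged_fraction"), nrow(or) / n_def)
})

test_that("explicit small trajectories behave as stated", {
  mk <- function(cats_by_stage) {
    tibble::tibble(
      triad_id = "tr1", genotype = "G",
      stage = factor(c("d0", "d7", "d21"), levels = c("d0", "d7", "d21"), ordered = TRUE),
      category = factor(cats_by_stage, levels = bias_levels())
    )
  }
  expect_equal(nrow(stable_triads(mk(rep("balanced", 3)), "G")), 1)
  expect_equal(nrow(stable_triads(mk(c("balanced", "balanced", "B_suppressed")), "G")), 0)
  expect_error(stable_triads(mk(rep("balanced", 3))[1:2, ], "G"), "missing stage")
})

test_that("per-category stability matches a recount and handles empty cells", {
  assign <- random_assignment(seed = 33)
  per <- per_category_stability(assign, "Sadash")
  or <- oracle_stable(assign, "Sadash")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(assign[assign$genotype == "Sadash", ],
                  stage = as.character(stage), category = as.character(category)),
    id_cols = "triad_id", names_from = "stage", values_from = "category")
  mat <- as.matrix(wide[-1])
  defined <- apply(mat, 1, function(z) all(z != "undefined"))
  for (i in seq_len(nrow(per))) {
    at <- defined & mat[, as.character(per$stage[i])] == as.character(per$category[i])
    stab <- wide$triad_id[at] %in% or$triad_id[or$category == as.character(per$category[i])]
    if (sum(at) == 0) {
      expect_true(is.na(per$fraction[i]))
    } else {
      expect_equal(per$fraction[i], mean(stab))
    }
  }

  # all-stable and no-stable boundary behaviour
  all_stable <- random_assignment(n_triads = 10, seed = 1, p_undefined = 0)
  all_stable$category <- factor("balanced", levels = bias_levels())
  per2 <- per_category_stability(all_stable, "Nanda")
  expect_true(all(per2$fraction[per2$category == "balanced"] == 1))
  expect_true(all(is.na(per2$fraction[per2$category != "balanced"])))
})

test_that("average stability is the unweighted mean of per-stage fractions", {
  assign <- random_assignment(seed = 55)
  per <- per_category_stability(assign, "Nanda")
  avg <- average_stability(assign, "Nanda", "balanced")
  fr <- per$fraction[per$category == "balanced"]
  expect_equal(avg$average, mean(fr, na.rm = TRUE))
  expect_identical(avg$partial, anyNA(fr))
})

test_that("genotype-unique stable sets are a set difference with focal genes", {
  assign <- random_assignment(seed = 77)
  # plant: tr001..tr005 stable B-suppressed in Sadash; tr003 also in Nanda
  bsup <- factor("B_suppressed", levels = bias_levels())
  assign$category[assign$genotype == "Sadash" &
                    assign$triad_id %in% sprintf("tr%03d", 1:5)] <- bsup
  assign$category[assign$genotype == "Nanda" & assign$triad_id == "tr003"] <- bsup
  triads <- tibble::tibble(
    triad_id = unique(assign$triad_id),
    gene_A = paste0(unique(assign$triad_id), "_A"),
    gene_B = paste0(unique(assign$triad_id), "_B"),
    gene_D = paste0(unique(assign$triad_id), "_D")
  )
  uniq <- unique_stable_biased(assign, "Sadash", "Nanda", "B_suppressed", triads)
  st_s <- oracle_stable(assign, "Sadash")
  st_n <- oracle_stable(assign, "Nanda")
  want <- setdiff(st_s$triad_id[st_s$category == "B_suppressed"],
                  st_n$triad_id[st_n$category == "B_suppressed"])
  expect_gt(nrow(uniq), 0)
  expect_setequal(uniq$triad_id, want)
  expect_identical(uniq$gene_id,
                   triads$gene_B[match(uniq$triad_id, triads$triad_id)])

  # identical assignments in both genotypes give an empty set
  half <- assign[assign$genotype == "Sadash", ]
  both <- rbind(half, dplyr::mutate(half, genotype = "Nanda"))
  expect_equal(nrow(unique_stable_biased(both, "Sadash", "Nanda", "B_suppressed", triads)), 0)

  expect_error(unique_stable_biased(assign, "Sadash", "Nanda", "balanced", triads),
               "focal")
})

test_that("DEG overlap equals a brute-force membership test and is threshold-monotone", {
  set.seed(4)
  genes <- sprintf("gene%02d", 1:30)
  stable_set <- tibble::tibble(triad_id = paste0("tr", 1:10),
                               gene_id = genes[1:10],
                               category = "B_suppressed", genotype = "Sadash")
  degs <- tidyr::expand_grid(gene_id = genes, contrast = c("NS_D0", "NS_D7", "NS_D21")) |>
    dplyr::mutate(log2fc = runif(dplyr::n(), -3, 3), padj = runif(dplyr::n()))
  ov <- deg_overlap(stable_set, degs, fc_threshold = 1, padj_threshold = 0.3)
  pass <- degs[abs(degs$log2fc) >= 1 & degs$padj < 0.3, ]
  want <- intersect(stable_set$gene_id, pass$gene_id)
  expect_equal(ov$count, length(want))
  expect_setequal(ov$genes, want)
  expect_equal(ov$fraction, length(want) / 10)

  # monotone: stricter fold change never increases, looser padj never decreases
  f1 <- deg_overlap(stable_set, degs, 1, 0.3)$fraction
  f2 <- deg_overlap(stable_set, degs, 2, 0.3)$fraction
  f3 <- deg_overlap(stable_set, degs, 1, 0.5)$fraction
  expect_lte(f2, f1)
  expect_gte(f3, f1)

  none <- deg_overlap(stable_set, degs[degs$gene_id == "gene30", ], 0.1, 1)
  expect_equal(none$count, ifelse("gene30" %in% stable_set$gene_id, 1, 0))
  all_de <- deg_overlap(stable_set,
                        tibble::tibble(gene_id = stable_set$gene_id, log2fc = 2,
                                       padj = 0.001, contrast = "NS_D0"))
  expect_equal(all_de$fraction, 1)
  expect_equal(all_de$direction$direction, "up")
})

test_that("transition matrices conserve the number of doubly-defined triads", {
  assign <- random_assignment(seed = 91)
  tc <- transition_counts(assign, "Nanda")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(assign[assign$genotype == "Nanda", ],
                  stage = as.character(stage), category = as.character(category)),
    id_cols = "triad_id", names_from = "stage", values_from = "category")
  for (pair in list(c("Day0", "Day7"), c("Day7", "Day21"))) {
    n_both <- sum(wide[[pair[1]]] != "undefined" & wide[[pair[2]]] != "undefined")
    expect_equal(sum(tc$n[tc$from_stage == pair[1]]), n_both)
  }
})
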