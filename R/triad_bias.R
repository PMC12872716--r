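#' Aggregate TPM per triad and condition
#'
#' Collapses replicate-level TPM to one value per homoeolog, triad and
#' condition (genotype x stage). The aggregation statistic is the arithmetic
#' mean by default; the median is available as an option.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param sample_sheet Tibble with `sample_id`, `genotype`, `stage`.
#' @param triads Triad table (`triad_id`, `gene_A`, `gene_B`, `gene_D`).
#' @param method `"mean"` (default) or `"median"`.
#' @return Tibble with one row per triad x condition: `triad_id`, `genotype`,
#'   `stage`, `tpm_A`, `tpm_B`, `tpm_D`.
#' @export
aggregate_condition_tpm <- function(tpm, sample_sheet, triads,
                                    method = c("mean", "median")) {
  method <- match.arg(method)
  check_unit(tpm, "TPM", "aggregate_condition_tpm()")
  genes_needed <- c(triads$gene_A, triads$gene_B, triads$gene_D)
  missing_genes <- setdiff(genes_needed, rownames(tpm))
  if (length(missing_genes) > 0) {
    abort(paste0("triad gene(s) absent from TPM matrix: ",
                 paste(head(missing_genes, 10), collapse = ", "),
                 if (length(missing_genes) > 10) sprintf(" (+%d more)", length(missing_genes) - 10) else ""))
  }
  missing_samples <- setdiff(sample_sheet$sample_id, colnames(tpm))
  if (length(missing_samples) > 0) {
    abort(paste0("sample(s) absent from TPM matrix: ", paste(missing_samples, collapse = ", ")))
  }
  agg_fun <- if (method == "mean") rowMeans else function(m) apply(m, 1, median)

  conditions <- distinct(sample_sheet, .data$genotype, .data$stage)
  per_cond <- purrr::pmap(conditions, function(genotype, stage) {
    ids <- sample_sheet$sample_id[sample_sheet$genotype == genotype &
                                    sample_sheet$stage == stage]
    if (length(ids) == 0) abort(sprintf("condition %s/%s has no samples", genotype, stage))
    sub <- unclass(tpm)[, ids, drop = FALSE]
    val <- agg_fun(sub)
    tibble(
      triad_id = triads$triad_id,
      genotype = genotype,
      stage = stage,
      tpm_A = unname(val[triads$gene_A]),
      tpm_B = unname(val[triads$gene_B]),
      tpm_D = unname(val[triads$gene_D])
    )
  })
  bind_rows(per_cond)
}

#' Expressed-triad filter
#'
#' A triad is considered expressed when the summed TPM of its three
#' homoeologs reaches `threshold` (>= semantics, boundary retained) in at
#' least one condition.
#'
#' @param cond_expr Output of [aggregate_condition_tpm()].
#' @param threshold Summed-TPM cutoff (default 5).
#' @return Character vector of expressed triad ids.
#' @export
filter_expressed_triads <- function(cond_expr, threshold = 5) {
  cond_expr |>
    mutate(total = .data$tpm_A + .data$tpm_B + .data$tpm_D) |>
    group_by(.data$triad_id) |>
    summarise(max_total = max(.data$total), .groups = "drop") |>
    filter(.data$max_total >= threshold) |>
    pull("triad_id")
}

#' Relative homoeolog expression
#'
#' Converts per-subgenome TPM into shares of total triad expression:
#' `rel_X = tpm_X / (tpm_A + tpm_B + tpm_D)`. Where the triad sum is zero the
#' shares are undefined and returned as `NA`.
#'
#' @param cond_expr Tibble with `tpm_A`, `tpm_B`, `tpm_D` columns.
#' @return The input with `rel_A`, `rel_B`, `rel_D` columns appended.
#' @export
relative_expression <- function(cond_expr) {
  if (any(cond_expr$tpm_A < 0 | cond_expr$tpm_B < 0 | cond_expr$tpm_D < 0)) {
    abort("negative TPM value")
  }
  total <- cond_expr$tpm_A + cond_expr$tpm_B + cond_expr$tpm_D
  mutate(cond_expr,
    rel_A = if_else(total > 0, .data$tpm_A / total, NA_real_),
    rel_B = if_else(total > 0, .data$tpm_B / total, NA_real_),
    rel_D = if_else(total > 0, .data$tpm_D / total, NA_real_)
  )
}

#' Classify one set of relative-expression shares
#'
#' Applies the seven-category rule set on the fraction scale. A triad is
#' `X_dominant` when `rel_X > 0.60` and both other shares are `<= 0.20`;
#' `X_suppressed` when `rel_X < 0.20` and both other shares are `< 0.80`;
#' anything else is `balanced`. Dominant rules take precedence over
#' suppressed rules where both fire (the overlap is reported via
#' `rule_conflict`). Undefined shares (`NA`, zero-sum triad) give
#' `"undefined"`.
#'
#' @param rel_A,rel_B,rel_D Numeric vectors of shares summing to 1 (or `NA`).
#' @param dominant_high,dominant_other,suppressed_low,suppressed_other
#'   Rule thresholds on the fraction scale (defaults 0.60, 0.20, 0.20, 0.80).
#' @return Tibble with `category` (factor over [bias_levels()]) and logical
#'   `rule_conflict` (a dominant and a suppressed rule both matched).
#' @export
classify_bias <- function(rel_A, rel_B, rel_D,
                          dominant_high = 0.60, dominant_other = 0.20,
                          suppressed_low = 0.20, suppressed_other = 0.80) {
  rel <- cbind(A = rel_A, B = rel_B, D = rel_D)
  n <- nrow(rel)
  dom <- sapply(1:3, function(i) {
    others <- rel[, -i, drop = FALSE]
    rel[, i] > dominant_high & others[, 1] <= dominant_other & others[, 2] <= dominant_other
  })
  sup <- sapply(1:3, function(i) {
    others <- rel[, -i, drop = FALSE]
    rel[, i] < suppressed_low & others[, 1] < suppressed_other & others[, 2] < suppressed_other
  })
  dom <- matrix(dom, nrow = n)
  sup <- matrix(sup, nrow = n)
  undef <- is.na(rel[, 1]) | is.na(rel[, 2]) | is.na(rel[, 3])
  subg <- c("A", "B", "D")
  category <- rep("balanced", n)
  # suppressed first, then dominant overwrites: dominant takes precedence
  sup_hit <- apply(sup, 1, function(z) {
    w <- which(z)
    if (length(w) == 0) NA_character_ else paste0(subg[w[1]], "_suppressed")
  })
  dom_hit <- apply(dom, 1, function(z) {
    w <- which(z)
    if (length(w) == 0) NA_character_ else paste0(subg[w[1]], "_dominant")
  })
  category[!is.na(sup_hit)] <- sup_hit[!is.na(sup_hit)]
  category[!is.na(dom_hit)] <- dom_hit[!is.na(dom_hit)]
  category[undef] <- "undefined"
  tibble(
    category = factor(category, levels = BIAS_LEVELS),
    rule_conflict = !undef & !is.na(dom_hit) & !is.na(sup_hit)
  )
}

#' Classify all expressed triads in all conditions
#'
#' Runs [relative_expression()] and [classify_bias()] over every expressed
#' triad x condition cell.
#'
#' @param cond_expr Output of [aggregate_condition_tpm()].
#' @param expressed Character vector of expressed triad ids (from
#'   [filter_expressed_triads()]); `NULL` keeps all.
#' @return Assignment tibble: `triad_id`, `genotype`, `stage`, `tpm_*`,
#'   `rel_*`, `category`, `rule_conflict`.
#' @export
classify_triads <- function(cond_expr, expressed = NULL) {
  if (!is.null(expressed)) {
    cond_expr <- filter(cond_expr, .data$triad_id %in% expressed)
  }
  rel <- relative_expression(cond_expr)
  bind_cols(rel, classify_bias(rel$rel_A, rel$rel_B, rel$rel_D))
}

#' Per-condition category proportions
#'
#' The denominator in each condition is the number of triads with a defined
#' category there; `undefined` cells are excluded.
#'
#' @param assign Assignment tibble from [classify_triads()].
#' @return Tibble `genotype`, `stage`, `category`, `n`, `proportion`;
#'   proportions sum to 1 within each condition.
#' @export
category_proportions <- function(assign) {
  assign |>
    filter(.data$category != "undefined") |>
    count(.data$genotype, .data$stage, .data$category, .drop = FALSE) |>
    filter(.data$category != "undefined") |>
    group_by(.data$genotype, .data$stage) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Ternary (barycentric) plot coordinates
#'
#' Maps shares to the planar triangle with the A vertex at the origin, B at
#' (1, 0) and D at (1/2, sqrt(3)/2): `x = rel_B + rel_D / 2`,
#' `y = sqrt(3) / 2 * rel_D`.
#'
#' @param rel Tibble with `rel_A`, `rel_B`, `rel_D`.
#' @return The input with `tern_x`, `tern_y` appended.
#' @export
ternary_coordinates <- function(rel) {
  mutate(rel,
    tern_x = .data$rel_B + .data$rel_D / 2,
    tern_y = sqrt(3) / 2 * .data$rel_D
  )
}
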