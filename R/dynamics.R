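stage_levels <- function(assign) {
  if (is.factor(assign$stage)) levels(assign$stage) else unique(assign$stage)
}

# wide category table: one row per triad, one column per stage
category_wide <- function(assign, genotype) {
  stages <- stage_levels(assign)
  sub <- filter(assign, .data$genotype == !!genotype)
  if (nrow(sub) == 0) abort(sprintf("no assignments for genotype '%s'", genotype))
  have <- unique(as.character(sub$stage))
  miss <- setdiff(stages, have)
  if (length(miss) > 0) {
    abort(paste0("genotype '", genotype, "' missing stage(s): ", paste(miss, collapse = ", ")))
  }
  sub |>
    mutate(stage = as.character(.data$stage), category = as.character(.data$category)) |>
    select("triad_id", "stage", "category") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "category")
}

#' Stage-to-stage category transition counts
#'
#' For each consecutive stage pair, counts triads moving from each category
#' to each category (8 x 8 including `undefined`). Only triads defined at
#' both stages of a pair enter that pair's matrix.
#'
#' @param assign Assignment tibble from [classify_triads()].
#' @param genotype Genotype to summarise.
#' @return Tibble `from_stage`, `to_stage`, `from_category`, `to_category`,
#'   `n` (complete category grid, zeros included).
#' @export
transition_counts <- function(assign, genotype) {
  stages <- stage_levels(assign)
  wide <- category_wide(assign, genotype)
  pairs <- purrr::map2(stages[-length(stages)], stages[-1], function(s1, s2) {
    tibble(
      from_stage = s1, to_stage = s2,
      from_category = factor(wide[[s1]], levels = BIAS_LEVELS),
      to_category = factor(wide[[s2]], levels = BIAS_LEVELS)
    ) |>
      filter(.data$from_category != "undefined", .data$to_category != "undefined") |>
      count(.data$from_stage, .data$to_stage, .data$from_category,
            .data$to_category, .drop = FALSE)
  })
  bind_rows(pairs)
}

#' Triads with an unchanged category across all stages
#'
#' A triad is stable when its category is defined and identical at every
#' stage. The overall unchanged fraction uses as denominator the triads with
#' a defined category at all stages.
#'
#' @inheritParams transition_counts
#' @return Tibble `triad_id`, `category` (one row per stable triad), with
#'   attributes `n_defined` (denominator) and `unchanged_fraction`.
#' @export
stable_triads <- function(assign, genotype) {
  stages <- stage_levels(assign)
  wide <- category_wide(assign, genotype)
  cats <- as.matrix(wide[stages])
  defined <- rowSums(cats == "undefined" | is.na(cats)) == 0
  same <- defined & apply(cats, 1, function(z) length(unique(z)) == 1)
  out <- tibble(
    triad_id = wide$triad_id[same],
    category = factor(cats[same, 1], levels = BIAS_LEVELS)
  )
  attr(out, "n_defined") <- sum(defined)
  attr(out, "unchanged_fraction") <- if (sum(defined) > 0) sum(same) / sum(defined) else NA_real_
  out
}

#' Overall unchanged fraction for a genotype
#'
#' @inheritParams transition_counts
#' @return A single fraction.
#' @export
overall_stability <- function(assign, genotype) {
  attr(stable_triads(assign, genotype), "unchanged_fraction")
}

#' Per-category, per-stage stability fractions
#'
#' For category `c` at stage `d`: the fraction of triads assigned `c` at `d`
#' (restricted to triads defined at all stages) that keep `c` at every
#' stage. Empty category-stage cells give `NA`, not 0.
#'
#' @inheritParams transition_counts
#' @return Tibble `stage`, `category`, `n_at_stage`, `n_stable`, `fraction`.
#' @export
per_category_stability <- function(assign, genotype) {
  stages <- stage_levels(assign)
  wide <- category_wide(assign, genotype)
  cats <- as.matrix(wide[stages])
  defined <- rowSums(cats == "undefined" | is.na(cats)) == 0
  stable_cat <- ifelse(defined & apply(cats, 1, function(z) length(unique(z)) == 1),
                       cats[, 1], NA_character_)
  real_cats <- setdiff(BIAS_LEVELS, "undefined")
  grid <- tidyr::expand_grid(stage = stages, category = real_cats)
  purrr::pmap(grid, function(stage, category) {
    at <- defined & cats[, stage] == category
    tibble(
      stage = stage, category = category,
      n_at_stage = sum(at),
      n_stable = sum(at & !is.na(stable_cat) & stable_cat == category),
      fraction = if (sum(at) > 0) sum(at & !is.na(stable_cat) & stable_cat == category) / sum(at) else NA_real_
    )
  }) |>
    bind_rows() |>
    mutate(category = factor(.data$category, levels = BIAS_LEVELS))
}

#' Average per-stage stability of a category
#'
#' Unweighted mean of the per-stage stability fractions for one category.
#' If any stage fraction is undefined (empty cell) the average is computed
#' over the defined stages and flagged `partial`.
#'
#' @inheritParams transition_counts
#' @param category A bias category.
#' @return One-row tibble `genotype`, `category`, `average`, `partial`.
#' @export
average_stability <- function(assign, genotype, category) {
  per <- filter(per_category_stability(assign, genotype), .data$category == !!category)
  fr <- per$fraction
  tibble(
    genotype = genotype, category = category,
    average = mean(fr, na.rm = TRUE),
    partial = anyNA(fr)
  )
}

focal_subgenome <- function(category) {
  m <- regmatches(category, regexec("^([ABD])_(dominant|suppressed)$", category))[[1]]
  if (length(m) == 0) {
    abort(sprintf("category '%s' has no focal subgenome (need X_dominant or X_suppressed)", category))
  }
  m[2]
}

#' Genotype-unique stable biased triads
#'
#' The triads stable in `category` in `genotype_a` but not stable in that
#' category in `genotype_b`, with the focal-subgenome gene id attached (for
#' `B_suppressed` the focal subgenome is B, etc.).
#'
#' @inheritParams transition_counts
#' @param genotype_a,genotype_b Genotypes to compare (a minus b).
#' @param category A dominant or suppressed category.
#' @param triads Triad table supplying the gene ids.
#' @return Tibble `triad_id`, `gene_id` (focal homoeolog), `category`,
#'   `genotype`.
#' @export
unique_stable_biased <- function(assign, genotype_a, genotype_b, category, triads) {
  sub <- focal_subgenome(category)
  st_a <- stable_triads(assign, genotype_a)
  st_b <- stable_triads(assign, genotype_b)
  ids_a <- st_a$triad_id[st_a$category == category]
  ids_b <- st_b$triad_id[st_b$category == category]
  ids <- setdiff(ids_a, ids_b)
  gene_col <- paste0("gene_", sub)
  triads |>
    filter(.data$triad_id %in% ids) |>
    transmute(
      triad_id = .data$triad_id,
      gene_id = .data[[gene_col]],
      category = category,
      genotype = genotype_a
    )
}

#' Overlap of a stable biased gene set with DEG lists
#'
#' Counts how many focal genes of a [unique_stable_biased()] set appear in
#' the union of DEG tables after thresholding (`|log2fc| >= fc_threshold`,
#' `padj < padj_threshold`), with a per-contrast breakdown and a gene-level
#' direction tally (`up`, `down`, or `mixed` when contrasts disagree).
#'
#' @param stable_set Output of [unique_stable_biased()].
#' @param degs DEG tibble (or list of tibbles, row-bound) with `gene_id`,
#'   `log2fc`, `padj`, `contrast`.
#' @param fc_threshold Absolute log2 fold-change cutoff (default 1).
#' @param padj_threshold Adjusted-p cutoff, strict `<` (default 0.01).
#' @return List: `count`, `fraction`, `genes`, `per_contrast` (tibble),
#'   `direction` (tibble).
#' @export
deg_overlap <- function(stable_set, degs, fc_threshold = 1, padj_threshold = 0.01) {
  if (is.list(degs) && !is.data.frame(degs)) degs <- bind_rows(degs)
  passing <- filter(degs, abs(.data$log2fc) >= fc_threshold, .data$padj < padj_threshold)
  focal <- unique(stable_set$gene_id)
  hits <- filter(passing, .data$gene_id %in% focal) |>
    mutate(direction = if_else(.data$log2fc >= 0, "up", "down"))
  genes <- unique(hits$gene_id)
  per_contrast <- hits |>
    group_by(.data$contrast) |>
    summarise(n = dplyr::n_distinct(.data$gene_id),
              n_up = dplyr::n_distinct(.data$gene_id[.data$direction == "up"]),
              n_down = dplyr::n_distinct(.data$gene_id[.data$direction == "down"]),
              .groups = "drop")
  direction <- hits |>
    group_by(.data$gene_id) |>
    summarise(direction = if (all(.data$direction == "up")) "up"
              else if (all(.data$direction == "down")) "down" else "mixed",
              .groups = "drop") |>
    count(.data$direction)
  list(
    count = length(genes),
    fraction = if (length(focal) > 0) length(genes) / length(focal) else NA_real_,
    genes = genes,
    per_contrast = per_contrast,
    direction = direction
  )
}
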