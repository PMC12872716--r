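#' Kernel smoothing of a per-gene statistic along a chromosome
#'
#' Nadaraya-Watson local constant regression with a Gaussian kernel in
#' base-pair space, evaluated at every gene position:
#' `smoothed_i = sum_j K((x_i - x_j)/h) y_j / sum_j K((x_i - x_j)/h)`.
#'
#' @param positions Numeric vector of gene positions (bp) on one chromosome.
#' @param values Per-gene statistic (log2 fold change).
#' @param bandwidth Gaussian kernel bandwidth in bp.
#' @return Numeric vector of smoothed values, aligned to `positions`.
#' @export
smooth_statistic <- function(positions, values, bandwidth) {
  if (bandwidth <= 0) abort("bandwidth must be positive")
  if (length(positions) != length(values)) abort("positions and values differ in length")
  if (length(positions) == 1) {
    warn("single-gene chromosome: smoothed value is the gene's own statistic")
    return(values)
  }
  W <- kernel_weights(positions, bandwidth)
  drop(W %*% values)
}

# row-normalized Gaussian weight matrix
kernel_weights <- function(positions, bandwidth) {
  d <- outer(positions, positions, "-") / bandwidth
  W <- exp(-0.5 * d^2)
  W / rowSums(W)
}

#' Positional significance of smoothed fold changes
#'
#' Two one-sided p-values per gene position (enrichment of up- and of
#' down-regulation). In `"permutation"` mode (default) the fold changes are
#' permuted over the chromosome's gene positions `n_perm` times and the
#' observed smoothed value is ranked in its positional null with add-one
#' continuity, so the smallest achievable p is `1 / (n_perm + 1)`. In `"t"`
#' mode a one-sample t-statistic of the kernel-weighted values against zero
#' is used, with a Satterthwaite-style effective sample size
#' `n_eff = (sum w)^2 / sum w^2` per position.
#'
#' @inheritParams smooth_statistic
#' @param mode `"permutation"` or `"t"`.
#' @param n_perm Number of permutations (>= 1000 recommended).
#' @param block Permutations are processed in blocks of this many columns to
#'   bound memory.
#' @return Tibble with `smoothed`, `p_up`, `p_down`, aligned to `positions`.
#' @export
positional_significance <- function(positions, values, bandwidth,
                                    mode = c("permutation", "t"),
                                    n_perm = 10000, block = 1000) {
  mode <- match.arg(mode)
  n <- length(positions)
  if (n == 1) {
    return(tibble(smoothed = values, p_up = 1, p_down = 1))
  }
  W <- kernel_weights(positions, bandwidth)
  smoothed <- drop(W %*% values)

  if (mode == "t") {
    Wraw <- exp(-0.5 * (outer(positions, positions, "-") / bandwidth)^2)
    sw <- rowSums(Wraw)
    n_eff <- sw^2 / rowSums(Wraw^2)
    resid2 <- sapply(seq_len(n), function(i) {
      sum(Wraw[i, ] * (values - smoothed[i])^2) / sw[i]
    })
    var_w <- resid2 * n_eff / pmax(n_eff - 1, 1e-8)
    se <- sqrt(var_w / n_eff)
    tstat <- ifelse(se > 0, smoothed / se, 0)
    df <- pmax(n_eff - 1, 1)
    p_up <- ifelse(se > 0, stats::pt(tstat, df, lower.tail = FALSE), 1)
    p_down <- ifelse(se > 0, stats::pt(tstat, df, lower.tail = TRUE), 1)
    return(tibble(smoothed = smoothed, p_up = p_up, p_down = p_down))
  }

  if (n_perm < 1) abort("n_perm must be >= 1")
  ge <- integer(n)
  le <- integer(n)
  done <- 0
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    P <- matrix(0, n, nb)
    for (b in seq_len(nb)) P[, b] <- values[sample.int(n)]
    S <- W %*% P
    ge <- ge + rowSums(S >= smoothed)
    le <- le + rowSums(S <= smoothed)
    done <- done + nb
  }
  tibble(
    smoothed = smoothed,
    p_up = (1 + ge) / (n_perm + 1),
    p_down = (1 + le) / (n_perm + 1)
  )
}

# deterministic tie-jitter: tiny position offset from a gene-id hash
jitter_ties <- function(positions, gene_ids) {
  dup <- duplicated(positions) | duplicated(positions, fromLast = TRUE)
  if (!any(dup)) return(positions)
  h <- vapply(gene_ids, function(g) {
    sum(utf8ToInt(g) * seq_along(utf8ToInt(g))) %% 9973
  }, numeric(1))
  positions[dup] <- positions[dup] + (h[dup] / 9973 - 0.5) * 1e-3
  positions
}

#' Genome scan for regions enriched in concordant differential expression
#'
#' Smooths per-gene log2 fold changes along each chromosome, computes
#' positional significance, applies Benjamini-Hochberg correction across all
#' positions genome-wide (separately for the up and down directions), and
#' merges runs of significant, direction-consistent genes into regions.
#' Genes present in the annotation but absent from the contrast's DEG table
#' enter with log2 fold change 0, so the whole annotated gene set is the
#' background.
#'
#' @param degs DEG tibble (`gene_id`, `log2fc`, `contrast`).
#' @param annotation Gene coordinate tibble (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param contrast Contrast label to scan; `NULL` uses all rows.
#' @param bandwidth Kernel bandwidth in bp (default 10 Mbp).
#' @param mode `"permutation"` (default) or `"t"`.
#' @param n_perm Permutations per chromosome (default 10000).
#' @param q_cutoff FDR cutoff for region calls (default 1e-5).
#' @param seed Integer seed for the permutation null.
#' @return List with `positions` (per-gene tibble: coordinates, log2fc,
#'   smoothed, p and q values, direction call) and `regions`
#'   (tibble `chrom`, `start`, `end`, `direction`, `peak_stat`, `min_q`,
#'   `n_genes`).
#' @export
scan_hotspots <- function(degs, annotation, contrast = NULL,
                          bandwidth = 10e6, mode = c("permutation", "t"),
                          n_perm = 10000, q_cutoff = 1e-5, seed = 1) {
  mode <- match.arg(mode)
  if (!is.null(contrast)) {
    degs <- filter(degs, .data$contrast == !!contrast)
  }
  fc <- setNames(degs$log2fc, degs$gene_id)
  pos_tab <- annotation |>
    mutate(
      midpoint = (.data$start + .data$end) / 2,
      log2fc = unname(fc[.data$gene_id]),
      log2fc = if_else(is.na(.data$log2fc), 0, .data$log2fc)
    ) |>
    arrange(.data$chrom, .data$midpoint, .data$gene_id)

  set.seed(seed)
  per_chrom <- pos_tab |>
    group_by(.data$chrom) |>
    dplyr::group_map(function(df, key) {
      pos <- jitter_ties(df$midpoint, df$gene_id)
      ord <- order(pos)
      df <- df[ord, ]
      pos <- pos[ord]
      sig <- if (nrow(df) == 1) {
        warn(sprintf("chromosome %s has a single gene; statistic left unsmoothed", key$chrom))
        tibble(smoothed = df$log2fc, p_up = 1, p_down = 1)
      } else {
        positional_significance(pos, df$log2fc, bandwidth, mode = mode, n_perm = n_perm)
      }
      bind_cols(mutate(df, chrom = key$chrom, position = pos), sig)
    }) |>
    bind_rows()

  per_chrom <- per_chrom |>
    mutate(
      q_up = p.adjust(.data$p_up, method = "BH"),
      q_down = p.adjust(.data$p_down, method = "BH"),
      direction = case_when(
        .data$q_up < q_cutoff & .data$q_up <= .data$q_down ~ "up",
        .data$q_down < q_cutoff ~ "down",
        TRUE ~ NA_character_
      )
    )
  list(
    positions = per_chrom,
    regions = call_regions(per_chrom, q_cutoff = q_cutoff)
  )
}

#' Merge significant positions into hotspot regions
#'
#' Maximal runs of consecutive genes (position order within chromosome) with
#' `q < q_cutoff` in the same direction become one region; region bounds are
#' the minimum start and maximum end of the member genes.
#'
#' @param positions Per-gene tibble from [scan_hotspots()] (needs `chrom`,
#'   `position`, `start`, `end`, `smoothed`, `q_up`, `q_down`, `direction`).
#' @param q_cutoff FDR cutoff (default 1e-5).
#' @return Tibble of regions (possibly empty): `chrom`, `start`, `end`,
#'   `direction`, `peak_stat`, `min_q`, `n_genes`.
#' @export
call_regions <- function(positions, q_cutoff = 1e-5) {
  empty <- tibble(
    chrom = character(), start = numeric(), end = numeric(),
    direction = character(), peak_stat = numeric(), min_q = numeric(),
    n_genes = integer()
  )
  sig <- positions |>
    arrange(.data$chrom, .data$position) |>
    group_by(.data$chrom) |>
    mutate(
      hit = !is.na(.data$direction),
      run = cumsum(.data$hit & (!dplyr::lag(.data$hit, default = FALSE) |
                                  .data$direction != dplyr::lag(.data$direction, default = "")))
    ) |>
    ungroup() |>
    filter(.data$hit)
  if (nrow(sig) == 0) return(empty)
  sig |>
    group_by(.data$chrom, .data$run, .data$direction) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      peak_stat = .data$smoothed[which.max(abs(.data$smoothed))],
      min_q = min(pmin(.data$q_up, .data$q_down)),
      n_genes = n(),
      .groups = "drop"
    ) |>
    select("chrom", "start", "end", "direction", "peak_stat", "min_q", "n_genes") |>
    arrange(.data$chrom, .data$start)
}
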