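#' Pipeline configuration
#'
#' One structured object holding every threshold and path of the full
#' analysis. Defaults are the conventional analysis settings: triads
#' expressed at summed TPM >= 5, genes expressed at CPM >= 1 in >= 1 sample,
#' DEGs at |log2FC| >= 1 and adjusted p < 0.01, hotspot FDR cutoff 1e-5,
#' 60/40 train/test split with fivefold cross-validation.
#'
#' @param sim Optional [sim_config()]; when given, inputs are simulated and
#'   the path arguments are ignored.
#' @param tpm_path,counts_path,samples_path,triads_path,degs_path,annotation_path
#'   Input file paths (used when `sim` is `NULL`).
#' @param out_dir Optional output directory; when given, all result tables
#'   and a run manifest are written there.
#' @param triad_threshold Summed-TPM triad expression cutoff (default 5).
#' @param cpm_threshold,cpm_min_samples Expressed-gene CPM filter (default
#'   >= 1 in >= 1 sample).
#' @param fc_threshold,padj_threshold DEG thresholds (default 1 and 0.01).
#' @param bandwidth,n_perm,q_cutoff,hotspot_mode Hotspot scan settings
#'   (default 10 Mbp, 10000 permutations, FDR 1e-5, permutation mode).
#' @param hotspot_contrast Contrast to scan; `NULL` scans the first contrast
#'   in the DEG table.
#' @param focal_category,compare Stable-bias comparison: the category and the
#'   pair `c(genotype_a, genotype_b)` (a-unique minus b); `NULL` uses the
#'   second vs first genotype of the sample sheet.
#' @param fraction_train,folds,repeats Classifier settings (default 0.6, 5, 2).
#' @param seed Global seed; per-stage seeds are derived by a fixed counter.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(sim = NULL,
                            tpm_path = NULL, counts_path = NULL,
                            samples_path = NULL, triads_path = NULL,
                            degs_path = NULL, annotation_path = NULL,
                            out_dir = NULL,
                            triad_threshold = 5,
                            cpm_threshold = 1, cpm_min_samples = 1,
                            fc_threshold = 1, padj_threshold = 0.01,
                            bandwidth = 10e6, n_perm = 10000,
                            q_cutoff = 1e-5,
                            hotspot_mode = "permutation",
                            hotspot_contrast = NULL,
                            focal_category = "B_suppressed",
                            compare = NULL,
                            fraction_train = 0.6, folds = 5, repeats = 2,
                            seed = 1) {
  stopifnot(triad_threshold > 0, cpm_threshold > 0, fc_threshold > 0,
            padj_threshold > 0, bandwidth > 0, q_cutoff > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

log_line <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(names(kv), kv, sep = "=", collapse = " ")))
}

require_file <- function(path, what) {
  if (is.null(path)) abort(sprintf("no %s path configured", what))
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate, then classify-triads, dynamics, hotspots
#' and biomarkers, returning all result tables in one report list and, if
#' `out_dir` is set, writing them to disk together with a manifest (config
#' plus hash) sufficient to reproduce the run.
#'
#' @param config A [pipeline_config()].
#' @return A report list: `assignment`, `proportions`, `expressed_triads`,
#'   `stability`, `per_category_stability`, `unique_stable`, `deg_overlap`,
#'   `hotspots`, `nsc` (model, metrics, features), `manifest`.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed

  data <- run_stage("input", {
    if (!is.null(config$sim)) {
      log_line("simulate", seed = config$sim$seed, n_triads = config$sim$n_triads)
      simulate_dataset(config$sim)
    } else {
      list(
        tpm = read_expression_matrix(require_file(config$tpm_path, "TPM matrix"), "TPM"),
        counts = read_expression_matrix(require_file(config$counts_path, "count matrix"), "counts"),
        sample_sheet = read_sample_sheet(require_file(config$samples_path, "sample sheet")),
        triads = read_triad_table(require_file(config$triads_path, "triad table")),
        deg_tables = read_deg_table(require_file(config$degs_path, "DEG table")),
        annotation = read_gene_annotation(require_file(config$annotation_path, "annotation"))
      )
    }
  })
  genotypes <- unique(data$sample_sheet$genotype)

  assign <- run_stage("classify-triads", {
    cond <- aggregate_condition_tpm(data$tpm, data$sample_sheet, data$triads)
    expressed <- filter_expressed_triads(cond, threshold = config$triad_threshold)
    log_line("classify-triads", n_triads = nrow(data$triads),
             n_expressed = length(expressed))
    classify_triads(cond, expressed)
  })
  proportions <- category_proportions(assign)

  dynamics <- run_stage("dynamics", {
    compare <- config$compare %||% c(genotypes[2], genotypes[1])
    stability <- purrr::map(genotypes, function(g) {
      tibble(genotype = g, unchanged_fraction = overall_stability(assign, g))
    }) |> bind_rows()
    per_cat <- purrr::map(genotypes, function(g) {
      mutate(per_category_stability(assign, g), genotype = g, .before = 1)
    }) |> bind_rows()
    uniq <- unique_stable_biased(assign, compare[1], compare[2],
                                 config$focal_category, data$triads)
    overlap <- deg_overlap(uniq, data$deg_tables,
                           fc_threshold = config$fc_threshold,
                           padj_threshold = config$padj_threshold)
    log_line("dynamics", n_unique_stable = nrow(uniq),
             overlap_count = overlap$count)
    list(stability = stability, per_category = per_cat,
         unique_stable = uniq, overlap = overlap,
         transitions = purrr::map(genotypes, function(g) {
           mutate(transition_counts(assign, g), genotype = g, .before = 1)
         }) |> bind_rows())
  })

  hotspots <- run_stage("hotspots", {
    contrast <- config$hotspot_contrast %||% data$deg_tables$contrast[1]
    log_line("hotspots", contrast = contrast, mode = config$hotspot_mode,
             n_perm = config$n_perm)
    scan_hotspots(data$deg_tables, data$annotation, contrast = contrast,
                  bandwidth = config$bandwidth, mode = config$hotspot_mode,
                  n_perm = config$n_perm, q_cutoff = config$q_cutoff,
                  seed = seed + 101L)
  })

  nsc <- run_stage("biomarkers", {
    cpm <- cpm_normalize(data$counts)
    expressed_genes <- filter_expressed_genes(cpm, config$cpm_threshold,
                                              config$cpm_min_samples)
    counts_f <- expr_matrix(unclass(data$counts)[expressed_genes, , drop = FALSE], "counts")
    X <- prepare_counts(counts_f)
    labels <- data$sample_sheet$genotype[match(colnames(X), data$sample_sheet$sample_id)]
    split <- split_train_test(colnames(X), labels,
                              fraction_train = config$fraction_train,
                              seed = seed + 202L)
    tr <- split$partition == "train"
    model <- train_nsc(unclass(X)[, tr, drop = FALSE], labels[tr],
                       folds = config$folds, repeats = config$repeats,
                       seed = seed + 303L)
    reference <- genotypes[length(genotypes)]
    metrics <- evaluate_nsc(model, unclass(X)[, !tr, drop = FALSE],
                            labels[!tr], reference = reference)
    log_line("biomarkers", delta = signif(model$delta, 4),
             n_selected = length(model$selected),
             accuracy = metrics$accuracy)
    list(model = model, metrics = metrics, features = selected_features(model),
         split = split, reference = reference)
  })

  manifest <- list(
    config = config_manifest(config),
    seed = seed,
    config_hash = rlang::hash(config_manifest(config)),
    n_expressed_triads = length(unique(assign$triad_id)),
    genotypes = genotypes
  )
  report <- list(
    assignment = assign, proportions = proportions,
    stability = dynamics$stability,
    per_category_stability = dynamics$per_category,
    transitions = dynamics$transitions,
    unique_stable = dynamics$unique_stable,
    deg_overlap = dynamics$overlap,
    hotspots = hotspots,
    nsc = nsc,
    truth = data$truth,
    manifest = manifest
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

config_manifest <- function(config) {
  out <- unclass(config)
  if (!is.null(out$sim)) {
    out$sim <- unclass(out$sim)
    out$sim$hotspot_spec <- as.data.frame(out$sim$hotspot_spec)
  }
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(report$assignment, p("assignment.tsv"))
  readr::write_tsv(report$proportions, p("proportions.tsv"))
  readr::write_tsv(report$stability, p("stability.tsv"))
  readr::write_tsv(report$per_category_stability, p("per_category_stability.tsv"))
  readr::write_tsv(report$transitions, p("transitions.tsv"))
  readr::write_tsv(report$unique_stable, p("unique_stable.tsv"))
  readr::write_tsv(ternary_coordinates(
    filter(report$assignment, !is.na(.data$rel_A))
  ), p("ternary_coordinates.tsv"))
  jsonlite::write_json(
    report$deg_overlap[c("count", "fraction", "genes")],
    p("deg_overlap.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(report$hotspots$positions, p("hotspot_positions.tsv"))
  if (nrow(report$hotspots$regions) > 0) {
    regions <- mutate(report$hotspots$regions,
                      region_id = sprintf("region_%03d", dplyr::row_number()))
    write_bed(select(regions, "chrom", "start", "end", "region_id",
                     "direction", "min_q", "n_genes"),
              p("hotspot_regions.bed"))
  }
  readr::write_tsv(report$nsc$features, p("nsc_selected.tsv"))
  readr::write_tsv(tibble(
    accuracy = report$nsc$metrics$accuracy,
    sensitivity = report$nsc$metrics$sensitivity,
    specificity = report$nsc$metrics$specificity,
    delta = report$nsc$model$delta,
    n_selected = length(report$nsc$model$selected)
  ), p("nsc_metrics.tsv"))
  jsonlite::write_json(report$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the end-to-end demonstration pipeline
#'
#' Simulates a compact hexaploid experiment and runs every stage on it.
#' Deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param n_triads,n_nontriad_genes Problem size (defaults keep the demo
#'   under a minute).
#' @param n_perm Permutations for the hotspot scan.
#' @return The pipeline report list.
#' @export
run_demo <- function(seed = 1, out_dir = NULL, n_triads = 300,
                     n_nontriad_genes = 900, n_perm = 2000) {
  cfg <- pipeline_config(
    sim = sim_config(n_triads = n_triads, n_nontriad_genes = n_nontriad_genes,
                     seed = seed),
    out_dir = out_dir, n_perm = n_perm, q_cutoff = 0.01, seed = seed
  )
  run_pipeline(cfg)
}
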