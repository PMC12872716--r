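#' Configuration for a synthetic hexaploid experiment
#'
#' Collects every knob of the simulator with defaults that emulate a
#' two-genotype (high- vs low-embryogenic), three-stage, three-replicate
#' hexaploid wheat time course: triads with planted bias categories evolving
#' under a simple Markov stability rule, negative-binomial count noise, a
#' planted chromosomal hotspot block of concordant between-genotype fold
#' change, planted biomarker genes, and additional planted DE genes.
#'
#' @param n_triads Number of A/B/D triads (default 1000).
#' @param n_nontriad_genes Genes outside triads (default 2000).
#' @param genotypes Two or more genotype labels; effects are applied to the
#'   first genotype relative to the others.
#' @param stages Ordered stage labels.
#' @param replicates Replicates per genotype x stage.
#' @param category_proportions Named probability vector over the seven bias
#'   categories used to draw each triad's starting category.
#' @param stability Probability that a triad keeps its category across one
#'   stage transition; on a change the category is redrawn from
#'   `category_proportions`.
#' @param concentration Dirichlet concentration around the category
#'   archetype; larger keeps draws inside the classification region.
#' @param nb_dispersion Negative-binomial dispersion (`0` gives the
#'   deterministic rounded-mean limit).
#' @param mean_log_expression,sd_log_expression Log-normal parameters of the
#'   triad total expression level (TPM-scale units).
#' @param gene_length_range Gene length interval in bp.
#' @param chrom_length Chromosome length in bp (all 21 chromosomes equal).
#' @param depth Expected counts per expression unit per kb of gene length.
#' @param hotspot_spec Tibble `chrom`, `start`, `end`, `direction`
#'   (`"up"`/`"down"`), `effect` (absolute log2 fold change) of planted
#'   hotspot blocks; effects are applied in the first genotype, at every
#'   stage.
#' @param hotspot_scope `"nontriad"` (default) shifts only non-triad genes
#'   inside a block, so planted bias categories stay exactly interpretable;
#'   `"all"` shifts every gene in the block (a dense structural-variant-like
#'   hotspot), at the cost of perturbing the realized bias of triads whose
#'   focal homoeolog falls inside it.
#' @param n_biomarkers,biomarker_effect Number of planted biomarker genes
#'   (non-triad, outside hotspots) and their absolute between-genotype log2
#'   effect; signs alternate starting with up.
#' @param deg_fraction,deg_effect Fraction of remaining non-triad genes given
#'   a between-genotype shift of `deg_effect` log2 units (random sign).
#' @param seed Integer seed fixing the entire output.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_triads = 1000,
                       n_nontriad_genes = 2000,
                       genotypes = c("Nanda", "Sadash"),
                       stages = c("Day0", "Day7", "Day21"),
                       replicates = 3,
                       category_proportions = c(
                         A_dominant = 0.009, B_dominant = 0.009, D_dominant = 0.009,
                         A_suppressed = 0.030, B_suppressed = 0.045, D_suppressed = 0.020,
                         balanced = 0.878
                       ),
                       stability = 0.73,
                       concentration = 200,
                       nb_dispersion = 0.05,
                       mean_log_expression = 4,
                       sd_log_expression = 1,
                       gene_length_range = c(1000, 5000),
                       chrom_length = 600e6,
                       depth = 5,
                       hotspot_spec = tibble(
                         chrom = "1B", start = 100e6, end = 330e6,
                         direction = "up", effect = 3
                       ),
                       hotspot_scope = c("nontriad", "all"),
                       n_biomarkers = 2,
                       biomarker_effect = 4,
                       deg_fraction = 0.05,
                       deg_effect = 2,
                       seed = 1) {
  cats <- setdiff(BIAS_LEVELS, "undefined")
  if (!setequal(names(category_proportions), cats)) {
    abort("category_proportions must be named over the seven bias categories")
  }
  category_proportions <- category_proportions[cats]
  if (abs(sum(category_proportions) - 1) > 1e-8) {
    abort("category_proportions must sum to 1")
  }
  if (stability < 0 || stability > 1) abort("stability must lie in [0, 1]")
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (concentration <= 0) abort("concentration must be positive")
  if (n_triads < 1) abort("n_triads must be >= 1")
  if (length(genotypes) < 2) abort("need >= 2 genotypes")
  if (diff(gene_length_range) < 0 || gene_length_range[1] < 1) {
    abort("invalid gene_length_range")
  }
  hotspot_scope <- match.arg(hotspot_scope)
  structure(
    list(
      n_triads = n_triads, n_nontriad_genes = n_nontriad_genes,
      genotypes = genotypes, stages = stages, replicates = replicates,
      category_proportions = category_proportions, stability = stability,
      concentration = concentration, nb_dispersion = nb_dispersion,
      mean_log_expression = mean_log_expression,
      sd_log_expression = sd_log_expression,
      gene_length_range = gene_length_range, chrom_length = chrom_length,
      depth = depth, hotspot_spec = hotspot_spec,
      hotspot_scope = hotspot_scope,
      n_biomarkers = n_biomarkers, biomarker_effect = biomarker_effect,
      deg_fraction = deg_fraction, deg_effect = deg_effect, seed = seed
    ),
    class = "sim_config"
  )
}

# Dirichlet centers of the seven categories, strictly inside the
# classification regions (dominant 0.8 > 0.60; suppressed 0.05 < 0.20).
category_archetypes <- function() {
  rbind(
    A_dominant = c(0.80, 0.10, 0.10),
    B_dominant = c(0.10, 0.80, 0.10),
    D_dominant = c(0.10, 0.10, 0.80),
    A_suppressed = c(0.050, 0.475, 0.475),
    B_suppressed = c(0.475, 0.050, 0.475),
    D_suppressed = c(0.475, 0.475, 0.050),
    balanced = c(1, 1, 1) / 3
  )
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Analytic expectation of the overall unchanged fraction
#'
#' Under the generator's Markov rule (keep the category with probability
#' `stability`, otherwise redraw from `proportions`), the probability that a
#' triad shows the same category at all stages is
#' `sum_c pi_c * (s + (1 - s) * pi_c)^(n_stages - 1)`.
#'
#' @param proportions Category probability vector.
#' @param stability Per-transition keep probability.
#' @param n_stages Number of stages (default 3).
#' @return Expected unchanged fraction.
#' @export
expected_unchanged_fraction <- function(proportions, stability, n_stages = 3) {
  sum(proportions * (stability + (1 - stability) * proportions)^(n_stages - 1))
}

#' Generate triads and gene coordinates
#'
#' Places `3 * n_triads` triad genes on the 21 wheat-style chromosomes
#' (1A..7D), with the A/B/D homoeologs of each triad on the cognate
#' chromosome group, plus the non-triad genes spread round-robin. Genes are
#' laid out in non-overlapping slots along each chromosome, order shuffled
#' within the chromosome.
#'
#' @param config A [sim_config()].
#' @return List with `triads` (tibble `triad_id`, `gene_A`, `gene_B`,
#'   `gene_D`) and `annotation` (tibble `gene_id`, `chrom`, `start`, `end`,
#'   `strand`), sorted by chromosome and start.
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  groups <- rep_len(1:7, config$n_triads)
  triads <- tibble(
    triad_id = sprintf("triad_%05d", seq_len(config$n_triads)),
    gene_A = sprintf("t%05dA", seq_len(config$n_triads)),
    gene_B = sprintf("t%05dB", seq_len(config$n_triads)),
    gene_D = sprintf("t%05dD", seq_len(config$n_triads)),
    group = groups
  )
  chroms <- as.vector(outer(1:7, c("A", "B", "D"), paste0))
  gene_chrom <- c(
    setNames(paste0(triads$group, "A"), triads$gene_A),
    setNames(paste0(triads$group, "B"), triads$gene_B),
    setNames(paste0(triads$group, "D"), triads$gene_D)
  )
  if (config$n_nontriad_genes > 0) {
    nt <- sprintf("ng%05d", seq_len(config$n_nontriad_genes))
    gene_chrom <- c(gene_chrom, setNames(rep_len(chroms, length(nt)), nt))
  }
  ann <- purrr::map(chroms, function(ch) {
    ids <- names(gene_chrom)[gene_chrom == ch]
    m <- length(ids)
    if (m == 0) return(NULL)
    slot <- config$chrom_length / (m + 1)
    if (slot - 1 < config$gene_length_range[1]) {
      abort(sprintf("chromosome capacity exceeded on %s (%d genes in %g bp)",
                    ch, m, config$chrom_length))
    }
    ids <- sample(ids)
    len <- pmin(round(runif(m, config$gene_length_range[1], config$gene_length_range[2])),
                floor(slot) - 1)
    start <- floor((seq_len(m) - 1) * slot) + 1
    tibble(gene_id = ids, chrom = ch, start = start, end = start + len - 1,
           strand = sample(c("+", "-"), m, replace = TRUE))
  }) |>
    bind_rows() |>
    arrange(.data$chrom, .data$start)
  list(triads = select(triads, -"group"), annotation = ann)
}

#' Simulate a complete hexaploid experiment
#'
#' Draws, for every triad, genotype and stage, a bias category (initial draw
#' from `category_proportions`, then a keep/redraw Markov rule with
#' probability `stability`), a triad total expression level (log-normal,
#' shared between genotypes so genotype differences come only from planted
#' effects), and subgenome shares from a Dirichlet centred on the category
#' archetype. Non-triad genes get a constant baseline, modified in the first
#' genotype by hotspot, biomarker and planted-DE effects. Per-replicate
#' counts are negative binomial around `expression x length_kb x depth`; TPM
#' is recomputed from the counts and lengths and column-normalized to 1e6.
#' DEG tables for the between-genotype contrast at each stage report the
#' true log2 fold change of expected expression, with `padj` assigned below
#' 0.01 for genes whose true |log2FC| >= 1 and above it otherwise.
#'
#' @param config A [sim_config()].
#' @return List: `counts`, `tpm` (matrices), `sample_sheet`, `triads`,
#'   `annotation`, `deg_tables`, `truth` (planted categories, DEG truth,
#'   hotspots, biomarkers), `config`.
#' @export
simulate_dataset <- function(config) {
  ann <- generate_annotation(config)
  set.seed(config$seed + 1L)
  genotypes <- config$genotypes
  stages <- config$stages
  n_t <- config$n_triads
  cats <- names(config$category_proportions)
  arch <- category_archetypes()

  # --- planted categories: Markov chain over stages, per triad x genotype
  cat_draw <- function(n) sample(cats, n, replace = TRUE, prob = config$category_proportions)
  truth_cat <- purrr::map(genotypes, function(g) {
    m <- matrix(NA_character_, n_t, length(stages))
    m[, 1] <- cat_draw(n_t)
    for (j in seq_along(stages)[-1]) {
      keep <- runif(n_t) < config$stability
      m[, j] <- ifelse(keep, m[, j - 1], cat_draw(n_t))
    }
    m
  })
  names(truth_cat) <- genotypes

  # --- expected expression per gene x (genotype, stage)
  conditions <- tidyr::expand_grid(genotype = genotypes, stage = stages)
  cond_id <- paste(conditions$genotype, conditions$stage, sep = ".")
  gene_ids <- ann$annotation$gene_id
  E <- matrix(0, length(gene_ids), nrow(conditions),
              dimnames = list(gene_ids, cond_id))

  # triad totals shared across genotypes: one level per triad x stage
  T_ts <- matrix(exp(stats::rnorm(n_t * length(stages),
                                  config$mean_log_expression,
                                  config$sd_log_expression)),
                 n_t, length(stages))
  for (gi in seq_along(genotypes)) {
    for (si in seq_along(stages)) {
      cc <- truth_cat[[gi]][, si]
      p <- matrix(NA_real_, n_t, 3)
      for (ct in cats) {
        idx <- cc == ct
        if (any(idx)) {
          p[idx, ] <- rdirichlet(sum(idx), config$concentration * arch[ct, ])
        }
      }
      col <- paste(genotypes[gi], stages[si], sep = ".")
      E[ann$triads$gene_A, col] <- T_ts[, si] * p[, 1]
      E[ann$triads$gene_B, col] <- T_ts[, si] * p[, 2]
      E[ann$triads$gene_D, col] <- T_ts[, si] * p[, 3]
    }
  }

  # non-triad baseline, constant over conditions
  nt_ids <- setdiff(gene_ids, c(ann$triads$gene_A, ann$triads$gene_B, ann$triads$gene_D))
  if (length(nt_ids) > 0) {
    base <- exp(stats::rnorm(length(nt_ids),
                             config$mean_log_expression - log(3),
                             config$sd_log_expression))
    E[nt_ids, ] <- matrix(base, length(nt_ids), ncol(E))
  }

  # --- planted effects in the first genotype
  first_cols <- grepl(paste0("^", genotypes[1], "\\."), colnames(E))
  midpt <- setNames((ann$annotation$start + ann$annotation$end) / 2,
                    ann$annotation$gene_id)
  chrom_of <- setNames(ann$annotation$chrom, ann$annotation$gene_id)

  hotspot_genes <- character(0)
  hs <- config$hotspot_spec
  hs_pool <- if (identical(config$hotspot_scope, "all")) gene_ids else nt_ids
  if (!is.null(hs) && nrow(hs) > 0) {
    for (k in seq_len(nrow(hs))) {
      in_block <- hs_pool[chrom_of[hs_pool] == hs$chrom[k] &
                            midpt[hs_pool] >= hs$start[k] &
                            midpt[hs_pool] <= hs$end[k]]
      sgn <- if (hs$direction[k] == "up") 1 else -1
      E[in_block, first_cols] <- E[in_block, first_cols] * 2^(sgn * hs$effect[k])
      hotspot_genes <- c(hotspot_genes, in_block)
    }
  }

  free <- setdiff(nt_ids, hotspot_genes)
  n_bio <- min(config$n_biomarkers, length(free))
  biomarker_genes <- if (n_bio > 0) sort(sample(free, n_bio)) else character(0)
  bio_sign <- rep_len(c(1, -1), n_bio)
  for (i in seq_len(n_bio)) {
    E[biomarker_genes[i], first_cols] <-
      E[biomarker_genes[i], first_cols] * 2^(bio_sign[i] * config$biomarker_effect)
  }

  free <- setdiff(free, biomarker_genes)
  n_deg <- round(config$deg_fraction * length(free))
  deg_genes <- if (n_deg > 0) sort(sample(free, n_deg)) else character(0)
  deg_sign <- sample(c(1, -1), length(deg_genes), replace = TRUE)
  if (n_deg > 0) {
    E[deg_genes, first_cols] <- E[deg_genes, first_cols] *
      2^(deg_sign * config$deg_effect)
  }

  # --- counts and TPM
  sample_sheet <- tidyr::expand_grid(
    genotype = genotypes, stage = stages, replicate = seq_len(config$replicates)
  ) |>
    mutate(sample_id = sprintf("%s_%s_R%d", .data$genotype, .data$stage, .data$replicate)) |>
    select("sample_id", "genotype", "stage", "replicate") |>
    mutate(stage = factor(.data$stage, levels = stages, ordered = TRUE))

  len_kb <- setNames((ann$annotation$end - ann$annotation$start + 1) / 1000,
                     ann$annotation$gene_id)[gene_ids]
  counts <- matrix(0, length(gene_ids), nrow(sample_sheet),
                   dimnames = list(gene_ids, sample_sheet$sample_id))
  for (s in seq_len(nrow(sample_sheet))) {
    col <- paste(sample_sheet$genotype[s], sample_sheet$stage[s], sep = ".")
    mu <- E[, col] * len_kb * config$depth
    counts[, s] <- if (config$nb_dispersion == 0) {
      round(mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
  }
  rate <- counts / len_kb
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6

  # --- DEG tables: first genotype vs each other genotype, per stage
  deg_tables <- purrr::map(seq_along(stages), function(si) {
    contrast <- sprintf("%s%s_%s", substr(genotypes[1], 1, 1),
                        substr(genotypes[2], 1, 1), stages[si])
    mu_a <- E[, paste(genotypes[1], stages[si], sep = ".")]
    mu_b <- E[, paste(genotypes[2], stages[si], sep = ".")]
    l2fc <- log2((mu_a + 0.01) / (mu_b + 0.01))
    de <- abs(l2fc) >= 1
    tibble(
      gene_id = gene_ids,
      log2fc = unname(l2fc),
      padj = ifelse(de, runif(length(l2fc), 0, 0.0099),
                    runif(length(l2fc), 0.0101, 1)),
      contrast = contrast
    )
  }) |> bind_rows()

  truth <- list(
    categories = purrr::map(genotypes, function(g) {
      tibble(
        triad_id = rep(ann$triads$triad_id, length(stages)),
        genotype = g,
        stage = rep(stages, each = n_t),
        category = as.vector(truth_cat[[g]])
      )
    }) |> bind_rows(),
    deg_truth = deg_tables |>
      mutate(is_de = abs(.data$log2fc) >= 1) |>
      select("gene_id", "contrast", true_log2fc = "log2fc", "is_de"),
    hotspots = if (!is.null(hs) && nrow(hs) > 0) {
      mutate(hs, n_genes = vapply(seq_len(nrow(hs)), function(k)
        sum(chrom_of[hotspot_genes] == hs$chrom[k] &
              midpt[hotspot_genes] >= hs$start[k] &
              midpt[hotspot_genes] <= hs$end[k]), numeric(1)))
    } else hs,
    biomarkers = tibble(
      gene_id = biomarker_genes,
      effect = bio_sign * config$biomarker_effect
    ),
    planted_deg = tibble(gene_id = deg_genes,
                         effect = deg_sign * config$deg_effect),
    expected_expression = E
  )

  list(
    counts = expr_matrix(counts, "counts"),
    tpm = expr_matrix(tpm, "TPM"),
    sample_sheet = sample_sheet,
    triads = ann$triads,
    annotation = ann$annotation,
    deg_tables = deg_tables,
    truth = truth,
    config = config
  )
}

#' Write a simulated dataset to disk
#'
#' Emits every format the readers consume (TSV matrices and tables, GFF3
#' annotation) plus a JSON manifest with the full configuration, so a run
#' can be reproduced from the manifest alone.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param directory Target directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  write_expression_matrix(dataset$counts, p("counts.tsv"))
  write_expression_matrix(dataset$tpm, p("tpm.tsv"))
  readr::write_tsv(dataset$sample_sheet, p("sample_sheet.tsv"))
  readr::write_tsv(dataset$triads, p("triads.tsv"))
  readr::write_tsv(dataset$deg_tables, p("degs.tsv"))
  readr::write_tsv(dataset$truth$categories, p("truth_categories.tsv"))
  gr <- GenomicRanges::GRanges(
    seqnames = dataset$annotation$chrom,
    ranges = IRanges::IRanges(dataset$annotation$start, dataset$annotation$end),
    strand = dataset$annotation$strand
  )
  gr$ID <- dataset$annotation$gene_id
  gr$type <- "gene"
  gr$source <- "hexbias"
  rtracklayer::export(gr, p("annotation.gff3"), format = "gff3")
  manifest <- dataset$config
  class(manifest) <- NULL
  manifest$category_proportions <- as.list(manifest$category_proportions)
  manifest$hotspot_spec <- as.data.frame(manifest$hotspot_spec)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Rebuild a simulation config from a manifest
#'
#' @param path Path to a `manifest.json` written by [write_fixture()].
#' @return A [sim_config()].
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$category_proportions <- unlist(m$category_proportions)
  m$hotspot_spec <- as_tibble(m$hotspot_spec)
  do.call(sim_config, m)
}
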