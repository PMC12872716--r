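#' Expression matrix with a declared unit
#'
#' A thin wrapper around a numeric genes x samples matrix that records what
#' the values are (raw counts, CPM, TPM or log2 scale) and enforces the basic
#' invariants every downstream step relies on: unique gene and sample
#' identifiers and no negative values.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param unit One of `"counts"`, `"CPM"`, `"TPM"`, `"log2"`.
#'
#' @return The matrix with a `unit` attribute, invisibly classed
#'   `"expr_matrix"`.
#' @export
expr_matrix <- function(values, unit = c("counts", "CPM", "TPM", "log2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g) > 0) {
    abort(paste0("duplicated gene id(s): ", paste(unique(dup_g), collapse = ", ")))
  }
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s) > 0) {
    abort(paste0("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", ")))
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric or missing value at gene '%s', sample '%s'",
      rownames(values)[idx[1]], colnames(values)[idx[2]]
    ))
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "negative value (%g) at gene '%s', sample '%s'",
      values[idx[1], idx[2]], rownames(values)[idx[1]], colnames(values)[idx[2]]
    ))
  }
  attr(values, "unit") <- unit
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Unit of an expression matrix
#'
#' @param x A matrix produced by [expr_matrix()] or one of the readers.
#' @return The unit string, or `NA` if none recorded.
#' @export
expr_unit <- function(x) attr(x, "unit") %||% NA_character_

check_unit <- function(x, expected, what) {
  u <- expr_unit(x)
  if (!is.na(u) && u != expected) {
    abort(sprintf("%s expects a matrix in %s, got %s", what, expected, u))
  }
  invisible(x)
}

#' Read a TSV expression matrix
#'
#' Tab-separated, first column gene identifiers, header row of sample
#' identifiers, `#` lines ignored. All values must be numeric and
#' non-negative; duplicated gene or sample ids are rejected by name.
#'
#' @param path Path to the TSV file.
#' @inheritParams expr_matrix
#' @return An [expr_matrix()] with the declared unit.
#' @export
read_expression_matrix <- function(path, unit = c("counts", "CPM", "TPM", "log2")) {
  unit <- match.arg(unit)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tab) < 2) abort("expression matrix needs a gene column and >= 1 sample column")
  genes <- tab[[1]]
  vals <- suppressWarnings(
    vapply(tab[-1], function(col) as.numeric(col), numeric(nrow(tab)))
  )
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(genes, names(tab)[-1]))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell at gene '%s', sample '%s' in %s",
                  genes[idx[1]], colnames(vals)[idx[2]], path))
  }
  expr_matrix(vals, unit)
}

#' Write an expression matrix as TSV
#'
#' @param x Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- tibble(gene_id = rownames(x))
  df <- bind_cols(df, as_tibble(unclass(x)[, , drop = FALSE]))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Columns `sample_id`, `genotype`, `stage`, `replicate`. Stages are ordered
#' as first encountered unless `stages` gives the order explicitly.
#'
#' @param path TSV path.
#' @param stages Optional character vector fixing the stage order.
#' @return Tibble with `stage` as an ordered factor.
#' @export
read_sample_sheet <- function(path, stages = NULL) {
  sheet <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("sample_id", "genotype", "stage", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0) abort(paste0("sample sheet missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(sheet$sample_id)) {
    abort(paste0("duplicated sample_id: ",
                 paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", ")))
  }
  stages <- stages %||% unique(sheet$stage)
  mutate(sheet, stage = factor(.data$stage, levels = stages, ordered = TRUE))
}

#' Read a triad table
#'
#' Columns `triad_id`, `gene_A`, `gene_B`, `gene_D`; exact 1:1:1
#' correspondence with no gene in two triads.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_triad_table <- function(path) {
  triads <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  validate_triad_table(triads)
}

validate_triad_table <- function(triads) {
  need <- c("triad_id", "gene_A", "gene_B", "gene_D")
  miss <- setdiff(need, names(triads))
  if (length(miss) > 0) abort(paste0("triad table missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(triads$triad_id)) abort("duplicated triad_id")
  genes <- c(triads$gene_A, triads$gene_B, triads$gene_D)
  if (any(is.na(genes)) || any(genes == "")) abort("every triad needs all three homoeolog slots filled")
  if (anyDuplicated(genes)) {
    abort(paste0("gene(s) assigned to more than one triad slot: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  as_tibble(triads)
}

#' Read a differential-expression table
#'
#' Columns `gene_id`, `log2fc`, `padj`, `contrast`. `padj` must lie in
#' \[0, 1\] and a gene may appear at most once per contrast. A derived
#' `direction` column (`"up"`/`"down"`) is added from the sign of `log2fc`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_deg_table <- function(path) {
  degs <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("gene_id", "log2fc", "padj", "contrast")
  miss <- setdiff(need, names(degs))
  if (length(miss) > 0) abort(paste0("DEG table missing column(s): ", paste(miss, collapse = ", ")))
  if (any(degs$padj < 0 | degs$padj > 1, na.rm = TRUE)) abort("padj outside [0, 1]")
  if (anyDuplicated(degs[c("gene_id", "contrast")])) {
    abort("gene appears more than once within a contrast")
  }
  mutate(degs, direction = if_else(.data$log2fc >= 0, "up", "down"))
}

#' Read gene coordinates from GFF3 or BED
#'
#' Coordinates are stored 1-based closed; BED input (0-based half-open) is
#' converted on read. For GFF3 the gene identifier is taken from the `ID`
#' attribute (a leading `gene:` prefix is stripped); for BED from the name
#' column.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"`, `"bed"`, or `"auto"` (from the file extension).
#' @param feature For GFF3, feature type to keep (default `"gene"`; set
#'   `NULL` to keep all records).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, dialect = c("auto", "gff3", "bed"),
                                 feature = "gene") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("gff", "gff3")) "gff3" else if (ext == "bed") "bed" else
      abort(sprintf("cannot infer dialect from extension '.%s'; pass `dialect`", ext))
  }
  gr <- if (dialect == "gff3") {
    rtracklayer::import(path, format = "gff3")
  } else {
    rtracklayer::import(path, format = "bed")
  }
  ann <- tibble(
    gene_id = if (dialect == "gff3") {
      sub("^gene:", "", as.character(gr$ID %||% gr$Name %||% seq_along(gr)))
    } else {
      as.character(gr$name %||% seq_along(gr))
    },
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = if (dialect == "gff3" && !is.null(gr$type)) as.character(gr$type) else NA_character_
  )
  if (dialect == "gff3" && !is.null(feature) && !all(is.na(ann$type))) {
    ann <- filter(ann, .data$type == feature)
  }
  ann <- select(ann, -"type")
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (any(ann$end < ann$start)) abort("annotation has end < start")
  if (any(ann$start < 1)) abort("annotation has non-positive coordinates")
  if (anyDuplicated(ann$gene_id)) {
    abort(paste0("duplicated gene_id in annotation: ",
                 paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", ")))
  }
  as_tibble(ann)
}

#' Write gene coordinates (or any interval table) as BED
#'
#' Internal 1-based closed coordinates are emitted 0-based half-open. Extra
#' columns beyond the standard six are appended in order.
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally a name column
#'   (`gene_id` or `region_id`), `score`, `strand`, plus extras.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  col_or <- function(nm, default) if (nm %in% names(x)) x[[nm]] else default
  bed <- tibble(
    chrom = x$chrom,
    start = x$start - 1L,
    end = x$end,
    name = col_or("gene_id", col_or("region_id", rep(".", nrow(x)))),
    score = col_or("score", rep(0, nrow(x))),
    strand = col_or("strand", rep(".", nrow(x)))
  )
  extra <- setdiff(names(x), c("chrom", "start", "end", "gene_id", "region_id",
                               "score", "strand"))
  if (length(extra) > 0) bed <- bind_cols(bed, x[extra])
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Counts-per-million normalization
#'
#' Scales each sample to a library size of one million:
#' `CPM[g, s] = counts[g, s] / sum(counts[, s]) * 1e6`. Library size is the
#' column sum of the matrix as loaded, before any gene filtering.
#'
#' @param counts Count matrix (unit `"counts"`).
#' @return An [expr_matrix()] in CPM; every column sums to 1e6.
#' @export
cpm_normalize <- function(counts) {
  check_unit(counts, "counts", "cpm_normalize()")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    abort(paste0("zero library size for sample(s): ",
                 paste(colnames(counts)[libsize == 0], collapse = ", ")))
  }
  expr_matrix(sweep(unclass(counts), 2, libsize, "/") * 1e6, "CPM")
}

#' Expressed-gene filter on CPM
#'
#' A gene is retained when its CPM is at least `threshold` in at least
#' `min_samples` samples; the boundary (CPM exactly equal to the threshold)
#' is retained.
#'
#' @param cpm CPM matrix.
#' @param threshold CPM cutoff (default 1).
#' @param min_samples Minimum number of samples meeting the cutoff (default 1).
#' @return Character vector of retained gene ids, in matrix order.
#' @export
filter_expressed_genes <- function(cpm, threshold = 1, min_samples = 1) {
  check_unit(cpm, "CPM", "filter_expressed_genes()")
  keep <- rowSums(unclass(cpm) >= threshold) >= min_samples
  rownames(cpm)[keep]
}
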