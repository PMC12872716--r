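# Shared fixtures, built in code. The small dataset is memoized per session
# because several test files reuse it.

tiny_config <- function(seed = 42, ...) {
  sim_config(n_triads = 60, n_nontriad_genes = 120, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- simulate_dataset(tiny_config())
  }
  .fixture_env$tiny
}

# small expression matrix with named dims
mk_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  expr_matrix(m, "counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random category assignment table over triads x genotypes x stages
random_assignment <- function(n_triads = 50, seed = 1,
                              genotypes = c("Nanda", "Sadash"),
                              stages = c("Day0", "Day7", "Day21"),
                              p_undefined = 0.05) {
  set.seed(seed)
  grid <- expand.grid(
    triad_id = sprintf("tr%03d", seq_len(n_triads)),
    genotype = genotypes, stage = stages,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cats <- bias_levels()
  probs <- c(rep(0.06, 6), 0.64, 0)
  grid$category <- factor(
    ifelse(runif(nrow(grid)) < p_undefined, "undefined",
           sample(cats[1:7], nrow(grid), replace = TRUE, prob = probs[1:7])),
    levels = cats
  )
  grid$stage <- factor(grid$stage, levels = stages, ordered = TRUE)
  tibble::as_tibble(grid)
}
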