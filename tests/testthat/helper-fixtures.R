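# Small fixtures shared across test files, built in code.

small_panel <- function(n_genes = 200, seed = 1L) {
  io_panel(n_genes = n_genes, seed = seed)
}

# A small simulated cohort (balanced groups) used where group sizes are
# irrelevant; full Table-1-sized cohorts are built explicitly where the
# design matters.
small_cohort <- function(seed = 1L, contrasts = NULL, ...) {
  panel <- small_panel()
  eff <- effect_spec(panel, contrasts = contrasts, seed = seed, ...)
  simulate_cohort(cohort_design(10, 10, 4, 2, 4), panel, eff,
                  seed = seed)
}

# Hand-built expression matrix: deterministic values, no simulator.
toy_expr <- function(genes, values) {
  out <- dplyr::bind_cols(
    tibble::tibble(gene = genes, probe_class = "Endogenous"),
    tibble::as_tibble(values))
  class(out) <- c("expr_matrix", class(out))
  out
}

# Hand-built cell-score tibble from a population x sample matrix.
toy_scores <- function(m) {
  out <- dplyr::bind_cols(tibble::tibble(population = rownames(m)),
                          tibble::as_tibble(m))
  class(out) <- c("cell_scores", class(out))
  out
}
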