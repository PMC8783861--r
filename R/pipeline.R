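#' Run the full immune-profiling pipeline
#'
#' One-call orchestration of every stage, in analysis order: (simulate
#' or ingest) raw counts, control-probe + housekeeper normalization,
#' immune population scoring, total-TIL and PD-L1 readouts,
#' immunological distances and closeness tests, hot/cold clustering
#' with label-association tests, and the differential analyses
#' (populations in three- and four-group mode and within strata, genes,
#' gene-set decomposition, PD-L1 Spearman panel).  In simulate mode a
#' truth-versus-estimate recovery table is appended.
#'
#' @param counts Count matrix tibble, or `NULL` to simulate.
#' @param metadata Cohort metadata tibble (required with `counts`).
#' @param design,panel,effects Simulator configuration, used when
#'   `counts` is `NULL`.
#' @param seed Seed for the simulation.
#' @param reference Optional reference expression table for
#'   data-driven housekeeper selection; `NULL` uses the housekeeping
#'   probe class / packaged list.
#' @param marker_map Marker map (default [default_marker_map()]).
#' @param gene_set Gene set for the set analysis (default
#'   [default_cytokine_set()]); `NULL` skips it.
#' @param fdr FDR level (default 0.05).
#' @param pdl1_gene PD-L1 symbol (default `CD274`).
#' @param run_genes Run the per-gene differential analysis (default
#'   TRUE; the slowest stage).
#' @return A `tme_report` list; see the individual stage functions for
#'   each element.
#' @export
#' @examples
#' rep <- run_pipeline(design = cohort_design(10, 10, 4, 2, 4),
#'                     panel = io_panel(n_genes = 200), seed = 1,
#'                     run_genes = FALSE)
#' glance(rep)
run_pipeline <- function(counts = NULL, metadata = NULL,
                         design = cohort_design(),
                         panel = io_panel(),
                         effects = NULL, seed = 1L,
                         reference = NULL,
                         marker_map = default_marker_map(),
                         gene_set = default_cytokine_set(),
                         fdr = 0.05, pdl1_gene = "CD274",
                         run_genes = TRUE) {
  truth <- NULL
  if (is.null(counts)) {
    effects <- effects %||% effect_spec(panel, contrasts = NULL,
                                        seed = seed)
    sim <- simulate_cohort(design, panel, effects, seed = seed)
    counts <- sim$counts
    metadata <- sim$metadata
    truth <- sim$truth
  } else {
    if (is.null(metadata)) abort("metadata required with explicit counts")
    validate_metadata(metadata, counts)
  }

  qc <- fit_control_factors(counts)
  hk <- if (is.null(reference)) {
    hk_probes <- counts$gene[counts$probe_class == "Housekeeping"]
    tibble(gene = if (length(hk_probes)) hk_probes else
      default_housekeepers(), selected = TRUE)
  } else {
    select_housekeepers(reference)
  }
  expr <- normalize_counts(counts, qc, hk)
  metadata <- metadata[metadata$sample_id %in% sample_ids(expr, "gene"), ]

  scores <- score_populations(expr, marker_map)
  til <- til_score(scores)
  dmat <- immune_distance(scores)
  clustering <- cluster_samples(scores, k = 2)
  assoc <- list(
    subgroup = association_test(clustering$labels, metadata, "subgroup"))
  pop_tree <- cluster_populations(scores)

  pop_3group <- test_populations(scores, metadata, "subgroup", fdr = fdr)
  grp <- group_label(metadata)
  pop_4group <- if (all(c("ALK", "EGFR", "LTR", "RP") %in% grp)) {
    test_populations(scores, metadata, "four_group", fdr = fdr)
  }
  strata <- list()
  for (v in intersect(c("smoking", "tp53"), names(metadata))) {
    strata[[v]] <- test_populations(scores, metadata, "subgroup",
                                    strata = v, fdr = fdr)
  }
  closeness <- list()
  if (all(c("LTR", "RP") %in% grp)) {
    for (q in intersect(c("ALK", "EGFR"), grp)) {
      closeness[[q]] <- closeness_test(scores, metadata, q)
    }
  }

  pdl1 <- if (pdl1_gene %in% expr$gene) pdl1_expression(expr, pdl1_gene)
  pdl1_cor <- NULL
  if (!is.null(pdl1)) {
    feats <- bind_rows(
      scores,
      bind_cols(tibble(population = "PD-L1"),
                as_tibble(as.list(setNames(pdl1$pdl1, pdl1$sample_id)))))
    pdl1_cor <- spearman_panel(feats, "PD-L1", metadata)
  }

  genes <- NULL; set_report <- NULL
  if (run_genes) {
    genes <- test_genes(expr, metadata, fdr = fdr)
    if (!is.null(gene_set)) {
      set_report <- gene_set_summary(genes, gene_set)
    }
  }

  recovery <- NULL
  if (!is.null(truth) && nrow(truth)) {
    est <- map_dbl(seq_len(nrow(truth)), function(i) {
      sel_a <- grp == truth$group_a[i] |
        metadata$subgroup == truth$group_a[i]
      sel_b <- grp == truth$group_b[i] |
        metadata$subgroup == truth$group_b[i]
      m <- wide_to_matrix(scores, "population")
      row <- m[truth$population[i], ]
      signed_fc(row[metadata$sample_id[sel_a & !is.na(sel_a)]],
                row[metadata$sample_id[sel_b & !is.na(sel_b)]])
    })
    recovery <- bind_cols(truth, tibble(estimated_fc = est))
  }

  structure(
    list(qc = qc, housekeepers = hk, expr = expr, scores = scores,
         til = til, distance = dmat, clustering = clustering,
         association = assoc, population_tree = pop_tree,
         populations = pop_3group, populations_4group = pop_4group,
         populations_strata = strata, closeness = closeness,
         pdl1 = pdl1, pdl1_correlations = pdl1_cor, genes = genes,
         gene_set = set_report, recovery = recovery, metadata = metadata,
         manifest = list(seed = seed, fdr = fdr,
                         n_samples = nrow(metadata),
                         package_version =
                           as.character(utils::packageVersion("immunoscape")))),
    class = "tme_report")
}

#' @export
print.tme_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<tme_report> %d samples | %d/%d populations significant (FDR %g)",
    g$n_samples, g$n_significant_populations, g$n_populations,
    x$manifest$fdr))
  if (!is.null(x$genes)) {
    cat(sprintf(" | %d/%d genes significant", g$n_significant_genes,
                g$n_genes))
  }
  cat("\n")
  invisible(x)
}

#' @method glance tme_report
#' @export
glance.tme_report <- function(x, ...) {
  pg <- glance(x$populations)
  out <- tibble(n_samples = x$manifest$n_samples,
                n_populations = pg$n_features,
                n_significant_populations = pg$n_significant_omnibus,
                n_hot = glance(x$clustering)$n_hot,
                n_cold = glance(x$clustering)$n_cold,
                cluster_subgroup_p = x$association$subgroup$p_value)
  if (!is.null(x$genes)) {
    gg <- glance(x$genes)
    out$n_genes <- gg$n_features
    out$n_significant_genes <- gg$n_significant_omnibus
  }
  out
}

#' @method tidy tme_report
#' @export
tidy.tme_report <- function(x, ...) tidy(x$populations)
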