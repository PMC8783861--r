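#' Marker-gene immune cell population scores
#'
#' The abundance score of a population in a sample is the arithmetic
#' mean of the log2 expression of that population's marker genes
#' (mean-of-logs, not log-of-mean), reported on log2 scale.  Marker
#' genes absent from the expression matrix are dropped from the mean
#' with a warning; a population left with no present marker is an
#' error.
#'
#' @param expr An `expr_matrix` (or any wide tibble `gene` + log2
#'   sample columns).
#' @param markers Marker map tibble (`population`, `gene`); default
#'   [default_marker_map()].
#' @return A `cell_scores` wide tibble: `population` plus one log2
#'   column per sample.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_design(), io_panel(n_genes = 200), seed = 1)
#' expr <- normalize_counts(sim$counts)
#' scores <- score_populations(expr)
#' scores[, 1:4]
score_populations <- function(expr, markers = default_marker_map()) {
  stopifnot("gene" %in% names(expr))
  samples <- setdiff(names(expr), c("gene", "probe_class"))
  m <- wide_to_matrix(as_tibble(expr)[, c("gene", samples)], "gene")
  pops_all <- unique(markers$population)
  missing <- setdiff(markers$gene, rownames(m))
  if (length(missing)) {
    warn(paste0("marker genes absent from expression matrix (dropped): ",
                paste(missing, collapse = ", ")))
    markers <- markers[!markers$gene %in% missing, ]
  }
  pops <- unique(markers$population)
  orphan <- setdiff(pops_all, pops)
  if (length(orphan)) {
    abort(paste0("population(s) with zero present markers: ",
                 paste(orphan, collapse = ", ")))
  }
  rows <- map(pops, function(p) {
    mk <- markers$gene[markers$population == p]
    colMeans(m[mk, , drop = FALSE])
  })
  out <- bind_cols(tibble(population = pops),
                   as_tibble(do.call(rbind, rows)))
  class(out) <- c("cell_scores", class(out))
  out
}

#' Total tumor-infiltrating lymphocyte score
#'
#' Per sample, the unweighted mean of the configured component
#' population scores; by default all 14 populations contribute.
#'
#' @param scores A `cell_scores` tibble.
#' @param populations Component populations (default: all rows of
#'   `scores`).
#' @return Tibble `sample_id`, `til`.
#' @export
til_score <- function(scores, populations = NULL) {
  populations <- populations %||% scores$population
  if (!length(populations)) abort("empty component population list")
  missing <- setdiff(populations, scores$population)
  if (length(missing)) {
    abort(paste0("unknown populations: ", paste(missing, collapse = ", ")))
  }
  m <- wide_to_matrix(scores, "population")
  tibble(sample_id = colnames(m),
         til = unname(colMeans(m[populations, , drop = FALSE])))
}

#' Immunological distance between tumors
#'
#' The immunological distance between two samples is the Manhattan (L1)
#' distance between their 14-dimensional immune-population score
#' vectors (raw log2 scores, not centered).
#'
#' @param scores A `cell_scores` tibble.
#' @return Symmetric sample-by-sample numeric matrix with zero
#'   diagonal.
#' @export
immune_distance <- function(scores) {
  m <- wide_to_matrix(scores, "population")
  if (any(!is.finite(m))) abort("scores contain missing values")
  as.matrix(dist(t(m), method = "manhattan"))
}

#' Is a query group immunologically closer to one reference group?
#'
#' For every sample of `query_group`, computes its mean immunological
#' distance to all samples of reference group A and to all of reference
#' group B, then compares the paired per-sample means with a two-sided
#' Wilcoxon signed-rank test.  A negative mean difference means the
#' query group sits closer to reference A.
#'
#' @param scores A `cell_scores` tibble.
#' @param metadata Cohort metadata (`sample_id`, `subgroup`,
#'   `icb_response`).
#' @param query_group Subgroup or response label of the query samples.
#' @param ref_a,ref_b Reference labels (defaults `LTR` and `RP`).
#' @return A `closeness_test` list: `samples` tibble (`sample_id`,
#'   `dist_a`, `dist_b`, `diff`), `mean_a`, `mean_b`, `mean_diff`,
#'   `p_value`, and the group labels.
#' @export
closeness_test <- function(scores, metadata, query_group,
                           ref_a = "LTR", ref_b = "RP") {
  d <- immune_distance(scores)
  grp <- group_label(metadata)
  pick <- function(g) metadata$sample_id[!is.na(grp) & grp == g]
  q <- pick(query_group); a <- pick(ref_a); b <- pick(ref_b)
  if (!length(q) || !length(a) || !length(b)) {
    abort("query and both reference groups must be nonempty")
  }
  dist_a <- unname(rowMeans(d[q, a, drop = FALSE]))
  dist_b <- unname(rowMeans(d[q, b, drop = FALSE]))
  diff <- dist_a - dist_b
  p <- if (all(diff == 0)) 1 else
    suppressWarnings(wilcox.test(dist_a, dist_b, paired = TRUE,
                                 exact = FALSE)$p.value)
  structure(
    list(samples = tibble(sample_id = q, dist_a = dist_a,
                          dist_b = dist_b, diff = diff),
         mean_a = mean(dist_a), mean_b = mean(dist_b),
         mean_diff = mean(diff), p_value = p,
         query_group = query_group, ref_a = ref_a, ref_b = ref_b),
    class = "closeness_test")
}

#' @export
print.closeness_test <- function(x, ...) {
  cat(sprintf(
    "<closeness_test> %s: mean distance to %s = %.3f, to %s = %.3f (diff %.3f, p = %.3g)\n",
    x$query_group, x$ref_a, x$mean_a, x$ref_b, x$mean_b, x$mean_diff,
    x$p_value))
  invisible(x)
}

# Combined grouping label: ALK / EGFR for the driver-positive samples,
# the ICB response (LTR/IR/RP) for NEG samples; plus the plain
# subgroups so both vocabularies resolve.
group_label <- function(metadata) {
  ifelse(metadata$subgroup == "NEG", metadata$icb_response,
         metadata$subgroup)
}

#' PD-L1 mRNA readout
#'
#' @param expr An `expr_matrix`.
#' @param gene Gene symbol encoding PD-L1 (default `CD274`).
#' @return Tibble `sample_id`, `pdl1` (log2 expression).
#' @export
pdl1_expression <- function(expr, gene = "CD274") {
  samples <- setdiff(names(expr), c("gene", "probe_class"))
  row <- which(expr$gene == gene)
  if (!length(row)) abort(sprintf("gene '%s' absent from panel", gene))
  tibble(sample_id = samples,
         pdl1 = as.numeric(as_tibble(expr)[row, samples]))
}
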