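#' Cluster tumors into immune-hot and immune-cold groups
#'
#' Samples are clustered on their immune-population score profiles with
#' hierarchical agglomeration: dissimilarity 1 - Pearson correlation
#' between sample profiles, average linkage, tree cut into `k` groups.
#' For `k = 2` the group with the higher mean total-TIL score is
#' labelled `"hot"`, the other `"cold"`.  A constant sample profile has
#' no defined correlation; it is assigned distance 1 to every other
#' sample, with a warning.
#'
#' @param scores A `cell_scores` tibble.
#' @param k Number of groups to cut (default 2).
#' @param center Center each population row before computing sample
#'   correlations (display-style centering; default `FALSE`, i.e. raw
#'   scores).
#' @return An `immune_clustering` list: `tree` (hclust), `labels`
#'   tibble (`sample_id`, `cluster`, `label`), `k`, and the TIL means
#'   per cluster.
#' @export
cluster_samples <- function(scores, k = 2, center = FALSE) {
  m <- wide_to_matrix(scores, "population")
  n <- ncol(m)
  if (k > n) abort("k exceeds the number of samples")
  if (center) m <- m - rowMeans(m)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn("constant sample profile(s); assigned correlation distance 1")
  }
  cc <- suppressWarnings(cor(m))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  d <- as.dist(1 - cc)
  tree <- hclust(d, method = "average")
  cluster <- unname(cutree(tree, k = k))
  til <- til_score(scores)
  til_by_cluster <- map_dbl(seq_len(k), function(i) {
    mean(til$til[cluster == i])
  })
  label <- as.character(cluster)
  if (k == 2) {
    hot <- which.max(til_by_cluster)
    label <- ifelse(cluster == hot, "hot", "cold")
  }
  structure(
    list(tree = tree,
         labels = tibble(sample_id = colnames(m), cluster = cluster,
                         label = label),
         k = k, til_by_cluster = til_by_cluster),
    class = "immune_clustering")
}

#' @export
print.immune_clustering <- function(x, ...) {
  tab <- table(x$labels$label)
  cat("<immune_clustering> ",
      paste(sprintf("%s n = %d", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy immune_clustering
#' @export
tidy.immune_clustering <- function(x, ...) x$labels

#' @method glance immune_clustering
#' @export
glance.immune_clustering <- function(x, ...) {
  tab <- table(x$labels$label)
  tibble(k = x$k, n = nrow(x$labels),
         n_hot = if ("hot" %in% names(tab)) as.integer(tab[["hot"]]) else NA_integer_,
         n_cold = if ("cold" %in% names(tab)) as.integer(tab[["cold"]]) else NA_integer_)
}

#' Cluster the population rows and report their co-expression
#'
#' Applies the same correlation/average-linkage clustering to the
#' population score rows and reports all pairwise Spearman correlations
#' between populations — the readout behind statements like "cytotoxic
#' cells, T cells, CD8+ T cells and exhausted CD8+ T cells cluster
#' tightly (all pairwise Spearman rho above a threshold)".
#'
#' @param scores A `cell_scores` tibble.
#' @param tight_rho Threshold for reporting a tight pair (default 0.77).
#' @return List: `tree` (hclust over populations), `rho` (Spearman
#'   correlation matrix), `tight_pairs` tibble of pairs with
#'   `rho > tight_rho`.
#' @export
cluster_populations <- function(scores, tight_rho = 0.77) {
  m <- wide_to_matrix(scores, "population")
  if (nrow(m) < 2) abort("need at least 2 populations")
  rho <- suppressWarnings(cor(t(m), method = "spearman"))
  cc <- suppressWarnings(cor(t(m)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  tree <- hclust(as.dist(1 - cc), method = "average")
  pairs <- which(upper.tri(rho) & rho > tight_rho, arr.ind = TRUE)
  tight <- tibble(
    population_1 = rownames(rho)[pairs[, 1]],
    population_2 = colnames(rho)[pairs[, 2]],
    rho = rho[pairs]
  )
  list(tree = tree, rho = rho, tight_pairs = arrange(tight, -rho))
}

#' Association between cluster labels and a categorical annotation
#'
#' Fisher's exact test (the Freeman-Halton extension for more than two
#' annotation levels) of the contingency between the hot/cold cluster
#' labels and a categorical sample label such as the genetic subgroup.
#' Annotation levels with zero samples are dropped with a warning.
#'
#' @param labels Tibble with `sample_id` and a cluster `label` column
#'   (e.g. `tidy()` of [cluster_samples()]).
#' @param annotation Tibble `sample_id` plus the annotation column, or
#'   a vector aligned with `labels`.
#' @param variable Name of the annotation column when `annotation` is a
#'   tibble.
#' @return List: `table` (contingency), `p_value` (two-sided),
#'   `variable`.
#' @export
association_test <- function(labels, annotation, variable = NULL) {
  if (is.data.frame(annotation)) {
    stopifnot(!is.null(variable), variable %in% names(annotation))
    idx <- match(labels$sample_id, annotation$sample_id)
    if (any(is.na(idx))) abort("labelings cover different samples")
    ann <- annotation[[variable]][idx]
  } else {
    ann <- annotation
    variable <- variable %||% "annotation"
  }
  keep <- !is.na(ann)
  ann <- factor(ann[keep])
  ann <- droplevels(ann)
  if (nlevels(ann) < 2) abort("annotation needs >= 2 nonempty levels")
  tab <- table(cluster = labels$label[keep], annotation = ann)
  p <- fisher.test(tab)$p.value
  list(table = tab, p_value = p, variable = variable)
}
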