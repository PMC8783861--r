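#' Signed fold change between two groups of log2 values
#'
#' With `d` the difference of group means on log2 scale (A minus B),
#' the signed fold change is `2^d` when `d >= 0` and `-2^(-d)`
#' otherwise, so a value of -2.1 reads "2.1-fold lower in A".  By
#' construction `|FC| >= 1`, `d = 0` maps to 1, and swapping the groups
#' flips the sign while keeping the magnitude.
#'
#' @param a,b Numeric vectors of log2-scale values.
#' @return A single signed fold change.
#' @export
#' @examples
#' signed_fc(c(3, 4), c(2, 3))   #  2
#' signed_fc(c(2, 3), c(3, 4))   # -2
signed_fc <- function(a, b) {
  if (!length(a) || !length(b)) abort("both groups must be nonempty")
  d <- mean(a) - mean(b)
  if (d >= 0) 2^d else -2^(-d)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis rank test with the chi-square
#' approximation on (levels - 1) degrees of freedom.  When all values
#' are identical the statistic is undefined; the test is reported as
#' degenerate with p = 1.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (>= 2 nonempty levels).
#' @return List: `statistic` (H), `p_value`, `df`, `degenerate`.
#' @export
kruskal_omnibus <- function(values, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) {
    abort("need at least 2 nonempty groups")
  }
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, p_value = 1,
                df = nlevels(droplevels(group)) - 1, degenerate = TRUE))
  }
  kt <- kruskal.test(values, group)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have at most 20 observations and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_pair <- function(a, b) {
  if (!length(a) || !length(b)) abort("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 20 && length(b) <= 20 && !ties
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement; order-preserving (q-values are returned in the input
#' order) and always at least the raw p-value.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

# Shared engine: omnibus + BH across features + all pairwise post-hoc
# contrasts, over the rows of a feature x sample matrix.
diff_engine <- function(m, groups, fdr = 0.05) {
  groups <- factor(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warn(paste0("grouping level(s) with < 2 samples excluded: ",
                paste(small, collapse = ", ")))
    keep <- !groups %in% small
    m <- m[, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  lv <- levels(groups)
  if (length(lv) < 2) abort("need at least 2 usable groups")
  omni <- map(seq_len(nrow(m)), function(i) kruskal_omnibus(m[i, ], groups))
  p_omni <- map_dbl(omni, "p_value")
  q_omni <- bh_adjust(p_omni)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    for (pr in pairs) {
      va <- m[i, groups == pr[1]]
      vb <- m[i, groups == pr[2]]
      rows[[length(rows) + 1]] <- tibble(
        feature = rownames(m)[i],
        statistic = omni[[i]]$statistic,
        p_omnibus = p_omni[i], q_omnibus = q_omni[i],
        group_a = pr[1], group_b = pr[2],
        n_a = length(va), n_b = length(vb),
        mean_a = mean(va), mean_b = mean(vb),
        fc = signed_fc(va, vb),
        p_posthoc = wilcoxon_pair(va, vb))
    }
  }
  out <- list_rbind(rows)
  out$significant <- out$q_omnibus < fdr & out$p_posthoc < 0.05
  out <- out[order(out$p_omnibus, out$feature), ]
  class(out) <- c("diff_result", class(out))
  attr(out, "fdr") <- fdr
  out
}

group_vector <- function(metadata, mode) {
  switch(mode,
    subgroup = metadata$subgroup,
    four_group = {
      g <- group_label(metadata)
      g[!g %in% c("ALK", "EGFR", "LTR", "RP")] <- NA  # IR excluded
      g
    },
    abort(sprintf("unknown grouping mode '%s'", mode)))
}

#' Differential analysis of immune cell population scores
#'
#' For every population: Kruskal-Wallis omnibus test across the groups,
#' Benjamini-Hochberg adjustment across the 14 omnibus p-values, then
#' per group pair a two-sided Wilcoxon rank-sum test and a signed fold
#' change.  A contrast is flagged significant when the omnibus q-value
#' is below `fdr` and the (unadjusted) post-hoc p is below 0.05.
#'
#' @param scores A `cell_scores` tibble.
#' @param metadata Cohort metadata.
#' @param mode `"subgroup"` (ALK / EGFR / NEG) or `"four_group"`
#'   (ALK / EGFR / LTR / RP; intermediate responders excluded).
#' @param strata Optional metadata column (e.g. `"smoking"`, `"tp53"`):
#'   the subgroup analysis is repeated within each stratum.
#' @param fdr FDR level for flagging (default 0.05).
#' @return A `diff_result` tibble; with `strata`, an extra `stratum`
#'   column.
#' @export
test_populations <- function(scores, metadata, mode = "subgroup",
                             strata = NULL, fdr = 0.05) {
  m <- wide_to_matrix(scores, "population")
  m <- m[, metadata$sample_id, drop = FALSE]
  if (is.null(strata)) {
    g <- group_vector(metadata, mode)
    keep <- !is.na(g)
    return(diff_engine(m[, keep, drop = FALSE], g[keep], fdr))
  }
  stopifnot(strata %in% names(metadata))
  out <- list()
  for (lev in unique(metadata[[strata]][!is.na(metadata[[strata]])])) {
    sel <- !is.na(metadata[[strata]]) & metadata[[strata]] == lev
    g <- group_vector(metadata[sel, ], mode)
    keep <- !is.na(g)
    res <- diff_engine(m[, metadata$sample_id[sel][keep], drop = FALSE],
                       g[keep], fdr)
    res$stratum <- lev
    out[[lev]] <- res
  }
  res <- list_rbind(out)
  class(res) <- c("diff_result", class(res))
  attr(res, "fdr") <- fdr
  res
}

#' Differential analysis of endogenous gene expression
#'
#' Same machinery as [test_populations()] applied to every endogenous
#' gene, with Benjamini-Hochberg adjustment across all tested genes.
#'
#' @param expr An `expr_matrix`.
#' @inheritParams test_populations
#' @return A `diff_result` tibble (rows sorted by omnibus p, ties by
#'   symbol).
#' @export
test_genes <- function(expr, metadata, mode = "subgroup", fdr = 0.05) {
  em <- endogenous_expression(expr)
  m <- wide_to_matrix(em, "gene")[, metadata$sample_id, drop = FALSE]
  g <- group_vector(metadata, mode)
  keep <- !is.na(g)
  diff_engine(m[, keep, drop = FALSE], g[keep], fdr)
}

#' @method tidy diff_result
#' @export
tidy.diff_result <- function(x, ...) as_tibble(x)

#' @method glance diff_result
#' @export
glance.diff_result <- function(x, ...) {
  omni <- distinct(as_tibble(x)[, c("feature", "q_omnibus")])
  tibble(n_features = nrow(omni),
         n_significant_omnibus = sum(omni$q_omnibus < attr(x, "fdr")),
         fdr = attr(x, "fdr"))
}

#' Differentially expressed features of one contrast
#'
#' @param result A `diff_result`.
#' @param group_a,group_b Contrast to extract.
#' @return Character vector of significant features.
#' @export
de_features <- function(result, group_a, group_b) {
  sel <- (result$group_a == group_a & result$group_b == group_b) |
    (result$group_a == group_b & result$group_b == group_a)
  unique(result$feature[sel & result$significant])
}

#' Decompose two differential gene lists into exclusive and shared sets
#'
#' @param list_a,list_b Character vectors (e.g. the ALK-vs-NEG and
#'   EGFR-vs-NEG differential gene lists).
#' @return List: `exclusive_a`, `exclusive_b`, `shared` (members) and
#'   `counts` (named integer vector).
#' @export
#' @examples
#' set_decomposition(c("g1", "g2", "g3"), c("g3", "g4"))$counts
set_decomposition <- function(list_a, list_b) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  ex_a <- setdiff(list_a, list_b)
  ex_b <- setdiff(list_b, list_a)
  sh <- intersect(list_a, list_b)
  list(exclusive_a = ex_a, exclusive_b = ex_b, shared = sh,
       counts = c(exclusive_a = length(ex_a), exclusive_b = length(ex_b),
                  shared = length(sh)))
}

#' Gene-set view of a differential analysis
#'
#' Restricts a gene-level `diff_result` to a gene set (e.g. the
#' cytokine-cytokine receptor panel genes), counts the set members
#' differentially expressed in each pairwise contrast, and decomposes
#' the two versus-NEG lists into exclusive and shared parts.
#'
#' @param gene_result A `diff_result` from [test_genes()].
#' @param gene_set Character vector of gene symbols.
#' @param ref_group Reference group of the decomposition (default
#'   `"NEG"`).
#' @return List: `set_size` (members tested), `counts` tibble per
#'   contrast, `decomposition` (see [set_decomposition()]).
#' @export
gene_set_summary <- function(gene_result, gene_set, ref_group = "NEG") {
  present <- intersect(gene_set, unique(gene_result$feature))
  if (!length(present)) {
    warn("gene set does not intersect the tested genes")
    return(list(set_size = 0L, counts = tibble(), decomposition = NULL))
  }
  sub <- gene_result[gene_result$feature %in% present, ]
  counts <- sub |>
    group_by(.data$group_a, .data$group_b) |>
    summarise(n_de = sum(.data$significant), .groups = "drop")
  others <- setdiff(unique(c(sub$group_a, sub$group_b)), ref_group)
  dec <- NULL
  if (length(others) >= 2) {
    dec <- set_decomposition(
      de_features(sub, others[1], ref_group),
      de_features(sub, others[2], ref_group))
  }
  list(set_size = length(present), counts = counts, decomposition = dec)
}

#' Spearman correlation of an anchor feature against all others
#'
#' Reports Spearman's rho and its p-value between the anchor row and
#' every other row of a wide feature table, overall and (optionally)
#' within metadata subgroups.  A constant feature has no defined rank
#' correlation and is reported with `rho = NA` and `constant = TRUE`.
#'
#' @param features Wide tibble: first column names the feature, the
#'   remaining columns are samples.  Bind the anchor row yourself if it
#'   lives elsewhere (e.g. PD-L1 expression vs cell scores).
#' @param anchor Feature name to correlate against.
#' @param metadata Optional metadata; adds per-subgroup correlations.
#' @return Tibble: `group`, `feature`, `rho`, `p_value`, `n`,
#'   `constant`.
#' @export
spearman_panel <- function(features, anchor, metadata = NULL) {
  feature_col <- names(features)[1]
  m <- wide_to_matrix(as_tibble(features), feature_col)
  if (!anchor %in% rownames(m)) {
    abort(sprintf("anchor feature '%s' not found", anchor))
  }
  if (ncol(m) < 3) abort("need at least 3 samples")
  run <- function(cols, label) {
    a <- m[anchor, cols]
    rows <- map(setdiff(rownames(m), anchor), function(f) {
      x <- m[f, cols]
      if (sd(x) == 0 || sd(a) == 0) {
        return(tibble(group = label, feature = f, rho = NA_real_,
                      p_value = NA_real_, n = length(cols),
                      constant = TRUE))
      }
      ct <- suppressWarnings(cor.test(a, x, method = "spearman"))
      tibble(group = label, feature = f, rho = unname(ct$estimate),
             p_value = ct$p.value, n = length(cols), constant = FALSE)
    })
    list_rbind(rows)
  }
  out <- run(colnames(m), "all")
  if (!is.null(metadata)) {
    for (g in unique(metadata$subgroup)) {
      cols <- intersect(colnames(m),
                        metadata$sample_id[metadata$subgroup == g])
      if (length(cols) >= 3) out <- bind_rows(out, run(cols, g))
    }
  }
  arrange(out, .data$group, -abs(dplyr::coalesce(.data$rho, 0)))
}
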