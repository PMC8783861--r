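#' Fit lane scale factors and background thresholds from control probes
#'
#' Per lane, positive-control counts are regressed on their nominal
#' concentration through the origin; the lane scale factor is the cohort
#' geometric-mean slope divided by the lane slope, renormalized so
#' factors average 1.  The background threshold is the mean + 2 sd of
#' the lane's (scaled) negative-control counts.  A lane whose fitted
#' slope is not positive fails QC and is flagged.
#'
#' @param counts Count matrix tibble (with `Positive` and `Negative`
#'   probe classes).
#' @return Tibble of class `lane_factors` with one row per sample:
#'   `sample_id`, `slope`, `scale_factor`, `background`, `qc_pass`.
#' @export
fit_control_factors <- function(counts) {
  validate_counts(counts)
  pos <- counts[counts$probe_class == "Positive", ]
  neg <- counts[counts$probe_class == "Negative", ]
  if (nrow(pos) < 2 || length(unique(pos$concentration)) < 2) {
    abort("need at least 2 positive controls with distinct concentrations")
  }
  if (nrow(neg) < 1) abort("need at least 1 negative control")
  samples <- sample_ids(counts)
  conc <- pos$concentration
  slope <- map_dbl(samples, function(s) {
    sum(conc * pos[[s]]) / sum(conc^2)
  })
  qc_pass <- slope > 0
  if (any(!qc_pass)) {
    warn(paste0("lanes failed positive-control QC (non-positive slope): ",
                paste(samples[!qc_pass], collapse = ", ")))
  }
  gm <- exp(mean(log(slope[qc_pass])))
  scale_factor <- ifelse(qc_pass, gm / slope, NA_real_)
  scale_factor <- scale_factor / mean(scale_factor, na.rm = TRUE)
  background <- map_dbl(seq_along(samples), function(i) {
    x <- neg[[samples[i]]] * ifelse(qc_pass[i], scale_factor[i], 1)
    mean(x) + 2 * sd(x)
  })
  structure(
    tibble(sample_id = samples, slope = slope,
           scale_factor = scale_factor, background = background,
           qc_pass = qc_pass),
    class = c("lane_factors", "tbl_df", "tbl", "data.frame"))
}

#' Select housekeeping genes from a reference expression table
#'
#' Implements the data-driven rule: among genes whose reference mean
#' expression (linear scale) is at least `min_expr`, keep the `k` with
#' the lowest coefficient of variation (sd/mean, linear scale).  Ties in
#' CV are broken lexicographically by gene symbol.  With no reference,
#' the packaged 20-gene list is returned.
#'
#' @param reference Wide tibble `gene` + linear-scale sample columns
#'   (>= 2 samples), or `NULL` to fall back to [default_housekeepers()].
#' @param k Number of housekeepers to select (default 20).
#' @param min_expr Minimum reference mean expression (default 100).
#' @return Tibble with columns `gene`, `mean_expr`, `cv`, `rank`,
#'   `selected`; exactly `k` rows have `selected = TRUE`.  In the
#'   fallback case a tibble with `gene` and `selected` only.
#' @export
select_housekeepers <- function(reference = NULL, k = 20,
                                min_expr = 100) {
  if (is.null(reference)) {
    return(tibble(gene = default_housekeepers(), mean_expr = NA_real_,
                  cv = NA_real_, rank = seq_len(20), selected = TRUE))
  }
  stopifnot("gene" %in% names(reference))
  samples <- setdiff(names(reference), "gene")
  if (length(samples) < 2) {
    abort("reference needs >= 2 samples (coefficient of variation undefined)")
  }
  m <- wide_to_matrix(reference, "gene")
  res <- tibble(
    gene = rownames(m),
    mean_expr = rowMeans(m),
    cv = apply(m, 1, sd) / rowMeans(m)
  )
  eligible <- res$mean_expr >= min_expr
  if (sum(eligible) < k) {
    abort(sprintf("only %d genes reach mean expression %g; %d required",
                  sum(eligible), min_expr, k))
  }
  res <- res[order(!eligible, res$cv, res$gene), ]
  res$rank <- seq_len(nrow(res))
  res$selected <- res$rank <= k
  res
}

#' Normalize a count matrix to log2 expression
#'
#' The full normalization chain: calibrate each lane against its
#' positive-control slope (counts per fM, times a fixed reference
#' sensitivity that restores a count-like scale), floor probe values at
#' the lane's negative-control background threshold, divide the profile
#' by the lane's median housekeeper value and multiply by the cohort
#' median of those medians, then log2 after flooring at 1 count.  After
#' this, the per-sample median of the housekeeper rows is constant
#' across samples, and multiplying any lane's raw counts by a positive
#' constant leaves every normalized profile unchanged (the lane's own
#' slope, background and housekeeper median absorb it exactly).
#'
#' @param counts Count matrix tibble.
#' @param factors `lane_factors` from [fit_control_factors()]; computed
#'   from `counts` when `NULL`.
#' @param housekeepers Character vector of housekeeping gene symbols, a
#'   [select_housekeepers()] result, or `NULL` to use the probes of
#'   class `Housekeeping` (falling back to the packaged list).
#' @param drop_failed Drop lanes flagged as failed QC (default TRUE).
#' @param reference_sensitivity Fixed anchor, in counts per fM, mapping
#'   spike-calibrated concentrations back to a count-like scale
#'   (default 30).  It shifts all log2 values by a common constant and
#'   nothing else; every downstream statistic is invariant to it.
#' @return An `expr_matrix` tibble: `gene`, `probe_class`, plus one
#'   log2-scale column per retained sample, with attributes
#'   `housekeepers` and `steps` recording provenance.
#' @export
normalize_counts <- function(counts, factors = NULL,
                             housekeepers = NULL, drop_failed = TRUE,
                             reference_sensitivity = 30) {
  validate_counts(counts)
  if (is.null(factors)) factors <- fit_control_factors(counts)
  if (is.null(housekeepers)) {
    housekeepers <- counts$gene[counts$probe_class == "Housekeeping"]
    if (!length(housekeepers)) housekeepers <- default_housekeepers()
  }
  if (is.data.frame(housekeepers)) {
    housekeepers <- housekeepers$gene[housekeepers$selected]
  }
  missing <- setdiff(housekeepers, counts$gene)
  if (length(missing)) {
    abort(paste0("housekeepers absent from count matrix: ",
                 paste(missing, collapse = ", ")))
  }
  samples <- sample_ids(counts)
  stopifnot(identical(samples, factors$sample_id))
  keep <- factors$qc_pass
  if (any(!keep) && !drop_failed) {
    abort("failed-QC lanes present; set drop_failed = TRUE or fix input")
  }
  samples <- samples[keep]
  # absolute per-lane calibration: counts -> reference count scale
  cal <- reference_sensitivity / factors$slope[keep]
  neg <- counts[counts$probe_class == "Negative", samples, drop = FALSE]
  bg <- vapply(seq_along(samples), function(i) {
    x <- neg[[i]] * cal[i]
    mean(x) + 2 * sd(x)
  }, 0)
  feature <- counts$probe_class %in% c("Endogenous", "Housekeeping")
  m <- wide_to_matrix(counts[feature, ], "gene")[, samples, drop = FALSE]
  m <- sweep(m, 2, cal, `*`)
  m <- pmax(m, rep(bg, each = nrow(m)))
  hk_median <- apply(m[housekeepers, , drop = FALSE], 2, median)
  if (any(hk_median <= 0)) {
    bad <- samples[hk_median <= 0]
    abort(paste0("zero housekeeper median in lane(s): ",
                 paste(bad, collapse = ", ")))
  }
  target <- median(hk_median)
  m <- sweep(m, 2, target / hk_median, `*`)
  m <- log2(pmax(m, 1))
  out <- bind_cols(
    counts[feature, c("gene", "probe_class")],
    as_tibble(m))
  attr(out, "housekeepers") <- housekeepers
  attr(out, "steps") <- c("positive_control_scaling", "background_floor",
                          "housekeeper_median_scaling", "log2_floor1")
  class(out) <- c("expr_matrix", class(out))
  out
}

#' Endogenous-gene expression submatrix
#'
#' @param expr An `expr_matrix`.
#' @return The rows of class `Endogenous`, as a plain wide tibble.
#' @export
endogenous_expression <- function(expr) {
  out <- expr[expr$probe_class == "Endogenous",
              setdiff(names(expr), "probe_class")]
  as_tibble(out)
}
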