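#' Packaged housekeeping gene list
#'
#' The 20 panel genes used for housekeeping normalization when no
#' reference expression table is supplied to [select_housekeepers()].
#' They were chosen, in a large lung adenocarcinoma reference cohort, as
#' the panel genes with the lowest coefficient of variation among those
#' with mean expression of at least 100.
#'
#' @return Character vector of 20 gene symbols.
#' @export
#' @examples
#' default_housekeepers()
default_housekeepers <- function() {
  readLines(system.file("extdata", "housekeepers.txt",
                        package = "immunoscape"))
}

#' Default immune cell marker map
#'
#' Marker gene sets for 14 immune cell populations, following the
#' Danaher et al. (2017) nCounter cell-score gene signatures.  The
#' packaged file `extdata/marker_map.tsv` is an editable resource,
#' externally sourced from that publication; edit or replace it to use
#' different signatures.
#'
#' @return A tibble with columns `population` and `gene`, one row per
#'   marker gene assignment.  A gene may serve several populations.
#' @export
#' @examples
#' dplyr::count(default_marker_map(), population)
default_marker_map <- function() {
  read_marker_map(system.file("extdata", "marker_map.tsv",
                              package = "immunoscape"))
}

#' Packaged synthetic cytokine-cytokine receptor gene set
#'
#' A 121-gene stand-in for the panel genes annotated to the KEGG
#' cytokine-cytokine receptor interaction pathway.  The true pathway
#' membership is not redistributable here, so the packaged set mixes
#' real cytokine/receptor symbols that are on the simulated panel with
#' synthetic filler symbols (`CYTSIM...`); it has the right size and
#' panel coverage for exercising gene-set analyses, but is labelled
#' synthetic and should be replaced with a curated list for real data.
#'
#' @return Character vector of 121 gene symbols.
#' @export
default_cytokine_set <- function() {
  read_gene_set(system.file("extdata", "cytokine_set_synthetic.tsv",
                            package = "immunoscape"))
}

# Named genes that every simulated panel carries: immune markers,
# checkpoint / driver genes highlighted in downstream analyses, and the
# cytokine set members.
panel_core_genes <- function() {
  unique(c(
    default_marker_map()$gene,
    "CD274", "PDCD1", "VHL", "EGFR", "BAD", "VEGFB",
    default_cytokine_set()
  ))
}

#' Standard positive-control titration ladder
#'
#' Six synthetic positive-control probes spiked at a geometric ladder of
#' nominal concentrations (fM), as on nCounter CodeSets.
#'
#' @return Tibble with columns `probe` and `concentration` (fM),
#'   strictly decreasing.
#' @export
positive_control_ladder <- function() {
  tibble(
    probe = paste0("POS_", LETTERS[1:6]),
    concentration = c(128, 32, 8, 2, 0.5, 0.125)
  )
}

#' Build an IO-panel specification
#'
#' Constructs the probe-level description of a simulated
#' immuno-oncology expression panel: endogenous genes (all marker,
#' checkpoint and cytokine genes plus anonymous filler genes up to
#' `n_genes`), a separate housekeeping probe class, six positive-control
#' probes on a geometric concentration ladder, and eight
#' negative-control probes.
#'
#' @param n_genes Number of endogenous genes (default 770).
#' @param seed Integer seed; controls the (otherwise irrelevant) order
#'   of filler genes so that panels are reproducible.
#' @param marker_map Marker assignment tibble (`population`, `gene`);
#'   defaults to [default_marker_map()].
#' @param housekeepers Character vector of housekeeping gene symbols;
#'   defaults to [default_housekeepers()].
#' @return An object of class `panel_spec`: a list with elements
#'   `endogenous` (character), `housekeeping` (character), `positives`
#'   (tibble `probe`, `concentration`), `negatives` (character), and
#'   `marker_map` (tibble).
#' @export
#' @examples
#' p <- io_panel()
#' length(p$endogenous)
io_panel <- function(n_genes = 770, seed = 1L,
                     marker_map = default_marker_map(),
                     housekeepers = default_housekeepers()) {
  core <- unique(c(marker_map$gene, panel_core_genes()))
  core <- setdiff(core, housekeepers)
  if (n_genes < length(core)) {
    abort(sprintf(
      "n_genes = %d is too small: the panel needs at least %d endogenous genes (%d missing)",
      n_genes, length(core), length(core) - n_genes))
  }
  n_fill <- n_genes - length(core)
  fillers <- sprintf("SIMG%04d", seq_len(n_fill))
  if (n_fill > 0) {
    set.seed(seed)
    fillers <- sample(fillers)
  }
  structure(
    list(
      endogenous = c(core, fillers),
      housekeeping = housekeepers,
      positives = positive_control_ladder(),
      negatives = paste0("NEG_", LETTERS[1:8]),
      marker_map = marker_map
    ),
    class = "panel_spec"
  )
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf(
    "<panel_spec> %d endogenous genes, %d housekeepers, %d positive / %d negative controls, %d populations\n",
    length(x$endogenous), length(x$housekeeping), nrow(x$positives),
    length(x$negatives), length(unique(x$marker_map$population))))
  invisible(x)
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_spec"))
  classes <- list(panel$endogenous, panel$housekeeping,
                  panel$positives$probe, panel$negatives)
  all_probes <- unlist(classes)
  if (anyDuplicated(all_probes)) {
    abort("panel probe classes overlap or contain duplicate symbols")
  }
  missing <- setdiff(panel$marker_map$gene, panel$endogenous)
  if (length(missing)) {
    abort(paste0("marker genes absent from endogenous panel: ",
                 paste(missing, collapse = ", ")))
  }
  conc <- panel$positives$concentration
  if (any(conc <= 0) || any(diff(conc) >= 0)) {
    abort("positive-control concentrations must be positive and strictly decreasing")
  }
  invisible(panel)
}
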