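#' Read a single RCC lane file
#'
#' Parses one nCounter "Reporter Code Count" lane file.  The dialect is
#' the vendor's sectioned CSV: `<Header>`, `<Sample_Attributes>`,
#' `<Lane_Attributes>` and `<Code_Summary>` blocks delimited by
#' `<Section>` / `</Section>` lines, with `CodeClass,Name,Accession,Count`
#' rows in the code summary.  Windows line endings are tolerated.
#' Positive-control nominal concentrations are recovered from the
#' conventional `POS_A(128)` name suffix.
#'
#' @param path Path to an RCC file.
#' @return A list of class `rcc_lane` with elements `sample_id`,
#'   `lane_id`, and `probes` — a tibble with columns `gene`,
#'   `probe_class` (`Endogenous`, `Housekeeping`, `Positive`,
#'   `Negative`), `concentration` (fM, `NA` except for positives) and
#'   `count` (integer).
#' @export
read_rcc <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  sections <- c("Header", "Sample_Attributes", "Lane_Attributes",
                "Code_Summary")
  blocks <- list()
  for (sec in sections) {
    open <- which(lines == paste0("<", sec, ">"))
    close <- which(lines == paste0("</", sec, ">"))
    if (length(open) != 1 || length(close) != 1 || close <= open) {
      abort(sprintf("RCC file %s: missing or malformed section <%s>",
                    path, sec))
    }
    blocks[[sec]] <- lines[(open + 1):(close - 1)]
  }
  attrs <- function(block) {
    kv <- strsplit(block, ",", fixed = TRUE)
    setNames(vapply(kv, function(x) paste(x[-1], collapse = ","), ""),
             vapply(kv, `[`, "", 1))
  }
  sample_attrs <- attrs(blocks$Sample_Attributes)
  lane_attrs <- attrs(blocks$Lane_Attributes)

  body <- blocks$Code_Summary
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% header)) {
    abort(sprintf("RCC file %s: Code_Summary header lacks %s", path,
                  paste(setdiff(need, header), collapse = ", ")))
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  get <- function(row, col) row[match(col, header)]
  name_raw <- vapply(rows, get, "", "Name")
  count_raw <- vapply(rows, get, "", "Count")
  bad <- which(!grepl("^[0-9]+$", count_raw))
  if (length(bad)) {
    abort(sprintf("RCC file %s: non-integer count '%s' at Code_Summary line %d",
                  path, count_raw[bad[1]], bad[1] + 1))
  }
  gene <- sub("\\(.*\\)$", "", name_raw)
  conc <- suppressWarnings(as.numeric(
    sub("^.*\\(([^)]*)\\)$", "\\1", name_raw)))
  conc[!grepl("\\(", name_raw)] <- NA_real_
  if (anyDuplicated(gene)) {
    dup <- gene[duplicated(gene)][1]
    abort(sprintf("RCC file %s: duplicate probe name '%s'", path, dup))
  }
  probes <- tibble(
    gene = gene,
    probe_class = vapply(rows, get, "", "CodeClass"),
    concentration = conc,
    count = as.integer(count_raw)
  )
  structure(
    list(sample_id = unname(sample_attrs[["ID"]] %||% basename(path)),
         lane_id = unname(lane_attrs[["ID"]] %||% NA_character_),
         probes = probes),
    class = "rcc_lane")
}

#' Write a single RCC lane file
#'
#' Inverse of [read_rcc()]; one lane (one sample column of a count
#' matrix) per file.
#'
#' @param counts Count matrix tibble (see [read_count_matrix()]).
#' @param sample Sample column to write.
#' @param path Output path.
#' @param lane_id Lane identifier recorded in `Lane_Attributes`.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(counts, sample, path, lane_id = 1L) {
  validate_counts(counts)
  if (!sample %in% sample_ids(counts)) {
    abort(sprintf("sample '%s' not found in count matrix", sample))
  }
  name <- ifelse(counts$probe_class == "Positive",
                 sprintf("%s(%g)", counts$gene, counts$concentration),
                 counts$gene)
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,immunoscape",
    "</Header>", "",
    "<Sample_Attributes>", paste0("ID,", sample), "Owner,", "Comments,",
    "</Sample_Attributes>", "",
    "<Lane_Attributes>", paste0("ID,", lane_id), "FovCount,280",
    "</Lane_Attributes>", "",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,NA,%d", counts$probe_class, name,
            as.integer(counts[[sample]])),
    "</Code_Summary>")
  writeLines(lines, path)
  invisible(path)
}

#' Assemble lane records into a count matrix
#'
#' @param lanes List of `rcc_lane` records (from [read_rcc()]).
#' @return Count matrix tibble with columns `gene`, `probe_class`,
#'   `concentration` and one integer column per lane, in input order.
#' @export
assemble_count_matrix <- function(lanes) {
  stopifnot(length(lanes) >= 1)
  ref <- lanes[[1]]$probes$gene
  for (ln in lanes[-1]) {
    if (!identical(sort(ln$probes$gene), sort(ref))) {
      d <- c(setdiff(ref, ln$probes$gene), setdiff(ln$probes$gene, ref))
      abort(paste0("lanes disagree on probe set; differing probes: ",
                   paste(d, collapse = ", ")))
    }
  }
  out <- lanes[[1]]$probes[, c("gene", "probe_class", "concentration")]
  for (ln in lanes) {
    counts <- ln$probes$count[match(out$gene, ln$probes$gene)]
    out[[ln$sample_id]] <- counts
  }
  validate_counts(out)
  out
}

#' Read / write a gene-by-sample count matrix
#'
#' The on-disk layout is a delimited table whose first columns are
#' `gene`, `probe_class` and `concentration` followed by one integer
#' column per sample.  Gene and sample order are preserved exactly.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return A validated count matrix tibble.
#' @export
read_count_matrix <- function(path, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  validate_counts(x)
  x
}

#' @rdname read_count_matrix
#' @param counts Count matrix tibble.
#' @export
write_count_matrix <- function(counts, path, delim = "\t") {
  validate_counts(counts)
  readr::write_delim(counts, path, delim = delim)
  invisible(path)
}

validate_counts <- function(x) {
  need <- c("gene", "probe_class")
  if (!all(need %in% names(x))) {
    abort("count matrix needs 'gene' and 'probe_class' columns")
  }
  if (!"concentration" %in% names(x)) x$concentration <- NA_real_
  if (anyDuplicated(x$gene)) {
    abort(sprintf("duplicate gene symbol: %s",
                  x$gene[duplicated(x$gene)][1]))
  }
  samples <- sample_ids(x)
  if (anyDuplicated(samples)) abort("duplicate sample identifiers")
  cm <- as.matrix(x[, samples, drop = FALSE])
  if (length(samples) && (any(!is.finite(cm)) || any(cm < 0))) {
    abort("counts must be finite and nonnegative")
  }
  pos <- x$probe_class == "Positive"
  if (any(pos) && any(!is.finite(x$concentration[pos]))) {
    abort("every Positive probe needs a nominal concentration")
  }
  invisible(x)
}

#' Read / write cohort metadata
#'
#' Per-sample annotations: `sample_id`, `subgroup` (one of `ALK`,
#' `EGFR`, `NEG`), `icb_response` (`LTR`, `IR`, `RP`, or `NA`; non-`NA`
#' only for `NEG` samples, which are the only ones treated with immune
#' checkpoint blockade in this design), and optional `smoking`, `tp53`
#' and `variant` columns.
#'
#' @param path File path (CSV).
#' @param counts Optional count matrix; if given, metadata rows whose
#'   sample is absent from the counts raise an error.
#' @return Metadata tibble.
#' @export
read_metadata <- function(path, counts = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(x, counts)
  x
}

#' @rdname read_metadata
#' @param metadata Metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_csv(metadata, path)
  invisible(path)
}

validate_metadata <- function(x, counts = NULL) {
  need <- c("sample_id", "subgroup", "icb_response")
  if (!all(need %in% names(x))) {
    abort(paste0("metadata needs columns: ", paste(need, collapse = ", ")))
  }
  if (!all(x$subgroup %in% c("ALK", "EGFR", "NEG"))) {
    abort("subgroup must be one of ALK, EGFR, NEG")
  }
  bad <- !is.na(x$icb_response) & x$subgroup != "NEG"
  if (any(bad)) {
    abort(sprintf(
      "icb_response is defined only for NEG samples (offender: %s)",
      x$sample_id[bad][1]))
  }
  if (!all(x$icb_response %in% c("LTR", "IR", "RP", NA))) {
    abort("icb_response must be LTR, IR, RP or NA")
  }
  if (!is.null(counts)) {
    missing <- setdiff(x$sample_id, sample_ids(counts))
    if (length(missing)) {
      abort(paste0("metadata samples absent from counts: ",
                   paste(missing, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Read a marker map file
#'
#' @param path TSV with columns `population` and `gene`.
#' @param panel Optional `panel_spec`; marker genes not on the panel are
#'   reported with a warning but retained.
#' @return Tibble (`population`, `gene`).
#' @export
read_marker_map <- function(path, panel = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("population", "gene") %in% names(x))) {
    abort("marker map needs 'population' and 'gene' columns")
  }
  x <- x[, c("population", "gene")]
  empty <- is.na(x$gene) | x$gene == ""
  if (any(empty)) {
    abort(sprintf("population '%s' has an empty marker entry",
                  x$population[empty][1]))
  }
  if (!is.null(panel)) {
    unknown <- setdiff(x$gene, panel$endogenous)
    if (length(unknown)) {
      warn(paste0("marker genes not on panel (retained): ",
                  paste(unknown, collapse = ", ")))
    }
  }
  x
}

#' Read a gene-set file
#'
#' @param path TSV/plain-text file with a `gene` column (or one symbol
#'   per line).
#' @return Character vector of unique gene symbols, order preserved.
#' @export
read_gene_set <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  if (length(lines) && lines[1] == "gene") lines <- lines[-1]
  unique(lines)
}
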