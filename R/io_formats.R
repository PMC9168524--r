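## Readers/writers for the tabular and gene-set formats the screen
## touches: gene-by-sample expression TSV, per-sample clinical TSV, and
## GMT marker panels. Validation is strict: the screen assumes unique
## uppercased gene symbols, finite log2-scale values and closed
## categorical vocabularies, and any violation is an error at parse
## time, not a silent fix downstream.

#' Construct a validated expression matrix
#'
#' Wraps a numeric gene-by-sample matrix of log2-scale expression values
#' together with a cohort label. Gene symbols are uppercased; duplicate
#' symbols (after uppercasing), duplicate sample ids, or non-finite
#' values are errors. The pipeline performs no normalisation: values are
#' assumed already normalised and on log2 scale.
#'
#' @param values Numeric matrix, rows = genes (rownames = symbols),
#'   columns = samples (colnames = sample ids).
#' @param cohort_id Short cohort label.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `cohort_id`, `gene_ids`, `sample_ids` and the numeric `values`
#'   matrix.
#' @export
expression_matrix <- function(values, cohort_id) {
  .assert(is.matrix(values) && is.numeric(values),
          "'values' must be a numeric matrix")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)),
          "expression matrix needs gene rownames and sample colnames")
  .assert(nrow(values) >= 1L, "expression matrix needs at least 1 gene")
  .assert(ncol(values) >= 2L, "expression matrix needs at least 2 samples")
  .assert(all(is.finite(values)),
          "expression matrix contains non-finite or missing values")
  .assert(is.character(cohort_id) && length(cohort_id) == 1L &&
            nzchar(cohort_id), "'cohort_id' must be a non-empty string")
  rownames(values) <- toupper(trimws(rownames(values)))
  dup_g <- duplicated(rownames(values))
  if (any(dup_g))
    stop("duplicate gene symbols after uppercasing: ",
         paste(unique(rownames(values)[dup_g]), collapse = ", "),
         call. = FALSE)
  dup_s <- duplicated(colnames(values))
  if (any(dup_s))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[dup_s]), collapse = ", "),
         call. = FALSE)
  structure(
    list(cohort_id = cohort_id,
         gene_ids = rownames(values),
         sample_ids = colnames(values),
         values = values),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d genes x %d samples\n",
              x$cohort_id, length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
genes <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$gene_ids
}

#' @rdname expression_matrix
#' @export
samples <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$sample_ids
}

#' Read / write an expression matrix as TSV
#'
#' The on-disk format is tab-separated with a header row of sample ids;
#' the first column holds gene symbols, remaining cells are log2
#' expression values. Non-numeric cells, duplicate symbols (case
#' insensitive) and duplicate sample ids are errors.
#'
#' @param path File path.
#' @param cohort_id Cohort label attached to the returned matrix.
#' @return `read_expression` returns an [expression_matrix()];
#'   `write_expression` invisibly returns `path`.
#' @export
read_expression <- function(path, cohort_id) {
  .assert(file.exists(path), paste0("file not found: ", path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  .assert(ncol(df) >= 3L, "expression TSV needs a gene column and >= 2 samples")
  gene_col <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric expression cells in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- as.character(gene_col)
  expression_matrix(m, cohort_id = cohort_id)
}

#' @rdname read_expression
#' @param x An `ExpressionMatrix`.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = x$gene_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_clinical <- function(df, kind) {
  .assert("sample_id" %in% names(df), "clinical table lacks 'sample_id'")
  df$sample_id <- as.character(df$sample_id)
  .assert(!anyDuplicated(df$sample_id), "duplicate sample_id in clinical table")
  if (kind == "predisposition") {
    need <- c("met_status", "bmfs_time", "bmfs_event")
    miss <- setdiff(need, names(df))
    .assert(length(miss) == 0L,
            paste0("clinical table lacks column(s): ",
                   paste(miss, collapse = ", ")))
    bad <- setdiff(unique(as.character(df$met_status)), .MET_STATUS)
    if (length(bad))
      stop("invalid met_status value(s): ", paste(bad, collapse = ", "),
           " (expected NONE/OTHER/BONE)", call. = FALSE)
    df$met_status <- as.character(df$met_status)
  } else {
    .assert("lesion_site" %in% names(df),
            "adaptive clinical table lacks 'lesion_site'")
  }
  if ("lesion_site" %in% names(df)) {
    ls <- as.character(df$lesion_site)
    bad <- setdiff(unique(ls[!is.na(ls)]), .LESION_SITES)
    if (length(bad))
      stop("invalid lesion_site value(s): ", paste(bad, collapse = ", "),
           " (expected PRIMARY/BONE_MET/OTHER_MET)", call. = FALSE)
    df$lesion_site <- ls
  }
  if ("bmfs_time" %in% names(df)) {
    .assert(is.numeric(df$bmfs_time), "'bmfs_time' must be numeric")
    present <- !is.na(df$bmfs_time)
    .assert(all(df$bmfs_time[present] > 0),
            "'bmfs_time' must be > 0 where present")
  }
  if ("bmfs_event" %in% names(df)) {
    ev <- df$bmfs_event[!is.na(df$bmfs_event)]
    .assert(all(ev %in% c(0, 1)), "'bmfs_event' must be 0/1")
    df$bmfs_event <- as.integer(df$bmfs_event)
  }
  class(df) <- c("ClinicalTable", "data.frame")
  attr(df, "kind") <- kind
  df
}

#' Read / write a per-sample clinical table
#'
#' Predisposition cohorts require columns `sample_id`, `met_status`
#' (NONE/OTHER/BONE), `bmfs_time` (months, > 0) and `bmfs_event` (0/1);
#' adaptive cohorts require `sample_id` and `lesion_site`
#' (PRIMARY/BONE_MET/OTHER_MET). Unknown categories, non-positive times
#' and duplicate sample ids are rejected.
#'
#' @param path File path of a TSV with a header row.
#' @param kind `"predisposition"` (default) or `"adaptive"` — selects
#'   which columns are mandatory.
#' @return A `ClinicalTable` (validated data frame).
#' @export
read_clinical <- function(path, kind = c("predisposition", "adaptive")) {
  kind <- match.arg(kind)
  .assert(file.exists(path), paste0("file not found: ", path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  .validate_clinical(df, kind)
}

#' @rdname read_clinical
#' @param clinical A `ClinicalTable` or plain data frame with the
#'   required columns.
#' @export
write_clinical <- function(clinical, path) {
  write.table(as.data.frame(clinical), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname read_clinical
#' @param df Data frame to validate in place.
#' @export
clinical_table <- function(df, kind = c("predisposition", "adaptive")) {
  .validate_clinical(as.data.frame(df, stringsAsFactors = FALSE),
                     match.arg(kind))
}

#' Construct a marker panel
#'
#' A panel is one biological axis of bone colonisation plus its curated
#' marker gene symbols. Symbols are uppercased and de-duplicated
#' preserving order.
#'
#' @param axis Axis label; with `strict = TRUE` it must be one of
#'   [axis_labels()].
#' @param description Free-text description.
#' @param genes Character vector of marker symbols (non-empty).
#' @param strict Enforce the closed axis vocabulary (default `TRUE`).
#' @return An object of class `MarkerPanel`.
#' @export
marker_panel <- function(axis, description = "", genes, strict = TRUE) {
  axis <- toupper(trimws(axis))
  if (strict && !axis %in% .AXES)
    stop("unknown axis '", axis, "'; expected one of: ",
         paste(.AXES, collapse = ", "), call. = FALSE)
  genes <- toupper(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  .assert(length(genes) >= 1L, "marker panel needs at least one gene")
  genes <- genes[!duplicated(genes)]
  structure(list(axis = axis, description = description, genes = genes),
            class = "MarkerPanel")
}

#' @export
print.MarkerPanel <- function(x, ...) {
  cat(sprintf("MarkerPanel %s (%d genes): %s\n", x$axis, length(x$genes),
              paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Read / write marker panels in GMT format
#'
#' GMT is the standard tab-separated gene-set exchange format: each line
#' carries a set name, a description, then one or more gene symbols.
#' Symbols are uppercased and de-duplicated preserving order.
#'
#' @param path File path.
#' @param strict Reject set names outside the five-axis vocabulary
#'   (default `FALSE` on read so arbitrary gene sets can be loaded).
#' @return `read_gmt` returns a list of [marker_panel()] objects.
#' @export
read_gmt <- function(path, strict = FALSE) {
  .assert(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) >= 1L, "empty GMT file")
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line with fewer than 3 fields: ", ln, call. = FALSE)
    marker_panel(parts[1L], parts[2L], parts[-(1:2)], strict = strict)
  })
}

#' @rdname read_gmt
#' @param panels List of `MarkerPanel` objects.
#' @export
write_gmt <- function(panels, path) {
  .assert(is.list(panels) && length(panels) >= 1L,
          "'panels' must be a non-empty list of MarkerPanel objects")
  lines <- vapply(panels, function(p) {
    stopifnot(inherits(p, "MarkerPanel"))
    paste(c(p$axis, p$description, p$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Built-in marker panels for the five bone-colonisation axes
#'
#' The curated marker sets used to score candidate genes: homing
#' (adhesion/chemotaxis lodging of circulating tumour cells in bone
#' marrow), immune escape (evasion of NK/T-cell surveillance),
#' neo-angiogenesis, osteoclastogenesis (osteolytic lesions) and
#' osteoblastogenesis (bone-forming lesions). CXCR7, TNFSF11 (RANKL) and
#' TNFRSF11B (OPG) are stored under their common symbols; marker
#' matching additionally tries the HGNC/common alias of each
#' (ACKR3/RANKL/OPG).
#'
#' @return Named list of five [marker_panel()] objects, one per axis in
#'   the order of [axis_labels()].
#' @export
default_panels <- function() {
  p <- list(
    marker_panel("HOMING",
                 "bone-marrow homing and adhesion markers",
                 c("CXCR4", "CXCR7", "CDH2", "ITGB3", "ANXA2", "CD44",
                   "CTGF", "ITGA2")),
    marker_panel("IMMUNE_ESCAPE",
                 "immune-surveillance escape markers",
                 c("ITGB2", "IRF7", "CD47", "CD274", "HSPA5", "KRT19",
                   "ADAM10")),
    marker_panel("ANGIOGENESIS",
                 "tumour neo-angiogenesis markers",
                 c("VEGFB", "VEGFC", "PECAM1", "CD34", "SPHK1", "HIF1A",
                   "S1PR1", "FGF2")),
    marker_panel("OSTEOCLASTIC",
                 "osteoclastogenesis regulators (osteolytic signature)",
                 c("TNFSF11", "TNFRSF11B", "CTSK", "SRC", "IL6", "NFATC4",
                   "FOS", "DKK1", "SOST", "IL1B")),
    marker_panel("OSTEOBLASTIC",
                 "osteoblastogenesis regulators",
                 c("BMP4", "BMP7", "EDN1", "PDGFA", "PDGFB", "WNT10B",
                   "PLAU", "CDH11", "RUNX2")))
  names(p) <- vapply(p, `[[`, character(1), "axis")
  p[.AXES]
}
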