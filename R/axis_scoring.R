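## Marker-panel scoring: per-gene Spearman correlations against each
## axis panel, summed coefficients, direction-aware ranking, dominant
## axis classification, and long-format export for heatmaps and bubble
## plots.

#' Score one gene against one marker panel
#'
#' Computes the Spearman correlation (rho, p) between the gene and each
#' panel marker available in the matrix, over all samples. The axis
#' score is the plain sum of all available marker rhos (no significance
#' filter by default: the screen sums every coefficient). Markers absent
#' from the matrix — after trying common/HGNC aliases — or with
#' undefined correlation (constant expression) are recorded as missing,
#' never imputed; the gene is excluded from its own marker list when it
#' overlaps the panel.
#'
#' @param gene Gene symbol (must be present in the matrix).
#' @param matrix An [expression_matrix()].
#' @param panel A [marker_panel()].
#' @param significant_only Sum only markers with p < 0.05 (default
#'   `FALSE`).
#' @return Object of class `AxisScoreRecord`: list with `gene`, `axis`,
#'   `marker_rhos` (data frame `marker`, `matched`, `rho`, `p_value`),
#'   `summed_score`, `n_markers_used`, `missing_markers`.
#' @export
axis_score <- function(gene, matrix, panel, significant_only = FALSE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(panel, "MarkerPanel"))
  gene <- toupper(gene)
  .assert(gene %in% matrix$gene_ids,
          paste0("gene not in matrix: ", gene))
  markers <- setdiff(panel$genes,
                     c(gene, unname(.SYMBOL_ALIASES[gene])))
  x <- matrix$values[gene, ]
  rows <- vector("list", length(markers))
  missing <- character(0)
  for (k in seq_along(markers)) {
    m <- markers[k]
    hit <- .resolve_symbol(m, matrix$gene_ids)
    if (is.na(hit)) {
      missing <- c(missing, m)
      next
    }
    res <- tryCatch(spearman(x, matrix$values[hit, ]),
                    error = function(e) NULL)
    if (is.null(res)) {
      missing <- c(missing, m)
      next
    }
    rows[[k]] <- data.frame(marker = m, matched = hit, rho = res$rho,
                            p_value = res$p_value,
                            stringsAsFactors = FALSE)
  }
  marker_rhos <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(marker_rhos))
    stop("no panel marker of axis ", panel$axis,
         " available in the matrix for gene ", gene, call. = FALSE)
  rownames(marker_rhos) <- NULL
  use <- if (significant_only) marker_rhos$p_value < 0.05 else
    rep(TRUE, nrow(marker_rhos))
  structure(
    list(gene = gene, axis = panel$axis, marker_rhos = marker_rhos,
         summed_score = sum(marker_rhos$rho[use]),
         n_markers_used = nrow(marker_rhos),
         missing_markers = missing),
    class = "AxisScoreRecord")
}

#' @export
print.AxisScoreRecord <- function(x, ...) {
  cat(sprintf("AxisScoreRecord %s / %s: summed rho = %.4f over %d markers%s\n",
              x$gene, x$axis, x$summed_score, x$n_markers_used,
              if (length(x$missing_markers))
                paste0(" (missing: ",
                       paste(x$missing_markers, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Score a gene list against all panels
#'
#' One [axis_score()] record per (gene, axis) pair, ordered by gene and
#' then by panel order. A pair that cannot be scored (gene absent, no
#' available markers) is omitted and recorded in the `"failed"`
#' attribute rather than aborting the run.
#'
#' @param genes Character vector of gene symbols.
#' @param matrix An [expression_matrix()].
#' @param panels List of [marker_panel()] objects (default
#'   [default_panels()]).
#' @param significant_only Passed to [axis_score()].
#' @return List of `AxisScoreRecord` objects with attribute `"failed"`
#'   (data frame `gene`, `axis`, `reason`).
#' @export
score_all <- function(genes, matrix, panels = default_panels(),
                      significant_only = FALSE) {
  genes <- toupper(genes)
  records <- list()
  failed <- list()
  for (g in genes) {
    for (p in panels) {
      rec <- tryCatch(axis_score(g, matrix, p,
                                 significant_only = significant_only),
                      error = function(e) conditionMessage(e))
      if (is.character(rec)) {
        failed[[length(failed) + 1L]] <-
          data.frame(gene = g, axis = p$axis, reason = rec,
                     stringsAsFactors = FALSE)
      } else {
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  attr(records, "failed") <- if (length(failed)) do.call(rbind, failed) else
    data.frame(gene = character(0), axis = character(0),
               reason = character(0))
  records
}

#' Summarise axis-score records as a data frame
#'
#' @param records List of `AxisScoreRecord` objects.
#' @return Data frame with one row per record: `gene`, `axis`,
#'   `summed_score`, `n_markers_used`, `n_significant` (markers with
#'   p < 0.05).
#' @export
score_summary <- function(records) {
  out <- do.call(rbind, lapply(records, function(r) {
    data.frame(gene = r$gene, axis = r$axis,
               summed_score = r$summed_score,
               n_markers_used = r$n_markers_used,
               n_significant = sum(r$marker_rhos$p_value < 0.05),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rank genes of one direction stratum by axis score
#'
#' Genes upregulated in the bone lesion are expected to correlate
#' positively with the axis markers and are ranked by descending summed
#' score; downregulated genes are expected to correlate inversely and
#' are ranked by ascending (most negative first) summed score.
#'
#' @param records List of `AxisScoreRecord` objects.
#' @param directions Named character vector or list mapping gene to
#'   `"UP"`/`"DOWN"`; every scored gene must be present.
#' @param axis Axis label to rank within.
#' @param direction Which stratum to return (`"UP"` or `"DOWN"`).
#' @param k Number of top genes (defaults to the full stratum; no
#'   padding when k exceeds the stratum size).
#' @return Character vector of gene symbols, best first.
#' @export
rank_by_axis <- function(records, directions, axis,
                         direction = c("UP", "DOWN"), k = Inf) {
  direction <- match.arg(direction)
  .assert(axis %in% .AXES, "unknown axis")
  df <- score_summary(records)
  df <- df[df$axis == axis, , drop = FALSE]
  dir <- unlist(directions)[df$gene]
  if (any(is.na(dir)))
    stop("unknown gene direction for: ",
         paste(df$gene[is.na(dir)], collapse = ", "), call. = FALSE)
  df <- df[dir == direction, , drop = FALSE]
  ord <- order(df$summed_score, decreasing = (direction == "UP"))
  head(df$gene[ord], n = min(k, nrow(df)))
}

#' Classify the dominant axis of one gene
#'
#' Picks the axis with the largest `|summed_score| / n_markers_used`.
#' Normalising by the number of markers used makes panels of different
#' sizes comparable. Exact ties are broken by the fixed axis order
#' [axis_labels()].
#'
#' @param records List of `AxisScoreRecord` objects for ONE gene,
#'   covering all five axes.
#' @return Single axis label.
#' @export
classify_top_axis <- function(records) {
  genes <- unique(vapply(records, `[[`, character(1), "gene"))
  .assert(length(genes) == 1L,
          "classify_top_axis expects records for exactly one gene")
  axes <- vapply(records, `[[`, character(1), "axis")
  miss <- setdiff(.AXES, axes)
  if (length(miss))
    stop("missing axis record(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  norm <- vapply(records, function(r)
    abs(r$summed_score) / r$n_markers_used, numeric(1))
  best <- which(norm >= max(norm) - 1e-12)
  axes[best][which.min(match(axes[best], .AXES))]
}

#' Bubble-plot table of summed scores
#'
#' Long-format table behind an overall-correlation bubble plot: one row
#' per (gene, axis) with the summed score and the number of
#' significantly correlated markers. Requires a complete gene-by-axis
#' grid (every scored gene present for all five axes).
#'
#' @param records List of `AxisScoreRecord` objects.
#' @return Data frame with `|genes| * 5` rows: `gene`, `axis`,
#'   `summed_score`, `n_markers_used`, `n_significant`.
#' @export
export_bubble <- function(records) {
  df <- score_summary(records)
  by_gene <- split(df$axis, df$gene)
  complete <- vapply(by_gene, function(a)
    length(a) == length(.AXES) && setequal(a, .AXES), logical(1))
  if (!all(complete))
    stop("incomplete gene x axis grid for: ",
         paste(names(by_gene)[!complete], collapse = ", "),
         call. = FALSE)
  df$axis <- factor(df$axis, levels = .AXES)
  df <- df[order(df$gene, df$axis), , drop = FALSE]
  df$axis <- as.character(df$axis)
  rownames(df) <- NULL
  df
}
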