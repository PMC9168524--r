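## Bone-metastasis-free survival screen: candidate genes are
## dichotomised at their median expression and the high/low arms
## compared with the log-rank test on the bone-specific endpoint.

#' Bone-metastasis-free survival endpoint
#'
#' Derives the (time, event) pair for the bone-specific endpoint: the
#' event is the occurrence of bone metastasis, so samples whose
#' metastasis went to another site are censored at their follow-up time
#' (as are metastasis-free samples).
#'
#' @param clinical A predisposition `ClinicalTable` with `met_status`,
#'   `bmfs_time`, `bmfs_event`.
#' @return List with `sample_id`, `time`, `event` (0/1).
#' @export
bmfs_label <- function(clinical) {
  need <- c("sample_id", "met_status", "bmfs_time", "bmfs_event")
  miss <- setdiff(need, names(clinical))
  .assert(length(miss) == 0L,
          paste0("clinical table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  .assert(all(is.finite(clinical$bmfs_time) & clinical$bmfs_time > 0),
          "bmfs_time must be positive")
  event <- ifelse(clinical$met_status == "BONE",
                  as.integer(clinical$bmfs_event), 0L)
  list(sample_id = clinical$sample_id,
       time = as.numeric(clinical$bmfs_time),
       event = as.integer(event))
}

#' Survival screen over candidate genes
#'
#' For each gene, samples are split into high/low expression arms at
#' the per-gene cutpoint (median by default; ties at the cut go to the
#' low arm) and the arms are compared with the log-rank test on the
#' bone-metastasis-free endpoint from [bmfs_label()]. `risk_direction`
#' compares restricted mean survival between the arms
#' (`HIGH_EXPR_WORSE` when the high arm has the smaller restricted
#' mean). Genes whose split leaves an empty arm (constant expression)
#' are skipped and recorded in the `"skipped"` attribute.
#'
#' @param matrix An [expression_matrix()].
#' @param clinical Predisposition `ClinicalTable` for the matrix
#'   samples.
#' @param genes Gene symbols to screen (must be present in the matrix).
#' @param alpha Significance threshold for the `significant` flag.
#' @param split `"median"` (default) or `"upper_quartile"` (high arm =
#'   top quartile).
#' @param bh Benjamini-Hochberg adjust p-values before flagging.
#' @return Data frame: `gene`, `cutpoint`, `n_high`, `n_low`,
#'   `logrank_stat`, `p_value`, `risk_direction`, `significant`.
#' @export
survival_screen <- function(matrix, clinical, genes, alpha = 0.05,
                            split = c("median", "upper_quartile"),
                            bh = FALSE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  split <- match.arg(split)
  genes <- toupper(genes)
  miss <- setdiff(genes, matrix$gene_ids)
  .assert(length(miss) == 0L,
          paste0("genes not in matrix: ", paste(head(miss, 5),
                                                collapse = ", ")))
  lab <- bmfs_label(clinical)
  .assert(all(lab$sample_id %in% matrix$sample_ids),
          "clinical sample ids missing from matrix")
  expr <- matrix$values[, lab$sample_id, drop = FALSE]
  rows <- vector("list", length(genes))
  skipped <- character(0)
  for (k in seq_along(genes)) {
    g <- genes[k]
    x <- expr[g, ]
    cut <- if (split == "median") median(x) else
      quantile(x, 0.75, names = FALSE)
    high <- x > cut
    if (!any(high) || all(high)) {
      skipped <- c(skipped, g)
      next
    }
    lr <- log_rank(lab$time[high], lab$event[high],
                   lab$time[!high], lab$event[!high])
    tau <- max(lab$time)
    rm_h <- .km_rmean(km_curve(lab$time[high], lab$event[high]), tau)
    rm_l <- .km_rmean(km_curve(lab$time[!high], lab$event[!high]), tau)
    rows[[k]] <- data.frame(
      gene = g, cutpoint = cut, n_high = sum(high), n_low = sum(!high),
      logrank_stat = lr$statistic, p_value = lr$p_value,
      risk_direction = if (rm_h < rm_l) "HIGH_EXPR_WORSE" else
        "LOW_EXPR_WORSE",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene = character(0), cutpoint = numeric(0),
                      n_high = integer(0), n_low = integer(0),
                      logrank_stat = numeric(0), p_value = numeric(0),
                      risk_direction = character(0),
                      stringsAsFactors = FALSE)
  padj <- if (bh && nrow(out)) p.adjust(out$p_value, method = "BH") else
    out$p_value
  out$significant <- padj < alpha
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
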