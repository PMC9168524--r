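## Differential-expression stages of the screen: per-gene testing for a
## metastasis contrast with the normality-gated test choice,
## cross-cohort intersection with direction concordance, the
## bone-specificity exclusion, and the two-contrast adaptive-lesion
## screen.

.CONTRASTS <- c("DISTANT_VS_NONE", "BONE_VS_NONE", "OTHER_VS_NONE",
                "ADAPTIVE_BONE")

.STAGES <- c("discovery", "validation", "bone_specific", "survival")

## sample ids of the two arms of a contrast
.contrast_arms <- function(clinical, contrast) {
  if (contrast == "ADAPTIVE_BONE") {
    .assert("lesion_site" %in% names(clinical),
            "contrast ADAPTIVE_BONE needs a 'lesion_site' column")
    interest <- clinical$sample_id[clinical$lesion_site == "BONE_MET"]
    reference <- clinical$sample_id[clinical$lesion_site == "PRIMARY"]
  } else {
    .assert("met_status" %in% names(clinical),
            "predisposition contrasts need a 'met_status' column")
    ms <- clinical$met_status
    interest <- switch(contrast,
      DISTANT_VS_NONE = clinical$sample_id[ms %in% c("BONE", "OTHER")],
      BONE_VS_NONE    = clinical$sample_id[ms == "BONE"],
      OTHER_VS_NONE   = clinical$sample_id[ms == "OTHER"])
    reference <- clinical$sample_id[ms == "NONE"]
  }
  list(interest = interest, reference = reference)
}

## gated two-group test for one gene; returns list(test_used, statistic,
## p_value) or NULL when the gene has zero variance in both arms
.gene_test <- function(xi, xr, alpha_norm, test_mode) {
  if (var(xi) == 0 && var(xr) == 0) return(NULL)
  choice <- switch(test_mode,
    auto = normality_gate(xi, xr, alpha_norm = alpha_norm),
    welch = "T_TEST", student = "T_TEST", mw = "MANN_WHITNEY")
  if (choice == "T_TEST") {
    res <- two_sample_t(xi, xr, equal_var = identical(test_mode, "student"))
    list(test_used = "T_TEST", statistic = res$statistic,
         p_value = res$p_value)
  } else {
    res <- mann_whitney(xi, xr)
    list(test_used = "MANN_WHITNEY", statistic = res$statistic,
         p_value = res$p_value)
  }
}

#' Per-gene differential expression for one contrast
#'
#' For every gene, the test (Student/Welch t vs Mann-Whitney) is chosen
#' by the Shapiro-Wilk normality gate, the two-sided p-value is
#' computed between the contrast arms, and the effect is the difference
#' of arm means of log2 expression (group of interest minus reference);
#' `direction` is UP iff the effect is positive. Only genes with
#' p < `alpha` (after optional Benjamini-Hochberg adjustment) are
#' returned. Genes with zero variance in both arms are skipped and
#' recorded in the `"skipped"` attribute.
#'
#' @param matrix An [expression_matrix()].
#' @param clinical A `ClinicalTable` covering the matrix samples.
#' @param contrast One of `"DISTANT_VS_NONE"`, `"BONE_VS_NONE"`,
#'   `"OTHER_VS_NONE"`, `"ADAPTIVE_BONE"` (BONE_MET vs PRIMARY lesions).
#' @param alpha Significance threshold (default 0.05, uncorrected).
#' @param alpha_norm Shapiro-Wilk level for the normality gate.
#' @param test `"auto"` (normality-gated, default), `"welch"`,
#'   `"student"` or `"mw"` to force a test.
#' @param bh Apply Benjamini-Hochberg adjustment before thresholding
#'   (default `FALSE`, matching a raw P < 0.05 screen).
#' @param keep_all Return all tested genes regardless of significance
#'   (adds a `significant` column).
#' @return Data frame of DEG records: `gene`, `contrast`, `test_used`,
#'   `statistic`, `p_value`, `direction`, `effect`. Attributes:
#'   `n_tested`, `skipped` (zero-variance genes).
#' @export
run_contrast <- function(matrix, clinical, contrast, alpha = 0.05,
                         alpha_norm = 0.05,
                         test = c("auto", "welch", "student", "mw"),
                         bh = FALSE, keep_all = FALSE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  test <- match.arg(test)
  .assert(contrast %in% .CONTRASTS,
          paste0("unknown contrast; expected one of: ",
                 paste(.CONTRASTS, collapse = ", ")))
  miss <- setdiff(clinical$sample_id, matrix$sample_ids)
  .assert(length(miss) == 0L,
          paste0("clinical sample ids missing from matrix: ",
                 paste(head(miss, 5), collapse = ", ")))
  arms <- .contrast_arms(clinical, contrast)
  .assert(length(arms$interest) >= 3L && length(arms$reference) >= 3L,
          "each contrast arm needs at least 3 samples")
  vi <- matrix$values[, arms$interest, drop = FALSE]
  vr <- matrix$values[, arms$reference, drop = FALSE]
  ng <- nrow(vi)
  effect <- rowMeans(vi) - rowMeans(vr)
  test_used <- character(ng); stat <- pval <- rep(NA_real_, ng)
  skipped <- character(0)
  for (i in seq_len(ng)) {
    res <- .gene_test(vi[i, ], vr[i, ], alpha_norm, test)
    if (is.null(res)) {
      skipped <- c(skipped, matrix$gene_ids[i])
      next
    }
    test_used[i] <- res$test_used
    stat[i] <- res$statistic
    pval[i] <- res$p_value
  }
  keep <- !is.na(pval)
  out <- data.frame(
    gene = matrix$gene_ids[keep],
    contrast = contrast,
    test_used = test_used[keep],
    statistic = stat[keep],
    p_value = pval[keep],
    direction = ifelse(effect[keep] > 0, "UP", "DOWN"),
    effect = effect[keep],
    stringsAsFactors = FALSE)
  padj <- if (bh) p.adjust(out$p_value, method = "BH") else out$p_value
  if (keep_all) {
    out$significant <- padj < alpha
  } else {
    out <- out[padj < alpha, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_tested") <- sum(keep)
  attr(out, "skipped") <- skipped
  out
}

#' Cross-cohort concordant intersection of DEG lists
#'
#' Genes significant in both cohorts with identical direction become
#' candidate genes; genes significant in both but with discordant
#' directions are excluded (recorded in the `"discordant"` attribute).
#'
#' @param deg_a,deg_b DEG record data frames from [run_contrast()] on
#'   two distinct cohorts, same contrast.
#' @return Candidate data frame: `gene`, `direction`, `discovery_p`,
#'   `validation_p`, `passed_stages`.
#' @export
intersect_concordant <- function(deg_a, deg_b) {
  for (d in list(deg_a, deg_b))
    if (anyDuplicated(d$gene))
      stop("duplicate gene within one DEG list", call. = FALSE)
  m <- merge(deg_a[, c("gene", "direction", "p_value")],
             deg_b[, c("gene", "direction", "p_value")],
             by = "gene", suffixes = c("_a", "_b"))
  concord <- m$direction_a == m$direction_b
  out <- data.frame(
    gene = m$gene[concord],
    direction = m$direction_a[concord],
    discovery_p = m$p_value_a[concord],
    validation_p = m$p_value_b[concord],
    passed_stages = rep("discovery;validation", sum(concord)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discordant") <- m$gene[!concord]
  out
}

#' Bone-specificity exclusion
#'
#' Removes from the bone-metastasis candidate list every gene that is
#' also differentially expressed with other-site distant metastasis, so
#' that the surviving candidates are specific to spread to bone. The
#' output gene set is always disjoint from `other_met_degs$gene`.
#'
#' @param bone_candidates Candidate data frame (needs a `gene` column),
#'   e.g. from [intersect_concordant()] on a bone contrast.
#' @param other_met_degs Data frame of DEG records for the other-site
#'   metastasis contrast (needs a `gene` column).
#' @return The filtered candidate data frame with `passed_stages`
#'   extended; excluded genes in the `"excluded"` attribute.
#' @export
bone_specific <- function(bone_candidates, other_met_degs) {
  other <- unique(other_met_degs$gene)
  keep <- !bone_candidates$gene %in% other
  out <- bone_candidates[keep, , drop = FALSE]
  if ("passed_stages" %in% names(out) && nrow(out))
    out$passed_stages <- paste0(out$passed_stages, ";bone_specific")
  rownames(out) <- NULL
  attr(out, "excluded") <- bone_candidates$gene[!keep]
  out
}

#' Adaptive-phenotype DEGs in bone lesions
#'
#' Screens for genes whose expression in bone metastatic lesions
#' differs from both primary tumours and other-site metastases: a gene
#' qualifies when it is significant (p < `alpha`) with the same
#' direction in BOTH contrasts BONE_MET vs PRIMARY and BONE_MET vs
#' OTHER_MET. Qualifying genes are split by direction.
#'
#' @inheritParams run_contrast
#' @return List with elements `up` and `down`, each a data frame:
#'   `gene`, `direction`, `p_vs_primary`, `p_vs_other`,
#'   `effect_vs_primary`, `effect_vs_other`.
#' @export
adaptive_degs <- function(matrix, clinical, alpha = 0.05,
                          alpha_norm = 0.05, bh = FALSE) {
  .assert("lesion_site" %in% names(clinical),
          "adaptive screen needs a 'lesion_site' column")
  counts <- table(factor(clinical$lesion_site, levels = .LESION_SITES))
  .assert(all(counts >= 3L),
          "adaptive screen needs >= 3 samples per lesion site")
  vs_primary <- run_contrast(matrix, clinical, "ADAPTIVE_BONE",
                             alpha = alpha, alpha_norm = alpha_norm,
                             bh = bh)
  clin_other <- clinical
  clin_other$lesion_site[clin_other$lesion_site == "PRIMARY"] <- NA
  clin_other$lesion_site[clin_other$lesion_site == "OTHER_MET"] <- "PRIMARY"
  clin_other <- clin_other[!is.na(clin_other$lesion_site), , drop = FALSE]
  vs_other <- run_contrast(matrix, clin_other, "ADAPTIVE_BONE",
                           alpha = alpha, alpha_norm = alpha_norm,
                           bh = bh)
  m <- merge(vs_primary[, c("gene", "direction", "p_value", "effect")],
             vs_other[, c("gene", "direction", "p_value", "effect")],
             by = "gene", suffixes = c("_p", "_o"))
  m <- m[m$direction_p == m$direction_o, , drop = FALSE]
  out <- data.frame(gene = m$gene, direction = m$direction_p,
                    p_vs_primary = m$p_value_p, p_vs_other = m$p_value_o,
                    effect_vs_primary = m$effect_p,
                    effect_vs_other = m$effect_o,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  list(up = out[out$direction == "UP", , drop = FALSE],
       down = out[out$direction == "DOWN", , drop = FALSE])
}
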