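## End-to-end orchestration of the screen: the predisposition cascade
## (two-cohort DEG discovery/validation -> bone specificity -> survival
## filter -> axis scoring), the adaptive screen, and file-level entry
## points mirroring what the generator writes.

.stage_counts <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(c(UP = 0L, DOWN = 0L))
  c(UP = sum(df$direction == "UP"), DOWN = sum(df$direction == "DOWN"))
}

#' Run the predisposition screen
#'
#' Executes the full cascade on a discovery and a validation cohort:
#' per-cohort DEG testing for the DISTANT/BONE/OTHER vs metastasis-free
#' contrasts, direction-concordant cross-cohort intersection of the
#' bone-contrast DEGs, exclusion of the (concordant, cross-cohort)
#' other-site metastasis DEGs, a bone-metastasis-free survival screen
#' on the discovery cohort, and marker-panel axis scoring of the
#' survival-significant genes. Candidate-list counts are
#' non-increasing along the cascade within each direction stratum.
#'
#' @param discovery,validation Lists with elements `expression`
#'   ([expression_matrix()]) and `clinical` (`ClinicalTable`), e.g.
#'   from [generate_cohort()].
#' @param panels Marker panels (default [default_panels()]).
#' @param alpha Significance threshold for every stage (default 0.05,
#'   uncorrected).
#' @param alpha_norm Shapiro-Wilk level for the normality gate.
#' @param bh Benjamini-Hochberg switch for the DEG and survival stages.
#' @param survival_split Dichotomisation rule for the survival screen.
#' @param outdir Optional directory; when given, stage TSVs and a JSON
#'   run summary are written there.
#' @return Object of class `RunSummary`: list with `counts` (per-stage
#'   UP/DOWN gene counts), `candidates` (the bone-specific candidate
#'   table annotated with `survival_p` and `survival_passed`),
#'   `survival` (full screen records), `scores`, `bubble`, `top_axis`,
#'   and the parameters used.
#' @export
run_predisposition <- function(discovery, validation,
                               panels = default_panels(), alpha = 0.05,
                               alpha_norm = 0.05, bh = FALSE,
                               survival_split = "median",
                               outdir = NULL) {
  for (c_ in list(discovery, validation))
    .assert(inherits(c_$expression, "ExpressionMatrix") &&
              is.data.frame(c_$clinical),
            "cohorts must carry 'expression' and 'clinical'")
  deg <- function(cohort, contrast)
    run_contrast(cohort$expression, cohort$clinical, contrast,
                 alpha = alpha, alpha_norm = alpha_norm, bh = bh)
  distant_d <- deg(discovery, "DISTANT_VS_NONE")
  bone_d <- deg(discovery, "BONE_VS_NONE")
  other_d <- deg(discovery, "OTHER_VS_NONE")
  bone_v <- deg(validation, "BONE_VS_NONE")
  other_v <- deg(validation, "OTHER_VS_NONE")

  validated <- intersect_concordant(bone_d, bone_v)
  other_consensus <- intersect_concordant(other_d, other_v)
  candidates <- bone_specific(validated, other_consensus)

  surv <- survival_screen(discovery$expression, discovery$clinical,
                          candidates$gene, alpha = alpha,
                          split = survival_split, bh = bh)
  candidates$survival_p <- surv$p_value[match(candidates$gene, surv$gene)]
  candidates$survival_passed <-
    candidates$gene %in% surv$gene[surv$significant]
  candidates$passed_stages <- ifelse(
    candidates$survival_passed,
    paste0(candidates$passed_stages, ";survival"),
    candidates$passed_stages)
  survived <- candidates$gene[candidates$survival_passed]

  scores <- NULL; bubble <- NULL; top_axis <- NULL
  if (length(survived)) {
    scores <- score_all(survived, discovery$expression, panels)
    bubble <- tryCatch(export_bubble(scores), error = function(e) NULL)
    top_axis <- data.frame(
      gene = survived,
      top_axis = vapply(survived, function(g)
        tryCatch(classify_top_axis(Filter(function(r) r$gene == g,
                                          scores)),
                 error = function(e) NA_character_),
        character(1)),
      stringsAsFactors = FALSE)
    rownames(top_axis) <- NULL
  }
  counts <- list(
    discovery_distant = .stage_counts(distant_d),
    discovery_bone = .stage_counts(bone_d),
    validated = .stage_counts(validated),
    bone_specific = .stage_counts(candidates),
    survival_passed = .stage_counts(
      candidates[candidates$survival_passed, , drop = FALSE]))
  out <- structure(
    list(kind = "predisposition", counts = counts,
         candidates = candidates, survival = surv, scores = scores,
         bubble = bubble, top_axis = top_axis,
         params = list(alpha = alpha, alpha_norm = alpha_norm, bh = bh,
                       survival_split = survival_split),
         version = as.character(utils::packageVersion("osteoscreen"))),
    class = "RunSummary")
  if (!is.null(outdir)) .write_summary(out, outdir)
  out
}

#' Run the adaptive-phenotype screen
#'
#' Two-contrast adaptive DEG detection (BONE_MET vs PRIMARY and vs
#' OTHER_MET, direction concordant), marker-panel scoring of every
#' adaptive DEG over all five axes, and per-axis ranked gene lists for
#' both direction strata.
#'
#' @param adaptive List with `expression` and `clinical` (with
#'   `lesion_site`), e.g. from [generate_adaptive()].
#' @inheritParams run_predisposition
#' @param k Number of top genes kept per (axis, direction) table.
#' @return `RunSummary` with `degs` (`up`/`down`), `scores`, `bubble`
#'   and `ranked` (named list `AXIS.DIRECTION` -> gene vector).
#' @export
run_adaptive <- function(adaptive, panels = default_panels(),
                         alpha = 0.05, alpha_norm = 0.05, bh = FALSE,
                         k = 10, outdir = NULL) {
  .assert("lesion_site" %in% names(adaptive$clinical),
          "adaptive cohort clinical table lacks 'lesion_site'")
  degs <- adaptive_degs(adaptive$expression, adaptive$clinical,
                        alpha = alpha, alpha_norm = alpha_norm, bh = bh)
  all_deg <- rbind(degs$up, degs$down)
  scores <- NULL; bubble <- NULL; ranked <- list()
  if (nrow(all_deg)) {
    scores <- score_all(all_deg$gene, adaptive$expression, panels)
    bubble <- tryCatch(export_bubble(scores), error = function(e) NULL)
    directions <- setNames(all_deg$direction, all_deg$gene)
    for (ax in .AXES)
      for (dir in c("UP", "DOWN"))
        ranked[[paste(ax, dir, sep = ".")]] <-
          rank_by_axis(scores, directions, ax, direction = dir, k = k)
  }
  out <- structure(
    list(kind = "adaptive",
         counts = list(up = nrow(degs$up), down = nrow(degs$down)),
         degs = degs, scores = scores, bubble = bubble, ranked = ranked,
         params = list(alpha = alpha, alpha_norm = alpha_norm, bh = bh,
                       k = k),
         version = as.character(utils::packageVersion("osteoscreen"))),
    class = "RunSummary")
  if (!is.null(outdir)) .write_summary(out, outdir)
  out
}

#' @export
print.RunSummary <- function(x, ...) {
  cat(sprintf("osteoscreen %s run\n", x$kind))
  if (x$kind == "predisposition") {
    for (nm in names(x$counts))
      cat(sprintf("  %-18s UP %4d  DOWN %4d\n", nm,
                  x$counts[[nm]]["UP"], x$counts[[nm]]["DOWN"]))
  } else {
    cat(sprintf("  adaptive DEGs: %d up, %d down\n",
                x$counts$up, x$counts$down))
  }
  invisible(x)
}

.write_summary <- function(summary, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    if (!is.null(df) && nrow(df))
      write.table(df, file.path(outdir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  if (summary$kind == "predisposition") {
    wtsv(summary$candidates, "candidates.tsv")
    wtsv(summary$survival, "survival_screen.tsv")
    if (!is.null(summary$scores)) {
      long <- do.call(rbind, lapply(summary$scores, function(r)
        data.frame(gene = r$gene, axis = r$axis, r$marker_rhos,
                   stringsAsFactors = FALSE)))
      wtsv(long, "axis_marker_rhos.tsv")
    }
    wtsv(summary$bubble, "bubble.tsv")
    wtsv(summary$top_axis, "top_axis.tsv")
  } else {
    wtsv(summary$degs$up, "adaptive_up.tsv")
    wtsv(summary$degs$down, "adaptive_down.tsv")
    wtsv(summary$bubble, "bubble.tsv")
  }
  json <- list(kind = summary$kind, counts = summary$counts,
               params = summary$params, version = summary$version)
  jsonlite::write_json(json, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Write a simulated study to disk
#'
#' Generates a discovery/validation pair (and optionally an adaptive
#' cohort) and writes every file the pipeline consumes: expression and
#' clinical TSVs per cohort, the marker panels as GMT, and the
#' ground-truth table as TSV.
#'
#' @param config Discovery [sim_config()]; the validation config is
#'   derived with a child seed.
#' @param outdir Output directory (created if needed).
#' @param adaptive_config Optional [sim_config()] for an adaptive
#'   cohort.
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_cohorts <- function(config, outdir, adaptive_config = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pair <- generate_pair(config)
  paths <- c()
  for (nm in c("discovery", "validation")) {
    co <- pair[[nm]]
    pe <- file.path(outdir, paste0(nm, "_expression.tsv"))
    pc <- file.path(outdir, paste0(nm, "_clinical.tsv"))
    write_expression(co$expression, pe)
    write_clinical(co$clinical, pc)
    paths[paste0(nm, "_expression")] <- pe
    paths[paste0(nm, "_clinical")] <- pc
  }
  pt <- file.path(outdir, "truth.tsv")
  write.table(pair$discovery$truth, pt, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["truth"] <- pt
  pg <- file.path(outdir, "panels.gmt")
  write_gmt(default_panels(), pg)
  paths["panels"] <- pg
  if (!is.null(adaptive_config)) {
    ad <- generate_adaptive(adaptive_config)
    pe <- file.path(outdir, "adaptive_expression.tsv")
    pc <- file.path(outdir, "adaptive_clinical.tsv")
    write_expression(ad$expression, pe)
    write_clinical(ad$clinical, pc)
    paths["adaptive_expression"] <- pe
    paths["adaptive_clinical"] <- pc
  }
  invisible(paths)
}
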