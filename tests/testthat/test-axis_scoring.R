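panel_matrix <- function(n = 40, seed = 2, extra = c("GENEA", "GENEB")) {
  all_markers <- unlist(lapply(default_panels(), `[[`, "genes"))
  fixture_matrix(c(extra, all_markers), n, seed = seed)
}

test_that("axis scores are additive in marker rhos and bounded by panel size", {
  mat <- panel_matrix()
  for (p in default_panels()) {
    rec <- axis_score("GENEA", mat, p)
    expect_equal(rec$summed_score, sum(rec$marker_rhos$rho),
                 tolerance = 1e-12)
    expect_lte(abs(rec$summed_score), rec$n_markers_used)
    expect_identical(rec$n_markers_used + length(rec$missing_markers),
                     length(p$genes))
  }
})

test_that("a marker identical to the gene contributes rho = 1 and self-overlap is excluded", {
  mat <- panel_matrix()
  # GENEA duplicates CXCR4's expression exactly
  mat$values["GENEA", ] <- mat$values["CXCR4", ]
  rec <- axis_score("GENEA", mat, default_panels()$HOMING)
  expect_equal(rec$marker_rhos$rho[rec$marker_rhos$marker == "CXCR4"], 1)
  # scoring a marker against its own panel drops the self-pair
  rec2 <- axis_score("CXCR4", mat, default_panels()$HOMING)
  expect_false("CXCR4" %in% rec2$marker_rhos$marker)
  expect_identical(rec2$n_markers_used + length(rec2$missing_markers), 7L)
})

test_that("absent markers are recorded as missing and aliases are matched", {
  all_markers <- unlist(lapply(default_panels(), `[[`, "genes"))
  keep <- setdiff(all_markers, c("CXCR4", "TNFSF11"))
  mat <- fixture_matrix(c("GENEA", keep, "RANKL"), 30, seed = 6)
  rec <- axis_score("GENEA", mat, default_panels()$HOMING)
  expect_identical(rec$missing_markers, "CXCR4")
  expect_identical(rec$n_markers_used, 7L)
  # TNFSF11 is stored in the panel; the matrix carries RANKL
  oc <- axis_score("GENEA", mat, default_panels()$OSTEOCLASTIC)
  row <- oc$marker_rhos[oc$marker_rhos$marker == "TNFSF11", ]
  expect_identical(row$matched, "RANKL")
  # no available markers at all is an error
  tiny <- fixture_matrix(c("GENEA", "GENEB"), 10, seed = 1)
  expect_error(axis_score("GENEA", tiny, default_panels()$HOMING),
               "no panel marker")
})

test_that("score_all yields one record per gene-axis pair, invariant to transforms", {
  mat <- panel_matrix()
  recs <- score_all(c("GENEA", "GENEB"), mat)
  expect_length(recs, 10L)
  smry <- score_summary(recs)
  expect_identical(nrow(smry), 10L)
  # monotone transform of one gene's values changes nothing
  mat2 <- mat
  mat2$values["GENEA", ] <- exp(mat2$values["GENEA", ])
  recs2 <- score_all(c("GENEA", "GENEB"), mat2)
  expect_equal(score_summary(recs2)$summed_score, smry$summed_score,
               tolerance = 1e-12)
  # sample permutation changes nothing
  set.seed(10)
  mat3 <- expression_matrix(mat$values[, sample(ncol(mat$values))], "P")
  expect_equal(score_summary(score_all(c("GENEA", "GENEB"), mat3))$summed_score,
               smry$summed_score, tolerance = 1e-12)
  # unknown gene is logged, not fatal
  recs3 <- score_all(c("GENEA", "NOPE"), mat)
  expect_length(recs3, 5L)
  expect_identical(unique(attr(recs3, "failed")$gene), "NOPE")
})

test_that("rank_by_axis ranks UP descending and DOWN ascending without padding", {
  mat <- panel_matrix(extra = c("GA", "GB", "GC", "GD"))
  # engineer scores: GA strongly positive on HOMING, GC strongly negative
  set.seed(12)
  f <- rnorm(ncol(mat$values))
  for (m in default_panels()$HOMING$genes)
    if (m %in% genes(mat)) mat$values[m, ] <- mat$values[m, ] + 2 * f
  mat$values["GA", ] <- mat$values["GA", ] + 2 * f
  mat$values["GC", ] <- mat$values["GC", ] - 2 * f
  recs <- score_all(c("GA", "GB", "GC", "GD"), mat)
  dirs <- c(GA = "UP", GB = "UP", GC = "DOWN", GD = "DOWN")
  expect_identical(rank_by_axis(recs, dirs, "HOMING", "UP")[1], "GA")
  expect_identical(rank_by_axis(recs, dirs, "HOMING", "DOWN")[1], "GC")
  expect_length(rank_by_axis(recs, dirs, "HOMING", "UP", k = 10), 2L)
  expect_error(rank_by_axis(recs, c(GA = "UP"), "HOMING", "UP"),
               "unknown gene direction")
})

test_that("classify_top_axis normalises by panel size and breaks ties by fixed order", {
  mk <- function(axis, score, n) structure(
    list(gene = "G", axis = axis,
         marker_rhos = data.frame(marker = "M", matched = "M",
                                  rho = score, p_value = 0.5),
         summed_score = score, n_markers_used = n,
         missing_markers = character(0)),
    class = "AxisScoreRecord")
  recs <- list(mk("HOMING", 0.45, 1), mk("IMMUNE_ESCAPE", 0.1, 1),
               mk("ANGIOGENESIS", 0.1, 1), mk("OSTEOCLASTIC", 0.1, 1),
               mk("OSTEOBLASTIC", 0.1, 1))
  expect_identical(classify_top_axis(recs), "HOMING")
  # same |score| but fewer markers wins on the normalised scale
  recs[[1]] <- mk("HOMING", 0.4, 4)    # 0.1 normalised
  recs[[4]] <- mk("OSTEOCLASTIC", -0.4, 2)  # 0.2, sign ignored
  expect_identical(classify_top_axis(recs), "OSTEOCLASTIC")
  # exact tie -> earlier axis in the fixed order
  recs[[4]] <- mk("OSTEOCLASTIC", 0.1, 1)
  recs[[3]] <- mk("ANGIOGENESIS", 0.1, 1)
  expect_identical(classify_top_axis(recs), "HOMING")
  expect_error(classify_top_axis(recs[1:4]), "missing axis")
})

test_that("bubble export needs a complete grid and round-trips to 1e-12", {
  mat <- panel_matrix(extra = sprintf("G%02d", 1:9))
  recs <- score_all(sprintf("G%02d", 1:9), mat)
  bub <- export_bubble(recs)
  expect_identical(nrow(bub), 45L)
  expect_true(all(table(bub$gene) == 5L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(bub, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(path)
  expect_lt(max(abs(back$summed_score - bub$summed_score)), 1e-12)
  expect_error(export_bubble(recs[-1]), "incomplete")
})
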