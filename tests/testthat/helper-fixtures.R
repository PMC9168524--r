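# Small deterministic fixtures built in code.

# gene-by-sample matrix with named rows; values drawn once per call
# from the supplied seed
fixture_matrix <- function(genes, n_samples, seed = 1, cohort = "FIX",
                           baseline = 8, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(length(genes) * n_samples, baseline, sd),
              nrow = length(genes),
              dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(m, cohort_id = cohort)
}

# two-arm predisposition clinical table over the samples of a matrix
fixture_clinical <- function(mat, n_bone, n_none,
                             n_other = length(samples(mat)) - n_bone - n_none) {
  ids <- samples(mat)
  stopifnot(n_bone + n_none + n_other == length(ids))
  clinical_table(data.frame(
    sample_id = ids,
    met_status = rep(c("BONE", "OTHER", "NONE"),
                     c(n_bone, n_other, n_none)),
    bmfs_time = seq_along(ids) + 1,
    bmfs_event = rep(c(1L, 0L, 0L), c(n_bone, n_other, n_none)),
    stringsAsFactors = FALSE))
}

# DEG record data frame shaped like run_contrast() output
fixture_degs <- function(genes, directions, p = 0.01) {
  n <- length(genes)
  data.frame(gene = genes, contrast = rep("BONE_VS_NONE", n),
             test_used = rep("T_TEST", n), statistic = rep(1, n),
             p_value = rep_len(p, n),
             direction = directions,
             effect = ifelse(directions == "UP", 1, -1),
             stringsAsFactors = FALSE)
}
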