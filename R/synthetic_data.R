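## Synthetic cohorts with the statistical structure the screen assumes:
## Gaussian log2 expression with planted class shifts, one latent
## factor per biological axis shared between a gene and its axis
## markers (giving a closed-form target correlation), and exponential
## survival with a log-linear hazard in standardised expression.
## Ground truth is returned for recovery tests.

.ROLES <- c("BONE_SPECIFIC", "PAN_METASTATIC", "NULL", "AXIS_LINKED",
            "SURVIVAL_LINKED")

#' Describe a planted gene
#'
#' @param gene Gene symbol.
#' @param role One of `BONE_SPECIFIC` (log2 shift in BONE samples
#'   only), `PAN_METASTATIC` (shift in BONE and OTHER),
#'   `NULL` (background-like, bookkept), `AXIS_LINKED` (loads on one
#'   axis latent factor), `SURVIVAL_LINKED` (expression drives the
#'   bone-metastasis hazard).
#' @param effect Non-negative log2 shift magnitude (DEG roles); the
#'   sign is applied from `direction`.
#' @param direction `"UP"` or `"DOWN"` (default `"UP"`).
#' @param axis Axis label (required for `AXIS_LINKED`).
#' @param loading Non-negative loading on the axis factor
#'   (`AXIS_LINKED`).
#' @param log_hr Per-standard-deviation log hazard ratio
#'   (`SURVIVAL_LINKED`).
#' @return List of class `PlantedGene`.
#' @export
planted_gene <- function(gene, role, effect = 0, direction = "UP",
                         axis = NULL, loading = 0, log_hr = 0) {
  .assert(role %in% .ROLES,
          paste0("unknown role; expected one of: ",
                 paste(.ROLES, collapse = ", ")))
  .assert(direction %in% c("UP", "DOWN"), "direction must be UP/DOWN")
  .assert(effect >= 0, "effect must be a non-negative magnitude")
  .assert(loading >= 0, "loading must be >= 0")
  if (role == "AXIS_LINKED") {
    .assert(!is.null(axis) && axis %in% .AXES,
            "AXIS_LINKED genes need a valid 'axis'")
    .assert(loading > 0, "AXIS_LINKED genes need a positive 'loading'")
  }
  structure(list(gene = toupper(gene), role = role, effect = effect,
                 direction = direction, axis = axis, loading = loading,
                 log_hr = log_hr),
            class = "PlantedGene")
}

#' Simulation configuration
#'
#' Defaults reflect a discovery-scale breast-cancer cohort: 100
#' metastasis-free, 30 other-site and 20 bone-metastasis samples, 1000
#' background genes, unit log2 noise around a baseline of 8, a baseline
#' bone-metastasis hazard of 0.02 per month and 40% administrative
#' censoring. `marker_loading` is the loading of every built-in panel
#' marker on its own axis factor (1 by default, so the marker
#' correlation structure the screen assumes is present).
#'
#' @param n_none,n_other,n_bone Samples per metastasis class (classes
#'   with 0 samples are simply absent; any used class in a contrast
#'   needs >= 3).
#' @param n_background_genes Number of independent background genes.
#' @param planted List of [planted_gene()] descriptions.
#' @param noise_sd Residual log2 SD (> 0).
#' @param baseline_mean Baseline log2 expression.
#' @param censor_rate Target administrative censoring fraction in
#'   `[0, 1)` (calibrated against the baseline hazard).
#' @param base_hazard Baseline event hazard per month (> 0).
#' @param marker_loading Axis-factor loading of built-in panel markers
#'   (>= 0; 0 drops the latent structure from the markers).
#' @param include_markers Include the built-in panel marker genes in
#'   the matrix (default `TRUE`).
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return List of class `SimConfig`.
#' @export
sim_config <- function(n_none = 100, n_other = 30, n_bone = 20,
                       n_background_genes = 1000, planted = list(),
                       noise_sd = 1, baseline_mean = 8,
                       censor_rate = 0.4, base_hazard = 0.02,
                       marker_loading = 1, include_markers = TRUE,
                       seed = 1) {
  .assert(noise_sd > 0, "noise_sd must be > 0")
  .assert(censor_rate >= 0 && censor_rate < 1,
          "censor_rate must be in [0, 1)")
  .assert(base_hazard > 0, "base_hazard must be > 0")
  .assert(marker_loading >= 0, "marker_loading must be >= 0")
  .assert(n_none + n_other + n_bone >= 2, "need at least 2 samples")
  for (p in planted) stopifnot(inherits(p, "PlantedGene"))
  pg <- vapply(planted, `[[`, character(1), "gene")
  .assert(!anyDuplicated(pg), "duplicate planted gene symbols")
  structure(list(n_none = n_none, n_other = n_other, n_bone = n_bone,
                 n_background_genes = n_background_genes,
                 planted = planted, noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 censor_rate = censor_rate, base_hazard = base_hazard,
                 marker_loading = marker_loading,
                 include_markers = include_markers,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Log hazard ratio giving a target median-split hazard ratio
#'
#' For a standard-normal expression score, the mean score in the
#' above-median arm is `sqrt(2/pi)` and `-sqrt(2/pi)` below, so a
#' per-SD log hazard ratio of `log(hr) / (2 * sqrt(2/pi))` gives
#' (approximately) hazard ratio `hr` between median-split arms.
#'
#' @param hr Target hazard ratio between the median-split arms.
#' @return Per-SD log hazard ratio.
#' @export
log_hr_for_split_hr <- function(hr) {
  .assert(hr > 0, "hr must be > 0")
  log(hr) / (2 * sqrt(2 / pi))
}

## horizon tau of Uniform(0, tau) administrative censoring such that
## P(C < T) = rate when T ~ Exp(h); (1 - exp(-h tau)) / (h tau) is
## decreasing in tau from 1 to 0
.censor_horizon <- function(base_hazard, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  f <- function(tau) (1 - exp(-base_hazard * tau)) / (base_hazard * tau) -
    censor_rate
  upper <- 10 / (base_hazard * censor_rate)
  uniroot(f, lower = 1e-9, upper = upper, tol = 1e-10)$root
}

.marker_axis_map <- function() {
  panels <- default_panels()
  m <- unlist(lapply(panels, function(p)
    setNames(rep(p$axis, length(p$genes)), p$genes)))
  names(m) <- unlist(lapply(panels, `[[`, "genes"))
  m
}

.signed_effect <- function(p)
  if (identical(p$direction, "DOWN")) -p$effect else p$effect

## core generator shared by the predisposition and adaptive layouts
.generate <- function(config, cohort_id, adaptive) {
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_none + config$n_other + config$n_bone
  cls <- rep(c("NONE", "OTHER", "BONE"),
             c(config$n_none, config$n_other, config$n_bone))
  sample_ids <- sprintf("%s_S%04d", cohort_id, seq_len(n))
  factors <- matrix(rnorm(n * length(.AXES)), nrow = n,
                    dimnames = list(sample_ids, .AXES))
  marker_map <- if (config$include_markers) .marker_axis_map() else
    setNames(character(0), character(0))
  planted_syms <- vapply(config$planted, `[[`, character(1), "gene")
  clash <- intersect(planted_syms, names(marker_map))
  .assert(length(clash) == 0L,
          paste0("planted gene symbols collide with panel markers: ",
                 paste(clash, collapse = ", ")))
  bg <- if (config$n_background_genes > 0)
    sprintf("BG%05d", seq_len(config$n_background_genes)) else character(0)
  all_genes <- c(planted_syms, names(marker_map), bg)
  G <- length(all_genes)
  .assert(G >= 1L, "config yields no genes (no planted, markers or background)")
  expr <- matrix(config$baseline_mean +
                   rnorm(G * n, sd = config$noise_sd),
                 nrow = G, dimnames = list(all_genes, sample_ids))
  in_bone <- cls == "BONE"
  in_other <- cls == "OTHER"
  for (p in config$planted) {
    g <- p$gene
    if (p$role %in% c("BONE_SPECIFIC", "PAN_METASTATIC")) {
      target <- if (p$role == "BONE_SPECIFIC") in_bone else
        (in_bone | in_other)
      expr[g, target] <- expr[g, target] + .signed_effect(p)
    }
    if (p$role == "AXIS_LINKED")
      expr[g, ] <- expr[g, ] + p$loading * factors[, p$axis]
  }
  if (length(marker_map) && config$marker_loading > 0)
    for (m in names(marker_map))
      expr[m, ] <- expr[m, ] +
        config$marker_loading * factors[, marker_map[m]]
  truth_rows <- lapply(config$planted, function(p)
    data.frame(gene = p$gene, role = p$role,
               effect = .signed_effect(p),
               direction = p$direction, axis = p$axis %||% NA_character_,
               loading = p$loading, log_hr = p$log_hr,
               stringsAsFactors = FALSE))
  if (length(marker_map))
    truth_rows <- c(truth_rows, list(data.frame(
      gene = names(marker_map), role = "MARKER", effect = 0,
      direction = NA_character_, axis = unname(marker_map),
      loading = config$marker_loading, log_hr = 0,
      stringsAsFactors = FALSE)))
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth))
    truth <- data.frame(gene = character(0), role = character(0),
                        effect = numeric(0), direction = character(0),
                        axis = character(0), loading = numeric(0),
                        log_hr = numeric(0))
  rownames(truth) <- NULL
  attr(truth, "factors") <- factors

  if (adaptive) {
    site <- c(NONE = "PRIMARY", OTHER = "OTHER_MET", BONE = "BONE_MET")
    clinical <- clinical_table(
      data.frame(sample_id = sample_ids,
                 lesion_site = unname(site[cls]),
                 stringsAsFactors = FALSE),
      kind = "adaptive")
  } else {
    ## exponential survival with log-linear hazard in the standardised
    ## expression of SURVIVAL_LINKED genes; only BONE-class samples can
    ## experience the bone-metastasis event
    lp <- rep(0, n)
    for (p in config$planted)
      if (p$role == "SURVIVAL_LINKED" && p$log_hr != 0)
        lp <- lp + p$log_hr * as.numeric(scale(expr[p$gene, ]))
    hazard <- config$base_hazard * exp(lp)
    t_event <- rexp(n, rate = hazard)
    tau <- .censor_horizon(config$base_hazard, config$censor_rate)
    c_time <- if (is.finite(tau)) runif(n, 0, tau) else rep(Inf, n)
    obs_time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
    clinical <- clinical_table(
      data.frame(sample_id = sample_ids, met_status = cls,
                 bmfs_time = pmax(obs_time, 1e-6),
                 bmfs_event = ifelse(cls == "BONE", event, 0L),
                 stringsAsFactors = FALSE),
      kind = "predisposition")
  }
  list(expression = expression_matrix(expr, cohort_id = cohort_id),
       clinical = clinical, truth = truth)
}

#' Generate one synthetic predisposition cohort
#'
#' Log2 expression for sample s and gene g is
#' `baseline_mean + shift_g(class(s)) + loading_g * F_axis(s) + noise`,
#' with one standard-normal latent factor per axis per sample shared
#' between AXIS_LINKED genes and the panel markers of that axis.
#' Bone-metastasis-free survival is exponential with hazard
#' `base_hazard * exp(sum log_hr_g * z_g(s))` over SURVIVAL_LINKED
#' genes, under uniform administrative censoring calibrated to
#' `censor_rate`; only BONE-class samples carry the event. The output
#' is deterministic given the config (including its seed).
#'
#' @param config A [sim_config()].
#' @param cohort_id Cohort label (default `"SIM"`).
#' @return List with `expression` ([expression_matrix()]), `clinical`
#'   (`ClinicalTable`) and `truth` (data frame of planted genes and
#'   markers, with the per-sample latent factors in its `"factors"`
#'   attribute).
#' @export
generate_cohort <- function(config, cohort_id = "SIM") {
  stopifnot(inherits(config, "SimConfig"))
  .generate(config, cohort_id, adaptive = FALSE)
}

#' Generate a discovery/validation cohort pair
#'
#' Both cohorts share the planted gene roster but have independent
#' samples, factors and noise. When `config_b` is omitted it is derived
#' from `config_a` with a child seed.
#'
#' @param config_a Discovery [sim_config()].
#' @param config_b Validation config (default: `config_a` with a
#'   derived seed).
#' @param shared_truth Require identical planted rosters (default
#'   `TRUE`; a mismatch is an error).
#' @return List with `discovery` and `validation`, each as returned by
#'   [generate_cohort()].
#' @export
generate_pair <- function(config_a, config_b = NULL, shared_truth = TRUE) {
  stopifnot(inherits(config_a, "SimConfig"))
  if (is.null(config_b)) {
    config_b <- config_a
    config_b$seed <- .child_seed(config_a$seed, 1L)
  }
  stopifnot(inherits(config_b, "SimConfig"))
  if (shared_truth) {
    ra <- vapply(config_a$planted, function(p)
      paste(p$gene, p$role, p$effect, p$direction), character(1))
    rb <- vapply(config_b$planted, function(p)
      paste(p$gene, p$role, p$effect, p$direction), character(1))
    .assert(identical(sort(ra), sort(rb)),
            "planted rosters differ between the paired configs")
  }
  list(discovery = generate_cohort(config_a, cohort_id = "DISC"),
       validation = generate_cohort(config_b, cohort_id = "VALID"))
}

#' Generate a synthetic adaptive (lesion-site) cohort
#'
#' Lesion sites map the class counts of the config: `n_none` PRIMARY
#' tumours, `n_other` OTHER_MET and `n_bone` BONE_MET lesions.
#' BONE_SPECIFIC planted genes shift only BONE_MET lesions;
#' PAN_METASTATIC genes shift BONE_MET and OTHER_MET. Axis and marker
#' structure mirror [generate_cohort()]; no survival layer.
#'
#' @inheritParams generate_cohort
#' @return List with `expression`, `clinical` (with `lesion_site`) and
#'   `truth`.
#' @export
generate_adaptive <- function(config, cohort_id = "ADAPT") {
  stopifnot(inherits(config, "SimConfig"))
  .assert(config$n_none >= 3 && config$n_other >= 3 && config$n_bone >= 3,
          "adaptive cohorts need >= 3 samples per lesion site")
  .generate(config, cohort_id, adaptive = TRUE)
}
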