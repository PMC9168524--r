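## Statistical primitives of the screen. These are implemented
## explicitly (midrank Spearman with a t-approximation, tie-corrected
## Mann-Whitney with exact small-sample enumeration, Student/Welch t,
## a Shapiro-Wilk normality gate, the Kaplan-Meier product-limit
## estimator and the two-group log-rank test) so that each one has a
## fully specified, testable definition; the test suite cross-checks
## them against independent reference implementations.

.midrank <- function(x) rank(x, ties.method = "average")

.new_test <- function(statistic, p_value, test_name, n1, n2) {
  structure(list(statistic = statistic, p_value = min(max(p_value, 0), 1),
                 test_name = test_name, n1 = n1, n2 = n2),
            class = "osteo_test")
}

#' @export
print.osteo_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g (n1 = %d, n2 = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Spearman rank correlation with midranks
#'
#' Computes rho as the Pearson correlation of midrank-transformed
#' inputs. The two-sided p-value uses the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom; `rho = +/-1` gives `p = 0`. For `n <= 8` an exact
#' permutation p-value over all `n!` rank orderings is available.
#'
#' @param x,y Numeric vectors of equal length >= 3, all finite.
#' @param exact Use exact permutation p-value (only honoured for
#'   `n <= 8`).
#' @return List of class `osteo_cor` with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  .assert(length(x) == length(y), "'x' and 'y' must have equal length")
  n <- length(x)
  .assert(n >= 3L, "spearman needs at least 3 paired observations")
  .assert(all(is.finite(x)) && all(is.finite(y)),
          "spearman inputs must be finite")
  rx <- .midrank(x); ry <- .midrank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("undefined correlation: zero variance in ranks", call. = FALSE)
  rho <- cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (exact && n <= 8L) {
    obs <- abs(rho)
    perms <- .permutations(n)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      r <- cor(rx, ry[perms[i, ]])
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = min(max(p, 0), 1), n = n),
            class = "osteo_cor")
}

#' @export
print.osteo_cor <- function(x, ...) {
  cat(sprintf("Spearman: rho = %.4f, p = %.4g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

## all permutations of 1..n as rows (used only for tiny n)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling. For `n1 + n2 <= 10` the
#' two-sided p-value is computed by exact enumeration over all
#' `choose(n1 + n2, n1)` group labelings; otherwise by normal
#' approximation with tie-corrected variance (no continuity
#' correction).
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact `NULL` (default) selects enumeration automatically for
#'   `n1 + n2 <= 10`; `TRUE`/`FALSE` forces the choice (forcing `TRUE`
#'   is only honoured for `n1 + n2 <= 12`).
#' @return An `osteo_test` where `statistic` is U for group `a`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  n1 <- length(a); n2 <- length(b)
  .assert(n1 >= 1L && n2 >= 1L, "both groups must be non-empty")
  .assert(all(is.finite(a)) && all(is.finite(b)),
          "mann_whitney inputs must be finite")
  pooled <- c(a, b)
  r <- .midrank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  use_exact <- if (is.null(exact)) N <= 10L else isTRUE(exact) && N <= 12L
  if (use_exact) {
    sets <- combn(N, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    lo <- min(u, n1 * n2 - u)
    hi <- n1 * n2 - lo
    p <- mean(u_all <= lo + 1e-9 | u_all >= hi - 1e-9)
    name <- "mann_whitney_exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sig2)
      p <- 2 * pnorm(-abs(z))
    }
    name <- "mann_whitney_normal"
  }
  .new_test(u, p, name, n1, n2)
}

#' Two-sample t-test
#'
#' Welch's unequal-variance t-test by default, or the pooled-variance
#' Student test with `equal_var = TRUE`. Two-sided p-value from the t
#' distribution.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param equal_var Use the pooled-variance Student test.
#' @return An `osteo_test`.
#' @export
two_sample_t <- function(a, b, equal_var = FALSE) {
  n1 <- length(a); n2 <- length(b)
  .assert(n1 >= 2L && n2 >= 2L, "each group needs at least 2 observations")
  v1 <- var(a); v2 <- var(b)
  if (v1 == 0 && v2 == 0) {
    if (mean(a) == mean(b)) return(.new_test(0, 1, "t_degenerate", n1, n2))
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    name <- "t_student"
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    name <- "t_welch"
  }
  tstat <- (mean(a) - mean(b)) / se
  .new_test(tstat, 2 * pt(-abs(tstat), df = df), name, n1, n2)
}

#' Normality gate between t-test and Mann-Whitney
#'
#' Chooses the test for a two-group comparison: Shapiro-Wilk is applied
#' to each group and the t-test is used only when both groups pass at
#' `alpha_norm`; otherwise (including any group of size < 3 or with
#' zero variance, where Shapiro-Wilk is undefined) the Mann-Whitney
#' test is used.
#'
#' @param a,b Numeric vectors.
#' @param alpha_norm Shapiro-Wilk significance level (default 0.05).
#' @return `"T_TEST"` or `"MANN_WHITNEY"`.
#' @export
normality_gate <- function(a, b, alpha_norm = 0.05) {
  ok <- function(g) {
    if (length(g) < 3L || length(g) > 5000L) return(FALSE)
    if (length(unique(g)) < 2L) return(FALSE)
    p <- tryCatch(shapiro.test(g)$p.value, error = function(e) 0)
    p >= alpha_norm
  }
  if (ok(a) && ok(b)) "T_TEST" else "MANN_WHITNEY"
}

#' Kaplan-Meier product-limit survival curve
#'
#' Events at a given time are handled before censorings at the same
#' time (standard convention): subjects censored at t remain at risk
#' for an event at t. Times with only censorings reduce the at-risk
#' count without a survival step.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @return Object of class `km_curve`: data frame with columns `time`
#'   (unique observed times), `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_curve <- function(times, events) {
  .assert(length(times) >= 1L, "empty survival input")
  .assert(length(times) == length(events), "times/events length mismatch")
  .assert(all(is.finite(times)) && all(times > 0), "times must be > 0")
  .assert(all(events %in% c(0, 1)), "events must be 0/1")
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  structure(out, class = c("km_curve", "data.frame"), n = length(times))
}

## restricted mean survival time: area under the KM step function up to
## tau (start at S = 1 on [0, t1))
.km_rmean <- function(curve, tau) {
  t0 <- c(0, curve$time)
  s0 <- c(1, curve$survival)
  t0 <- pmin(t0, tau)
  area <- 0
  for (i in seq_len(length(t0) - 1L))
    area <- area + s0[i] * (t0[i + 1L] - t0[i])
  if (max(curve$time) < tau)
    area <- area + s0[length(s0)] * (tau - max(curve$time))
  area
}

#' Two-group log-rank test
#'
#' Chi-square statistic `(O1 - E1)^2 / V` with hypergeometric variance
#' on 1 degree of freedom, two-sided p-value. If the pooled data
#' contain no events the statistic is 0 and p = 1.
#'
#' @param times1,events1 Follow-up times and 0/1 indicators, group 1.
#' @param times2,events2 Same for group 2.
#' @return An `osteo_test` with the chi-square `statistic`.
#' @export
log_rank <- function(times1, events1, times2, events2) {
  .assert(length(times1) >= 1L && length(times2) >= 1L,
          "both groups must be non-empty")
  .assert(all(c(events1, events2) %in% c(0, 1)), "events must be 0/1")
  n1 <- length(times1); n2 <- length(times2)
  if (sum(events1) + sum(events2) == 0)
    return(.new_test(0, 1, "log_rank", n1, n2))
  times <- c(times1, times2)
  events <- c(events1, events2)
  grp1 <- rep(c(TRUE, FALSE), c(n1, n2))
  ut <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at <- times >= t
    nj <- sum(at)
    n1j <- sum(at & grp1)
    dj <- sum(times == t & events == 1)
    d1j <- sum(times == t & events == 1 & grp1)
    o1 <- o1 + d1j
    e1 <- e1 + dj * n1j / nj
    if (nj > 1)
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  if (v <= 0) return(.new_test(0, 1, "log_rank", n1, n2))
  chisq <- (o1 - e1)^2 / v
  .new_test(chisq, pchisq(chisq, df = 1, lower.tail = FALSE),
            "log_rank", n1, n2)
}
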