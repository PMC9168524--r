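test_that("spearman equals brute-force midrank Pearson on all small permutations", {
  base_vectors <- list(1:4, c(1, 2, 2, 3), 1:5, c(1, 3, 3, 5, 7),
                       1:6, c(2, 2, 4, 4, 6, 6))
  x5 <- c(0.3, 1.2, 1.2, 2.5, 9, 9)
  for (y0 in base_vectors) {
    n <- length(y0)
    x <- x5[seq_len(n)]
    perms <- all_perms(n)
    for (i in seq_len(nrow(perms))) {
      y <- y0[perms[i, ]]
      got <- spearman(x, y)$rho
      expect_lt(abs(got - oracle_spearman_rho(x, y)), 1e-12)
    }
  }
})

test_that("spearman reproduces hand-derived values and exact monotone cases", {
  expect_equal(spearman(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman(1:4, c(10, 20, 30, 40))$p_value, 0)
  expect_equal(spearman(1:4, c(4, 3, 2, 1))$rho, -1)
  # midrank hand calculation: ranks of y are (1, 2, 3.5, 5, 3.5)
  s <- spearman(1:5, c(5, 6, 7, 8, 7))
  expect_equal(s$rho, 8 / sqrt(95), tolerance = 1e-12)
  expect_identical(s$n, 5L)
})

test_that("spearman p matches the t-approximation reference", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30) + 0.5 * x
    ref <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))
    got <- spearman(x, y)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(7)
  transforms <- list(exp, function(v) v^3, function(v) 2 * v + 13)
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20)
    base <- spearman(x, y)$rho
    for (f in transforms) {
      expect_equal(spearman(f(x), y)$rho, base, tolerance = 1e-12)
      expect_equal(spearman(x, f(y))$rho, base, tolerance = 1e-12)
    }
  }
})

test_that("spearman rejects degenerate input", {
  expect_error(spearman(1:3, 1:4), "equal length")
  expect_error(spearman(1:2, 1:2), "at least 3")
  expect_error(spearman(c(1, 1, 1), 1:3), "zero variance")
})

test_that("mann_whitney exact p equals full labeling enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  cases <- list(
    list(a = c(1, 2, 3), b = c(4, 5, 6)),
    list(a = c(1, 5, 9), b = c(2, 3, 7, 8)),
    list(a = c(1, 2, 2, 3), b = c(2, 4, 4)),          # ties
    list(a = c(3, 1, 4, 1, 5), b = c(9, 2, 6, 5, 3)), # ties across groups
    list(a = c(10, 20), b = c(5, 15, 25, 35)))
  for (cs in cases) {
    got <- mann_whitney(cs$a, cs$b)
    expect_identical(got$test_name, "mann_whitney_exact")
    expect_equal(got$statistic, oracle_u(cs$a, cs$b))
    expect_equal(got$p_value, oracle_mw_exact_p(cs$a, cs$b))
  }
})

test_that("mann_whitney is symmetric and null on identical multisets", {
  a <- c(1, 2, 2, 5); b <- c(1, 2, 2, 5)
  expect_equal(mann_whitney(a, b)$p_value, 1)
  set.seed(1)
  x <- rnorm(15); y <- rnorm(12)
  expect_equal(mann_whitney(x, y)$p_value, mann_whitney(y, x)$p_value)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("mann_whitney normal approximation matches the reference", {
  set.seed(11)
  for (i in 1:8) {
    a <- round(rnorm(25, sd = 2), 1)  # rounding induces ties
    b <- round(rnorm(30, 0.5, 2), 1)
    got <- mann_whitney(a, b)
    ref <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("two_sample_t matches the reference for Welch and Student", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  a <- c(0, 0, 0, 0); b <- c(1, 1, 1, 1) + rnorm(4, sd = 1e-9)
  expect_lt(two_sample_t(a, b)$p_value, 1e-6)
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(20, 0.4, 1.6)
    expect_equal(two_sample_t(x, y)$p_value,
                 t.test(x, y)$p.value, tolerance = 1e-8)
    expect_equal(two_sample_t(x, y, equal_var = TRUE)$p_value,
                 t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-8)
  }
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("normality gate routes by Shapiro-Wilk in both groups", {
  set.seed(2024)
  # exponential data at n = 200: Shapiro-Wilk power is ~1
  expect_identical(normality_gate(rexp(200), rnorm(200)), "MANN_WHITNEY")
  # groups below size 3 force the rank test
  expect_identical(normality_gate(c(1, 2), rnorm(50)), "MANN_WHITNEY")
  expect_identical(normality_gate(rep(1, 10), rnorm(50)), "MANN_WHITNEY")
  # two clean normal samples pass the gate at roughly 0.95^2 of seeds
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    if (normality_gate(rnorm(50), rnorm(50)) == "T_TEST") hits <- hits + 1L
  }
  expect_gte(hits / 100, 0.9025 - 3 * sqrt(0.9025 * 0.0975 / 100))
})

test_that("km_curve matches the product-limit estimator", {
  k <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km_curve(c(4, 8, 15), c(0, 0, 0))$survival, c(1, 1, 1))
  # censor at an event time stays at risk for that event
  k <- km_curve(c(1, 2, 2, 3), c(1, 0, 1, 1))
  expect_equal(k$survival, c(3 / 4, 1 / 2, 0))
  expect_equal(k$n_risk, c(4, 3, 1))
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
  expect_error(km_curve(c(0, 1), c(1, 1)), "> 0")
})

test_that("km_curve equals 1 - ECDF with no censoring and matches survfit", {
  skip_if_not_installed("survival")
  set.seed(31)
  tm <- round(rexp(40, 0.1), 1) + 0.1
  ev <- rbinom(40, 1, 0.7)
  k <- km_curve(tm, ev)
  ref <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  expect_equal(k$survival, ref$surv, tolerance = 1e-12)
  expect_equal(k$n_risk, ref$n.risk, tolerance = 1e-12)
  # no censoring: survivor function is 1 - empirical CDF at event times
  k2 <- km_curve(tm, rep(1, 40))
  expect_equal(k2$survival,
               vapply(k2$time, function(t) mean(tm > t), numeric(1)))
})

test_that("log_rank reproduces the hand-computed toy and is symmetric", {
  # O1 = 3, E1 = 0.5 + 0.4 + 0.25, V = 0.25 + 0.24 + 0.1875
  lr <- log_rank(c(1, 2, 3), c(1, 1, 1), c(4, 5, 6), c(1, 1, 1))
  expect_equal(lr$statistic, (3 - 1.15)^2 / 0.6775, tolerance = 1e-12)
  expect_equal(lr$statistic, 5.05, tolerance = 0.01)
  expect_equal(lr$p_value, 0.0246, tolerance = 1e-3)

  same <- log_rank(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(8)
  t1 <- rexp(20, 0.2); e1 <- rbinom(20, 1, 0.7)
  t2 <- rexp(25, 0.4); e2 <- rbinom(25, 1, 0.7)
  expect_equal(log_rank(t1, e1, t2, e2)$statistic,
               log_rank(t2, e2, t1, e1)$statistic, tolerance = 1e-12)
  expect_gte(log_rank(t1, e1, t2, e2)$statistic, 0)

  expect_equal(log_rank(c(1, 2), c(0, 0), c(3, 4), c(0, 0))$p_value, 1)
})

test_that("log_rank matches survdiff on censored data", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (i in 1:5) {
    t1 <- rexp(30, 0.1); e1 <- rbinom(30, 1, 0.6)
    t2 <- rexp(35, 0.15); e2 <- rbinom(35, 1, 0.6)
    if (sum(e1) + sum(e2) == 0) next
    ref <- survival::survdiff(
      survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(30, 35)))
    expect_equal(log_rank(t1, e1, t2, e2)$statistic, ref$chisq,
                 tolerance = 1e-8)
  }
})
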