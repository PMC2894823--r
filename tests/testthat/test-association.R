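# OLS engine, t-test, Bonferroni bookkeeping, filters, and the region-wise
# GWAS driver.

test_that("exact linear data is fitted exactly", {
  x <- 1:5
  X <- cbind(`(intercept)` = 1, x = x)
  fit <- fit_ols(X, 2 + 3 * x)
  expect_equal(unname(fit$betas), c(2, 3), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)
  expect_equal(unname(fit$ses), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$df, 3)
})

test_that("Gaussian-elimination OLS matches the reference least-squares fit", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(20:100, 1)
    k <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
    colnames(X) <- c("(intercept)", paste0("x", seq_len(k - 1)))
    y <- rnorm(n)
    fit <- fit_ols(X, y)
    ref <- stats::lm(y ~ X - 1)
    ref_sum <- summary(ref)$coefficients
    expect_equal(unname(fit$betas), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(unname(fit$ses), unname(ref_sum[, 2]), tolerance = 1e-8)
    expect_equal(fit$df, ref$df.residual)
  }
})

test_that("duplicated columns raise a collinearity error naming the column", {
  x <- rnorm(20)
  X <- cbind(`(intercept)` = 1, a = x, b = x)
  expect_error(fit_ols(X, rnorm(20)), "collinear.*b",
               class = "cnvrkit_collinear")
  expect_error(fit_ols(X[1:2, 1:2], rnorm(2)), "insufficient")
})

test_that("t-test p-values match direct quadrature of the t density", {
  # density written out from the closed form, independent of pt()
  dt_manual <- function(x, v) {
    gamma((v + 1) / 2) / (sqrt(v * pi) * gamma(v / 2)) *
      (1 + x^2 / v)^(-(v + 1) / 2)
  }
  for (case in list(c(t = 2.0, df = 10), c(t = 0.5, df = 3),
                    c(t = 4.2, df = 57))) {
    p_quad <- 2 * stats::integrate(dt_manual, case[["t"]], Inf,
                                   v = case[["df"]],
                                   rel.tol = 1e-12)$value
    expect_equal(t_test_pvalue(case[["t"]], 1, case[["df"]]), p_quad,
                 tolerance = 1e-8)
  }
  expect_equal(t_test_pvalue(0, 1.5, 10), 1.0)
  expect_equal(t_test_pvalue(1, 0, 10), 0.0)   # exact fit, nonzero effect
  expect_equal(t_test_pvalue(0, 0, 10), 1.0)
  expect_error(t_test_pvalue(1, 1, 0), "df")
})

test_that("Bonferroni threshold is alpha over the number of tested regions", {
  expect_equal(bonferroni_threshold(0.05, 1000), 5e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 25007), 0.05 / 25007)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("subject filters conjoin, exclude missing, and reject unknown columns", {
  ph <- data.frame(subject_id = c("A", "B", "C", "D"),
                   sex = c(1, 1, 2, NA), age = c(30, 60, 50, 40))
  expect_equal(apply_filters(ph), ph$subject_id)
  expect_equal(apply_filters(ph, list(subject_filter("sex", "==", 1))),
               c("A", "B"))
  expect_equal(apply_filters(ph, list(subject_filter("sex", "==", 1),
                                      subject_filter("age", ">=", 40))),
               "B")
  # contradictory filters: empty set
  expect_length(apply_filters(ph, list(subject_filter("age", "<", 0),
                                       subject_filter("age", ">", 0))), 0)
  expect_error(apply_filters(ph, list(subject_filter("height", ">", 1))),
               "height")
  expect_equal(parse_filter("sex==1"), subject_filter("sex", "==", 1))
  expect_equal(parse_filter("age >= 40.5"),
               subject_filter("age", ">=", 40.5))
})

test_that("design matrix uses complete cases and flags monomorphic regions", {
  ph <- data.frame(subject_id = c("A", "B", "C", "D", "E"),
                   y = c(1, 2, 3, 4, 5), age = c(30, NA, 50, 60, 70))
  states <- setNames(c(1, 0, -1, 0, 1), ph$subject_id)
  cfg <- association_config("y", covariates = "age")
  d <- build_design_matrix(states, ph, cfg, ph$subject_id)
  expect_equal(dim(d$X), c(4L, 3L))     # B dropped (missing age)
  expect_equal(colnames(d$X), c("(intercept)", "state", "age"))

  expect_error(
    build_design_matrix(setNames(rep(0, 5), ph$subject_id), ph, cfg,
                        ph$subject_id),
    "monomorphic", class = "cnvrkit_monomorphic")
  expect_error(
    build_design_matrix(states[1:3], ph[1:3, ], association_config("y"),
                        c("A", "B")),
    "insufficient", class = "cnvrkit_insufficient_n")
})

test_that("a perfect single-region association is Bonferroni-significant at M=1", {
  ph <- data.frame(subject_id = sprintf("S%d", 1:10),
                   y = c(rep(0, 5), rep(1, 5)) + (1:10) * 1e-6)
  states <- matrix(c(rep(0, 5), rep(1, 5)), 1,
                   dimnames = list("r1", ph$subject_id))
  regions <- data.frame(region_id = "r1", chromosome = "1", start = 1,
                        end = 100, region_length = 100, frequency = 0.5,
                        n_carriers = 5)
  res <- run_gwas(regions, states, ph, association_config("y"))
  expect_equal(nrow(res), 1L)
  expect_true(res$significant)
  expect_equal(attr(res, "m"), 1L)
})

test_that("monomorphic regions are skipped with a reason, not dropped silently", {
  ph <- data.frame(subject_id = sprintf("S%d", 1:20), y = rnorm(20))
  states <- rbind(r1 = c(rep(1, 5), rep(0, 15)), r2 = rep(0, 20))
  colnames(states) <- ph$subject_id
  regions <- data.frame(region_id = c("r1", "r2"), chromosome = "1",
                        start = c(1, 500), end = c(100, 600),
                        region_length = c(100, 101),
                        frequency = c(0.25, 0), n_carriers = c(5, 0))
  res <- run_gwas(regions, states, ph, association_config("y"))
  expect_equal(nrow(res), 1L)
  expect_equal(attr(res, "m"), 1L)      # M counts regions actually tested
  skipped <- attr(res, "skipped")
  expect_equal(skipped$region_id, "r2")
  expect_match(skipped$reason, "monomorphic")
})

test_that("significance flags are exactly {p < alpha/M} and rescale without refit", {
  set.seed(21)
  ph <- data.frame(subject_id = sprintf("S%03d", 1:100), y = rnorm(100))
  null <- simulate_null_states(100, 30)
  ph$subject_id <- null$subjects
  res <- run_gwas(null$regions, null$states, ph, association_config("y"))
  m <- attr(res, "m")
  expect_identical(res$significant, res$p < 0.05 / m)
  relaxed <- set_significance(res, alpha = 0.5)
  expect_identical(relaxed$significant, res$p < 0.5 / m)
  expect_identical(relaxed$p, res$p)
})

test_that("permuting subject order and adding filtered-out subjects changes nothing", {
  set.seed(31)
  null <- simulate_null_states(50, 10)
  ph <- data.frame(subject_id = null$subjects, y = rnorm(50),
                   sex = rep(1, 50))
  res <- run_gwas(null$regions, null$states, ph, association_config("y"))

  perm <- sample(50)
  res_perm <- run_gwas(null$regions, null$states[, perm], ph[perm, ],
                       association_config("y"))
  expect_equal(res_perm$beta, res$beta)
  expect_equal(res_perm$p, res$p)

  # an extra subject excluded by a filter must not alter any statistic
  ph2 <- rbind(ph, data.frame(subject_id = "EXTRA", y = 99, sex = 2))
  states2 <- cbind(null$states, EXTRA = rep(1, 10))
  cfg_f <- association_config("y",
                              filters = list(subject_filter("sex", "==", 1)))
  res_f <- run_gwas(null$regions, states2, ph2, cfg_f)
  expect_equal(res_f$beta, res$beta)
  expect_equal(res_f$p, res$p)
})

test_that("under the null the raw p-value rate is near alpha and Bonferroni holds", {
  set.seed(61)
  n_rep <- 40
  hits <- 0
  frac <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    null <- simulate_null_states(100, 50)
    ph <- data.frame(subject_id = null$subjects, y = rnorm(100))
    res <- run_gwas(null$regions, null$states, ph, association_config("y"))
    frac[r] <- mean(res$p < 0.05)
    hits <- hits + any(res$significant)
  }
  expect_gt(mean(frac), 0.025)
  expect_lt(mean(frac), 0.075)
  expect_lte(hits / n_rep, 0.1)
})
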