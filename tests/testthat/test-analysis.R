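test_that("log transform maps 0 to 0 and is strictly increasing", {
  expect_identical(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  expect_equal(log_transform(100), log(101))
  expect_error(log_transform(-1), "non-negative")
})

test_that("unit-weight WLS equals the pooled t-test and lm oracles", {
  set.seed(41)
  for (i in 1:5) {
    d <- make_dataset(seed = 100 + i)
    out <- fit_group_comparison(d, method_spec("ols_pmr"))
    oracle <- pooled_t_test(d$pmr, d$group == "2")
    expect_equal(out$p_value, oracle$p_value, tolerance = 1e-10)
    expect_equal(out$estimate, oracle$estimate, tolerance = 1e-10)
    lmfit <- summary(lm(pmr ~ group, data = d))$coefficients
    expect_equal(out$p_value, lmfit[2, 4], tolerance = 1e-10)
    expect_equal(out$std_error, lmfit[2, 2], tolerance = 1e-10)
  }
})

test_that("weighted fits agree with lm(weights =) across schemes", {
  d <- make_dataset(seed = 55)
  for (m in list(method_spec("wls_q"), method_spec("wls_w"),
                 method_spec("wls_w", log_scale = TRUE))) {
    out <- fit_group_comparison(d, m)
    y <- if (m$log_scale) log_transform(d$pmr) else d$pmr
    sch <- if (m$name == "wls_q") quantile_variances(y, d$surrogate, m$k)
           else window_variances(y, d$surrogate, m$w)
    lmfit <- summary(lm(y ~ d$group, weights = sch$weights))$coefficients
    expect_equal(out$estimate, lmfit[2, 1], tolerance = 1e-12)
    expect_equal(out$std_error, lmfit[2, 2], tolerance = 1e-12)
    expect_equal(out$p_value, lmfit[2, 4], tolerance = 1e-12)
  }
})

test_that("threshold fit is bit-identical to OLS on the filtered subset", {
  d <- make_dataset(seed = 66)
  for (t in c(1, 10)) {
    out <- fit_group_comparison(d, method_spec("ols_thresh", threshold = t))
    sub <- d[d$surrogate > t, ]
    ols <- fit_group_comparison(sub, method_spec("ols_pmr"))
    expect_identical(out$estimate, ols$estimate)
    expect_identical(out$std_error, ols$std_error)
    expect_identical(out$p_value, ols$p_value)
    expect_identical(out$n_effective, nrow(sub))
  }
})

test_that("p-values are scale-equivariant and label-symmetric", {
  d <- make_dataset(seed = 77)
  flipped <- d
  flipped$group <- factor(ifelse(d$group == "1", "2", "1"))
  scaled <- d
  scaled$pmr <- d$pmr * 3.7
  for (m in list(method_spec("ols_pmr"), method_spec("ols_thresh", threshold = 10),
                 method_spec("wls_q"), method_spec("wls_w"))) {
    base <- fit_group_comparison(d, m)
    sym <- fit_group_comparison(flipped, m)
    expect_equal(sym$estimate, -base$estimate)
    expect_equal(sym$p_value, base$p_value)
    sc <- fit_group_comparison(scaled, m)
    expect_equal(sc$p_value, base$p_value, tolerance = 1e-12)
    expect_equal(sc$estimate, 3.7 * base$estimate, tolerance = 1e-12)
  }
})

test_that("clear separation forces an extreme test statistic", {
  set.seed(88)
  d <- data.frame(pmr = c(abs(rnorm(100, 0, 0.01)), rnorm(100, 50, 0.5)),
                  surrogate = runif(200, 1, 100),
                  group = factor(rep(c("1", "2"), each = 100)))
  out <- fit_group_comparison(d, method_spec("ols_pmr"))
  expect_lt(out$p_value, 1e-6)
})

test_that("degenerate contrasts and fits raise informative errors", {
  d <- data.frame(pmr = c(1, 2, 3, 4), surrogate = c(1, 2, 50, 60),
                  group = factor(c("1", "1", "2", "2")))
  expect_error(
    fit_group_comparison(d, method_spec("ols_thresh", threshold = 10)),
    "zero-weighted")
  d2 <- data.frame(pmr = rep(c(0, 5), each = 10), surrogate = 1:20,
                   group = factor(rep(c("1", "2"), each = 10)))
  expect_error(fit_group_comparison(d2, method_spec("ols_pmr")),
               "degenerate fit")
})

test_that("the suite runs all requested methods and tolerates failures", {
  d <- make_dataset(seed = 99)
  res <- run_method_suite(d)
  expect_equal(nrow(res), 6)
  expect_true(all(is.na(res$error)))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$method[1:2], c("ols_pmr", "ols_log"))
  # a failing threshold does not abort the others
  d$surrogate <- pmin(d$surrogate, 5)
  res2 <- run_method_suite(d, list(method_spec("ols_thresh", threshold = 10),
                                   method_spec("ols_pmr")))
  expect_true(is.na(res2$p_value[1]) && !is.na(res2$error[1]))
  expect_false(is.na(res2$p_value[2]))
  expect_equal(nrow(run_method_suite(d, list())), 0)
})

test_that("log-scale variants label and transform correctly", {
  d <- make_dataset(seed = 111)
  m <- method_spec("wls_w", log_scale = TRUE)
  expect_equal(method_label(m), "wls_w(41)+log")
  out <- fit_group_comparison(d, m)
  # estimate lives on the log scale: bounded by the log-range of the data
  expect_lt(abs(out$estimate), diff(range(log_transform(d$pmr))))
})
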