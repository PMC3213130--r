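# Two-group comparison tests for PMR data: ordinary least squares on the raw
# or log scale, threshold-filtered OLS, and the two empirically weighted
# least squares tests (quantile- and window-based inverse-variance weights).
#
# All tests reduce to a weighted least squares regression of the outcome on
# a binary group indicator; the scheme supplies the weights (uniform for
# OLS, 0/1 for thresholding, inverse empirical variance for WLS-Q/WLS-W).
# With a single binary predictor the fit has a closed form, used here for
# speed in large simulation studies; it agrees with lm(y ~ g, weights = w)
# to machine precision.

#' Log transform for skewed PMR outcomes
#'
#' ln(PMR + 1): maps 0 to 0, compresses the long right tail, strictly
#' increasing.
#'
#' @param pmr Non-negative PMR values.
#' @return log(pmr + 1).
#' @export
log_transform <- function(pmr) {
  if (any(pmr < 0)) stop("PMR values must be non-negative")
  log1p(pmr)
}

#' Specify an analysis method
#'
#' @param name One of `"ols_pmr"` (OLS on raw PMR), `"ols_log"` (OLS on
#'   ln(PMR+1)), `"ols_thresh"` (OLS after excluding low-DNA observations),
#'   `"wls_q"` (quantile-based inverse-variance WLS), `"wls_w"`
#'   (window-based inverse-variance WLS).
#' @param log_scale Analyse ln(PMR+1) instead of raw PMR.  Implied by
#'   `"ols_log"`.
#' @param k Number of quantile bins for `"wls_q"` (default 5).
#' @param w Window size for `"wls_w"` (default 41, must be odd).
#' @param threshold Minimum effective DNA quantity for `"ols_thresh"`
#'   (default 1 genome equivalent; 10 is the stricter conventional cut).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `method_spec`.
#' @examples
#' method_spec("wls_w")
#' method_spec("ols_thresh", threshold = 10)
#' @export
method_spec <- function(name = c("ols_pmr", "ols_log", "ols_thresh",
                                 "wls_q", "wls_w"),
                        log_scale = FALSE, k = 5L, w = 41L,
                        threshold = 1, alpha = 0.05) {
  name <- match.arg(name)
  stopifnot(alpha > 0, alpha < 1)
  if (name == "ols_log") log_scale <- TRUE
  structure(
    list(name = name, log_scale = log_scale, k = as.integer(k),
         w = as.integer(w), threshold = threshold, alpha = alpha),
    class = "method_spec"
  )
}

#' Display label for a method
#'
#' @param method A [method_spec()].
#' @return Character label such as `"wls_w(41)"` or `"ols_thresh(10)+log"`.
#' @export
method_label <- function(method) {
  base <- switch(method$name,
    ols_pmr = "ols_pmr",
    ols_log = "ols_log",
    ols_thresh = sprintf("ols_thresh(%g)", method$threshold),
    wls_q = sprintf("wls_q(%d)", method$k),
    wls_w = sprintf("wls_w(%d)", method$w))
  if (method$log_scale && method$name != "ols_log")
    base <- paste0(base, "+log")
  base
}

#' The standard six-method suite
#'
#' OLS on raw PMR, OLS on ln(PMR+1), threshold-filtered OLS at 1 and 10
#' genome equivalents, and the two inverse-variance WLS tests (quintiles
#' k = 5, window w = 41).
#'
#' @param alpha Significance level applied to every method.
#' @return List of [method_spec()] objects.
#' @export
default_method_suite <- function(alpha = 0.05) {
  list(
    method_spec("ols_pmr", alpha = alpha),
    method_spec("ols_log", alpha = alpha),
    method_spec("ols_thresh", threshold = 1, alpha = alpha),
    method_spec("ols_thresh", threshold = 10, alpha = alpha),
    method_spec("wls_q", k = 5L, alpha = alpha),
    method_spec("wls_w", w = 41L, alpha = alpha)
  )
}

# Closed-form WLS of y on (intercept, group indicator) with fixed weights.
# Equivalent to summary(lm(y ~ g, weights = w)): estimate is the difference
# in weighted group means, residual variance is the weighted RSS over
# n_eff - 2 degrees of freedom (n_eff = observations with positive weight),
# Var(estimate) = s2 * (1/W1 + 1/W2) with Wg the group weight totals.
.wls_two_group <- function(y, g2, w) {
  pos <- w > 0
  n_eff <- sum(pos)
  if (!any(pos & g2) || !any(pos & !g2))
    stop("a group is entirely zero-weighted; contrast not estimable")
  if (n_eff < 3)
    stop("fewer than 3 positively weighted observations")
  w1 <- sum(w[!g2]); w2 <- sum(w[g2])
  m1 <- sum(w[!g2] * y[!g2]) / w1
  m2 <- sum(w[g2] * y[g2]) / w2
  fitted <- ifelse(g2, m2, m1)
  rss <- sum(w * (y - fitted)^2)
  df <- n_eff - 2
  s2 <- rss / df
  if (s2 <= 0)
    stop("degenerate fit: zero weighted residual variance")
  se <- sqrt(s2 * (1 / w1 + 1 / w2))
  est <- m2 - m1
  tval <- est / se
  list(estimate = est, std_error = se,
       p_value = 2 * stats::pt(-abs(tval), df), n_effective = n_eff)
}

# Resolve a method_spec to a weight scheme for the given data.
.weights_for_method <- function(method, pmr, surrogate, orientation) {
  switch(method$name,
    ols_pmr = ,
    ols_log = uniform_weights(length(pmr)),
    ols_thresh = threshold_weights(surrogate, method$threshold, orientation),
    wls_q = quantile_variances(pmr, surrogate, k = method$k,
                               orientation = orientation),
    wls_w = window_variances(pmr, surrogate, w = method$w,
                             orientation = orientation))
}

#' Test for differential methylation between two groups
#'
#' Fits a weighted least squares regression of the PMR outcome (raw or
#' ln(PMR+1)) on a binary group indicator, with weights determined by the
#' method: uniform (OLS), 0/1 (threshold filter), or empirical
#' inverse-variance (WLS-Q / WLS-W).  Weights are always estimated from the
#' raw-scale or log-scale outcome actually analysed, treated as known in the
#' fit, and the two-sided p-value uses the t distribution with
#' `n_effective - 2` degrees of freedom.
#'
#' @param data Data frame with columns `pmr`, `surrogate` and `group` (two
#'   levels), e.g. from [simulate_dataset()] or [read_pmr_table()].
#' @param method A [method_spec()].
#' @param orientation Surrogate orientation: `"quantity"` or `"ct"`.
#' @return An object of class `test_outcome`: list with `estimate` (group-2
#'   minus group-1 mean on the analysis scale), `std_error`, `p_value`,
#'   `n_effective`, `method` and `label`.
#' @examples
#' set.seed(11)
#' d <- simulate_dataset(get_scenario("a.i"))
#' fit_group_comparison(d, method_spec("wls_q"))
#' @export
fit_group_comparison <- function(data, method = method_spec("ols_pmr"),
                                 orientation = "quantity") {
  stopifnot(inherits(method, "method_spec"),
            all(c("pmr", "surrogate", "group") %in% names(data)))
  grp <- factor(data$group)
  if (nlevels(grp) != 2)
    stop("'group' must have exactly two levels; found ", nlevels(grp))
  y <- if (method$log_scale) log_transform(data$pmr) else data$pmr
  scheme <- .weights_for_method(method, y, data$surrogate, orientation)
  fit <- .wls_two_group(y, grp == levels(grp)[2], scheme$weights)
  structure(
    c(fit, list(method = method, label = method_label(method),
                scheme = scheme)),
    class = "test_outcome"
  )
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(sprintf("%s: estimate = %.4g (SE %.4g), p = %.3g, n_eff = %d\n",
              x$label, x$estimate, x$std_error, x$p_value, x$n_effective))
  invisible(x)
}

#' Run several analysis methods on one dataset
#'
#' Applies each method to the same data.  A method that fails (for example a
#' threshold that empties one group) yields a row of `NA`s with the error
#' message recorded; the remaining methods still run.
#'
#' @param data As in [fit_group_comparison()].
#' @param methods List of [method_spec()]s; default the six-method suite.
#' @param orientation Surrogate orientation.
#' @return Data frame with one row per method: `method`, `estimate`,
#'   `std_error`, `p_value`, `n_effective`, `error`.
#' @export
run_method_suite <- function(data, methods = default_method_suite(),
                             orientation = "quantity") {
  fits <- .suite_fits(data, methods, orientation)
  data.frame(
    method = vapply(seq_along(methods), function(i) {
      f <- fits[[i]]
      if (is.null(f$label)) method_label(methods[[i]]) else f$label
    }, character(1)),
    estimate = vapply(fits, function(f) f$estimate %||% NA_real_, numeric(1)),
    std_error = vapply(fits, function(f) f$std_error %||% NA_real_, numeric(1)),
    p_value = vapply(fits, function(f) f$p_value %||% NA_real_, numeric(1)),
    n_effective = vapply(fits, function(f) f$n_effective %||% NA_integer_,
                         integer(1)),
    error = vapply(fits, function(f) f$error %||% NA_character_, character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fit every method, trapping per-method errors; shared preparation (group
# coding, log transform) is done once.  Used by both run_method_suite and
# the replicate engine, which only keeps the p-values.
.suite_fits <- function(data, methods, orientation) {
  grp <- factor(data$group)
  if (nlevels(grp) != 2)
    stop("'group' must have exactly two levels; found ", nlevels(grp))
  g2 <- grp == levels(grp)[2]
  pmr_raw <- data$pmr
  any_log <- any(vapply(methods, function(m) m$log_scale, logical(1)))
  pmr_log <- if (any_log) log_transform(pmr_raw) else NULL
  lapply(methods, function(m) {
    out <- tryCatch({
      y <- if (m$log_scale) pmr_log else pmr_raw
      scheme <- .weights_for_method(m, y, data$surrogate, orientation)
      fit <- .wls_two_group(y, g2, scheme$weights)
      c(fit, list(label = method_label(m), error = NA_character_))
    }, error = function(e) list(error = conditionMessage(e)))
    out
  })
}
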