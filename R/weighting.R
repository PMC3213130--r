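# Empirical estimation of PMR variance as a function of a DNA-quantity
# surrogate, and its conversion to regression weights.
#
# Variances are always estimated from the two comparison groups pooled: the
# measurement noise under study depends on input DNA quantity only, not on
# the grouping variable.  Ranking is by increasing *effective* DNA quantity,
# so a C(t)-type surrogate (more cycles = less DNA) is ranked in decreasing
# surrogate order.

# Weights become 1/variance; a bin of identical PMRs (e.g. all zero at very
# low input) has variance 0, so variances are floored to keep weights
# finite.  The floor is negligible relative to any well-behaved bin and a
# fully degenerate dataset collapses to equal weights, i.e. OLS.
.variance_floor <- function(v) {
  max(.Machine$double.eps, 1e-8 * max(v))
}

.check_orientation <- function(orientation) {
  if (is.null(orientation) || is.na(orientation) || !nzchar(orientation))
    stop("surrogate orientation must be declared: 'quantity' (larger value ",
         "= more DNA) or 'ct' (larger value = less DNA)")
  match.arg(orientation, c("quantity", "ct"))
}

#' Rank observations by increasing effective DNA quantity
#'
#' Returns the permutation that orders observations from least to most input
#' DNA.  For a quantity-like surrogate (genome equivalents, absorbance) this
#' is increasing surrogate order; for a C(t)-like surrogate it is decreasing,
#' since more amplification cycles mean less DNA.  Ties keep input order.
#'
#' @param surrogate Numeric surrogate measurements, all finite.
#' @param orientation `"quantity"` or `"ct"`.
#' @return Integer permutation of `seq_along(surrogate)`.
#' @examples
#' rank_by_surrogate(c(3, 1, 2), "quantity")  # 2 3 1
#' rank_by_surrogate(c(3, 1, 2), "ct")        # 1 3 2
#' @export
rank_by_surrogate <- function(surrogate, orientation = "quantity") {
  orientation <- .check_orientation(orientation)
  if (length(surrogate) == 0L) stop("empty observation list")
  if (any(!is.finite(surrogate))) stop("surrogate values must be finite")
  key <- if (orientation == "ct") -surrogate else surrogate
  order(key)  # radix order: stable, ties by original index
}

.new_weight_scheme <- function(method, variances, weights, params = list()) {
  structure(
    list(method = method, params = params,
         variances = variances, weights = weights),
    class = "weight_scheme"
  )
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Weight scheme:", x$method)
  if (length(x$params))
    cat(" (", paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "), ")", sep = "")
  cat("\n  n =", length(x$weights),
      " weight range: [", format(min(x$weights), digits = 4), ",",
      format(max(x$weights), digits = 4), "]\n")
  invisible(x)
}

#' Audit table for a weight scheme
#'
#' @param x A `weight_scheme`.
#' @param ... Unused.
#' @return Data frame with columns `variance` and `weight` in input order.
#' @export
as.data.frame.weight_scheme <- function(x, ...) {
  data.frame(variance = x$variances, weight = x$weights)
}

# Split n ranked observations into k contiguous blocks of size floor(n/k),
# distributing the remainder one-per-block starting from the lowest-quantity
# block.  Returns the block index for each rank.
.quantile_blocks <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  rep.int(seq_len(k), sizes)
}

#' Quantile-binned variance weights (WLS-Q)
#'
#' Orders observations by increasing effective DNA quantity, splits them
#' into `k` contiguous, nearly equal bins, and assigns every observation the
#' sample variance (n-1 denominator) of PMR within its bin.  Weights are the
#' reciprocal of the (floored) variances.  With the default k = 5 and 200
#' observations each quintile holds 40 observations.
#'
#' @param pmr Non-negative PMR values.
#' @param surrogate DNA-quantity surrogate, same length.
#' @param k Number of quantile bins (default 5).
#' @param orientation Surrogate orientation, see [rank_by_surrogate()].
#' @return A `weight_scheme` with per-observation variances and weights in
#'   the original input order.
#' @export
quantile_variances <- function(pmr, surrogate, k = 5L,
                               orientation = "quantity") {
  n <- length(pmr)
  stopifnot(length(surrogate) == n, k >= 1)
  if (n < 2 * k)
    stop("need at least 2 observations per quantile bin: n = ", n,
         " < 2k = ", 2 * k)
  ord <- rank_by_surrogate(surrogate, orientation)
  blocks <- .quantile_blocks(n, k)
  v_block <- vapply(split(pmr[ord], blocks), stats::var, numeric(1))
  v_ranked <- v_block[blocks]
  variances <- numeric(n)
  variances[ord] <- v_ranked
  floor_v <- .variance_floor(variances)
  .new_weight_scheme("quantile", variances, 1 / pmax(variances, floor_v),
                     params = list(k = k))
}

#' Sliding-window variance weights (WLS-W)
#'
#' Orders observations by increasing effective DNA quantity and estimates
#' each observation's PMR variance over a centred window of `w` ranked
#' observations ((w-1)/2 on each side).  The (w-1)/2 lowest-ranked
#' observations, whose window cannot be centred, share the variance of the
#' `w` bottom-most observations, and symmetrically at the top.  Weights are
#' inverse floored variances.
#'
#' @inheritParams quantile_variances
#' @param w Odd window size (default 41).
#' @return A `weight_scheme` in original input order.
#' @export
window_variances <- function(pmr, surrogate, w = 41L,
                             orientation = "quantity") {
  n <- length(pmr)
  stopifnot(length(surrogate) == n)
  if (w %% 2 == 0) stop("window size must be odd (centred windows); got ", w)
  if (w < 3) stop("window size must be at least 3")
  if (n < w) stop("need at least w observations: n = ", n, " < w = ", w)
  ord <- rank_by_surrogate(surrogate, orientation)
  y <- pmr[ord]
  m <- (w - 1L) %/% 2L
  # windowed sums via zero-prepended cumulative sums; sample variance with
  # n-1 denominator
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  win_var <- function(lo, hi) {
    s <- cs[hi + 1L] - cs[lo]
    s2 <- cs2[hi + 1L] - cs2[lo]
    (s2 - s^2 / w) / (w - 1)
  }
  idx <- seq_len(n)
  lo <- pmin(pmax(idx - m, 1L), n - w + 1L)
  v_ranked <- win_var(lo, lo + w - 1L)
  v_ranked <- pmax(v_ranked, 0)  # guard tiny negative from cancellation
  variances <- numeric(n)
  variances[ord] <- v_ranked
  floor_v <- .variance_floor(variances)
  .new_weight_scheme("window", variances, 1 / pmax(variances, floor_v),
                     params = list(w = w))
}

#' Threshold (0/1) weights
#'
#' The inclusion/exclusion filter as a weighting scheme: weight 1 for
#' observations whose effective DNA quantity exceeds `min_quantity`, 0
#' otherwise.  With a quantity-like surrogate the cut is `surrogate >
#' min_quantity`; with a C(t)-like surrogate it is `surrogate <
#' min_quantity` (fewer cycles = more DNA).
#'
#' @param surrogate DNA-quantity surrogate.
#' @param min_quantity Inclusion threshold, on the surrogate scale.
#' @param orientation Surrogate orientation; must be declared.
#' @return A `weight_scheme` with 0/1 weights (variances reported as 1).
#' @export
threshold_weights <- function(surrogate, min_quantity,
                              orientation = "quantity") {
  orientation <- .check_orientation(orientation)
  keep <- if (orientation == "ct") surrogate < min_quantity
          else surrogate > min_quantity
  if (!any(keep))
    stop("threshold ", min_quantity, " excludes every observation")
  .new_weight_scheme("threshold", rep(1, length(surrogate)), as.numeric(keep),
                     params = list(t = min_quantity))
}

#' Uniform weights
#'
#' All-equal weights: weighted least squares with this scheme is ordinary
#' least squares.
#'
#' @param n Number of observations.
#' @return A `weight_scheme` of unit weights.
#' @export
uniform_weights <- function(n) {
  .new_weight_scheme("uniform", rep(1, n), rep(1, n))
}
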