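# Population-level models: the distribution of true methylation proportions
# within each patient group (Beta, optionally zero-inflated through a
# Bernoulli positivity indicator) and the distribution of DNA input quantity
# across specimens, plus the registry of named simulation scenarios.

#' Beta shape parameters from mean and variance
#'
#' Inverts the first two moments of a Beta distribution:
#' with k = mean (1 - mean) / var - 1, alpha = mean k and beta = (1 - mean) k.
#' The variance must respect the Beta feasibility bound
#' var < mean (1 - mean).
#'
#' @param mean Target mean in (0, 1).
#' @param var Target variance (> 0).
#' @return Named numeric vector `c(alpha =, beta =)`.
#' @examples
#' beta_from_moments(0.2, 0.01)  # Beta(3, 12)
#' @export
beta_from_moments <- function(mean, var) {
  stopifnot(length(mean) == 1L, length(var) == 1L,
            mean > 0, mean < 1, var > 0)
  bound <- mean * (1 - mean)
  if (var >= bound)
    stop(sprintf(
      "infeasible Beta variance: var = %g must be < mean(1-mean) = %g",
      var, bound))
  k <- bound / var - 1
  c(alpha = mean * k, beta = (1 - mean) * k)
}

#' Group-level distribution of true methylation proportions
#'
#' Each tumour in a group is methylation-positive with probability
#' `positivity_prob`; a positive tumour's true methylated proportion p is
#' drawn from a Beta distribution parameterised by its mean and variance,
#' and a negative tumour has p = 0.  `positivity_prob = 1` gives a pure Beta
#' population.
#'
#' @param beta_mean Mean of the Beta component, in (0, 1).
#' @param beta_var Variance of the Beta component (feasible for the mean).
#' @param positivity_prob Bernoulli probability a tumour is
#'   methylation-positive, in `[0, 1]`.  Default 1.
#' @return An object of class `group_distribution`.
#' @export
group_distribution <- function(beta_mean, beta_var, positivity_prob = 1) {
  stopifnot(length(positivity_prob) == 1L,
            positivity_prob >= 0, positivity_prob <= 1)
  shapes <- beta_from_moments(beta_mean, beta_var)
  structure(
    list(beta_mean = beta_mean, beta_var = beta_var,
         positivity_prob = positivity_prob,
         alpha = unname(shapes["alpha"]), beta = unname(shapes["beta"])),
    class = "group_distribution"
  )
}

#' Overall mean and variance of a group distribution
#'
#' Moments of the Bernoulli-Beta mixture: mean pi * mu and variance
#' pi * (sigma^2 + mu^2) - (pi * mu)^2, reducing to the Beta moments when
#' pi = 1.
#'
#' @param dist A [group_distribution()].
#' @return Named vector `c(mean =, var =)`.
#' @export
group_moments <- function(dist) {
  stopifnot(inherits(dist, "group_distribution"))
  pi <- dist$positivity_prob
  mu <- dist$beta_mean
  s2 <- dist$beta_var
  c(mean = pi * mu, var = pi * (s2 + mu^2) - (pi * mu)^2)
}

#' Two-group simulation scenario
#'
#' Pairs a group-level methylation distribution for each of two patient
#' groups with the group sample sizes.  Under a null scenario the two groups
#' share one distribution.
#'
#' @param label Scenario identifier.
#' @param group1,group2 [group_distribution()] objects.
#' @param n1,n2 Group sample sizes (positive integers).  Defaults 100/100.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, group1, group2, n1 = 100L, n2 = 100L) {
  stopifnot(inherits(group1, "group_distribution"),
            inherits(group2, "group_distribution"),
            n1 >= 1, n2 >= 1)
  structure(
    list(label = label, group1 = group1, group2 = group2,
         n1 = as.integer(n1), n2 = as.integer(n2)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  fmt <- function(g) sprintf("pi=%.2f Beta(mean=%.2f, var=%.2f)",
                             g$positivity_prob, g$beta_mean, g$beta_var)
  cat("Scenario", x$label, "\n")
  cat("  group 1 (n=", x$n1, "): ", fmt(x$group1), "\n", sep = "")
  cat("  group 2 (n=", x$n2, "): ", fmt(x$group2), "\n", sep = "")
  invisible(x)
}

#' DNA-quantity model
#'
#' Specimens' genome-equivalent input Q follows
#' log10 Q = log10_cap - L with L lognormal (meanlog `log_mean`, sdlog
#' `log_sd`).  Since L > 0, Q is capped at 10^log10_cap.  At the defaults
#' (cap 2.74, sdlog 0.75) the maximum is about 550 genomes, about 23% of
#' specimens carry fewer than 10 genomes and about 9% fewer than 1 — the
#' shape seen for archival colorectal tumour DNA.
#'
#' @param log10_cap Upper bound of log10 genome count.  Default 2.74.
#' @param log_sd Standard deviation of log L.  Default 0.75.
#' @param log_mean Mean of log L.  Default 0.
#' @return An object of class `quantity_model`.
#' @export
quantity_model <- function(log10_cap = 2.74, log_sd = 0.75, log_mean = 0) {
  stopifnot(is.finite(log10_cap), log_sd > 0, is.finite(log_mean))
  structure(
    list(log10_cap = log10_cap, log_sd = log_sd, log_mean = log_mean),
    class = "quantity_model"
  )
}

#' Sample DNA quantities (genome equivalents)
#'
#' @param model A [quantity_model()].
#' @param n Number of draws.
#' @return Positive numeric vector, bounded above by 10^log10_cap.
#' @export
sample_dna_quantity <- function(model = quantity_model(), n) {
  stopifnot(inherits(model, "quantity_model"), n >= 1)
  L <- stats::rlnorm(n, meanlog = model$log_mean, sdlog = model$log_sd)
  10^(model$log10_cap - L)
}

#' Analytic CDF of the DNA-quantity model
#'
#' P(Q < q) = P(L > log10_cap - log10 q), from the lognormal law of L.
#'
#' @param model A [quantity_model()].
#' @param q Genome-equivalent values (vectorised).
#' @return P(Q < q) for each q.
#' @examples
#' quantity_cdf(quantity_model(), c(1, 10))  # about 0.09 and 0.23
#' @export
quantity_cdf <- function(model = quantity_model(), q) {
  stopifnot(inherits(model, "quantity_model"))
  out <- numeric(length(q))
  pos <- q > 0
  out[pos] <- 1 - stats::plnorm(model$log10_cap - log10(q[pos]),
                                meanlog = model$log_mean,
                                sdlog = model$log_sd)
  out
}

#' Sample true methylation proportions for one group
#'
#' Each draw is 0 with probability 1 - positivity_prob, otherwise a Beta
#' deviate with the group's shape parameters.
#'
#' @param dist A [group_distribution()].
#' @param n Number of tumours.
#' @return Numeric vector in `[0, 1]`.
#' @export
sample_true_proportions <- function(dist, n) {
  stopifnot(inherits(dist, "group_distribution"), n >= 1)
  p <- numeric(n)
  positive <- stats::runif(n) < dist$positivity_prob
  if (any(positive))
    p[positive] <- stats::rbeta(sum(positive), dist$alpha, dist$beta)
  p
}

#' Registry of named simulation scenarios
#'
#' Returns the standard scenario set: nine alternatives and six nulls, all
#' with 200 tumours (100 per group) by default.
#'
#' Alternatives cross two Beta mean pairs (`a`: 0.20 vs 0.27; `b`: 0.40 vs
#' 0.47; both an overall-mean difference of 0.07) with three variance
#' patterns (`i`: 0.01/0.01, `ii`: 0.04/0.04, `iii`: 0.01/0.04); the `c`
#' scenarios are Bernoulli-Beta mixtures with positivity 0.5 vs 0.7 over the
#' `b` Beta components (overall-mean difference 0.13).  Nulls use identical
#' distributions in both groups: the four pure Betas crossing means
#' {0.2, 0.4} with variances {0.01, 0.04} (`null.a.i`, `null.a.ii`,
#' `null.b.i`, `null.b.ii`) and two mixtures at positivity 0.67 over the
#' `b.i`/`b.ii` Betas (`null.c.i`, `null.c.ii`).
#'
#' @param n1,n2 Group sample sizes applied to every scenario.
#' @return Named list of [scenario_spec()] objects.
#' @export
scenario_registry <- function(n1 = 100L, n2 = 100L) {
  g <- group_distribution
  alt <- list(
    a.i   = scenario_spec("a.i",   g(0.20, 0.01), g(0.27, 0.01), n1, n2),
    a.ii  = scenario_spec("a.ii",  g(0.20, 0.04), g(0.27, 0.04), n1, n2),
    a.iii = scenario_spec("a.iii", g(0.20, 0.01), g(0.27, 0.04), n1, n2),
    b.i   = scenario_spec("b.i",   g(0.40, 0.01), g(0.47, 0.01), n1, n2),
    b.ii  = scenario_spec("b.ii",  g(0.40, 0.04), g(0.47, 0.04), n1, n2),
    b.iii = scenario_spec("b.iii", g(0.40, 0.01), g(0.47, 0.04), n1, n2),
    c.i   = scenario_spec("c.i",   g(0.40, 0.01, 0.5), g(0.47, 0.01, 0.7), n1, n2),
    c.ii  = scenario_spec("c.ii",  g(0.40, 0.04, 0.5), g(0.47, 0.04, 0.7), n1, n2),
    c.iii = scenario_spec("c.iii", g(0.40, 0.01, 0.5), g(0.47, 0.04, 0.7), n1, n2)
  )
  null_of <- function(lbl, dist) scenario_spec(lbl, dist, dist, n1, n2)
  nulls <- list(
    null.a.i  = null_of("null.a.i",  g(0.20, 0.01)),
    null.a.ii = null_of("null.a.ii", g(0.20, 0.04)),
    null.b.i  = null_of("null.b.i",  g(0.40, 0.01)),
    null.b.ii = null_of("null.b.ii", g(0.40, 0.04)),
    null.c.i  = null_of("null.c.i",  g(0.40, 0.01, 0.67)),
    null.c.ii = null_of("null.c.ii", g(0.40, 0.04, 0.67))
  )
  c(alt, nulls)
}

#' Look up a scenario by label
#'
#' @param label A registry label such as `"a.i"` or `"null.b.ii"`.
#' @inheritParams scenario_registry
#' @return A [scenario_spec()].
#' @export
get_scenario <- function(label, n1 = 100L, n2 = 100L) {
  reg <- scenario_registry(n1, n2)
  if (!label %in% names(reg))
    stop("unknown scenario label '", label, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[label]]
}

#' Split a total sample size by ratio
#'
#' Returns (n1, n2) for a total of `n_total` tumours at ratio `"1:1"`,
#' `"1:2"` or `"2:1"`.  When the split is not exact the smaller group takes
#' the nearest integer (200 at 1:2 gives 67/133).
#'
#' @param n_total Total sample size.
#' @param ratio One of `"1:1"`, `"1:2"`, `"2:1"`.
#' @return Integer vector `c(n1, n2)` summing to `n_total`.
#' @export
split_sample_sizes <- function(n_total, ratio = c("1:1", "1:2", "2:1")) {
  ratio <- match.arg(ratio)
  n_total <- as.integer(n_total)
  stopifnot(n_total >= 2)
  small <- as.integer(round(n_total / 3))
  switch(ratio,
    "1:1" = c(n_total %/% 2L, n_total - n_total %/% 2L),
    "1:2" = c(small, n_total - small),
    "2:1" = c(n_total - small, small))
}

#' Simulate a two-group PMR dataset
#'
#' Draws, for each tumour, a true methylated proportion from its group's
#' distribution and a DNA quantity from the quantity model, then simulates
#' the PMR measurement by binomial fragment sampling.  Group membership is
#' fixed by count (the first `n1` tumours form group 1), so every dataset
#' has exact group sizes.
#'
#' @param spec A [scenario_spec()].
#' @param consts A [sim_constants()].
#' @param qmodel A [quantity_model()].
#' @return A data frame with columns `id`, `pmr`, `surrogate` (the
#'   genome-equivalent DNA quantity; larger means more DNA), `group` (factor
#'   with levels `"1"`, `"2"`), and audit columns `genomes` and `p_true`.
#' @examples
#' set.seed(7)
#' head(simulate_dataset(get_scenario("a.i")))
#' @export
simulate_dataset <- function(spec, consts = sim_constants(),
                             qmodel = quantity_model()) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n1 + spec$n2
  p <- c(sample_true_proportions(spec$group1, spec$n1),
         sample_true_proportions(spec$group2, spec$n2))
  h <- sample_dna_quantity(qmodel, n)
  pmr <- simulate_pmr(h, p, consts)
  data.frame(
    id = sprintf("s%03d", seq_len(n)),
    pmr = pmr,
    surrogate = h,
    group = factor(rep(c("1", "2"), c(spec$n1, spec$n2))),
    genomes = h,
    p_true = p
  )
}
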