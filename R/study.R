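# Replicate engine for power and false-positive-rate experiments: simulate
# many datasets under a scenario, apply a suite of analysis methods to each,
# and aggregate rejection rates with Monte-Carlo standard errors.
#
# Reproducibility contract: a study config carries one integer seed; a
# vector of per-replicate seeds is drawn from it up front, so each replicate
# runs on its own substream and results do not depend on execution order.

#' Configure a simulation study
#'
#' @param scenario A registry label (see [scenario_registry()]) or a
#'   [scenario_spec()].
#' @param n_total Total tumours per replicate dataset (default 200).
#' @param ratio Group sample-size ratio: `"1:1"`, `"1:2"` or `"2:1"`.
#' @param replicates Number of replicate datasets.  Conventional sizes:
#'   10000 for null (false-positive) studies, 1000 for power.
#' @param alpha Significance level (default 0.05).
#' @param seed Integer master seed.
#' @param methods List of [method_spec()]s (default six-method suite).
#' @param consts [sim_constants()].
#' @param qmodel [quantity_model()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(scenario, n_total = 200L, ratio = "1:1",
                         replicates = 1000L, alpha = 0.05, seed = 1L,
                         methods = default_method_suite(alpha),
                         consts = sim_constants(),
                         qmodel = quantity_model()) {
  stopifnot(replicates >= 1, alpha > 0, alpha < 1)
  sizes <- split_sample_sizes(n_total, ratio)
  spec <- if (inherits(scenario, "scenario_spec")) {
    scenario_spec(scenario$label, scenario$group1, scenario$group2,
                  sizes[1], sizes[2])
  } else {
    get_scenario(scenario, sizes[1], sizes[2])
  }
  structure(
    list(spec = spec, n_total = as.integer(n_total), ratio = ratio,
         replicates = as.integer(replicates), alpha = alpha,
         seed = as.integer(seed), methods = methods,
         consts = consts, qmodel = qmodel),
    class = "study_config"
  )
}

#' Run a simulation study
#'
#' For each replicate: derive the replicate's seed, simulate a dataset under
#' the configured scenario, run every analysis method, and record whether
#' each rejects at the configured level.  Replicates where a method errors
#' (for example a degenerate all-zero group) are excluded from that method's
#' denominator and counted as failures; a failure fraction above 1% raises a
#' warning.
#'
#' @param config A [study_config()].
#' @return An object of class `study_result`: data frame `rates` with one
#'   row per method (`method`, `rejections`, `used`, `failures`,
#'   `rejection_rate`, `mc_std_error`) plus the config.
#' @examples
#' res <- run_study(study_config("a.i", replicates = 20, seed = 3))
#' res$rates
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  reps <- config$replicates
  labels <- vapply(config$methods, method_label, character(1))
  nm <- length(labels)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  reject <- matrix(NA, nrow = reps, ncol = nm, dimnames = list(NULL, labels))
  spec <- config$spec
  g2 <- rep(c(FALSE, TRUE), c(spec$n1, spec$n2))
  any_log <- any(vapply(config$methods, function(m) m$log_scale, logical(1)))
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    p <- c(sample_true_proportions(spec$group1, spec$n1),
           sample_true_proportions(spec$group2, spec$n2))
    h <- sample_dna_quantity(config$qmodel, spec$n1 + spec$n2)
    pmr <- simulate_pmr(h, p, config$consts)
    pmr_log <- if (any_log) log_transform(pmr) else NULL
    pv <- vapply(config$methods, function(m) {
      tryCatch({
        y <- if (m$log_scale) pmr_log else pmr
        scheme <- .weights_for_method(m, y, h, "quantity")
        .wls_two_group(y, g2, scheme$weights)$p_value
      }, error = function(e) NA_real_)
    }, numeric(1))
    reject[r, ] <- pv <= config$alpha
  }
  used <- colSums(!is.na(reject))
  rejections <- colSums(reject, na.rm = TRUE)
  rate <- rejections / used
  failures <- reps - used
  if (any(failures / reps > 0.01))
    warning("method(s) ", paste(labels[failures / reps > 0.01], collapse = ", "),
            " failed on more than 1% of replicates")
  rates <- data.frame(
    method = labels,
    rejections = rejections,
    used = used,
    failures = failures,
    rejection_rate = rate,
    mc_std_error = sqrt(rate * (1 - rate) / used),
    row.names = NULL
  )
  structure(list(rates = rates, config = config), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Study: scenario %s, n = %d (%s), %d replicates, alpha = %g\n",
              x$config$spec$label, x$config$n_total, x$config$ratio,
              x$config$replicates, x$config$alpha))
  df <- x$rates
  df$rejection_rate <- sprintf("%.3f", df$rejection_rate)
  df$mc_std_error <- sprintf("%.4f", df$mc_std_error)
  print(df, row.names = FALSE)
  invisible(x)
}

# Shared grid runner: one study per scenario label, rows = scenarios,
# columns = methods, cells = rejection rates.
.study_grid <- function(labels, methods, replicates, n_total, ratio,
                        alpha, seed, consts, qmodel) {
  studies <- lapply(seq_along(labels), function(i) {
    run_study(study_config(labels[i], n_total = n_total, ratio = ratio,
                           replicates = replicates, alpha = alpha,
                           seed = seed + i - 1L, methods = methods,
                           consts = consts, qmodel = qmodel))
  })
  names(studies) <- labels
  wide <- do.call(rbind, lapply(labels, function(l) {
    r <- studies[[l]]$rates
    stats::setNames(as.data.frame(as.list(r$rejection_rate)), r$method)
  }))
  wide <- cbind(scenario = labels, wide)
  rownames(wide) <- NULL
  list(table = wide, studies = studies)
}

#' Power table across alternative scenarios
#'
#' Runs one power study per alternative scenario and tabulates rejection
#' rates (scenario rows, method columns).  Detail per-method counts and
#' Monte-Carlo errors are kept in `$studies`.
#'
#' @param scenarios Character vector of registry labels; default the nine
#'   alternatives.
#' @param methods Method list; default the six-method suite.
#' @param replicates Replicates per scenario (default 1000).
#' @param n_total,ratio,alpha,seed,consts,qmodel As in [study_config()].
#' @return List with `table` (data frame of rejection rates) and `studies`
#'   (named list of `study_result`s).
#' @export
power_table <- function(scenarios = c("a.i", "a.ii", "a.iii",
                                      "b.i", "b.ii", "b.iii",
                                      "c.i", "c.ii", "c.iii"),
                        methods = default_method_suite(alpha),
                        replicates = 1000L, n_total = 200L, ratio = "1:1",
                        alpha = 0.05, seed = 1L,
                        consts = sim_constants(), qmodel = quantity_model()) {
  stopifnot(length(scenarios) >= 1)
  .study_grid(scenarios, methods, replicates, n_total, ratio, alpha, seed,
              consts, qmodel)
}

#' False-positive-rate table across null scenarios
#'
#' As [power_table()] over the six null scenarios, conventionally at 10000
#' replicates; every entry should lie within Monte-Carlo error of the
#' nominal level.
#'
#' @inheritParams power_table
#' @export
fpr_table <- function(scenarios = c("null.a.i", "null.a.ii",
                                    "null.b.i", "null.b.ii",
                                    "null.c.i", "null.c.ii"),
                      methods = default_method_suite(alpha),
                      replicates = 10000L, n_total = 200L, ratio = "1:1",
                      alpha = 0.05, seed = 1L,
                      consts = sim_constants(), qmodel = quantity_model()) {
  stopifnot(length(scenarios) >= 1)
  .study_grid(scenarios, methods, replicates, n_total, ratio, alpha, seed,
              consts, qmodel)
}

#' Type-I-error sensitivity to window size and sample size
#'
#' Runs a null-scenario study using only the window-based WLS test at a
#' given sample size and window size.  Window-based variance estimation
#' needs enough observations per window to be stable: small windows at small
#' sample sizes inflate the type-I error, which this probe measures.
#'
#' @param n Total sample size (split 1:1).
#' @param w Odd window size, `w <= n`.
#' @param replicates Number of null replicates.
#' @param seed Integer seed.
#' @param scenario Null registry label (default `"null.b.i"`).
#' @param alpha Significance level.
#' @return A `study_result` for the single `wls_w(w)` method.
#' @export
window_size_sensitivity <- function(n, w, replicates = 2000L, seed = 1L,
                                    scenario = "null.b.i", alpha = 0.05) {
  stopifnot(n >= w)
  run_study(study_config(scenario, n_total = n, replicates = replicates,
                         alpha = alpha, seed = seed,
                         methods = list(method_spec("wls_w", w = w,
                                                    alpha = alpha))))
}
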