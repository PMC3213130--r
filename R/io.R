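# File I/O: delimited PMR tables in and out, result tables, and scenario
# configuration files (YAML or JSON) so custom scenarios can be defined with
# the same fields as the built-in registry.

.detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a PMR observation table
#'
#' Reads a CSV or TSV with required columns `id`, `pmr`, `surrogate` and
#' `group` (delimiter auto-detected from the header line unless given).
#' Validation is strict: `pmr` must parse as non-negative numbers
#' (values above 100 are legitimate), `surrogate` must be finite, and
#' `group` must take exactly two values.  Offending rows are reported with
#' their line numbers.
#'
#' @param path Path to the delimited file.
#' @param delim Optional delimiter override (`","` or `"\t"`).
#' @return Data frame of validated observations with `group` as a factor.
#' @export
read_pmr_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .detect_delim(path, delim)
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE)
  required <- c("id", "pmr", "surrogate", "group")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  pmr <- suppressWarnings(as.numeric(df$pmr))
  sur <- suppressWarnings(as.numeric(df$surrogate))
  bad <- which(is.na(pmr) | pmr < 0 | !is.finite(sur))
  if (length(bad))
    stop("unparseable or invalid rows (file line numbers): ",
         paste(bad + 1L, collapse = ", "),
         " — pmr must be a non-negative number and surrogate finite")
  df$pmr <- pmr
  df$surrogate <- sur
  df$group <- factor(df$group)
  if (nlevels(df$group) != 2)
    stop("'group' must have exactly two levels; found ",
         nlevels(df$group), " (", paste(levels(df$group), collapse = ", "), ")")
  df
}

#' Write a PMR observation table
#'
#' Writes a dataset (e.g. from [simulate_dataset()]) as TSV, round-trippable
#' through [read_pmr_table()].
#'
#' @param data Data frame with at least `id`, `pmr`, `surrogate`, `group`.
#' @param path Output path.
#' @param audit_columns Keep the simulation audit columns `genomes` and
#'   `p_true` when present (default TRUE).
#' @return `path`, invisibly.
#' @export
write_pmr_table <- function(data, path, audit_columns = TRUE) {
  keep <- c("id", "pmr", "surrogate", "group")
  if (audit_columns) keep <- c(keep, intersect(c("genomes", "p_true"), names(data)))
  utils::write.table(data[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a weight scheme audit table
#'
#' Per-sample TSV of id, surrogate, fitted variance and weight.
#'
#' @param scheme A `weight_scheme`.
#' @param data The data frame the scheme was fitted to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_audit <- function(scheme, data, path) {
  stopifnot(inherits(scheme, "weight_scheme"),
            nrow(data) == length(scheme$weights))
  out <- data.frame(id = data$id, surrogate = data$surrogate,
                    variance = scheme$variances, weight = scheme$weights)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis results
#'
#' Serialises a [run_method_suite()] table as TSV or JSON.
#'
#' @param results Data frame from [run_method_suite()].
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   TSV otherwise).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.dist_to_list <- function(g) {
  list(beta_mean = g$beta_mean, beta_var = g$beta_var,
       positivity_prob = g$positivity_prob)
}

.dist_from_list <- function(x) {
  group_distribution(beta_mean = x$beta_mean, beta_var = x$beta_var,
                     positivity_prob = if (is.null(x$positivity_prob)) 1
                                       else x$positivity_prob)
}

#' Write scenarios to a config file
#'
#' Serialises scenarios (YAML or JSON, by extension) with the same fields as
#' the built-in registry: per-group Beta mean/variance and positivity
#' probability, plus sample sizes.
#'
#' @param scenarios Named list of [scenario_spec()]s (e.g. from
#'   [scenario_registry()]).
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenarios, path) {
  payload <- lapply(scenarios, function(s) {
    list(label = s$label, n1 = s$n1, n2 = s$n2,
         group1 = .dist_to_list(s$group1), group2 = .dist_to_list(s$group2))
  })
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unrecognised config extension (use .yaml, .yml or .json): ", path)
  }
  invisible(path)
}

#' Read scenarios from a config file
#'
#' @param path A YAML or JSON file produced by [write_scenario_config()] or
#'   hand-written with the same fields.
#' @return Named list of [scenario_spec()]s.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("unrecognised config extension (use .yaml, .yml or .json): ", path)
  }
  out <- lapply(payload, function(s) {
    scenario_spec(s$label, .dist_from_list(s$group1), .dist_from_list(s$group2),
                  n1 = s$n1, n2 = s$n2)
  })
  names(out) <- vapply(out, function(s) s$label, character(1))
  out
}
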