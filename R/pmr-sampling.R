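# Generative model of a single specimen's PMR measurement.
#
# A specimen contributes h haploid genome equivalents of fragmented DNA, of
# which a proportion p carries the methylated target.  Each genome yields f
# measurable fragments, so the specimen is a pool of G = h * f fragments in
# which a methylated target allele occurs with frequency p / f.  The assay
# reports PMR = 100 * (B/G) / (B^r/G^r), the methylated-allele fraction of
# the specimen scaled to that of a fully methylated reference.

#' Assay constants for the PMR sampling model
#'
#' Bundles the fragmentation and reference-reaction constants shared by all
#' simulated specimens: the number of measurable DNA fragments contributed by
#' one haploid genome, the number of genomes in the M.SssI-treated fully
#' methylated reference aliquot, and the proportion of reference target
#' molecules actually methylated (1 means complete enzymatic conversion;
#' values below 1 model an incompletely converted reference, which biases PMR
#' upward).
#'
#' @param fragments_per_genome Number of measurable fragments per haploid
#'   genome (integer-valued, >= 1).  Default `1e4`, the scaling used for
#'   ALU-based DNA quantification.
#' @param reference_genomes Haploid genome equivalents in the reference
#'   reaction (> 0).  Default 5500.
#' @param conversion_efficiency Proportion of the reference target that is
#'   methylated, in (0, 1].  Default 1 (fully converted reference).
#' @return An object of class `sim_constants`.
#' @examples
#' sim_constants()
#' sim_constants(conversion_efficiency = 0.8)  # incompletely converted reference
#' @export
sim_constants <- function(fragments_per_genome = 1e4,
                          reference_genomes = 5500,
                          conversion_efficiency = 1) {
  stopifnot(
    length(fragments_per_genome) == 1L, is.finite(fragments_per_genome),
    fragments_per_genome >= 1, fragments_per_genome == round(fragments_per_genome),
    length(reference_genomes) == 1L, is.finite(reference_genomes),
    reference_genomes > 0,
    length(conversion_efficiency) == 1L, is.finite(conversion_efficiency),
    conversion_efficiency > 0, conversion_efficiency <= 1
  )
  structure(
    list(
      fragments_per_genome = fragments_per_genome,
      reference_genomes = reference_genomes,
      conversion_efficiency = conversion_efficiency
    ),
    class = "sim_constants"
  )
}

#' @export
print.sim_constants <- function(x, ...) {
  cat("PMR assay constants:\n")
  cat("  fragments per genome :", format(x$fragments_per_genome), "\n")
  cat("  reference genomes    :", format(x$reference_genomes), "\n")
  cat("  conversion efficiency:", format(x$conversion_efficiency), "\n")
  invisible(x)
}

#' Percent of methylated reference from fragment counts
#'
#' Computes PMR = 100 * (B/G) / (B^r/G^r): the methylated-allele fraction in
#' the tumour aliquot relative to that in the fully methylated reference,
#' expressed as a percentage.  A PMR of 0 occurs exactly when no methylated
#' allele was sampled (B = 0); values above 100 are legal and arise by
#' sampling chance at low DNA input.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param methylated_tumor B, methylated-allele count in the tumour aliquot.
#' @param fragments_tumor G, total fragment count in the tumour aliquot
#'   (must be > 0).
#' @param methylated_reference B^r, methylated-allele count in the reference
#'   (must be > 0 whenever B > 0).
#' @param fragments_reference G^r, total fragment count in the reference
#'   (must be > 0).
#' @return Numeric vector of PMR values (percent, >= 0).
#' @examples
#' compute_pmr(11, 1e5, 5500, 5.5e7)  # 110
#' @export
compute_pmr <- function(methylated_tumor, fragments_tumor,
                        methylated_reference, fragments_reference) {
  n <- max(length(methylated_tumor), length(fragments_tumor),
           length(methylated_reference), length(fragments_reference))
  B  <- rep_len(methylated_tumor, n)
  G  <- rep_len(fragments_tumor, n)
  Br <- rep_len(methylated_reference, n)
  Gr <- rep_len(fragments_reference, n)
  if (any(B < 0) || any(Br < 0) || any(B > G) || any(Br > Gr))
    stop("methylated counts must satisfy 0 <= B <= G and 0 <= B^r <= G^r")
  if (any(G <= 0))
    stop("degenerate specimen draw: zero fragments in the tumor aliquot (G = 0)")
  if (any(Gr <= 0))
    stop("reference fragment count G^r must be positive")
  if (any(B > 0 & Br == 0))
    stop("undefined PMR ratio: methylated alleles observed in the tumor but ",
         "none in the reference (B > 0 with B^r = 0)")
  pmr <- numeric(n)
  pos <- B > 0
  pmr[pos] <- 100 * (B[pos] / G[pos]) / (Br[pos] / Gr[pos])
  pmr
}

#' Draw fragment counts for one or more specimens
#'
#' Simulates the fragment-sampling step of a MethyLight measurement.  A
#' specimen with `genomes` = h genome equivalents contributes
#' G = round(h * f) fragments; the number of methylated target alleles B is
#' Binomial(G, p/f).  The reference reaction has
#' G^r = round(reference_genomes * f) fragments and
#' B^r ~ Binomial(G^r, conversion_efficiency / f), drawn independently per
#' specimen (one reference aliquot per reaction).
#'
#' @param genomes Vector of haploid genome equivalents h (>= 0).
#' @param methylation_proportion Vector of true methylated proportions p in
#'   `[0, 1]`, recycled against `genomes`.
#' @param consts A [sim_constants()] object.
#' @return A data frame with columns `methylated_tumor`, `fragments_tumor`,
#'   `methylated_reference`, `fragments_reference`, one row per specimen.
#' @examples
#' set.seed(1)
#' sample_fragment_draw(c(10, 500), 0.2, sim_constants())
#' @export
sample_fragment_draw <- function(genomes, methylation_proportion,
                                 consts = sim_constants()) {
  stopifnot(inherits(consts, "sim_constants"))
  n <- max(length(genomes), length(methylation_proportion))
  h <- rep_len(genomes, n)
  p <- rep_len(methylation_proportion, n)
  if (any(!is.finite(h)) || any(h < 0))
    stop("'genomes' must be finite and non-negative")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'methylation_proportion' must lie in [0, 1]")
  f <- consts$fragments_per_genome
  G <- round(h * f)
  Gr <- round(consts$reference_genomes * f)
  B <- stats::rbinom(n, size = G, prob = p / f)
  Br <- stats::rbinom(n, size = Gr, prob = consts$conversion_efficiency / f)
  data.frame(
    methylated_tumor = B,
    fragments_tumor = G,
    methylated_reference = Br,
    fragments_reference = Gr
  )
}

#' Probability that a specimen yields PMR = 0
#'
#' A methylated specimen can still return PMR = 0 when none of its methylated
#' alleles is captured among the sampled fragments — a false-negative
#' detection.  Two forms are available: `"genome"` gives the genome-level
#' approximation (1 - p)^h, and `"fragment"` the exact binomial form
#' (1 - p/f)^round(h f) implied by the fragment-sampling model.  The two
#' agree closely for moderate p; both are 1 when p = 0 or h = 0.
#'
#' @param genomes Haploid genome equivalents h (>= 0), vectorised.
#' @param methylation_proportion True methylated proportion p in `[0, 1]`,
#'   recycled.
#' @param method `"genome"` for (1 - p)^h, `"fragment"` for the exact
#'   binomial zero-probability.
#' @param fragments_per_genome Fragments per genome f, used only by the
#'   `"fragment"` form.
#' @return Probability vector in `[0, 1]`, decreasing in both p and h.
#' @examples
#' prob_zero_detection(10, 0.2)                       # 0.8^10
#' prob_zero_detection(10, 0.2, method = "fragment")  # (1 - 2e-5)^1e5
#' @export
prob_zero_detection <- function(genomes, methylation_proportion,
                                method = c("genome", "fragment"),
                                fragments_per_genome = 1e4) {
  method <- match.arg(method)
  n <- max(length(genomes), length(methylation_proportion))
  h <- rep_len(genomes, n)
  p <- rep_len(methylation_proportion, n)
  stopifnot(all(h >= 0), all(p >= 0), all(p <= 1))
  if (method == "genome") {
    (1 - p)^h
  } else {
    (1 - p / fragments_per_genome)^round(h * fragments_per_genome)
  }
}

#' Simulate PMR measurements
#'
#' Composes [sample_fragment_draw()] and [compute_pmr()] to produce one PMR
#' value per specimen.  A specimen whose aliquot rounds to zero fragments
#' (h < 1/(2f)) contains no measurable DNA and reports PMR = 0.  A reference
#' draw with B^r = 0 would leave the ratio undefined; it is redrawn up to
#' `max_retries` times (at the default constants its probability is about
#' exp(-5500), so retries are never triggered in practice, but a user-set
#' tiny reference can reach it).
#'
#' @inheritParams sample_fragment_draw
#' @param max_retries Bound on reference redraws before erroring.
#' @return Numeric vector of simulated PMR values (percent).
#' @examples
#' set.seed(42)
#' mean(simulate_pmr(rep(500, 1000), 0.2))  # close to 20
#' @export
simulate_pmr <- function(genomes, methylation_proportion,
                         consts = sim_constants(), max_retries = 100L) {
  stopifnot(inherits(consts, "sim_constants"))
  n <- max(length(genomes), length(methylation_proportion))
  h <- rep_len(genomes, n)
  p <- rep_len(methylation_proportion, n)
  if (any(!is.finite(h)) || any(h < 0))
    stop("'genomes' must be finite and non-negative")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'methylation_proportion' must lie in [0, 1]")
  f <- consts$fragments_per_genome
  G <- round(h * f)
  Gr <- round(consts$reference_genomes * f)
  B <- stats::rbinom(n, size = G, prob = p / f)
  Br <- stats::rbinom(n, size = Gr, prob = consts$conversion_efficiency / f)
  bad <- B > 0 & Br == 0
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > max_retries)
      stop("reference reaction produced zero methylated fragments in ",
           sum(bad), " specimen(s) after ", max_retries, " redraws; ",
           "increase 'reference_genomes' or 'max_retries'")
    Br[bad] <- stats::rbinom(sum(bad), size = Gr,
                             prob = consts$conversion_efficiency / f)
    bad <- B > 0 & Br == 0
  }
  pmr <- numeric(n)
  pos <- B > 0  # G > 0 wherever B > 0; a zero-fragment aliquot reads PMR 0
  pmr[pos] <- 100 * (B[pos] / G[pos]) / (Br[pos] / Gr)
  pmr
}
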