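#' Convert a genetic distance to a recombination fraction
#'
#' Map functions translate a genetic distance in centimorgan into the
#' probability that a single meiosis produces a recombinant gamete over
#' that interval. Haldane's function assumes crossovers arrive as a
#' Poisson process with no interference; Kosambi's allows for positive
#' interference and is the convention of many linkage maps.
#'
#' @param distance_cm Genetic distance in centimorgan (non-negative;
#'   vectorised).
#' @param method `"haldane"` (default) or `"kosambi"`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' map_cm_to_r(10)                # Haldane: 0.0906
#' map_cm_to_r(10, "kosambi")     # 0.0987
#' @export
map_cm_to_r <- function(distance_cm, method = c("haldane", "kosambi")) {
  method <- match.arg(method)
  if (any(!is.finite(distance_cm) | distance_cm < 0))
    stop("'distance_cm' must be finite and >= 0")
  m <- distance_cm / 100 # Morgans
  switch(method,
    haldane = 0.5 * (1 - exp(-2 * m)),
    kosambi = 0.5 * tanh(2 * m)
  )
}

#' Composition of a sequenced phenotypic bulk at the causal locus
#'
#' @param n_hom_mutant,n_het,n_hom_wildtype Plant counts by genotype at
#'   the causal locus. All must be non-negative and sum to a positive
#'   total.
#' @return An object of class `bulk_composition`.
#' @examples
#' bulk_composition(17, 1, 0)  # mutant bulk with one mis-phenotyped het
#' @export
bulk_composition <- function(n_hom_mutant, n_het, n_hom_wildtype) {
  counts <- c(n_hom_mutant = n_hom_mutant, n_het = n_het,
              n_hom_wildtype = n_hom_wildtype)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("bulk counts must be non-negative integers")
  if (sum(counts) == 0) stop("bulk must contain at least one plant")
  structure(as.list(counts), class = "bulk_composition")
}

#' Expected mutant-allele frequency in a pooled bulk
#'
#' For a bulk of plants with known genotypes at the causal locus, the
#' expected frequency of the mutant-linked allele at a marker a
#' recombination fraction `r` away is an average over the bulk's `2N`
#' chromosomes: a chromosome carrying the mutant causal allele carries
#' the linked marker allele with probability `1 - r`, a wildtype
#' chromosome with probability `r`. At `r = 0` this is the mutant-allele
#' dosage fraction of the bulk; at `r = 0.5` it is 0.5 regardless of
#' composition.
#'
#' @param r Recombination fraction between marker and causal locus, in
#'   `[0, 0.5]` (vectorised).
#' @param composition A [bulk_composition()], or a length-3 numeric
#'   vector `(n_hom_mutant, n_het, n_hom_wildtype)`.
#' @return Expected allele frequency in `[0, 1]`.
#' @examples
#' expected_bulk_freq(0, bulk_composition(17, 1, 0))    # 35/36, the 97% peak
#' expected_bulk_freq(0, bulk_composition(0, 20, 10))   # 1/3: the 2:1 wt bulk
#' @export
expected_bulk_freq <- function(r, composition) {
  if (any(r < 0 | r > 0.5)) stop("'r' must lie in [0, 0.5]")
  if (!inherits(composition, "bulk_composition"))
    composition <- bulk_composition(composition[[1]], composition[[2]],
                                    composition[[3]])
  n2 <- 2 * (composition$n_hom_mutant + composition$n_het +
             composition$n_hom_wildtype)
  mut_chrom <- 2 * composition$n_hom_mutant + composition$n_het
  wt_chrom <- n2 - mut_chrom
  (mut_chrom * (1 - r) + wt_chrom * r) / n2
}

#' Chi-square test of a monogenic segregation ratio
#'
#' Pearson goodness-of-fit of observed mutant/wildtype counts against an
#' expected mutant fraction (1/4 for a recessive allele in an F2), with
#' one degree of freedom and no continuity correction.
#'
#' @param n_mutant,n_wildtype Observed plant counts.
#' @param expected_mutant_fraction Expected fraction of mutants, in
#'   (0, 1). Default 0.25, the recessive F2 expectation.
#' @return A list of class `segregation_test` with elements `chi2`,
#'   `p_value`, `df`, `observed`, `expected`.
#' @examples
#' segregation_chi2(19, 81)   # chi2 = 1.92, p = 0.166
#' @export
segregation_chi2 <- function(n_mutant, n_wildtype,
                             expected_mutant_fraction = 0.25) {
  n <- n_mutant + n_wildtype
  if (n <= 0) stop("total count must be positive")
  if (expected_mutant_fraction <= 0 || expected_mutant_fraction >= 1)
    stop("'expected_mutant_fraction' must lie strictly in (0, 1)")
  p <- c(expected_mutant_fraction, 1 - expected_mutant_fraction)
  ht <- stats::chisq.test(c(n_mutant, n_wildtype), p = p)
  structure(list(chi2 = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = as.integer(unname(ht$parameter)),
                 observed = c(mutant = n_mutant, wildtype = n_wildtype),
                 expected = unname(ht$expected)),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat("Segregation test (Pearson goodness-of-fit, df =", x$df, ")\n")
  cat(sprintf("  observed: %d mutant / %d wildtype\n",
              x$observed[["mutant"]], x$observed[["wildtype"]]))
  cat(sprintf("  chi2 = %.3g, P = %.3g\n", x$chi2, x$p_value))
  invisible(x)
}

#' @export
print.bulk_composition <- function(x, ...) {
  cat(sprintf(
    "bulk of %d plants: %d hom. mutant, %d het., %d hom. wildtype\n",
    x$n_hom_mutant + x$n_het + x$n_hom_wildtype,
    x$n_hom_mutant, x$n_het, x$n_hom_wildtype))
  invisible(x)
}
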