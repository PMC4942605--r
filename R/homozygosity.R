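#' Observed homozygosity in a region
#'
#' Fraction of eligible families whose two alleles carry the same variant
#' identity. Families with an undetected allele never reach this
#' statistic: they are removed by [genotype_analysis_subset()] before the
#' genotype spectrum is built.
#'
#' @param gspec a `genotype_spectrum`.
#' @param region region name present in the spectrum.
#' @return a `homozygosity_report` with fields `region`, `kind`
#'   (`"observed"`), `numerator`, `denominator` and `value` (fraction).
#' @export
observed_homozygosity <- function(gspec, region) {
  stopifnot(inherits(gspec, "genotype_spectrum"))
  if (!region %in% names(gspec$N_families))
    stop("region not present in genotype spectrum: ", region)
  den <- gspec$N_families[[region]]
  if (den == 0) stop("observed homozygosity undefined: no families in ", region)
  homo <- is_homozygous_identity(rownames(gspec$counts))
  num <- sum(gspec$counts[homo, region])
  structure(list(region = region, kind = "observed",
                 numerator = num, denominator = den, value = num / den,
                 n_families = den),
            class = "homozygosity_report")
}

#' Theoretical homozygosity (gene identity J) in a region
#'
#' J = sum(Xi^2) over all alleles, the probability that two alleles drawn
#' at random are identical; 1 - J is the gene diversity (allelic
#' heterogeneity). Each detected identity i contributes (m_i / N)^2.
#' Undetected alleles are conservatively treated as pairwise-distinct
#' alleles, each of frequency 1/N, so u undetected alleles add
#' u * (1/N)^2.
#'
#' @param spec a `regional_spectrum`.
#' @param region region name present in the spectrum, or `"all"` to pool.
#' @param n_families optional family count carried along for the
#'   comparison convention of [compare_homozygosity()].
#' @return a `homozygosity_report` with `value` = J (fraction in
#'   (0, 1]), plus the allele frequencies used.
#' @export
theoretical_homozygosity <- function(spec, region, n_families = NULL) {
  stopifnot(inherits(spec, "regional_spectrum"))
  region <- resolve_spectrum_region(spec, region)
  if (region == "all") {
    m <- rowSums(spec$counts); u <- sum(spec$unknown); N <- sum(spec$N)
  } else {
    m <- stats::setNames(spec$counts[, region], rownames(spec$counts))
    u <- spec$unknown[[region]]; N <- spec$N[[region]]
  }
  if (N == 0) stop("theoretical homozygosity undefined: N = 0 in ", region)
  x <- m / N
  J <- sum(x^2) + u * (1 / N)^2
  structure(list(region = region, kind = "theoretical", value = J,
                 N = N, unknown = u, allele_frequencies = x[m > 0],
                 unknown_allele_policy = "each-unique",
                 n_families = n_families),
            class = "homozygosity_report")
}

#' @export
print.homozygosity_report <- function(x, ...) {
  if (x$kind == "observed")
    cat(sprintf("<observed homozygosity> %s: %d/%d = %.2f%%\n",
                x$region, x$numerator, x$denominator, 100 * x$value))
  else
    cat(sprintf("<theoretical homozygosity> %s: J = %.2f%% (N = %d, %d undetected)\n",
                x$region, 100 * x$value, x$N, x$unknown))
  invisible(x)
}

#' Compare homozygosity between two regions
#'
#' Observed homozygosity is compared on the 2 x 2 table of homozygous vs
#' heterozygous family counts, under the package's usual test-selection
#' rule (Pearson without continuity correction when expected counts
#' permit, exact otherwise). For theoretical homozygosity no test is
#' standard; the declared convention here converts each J into an
#' expected homozygote count `round(J * n_families)` and reuses the same
#' 2 x 2 machinery. That convention is deterministic and documented, not
#' a reproduction claim for any published value.
#'
#' @param a,b `homozygosity_report` objects of the same kind.
#' @param expected_min expected-count threshold for the asymptotic test.
#' @return a `cd_test_result`.
#' @export
compare_homozygosity <- function(a, b, expected_min = 5) {
  stopifnot(inherits(a, "homozygosity_report"),
            inherits(b, "homozygosity_report"))
  if (!identical(a$kind, b$kind))
    stop("cannot compare homozygosity reports of different kinds: ",
         a$kind, " vs ", b$kind)
  if (a$kind == "observed") {
    num <- c(a$numerator, b$numerator)
    den <- c(a$denominator, b$denominator)
  } else {
    if (is.null(a$n_families) || is.null(b$n_families))
      stop("theoretical comparison needs n_families in both reports")
    den <- c(a$n_families, b$n_families)
    num <- round_half_up(c(a$value, b$value) * den)
  }
  names(num) <- names(den) <- c(a$region, b$region)
  omnibus_test(num, den, expected_min = expected_min)
}
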