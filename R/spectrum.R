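#' Construct a regional allele spectrum
#'
#' Low-level constructor; most users build spectra with
#' [allele_spectrum()] (from a cohort) or [build_table2_fixture()] (from
#' printed relative frequencies).
#'
#' @param counts integer matrix, detected allele identities x regions.
#' @param unknown named integer vector of undetected-allele counts per
#'   region (same column order as `counts`).
#' @return a `regional_spectrum`: list with `counts`, `unknown` and the
#'   per-region allele totals `N` (detected + unknown).
#' @export
new_regional_spectrum <- function(counts, unknown = NULL) {
  counts <- as.matrix(counts)
  if (is.null(unknown)) unknown <- stats::setNames(rep(0L, ncol(counts)), colnames(counts))
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0), all(unknown >= 0),
            identical(names(unknown), colnames(counts)))
  N <- colSums(counts) + unknown
  structure(list(counts = counts, unknown = unknown, N = N),
            class = "regional_spectrum")
}

#' @export
print.regional_spectrum <- function(x, ...) {
  cat("<regional allele spectrum>\n")
  cat("  regions: ", paste(sprintf("%s (N=%d)", names(x$N), x$N), collapse = ", "), "\n")
  cat("  detected identities: ", nrow(x$counts),
      "; undetected alleles: ", sum(x$unknown), "\n", sep = "")
  invisible(x)
}

#' Construct a regional genotype spectrum
#'
#' @param counts integer matrix, unordered genotype identities x regions.
#' @return a `genotype_spectrum` with `counts` and per-region family
#'   totals `N_families`.
#' @export
new_genotype_spectrum <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0))
  structure(list(counts = counts, N_families = colSums(counts)),
            class = "genotype_spectrum")
}

#' @export
print.genotype_spectrum <- function(x, ...) {
  cat("<regional genotype spectrum>\n")
  cat("  regions: ", paste(sprintf("%s (n=%d)", names(x$N_families), x$N_families),
                           collapse = ", "), "\n")
  cat("  distinct genotypes: ", nrow(x$counts), "\n", sep = "")
  invisible(x)
}

#' Tally the allele spectrum of a cohort
#'
#' Each family representative contributes exactly two independent
#' alleles, tallied per region under the allele's identity. A cis-compound
#' allele counts once, under its own compound identity, which keeps the
#' per-region counts summing to the allele total N. Undetected alleles are
#' tallied separately and enter N.
#'
#' @param cohort a family-deduplicated `cd_cohort`.
#' @return a `regional_spectrum` whose columns are the regions present in
#'   the cohort.
#' @export
allele_spectrum <- function(cohort) {
  stopifnot(inherits(cohort, "cd_cohort"))
  df <- as.data.frame(cohort)
  ids <- c(df$allele1, df$allele2)
  regions <- rep(df$region, 2)
  region_levels <- unique(df$region)
  known <- ids != "?"
  identities <- sort(unique(ids[known]), method = "radix")
  counts <- matrix(0L, nrow = length(identities), ncol = length(region_levels),
                   dimnames = list(identities, region_levels))
  if (any(known)) {
    tab <- table(factor(ids[known], levels = identities),
                 factor(regions[known], levels = region_levels))
    counts[] <- as.integer(tab)
  }
  unk <- table(factor(regions[!known], levels = region_levels))
  new_regional_spectrum(counts, stats::setNames(as.integer(unk), region_levels))
}

#' Tally the genotype spectrum of a cohort
#'
#' @param cohort a `cd_cohort` that has passed
#'   [genotype_analysis_subset()] (both alleles identified, unambiguous
#'   region).
#' @return a `genotype_spectrum`; unordered genotype identities per
#'   region.
#' @export
genotype_spectrum <- function(cohort) {
  stopifnot(inherits(cohort, "cd_cohort"))
  df <- as.data.frame(cohort)
  gid <- mapply(genotype_identity, df$allele1, df$allele2, USE.NAMES = FALSE)
  region_levels <- unique(df$region)
  identities <- sort(unique(gid), method = "radix")
  tab <- table(factor(gid, levels = identities),
               factor(df$region, levels = region_levels))
  counts <- matrix(as.integer(tab), nrow = length(identities),
                   dimnames = list(identities, region_levels))
  new_genotype_spectrum(counts)
}

resolve_spectrum_region <- function(spec, region) {
  if (identical(region, "all")) return("all")
  if (!region %in% names(spec$N))
    stop("region not present in spectrum: ", region)
  region
}

#' Relative allele frequencies
#'
#' Frequencies on the printed percentage scale (58.33 means 58.33%).
#' `region = "all"` pools the regional counts before dividing by the
#' pooled allele total. The undetected-allele class appears as
#' `"Unknown"`.
#'
#' @param spec a `regional_spectrum`.
#' @param region one region name or `"all"`.
#' @return named numeric vector of percentages (full precision; round
#'   with [round_half_up()] for table display).
#' @export
relative_frequencies <- function(spec, region = "all") {
  region <- resolve_spectrum_region(spec, region)
  if (region == "all") {
    m <- rowSums(spec$counts); u <- sum(spec$unknown); N <- sum(spec$N)
  } else {
    m <- stats::setNames(spec$counts[, region], rownames(spec$counts))
    u <- spec$unknown[[region]]; N <- spec$N[[region]]
  }
  if (N == 0) stop("undefined frequency: allele total N is 0 for region ", region)
  c(100 * m / N, Unknown = 100 * u / N)
}

#' Diagnostic efficiency of the spectrum
#'
#' Percentage of cohort alleles on which a mutation was identified:
#' `100 * (N - unknown) / N` over all regions pooled.
#'
#' @param spec a `regional_spectrum`.
#' @return a percentage.
#' @export
diagnostic_efficiency <- function(spec) {
  N <- sum(spec$N)
  if (N == 0) stop("empty spectrum")
  100 * (N - sum(spec$unknown)) / N
}

#' Pooled relative frequency of a set of mutations
#'
#' The combined all-region percentage of the listed allele identities,
#' e.g. of the high-frequency screening panel.
#'
#' @param spec a `regional_spectrum`.
#' @param identities character vector of allele identities (canonical).
#' @return a percentage.
#' @export
combined_frequency <- function(spec, identities) {
  if (length(identities) == 0) return(0)
  missing <- setdiff(identities, rownames(spec$counts))
  if (length(missing) > 0)
    stop("identity not in spectrum: ", paste(missing, collapse = ", "))
  100 * sum(spec$counts[identities, , drop = FALSE]) / sum(spec$N)
}

#' Export a spectrum as a table
#'
#' One row per detected identity (plus the Unknown class) with regional
#' and pooled percentages rounded to two decimals, mirroring the layout
#' of published mutation-spectrum tables. Registry metadata (protein
#' effect, category, location) is joined where available.
#'
#' @param spec a `regional_spectrum`.
#' @param registry a `variant_registry` for annotation, or `NULL`.
#' @return a data frame.
#' @export
spectrum_table <- function(spec, registry = default_registry()) {
  regions <- names(spec$N)
  freq <- vapply(regions, function(r) relative_frequencies(spec, r),
                 numeric(nrow(spec$counts) + 1))
  all_freq <- relative_frequencies(spec, "all")
  ids <- c(rownames(spec$counts), "Unknown")
  out <- data.frame(identity = ids, stringsAsFactors = FALSE)
  if (!is.null(registry)) {
    idx <- match(out$identity, registry$canonical_id)
    out$protein_effect <- registry$protein_effect[idx]
    out$category <- registry$category[idx]
    out$location <- registry$location_label[idx]
  }
  for (r in regions) out[[r]] <- fmt_pct(freq[, r])
  out$all <- fmt_pct(all_freq)
  out$count <- c(rowSums(spec$counts), sum(spec$unknown))
  out
}
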