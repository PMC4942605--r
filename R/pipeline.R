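#' Region-stratified analysis of allele and genotype spectra
#'
#' Core report generator shared by every front end: takes an allele
#' spectrum and (optionally) a genotype spectrum and produces the full
#' result surface — frequency tables, diagnostic efficiency, omnibus and
#' pairwise geographic tests, and observed/theoretical homozygosity with
#' between-region comparisons.
#'
#' @param spec a `regional_spectrum`.
#' @param gspec a `genotype_spectrum` or `NULL`.
#' @param alpha,alpha_pairwise,expected_min statistical thresholds (see
#'   [scan_spectrum()]).
#' @param registry a `variant_registry` for annotation.
#' @return a list of class `cd_report`: `spectrum_table`,
#'   `diagnostic_efficiency`, `allele_scan`, `genotype_scan`,
#'   `homozygosity` (data frame per region) and
#'   `homozygosity_comparisons`.
#' @export
analyze_spectra <- function(spec, gspec = NULL, alpha = 0.05,
                            alpha_pairwise = 0.05 / 3, expected_min = 5,
                            registry = default_registry()) {
  out <- list(
    spectrum_table = spectrum_table(spec, registry),
    diagnostic_efficiency = diagnostic_efficiency(spec),
    allele_scan = scan_spectrum(spec, alpha, alpha_pairwise, expected_min)
  )
  regions <- names(spec$N)
  if (!is.null(gspec)) {
    out$genotype_scan <- scan_genotypes(gspec, alpha, alpha_pairwise, expected_min)
    obs <- lapply(regions, function(r) observed_homozygosity(gspec, r))
    theo <- lapply(regions, function(r)
      theoretical_homozygosity(spec, r, n_families = gspec$N_families[[r]]))
    out$homozygosity <- data.frame(
      region = regions,
      observed_numerator = vapply(obs, `[[`, numeric(1), "numerator"),
      observed_denominator = vapply(obs, `[[`, numeric(1), "denominator"),
      observed_pct = fmt_pct(100 * vapply(obs, `[[`, numeric(1), "value")),
      theoretical_J_pct = fmt_pct(100 * vapply(theo, `[[`, numeric(1), "value")),
      stringsAsFactors = FALSE)
    if (length(regions) >= 2) {
      pairs <- utils::combn(seq_along(regions), 2)
      cmp <- lapply(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1, k]; j <- pairs[2, k]
        data.frame(
          pair = paste(regions[i], regions[j], sep = "-vs-"),
          observed_p = compare_homozygosity(obs[[i]], obs[[j]], expected_min)$p,
          theoretical_p = compare_homozygosity(theo[[i]], theo[[j]], expected_min)$p,
          stringsAsFactors = FALSE)
      })
      out$homozygosity_comparisons <- do.call(rbind, cmp)
    }
  }
  structure(out, class = "cd_report")
}

#' @export
print.cd_report <- function(x, ...) {
  cat("<citrin-deficiency spectrum report>\n")
  if (!is.null(x$diagnostic_efficiency))
    cat(sprintf("  diagnostic efficiency: %.2f%%\n",
                round_half_up(x$diagnostic_efficiency, 2)))
  if (!is.null(x$allele_scan))
    cat("  geographically heterogeneous identities: ",
        paste(x$allele_scan$significant, collapse = ", "), "\n", sep = "")
  if (!is.null(x$genotype_scan))
    cat("  geographically heterogeneous genotypes: ",
        paste(x$genotype_scan$significant, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the whole pipeline on a cohort table
#'
#' Read, deduplicate families, restrict to the genotype-comparison
#' subset, build both spectra and produce the [analyze_spectra()] report
#' bundle. When the cohort has no region information (all `unstated`)
#' the geographic scans and homozygosity comparisons are skipped and only
#' pooled spectrum summaries are returned.
#'
#' @param cohort a `cd_cohort` or a path to a cohort TSV.
#' @param out_dir if non-NULL, report tables are written there as TSVs.
#' @inheritParams analyze_spectra
#' @param region_map a `region_map` (used when `cohort` is a path).
#' @return a `cd_report` (see [analyze_spectra()]), with additional
#'   elements `n_records`, `n_families` and `exclusions`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, alpha = 0.05,
                         alpha_pairwise = 0.05 / 3, expected_min = 5,
                         region_map = default_region_map(),
                         registry = default_registry()) {
  if (is.character(cohort))
    cohort <- read_cohort(cohort, region_map = region_map, registry = registry)
  stopifnot(inherits(cohort, "cd_cohort"))
  if (nrow(as.data.frame(cohort)) == 0) {
    report <- structure(list(n_records = 0L, n_families = 0L), class = "cd_report")
    return(report)
  }
  fams <- dedupe_families(cohort)
  subset <- genotype_analysis_subset(fams)
  spec <- allele_spectrum(fams)
  regional <- all(names(spec$N) %in% c("north", "border", "south")) &&
    length(spec$N) >= 2
  if (regional) {
    gspec <- if (nrow(as.data.frame(subset)) > 0) genotype_spectrum(subset) else NULL
    report <- analyze_spectra(spec, gspec, alpha, alpha_pairwise,
                              expected_min, registry)
  } else {
    report <- structure(list(
      spectrum_table = spectrum_table(spec, registry),
      diagnostic_efficiency = diagnostic_efficiency(spec)
    ), class = "cd_report")
  }
  report$n_records <- nrow(as.data.frame(cohort))
  report$n_families <- attr(fams, "n_families")
  report$exclusions <- attr(subset, "exclusions")
  if (!is.null(out_dir)) export_report(report, out_dir)
  report
}

#' Write a report bundle to disk
#'
#' Every rendered number stays re-derivable from these exported count and
#' P-value tables; nothing is kept in hidden state.
#'
#' @param report a `cd_report`.
#' @param out_dir directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
export_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  wr(report$spectrum_table, "spectrum.tsv")
  if (!is.null(report$allele_scan)) {
    sc <- report$allele_scan$omnibus
    sc$p_printed <- format_p(sc$p)
    wr(sc, "allele_scan.tsv")
    if (length(report$allele_scan$pairwise) > 0) {
      pw <- do.call(rbind, Map(function(id, df) cbind(identity = id, df),
                               names(report$allele_scan$pairwise),
                               report$allele_scan$pairwise))
      wr(pw, "allele_pairwise.tsv")
    }
  }
  if (!is.null(report$genotype_scan)) {
    sc <- report$genotype_scan$omnibus
    sc$p_printed <- format_p(sc$p)
    wr(sc, "genotype_scan.tsv")
  }
  if (!is.null(report$homozygosity)) wr(report$homozygosity, "homozygosity.tsv")
  if (!is.null(report$homozygosity_comparisons))
    wr(report$homozygosity_comparisons, "homozygosity_comparisons.tsv")
  if (!is.null(report$exclusions)) wr(report$exclusions, "exclusions.tsv")
  invisible(out_dir)
}
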