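#' Reconstruct integer counts from printed relative frequencies
#'
#' Published spectrum tables print per-region relative frequencies to two
#' decimals together with the regional total N. Because every frequency
#' is m/N for an integer m, `round(freq * N / 100)` (half away from zero)
#' recovers the integer counts exactly; the reconstruction is validated
#' by requiring each regional column to sum back to its printed N.
#'
#' @param freq_pct numeric matrix of percentages (rows = identities,
#'   columns = regions).
#' @param N named integer vector of regional totals.
#' @return integer matrix of counts.
#' @export
reconstruct_counts <- function(freq_pct, N) {
  freq_pct <- as.matrix(freq_pct)
  stopifnot(identical(colnames(freq_pct), names(N)))
  counts <- round_half_up(sweep(freq_pct, 2, N, function(f, n) f * n / 100))
  storage.mode(counts) <- "integer"
  sums <- colSums(counts)
  off <- sums != N
  if (any(off))
    stop("reconstructed column(s) do not sum to the stated total: ",
         paste(sprintf("%s (sum %d, expected %d, residual %+d)",
                       names(N)[off], sums[off], N[off], sums[off] - N[off]),
               collapse = "; "))
  counts
}

#' Regional allele-count spectrum reconstructed from the printed table
#'
#' Rebuilds the integer allele counts of the 41 detected SLC25A13
#' mutations (plus the undetected class) in the three geographic regions
#' from the packaged relative-frequency table, with regional allele
#' totals N = 55 (north), 81 (border) and 392 (south).
#'
#' @param registry a `variant_registry` used to canonicalize identities.
#' @return a `regional_spectrum`.
#' @export
build_table2_fixture <- function(registry = default_registry()) {
  path <- system.file("extdata", "table2_relative_frequencies.tsv",
                      package = "citrinspectrum", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  N <- c(north = 55L, border = 81L, south = 392L)
  freq <- as.matrix(df[, c("north", "border", "south")])
  rownames(freq) <- df$identity
  counts <- reconstruct_counts(freq, N)
  unk_row <- rownames(counts) == "Unknown"
  if (sum(unk_row) != 1) stop("fixture must contain exactly one Unknown row")
  detected <- counts[!unk_row, , drop = FALSE]
  ids <- vapply(rownames(detected),
                function(x) allele_identity(parse_allele(x, registry)),
                character(1), USE.NAMES = FALSE)
  rownames(detected) <- ids
  new_regional_spectrum(detected,
                        stats::setNames(as.integer(counts[unk_row, ]), names(N)))
}

#' Regional genotype-count spectrum reconstructed from the printed table
#'
#' Rebuilds the integer genotype counts of the 53 distinct biallelic
#' genotypes among the families eligible for genotype comparison, with
#' regional family totals n = 23 (north), 35 (border) and 187 (south).
#' Genotype labels are canonicalized through the registry, so legacy
#' spellings collapse onto their systematic names.
#'
#' @param registry a `variant_registry`.
#' @return a `genotype_spectrum`.
#' @export
build_table4_fixture <- function(registry = default_registry()) {
  path <- system.file("extdata", "table4_relative_frequencies.tsv",
                      package = "citrinspectrum", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  N <- c(north = 23L, border = 35L, south = 187L)
  freq <- as.matrix(df[, c("north", "border", "south")])
  rownames(freq) <- df$genotype
  counts <- reconstruct_counts(freq, N)
  ids <- vapply(rownames(counts), function(g) {
    alleles <- parse_genotype(g, registry)
    genotype_identity(alleles[[1]], alleles[[2]])
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(ids))
    stop("genotype rows collapse onto a duplicate identity: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  rownames(counts) <- ids
  new_genotype_spectrum(counts)
}
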