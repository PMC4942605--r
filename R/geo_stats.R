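#' @keywords internal
new_test_result <- function(p, method, statistic = NA_real_, expected_min = NA_real_) {
  structure(list(p = p, method = method, statistic = statistic,
                 expected_min = expected_min),
            class = "cd_test_result")
}

#' @export
print.cd_test_result <- function(x, ...) {
  cat(sprintf("<%s> p = %s", x$method, format_p(x$p)))
  if (!is.na(x$statistic)) cat(sprintf(", X2 = %.4f", x$statistic))
  cat("\n")
  invisible(x)
}

#' Render a P value the way spectrum tables print it
#'
#' Values below 0.0005 print as `"0.000"`; internal values are never
#' truncated.
#'
#' @param p numeric vector of probabilities.
#' @return character vector.
#' @export
format_p <- function(p) sprintf("%.3f", round_half_up(p, 3))

validate_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("contingency table has negative cells")
  if (any(tab != floor(tab))) stop("contingency table has non-integer cells")
  storage.mode(tab) <- "double"  # counts can exceed int range in products
  tab
}

expected_counts <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(tab * 0)
  outer(rowSums(tab), colSums(tab)) / n
}

# log point-probability of a table under the multivariate hypergeometric
# (fixed margins) null: prod(r_i!) prod(c_j!) / (n! prod(a_ij!))
log_table_prob <- function(tab) {
  n <- sum(tab)
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(n + 1) - sum(lgamma(tab + 1))
}

# enumerate all non-negative integer matrices with the given margins,
# calling fn(tab) for each; recursion fills row by row
enumerate_margin_tables <- function(row_totals, col_totals, fn) {
  nr <- length(row_totals); nc <- length(col_totals)
  tab <- matrix(0, nr, nc)
  fill_row <- function(r, col_left) {
    if (r == nr) {
      tab[nr, ] <<- col_left
      fn(tab)
      return(invisible(NULL))
    }
    fill_cell <- function(c, left_in_row, col_left) {
      if (c == nc) {
        if (left_in_row <= col_left[nc]) {
          tab[r, nc] <<- left_in_row
          fill_row(r + 1, col_left - tab[r, ])
        }
        return(invisible(NULL))
      }
      # remaining row mass must still fit into the remaining columns
      max_here <- min(left_in_row, col_left[c])
      min_here <- max(0, left_in_row - sum(col_left[(c + 1):nc]))
      for (v in seq(min_here, max_here)) {
        tab[r, c] <<- v
        fill_cell(c + 1, left_in_row - v, col_left)
      }
    }
    fill_cell(1, row_totals[r], col_left)
  }
  fill_row(1, col_totals)
  invisible(NULL)
}

#' Freeman-Halton exact test
#'
#' Fisher's exact test generalized to an R x C table by full enumeration:
#' every table with the observed margins is generated, and the two-sided
#' P value is the sum of the point probabilities of all tables whose
#' multivariate-hypergeometric probability does not exceed that of the
#' observed table (the "probability method"), with a relative tie
#' tolerance of 1e-7. No Monte Carlo approximation is involved.
#'
#' @param tab non-negative integer matrix (typically carriers vs
#'   non-carriers across regions, either orientation).
#' @return a `cd_test_result` with method `freeman-halton-exact`; the
#'   `statistic` field is absent (NA) since the test orders tables by
#'   probability, not by a statistic.
#' @export
freeman_halton_exact <- function(tab) {
  tab <- validate_table(tab)
  if (sum(tab) == 0) return(new_test_result(1, "freeman-halton-exact"))
  # degenerate margins (an all-zero row or column) admit a single table
  lp_obs <- log_table_prob(tab)
  tol <- log1p(1e-7)
  p <- 0
  enumerate_margin_tables(rowSums(tab), colSums(tab), function(t2) {
    lp <- log_table_prob(t2)
    if (lp <= lp_obs + tol) p <<- p + exp(lp)
  })
  new_test_result(min(p, 1), "freeman-halton-exact",
                  expected_min = min(expected_counts(tab)))
}

#' Pearson chi-square test on a contingency table
#'
#' Thin wrapper around [stats::chisq.test()] reporting the statistic,
#' the P value and the smallest expected cell count (the quantity that
#' drives the choice between the asymptotic and the exact test).
#'
#' @param tab non-negative integer matrix with positive margins.
#' @param yates apply the continuity correction (2 x 2 tables only).
#' @return a `cd_test_result`.
#' @export
pearson_chi2 <- function(tab, yates = FALSE) {
  tab <- validate_table(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined: zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  new_test_result(unname(res$p.value),
                  if (yates) "pearson-chi2-yates" else "pearson-chi2",
                  statistic = unname(res$statistic),
                  expected_min = min(expected_counts(tab)))
}

#' Omnibus regional frequency-difference test
#'
#' Builds the carriers-vs-rest x regions table and applies the standard
#' test-selection rule: Pearson chi-square when every expected cell count
#' is at least `expected_min`, otherwise the Freeman-Halton exact test.
#' The choice is recorded in the result's `method`.
#'
#' @param carriers integer vector of carrier allele (or genotype) counts
#'   per region.
#' @param totals integer vector of per-region totals (same order).
#' @param expected_min expected-count threshold for the asymptotic test
#'   (default 5, the usual validity rule).
#' @return a `cd_test_result`.
#' @export
omnibus_test <- function(carriers, totals, expected_min = 5) {
  stopifnot(length(carriers) == length(totals), all(carriers <= totals))
  if (sum(carriers) == 0 || all(carriers == totals))
    return(new_test_result(1, "freeman-halton-exact"))
  tab <- rbind(carriers = carriers, rest = totals - carriers)
  if (min(expected_counts(tab)) >= expected_min) pearson_chi2(tab, yates = FALSE)
  else freeman_halton_exact(tab)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' After a significant omnibus test, each pair of regions is compared on
#' a 2 x 2 carriers-vs-rest table, using the same test-selection rule
#' (Pearson without continuity correction when expected counts allow,
#' exact otherwise). Significance is judged against the Bonferroni
#' threshold alpha/npairs (0.05/3 = 0.017 for three regions).
#'
#' @inheritParams omnibus_test
#' @param alpha_pairwise per-comparison threshold.
#' @return a data frame with one row per region pair: `pair`, `method`,
#'   `p`, `significant`.
#' @export
pairwise_tests <- function(carriers, totals, expected_min = 5,
                           alpha_pairwise = 0.05 / 3) {
  regions <- names(carriers) %||% as.character(seq_along(carriers))
  pairs <- utils::combn(seq_along(carriers), 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    res <- omnibus_test(carriers[c(i, j)], totals[c(i, j)], expected_min)
    data.frame(pair = paste(regions[i], regions[j], sep = "-vs-"),
               method = res$method, p = res$p,
               significant = res$p < alpha_pairwise,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

scan_counts <- function(counts, totals, alpha, alpha_pairwise, expected_min) {
  if (any(totals == 0))
    stop("region with zero total: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  rows <- lapply(rownames(counts), function(id) {
    res <- omnibus_test(counts[id, ], totals, expected_min)
    data.frame(identity = id, method = res$method, p = res$p,
               significant = res$p < alpha, stringsAsFactors = FALSE)
  })
  omnibus <- do.call(rbind, rows)
  pairwise <- lapply(omnibus$identity[omnibus$significant], function(id) {
    pairwise_tests(counts[id, ], totals, expected_min, alpha_pairwise)
  })
  names(pairwise) <- omnibus$identity[omnibus$significant]
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 significant = omnibus$identity[omnibus$significant],
                 alpha = alpha, alpha_pairwise = alpha_pairwise),
            class = "cd_scan")
}

#' @export
print.cd_scan <- function(x, ...) {
  cat("<regional frequency scan> ", nrow(x$omnibus), " identities, ",
      length(x$significant), " significant at alpha = ", x$alpha, "\n", sep = "")
  if (length(x$significant) > 0)
    cat("  significant:", paste(x$significant, collapse = ", "), "\n")
  invisible(x)
}

#' Scan every allele identity for regional frequency differences
#'
#' Runs the omnibus test per detected identity (and for the undetected
#' class, which participates in the table like any other row) and, for
#' omnibus-significant identities, the three Bonferroni-corrected
#' pairwise comparisons.
#'
#' @param spec a `regional_spectrum`.
#' @param alpha omnibus significance level.
#' @param alpha_pairwise pairwise Bonferroni threshold.
#' @param expected_min expected-count threshold for using the asymptotic
#'   chi-square test.
#' @return a `cd_scan`: list with `omnibus` (data frame), `pairwise`
#'   (list of data frames, one per significant identity) and
#'   `significant` (character vector).
#' @export
scan_spectrum <- function(spec, alpha = 0.05, alpha_pairwise = 0.05 / 3,
                          expected_min = 5) {
  stopifnot(inherits(spec, "regional_spectrum"))
  counts <- rbind(spec$counts, Unknown = spec$unknown)
  scan_counts(counts, spec$N, alpha, alpha_pairwise, expected_min)
}

#' Scan every genotype for regional frequency differences
#'
#' @param gspec a `genotype_spectrum`.
#' @inheritParams scan_spectrum
#' @return a `cd_scan`.
#' @export
scan_genotypes <- function(gspec, alpha = 0.05, alpha_pairwise = 0.05 / 3,
                           expected_min = 5) {
  stopifnot(inherits(gspec, "genotype_spectrum"))
  scan_counts(gspec$counts, gspec$N_families, alpha, alpha_pairwise, expected_min)
}
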