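#' Define a regional sampling profile for cohort simulation
#'
#' A profile captures the generative structure the analysis assumes in
#' one region: a mutant-allele frequency vector, random-mating genotype
#' formation with an optional homozygosity excess (probability that a
#' family's second allele copies its first, over and above chance), a
#' per-allele detection-failure rate (masking the allele to unknown), a
#' sibling-duplication rate, and a rate of cis-compound alleles.
#'
#' @param region region label (`north`/`border`/`south` or any label).
#' @param allele_freqs named probability vector over allele identities,
#'   summing to 1.
#' @param n_families number of families to simulate.
#' @param homozygosity_excess,detection_failure_rate,sibling_rate,compound_rate
#'   probabilities in `[0, 1]`.
#' @param province province name written into the simulated records
#'   (defaults to a representative province of the region, so that the
#'   standard region map resolves it back).
#' @return a `region_profile`.
#' @export
region_profile <- function(region, allele_freqs, n_families,
                           homozygosity_excess = 0,
                           detection_failure_rate = 0,
                           sibling_rate = 0,
                           compound_rate = 0,
                           province = NULL) {
  probs <- c(homozygosity_excess, detection_failure_rate, sibling_rate,
             compound_rate)
  if (any(probs < 0 | probs > 1)) stop("profile rates must lie in [0, 1]")
  if (any(allele_freqs < 0) || is.null(names(allele_freqs)))
    stop("allele_freqs must be a named non-negative vector")
  if (abs(sum(allele_freqs) - 1) > 1e-12)
    stop("allele frequencies must sum to 1 (got ", sum(allele_freqs), ")")
  if (n_families < 0) stop("n_families must be non-negative")
  if (is.null(province)) {
    province <- c(north = "Beijing", border = "Shanghai",
                  south = "Guangdong")[region]
    if (is.na(province)) province <- NA_character_
  }
  structure(list(region = region, allele_freqs = allele_freqs,
                 n_families = as.integer(n_families),
                 homozygosity_excess = homozygosity_excess,
                 detection_failure_rate = detection_failure_rate,
                 sibling_rate = sibling_rate,
                 compound_rate = compound_rate,
                 province = province),
            class = "region_profile")
}

#' Default simulation profiles mirroring the reconstructed spectrum
#'
#' One profile per region with the detected-allele frequency vector taken
#' from the reconstructed regional allele counts, the detection-failure
#' rate set to the regional undetected-allele fraction (1/55, 0, 5/392),
#' and family counts of half the regional allele totals rounded up
#' (28, 41, 196).
#'
#' @param spec a `regional_spectrum` to mirror (default: the
#'   reconstructed printed spectrum).
#' @return list of three `region_profile` objects.
#' @export
reference_profiles <- function(spec = build_table2_fixture()) {
  lapply(names(spec$N), function(r) {
    m <- spec$counts[, r]
    m <- m[m > 0]
    detected <- spec$N[[r]] - spec$unknown[[r]]
    region_profile(
      region = r,
      allele_freqs = m / detected,
      n_families = as.integer(ceiling(spec$N[[r]] / 2)),
      detection_failure_rate = spec$unknown[[r]] / spec$N[[r]]
    )
  })
}

# deterministic per-family substream: family counts can grow without
# reshuffling earlier families of the same profile
family_seed <- function(seed, profile_index, family_index) {
  (as.integer(seed) + 1000003L * profile_index + 131L * family_index) %%
    2147483629L
}

#' Simulate a cohort under regional sampling profiles
#'
#' For each family, allele 1 is drawn from the profile's frequency
#' vector; with probability `homozygosity_excess` allele 2 copies it,
#' otherwise allele 2 is drawn independently (random mating). Each allele
#' is then independently turned into a two-variant cis compound with
#' probability `compound_rate`, masked to unknown with probability
#' `detection_failure_rate`, and the family contributes a genotype-
#' identical sibling record with probability `sibling_rate`. One integer
#' seed drives everything through deterministic per-family substreams, so
#' a fixed seed yields a byte-identical cohort TSV.
#'
#' @param profiles a `region_profile` or list of them.
#' @param seed integer seed.
#' @return a `cd_cohort` (writable with [write_cohort()], re-readable
#'   with [read_cohort()] when identities are registry-resolvable).
#' @export
generate_cohort <- function(profiles, seed) {
  if (inherits(profiles, "region_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "region_profile")))
  rows <- list()
  for (pi in seq_along(profiles)) {
    pr <- profiles[[pi]]
    ids <- names(pr$allele_freqs)
    for (fi in seq_len(pr$n_families)) {
      set.seed(family_seed(seed, pi, fi))
      a1 <- sample(ids, 1, prob = pr$allele_freqs)
      a2 <- if (stats::runif(1) < pr$homozygosity_excess) a1
            else sample(ids, 1, prob = pr$allele_freqs)
      alleles <- c(a1, a2)
      for (k in 1:2) {
        if (stats::runif(1) < pr$compound_rate) {
          partner <- sample(ids, 1, prob = pr$allele_freqs)
          alleles[k] <- paste0("[", alleles[k], ";", partner, "]")
        }
        if (stats::runif(1) < pr$detection_failure_rate) alleles[k] <- "?"
      }
      sex <- sample(c("male", "female"), 1)
      fam <- sprintf("SIM-%s-%04d", pr$region, fi)
      rec <- data.frame(patient_id = fam, family_id = fam, sex = sex,
                        father_province = pr$province,
                        mother_province = pr$province,
                        region = pr$region,
                        allele1 = alleles[1], allele2 = alleles[2],
                        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- rec
      if (stats::runif(1) < pr$sibling_rate) {
        sib <- rec
        sib$patient_id <- paste0(fam, "S")
        sib$sex <- sample(c("male", "female"), 1)
        rows[[length(rows) + 1]] <- sib
      }
    }
  }
  new_cohort(do.call(rbind, rows))
}

#' Frequency- and homozygosity-recovery experiment
#'
#' Runs the full pipeline (simulate, deduplicate, allele spectrum,
#' omnibus scan, theoretical homozygosity) on `n_reps` replicate cohorts
#' and summarizes estimator quality: per-identity per-region bias and
#' RMSE of the allele-frequency estimates, the omnibus rejection rate per
#' identity, and per-region bias of J. Under identical profiles the
#' rejection rates estimate the type-I error; under region-specific
#' profiles they estimate power.
#'
#' @param profiles list of `region_profile` objects (one per region).
#' @param n_reps number of replicates (at least 1).
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param alpha omnibus significance level.
#' @return list with `frequencies` (data frame: identity, region,
#'   true, mean_est, bias, rmse), `rejection` (data frame: identity,
#'   reject_rate) and `homozygosity` (data frame: region, true_J,
#'   mean_J, bias). Standard errors are omitted when `n_reps = 1`.
#' @export
recovery_experiment <- function(profiles, n_reps, seed, alpha = 0.05) {
  stopifnot(n_reps >= 1)
  regions <- vapply(profiles, function(p) p$region, character(1))
  ids <- sort(unique(unlist(lapply(profiles, function(p) names(p$allele_freqs)))),
              method = "radix")
  true_freq <- sapply(profiles, function(p) {
    f <- stats::setNames(rep(0, length(ids)), ids)
    f[names(p$allele_freqs)] <- p$allele_freqs
    # truth is stated on the detected-allele scale
    f * (1 - p$detection_failure_rate)
  })
  colnames(true_freq) <- regions
  true_J <- vapply(profiles, function(p) {
    u_rate <- p$detection_failure_rate
    sum((p$allele_freqs * (1 - u_rate))^2)  # masked alleles are each-unique
  }, numeric(1))

  est <- array(NA_real_, dim = c(length(ids), length(regions), n_reps),
               dimnames = list(ids, regions, NULL))
  Jest <- matrix(NA_real_, n_reps, length(regions),
                 dimnames = list(NULL, regions))
  reject <- matrix(FALSE, n_reps, length(ids), dimnames = list(NULL, ids))
  for (r in seq_len(n_reps)) {
    cohort <- generate_cohort(profiles, seed + r)
    fams <- dedupe_families(cohort)
    spec <- allele_spectrum(fams)
    for (reg in regions) {
      f <- relative_frequencies(spec, reg) / 100
      hit <- intersect(ids, names(f))
      est[hit, reg, r] <- f[hit]
      est[setdiff(ids, hit), reg, r] <- 0
      Jest[r, reg] <- theoretical_homozygosity(spec, reg)$value
    }
    scan <- scan_spectrum(spec, alpha = alpha)
    sig <- intersect(scan$significant, ids)
    reject[r, sig] <- TRUE
  }
  freq_df <- do.call(rbind, lapply(regions, function(reg) {
    data.frame(identity = ids, region = reg,
               true = true_freq[, reg],
               mean_est = apply(est[, reg, , drop = FALSE], 1, mean),
               bias = apply(est[, reg, , drop = FALSE], 1, mean) - true_freq[, reg],
               rmse = sqrt(apply((est[, reg, , drop = FALSE] -
                                    true_freq[, reg])^2, 1, mean)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rej_df <- data.frame(identity = ids, reject_rate = colMeans(reject),
                       stringsAsFactors = FALSE, row.names = NULL)
  if (n_reps > 1)
    rej_df$se <- sqrt(rej_df$reject_rate * (1 - rej_df$reject_rate) / n_reps)
  hom_df <- data.frame(region = regions, true_J = true_J,
                       mean_J = colMeans(Jest),
                       bias = colMeans(Jest) - true_J,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(frequencies = freq_df, rejection = rej_df, homozygosity = hom_df,
       n_reps = n_reps)
}
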