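test_that("profile validation rejects malformed configurations", {
  expect_error(region_profile("south", c(a = 0.5, b = 0.4), 10), "sum to 1")
  expect_error(region_profile("south", c(a = 1), 10, homozygosity_excess = 1.2),
               "\\[0, 1\\]")
  expect_error(region_profile("south", c(0.5, 0.5), 10), "named")
})

test_that("a monomorphic profile yields only homozygotes", {
  pr <- region_profile("south", c("c.851_854del4" = 1), n_families = 10)
  cohort <- generate_cohort(pr, seed = 1)
  expect_true(all(cohort$allele1 == "c.851_854del4"))
  expect_true(all(cohort$allele2 == "c.851_854del4"))
  gspec <- genotype_spectrum(genotype_analysis_subset(dedupe_families(cohort)))
  expect_equal(observed_homozygosity(gspec, "south")$value, 1)
})

test_that("generation is byte-deterministic for a fixed seed", {
  profiles <- reference_profiles(table2_spec)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(generate_cohort(profiles, seed = 123), f1)
  write_cohort(generate_cohort(profiles, seed = 123), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # different seed, different cohort
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(generate_cohort(profiles, seed = 124), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
  # earlier families are unchanged when the count grows
  small <- region_profile("north", c(a = 0.5, b = 0.5), 20)
  big <- region_profile("north", c(a = 0.5, b = 0.5), 40)
  c_small <- generate_cohort(small, seed = 5)
  c_big <- generate_cohort(big, seed = 5)
  expect_identical(as.data.frame(c_small),
                   as.data.frame(c_big)[seq_len(nrow(c_small)), ],
                   ignore_attr = TRUE)
})

test_that("simulated cohorts round-trip through the TSV reader", {
  pr <- region_profile("south",
                       c("c.851_854del4" = 0.7, "IVS16ins3kb" = 0.3),
                       n_families = 30, detection_failure_rate = 0.1,
                       sibling_rate = 0.2,
                       compound_rate = 0.05)
  cohort <- generate_cohort(pr, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, tmp)
  back <- read_cohort(tmp)
  expect_equal(nrow(back), nrow(cohort))
  expect_identical(back$allele1, cohort$allele1)
  expect_identical(back$region, cohort$region)  # province resolves back
  # siblings share the proband genotype
  fams <- dedupe_families(back)
  expect_lte(nrow(fams), nrow(back))
})

test_that("allele frequencies and homozygosity are recovered at scale", {
  freqs <- c("c.851_854del4" = 0.6556, "IVS16ins3kb" = 0.2, "IVS6+5G>A" = 0.1444)
  pr <- region_profile("south", freqs, n_families = 5000)
  cohort <- dedupe_families(generate_cohort(pr, seed = 99))
  spec <- allele_spectrum(cohort)
  n_alleles <- 2 * 5000
  est <- relative_frequencies(spec, "south")[["c.851_854del4"]] / 100
  se <- sqrt(0.6556 * (1 - 0.6556) / n_alleles)
  expect_lt(abs(est - 0.6556), 3 * se)
  J_true <- sum(freqs^2)
  J_est <- theoretical_homozygosity(spec, "south")$value
  expect_lt(abs(J_est - J_true), 0.02)
})

test_that("masking produces the expected undetected-allele fraction", {
  pr <- region_profile("north", c(a = 0.5, b = 0.5), n_families = 2000,
                       detection_failure_rate = 0.15)
  cohort <- generate_cohort(pr, seed = 17)
  frac <- mean(c(cohort$allele1, cohort$allele2) == "?")
  se <- sqrt(0.15 * 0.85 / (2 * 2000))
  expect_lt(abs(frac - 0.15), 3 * se)
})

test_that("genotype frequencies follow Hardy-Weinberg without excess", {
  freqs <- c(a = 0.7, b = 0.3)
  pr <- region_profile("border", freqs, n_families = 4000)
  gspec <- genotype_spectrum(genotype_analysis_subset(
    dedupe_families(generate_cohort(pr, seed = 31))))
  n <- sum(gspec$N_families)
  p_aa <- gspec$counts["a/a", "border"] / n
  p_ab <- gspec$counts["a/b", "border"] / n
  expect_lt(abs(p_aa - 0.49), 3 * sqrt(0.49 * 0.51 / n))
  expect_lt(abs(p_ab - 0.42), 3 * sqrt(0.42 * 0.58 / n))
  # homozygosity excess shifts mass onto the diagonal
  pr2 <- region_profile("border", freqs, n_families = 4000,
                        homozygosity_excess = 0.5)
  gspec2 <- genotype_spectrum(genotype_analysis_subset(
    dedupe_families(generate_cohort(pr2, seed = 31))))
  p_aa2 <- gspec2$counts["a/a", "border"] / sum(gspec2$N_families)
  expect_gt(p_aa2, p_aa + 0.05)
})

test_that("recovery experiment summarizes bias, RMSE and rejections", {
  profiles <- list(
    region_profile("north", c(a = 0.5, b = 0.5), 30),
    region_profile("south", c(a = 0.9, b = 0.1), 120))
  res <- recovery_experiment(profiles, n_reps = 3, seed = 50)
  expect_named(res, c("frequencies", "rejection", "homozygosity", "n_reps"))
  expect_setequal(unique(res$frequencies$region), c("north", "south"))
  expect_true(all(res$rejection$reject_rate >= 0 & res$rejection$reject_rate <= 1))
  expect_true(all(is.finite(res$homozygosity$mean_J)))
  # a single replicate carries no standard error column
  res1 <- recovery_experiment(profiles, n_reps = 1, seed = 51)
  expect_false("se" %in% names(res1$rejection))
  # the strong north/south split should be detected
  expect_gte(res$rejection$reject_rate[res$rejection$identity == "a"], 2 / 3)
})
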