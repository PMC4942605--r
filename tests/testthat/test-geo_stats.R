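test_that("exact test reproduces the hand-verifiable printed P values", {
  cases <- list(
    list(k = c(0, 2, 0), p = 0.034),
    list(k = c(2, 0, 1), p = 0.041),
    list(k = c(1, 0, 0), p = 0.104),
    list(k = c(0, 1, 0), p = 0.258),
    list(k = c(0, 0, 1), p = 1.000)
  )
  for (cs in cases) {
    tab <- rbind(cs$k, regional_N - cs$k)
    expect_equal(round_half_up(freeman_halton_exact(tab)$p, 3), cs$p)
  }
  # the singleton case has a closed form: only the observed table is as
  # improbable, so p = 55/528
  expect_equal(freeman_halton_exact(rbind(c(1, 0, 0), regional_N - c(1, 0, 0)))$p,
               55 / 528)
})

test_that("exact test handles degenerate margins and validates input", {
  expect_equal(freeman_halton_exact(rbind(c(0, 0, 0), c(5, 5, 5)))$p, 1)
  expect_equal(freeman_halton_exact(matrix(0, 2, 2))$p, 1)
  expect_error(freeman_halton_exact(rbind(c(-1, 2), c(3, 4))), "negative")
})

test_that("exact p is invariant under row and column permutation", {
  tabs <- list(rbind(c(3, 1, 0), c(10, 9, 25)),
               rbind(c(2, 5), c(8, 4)),
               rbind(c(0, 2, 0), regional_N - c(0, 2, 0)))
  for (tab in tabs) {
    p <- freeman_halton_exact(tab)$p
    expect_equal(freeman_halton_exact(tab[2:1, ])$p, p)
    expect_equal(freeman_halton_exact(tab[, rev(seq_len(ncol(tab)))])$p, p)
    expect_equal(freeman_halton_exact(t(tab))$p, p)
  }
})

test_that("exact test matches independent oracles on small 2x2 tables", {
  # brute-force hypergeometric enumeration (helper) and fisher.test agree
  for (n1 in 2:6) for (n2 in 2:6) for (a in 0:n1) for (b in 0:n2) {
    tab <- rbind(c(a, n1 - a), c(b, n2 - b))
    p <- freeman_halton_exact(tab)$p
    expect_equal(p, brute_force_2x2_p(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("exact test matches fisher.test and Monte Carlo on a 2x3 table", {
  tab <- rbind(c(3, 1, 7), c(12, 19, 8))
  p <- freeman_halton_exact(tab)$p
  expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  # Monte Carlo estimate from margin-preserving sampled tables
  set.seed(42)
  sims <- stats::r2dtable(1e5, rowSums(tab), colSums(tab))
  lp_obs <- sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
  lp_sim <- vapply(sims, function(t2) -sum(lgamma(t2 + 1)), numeric(1)) +
    sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1)
  phat <- mean(lp_sim <= lp_obs + log1p(1e-7))
  se <- sqrt(phat * (1 - phat) / 1e5)
  expect_lt(abs(p - phat), 3 * se)
})

test_that("Pearson chi-square wraps the asymptotic test with expected counts", {
  flat <- rbind(c(10, 10), c(10, 10))
  res <- pearson_chi2(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$expected_min, 10)

  # printed pairwise comparison: IVS16ins3kb carriers south vs border
  res2 <- pearson_chi2(rbind(c(29, 392 - 29), c(13, 81 - 13)))
  expect_equal(round_half_up(res2$p, 3), 0.013)
  # observed homozygosity south vs north
  res3 <- pearson_chi2(rbind(c(99, 88), c(4, 19)))
  expect_equal(round_half_up(res3$p, 3), 0.001)

  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "zero row or column")
})

test_that("Pearson X2 on 2x2 equals the squared two-proportion z statistic", {
  tabs <- list(rbind(c(29, 363), c(13, 68)), rbind(c(99, 88), c(4, 19)),
               rbind(c(7, 13), c(11, 9)))
  for (tab in tabs) {
    n <- rowSums(tab); x <- tab[, 1]
    phat <- sum(x) / sum(n)
    z <- (x[1] / n[1] - x[2] / n[2]) /
      sqrt(phat * (1 - phat) * (1 / n[1] + 1 / n[2]))
    expect_equal(pearson_chi2(tab)$statistic, z^2)
  }
})

test_that("omnibus test selects the method by the expected-count rule", {
  res <- omnibus_test(c(15, 36, 257), regional_N)
  expect_identical(res$method, "pearson-chi2")
  expect_lt(res$p, 0.0005)

  res2 <- omnibus_test(c(0, 2, 0), regional_N)
  expect_identical(res2$method, "freeman-halton-exact")
  expect_equal(round_half_up(res2$p, 3), 0.034)

  expect_equal(omnibus_test(c(0, 0, 0), regional_N)$p, 1)
})

test_that("spectrum scan flags exactly the seven heterogeneous mutations", {
  scan <- scan_spectrum(table2_spec)
  expect_setequal(scan$significant,
                  c("c.775C>T", "c.851_854del4", "c.1078C>T", "IVS11+1G>A",
                    "c.1364G>T", "c.1399C>T", "IVS16ins3kb"))
  # the undetected class participates in the scan like a spectrum row
  expect_true("Unknown" %in% scan$omnibus$identity)
  # pairwise reports only exist for omnibus-significant identities
  expect_setequal(names(scan$pairwise), scan$significant)
  # reproducible pairwise values: IVS16ins3kb lower in the south than in
  # the border (0.013) and the north (0.005)
  pw <- scan$pairwise[["IVS16ins3kb"]]
  expect_equal(round_half_up(pw$p[pw$pair == "border-vs-south"], 3), 0.013)
  expect_equal(round_half_up(pw$p[pw$pair == "north-vs-south"], 3), 0.005)
  # Bonferroni threshold: 0.013 < 0.017 is significant, 0.55 is not
  expect_true(pw$significant[pw$pair == "border-vs-south"])
  expect_false(pw$significant[pw$pair == "north-vs-border"])

  one_region <- new_regional_spectrum(
    matrix(c(3L, 0L), 2, 1, dimnames = list(c("a", "b"), "x")))
  expect_error(scan_spectrum(new_regional_spectrum(
    matrix(c(3L, 0L, 0L, 0L), 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))),
    "zero total")
  expect_s3_class(scan_spectrum(one_region), "cd_scan")
})

test_that("genotype scan flags exactly the two heterogeneous genotypes", {
  scan <- scan_genotypes(table4_gspec)
  expect_setequal(scan$significant,
                  c("c.851_854del4/c.851_854del4", "c.1399C>T/c.851_854del4"))
  del4 <- scan$omnibus[scan$omnibus$identity == "c.851_854del4/c.851_854del4", ]
  expect_identical(del4$method, "pearson-chi2")
  expect_lt(del4$p, 0.0005)
  # del4 homozygote much commoner in the south than the north
  pw <- scan$pairwise[["c.851_854del4/c.851_854del4"]]
  expect_lt(pw$p[pw$pair == "north-vs-south"], 0.0005)

  solo <- new_genotype_spectrum(matrix(c(2L, 3L), 1, 2,
                                       dimnames = list("a/a", c("x", "y"))))
  expect_equal(scan_genotypes(solo)$omnibus$p, 1)
})

test_that("null calibration: exact omnibus rejection rate is at most nominal", {
  # simulate null 3-region carrier tables at the study's allele totals
  set.seed(2024)
  n_sims <- 1000
  rate <- 0.04  # a typical low-frequency mutation
  rejections <- 0L
  for (i in seq_len(n_sims)) {
    k <- stats::rbinom(3, regional_N, rate)
    if (omnibus_test(k, regional_N)$p < 0.05) rejections <- rejections + 1L
  }
  prop <- rejections / n_sims
  se <- sqrt(0.05 * 0.95 / n_sims)
  expect_lte(prop, 0.05 + 3 * se)
})

test_that("P value rendering truncates below half a thousandth", {
  expect_identical(format_p(c(0.0004, 0.0126, 1)), c("0.000", "0.013", "1.000"))
})
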