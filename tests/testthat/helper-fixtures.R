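# shared fixtures, built once per test run
reg <- default_registry()
table2_spec <- build_table2_fixture(reg)
table4_gspec <- build_table4_fixture(reg)
regional_N <- c(north = 55L, border = 81L, south = 392L)
family_N <- c(north = 23L, border = 35L, south = 187L)

# build a small in-memory cohort data frame without going through a file
make_cohort <- function(patient_id, allele1, allele2,
                        family_id = patient_id,
                        region = "unstated", sex = "unstated") {
  structure(
    data.frame(patient_id = patient_id, family_id = family_id, sex = sex,
               father_province = NA_character_, mother_province = NA_character_,
               region = region, allele1 = allele1, allele2 = allele2,
               stringsAsFactors = FALSE),
    class = c("cd_cohort", "data.frame"))
}

# independent brute-force two-sided exact p for a 2x2 table
# (probability method: sum of hypergeometric point probabilities not
# exceeding the observed one)
brute_force_2x2_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
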