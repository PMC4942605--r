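test_that("province-to-region map partitions the 26 provinces", {
  rmap <- default_region_map()
  expect_length(rmap, 26)
  expect_setequal(unique(unname(rmap)), c("north", "border", "south"))
  expect_equal(sum(rmap == "north"), 10)
  expect_equal(sum(rmap == "border"), 6)
  expect_equal(sum(rmap == "south"), 10)
  expect_identical(unname(rmap["Guangdong"]), "south")
  expect_identical(unname(rmap["Beijing"]), "north")
  expect_identical(unname(rmap["Sichuan"]), "border")
})

test_that("region resolution handles shared, mixed and missing parents", {
  expect_identical(resolve_region("Guangdong", "Guangxi"), "south")
  expect_identical(resolve_region("Beijing", "Guangdong"), "mixed")
  expect_identical(resolve_region("Hubei", NA), "border")
  expect_identical(resolve_region(NA_character_, NA_character_), "unstated")
  expect_identical(resolve_region("Atlantis", NA), "unstated")
})

test_that("read_cohort parses the packaged table and tolerates bad rows", {
  cohort <- packaged_cohort()
  expect_s3_class(cohort, "cd_cohort")
  expect_equal(nrow(cohort), 154)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tfamily_id\tsex\tfather_province\tmother_province\tallele1\tallele2",
               "P1\tP1\tmale\tGuangdong\tGuangdong\tc.851_854del4\tc.851_854del4",
               "P2\tP2\tfemale\tGuangdong\tGuangdong\tc.bogus\tc.851_854del4"),
             tmp)
  co <- read_cohort(tmp)
  expect_equal(nrow(co), 1)
  expect_identical(co$region, "south")
  errs <- attr(co, "parse_errors")
  expect_equal(nrow(errs), 1)
  expect_identical(errs$patient_id, "P2")
  expect_match(errs$error, "unresolvable")

  # empty file with header
  writeLines("patient_id\tfamily_id\tsex\tfather_province\tmother_province\tallele1\tallele2",
             tmp)
  expect_equal(nrow(read_cohort(tmp)), 0)

  # missing column is a format error
  writeLines(c("patient_id\tallele1\tallele2", "P1\ta\tb"), tmp)
  expect_error(read_cohort(tmp), "required column")
})

test_that("family deduplication keeps one representative, checks concordance", {
  cohort <- packaged_cohort()
  fams <- dedupe_families(cohort)
  expect_equal(attr(fams, "n_families"), 151)
  expect_false(any(duplicated(fams$family_id)))
  # siblings removed, proband (smallest id) kept
  expect_true("C0253" %in% fams$patient_id)
  expect_false("C0253S" %in% fams$patient_id)

  no_sibs <- make_cohort(c("A", "B"), c("c.851_854del4", "c.2T>C"),
                         c("c.851_854del4", "c.72T>A"))
  expect_equal(nrow(dedupe_families(no_sibs)), 2)

  discordant <- make_cohort(c("A", "AS"), c("c.851_854del4", "c.2T>C"),
                            c("c.851_854del4", "c.72T>A"), family_id = c("A", "A"))
  expect_error(dedupe_families(discordant), "discordant")
})

test_that("genotype-analysis subset excludes unknown-allele and mixed-region families", {
  cohort <- make_cohort(
    c("A", "B", "C", "D"),
    c("c.851_854del4", "c.851_854del4", "c.2T>C", "?"),
    c("c.851_854del4", "?", "c.72T>A", "?"),
    region = c("south", "south", "mixed", "north"))
  sub <- genotype_analysis_subset(cohort)
  expect_identical(sub$patient_id, "A")
  excl <- attr(sub, "exclusions")
  expect_equal(nrow(sub) + nrow(excl), nrow(cohort))
  expect_identical(excl$reason[match(c("B", "C", "D"), excl$family_id)],
                   c("unknown_allele", "mixed_region", "unknown_allele"))

  clean <- make_cohort("A", "c.851_854del4", "c.851_854del4", region = "south")
  expect_equal(nrow(genotype_analysis_subset(clean)), 1)

  all_unknown <- make_cohort(c("A", "B"), c("?", "?"), c("?", "?"),
                             region = c("north", "south"))
  sub2 <- genotype_analysis_subset(all_unknown)
  expect_equal(nrow(sub2), 0)
  expect_equal(nrow(attr(sub2, "exclusions")), 2)
})

test_that("count reconstruction recovers exact integer columns", {
  expect_identical(unname(colSums(table2_spec$counts) + table2_spec$unknown),
                   as.numeric(regional_N))
  expect_identical(unname(table2_spec$N), as.numeric(regional_N))
  expect_equal(table2_spec$counts["c.851_854del4", "north"], 15)
  expect_equal(table2_spec$counts["c.851_854del4", "south"], 257)
  expect_identical(unname(table2_spec$unknown), c(1L, 0L, 5L))

  expect_identical(unname(colSums(table4_gspec$counts)), as.numeric(family_N))
  homo <- rownames(table4_gspec$counts)[
    vapply(strsplit(rownames(table4_gspec$counts), "/", fixed = TRUE),
           function(x) length(x) == 2 && x[1] == x[2], logical(1))]
  expect_equal(sum(table4_gspec$counts[homo, "north"]), 4)

  # a frequency column that cannot be a count vector is rejected
  bad <- matrix(c(50, 40), ncol = 1, dimnames = list(c("a", "b"), "x"))
  expect_error(reconstruct_counts(bad, c(x = 10L)), "do not sum")
})
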