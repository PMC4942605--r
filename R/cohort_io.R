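#' Read a province-to-region map
#'
#' Geographic stratification uses the Yangtze River as the historical
#' population boundary: provinces are assigned to `north`, `border`
#' (straddling the river) or `south`. The packaged default covers the 26
#' provinces, autonomous regions and municipalities represented in the
#' cohort.
#'
#' @param path tab-separated file with columns `province` and `region`.
#' @return named character vector mapping province to region, class
#'   `region_map`.
#' @export
read_region_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("province", "region") %in% names(df)))
    stop("region map needs columns 'province' and 'region'")
  bad <- setdiff(unique(df$region), c("north", "border", "south"))
  if (length(bad) > 0) stop("unknown region label: ", paste(bad, collapse = ", "))
  if (anyDuplicated(tolower(df$province)))
    stop("province mapped more than once: ",
         paste(df$province[duplicated(tolower(df$province))], collapse = ", "))
  structure(stats::setNames(df$region, df$province), class = "region_map")
}

#' @rdname read_region_map
#' @export
default_region_map <- function() {
  read_region_map(system.file("extdata", "region_map.tsv",
                              package = "citrinspectrum", mustWork = TRUE))
}

resolve_province <- function(province, region_map) {
  vapply(province, function(p) {
    if (is.na(p) || !nzchar(p) || identical(p, "NA")) return(NA_character_)
    hit <- match(tolower(p), tolower(names(region_map)))
    if (is.na(hit)) NA_character_ else unname(region_map[hit])
  }, character(1), USE.NAMES = FALSE)
}

#' Resolve a patient's region from parental provinces
#'
#' The region of a case is the region shared by both parents; parents
#' from different regions give `mixed` (such families are excluded from
#' genotype-level comparisons). A single stated parent determines the
#' region alone; no stated or resolvable parent gives `unstated`.
#'
#' @param father_province,mother_province character vectors.
#' @param region_map a `region_map`.
#' @return character vector of `north`/`border`/`south`/`mixed`/`unstated`.
#' @export
resolve_region <- function(father_province, mother_province,
                           region_map = default_region_map()) {
  rf <- resolve_province(father_province, region_map)
  rm_ <- resolve_province(mother_province, region_map)
  out <- ifelse(is.na(rf) & is.na(rm_), "unstated",
         ifelse(is.na(rf), rm_,
         ifelse(is.na(rm_), rf,
         ifelse(rf == rm_, rf, "mixed"))))
  out
}

new_cohort <- function(df, parse_errors = NULL) {
  rownames(df) <- NULL
  structure(df, parse_errors = parse_errors,
            class = c("cd_cohort", "data.frame"))
}

#' Read a cohort genotype table
#'
#' Reads a tab-separated cohort table (one row per patient) and parses
#' every genotype against the variant registry. Rows that fail to parse
#' are dropped and reported in the `parse_errors` attribute rather than
#' aborting the whole read, so a single typo never blocks a cohort.
#'
#' @param path TSV with header columns `patient_id`, `family_id`, `sex`,
#'   `father_province`, `mother_province`, `allele1`, `allele2`.
#'   `"?"` marks an undetected allele and `"NA"` an unstated field.
#' @param region_map a `region_map` used to resolve parental provinces.
#' @param registry a `variant_registry`.
#' @return a `cd_cohort`: data frame with the input columns plus `region`
#'   and canonical `allele1`/`allele2` identity strings. Attribute
#'   `parse_errors` holds a per-row error report (possibly empty).
#' @export
read_cohort <- function(path, region_map = default_region_map(),
                        registry = default_registry()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                          quote = "", colClasses = "character")
  needed <- c("patient_id", "family_id", "sex", "father_province",
              "mother_province", "allele1", "allele2")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("cohort file lacks required column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    out <- data.frame(patient_id = character(0), family_id = character(0),
                      sex = character(0), father_province = character(0),
                      mother_province = character(0), region = character(0),
                      allele1 = character(0), allele2 = character(0),
                      stringsAsFactors = FALSE)
    return(new_cohort(out, parse_errors = data.frame(patient_id = character(0),
                                                     error = character(0))))
  }
  df$family_id[is.na(df$family_id) | !nzchar(df$family_id)] <-
    sub("S$", "", df$patient_id[is.na(df$family_id) | !nzchar(df$family_id)])
  df$sex <- ifelse(is.na(df$sex), "unstated", tolower(df$sex))
  df$sex[!df$sex %in% c("male", "female")] <- "unstated"
  df$region <- resolve_region(df$father_province, df$mother_province, region_map)

  errs <- character(nrow(df))
  a1 <- a2 <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    res <- tryCatch({
      al1 <- parse_allele(df$allele1[i], registry)
      al2 <- parse_allele(df$allele2[i], registry)
      c(allele_identity(al1), allele_identity(al2))
    }, error = function(e) conditionMessage(e))
    if (length(res) == 2) {
      a1[i] <- res[1]; a2[i] <- res[2]
    } else {
      errs[i] <- res
    }
  }
  bad <- nzchar(errs)
  report <- data.frame(patient_id = df$patient_id[bad], error = errs[bad],
                       stringsAsFactors = FALSE)
  df$allele1 <- a1
  df$allele2 <- a2
  out <- df[!bad, c("patient_id", "family_id", "sex", "father_province",
                    "mother_province", "region", "allele1", "allele2")]
  new_cohort(out, parse_errors = report)
}

#' Write a cohort to TSV
#'
#' Inverse of [read_cohort()]: allele identities are written in canonical
#' form and unstated fields as `"NA"`. Byte-stable for a given cohort, so
#' seeded simulations round-trip identically.
#'
#' @param cohort a `cd_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("patient_id", "family_id", "sex", "father_province",
            "mother_province", "allele1", "allele2")
  df <- as.data.frame(cohort)[, cols]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged newly-diagnosed patient cohort
#'
#' The 154 newly diagnosed NICCD patients with their biallelic SLC25A13
#' genotypes and sex. Sibling records share the proband's family id
#' (patient ids carry an `S` suffix). Parental provinces are not part of
#' the published per-patient table and are therefore unstated here;
#' region-stratified results in this package come from the reconstructed
#' regional count fixtures instead (see [build_table2_fixture()]).
#'
#' @inheritParams read_cohort
#' @return a `cd_cohort` of 154 records.
#' @export
packaged_cohort <- function(region_map = default_region_map(),
                            registry = default_registry()) {
  read_cohort(system.file("extdata", "table1_cohort.tsv",
                          package = "citrinspectrum", mustWork = TRUE),
              region_map = region_map, registry = registry)
}

#' Collapse a cohort to one representative per family
#'
#' Siblings (shared `family_id`) carry the same biallelic genotype, so a
#' family contributes a single pair of independent alleles. The
#' representative is the lexicographically smallest `patient_id` — an
#' arbitrary but deterministic choice. Discordant genotypes within a
#' family are a data error and abort.
#'
#' @param cohort a `cd_cohort`.
#' @return a `cd_cohort` with one record per family; attribute
#'   `n_families` gives the family count.
#' @export
dedupe_families <- function(cohort) {
  stopifnot(inherits(cohort, "cd_cohort"))
  df <- as.data.frame(cohort)
  if (nrow(df) == 0) return(new_cohort(df))
  gid <- mapply(genotype_identity, df$allele1, df$allele2, USE.NAMES = FALSE)
  split_gid <- split(gid, df$family_id)
  discordant <- names(split_gid)[vapply(split_gid, function(g)
    length(unique(g)) > 1, logical(1))]
  if (length(discordant) > 0)
    stop("siblings with discordant genotypes in family(ies): ",
         paste(discordant, collapse = ", "))
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$family_id), function(idx) {
    idx[order(df$patient_id[idx], method = "radix")[1]]
  }), use.names = FALSE)
  out <- df[sort(keep), , drop = FALSE]
  res <- new_cohort(out)
  attr(res, "n_families") <- nrow(out)
  res
}

#' Restrict to families eligible for genotype-level comparison
#'
#' Between-region genotype comparisons require both mutations identified
#' and an unambiguous region, so families with an undetected allele and
#' families whose parents come from different regions are excluded. Every
#' excluded family is logged with exactly one reason (`unknown_allele`
#' takes precedence over `mixed_region`).
#'
#' @param cohort a family-deduplicated `cd_cohort`.
#' @return the included subset, a `cd_cohort`; attribute `exclusions` is
#'   a data frame of `family_id` and `reason`.
#' @export
genotype_analysis_subset <- function(cohort) {
  stopifnot(inherits(cohort, "cd_cohort"))
  df <- as.data.frame(cohort)
  unknown <- df$allele1 == "?" | df$allele2 == "?"
  mixed <- df$region == "mixed"
  reason <- ifelse(unknown, "unknown_allele",
            ifelse(mixed, "mixed_region", NA_character_))
  excl <- data.frame(family_id = df$family_id[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  out <- new_cohort(df[is.na(reason), , drop = FALSE])
  attr(out, "exclusions") <- excl
  out
}
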