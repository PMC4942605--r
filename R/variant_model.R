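#' Normalize an SLC25A13 variant string
#'
#' Published mutation tables mix typographic conventions: spaces around
#' `+`/`>`/`/`, the Unicode minus sign, and occasional non-breaking
#' spaces. This transform maps every spelling of a variant to a single
#' whitespace-free ASCII form so that registry lookups are total.
#'
#' The transform removes all whitespace (including non-breaking spaces),
#' maps Unicode minus/dash characters to ASCII `-`, and leaves brackets
#' untouched. It is idempotent and purely syntactic: no HGVS semantic
#' validation is attempted.
#'
#' @param raw character vector of raw variant spellings.
#' @return character vector of normalized spellings.
#' @examples
#' normalize_variant_string("c.1452 + 1G > A")
#' normalize_variant_string("c.851_854del4")
#' @export
normalize_variant_string <- function(raw) {
  stopifnot(is.character(raw))
  x <- gsub("[\u2212\u2013\u2014]", "-", raw)
  gsub("[[:space:]\u00a0]+", "", x)
}

# Strip trailing protein-level annotations such as "(p.R467X)" that some
# tables append to the cDNA-level name. Applied at lookup time only, so
# normalize_variant_string() stays the documented pure transform.
strip_protein_annotation <- function(x) {
  gsub("\\([pP]\\.[^()]*\\)", "", x)
}

#' Read a variant registry
#'
#' A registry is the catalogue of distinct SLC25A13 mutation/variation
#' entities: one row per entity with its canonical cDNA-level name,
#' protein-level effect, mutational category, exon/intron location label
#' and any accepted legacy aliases (pipe-separated), e.g. the intron-based
#' IVS names used interchangeably with systematic names in the literature.
#'
#' @param path path to a tab-separated registry file with columns
#'   `canonical_id`, `protein_effect`, `category`, `location_label` and
#'   optionally `aliases`.
#' @return an object of class `variant_registry`: a data frame of the
#'   entries with a prebuilt alias lookup table in attribute `lookup`.
#' @seealso [default_registry()] for the packaged catalogue.
#' @export
read_variant_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          fill = TRUE, quote = "")
  needed <- c("canonical_id", "protein_effect", "category", "location_label")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("registry file lacks required column(s): ", paste(missing, collapse = ", "))
  if (!"aliases" %in% names(df)) df$aliases <- ""
  df$aliases[is.na(df$aliases)] <- ""
  df$canonical_id <- normalize_variant_string(df$canonical_id)
  if (anyDuplicated(df$canonical_id))
    stop("duplicated canonical_id in registry: ",
         paste(unique(df$canonical_id[duplicated(df$canonical_id)]), collapse = ", "))

  ok_cat <- c("missense", "nonsense", "deletion", "insertion", "duplication",
              "splice-site", "complex", "pathogenic-SNP", "aberrant-transcript")
  bad <- setdiff(unique(df$category), ok_cat)
  if (length(bad) > 0)
    stop("unknown variant category: ", paste(bad, collapse = ", "))

  alias_list <- strsplit(df$aliases, "|", fixed = TRUE)
  keys <- character(0); vals <- character(0)
  for (i in seq_len(nrow(df))) {
    al <- normalize_variant_string(alias_list[[i]])
    al <- al[nzchar(al)]
    ks <- unique(c(df$canonical_id[i], al))
    keys <- c(keys, ks)
    vals <- c(vals, rep(df$canonical_id[i], length(ks)))
  }
  if (anyDuplicated(keys))
    stop("alias sets are not pairwise disjoint: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  lookup <- stats::setNames(vals, keys)
  structure(df, lookup = lookup, class = c("variant_registry", "data.frame"))
}

#' The packaged SLC25A13 variant catalogue
#'
#' Forty-one detected mutation/variation entities with their protein
#' effects, categories, exon/intron locations and legacy aliases.
#' The undetected ("unknown") allele is a sentinel handled by the parser
#' and spectra, never a registry entry.
#'
#' @return a `variant_registry`.
#' @export
default_registry <- function() {
  read_variant_registry(system.file("extdata", "variant_registry.tsv",
                                    package = "citrinspectrum", mustWork = TRUE))
}

registry_lookup <- function(registry, token) {
  lookup <- attr(registry, "lookup")
  tok <- strip_protein_annotation(normalize_variant_string(token))
  unname(lookup[tok])
}

#' Parse one allele string
#'
#' One side of a biallelic genotype string. Three grammars are accepted:
#' `"?"` for an undetected allele; `"[a; b]"` for a cis-compound allele
#' carrying two (or more) mutations on one chromosome, unless the whole
#' bracketed string is itself a catalogued complex entity; and a plain
#' variant name (systematic or legacy alias) for a single-mutation allele.
#'
#' @param raw allele string.
#' @param registry a `variant_registry` used to resolve names.
#' @return an object of class `cd_allele`: list with `variants` (character
#'   vector of canonical ids, in cis order) and `unknown` (logical).
#' @export
parse_allele <- function(raw, registry = default_registry()) {
  stopifnot(is.character(raw), length(raw) == 1)
  x <- normalize_variant_string(raw)
  if (!nzchar(x)) stop("empty allele string")
  if (x == "?")
    return(structure(list(variants = character(0), unknown = TRUE),
                     class = "cd_allele"))
  # a catalogued complex entity wins over the compound grammar
  hit <- registry_lookup(registry, x)
  if (!is.na(hit))
    return(structure(list(variants = hit, unknown = FALSE), class = "cd_allele"))
  if (startsWith(x, "[") && endsWith(x, "]")) {
    parts <- strsplit(substr(x, 2, nchar(x) - 1), ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 1) stop("empty compound allele: ", raw)
    ids <- vapply(parts, function(p) registry_lookup(registry, p), character(1))
    if (anyNA(ids))
      stop("unresolvable variant string(s): ",
           paste(parts[is.na(ids)], collapse = ", "))
    return(structure(list(variants = unname(ids), unknown = FALSE),
                     class = "cd_allele"))
  }
  stop("unresolvable variant string: ", x)
}

#' Allele identity string
#'
#' Canonical label under which an allele is tallied: `"?"` for an
#' undetected allele, the canonical id for a single-mutation allele, and
#' the bracketed cis-ordered tuple `"[a;b]"` for a compound allele.
#'
#' @param allele a `cd_allele`.
#' @return a character scalar.
#' @export
allele_identity <- function(allele) {
  stopifnot(inherits(allele, "cd_allele"))
  if (allele$unknown) return("?")
  if (length(allele$variants) == 1) return(allele$variants)
  paste0("[", paste(allele$variants, collapse = ";"), "]")
}

#' @export
format.cd_allele <- function(x, ...) allele_identity(x)

#' @export
print.cd_allele <- function(x, ...) {
  cat("<allele> ", allele_identity(x), "\n", sep = "")
  invisible(x)
}

# split a genotype string at top-level "/" (not inside brackets)
split_genotype_string <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "[") depth <- depth + 1L
    else if (chars[i] == "]") depth <- depth - 1L
    else if (chars[i] == "/" && depth == 0L) cuts <- c(cuts, i)
  }
  if (length(cuts) != 1)
    stop("genotype string must contain exactly one top-level '/': ", x)
  c(substr(x, 1, cuts - 1), substr(x, cuts + 1, nchar(x)))
}

#' Parse a biallelic genotype string
#'
#' @param raw genotype string, two allele strings joined by a top-level
#'   `/` (a `/` inside a bracketed compound allele does not split).
#' @param registry a `variant_registry`.
#' @return list of two `cd_allele` objects, in source order. Downstream
#'   genotype identity is unordered; source order is retained only for
#'   round-tripping.
#' @export
parse_genotype <- function(raw, registry = default_registry()) {
  stopifnot(is.character(raw), length(raw) == 1)
  x <- normalize_variant_string(raw)
  sides <- split_genotype_string(x)
  lapply(sides, parse_allele, registry = registry)
}

#' Unordered genotype identity
#'
#' @param a1,a2 `cd_allele` objects or identity strings.
#' @return a character scalar `"x/y"` with the two allele identities in
#'   sorted order, so that phase order never distinguishes genotypes.
#' @export
genotype_identity <- function(a1, a2) {
  id1 <- if (inherits(a1, "cd_allele")) allele_identity(a1) else a1
  id2 <- if (inherits(a2, "cd_allele")) allele_identity(a2) else a2
  ids <- sort(c(id1, id2), method = "radix")
  paste(ids, collapse = "/")
}

# is a tallied genotype identity homozygous (identical allele identities)?
is_homozygous_identity <- function(genotype_id) {
  vapply(genotype_id, function(g) {
    sides <- split_genotype_string(g)
    sides[1] == sides[2]
  }, logical(1), USE.NAMES = FALSE)
}
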