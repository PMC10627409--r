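#' Normalize an ICD code for matching
#'
#' EHR extracts store ICD-10-CM codes both dotted ("K40.1") and undotted
#' ("K401"), with inconsistent case and stray whitespace. All matching inside
#' the package happens on the normalized form: uppercased, dots and whitespace
#' removed. Matching is exact after normalization; there is no prefix or
#' truncation fallback (unmapped codes are reported, never silently remapped).
#'
#' @param x character vector of ICD codes.
#' @return character vector of normalized codes.
#' @examples
#' normalize_icd(c("k40.1", " E10.9 ")) # "K401" "E109"
#' @export
normalize_icd <- function(x) {
  gsub("[.[:space:]]", "", toupper(as.character(x)))
}

# Supported vocabulary tokens, canonical form.
VOCABULARIES <- c("ICD9CM", "ICD10CM", "ICD10WHO")

#' Normalize a vocabulary token
#'
#' Accepts the canonical tokens `ICD9CM`, `ICD10CM`, `ICD10WHO` in any case
#' and with any punctuation (e.g. "ICD-10-CM"), plus the common spelling
#' "WHOICD10". Unknown tokens return `NA`.
#'
#' @param x character vector of vocabulary tokens.
#' @return character vector of canonical tokens, `NA` where unrecognized.
#' @export
normalize_vocab <- function(x) {
  v <- gsub("[^A-Z0-9]", "", toupper(as.character(x)))
  v[v == "WHOICD10"] <- "ICD10WHO"
  v[!(v %in% VOCABULARIES)] <- NA_character_
  v
}

#' Proportion with sanity checks
#'
#' Shared reporting helper used by the map summarizer and coverage reports:
#' the fraction `count / total`, validated to lie in \[0, 1\].
#'
#' @param count non-negative count (numerator).
#' @param total positive count (denominator).
#' @return numeric fraction in \[0, 1\].
#' @examples
#' prop_stat(6829, 54520) # ~0.125
#' @export
prop_stat <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0, count >= 0)
  if (any(count > total)) stop("count exceeds total")
  count / total
}

#' Fold ratio between two counts
#'
#' Used for category-growth reporting (e.g. number of codes in a category in
#' one map release relative to another).
#'
#' @param count numerator count.
#' @param reference positive reference count.
#' @return numeric ratio.
#' @examples
#' ratio_stat(297, 58) # ~5.1
#' @export
ratio_stat <- function(count, reference) {
  stopifnot(is.numeric(count), is.numeric(reference), reference > 0, count >= 0)
  count / reference
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so simulations do not perturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
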