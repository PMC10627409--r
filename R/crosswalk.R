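#' Construct a crosswalk between legacy and prefixed phecodes
#'
#' A crosswalk is a partial translation table between legacy numeric phecodes
#' and prefixed hierarchical labels. It is partial by design: many legacy
#' codes (notably injury/poisoning codes) have no counterpart, and lookups of
#' unlisted codes return an explicit empty result rather than failing. A code
#' may have several counterparts; translations are returned in sorted order.
#'
#' @param v12 character vector of legacy code strings.
#' @param x character vector of prefixed labels, same length.
#' @return object of class `phecode_crosswalk`.
#' @export
phecode_crosswalk <- function(v12, x) {
  v12 <- trimws(as.character(v12))
  x <- trimws(as.character(x))
  stopifnot(length(v12) == length(x))
  parse_phecode(v12, dialect = "v1.2")   # grammar check
  parse_phecode(x, dialect = "phecodeX")
  pairs <- unique(data.frame(v12 = v12, x = x, stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$v12, pairs$x), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs), class = "phecode_crosswalk")
}

#' Read a crosswalk file
#'
#' @param path delimited file (comma default, tab accepted) with header
#'   columns `phecode_v12` and `phecode_x` (overridable via `col_config`).
#' @param col_config named list mapping canonical names `phecode_v12`,
#'   `phecode_x` to the file's column names.
#' @return a `phecode_crosswalk`.
#' @export
read_crosswalk <- function(path, col_config = list()) {
  cols <- c(phecode_v12 = "phecode_v12", phecode_x = "phecode_x")
  for (nm in names(col_config)) cols[[nm]] <- col_config[[nm]]
  raw <- read_delimited(path)
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss))
    stop("crosswalk file lacks column(s): ", paste(miss, collapse = ", "))
  phecode_crosswalk(raw[[cols[["phecode_v12"]]]], raw[[cols[["phecode_x"]]]])
}

#' Translate a phecode through the crosswalk
#'
#' @param crosswalk a `phecode_crosswalk`.
#' @param code single code string (legacy or prefixed, matching `direction`).
#' @param direction `"v12_to_X"` or `"X_to_v12"`.
#' @return sorted character vector of counterpart labels; a zero-length
#'   vector is the explicit "no counterpart" marker (never an error).
#' @examples
#' xw <- phecode_crosswalk("427.2", "CV_416.2")
#' translate_phecode(xw, "427.2", "v12_to_X")   # "CV_416.2"
#' translate_phecode(xw, "800.1", "v12_to_X")   # character(0): no counterpart
#' @export
translate_phecode <- function(crosswalk, code,
                              direction = c("v12_to_X", "X_to_v12")) {
  stopifnot(inherits(crosswalk, "phecode_crosswalk"), length(code) == 1L)
  direction <- match.arg(direction)
  p <- crosswalk$pairs
  if (direction == "v12_to_X") sort(unique(p$x[p$v12 == code]))
  else sort(unique(p$v12[p$x == code]))
}

#' @export
print.phecode_crosswalk <- function(x, ...) {
  p <- x$pairs
  cat(sprintf("<phecode_crosswalk> %d pairs: %d legacy codes <-> %d prefixed labels\n",
              nrow(p), length(unique(p$v12)), length(unique(p$x))))
  invisible(x)
}

#' Crosswalk coverage report
#'
#' Given the set of codes in a source map and a crosswalk, reports how many
#' source codes have at least one counterpart — the coverage statistic quoted
#' when comparing map releases.
#'
#' @param codes character vector of source codes.
#' @param crosswalk a `phecode_crosswalk`.
#' @param direction translation direction as in [translate_phecode()].
#' @return list with `n_source`, `n_covered`, `frac_covered`, and
#'   `uncovered` (character vector).
#' @export
crosswalk_coverage <- function(codes, crosswalk,
                               direction = c("v12_to_X", "X_to_v12")) {
  direction <- match.arg(direction)
  codes <- unique(as.character(codes))
  listed <- if (direction == "v12_to_X") crosswalk$pairs$v12 else crosswalk$pairs$x
  covered <- codes %in% listed
  list(n_source = length(codes), n_covered = sum(covered),
       frac_covered = prop_stat(sum(covered), length(codes)),
       uncovered = sort(codes[!covered]))
}
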