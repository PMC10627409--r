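#' Parse phecode labels
#'
#' The prefixed hierarchical label grammar is `<AA>_<DDD>` or
#' `<AA>_<DDD>.<d{1..3}>`: a two-letter uppercase category prefix, an
#' underscore, a three-digit root code (leading zeros significant), and an
#' optional decimal suffix of one to three digits. Each suffix digit adds one
#' level of specificity, so the suffix length is the depth of the code in the
#' phenotype tree (depth 0 = root, up to depth 3).
#'
#' The legacy dialect (`"v1.2"`) instead uses bare numeric codes of three
#' digits with at most two decimals (e.g. `"427.2"`, `"008"`); leading zeros
#' are preserved, the category prefix is empty, and such codes are rejected by
#' the prefixed grammar.
#'
#' @param x character vector of label strings.
#' @param dialect `"phecodeX"` (prefixed grammar, default) or `"v1.2"`
#'   (legacy numeric grammar).
#' @return data.frame of class `phecode_label` with one row per input:
#'   `label` (canonical serialized form), `category_prefix`, `root`
#'   (3-digit string), `suffix` (0-3 digit string, `""` at depth 0), and
#'   `depth` (integer, number of suffix digits).
#' @examples
#' parse_phecode("CV_416.22")
#' parse_phecode("427.2", dialect = "v1.2")
#' @seealso [format_phecode()], [phecode_ancestors()]
#' @export
parse_phecode <- function(x, dialect = c("phecodeX", "v1.2")) {
  dialect <- match.arg(dialect)
  x <- as.character(x)
  if (length(x) == 0L || any(!nzchar(x) | is.na(x)))
    stop("malformed label: empty label string")
  if (dialect == "phecodeX") {
    m <- regmatches(x, regexec("^([A-Z]{2})_([0-9]{3})(?:\\.([0-9]{1,3}))?$", x))
    bad <- which(lengths(m) == 0L)
    if (length(bad)) stop(describe_label_error(x[bad[1L]]))
    prefix <- vapply(m, `[`, "", 2L)
    root <- vapply(m, `[`, "", 3L)
    suffix <- vapply(m, `[`, "", 4L)
  } else {
    m <- regmatches(x, regexec("^([0-9]{3})(?:\\.([0-9]{1,2}))?$", x))
    bad <- which(lengths(m) == 0L)
    if (length(bad))
      stop(sprintf(
        "malformed label '%s': legacy codes are 3 digits with at most 2 decimals",
        x[bad[1L]]))
    prefix <- rep("", length(x))
    root <- vapply(m, `[`, "", 2L)
    suffix <- vapply(m, `[`, "", 3L)
  }
  out <- data.frame(
    label = format_phecode(prefix, root, suffix),
    category_prefix = prefix, root = root, suffix = suffix,
    depth = nchar(suffix), stringsAsFactors = FALSE
  )
  class(out) <- c("phecode_label", "data.frame")
  out
}

# Name the offending grammar component in the error message.
describe_label_error <- function(s) {
  if (!grepl("_", s, fixed = TRUE))
    return(sprintf("malformed label '%s': missing underscore between category prefix and root code", s))
  parts <- strsplit(s, "_", fixed = TRUE)[[1L]]
  prefix <- parts[1L]
  rest <- paste(parts[-1L], collapse = "_")
  if (!grepl("^[A-Z]{2}$", prefix))
    return(sprintf("malformed label '%s': category prefix must be 2 uppercase letters, got '%s'", s, prefix))
  num <- strsplit(rest, ".", fixed = TRUE)[[1L]]
  root <- num[1L]
  if (!grepl("^[0-9]{3}$", root))
    return(sprintf("malformed label '%s': root code must be exactly 3 digits, got '%s'", s, root))
  suffix <- if (length(num) > 1L) paste(num[-1L], collapse = ".") else ""
  sprintf("malformed label '%s': decimal suffix must be 1-3 digits, got '%s'", s, suffix)
}

#' Serialize phecode label components
#'
#' Inverse of [parse_phecode()]: `parse_phecode(format_phecode(p)) == p` for
#' every valid label.
#'
#' @param prefix either a `phecode_label` data.frame, or a character vector of
#'   2-letter prefixes (`""` for the legacy dialect).
#' @param root 3-digit root strings (ignored when `prefix` is a
#'   `phecode_label`).
#' @param suffix 0-3 digit suffix strings.
#' @return character vector of serialized labels.
#' @export
format_phecode <- function(prefix, root = NULL, suffix = "") {
  if (inherits(prefix, "phecode_label")) {
    root <- prefix$root; suffix <- prefix$suffix; prefix <- prefix$category_prefix
  }
  base <- ifelse(nzchar(prefix), paste0(prefix, "_", root), root)
  ifelse(nzchar(suffix), paste0(base, ".", suffix), base)
}

#' Ancestors of a phecode
#'
#' Parent codes are obtained by successively dropping the last decimal digit:
#' a depth-3 code has its depth-2, depth-1 and root ancestors, in that order.
#' The chain length always equals the code's depth.
#'
#' @param label a single label string.
#' @param dialect label dialect as in [parse_phecode()].
#' @return character vector of ancestor labels from immediate parent to root
#'   (empty for a root code).
#' @examples
#' phecode_ancestors("CV_416.221") # CV_416.22, CV_416.2, CV_416
#' @export
phecode_ancestors <- function(label, dialect = c("phecodeX", "v1.2")) {
  dialect <- match.arg(dialect)
  p <- parse_phecode(label, dialect = dialect)
  if (nrow(p) != 1L) stop("phecode_ancestors() takes a single label")
  d <- p$depth
  if (d == 0L) return(character(0))
  vapply(seq.int(d - 1L, 0L), function(k)
    format_phecode(p$category_prefix, p$root, substr(p$suffix, 1L, k)), "")
}

# Immediate parent (NA for roots); vectorized over parsed labels.
phecode_parent <- function(parsed) {
  ifelse(parsed$depth > 0L,
         format_phecode(parsed$category_prefix, parsed$root,
                        substr(parsed$suffix, 1L, parsed$depth - 1L)),
         NA_character_)
}

#' @export
print.phecode_label <- function(x, ...) {
  cat(sprintf("<phecode_label> %d label(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
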