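#' Construct a phecode map
#'
#' A phecode map couples a set of phecode entries (label, description,
#' category, ICD-10-only flag) with a set of ICD-to-phecode mappings across
#' up to three vocabularies (ICD-9-CM, ICD-10-CM, WHO ICD-10). The prefixed
#' dialect (`"phecodeX"`) allows one ICD code to map to several phecodes
#' (multi-mapping) and carries no exclude ranges; the legacy dialect
#' (`"v1.2"`) uses bare numeric labels and may attach per-phecode exclude
#' ranges used to prune control groups.
#'
#' Most users will call [read_phecode_map()] or [simulate_phecode_map()]
#' rather than this constructor.
#'
#' @param entries data.frame with columns `phecode`, `description`,
#'   `category`, `icd10_only` (one row per phecode).
#' @param mappings data.frame with columns `icd_code`, `vocabulary`,
#'   `phecode`. ICD codes are normalized with [normalize_icd()] on entry.
#' @param dialect `"phecodeX"` or `"v1.2"`.
#' @param exclude_ranges `NULL`, or a data.frame with columns `phecode`,
#'   `low`, `high`, `text` (legacy dialect only).
#' @param version free-text map version tag (releases carry their own version
#'   number).
#' @param registry category registry, see [default_registry()].
#' @return object of class `phecode_map`.
#' @export
phecode_map <- function(entries, mappings,
                        dialect = c("phecodeX", "v1.2"),
                        exclude_ranges = NULL, version = NA_character_,
                        registry = default_registry()) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(entries), is.data.frame(mappings))
  need_e <- c("phecode", "description", "category", "icd10_only")
  need_m <- c("icd_code", "vocabulary", "phecode")
  if (!all(need_e %in% names(entries)))
    stop("entries must have columns: ", paste(need_e, collapse = ", "))
  if (!all(need_m %in% names(mappings)))
    stop("mappings must have columns: ", paste(need_m, collapse = ", "))

  parsed <- parse_phecode(entries$phecode, dialect = dialect)
  entries <- data.frame(
    phecode = parsed$label,
    description = as.character(entries$description),
    category = as.character(entries$category),
    icd10_only = as.logical(entries$icd10_only),
    category_prefix = parsed$category_prefix,
    root = parsed$root, suffix = parsed$suffix, depth = parsed$depth,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(entries$phecode))
    stop("duplicate phecode entries: ",
         paste(unique(entries$phecode[duplicated(entries$phecode)]), collapse = ", "))
  entries <- entries[order(entries$phecode), , drop = FALSE]
  rownames(entries) <- NULL

  mappings <- data.frame(
    icd_code = normalize_icd(mappings$icd_code),
    vocabulary = normalize_vocab(mappings$vocabulary),
    phecode = as.character(mappings$phecode),
    stringsAsFactors = FALSE
  )
  if (anyNA(mappings$vocabulary)) stop("unknown vocabulary in mappings")
  mappings <- mappings[order(mappings$vocabulary, mappings$icd_code,
                             mappings$phecode), , drop = FALSE]
  rownames(mappings) <- NULL

  if (!is.null(exclude_ranges) && nrow(exclude_ranges)) {
    stopifnot(all(c("phecode", "low", "high") %in% names(exclude_ranges)))
    if (is.null(exclude_ranges$text))
      exclude_ranges$text <- format_range(exclude_ranges$low, exclude_ranges$high)
    exclude_ranges <- exclude_ranges[order(exclude_ranges$phecode,
                                           exclude_ranges$low), , drop = FALSE]
    rownames(exclude_ranges) <- NULL
  } else {
    exclude_ranges <- data.frame(phecode = character(0), low = numeric(0),
                                 high = numeric(0), text = character(0),
                                 stringsAsFactors = FALSE)
  }

  structure(list(entries = entries, mappings = mappings, dialect = dialect,
                 exclude_ranges = exclude_ranges,
                 version = as.character(version), registry = registry),
            class = "phecode_map")
}

#' @export
print.phecode_map <- function(x, ...) {
  cat(sprintf("<phecode_map> dialect=%s version=%s\n", x$dialect, x$version))
  cat(sprintf("  %d phecodes in %d categories; %d ICD mappings\n",
              nrow(x$entries), length(unique(x$entries$category)),
              nrow(x$mappings)))
  tab <- table(x$mappings$vocabulary)
  for (v in names(tab)) cat(sprintf("    %s: %d mappings\n", v, tab[[v]]))
  if (nrow(x$exclude_ranges))
    cat(sprintf("  exclude ranges for %d phecodes\n",
                length(unique(x$exclude_ranges$phecode))))
  invisible(x)
}

# ---- reading / writing ------------------------------------------------------

map_default_columns <- c(icd_code = "icd_code", vocabulary = "vocabulary",
                         phecode = "phecode", phecode_string = "phecode_string",
                         category = "category", icd10_only = "icd10_only",
                         exclude_range = "exclude_range")

#' Read a phecode mapping file
#'
#' Reads a delimited mapping file (comma default, tab accepted; header row
#' required) into a [phecode_map()]. Expected columns are `icd_code`,
#' `vocabulary`, `phecode`, and optionally `phecode_string`, `category`,
#' `icd10_only` (true/false) and, for the legacy dialect, `exclude_range`
#' (e.g. `"410-414.99"`). Published release files with different headers can
#' be read by overriding column names via `col_config`. Rows with an empty
#' `icd_code` declare a phecode entry without any ICD mapping (used to round-
#' trip entries that no vocabulary covers, e.g. under the smaller WHO map).
#'
#' ICD codes are normalized (uppercase, dots and whitespace removed) before
#' storage. Problems are reported with the 1-based data row number.
#'
#' @param path file path.
#' @param dialect `"phecodeX"` (default) or `"v1.2"`.
#' @param col_config named character vector/list mapping canonical column
#'   names (e.g. `icd_code`) to the names actually used in the file.
#' @param registry category registry used to fill a missing `category` column
#'   from label prefixes.
#' @param version version tag to attach to the map.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab.
#' @return a `phecode_map`.
#' @export
read_phecode_map <- function(path, dialect = c("phecodeX", "v1.2"),
                             col_config = list(), registry = default_registry(),
                             version = NA_character_, sep = NULL) {
  dialect <- match.arg(dialect)
  raw <- read_delimited(path, sep = sep)
  if (nrow(raw) == 0L) stop(sprintf("empty mapping file: %s", path))
  cols <- map_default_columns
  for (nm in names(col_config)) cols[[nm]] <- col_config[[nm]]
  need <- cols[c("icd_code", "vocabulary", "phecode")]
  miss <- setdiff(unname(need), names(raw))
  if (length(miss))
    stop("mapping file lacks required column(s): ", paste(miss, collapse = ", "))
  getcol <- function(nm) if (cols[[nm]] %in% names(raw)) raw[[cols[[nm]]]] else NULL

  icd <- trimws(getcol("icd_code"))
  vocab_raw <- getcol("vocabulary")
  label_raw <- trimws(getcol("phecode"))
  has_icd <- nzchar(icd)

  vocab <- normalize_vocab(vocab_raw)
  bad <- which(has_icd & is.na(vocab))
  if (length(bad))
    stop(sprintf("row %d: unknown vocabulary '%s' (expected %s)",
                 bad[1L], vocab_raw[bad[1L]], paste(VOCABULARIES, collapse = ", ")))

  rx <- if (dialect == "phecodeX") "^[A-Z]{2}_[0-9]{3}(\\.[0-9]{1,3})?$"
        else "^[0-9]{3}(\\.[0-9]{1,2})?$"
  badlab <- which(!grepl(rx, label_raw))
  if (length(badlab)) {
    msg <- if (dialect == "phecodeX") describe_label_error(label_raw[badlab[1L]])
           else sprintf("malformed label '%s': legacy codes are 3 digits with at most 2 decimals",
                        label_raw[badlab[1L]])
    stop(sprintf("row %d: %s", badlab[1L], msg))
  }

  desc <- getcol("phecode_string") %||% rep("", nrow(raw))
  categ <- getcol("category")
  if (is.null(categ)) {
    categ <- if (dialect == "phecodeX")
      registry_name(substr(label_raw, 1L, 2L), registry) else rep("", nrow(raw))
    categ[is.na(categ)] <- ""
  }
  i10 <- parse_logical_column(getcol("icd10_only"), default = FALSE)
  if (length(i10) == 1L) i10 <- rep(i10, nrow(raw))

  first <- !duplicated(label_raw)
  entries <- data.frame(phecode = label_raw[first], description = desc[first],
                        category = categ[first], icd10_only = i10[first],
                        stringsAsFactors = FALSE)
  mappings <- data.frame(icd_code = icd[has_icd], vocabulary = vocab[has_icd],
                         phecode = label_raw[has_icd], stringsAsFactors = FALSE)

  ranges <- NULL
  if (dialect == "v1.2") {
    xr <- getcol("exclude_range")
    if (!is.null(xr)) {
      xr <- trimws(xr)
      keep <- first & nzchar(xr)
      if (any(keep)) ranges <- parse_exclude_ranges(label_raw[keep], xr[keep])
    }
  }
  phecode_map(entries, mappings, dialect = dialect, exclude_ranges = ranges,
              version = version, registry = registry)
}

# "410-414.99; 420" -> one row per interval, inclusive endpoints.
parse_exclude_ranges <- function(phecode, text) {
  pieces <- strsplit(text, "[,;]")
  out <- do.call(rbind, lapply(seq_along(pieces), function(i) {
    ps <- trimws(pieces[[i]])
    ps <- ps[nzchar(ps)]
    ends <- strsplit(ps, "-", fixed = TRUE)
    data.frame(
      phecode = phecode[i],
      low = vapply(ends, function(e) as.numeric(e[1L]), 0),
      high = vapply(ends, function(e) as.numeric(e[length(e)]), 0),
      text = ps, stringsAsFactors = FALSE)
  }))
  if (anyNA(out$low) || anyNA(out$high))
    stop("unparseable exclude range: ", paste(out$text[is.na(out$low) | is.na(out$high)], collapse = ", "))
  out
}

format_range <- function(low, high) {
  ifelse(low == high, as.character(low), paste0(low, "-", high))
}

#' Write a phecode map to a delimited file
#'
#' Emits one row per ICD mapping (plus one entry-only row, with empty
#' `icd_code`, for any phecode that has no mapping), in the same schema
#' [read_phecode_map()] consumes, so that a write/read round trip reproduces
#' the map exactly.
#'
#' @param map a `phecode_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phecode_map <- function(map, path) {
  e <- map$entries
  m <- map$mappings
  unmapped <- setdiff(e$phecode, m$phecode)
  if (length(unmapped))
    m <- rbind(m, data.frame(icd_code = "", vocabulary = "",
                             phecode = unmapped, stringsAsFactors = FALSE))
  i <- match(m$phecode, e$phecode)
  out <- data.frame(icd_code = m$icd_code, vocabulary = m$vocabulary,
                    phecode = m$phecode, phecode_string = e$description[i],
                    category = e$category[i],
                    icd10_only = tolower(e$icd10_only[i]),
                    stringsAsFactors = FALSE)
  if (map$dialect == "v1.2") {
    xr <- map$exclude_ranges
    txt <- vapply(split(xr$text, xr$phecode), paste, "", collapse = ";")
    out$exclude_range <- ifelse(is.na(match(m$phecode, names(txt))), "",
                                txt[m$phecode])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- lookup -----------------------------------------------------------------

#' Look up the phecodes an ICD code maps to
#'
#' Returns the set of directly mapped phecodes (no ancestor expansion) for a
#' single ICD code in one vocabulary. The query code is normalized exactly
#' like stored codes, so `"K40.1"` and `"k401"` are the same query. Unmapped
#' codes return an empty character vector; there is no truncation fallback.
#'
#' @param map a `phecode_map`.
#' @param icd_code single ICD code.
#' @param vocabulary one of `"ICD9CM"`, `"ICD10CM"`, `"ICD10WHO"`.
#' @return sorted character vector of phecode labels (possibly empty; more
#'   than one element under multi-mapping).
#' @examples
#' \dontrun{lookup_phecode(map, "K40.1", "ICD10CM")}
#' @export
lookup_phecode <- function(map, icd_code, vocabulary) {
  stopifnot(inherits(map, "phecode_map"), length(icd_code) == 1L)
  v <- normalize_vocab(vocabulary)
  if (is.na(v)) stop(sprintf("unknown vocabulary '%s'", vocabulary))
  code <- normalize_icd(icd_code)
  hit <- map$mappings$icd_code == code & map$mappings$vocabulary == v
  sort(unique(map$mappings$phecode[hit]))
}

# ---- validation -------------------------------------------------------------

#' Validate a phecode map
#'
#' Checks the structural rules of the dialect and returns a report of
#' findings rather than raising: an empty report means the map is valid.
#' Rules checked:
#' \describe{
#'   \item{orphan_child}{an entry of depth > 0 whose truncation parent is
#'     absent (the hierarchy must be closed under parent truncation).}
#'   \item{category_prefix_mismatch}{an entry whose label prefix is registered
#'     to a different category name than the entry declares.}
#'   \item{duplicate_mapping}{a repeated (icd_code, vocabulary, phecode)
#'     triple.}
#'   \item{mapping_without_entry}{a mapping pointing at a phecode with no
#'     entry.}
#'   \item{icd10_only_has_icd9}{an ICD-10-only phecode that nevertheless has
#'     an ICD-9-CM mapping.}
#'   \item{icd10_only_missing_star}{prefixed dialect: an ICD-10-only phecode
#'     whose description does not end in `*`.}
#'   \item{exclude_ranges_in_phecodex}{exclude ranges attached to a prefixed-
#'     dialect map (the dialect defines none).}
#' }
#' Orphan children are reported, never auto-repaired: the released map stays
#' authoritative.
#'
#' @param map a `phecode_map`.
#' @return data.frame of class `phecode_validation` with columns `rule`,
#'   `severity`, `ref`, `message`; zero rows when the map is valid.
#' @seealso [map_is_valid()], [write_validation_report()]
#' @export
validate_phecode_map <- function(map) {
  stopifnot(inherits(map, "phecode_map"))
  e <- map$entries
  m <- map$mappings
  f <- list()
  add <- function(rule, severity, ref, message) {
    if (length(ref))
      f[[length(f) + 1L]] <<- data.frame(rule = rule, severity = severity,
                                         ref = ref, message = message,
                                         stringsAsFactors = FALSE)
  }

  parent <- phecode_parent(e)
  orphan <- !is.na(parent) & !(parent %in% e$phecode)
  add("orphan_child", "error", e$phecode[orphan],
      sprintf("parent %s is missing from the map", parent[orphan]))

  if (map$dialect == "phecodeX") {
    regname <- registry_name(e$category_prefix, map$registry)
    mism <- !is.na(regname) & nzchar(e$category) & e$category != regname
    add("category_prefix_mismatch", "error", e$phecode[mism],
        sprintf("category '%s' but prefix %s is registered as '%s'",
                e$category[mism], e$category_prefix[mism], regname[mism]))
  }

  key <- paste(m$icd_code, m$vocabulary, m$phecode, sep = "\r")
  dup <- which(duplicated(key))
  add("duplicate_mapping", "warning",
      paste0(m$icd_code[dup], "/", m$vocabulary[dup], "->", m$phecode[dup])[seq_along(dup)],
      "duplicate (icd_code, vocabulary, phecode) triple")

  noent <- !(m$phecode %in% e$phecode)
  add("mapping_without_entry", "error", unique(m$phecode[noent]),
      "mapping points at a phecode with no entry")

  has9 <- unique(m$phecode[m$vocabulary == "ICD9CM"])
  bad9 <- e$icd10_only & e$phecode %in% has9
  add("icd10_only_has_icd9", "error", e$phecode[bad9],
      "flagged icd10_only but an ICD-9-CM mapping exists")

  if (map$dialect == "phecodeX") {
    nostar <- e$icd10_only & !endsWith(e$description, "*")
    add("icd10_only_missing_star", "warning", e$phecode[nostar],
        "icd10_only description must end with '*'")
    add("exclude_ranges_in_phecodex", "error",
        unique(map$exclude_ranges$phecode),
        "this dialect does not define exclude ranges")
  }

  out <- if (length(f)) do.call(rbind, f)
         else data.frame(rule = character(0), severity = character(0),
                         ref = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("phecode_validation", "data.frame")
  out
}

#' Is a validation report clean?
#' @param report result of [validate_phecode_map()].
#' @return `TRUE` when the report has no findings.
#' @export
map_is_valid <- function(report) {
  stopifnot(inherits(report, "phecode_validation"))
  nrow(report) == 0L
}

#' Write a validation report as JSON
#' @param report result of [validate_phecode_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(
    list(valid = nrow(report) == 0L, n_findings = nrow(report),
         findings = as.data.frame(report)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.phecode_validation <- function(x, ...) {
  if (nrow(x) == 0L) cat("<phecode_validation> map is valid (no findings)\n")
  else {
    cat(sprintf("<phecode_validation> %d finding(s)\n", nrow(x)))
    print.data.frame(x, ...)
  }
  invisible(x)
}

# ---- summary ----------------------------------------------------------------

#' Summarize a phecode map
#'
#' Computes the descriptive statistics used to characterize a map release:
#' per-category phecode counts, per-vocabulary ICD totals with the count and
#' fraction of ICD codes mapped to more than one phecode (multi-mapping), the
#' leaf-code count and the count/fraction of leaves receiving at least one
#' multi-mapped ICD, and the number of ICD-10-only phecodes. A leaf is an
#' entry with no child entry present in the map. High-level combination
#' phecodes (deliberately multi-mapped umbrella codes) can be excluded from
#' the leaf denominator via `exclude_high_level`.
#'
#' @param map a `phecode_map`.
#' @param exclude_high_level character vector of phecode labels removed from
#'   the leaf statistics (default none).
#' @return list of class `phecode_map_summary`: `n_phecodes`,
#'   `category_counts` (named vector summing to `n_phecodes`), `vocabulary`
#'   (data.frame with `vocabulary`, `n_icd`, `n_multi`, `frac_multi`),
#'   `n_leaves`, `n_multi_leaves`, `frac_multi_leaves`, `n_icd10_only`.
#' @export
summarize_phecode_map <- function(map, exclude_high_level = character(0)) {
  stopifnot(inherits(map, "phecode_map"))
  e <- map$entries
  m <- map$mappings

  cat_counts <- table(e$category)
  cat_counts <- stats::setNames(as.integer(cat_counts), names(cat_counts))

  per_vocab <- do.call(rbind, lapply(sort(unique(m$vocabulary)), function(v) {
    mv <- m[m$vocabulary == v, , drop = FALSE]
    nper <- tapply(mv$phecode, mv$icd_code, function(p) length(unique(p)))
    n_icd <- length(nper)
    n_multi <- sum(nper > 1L)
    data.frame(vocabulary = v, n_icd = n_icd, n_multi = n_multi,
               frac_multi = prop_stat(n_multi, n_icd),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_vocab))
    per_vocab <- data.frame(vocabulary = character(0), n_icd = integer(0),
                            n_multi = integer(0), frac_multi = numeric(0))

  parents <- stats::na.omit(phecode_parent(e))
  leaves <- setdiff(e$phecode[!(e$phecode %in% parents)], exclude_high_level)

  key <- paste(m$icd_code, m$vocabulary, sep = "\r")
  nper_all <- tapply(m$phecode, key, function(p) length(unique(p)))
  multi_keys <- names(nper_all)[nper_all > 1L]
  multi_phecodes <- unique(m$phecode[key %in% multi_keys])
  n_multi_leaves <- sum(leaves %in% multi_phecodes)

  structure(list(
    n_phecodes = nrow(e),
    category_counts = cat_counts,
    vocabulary = per_vocab,
    n_leaves = length(leaves),
    n_multi_leaves = n_multi_leaves,
    frac_multi_leaves = if (length(leaves)) prop_stat(n_multi_leaves, length(leaves)) else NA_real_,
    n_icd10_only = sum(e$icd10_only),
    excluded_high_level = exclude_high_level
  ), class = "phecode_map_summary")
}

#' @export
print.phecode_map_summary <- function(x, ...) {
  cat(sprintf("<phecode_map_summary> %d phecodes, %d categories, %d leaves\n",
              x$n_phecodes, length(x$category_counts), x$n_leaves))
  for (i in seq_len(nrow(x$vocabulary))) {
    v <- x$vocabulary[i, ]
    cat(sprintf("  %s: %d ICD codes, %d (%.1f%%) multi-mapped\n",
                v$vocabulary, v$n_icd, v$n_multi, 100 * v$frac_multi))
  }
  cat(sprintf("  leaves with >=1 multi-mapped ICD: %d (%.1f%%)\n",
              x$n_multi_leaves, 100 * x$frac_multi_leaves))
  cat(sprintf("  icd10_only phecodes: %d\n", x$n_icd10_only))
  invisible(x)
}
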