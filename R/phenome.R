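#' Read a person-level ICD event table
#'
#' Expects a delimited file (comma default, tab accepted) with header columns
#' `person_id`, `icd_code`, `vocabulary`, `date` (ISO 8601, `YYYY-MM-DD`).
#'
#' @param path file path.
#' @return data.frame with those four columns, `date` as `Date`.
#' @export
read_icd_events <- function(path) {
  raw <- read_delimited(path)
  need <- c("person_id", "icd_code", "vocabulary", "date")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("event file lacks column(s): ", paste(miss, collapse = ", "))
  badd <- which(!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", raw$date))
  if (length(badd))
    stop(sprintf("row %d: date '%s' is not ISO 8601 (YYYY-MM-DD)",
                 badd[1L], raw$date[badd[1L]]))
  v <- normalize_vocab(raw$vocabulary)
  badv <- which(is.na(v))
  if (length(badv))
    stop(sprintf("row %d: unknown vocabulary '%s'", badv[1L],
                 raw$vocabulary[badv[1L]]))
  data.frame(person_id = raw$person_id, icd_code = raw$icd_code,
             vocabulary = v, date = as.Date(raw$date),
             stringsAsFactors = FALSE)
}

#' Read a person roster (one id per line)
#' @param path file path.
#' @return character vector of person ids.
#' @export
read_roster <- function(path) {
  ids <- trimws(readLines(path))
  unique(ids[nzchar(ids)])
}

# Self-plus-ancestors closure over the entries actually present in the map
# (child -> each of child, parent, ..., root). Orphan links to absent parents
# are dropped; the validator reports those separately.
ancestor_closure <- function(map) {
  e <- map$entries
  rows <- lapply(seq_len(nrow(e)), function(i) {
    chain <- c(e$phecode[i],
               if (e$depth[i] > 0L)
                 vapply(seq.int(e$depth[i] - 1L, 0L), function(k)
                   format_phecode(e$category_prefix[i], e$root[i],
                                  substr(e$suffix[i], 1L, k)), ""))
    data.table(phecode = e$phecode[i], target = chain)
  })
  cl <- rbindlist(rows)
  cl[target %in% e$phecode]
}

#' Map ICD events to hierarchical phecode counts
#'
#' Each event contributes to every phecode its ICD code maps to directly
#' (including several under multi-mapping) and, when `rollup = TRUE`, to
#' every ancestor of those phecodes present in the map. Contributions are
#' deduplicated to one per (person, phecode, date) before counting, so the
#' counting unit is distinct coded dates — same-day duplicate billing cannot
#' inflate a count. Events whose ICD code has no mapping are tallied in the
#' unmapped-event report, never dropped silently.
#'
#' @param events data.frame as returned by [read_icd_events()] (columns
#'   `person_id`, `icd_code`, `vocabulary`, `date`).
#' @param map a `phecode_map`.
#' @param rollup propagate counts to ancestor phecodes (default `TRUE`).
#' @param roster optional character vector of person ids forming the cohort
#'   universe in addition to persons appearing in `events`; persons with no
#'   events are genuine zero-count controls.
#' @return object of class `phenome_counts`: list with `counts` (data.frame
#'   `person_id`, `phecode`, `count`), `persons` (cohort universe),
#'   `unmapped` (data.frame `icd_code`, `vocabulary`, `n_events`), `rollup`,
#'   and `dialect`.
#' @export
map_events <- function(events, map, rollup = TRUE, roster = NULL) {
  stopifnot(inherits(map, "phecode_map"), is.data.frame(events))
  need <- c("person_id", "icd_code", "vocabulary", "date")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events lack column(s): ", paste(miss, collapse = ", "))
  v <- normalize_vocab(events$vocabulary)
  if (anyNA(v))
    stop("unknown vocabulary in events: ",
         paste(unique(events$vocabulary[is.na(v)]), collapse = ", "))

  ev <- data.table(person_id = as.character(events$person_id),
                   icd_code = normalize_icd(events$icd_code),
                   vocabulary = v,
                   date_ = as.character(events$date))
  mp <- as.data.table(map$mappings)
  mp <- unique(mp)

  hit <- mp[ev, on = c("icd_code", "vocabulary"), allow.cartesian = TRUE]
  unmapped <- hit[is.na(phecode),
                  .(n_events = .N), by = .(icd_code, vocabulary)]
  hit <- hit[!is.na(phecode)]

  if (rollup && nrow(hit)) {
    cl <- ancestor_closure(map)
    hit <- cl[hit, on = "phecode", allow.cartesian = TRUE]
    hit <- hit[!is.na(target), .(person_id, phecode = target, date_)]
  } else {
    hit <- hit[, .(person_id, phecode, date_)]
  }
  hit <- unique(hit)
  counts <- hit[, .(count = .N), by = .(person_id, phecode)]
  setorder(counts, person_id, phecode)

  persons <- sort(unique(c(ev$person_id, as.character(roster %||% character(0)))))
  setorder(unmapped, icd_code, vocabulary)
  structure(list(counts = as.data.frame(counts), persons = persons,
                 unmapped = as.data.frame(unmapped), rollup = rollup,
                 dialect = map$dialect),
            class = "phenome_counts")
}

#' @export
print.phenome_counts <- function(x, ...) {
  cat(sprintf("<phenome_counts> %d persons, %d phecodes, %d nonzero cells (rollup=%s)\n",
              length(x$persons), length(unique(x$counts$phecode)),
              nrow(x$counts), x$rollup))
  if (nrow(x$unmapped))
    cat(sprintf("  unmapped: %d ICD codes covering %d events\n",
                nrow(x$unmapped), sum(x$unmapped$n_events)))
  invisible(x)
}

#' Assign case/control/neither status from phecode counts
#'
#' A person is a case for a phecode when their distinct-date count reaches
#' `min_code_count` (default 2), a control when the count is exactly zero,
#' and neither otherwise (excluded from both arms). Persons in the cohort
#' universe with no events at all are controls for every phecode.
#'
#' @param counts a `phenome_counts` object.
#' @param min_code_count minimum distinct-date count defining a case
#'   (integer, at least 1; default 2).
#' @return object of class `case_control`: list with `status` (sparse
#'   data.frame `person_id`, `phecode`, `status` holding only non-control
#'   cells), `persons`, `phecodes`, `min_code_count`, `exclude_policy`.
#' @seealso [cc_status()], [as.matrix.case_control()],
#'   [apply_exclude_ranges()]
#' @export
assign_case_control <- function(counts, min_code_count = 2L) {
  stopifnot(inherits(counts, "phenome_counts"))
  if (!is.numeric(min_code_count) || length(min_code_count) != 1L ||
      min_code_count < 1)
    stop("min_code_count must be an integer >= 1")
  cdf <- counts$counts
  status <- ifelse(cdf$count >= min_code_count, "case", "neither")
  structure(list(
    status = data.frame(person_id = cdf$person_id, phecode = cdf$phecode,
                        status = status, stringsAsFactors = FALSE),
    persons = counts$persons,
    phecodes = sort(unique(cdf$phecode)),
    min_code_count = as.integer(min_code_count),
    exclude_policy = "none",
    dialect = counts$dialect
  ), class = "case_control")
}

#' @export
print.case_control <- function(x, ...) {
  tab <- table(x$status$status)
  cat(sprintf("<case_control> %d persons x %d phecodes (min_code_count=%d, exclude=%s)\n",
              length(x$persons), length(x$phecodes), x$min_code_count,
              x$exclude_policy))
  cat(sprintf("  case cells: %d; neither cells: %d; all other cells are controls\n",
              tab["case"] %|na|% 0L, tab["neither"] %|na|% 0L))
  invisible(x)
}

`%|na|%` <- function(a, b) if (is.na(a) || is.null(a)) b else a

#' Status vector for one phecode
#'
#' @param ccm a `case_control` object.
#' @param phecode single phecode label.
#' @return named character vector over all persons in the universe with
#'   values `"case"`, `"control"` or `"neither"`.
#' @export
cc_status <- function(ccm, phecode) {
  stopifnot(inherits(ccm, "case_control"), length(phecode) == 1L)
  out <- setNames(rep("control", length(ccm$persons)), ccm$persons)
  s <- ccm$status[ccm$status$phecode == phecode, , drop = FALSE]
  out[s$person_id] <- s$status
  out
}

#' Dense status matrix
#'
#' Materializes the full person-by-phecode status matrix; intended for small
#' cohorts and tests (every cell is exactly one of case/control/neither).
#'
#' @param x a `case_control` object.
#' @param ... unused.
#' @return character matrix, rows = persons, columns = phecodes.
#' @export
as.matrix.case_control <- function(x, ...) {
  m <- matrix("control", length(x$persons), length(x$phecodes),
              dimnames = list(x$persons, x$phecodes))
  s <- x$status
  m[cbind(match(s$person_id, x$persons), match(s$phecode, x$phecodes))] <- s$status
  m
}

#' Apply legacy exclude ranges to a case/control matrix
#'
#' In the legacy dialect each phecode may carry exclude ranges: numeric
#' intervals of related phecodes whose carriers are removed from that
#' phecode's control group (status control becomes neither). Cases are never
#' changed, so the operation can only shrink the control arm. The prefixed
#' dialect defines no exclude ranges, so for such maps this is the identity
#' transform — and attaching ranges to one is an error.
#'
#' Range membership is a numeric interval test with inclusive endpoints
#' (e.g. phecode `414` lies in `410-414.99`). A carrier is any person with a
#' nonzero count on an in-range phecode; `threshold = "min_code_count"`
#' restricts removal to persons whose in-range count reaches the case
#' threshold instead.
#'
#' @param matrix a `case_control` object.
#' @param counts the `phenome_counts` the matrix was derived from.
#' @param map the `phecode_map` carrying `exclude_ranges`.
#' @param threshold `"any"` (default: any nonzero in-range count removes a
#'   control) or `"min_code_count"`.
#' @return a `case_control` object with controls in range demoted to neither.
#' @export
apply_exclude_ranges <- function(matrix, counts, map,
                                 threshold = c("any", "min_code_count")) {
  stopifnot(inherits(matrix, "case_control"),
            inherits(counts, "phenome_counts"),
            inherits(map, "phecode_map"))
  threshold <- match.arg(threshold)
  if (map$dialect == "phecodeX") {
    if (nrow(map$exclude_ranges))
      stop("exclude ranges are not defined for the phecodeX dialect")
    return(matrix)
  }
  xr <- map$exclude_ranges
  if (!nrow(xr)) return(matrix)

  cdf <- counts$counts
  cmin <- if (threshold == "any") 1L else matrix$min_code_count
  cdf <- cdf[cdf$count >= cmin, , drop = FALSE]
  val <- suppressWarnings(as.numeric(cdf$phecode))

  new_rows <- list()
  for (p in unique(xr$phecode)) {
    rr <- xr[xr$phecode == p, , drop = FALSE]
    inrange <- rep(FALSE, nrow(cdf))
    for (j in seq_len(nrow(rr)))
      inrange <- inrange | (!is.na(val) & val >= rr$low[j] & val <= rr$high[j])
    carriers <- unique(cdf$person_id[inrange])
    ncs <- matrix$status[matrix$status$phecode == p, , drop = FALSE]
    demote <- setdiff(carriers, ncs$person_id)  # controls only
    if (length(demote))
      new_rows[[p]] <- data.frame(person_id = demote, phecode = p,
                                  status = "neither", stringsAsFactors = FALSE)
  }
  if (length(new_rows)) {
    matrix$status <- rbind(matrix$status, do.call(rbind, new_rows))
    matrix$status <- matrix$status[order(matrix$status$phecode,
                                         matrix$status$person_id), , drop = FALSE]
    rownames(matrix$status) <- NULL
    matrix$phecodes <- sort(unique(c(matrix$phecodes, names(new_rows))))
  }
  matrix$exclude_policy <- sprintf("v1.2 ranges (threshold=%s)", threshold)
  matrix
}

#' Re-key a phenome through a crosswalk
#'
#' Translates the phecode keys of a count table into the counterpart coding
#' system. Phecodes with no counterpart are routed to the dropped-codes
#' report (accessible as the `dropped` element), never silently discarded.
#' When several source codes translate to one target, the target receives
#' the maximum of the source counts, not the sum: the sources typically
#' derive from the same underlying events, and summing would double-count.
#'
#' @param counts a `phenome_counts` object.
#' @param crosswalk a `phecode_crosswalk`.
#' @param direction `"v12_to_X"` or `"X_to_v12"`.
#' @param combine aggregation for many-to-one targets: `"max"` (default) or
#'   `"sum"`.
#' @return a `phenome_counts` object keyed by counterpart labels, with a
#'   `dropped` element listing source phecodes that had no counterpart.
#' @export
crosswalk_phenome <- function(counts, crosswalk,
                              direction = c("v12_to_X", "X_to_v12"),
                              combine = c("max", "sum")) {
  stopifnot(inherits(counts, "phenome_counts"),
            inherits(crosswalk, "phecode_crosswalk"))
  direction <- match.arg(direction)
  combine <- match.arg(combine)
  p <- crosswalk$pairs
  lut <- if (direction == "v12_to_X")
    data.table(src = p$v12, dst = p$x) else data.table(src = p$x, dst = p$v12)

  cdf <- as.data.table(counts$counts)
  joined <- lut[cdf, on = c(src = "phecode"), allow.cartesian = TRUE]
  dropped <- sort(unique(joined$src[is.na(joined$dst)]))
  joined <- joined[!is.na(dst)]
  agg <- if (combine == "max")
    joined[, .(count = max(count)), by = .(person_id, phecode = dst)]
  else joined[, .(count = sum(count)), by = .(person_id, phecode = dst)]
  setorder(agg, person_id, phecode)

  structure(list(counts = as.data.frame(agg), persons = counts$persons,
                 unmapped = counts$unmapped, rollup = counts$rollup,
                 dialect = if (direction == "v12_to_X") "phecodeX" else "v1.2",
                 dropped = dropped),
            class = "phenome_counts")
}

# ---- export helpers (long/wide delimited text, JSON reports) ----------------

#' Write phenome counts or statuses to delimited text
#'
#' @param x a `phenome_counts` or `case_control` object.
#' @param path output path (CSV).
#' @param wide write the dense person-by-phecode matrix instead of the
#'   default long format (`person_id`, `phecode`, `value`).
#' @return `path`, invisibly.
#' @export
write_phenome <- function(x, path, wide = FALSE) {
  if (inherits(x, "phenome_counts")) {
    long <- data.frame(person_id = x$counts$person_id,
                       phecode = x$counts$phecode, value = x$counts$count)
  } else if (inherits(x, "case_control")) {
    long <- data.frame(person_id = x$status$person_id,
                       phecode = x$status$phecode, value = x$status$status)
  } else stop("x must be phenome_counts or case_control")
  if (wide) {
    dt <- as.data.table(long)
    w <- dcast(dt, person_id ~ phecode, value.var = "value",
               fill = if (inherits(x, "case_control")) "control" else 0)
    utils::write.csv(w, path, row.names = FALSE)
  } else {
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write the unmapped-event report as JSON
#' @param counts a `phenome_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_unmapped_report <- function(counts, path) {
  stopifnot(inherits(counts, "phenome_counts"))
  jsonlite::write_json(
    list(n_unmapped_codes = nrow(counts$unmapped),
         n_unmapped_events = sum(counts$unmapped$n_events),
         codes = counts$unmapped),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a long-format case/control file
#'
#' Inverse of [write_phenome()] applied to a `case_control` object: reads a
#' long CSV (`person_id`, `phecode`, `value` in case/neither) plus a roster
#' giving the full person universe.
#'
#' @param path long-format status file.
#' @param persons character vector of all person ids (controls are implicit).
#' @param min_code_count provenance value to attach.
#' @return a `case_control` object.
#' @export
read_case_control <- function(path, persons, min_code_count = 2L) {
  raw <- read_delimited(path)
  need <- c("person_id", "phecode", "value")
  if (!all(need %in% names(raw)))
    stop("case/control file lacks column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  if (!all(raw$value %in% c("case", "neither")))
    stop("status values must be 'case' or 'neither' (controls are implicit)")
  structure(list(
    status = data.frame(person_id = raw$person_id, phecode = raw$phecode,
                        status = raw$value, stringsAsFactors = FALSE),
    persons = sort(unique(c(persons, raw$person_id))),
    phecodes = sort(unique(raw$phecode)),
    min_code_count = as.integer(min_code_count),
    exclude_policy = "unknown (read from file)",
    dialect = NA_character_
  ), class = "case_control")
}
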