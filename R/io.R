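# Shared delimited-text reading. Comma is the default field separator; a tab
# in the header line switches to tab. Everything is read as character so that
# numeric-looking codes (e.g. legacy phecode "008") are never corrupted.
read_delimited <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop(sprintf("empty file: %s", path))
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = NULL,
                    comment.char = "", strip.white = TRUE)
}

parse_logical_column <- function(x, default = FALSE) {
  if (is.null(x)) return(default)
  v <- tolower(trimws(as.character(x)))
  out <- v %in% c("true", "t", "1", "yes", "y")
  out[v %in% c("", "na")] <- default
  out
}
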