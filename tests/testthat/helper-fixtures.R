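# Shared fixtures and independent oracles for the test suite.

demo_map <- function() {
  read_phecode_map(system.file("extdata", "phecodex_demo_map.csv",
                               package = "phenomap"))
}

v12_map <- function() {
  read_phecode_map(system.file("extdata", "v12_demo_map.csv",
                               package = "phenomap"), dialect = "v1.2")
}

demo_crosswalk <- function() {
  read_crosswalk(system.file("extdata", "crosswalk_demo.csv",
                             package = "phenomap"))
}

# Events table built in code.
make_events <- function(person, icd, vocab, date) {
  data.frame(person_id = person, icd_code = icd, vocabulary = vocab,
             date = as.Date(date), stringsAsFactors = FALSE)
}

# ---- independent rollup oracle ---------------------------------------------
# Brute-force recomputation of map_events: expand every event to its mapped
# phecodes plus all ancestors (string truncation, reimplemented here), dedup
# by person/phecode/date, count. Deliberately slow and simple.

oracle_ancestors <- function(p) {
  out <- character(0)
  while (grepl(".", p, fixed = TRUE)) {
    p <- substr(p, 1L, nchar(p) - 1L)
    if (endsWith(p, ".")) p <- substr(p, 1L, nchar(p) - 1L)
    out <- c(out, p)
  }
  out
}

oracle_counts <- function(events, map, rollup = TRUE) {
  norm <- function(x) gsub("[.[:space:]]", "", toupper(x))
  ent <- map$entries$phecode
  mp_icd <- norm(map$mappings$icd_code)
  triples <- character(0)
  for (i in seq_len(nrow(events))) {
    code <- norm(events$icd_code[i])
    hit <- mp_icd == code & map$mappings$vocabulary == events$vocabulary[i]
    ph <- unique(map$mappings$phecode[hit])
    if (!length(ph)) next
    if (rollup)
      ph <- unique(c(ph, unlist(lapply(ph, oracle_ancestors))))
    ph <- ph[ph %in% ent]
    triples <- c(triples, paste(events$person_id[i], ph,
                                as.character(events$date[i]), sep = "|"))
  }
  triples <- unique(triples)
  if (!length(triples))
    return(data.frame(person_id = character(0), phecode = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(triples, "|", fixed = TRUE)
  pp <- paste(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L), sep = "|")
  tab <- table(pp)
  keyparts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(person_id = vapply(keyparts, `[`, "", 1L),
                    phecode = vapply(keyparts, `[`, "", 2L),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$person_id, out$phecode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Normalize a phenome_counts count table for comparison with the oracle.
counts_df <- function(pc) {
  out <- pc$counts[order(pc$counts$person_id, pc$counts$phecode), , drop = FALSE]
  out$count <- as.integer(out$count)
  rownames(out) <- NULL
  out
}

# Small random map + cohort pair for property tests; fully determined by seed.
# Maps are kept at <= 50 phecodes (re-drawn under a shifted seed if branching
# overshoots) so the brute-force oracle stays cheap.
random_map_cohort <- function(seed, n_persons = NULL) {
  set.seed(seed)
  repeat {
    sm <- simulate_phecode_map(
      n_categories = 2L, roots_per_category = sample(2:4, 1L),
      p_child = stats::runif(1, 0.3, 0.9), p_grandchild = stats::runif(1, 0.1, 0.6),
      multi_map_rate = stats::runif(1, 0, 0.3), icd10_only_frac = 0.1,
      seed = seed)
    if (nrow(sm$map$entries) <= 50L) break
    seed <- seed + 20000L
  }
  sim <- simulate_cohort(
    sm$map, n_persons = n_persons %||% sample(20:200, 1L),
    prevalence = 0.1, mean_dates = 2.5, background_rate = 1.5,
    seed = seed + 10000L)
  list(map = sm$map, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
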