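test_that("reading a small mapping file yields the expected entries and mappings", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "icd_code,vocabulary,phecode,phecode_string,category,icd10_only",
    "A00.1,ICD10CM,ID_001,Cholera,Infectious Diseases,false",
    "001.1,ICD9CM,ID_001,Cholera,Infectious Diseases,false",
    "K40.1,ICD10CM,GI_520,Hernia,Gastrointestinal,false",
    "K40.1,ICD10CM,ID_091,Gangrene,Infectious Diseases,false",
    "I48.3,ICD10CM,CV_416,Arrhythmia,Cardiovascular,false",
    "U07.1,ICD10CM,RE_010,COVID-19*,Respiratory,true"), tmp)
  map <- read_phecode_map(tmp)
  expect_s3_class(map, "phecode_map")
  expect_equal(nrow(map$mappings), 6L)     # 6 rows, one ICD multi-mapped
  expect_equal(nrow(map$entries), 5L)      # 5 distinct phecodes
  expect_true(all(map$mappings$icd_code == normalize_icd(map$mappings$icd_code)))
  # determinism: same file read twice gives value-identical maps
  expect_identical(read_phecode_map(tmp), map)
})

test_that("unknown vocabulary tokens are rejected with the row number", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("icd_code,vocabulary,phecode,phecode_string,category,icd10_only",
               "A00.1,ICD10CM,ID_001,Cholera,Infectious Diseases,false",
               "B99.9,ICD11,ID_002,Eek,Infectious Diseases,false"), tmp)
  expect_error(read_phecode_map(tmp), "row 2.*ICD11")
})

test_that("empty and malformed files are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("icd_code,vocabulary,phecode,phecode_string,category,icd10_only", tmp)
  expect_error(read_phecode_map(tmp), "empty")
  writeLines(c("icd_code,vocabulary,phecode",
               "A00.1,ICD10CM,427.2"), tmp)
  expect_error(read_phecode_map(tmp), "row 1.*malformed")
  writeLines(c("a,b", "1,2"), tmp)
  expect_error(read_phecode_map(tmp), "required column")
})

test_that("lookup reproduces the pre-coordinated-code worked examples", {
  map <- demo_map()
  expect_equal(lookup_phecode(map, "K40.1", "ICD10CM"),
               c("GI_520.11", "ID_091"))
  expect_equal(lookup_phecode(map, "550.0", "ICD9CM"),
               c("GI_520.11", "ID_091"))
  expect_setequal(lookup_phecode(map, "J15.2", "ICD10CM"),
                  c("ID_009", "RE_468.2"))
  expect_setequal(lookup_phecode(map, "482.4", "ICD9CM"),
                  c("ID_009", "RE_468.2"))
  # normalization contract: dotted, undotted, lowercase queries agree
  expect_equal(lookup_phecode(map, "k401", "ICD10CM"),
               lookup_phecode(map, "K40.1", "ICD10CM"))
  # unmapped code -> empty set, no error
  expect_equal(lookup_phecode(map, "Z99.99", "ICD10CM"), character(0))
  expect_error(lookup_phecode(map, "K40.1", "ICD11"), "vocabulary")
})

test_that("validator reports orphans, prefix mismatches and flag inconsistencies", {
  entries <- data.frame(
    phecode = c("CV_416", "CV_416.22", "GI_520"),
    description = c("Arrhythmia", "Flutter", "Hernia"),
    category = c("Cardiovascular", "Cardiovascular", "Cardiovascular"),
    icd10_only = c(FALSE, TRUE, FALSE))
  mappings <- data.frame(
    icd_code = c("I49.9", "I48.92", "427.32", "K40", "K40"),
    vocabulary = c("ICD10CM", "ICD10CM", "ICD9CM", "ICD10CM", "ICD10CM"),
    phecode = c("CV_416", "CV_416.22", "CV_416.22", "GI_520", "GI_520"))
  map <- phecode_map(entries, mappings, dialect = "phecodeX")
  rep <- validate_phecode_map(map)
  expect_false(map_is_valid(rep))
  # CV_416.22 present without CV_416.2 -> exactly one orphan finding
  expect_equal(sum(rep$rule == "orphan_child"), 1L)
  expect_equal(rep$ref[rep$rule == "orphan_child"], "CV_416.22")
  # GI_520 labelled Cardiovascular although GI is Gastrointestinal
  expect_equal(rep$ref[rep$rule == "category_prefix_mismatch"], "GI_520")
  # icd10_only entry with an ICD-9 mapping and no star
  expect_equal(rep$ref[rep$rule == "icd10_only_has_icd9"], "CV_416.22")
  expect_equal(rep$ref[rep$rule == "icd10_only_missing_star"], "CV_416.22")
  # duplicated triple K40/ICD10CM->GI_520
  expect_equal(sum(rep$rule == "duplicate_mapping"), 1L)
})

test_that("exclude ranges attached to a prefixed-dialect map are a finding", {
  entries <- data.frame(phecode = "CV_416", description = "Arrhythmia",
                        category = "Cardiovascular", icd10_only = FALSE)
  mappings <- data.frame(icd_code = "I49.9", vocabulary = "ICD10CM",
                         phecode = "CV_416")
  xr <- data.frame(phecode = "CV_416", low = 410, high = 414.99)
  map <- phecode_map(entries, mappings, dialect = "phecodeX",
                     exclude_ranges = xr)
  rep <- validate_phecode_map(map)
  expect_true("exclude_ranges_in_phecodex" %in% rep$rule)
})

test_that("demo fixtures are valid; legacy dialect allows exclude ranges", {
  expect_true(map_is_valid(validate_phecode_map(demo_map())))
  v12 <- v12_map()
  expect_true(map_is_valid(validate_phecode_map(v12)))
  expect_equal(sort(unique(v12$exclude_ranges$phecode)),
               c("250", "250.1", "410", "411", "414", "427", "427.2", "428"))
  expect_equal(v12$exclude_ranges$low[v12$exclude_ranges$phecode == "411"], 410)
  expect_equal(v12$exclude_ranges$high[v12$exclude_ranges$phecode == "411"], 414.99)
})

test_that("map summary counts multi-mapping and partitions categories", {
  # constructed: 10 ICD-10-CM codes, 3 of them multi-mapped -> fraction 0.3
  entries <- data.frame(
    phecode = c("ID_001", "ID_002", "GI_520"),
    description = c("A", "B", "C"),
    category = c("Infectious Diseases", "Infectious Diseases", "Gastrointestinal"),
    icd10_only = FALSE)
  icd <- sprintf("A%02d.1", 1:10)
  mappings <- rbind(
    data.frame(icd_code = icd, vocabulary = "ICD10CM", phecode = "ID_001"),
    data.frame(icd_code = icd[1:3], vocabulary = "ICD10CM", phecode = "ID_002"))
  map <- phecode_map(entries, mappings, dialect = "phecodeX")
  s <- summarize_phecode_map(map)
  expect_equal(s$vocabulary$n_icd, 10L)
  expect_equal(s$vocabulary$n_multi, 3L)
  expect_equal(s$vocabulary$frac_multi, 0.3)
  expect_equal(sum(s$category_counts), nrow(map$entries))
  # ID_002 and GI_520 and ID_001 are all leaves; ID_001, ID_002 get multi ICDs
  expect_equal(s$n_leaves, 3L)
  expect_equal(s$n_multi_leaves, 2L)
  # excluding a high-level combination code shrinks the leaf denominator
  s2 <- summarize_phecode_map(map, exclude_high_level = "GI_520")
  expect_equal(s2$n_leaves, 2L)
  expect_equal(s2$frac_multi_leaves, 1)
})

test_that("summary multi-map fraction matches a brute-force recount on random maps", {
  set.seed(7)
  for (seed in c(11, 23, 57)) {
    sm <- simulate_phecode_map(n_categories = 3, roots_per_category = 6,
                               multi_map_rate = 0.2, seed = seed)
    s <- summarize_phecode_map(sm$map)
    m <- sm$map$mappings
    for (i in seq_len(nrow(s$vocabulary))) {
      v <- s$vocabulary$vocabulary[i]
      mv <- m[m$vocabulary == v, ]
      sizes <- vapply(split(mv$phecode, mv$icd_code),
                      function(p) length(unique(p)), 0L)
      expect_equal(s$vocabulary$n_multi[i], sum(sizes > 1))
      expect_equal(s$vocabulary$frac_multi[i], sum(sizes > 1) / length(sizes))
    }
    expect_equal(sum(s$category_counts), nrow(sm$map$entries))
  }
})

test_that("write/read round trip reproduces the map exactly", {
  for (map in list(demo_map(), v12_map(),
                   simulate_phecode_map(seed = 5)$map)) {
    tmp <- withr::local_tempfile(fileext = ".csv")
    write_phecode_map(map, tmp)
    back <- read_phecode_map(tmp, dialect = map$dialect)
    expect_identical(back$entries, map$entries)
    expect_identical(back$mappings, map$mappings)
    expect_identical(back$exclude_ranges[, c("phecode", "low", "high")],
                     map$exclude_ranges[, c("phecode", "low", "high")])
  }
})

test_that("column overrides let release-style headers be read", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ICD,flag,code,str",
               "A00.1,ICD10CM,ID_001,Cholera"), tmp)
  map <- read_phecode_map(tmp, col_config = list(
    icd_code = "ICD", vocabulary = "flag", phecode = "code",
    phecode_string = "str"))
  expect_equal(map$entries$phecode, "ID_001")
  expect_equal(map$entries$category, "Infectious Diseases") # from registry
  expect_equal(map$mappings$icd_code, "A001")
})
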