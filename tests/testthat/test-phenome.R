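test_that("multi-mapped events roll up the full ancestor chain", {
  map <- demo_map()
  ev <- make_events("A", rep("K40.1", 2), "ICD10CM",
                    c("2020-01-01", "2020-03-05"))
  pc <- map_events(ev, map, rollup = TRUE)
  got <- setNames(pc$counts$count, pc$counts$phecode)
  expect_equal(got[c("GI_520.11", "GI_520.1", "GI_520", "ID_091")],
               c(GI_520.11 = 2L, GI_520.1 = 2L, GI_520 = 2L, ID_091 = 2L))
  expect_equal(nrow(pc$counts), 4L)
})

test_that("same-day duplicate billing counts once; rollup flag controls expansion", {
  map <- demo_map()
  ev <- make_events("A", rep("K40.1", 2), "ICD10CM", rep("2020-01-01", 2))
  pc <- map_events(ev, map)
  expect_true(all(pc$counts$count == 1L))
  pc_flat <- map_events(ev, map, rollup = FALSE)
  expect_setequal(pc_flat$counts$phecode, c("GI_520.11", "ID_091"))
})

test_that("unmapped events are reported, not dropped silently", {
  map <- demo_map()
  ev <- make_events(c("A", "A"), c("K40.1", "Z99.99"), "ICD10CM", "2020-01-01")
  pc <- map_events(ev, map)
  expect_equal(pc$unmapped$icd_code, "Z9999")
  expect_equal(pc$unmapped$n_events, 1L)
  expect_error(map_events(transform(ev, vocabulary = "ICD11"), map),
               "vocabulary")
})

test_that("duplicating every event row leaves the phenome unchanged", {
  mc <- random_map_cohort(3)
  pc1 <- map_events(mc$sim$events, mc$map, roster = mc$sim$roster)
  pc2 <- map_events(rbind(mc$sim$events, mc$sim$events), mc$map,
                    roster = mc$sim$roster)
  expect_identical(counts_df(pc1), counts_df(pc2))
})

test_that("rollup equals the brute-force oracle and is monotone parent >= child", {
  n_reps <- 25
  set.seed(99)
  for (r in seq_len(n_reps)) {
    mc <- random_map_cohort(seed = 500 + r, n_persons = 40)
    pc <- map_events(mc$sim$events, mc$map)
    expect_identical(counts_df(pc), oracle_counts(mc$sim$events, mc$map))
    # monotonicity: count(person, parent) >= count(person, child)
    cdf <- pc$counts
    key <- paste(cdf$person_id, cdf$phecode, sep = "|")
    cnt <- setNames(cdf$count, key)
    parsed <- parse_phecode(cdf$phecode)
    parent <- ifelse(parsed$depth > 0,
                     format_phecode(parsed$category_prefix, parsed$root,
                                    substr(parsed$suffix, 1, parsed$depth - 1)),
                     NA)
    has_parent <- !is.na(parent) & parent %in% mc$map$entries$phecode
    pkey <- paste(cdf$person_id, parent, sep = "|")[has_parent]
    expect_true(all(cnt[pkey] >= cdf$count[has_parent]))
  }
})

test_that("case/control assignment follows the minimum code count rule", {
  map <- demo_map()
  ev <- rbind(
    make_events("P1", rep("K40.1", 2), "ICD10CM", c("2020-01-01", "2020-02-01")),
    make_events("P2", "K40.1", "ICD10CM", "2020-01-01"))
  pc <- map_events(ev, map, roster = c("P1", "P2", "P3"))
  ccm <- assign_case_control(pc, min_code_count = 2)
  m <- as.matrix(ccm)
  expect_equal(m["P1", "GI_520.11"], "case")      # count 2, min 2
  expect_equal(m["P2", "GI_520.11"], "neither")   # count 1, min 2
  expect_equal(unname(m["P3", ]), rep("control", ncol(m)))  # count 0
  # status partition: every cell is exactly one of the three states
  expect_true(all(m %in% c("case", "control", "neither")))
  expect_error(assign_case_control(pc, min_code_count = 0), ">= 1")
})

test_that("exclude ranges demote exactly the hand-enumerated controls", {
  v12 <- v12_map()
  ev <- rbind(
    make_events("P1", rep("411.1", 2), "ICD9CM", c("2020-01-01", "2020-02-01")),
    make_events("P2", "414.8", "ICD9CM", "2020-01-01"),
    make_events("P3", rep("428.0", 2), "ICD9CM", c("2020-01-01", "2020-02-01")),
    make_events("P5", "427.31", "ICD9CM", "2020-01-01"))
  pc <- map_events(ev, v12, roster = paste0("P", 1:5))
  ccm <- assign_case_control(pc, min_code_count = 2)
  out <- apply_exclude_ranges(ccm, pc, v12)

  before <- as.matrix(ccm)
  after <- as.matrix(out)
  # P2 carries 414 (in 410-414.99): loses control status for 410 and 411;
  # P1 carries 411 (also in range): loses control status for 410 and 414
  expect_equal(after["P2", "411"], "neither")
  expect_equal(after["P2", "410"], "neither")
  expect_equal(after["P1", "414"], "neither")
  expect_equal(after["P1", "410"], "neither")
  # cases are never touched
  expect_equal(after["P1", "411"], "case")
  expect_equal(after["P3", "428"], "case")
  # a person with zero counts everywhere stays a control for all phecodes
  expect_equal(unname(after["P4", ]), rep("control", ncol(after)))
  # P3's heart-failure codes are outside 410-414.99: still a control for 411
  expect_equal(after["P3", "411"], "control")
  # the demotions above are the complete set of changes to existing columns
  changed <- which(after[, colnames(before)] != before, arr.ind = TRUE)
  demoted <- sort(paste(rownames(before)[changed[, 1]],
                        colnames(before)[changed[, 2]]))
  expect_equal(demoted, c("P1 414", "P2 411"))
  # phecode 410 had no counts at all; it enters only through its range
  expect_setequal(setdiff(colnames(after), colnames(before)), "410")
  expect_equal(after["P3", "410"], "control")
  expect_equal(after["P5", "410"], "control")
  # exclusion never increases the number of controls (per shared column)
  common <- colnames(before)
  expect_true(all(colSums(after[, common] == "control") <=
                    colSums(before == "control")))
})

test_that("exclude ranges are the identity for the prefixed dialect", {
  map <- demo_map()
  ev <- make_events("P1", rep("K40.1", 2), "ICD10CM",
                    c("2020-01-01", "2020-02-01"))
  pc <- map_events(ev, map)
  ccm <- assign_case_control(pc)
  expect_identical(apply_exclude_ranges(ccm, pc, map), ccm)
  # but attaching ranges to a prefixed-dialect map is an error
  map2 <- map
  map2$exclude_ranges <- data.frame(phecode = "CV_416", low = 1, high = 2,
                                    text = "1-2")
  expect_error(apply_exclude_ranges(ccm, pc, map2), "exclude ranges")
})

test_that("crosswalking a phenome re-keys counts, takes max on collisions, reports drops", {
  xw <- demo_crosswalk()
  pc <- structure(list(
    counts = data.frame(person_id = c("A", "A", "A", "B"),
                        phecode = c("427.2", "410", "411", "800.3"),
                        count = c(3L, 2L, 5L, 1L)),
    persons = c("A", "B"), unmapped = data.frame(), rollup = TRUE,
    dialect = "v1.2"), class = "phenome_counts")
  out <- crosswalk_phenome(pc, xw, "v12_to_X")
  got <- setNames(out$counts$count, out$counts$phecode)
  expect_equal(got[["CV_416.2"]], 3L)
  # 410 (2) and 411 (5) both land on CV_404: max, not sum
  expect_equal(got[["CV_404"]], 5L)
  expect_equal(out$dropped, "800.3")
  expect_false("800.3" %in% out$counts$phecode)
  # sum mode is available but explicit
  out2 <- crosswalk_phenome(pc, xw, "v12_to_X", combine = "sum")
  expect_equal(setNames(out2$counts$count, out2$counts$phecode)[["CV_404"]], 7L)
})

test_that("event and roster files read back correctly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,icd_code,vocabulary,date",
               "P1,K40.1,ICD10CM,2020-01-01"), tmp)
  ev <- read_icd_events(tmp)
  expect_s3_class(ev$date, "Date")
  writeLines(c("person_id,icd_code,vocabulary,date",
               "P1,K40.1,ICD10CM,01/02/2020"), tmp)
  expect_error(read_icd_events(tmp), "ISO 8601")
  writeLines(c("person_id,icd_code,vocabulary,date",
               "P1,K40.1,SNOMED,2020-01-01"), tmp)
  expect_error(read_icd_events(tmp), "vocabulary")
  ros <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("P1", "", "P2"), ros)
  expect_equal(read_roster(ros), c("P1", "P2"))
})
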