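#' Simulate a grammar-valid miniature phecode map
#'
#' Generates a synthetic map in the prefixed dialect: a 1-3-level phenotype
#' tree per root (children carry one extra decimal digit), vocabulary-shaped
#' synthetic ICD codes (letter + digits for ICD-10-like, digits for
#' ICD-9-like), a controllable multi-mapping rate per vocabulary, and a
#' controllable fraction of ICD-10-only phecodes (starred descriptions, no
#' ICD-9 mapping). Every generated map passes [validate_phecode_map()] with
#' an empty report, by construction. With at least a couple hundred ICD
#' codes the realized multi-map rate lands within 0.05 of the target (it is
#' exact up to rounding).
#'
#' @param n_categories number of categories drawn from the registry.
#' @param roots_per_category root phecodes per category.
#' @param p_child probability a node of depth < 3 receives children (2-3 of
#'   them); applied at depth 0 with this value and at depths 1-2 with
#'   `p_grandchild`.
#' @param p_grandchild branching probability below depth 1.
#' @param multi_map_rate target fraction of ICD codes (per vocabulary)
#'   mapped to more than one phecode.
#' @param icd10_only_frac fraction of phecodes supported only by ICD-10
#'   codes.
#' @param icd_per_entry maximum ICD-10 codes per phecode (1 to this many).
#' @param vocabularies vocabularies to populate; `ICD10WHO`, if requested,
#'   covers a `who_coverage` fraction of phecodes (the WHO system has fewer
#'   codes, so some phecodes simply have no WHO mapping).
#' @param who_coverage fraction of phecodes covered by the WHO vocabulary.
#' @param registry category registry.
#' @param seed RNG seed for reproducibility.
#' @return list with `map` (a `phecode_map`) and `truth` (ground-truth
#'   record: `leaves`; `clean_leaves`, the leaves untouched by any
#'   multi-mapped ICD, whose event counts are free of cross-phenotype
#'   contamination; per-vocabulary multi-mapped code sets; `params`).
#' @export
simulate_phecode_map <- function(n_categories = 3L, roots_per_category = 5L,
                                 p_child = 0.6, p_grandchild = 0.3,
                                 multi_map_rate = 0.125,
                                 icd10_only_frac = 0.1, icd_per_entry = 2L,
                                 vocabularies = c("ICD10CM", "ICD9CM"),
                                 who_coverage = 0.8,
                                 registry = default_registry(), seed = NULL) {
  stopifnot(n_categories >= 1L, roots_per_category >= 1L,
            p_child >= 0, p_child <= 1, p_grandchild >= 0, p_grandchild <= 1,
            multi_map_rate >= 0, multi_map_rate <= 1,
            icd10_only_frac >= 0, icd10_only_frac <= 1, icd_per_entry >= 1L)
  vocabularies <- match.arg(vocabularies, VOCABULARIES, several.ok = TRUE)
  if (n_categories > nrow(registry))
    stop("n_categories exceeds the registry size")
  if (n_categories * roots_per_category > 999L)
    stop("infeasible config: more than 999 root codes requested")

  with_seed(seed, {
    cats <- registry[seq_len(n_categories), , drop = FALSE]

    # tree: root numbers are globally unique (001, 002, ...)
    labels <- character(0); prefixes <- character(0)
    root_no <- 0L
    for (ci in seq_len(n_categories)) {
      for (r in seq_len(roots_per_category)) {
        root_no <- root_no + 1L
        root_lab <- sprintf("%s_%03d", cats$prefix[ci], root_no)
        node_labs <- root_lab
        if (stats::runif(1) < p_child) {
          for (c1 in seq_len(sample(2:3, 1L))) {
            lab1 <- paste0(root_lab, ".", c1)
            node_labs <- c(node_labs, lab1)
            if (stats::runif(1) < p_grandchild) {
              for (c2 in seq_len(sample(2:3, 1L))) {
                lab2 <- paste0(lab1, c2)
                node_labs <- c(node_labs, lab2)
                if (stats::runif(1) < p_grandchild) {
                  for (c3 in seq_len(sample(1:2, 1L)))
                    node_labs <- c(node_labs, paste0(lab2, c3))
                }
              }
            }
          }
        }
        labels <- c(labels, node_labs)
        prefixes <- c(prefixes, rep(cats$prefix[ci], length(node_labs)))
      }
    }

    n_entries <- length(labels)
    icd10_only <- stats::runif(n_entries) < icd10_only_frac
    entries <- data.frame(
      phecode = labels,
      description = paste0("Synthetic phenotype ", labels,
                           ifelse(icd10_only, "*", "")),
      category = registry_name(prefixes, registry),
      icd10_only = icd10_only, stringsAsFactors = FALSE)

    icd10_code <- function(i) {
      sprintf("%s%02d.%d", LETTERS[((i - 1L) %/% 1000L) + 1L],
              ((i - 1L) %% 1000L) %/% 10L, (i - 1L) %% 10L)
    }
    icd9_code <- function(i) {
      sprintf("%03d.%d", 100L + ((i - 1L) %/% 10L) %% 900L, (i - 1L) %% 10L)
    }
    who_code <- function(i) {
      sprintf("%s%02d", LETTERS[((i - 1L) %/% 100L) + 1L], (i - 1L) %% 100L)
    }

    maps <- list(); c10 <- 0L; c9 <- 0L; cw <- 0L
    add <- function(icd, vocab, phecode)
      maps[[length(maps) + 1L]] <<- data.frame(icd_code = icd, vocabulary = vocab,
                                               phecode = phecode,
                                               stringsAsFactors = FALSE)
    for (i in seq_len(n_entries)) {
      if ("ICD10CM" %in% vocabularies) {
        for (k in seq_len(sample(seq_len(icd_per_entry), 1L))) {
          c10 <- c10 + 1L; add(icd10_code(c10), "ICD10CM", labels[i])
        }
      }
      if ("ICD9CM" %in% vocabularies && !icd10_only[i]) {
        for (k in seq_len(sample(1:2, 1L))) {
          c9 <- c9 + 1L; add(icd9_code(c9), "ICD9CM", labels[i])
        }
      }
      if ("ICD10WHO" %in% vocabularies && stats::runif(1) < who_coverage) {
        cw <- cw + 1L; add(who_code(cw), "ICD10WHO", labels[i])
      }
    }
    mappings <- do.call(rbind, maps)

    # plant multi-mapping: selected codes get exactly one extra phecode
    multi_truth <- list()
    for (v in vocabularies) {
      mv <- mappings[mappings$vocabulary == v, , drop = FALSE]
      codes <- unique(mv$icd_code)
      n_multi <- round(multi_map_rate * length(codes))
      if (n_multi == 0L) { multi_truth[[v]] <- character(0); next }
      eligible_targets <- if (v == "ICD9CM") labels[!icd10_only] else labels
      if (length(eligible_targets) < 2L)
        stop("infeasible config: multi-mapping needs at least 2 eligible phecodes")
      chosen <- sample(codes, n_multi)
      extra <- lapply(chosen, function(cd) {
        current <- mv$phecode[mv$icd_code == cd]
        pool <- setdiff(eligible_targets, current)
        if (!length(pool)) stop("infeasible config: no distinct multi-map target")
        data.frame(icd_code = cd, vocabulary = v,
                   phecode = if (length(pool) == 1L) pool else sample(pool, 1L),
                   stringsAsFactors = FALSE)
      })
      mappings <- rbind(mappings, do.call(rbind, extra))
      multi_truth[[v]] <- sort(chosen)
    }

    map <- phecode_map(entries, mappings, dialect = "phecodeX",
                       version = "synthetic", registry = registry)
    parents <- na.omit(phecode_parent(map$entries))
    leaves <- setdiff(map$entries$phecode, parents)
    # leaves whose ICDs map to them alone: their counts cannot be contaminated
    # by multi-mapped codes emitted for other phenotypes
    n_targets <- tapply(map$mappings$phecode,
                        paste(map$mappings$icd_code, map$mappings$vocabulary),
                        function(p) length(unique(p)))
    multi_icd <- names(n_targets)[n_targets > 1L]
    key <- paste(map$mappings$icd_code, map$mappings$vocabulary)
    touched <- unique(map$mappings$phecode[key %in% multi_icd])
    truth <- list(
      leaves = leaves,
      clean_leaves = setdiff(leaves, touched),
      multi_mapped = multi_truth,
      params = list(n_categories = n_categories,
                    roots_per_category = roots_per_category,
                    p_child = p_child, p_grandchild = p_grandchild,
                    multi_map_rate = multi_map_rate,
                    icd10_only_frac = icd10_only_frac,
                    icd_per_entry = icd_per_entry,
                    vocabularies = vocabularies, seed = seed))
    list(map = map, truth = truth)
  })
}

#' Simulate a cohort of ICD events with planted genotype effects
#'
#' Generative model: each person carries a biallelic genotype
#' `g ~ Binomial(2, MAF)`. For every leaf phecode, the person is affected
#' with probability `plogis(qlogis(prevalence) + beta * g)`, where `beta`
#' is the planted log-odds-ratio (0 unless the leaf is named in `effects`).
#' Affected persons emit ICD codes drawn uniformly from the leaf's mapped
#' ICDs on `D` distinct dates, `D ~ 1 + Poisson(mean_dates - 1)`, so most
#' affected persons clear a minimum code count of 2 when `mean_dates >= 3`
#' (the miss rate is `dpois(0, mean_dates - 1)`). Background noise events
#' draw ICDs uniformly from the whole map at `background_rate` expected
#' events per person, creating sparse contamination. Effects are planted at
#' leaves only; ancestors inherit signal exclusively through hierarchical
#' rollup, which is exactly the mechanism the pipeline is meant to test.
#'
#' @param map a `phecode_map` (typically from [simulate_phecode_map()]).
#' @param n_persons cohort size (at least 2).
#' @param maf minor-allele frequency in (0, 0.5].
#' @param effects named numeric vector of planted log-odds-ratios; names
#'   must be leaf phecodes of `map` with at least one mapped ICD.
#' @param prevalence baseline (genotype-0) prevalence per leaf phecode;
#'   scalar or named vector, values in (0, 1).
#' @param mean_dates mean distinct coded dates per affected phenotype.
#' @param background_rate expected background events per person.
#' @param date_origin,date_window events are dated uniformly in
#'   `[date_origin, date_origin + date_window)` days.
#' @param seed RNG seed.
#' @return list with `events` (data.frame `person_id`, `icd_code`,
#'   `vocabulary`, `date`), `predictors` (data.frame `person_id`,
#'   `genotype`, `age`, `sex`), `roster` (all person ids), and `truth`
#'   (affection table and parameters).
#' @export
simulate_cohort <- function(map, n_persons = 1000L, maf = 0.3,
                            effects = numeric(0), prevalence = 0.05,
                            mean_dates = 3, background_rate = 1,
                            date_origin = as.Date("2015-01-01"),
                            date_window = 730L, seed = NULL) {
  stopifnot(inherits(map, "phecode_map"), n_persons >= 2L,
            maf > 0, maf <= 0.5, all(prevalence > 0), all(prevalence < 1),
            mean_dates >= 1, background_rate >= 0)
  parents <- na.omit(phecode_parent(map$entries))
  leaves <- setdiff(map$entries$phecode, parents)
  mapped <- unique(map$mappings$phecode)
  leaves <- leaves[leaves %in% mapped]
  if (length(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects))))
      stop("effects must be a named vector of log-odds-ratios")
    bad <- setdiff(names(effects), leaves)
    if (length(bad))
      stop("planted phecode(s) absent from map leaves (or without mapped ICDs): ",
           paste(bad, collapse = ", "))
  }

  prev <- if (length(prevalence) == 1L) setNames(rep(prevalence, length(leaves)), leaves)
          else prevalence[leaves]
  if (anyNA(prev)) stop("prevalence must cover every leaf phecode")
  beta <- setNames(rep(0, length(leaves)), leaves)
  beta[names(effects)] <- effects

  with_seed(seed, {
    persons <- sprintf("P%06d", seq_len(n_persons))
    g <- rbinom(n_persons, 2L, maf)

    # affection draws, leaf by leaf (vectorized over persons)
    aff_p <- integer(0); aff_l <- integer(0)
    for (j in seq_along(leaves)) {
      pr <- plogis(qlogis(prev[j]) + beta[j] * g)
      hit <- which(stats::runif(n_persons) < pr)
      aff_p <- c(aff_p, hit)
      aff_l <- c(aff_l, rep(j, length(hit)))
    }

    mp <- as.data.table(map$mappings)
    setorder(mp, phecode, vocabulary, icd_code)
    mp_by_leaf <- split(seq_len(nrow(mp)), mp$phecode)

    ev <- NULL
    if (length(aff_p)) {
      d <- 1L + rpois(length(aff_p), max(mean_dates - 1, 0))
      pe <- rep(aff_p, d); le <- rep(aff_l, d)
      ord <- order(le)
      pe <- pe[ord]; le <- le[ord]
      rows <- integer(length(le))
      for (j in unique(le)) {
        sel <- which(le == j)
        pool <- mp_by_leaf[[leaves[j]]]
        rows[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
      }
      ev <- data.table(
        person_id = persons[pe],
        icd_code = mp$icd_code[rows],
        vocabulary = mp$vocabulary[rows],
        date = date_origin + sample.int(date_window, length(pe), replace = TRUE) - 1L)
    }

    n_bg <- rpois(n_persons, background_rate)
    if (sum(n_bg)) {
      rows <- sample.int(nrow(mp), sum(n_bg), replace = TRUE)
      bg <- data.table(
        person_id = rep(persons, n_bg),
        icd_code = mp$icd_code[rows],
        vocabulary = mp$vocabulary[rows],
        date = date_origin + sample.int(date_window, sum(n_bg), replace = TRUE) - 1L)
      ev <- if (is.null(ev)) bg else rbind(ev, bg)
    }
    if (is.null(ev))
      ev <- data.table(person_id = character(0), icd_code = character(0),
                       vocabulary = character(0), date = as.Date(character(0)))
    setorder(ev, person_id, date, vocabulary, icd_code)

    predictors <- data.frame(
      person_id = persons, genotype = g,
      age = round(rnorm(n_persons, 55, 12), 1),
      sex = rbinom(n_persons, 1L, 0.5), stringsAsFactors = FALSE)

    truth <- list(
      affected = data.frame(person_id = persons[aff_p],
                            phecode = leaves[aff_l],
                            stringsAsFactors = FALSE),
      params = list(n_persons = n_persons, maf = maf, effects = effects,
                    prevalence = prevalence, mean_dates = mean_dates,
                    background_rate = background_rate, seed = seed),
      leaves = leaves)
    list(events = as.data.frame(ev), predictors = predictors,
         roster = persons, truth = truth)
  })
}

#' Empirical type-I error of the full pipeline under the null
#'
#' Simulates a cohort with no planted effects on the given map, builds the
#' rolled-up phenome, assigns case/control status, runs the scan, and
#' returns the fraction of tested phecodes with `p < alpha` together with
#' its binomial standard error. Under the null this fraction should sit
#' within sampling error of `alpha`.
#'
#' @param map a `phecode_map`.
#' @param n_persons,maf,prevalence,mean_dates,background_rate cohort
#'   parameters, see [simulate_cohort()].
#' @param alpha rejection level compared against each p-value (in (0, 1]).
#' @param min_code_count case threshold, see [assign_case_control()].
#' @param min_cases case-count filter, see [run_phewas()].
#' @param seed RNG seed.
#' @return list with `rate`, `se` (binomial standard error), `n_tested`,
#'   `alpha`, and the `scan` itself.
#' @export
null_calibration <- function(map, n_persons = 5000L, maf = 0.3,
                             prevalence = 0.05, mean_dates = 3,
                             background_rate = 1, alpha = 0.05,
                             min_code_count = 2L, min_cases = 100L,
                             seed = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  sim <- simulate_cohort(map, n_persons = n_persons, maf = maf,
                         prevalence = prevalence, mean_dates = mean_dates,
                         background_rate = background_rate, seed = seed)
  pc <- map_events(sim$events, map, rollup = TRUE, roster = sim$roster)
  ccm <- assign_case_control(pc, min_code_count = min_code_count)
  scan <- run_phewas(ccm, sim$predictors, predictor = "genotype",
                     min_cases = min_cases)
  p <- scan$p_value[is.na(scan$skipped) & !is.na(scan$p_value)]
  n <- length(p)
  if (n == 0L) stop("no phecodes were tested; increase cohort size or lower min_cases")
  rate <- mean(p < alpha)
  list(rate = rate, se = sqrt(rate * (1 - rate) / n), n_tested = n,
       alpha = alpha, scan = scan)
}
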