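#' Logistic regression fit for one phenotype
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (the `stats::glm.fit` engine), with a convergence tolerance of
#' 1e-8 on the deviance-based criterion and at most 25 iterations by
#' default. Quasi-separation (fitted probabilities pinned at 0/1) and
#' non-convergence are reported through the `converged` flag, never
#' silently.
#'
#' @param outcome binary vector (0/1 or logical), both classes present.
#' @param design numeric design matrix including the intercept column; must
#'   have full column rank.
#' @param epsilon convergence tolerance (default 1e-8).
#' @param maxit maximum IRLS iterations (default 25).
#' @return list with `beta` (named coefficient vector), `se` (Wald standard
#'   errors), `converged` (logical), `iter` (iterations used).
#' @examples
#' x <- rep(c(1, 0), each = 100)
#' y <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
#' fit <- fit_logistic(y, cbind(1, x))
#' fit$beta[2]  # log((20*90)/(80*10))
#' @export
fit_logistic <- function(outcome, design, epsilon = 1e-8, maxit = 25L) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (length(y) != nrow(X)) stop("outcome and design have different lengths")
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; cannot fit")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))

  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = binomial(),
                   control = glm.control(epsilon = epsilon, maxit = maxit))
  )
  p <- fit$rank
  Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rmat[lower.tri(Rmat)] <- 0
  cov <- chol2inv(Rmat)
  se <- sqrt(diag(cov))
  separated <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  list(beta = setNames(fit$coefficients, colnames(X)),
       se = setNames(se, colnames(X)),
       converged = fit$converged && !fit$boundary && !separated,
       iter = fit$iter)
}

#' Bonferroni significance threshold
#'
#' The family-wise threshold `alpha / n_tests` used as the nominal
#' significance line of a phenome-wide scan. Strictly decreasing in the
#' number of tests: a map with more testable phenotypes pays a stricter
#' per-test threshold.
#'
#' @param alpha family-wise error rate (in (0,1)).
#' @param n_tests number of tests performed (integer, at least 1).
#' @return per-test significance threshold.
#' @examples
#' bonferroni_threshold(0.05, 1866) # 2.68e-5
#' bonferroni_threshold(0.05, 3612) # 1.38e-5
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1)
    stop("n_tests must be a positive integer")
  alpha / n_tests
}

#' Run a phenome-wide association scan
#'
#' For every phecode with at least `min_cases` cases (after joining to the
#' predictor table), fits a logistic regression of case status on the
#' predictor plus covariates and reports the log-odds-ratio, Wald standard
#' error, odds ratio and p-value. Persons with status `neither` for a
#' phecode are dropped from that phecode's test only (test-wise deletion).
#' Phecodes below the case threshold are emitted with `skipped` reason
#' `"low_case_count"` rather than omitted. Rows are ordered by phecode
#' label, so a scan is deterministic.
#'
#' @param ccm a `case_control` object.
#' @param predictors data.frame with one row per person: `person_id`, the
#'   predictor column, and any covariate columns; no missing predictor
#'   values.
#' @param predictor name of the predictor column (default `"genotype"`).
#' @param covariates character vector of covariate column names (default
#'   none).
#' @param min_cases minimum case count for a phecode to be tested
#'   (default 100).
#' @param alpha family-wise error rate used for the reported Bonferroni
#'   threshold (default 0.05).
#' @param epsilon,maxit IRLS control, see [fit_logistic()].
#' @return data.frame of class `phewas_scan` with columns `phecode`,
#'   `n_case`, `n_control`, `beta`, `se`, `odds_ratio`, `p_value`,
#'   `converged`, `skipped`; attributes `n_tests`, `bonferroni`, `alpha`,
#'   `min_cases`, `predictor`.
#' @seealso [bonferroni_threshold()], [phenome_plot_data()]
#' @export
run_phewas <- function(ccm, predictors, predictor = "genotype",
                       covariates = character(0), min_cases = 100L,
                       alpha = 0.05, epsilon = 1e-8, maxit = 25L) {
  stopifnot(inherits(ccm, "case_control"), is.data.frame(predictors))
  if (!("person_id" %in% names(predictors)))
    stop("predictors must have a person_id column")
  vars <- c(predictor, covariates)
  miss <- setdiff(vars, names(predictors))
  if (length(miss))
    stop("predictor table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(predictors$person_id))
    stop("predictors must have one row per person")
  if (anyNA(predictors[[predictor]]))
    stop("missing predictor values are not allowed")
  if (min_cases < 1) stop("min_cases must be >= 1")

  persons <- intersect(ccm$persons, as.character(predictors$person_id))
  if (length(persons) == 0L)
    stop("empty join: no person ids shared between phenome and predictors")
  pr <- predictors[match(persons, as.character(predictors$person_id)), , drop = FALSE]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(lapply(pr[vars], as.numeric))))
  colnames(X) <- c("(Intercept)", vars)

  s <- ccm$status[ccm$status$person_id %in% persons, , drop = FALSE]
  idx <- match(s$person_id, persons)
  case_by_phecode <- split(idx[s$status == "case"], s$phecode[s$status == "case"])
  neither_by_phecode <- split(idx[s$status == "neither"], s$phecode[s$status == "neither"])

  phecodes <- sort(ccm$phecodes)
  n <- length(persons)
  res <- vector("list", length(phecodes))
  for (k in seq_along(phecodes)) {
    p <- phecodes[k]
    ci <- case_by_phecode[[p]] %||% integer(0)
    ni <- neither_by_phecode[[p]] %||% integer(0)
    y <- numeric(n); y[ci] <- 1
    keep <- rep(TRUE, n); keep[ni] <- FALSE
    n_case <- length(ci)
    n_control <- n - n_case - length(ni)
    row <- data.frame(phecode = p, n_case = n_case, n_control = n_control,
                      beta = NA_real_, se = NA_real_, odds_ratio = NA_real_,
                      p_value = NA_real_, converged = NA,
                      skipped = NA_character_, stringsAsFactors = FALSE)
    if (n_case < min_cases) {
      row$skipped <- "low_case_count"
    } else if (n_control == 0L) {
      row$skipped <- "no_controls"
    } else {
      fit <- tryCatch(
        fit_logistic(y[keep], X[keep, , drop = FALSE],
                     epsilon = epsilon, maxit = maxit),
        error = function(e) NULL)
      if (is.null(fit)) {
        row$skipped <- "degenerate_fit"
      } else {
        b <- fit$beta[[predictor]]
        se <- fit$se[[predictor]]
        row$beta <- b
        row$se <- se
        row$odds_ratio <- exp(b)
        row$p_value <- 2 * pnorm(-abs(b / se))
        row$converged <- fit$converged
      }
    }
    res[[k]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  tested <- sum(is.na(out$skipped))
  attr(out, "n_tests") <- tested
  attr(out, "bonferroni") <- if (tested > 0) bonferroni_threshold(alpha, tested) else NA_real_
  attr(out, "alpha") <- alpha
  attr(out, "min_cases") <- as.integer(min_cases)
  attr(out, "predictor") <- predictor
  class(out) <- c("phewas_scan", "data.frame")
  out
}

#' @export
print.phewas_scan <- function(x, n = 10L, ...) {
  tested <- sum(is.na(x$skipped))
  cat(sprintf("<phewas_scan> %d phecodes: %d tested, %d skipped (predictor=%s, min_cases=%d)\n",
              nrow(x), tested, nrow(x) - tested, attr(x, "predictor"),
              attr(x, "min_cases")))
  if (tested > 0)
    cat(sprintf("  Bonferroni threshold: %.3g (alpha=%.3g over %d tests)\n",
                attr(x, "bonferroni"), attr(x, "alpha"), tested))
  top <- x[is.na(x$skipped), , drop = FALSE]
  top <- top[order(top$p_value), , drop = FALSE]
  print.data.frame(utils::head(top, n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.phewas_scan <- function(object, ...) {
  tested <- object[is.na(object$skipped), , drop = FALSE]
  thr <- attr(object, "bonferroni")
  sig <- tested[!is.na(tested$p_value) & tested$p_value < thr, , drop = FALSE]
  sig <- sig[order(sig$p_value), , drop = FALSE]
  structure(list(n_phecodes = nrow(object), n_tested = nrow(tested),
                 n_skipped = nrow(object) - nrow(tested),
                 bonferroni = thr, alpha = attr(object, "alpha"),
                 significant = sig),
            class = "summary.phewas_scan")
}

#' @export
print.summary.phewas_scan <- function(x, ...) {
  cat(sprintf("PheWAS scan: %d phecodes (%d tested, %d skipped)\n",
              x$n_phecodes, x$n_tested, x$n_skipped))
  cat(sprintf("Bonferroni threshold %.3g at alpha %.3g\n", x$bonferroni, x$alpha))
  if (nrow(x$significant) == 0) cat("No phenome-wide significant associations.\n")
  else {
    cat(sprintf("%d phenome-wide significant association(s):\n", nrow(x$significant)))
    print.data.frame(x$significant, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.phewas_scan <- function(object, ...) {
  tested <- object[is.na(object$skipped), , drop = FALSE]
  setNames(tested$beta, tested$phecode)
}

#' Build the Manhattan-style plot table for a scan
#'
#' Lays tested phecodes out on an x-axis grouped by category in registry
#' order (alphabetical by label within category), with -log10 p on the
#' y-axis and the direction of effect. Phecodes whose prefix is not in the
#' registry are placed in an `"other"` group with a warning. The Bonferroni
#' threshold for the number of tests actually performed is attached as the
#' `threshold` attribute.
#'
#' @param results a `phewas_scan`.
#' @param registry category registry (see [default_registry()]).
#' @return data.frame with columns `phecode`, `category`, `x`,
#'   `neg_log10_p`, `direction`; attribute `threshold`.
#' @export
phenome_plot_data <- function(results, registry = default_registry()) {
  stopifnot(inherits(results, "phewas_scan"))
  tested <- results[is.na(results$skipped), , drop = FALSE]
  if (nrow(tested) == 0L) stop("no tested phecodes to plot")
  prefix <- sub("_.*$", "", tested$phecode)
  prefix[!grepl("^[A-Z]{2}$", prefix)] <- ""
  category <- registry_name(prefix, registry)
  if (anyNA(category)) {
    warning(sprintf("%d phecode(s) with unregistered prefix placed in 'other'",
                    sum(is.na(category))))
    category[is.na(category)] <- "other"
  }
  lev <- c(registry$name, "other")
  ord <- order(match(category, lev), tested$phecode)
  out <- data.frame(phecode = tested$phecode[ord], category = category[ord],
                    x = seq_len(nrow(tested)),
                    neg_log10_p = -log10(tested$p_value[ord]),
                    direction = sign(tested$beta[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- attr(results, "bonferroni")
  out
}

#' Manhattan-style plot of a PheWAS scan
#'
#' @param x a `phewas_scan`.
#' @param registry category registry.
#' @param ... passed to [graphics::plot()].
#' @return the plot table, invisibly.
#' @export
plot.phewas_scan <- function(x, registry = default_registry(), ...) {
  pd <- phenome_plot_data(x, registry = registry)
  cats <- unique(pd$category)
  cols <- setNames(hcl.colors(max(3L, length(cats)), "Dark 3")[seq_along(cats)], cats)
  thr <- attr(pd, "threshold")
  plot(pd$x, pd$neg_log10_p, col = cols[pd$category],
       pch = ifelse(pd$direction >= 0, 24, 25), bg = cols[pd$category],
       xlab = "phecode (grouped by category)",
       ylab = expression(-log[10](p)), xaxt = "n", ...)
  mid <- tapply(pd$x, pd$category, stats::median)
  axis(1, at = mid[cats], labels = cats, las = 2, cex.axis = 0.7)
  if (!is.na(thr)) abline(h = -log10(thr), lty = 2, col = "red")
  invisible(pd)
}
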