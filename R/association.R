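# --- 2x2 exact / asymptotic tests, rank test, partial correlation ------------
#
# These are the field-standard tests (base `stats` does the computation);
# the wrappers enforce the module's contracts: degenerate-margin handling,
# expected-count warnings, a uniform one-row tibble result shape, and a
# recorded method label so any published p-value can be matched to its
# dialect post hoc.

test_result <- function(method, statistic = NA_real_, df = NA_real_,
                        p_value, note = NA_character_) {
  tibble::tibble(method = method, statistic = statistic, df = df,
                 p_value = p_value, note = note)
}

expected_counts <- function(m) outer(rowSums(m), colSums(m)) / sum(m)

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p: the sum of point hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (with a small relative tolerance guarding
#' floating-point ties). A table with a zero margin is degenerate and
#' returns p = 1 with a note.
#'
#' @param table An `fcd_crosstab` or 2x2 count matrix.
#' @return One-row tibble: `method`, `statistic` (NA; exact test),
#'   `df`, `p_value`, `note`.
#' @export
#' @examples
#' fisher_exact_2x2(crosstab_counts(7, 1, 1, 5)) # p = 0.026
fisher_exact_2x2 <- function(table) {
  m <- as_counts_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate margin: exact p is 1")
    return(test_result("fisher_exact", p_value = 1,
                       note = "degenerate margin"))
  }
  test_result("fisher_exact",
              p_value = stats::fisher.test(m)$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic on 1 degree of freedom with upper-tail p, optionally
#' with the Yates continuity correction. Emits a warning (and a `note`)
#' when any expected cell count is below 5, the usual trigger for
#' preferring the exact test.
#'
#' @param table An `fcd_crosstab` or 2x2 count matrix.
#' @param yates Apply the continuity correction? Default `FALSE`.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`, `note`.
#' @export
#' @examples
#' chi_square_2x2(crosstab_counts(25, 16, 9, 25)) # statistic 8.93
chi_square_2x2 <- function(table, yates = FALSE) {
  m <- as_counts_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort_fcd("zero margin: use fisher_exact_2x2()", "domain_error")
  }
  note <- NA_character_
  if (any(expected_counts(m) < 5)) {
    note <- "expected cell count < 5"
    warning("expected cell count < 5; consider the exact test")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = yates))
  test_result(if (yates) "chi_square_yates" else "chi_square_pearson",
              statistic = unname(ct$statistic), df = 1,
              p_value = ct$p.value, note = note)
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' Cross-product ratio `(a d)/(b c)` with the Woolf (log-scale normal)
#' 95% interval. A zero cell is only admitted with the documented 0.5
#' continuity correction (`correct = TRUE`), which is always flagged.
#'
#' @param table An `fcd_crosstab` or 2x2 count matrix.
#' @param correct Add 0.5 to every cell when a zero cell is present.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `note`.
#' @export
#' @examples
#' odds_ratio_2x2(crosstab_counts(25, 16, 9, 25)) # 4.34
odds_ratio_2x2 <- function(table, correct = FALSE, conf_level = 0.95) {
  m <- as_counts_matrix(table)
  note <- NA_character_
  if (any(m == 0)) {
    if (!correct) {
      abort_fcd("zero cell: rerun with correct = TRUE (0.5 added to all cells)",
                "domain_error")
    }
    m <- m + 0.5
    note <- "0.5 continuity correction applied"
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(estimate = or,
                 conf.low = exp(log(or) - z * se),
                 conf.high = exp(log(or) + z * se),
                 note = note)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midrank tie handling; exact p for combined n <= 20 without ties,
#' otherwise the normal approximation with tie-corrected variance. The
#' method actually used is recorded in the result.
#'
#' @param x,y Numeric samples (nonempty).
#' @return One-row tibble: `method`, `statistic` (W), `p_value`, `note`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort_fcd("both samples must be nonempty", "domain_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  test_result(if (exact) "wilcoxon_exact" else "wilcoxon_normal_ties",
              statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Auto-dialect 2x2 association test
#'
#' The published tables do not state which test produced each p-value.
#' The auto rule applies Fisher's exact test when any expected cell count
#' is below 5 and the Pearson chi-square otherwise; `verbose = TRUE`
#' returns all three dialects (Pearson, Yates, exact) so a printed value
#' can be matched post hoc.
#'
#' @param table An `fcd_crosstab` or 2x2 count matrix.
#' @param dialect `"auto"`, `"pearson"`, `"yates"` or `"fisher"`.
#' @param verbose Return all three dialects?
#' @return One-row tibble (or three rows when `verbose`).
#' @export
assoc_test_2x2 <- function(table,
                           dialect = c("auto", "pearson", "yates", "fisher"),
                           verbose = FALSE) {
  dialect <- match.arg(dialect)
  m <- as_counts_matrix(table)
  if (verbose) {
    return(dplyr::bind_rows(
      suppressWarnings(chi_square_2x2(m, yates = FALSE)),
      suppressWarnings(chi_square_2x2(m, yates = TRUE)),
      suppressWarnings(fisher_exact_2x2(m))))
  }
  if (dialect == "auto") {
    dialect <- if (any(expected_counts(m) < 5)) "fisher" else "pearson"
  }
  switch(dialect,
         pearson = chi_square_2x2(m, yates = FALSE),
         yates = chi_square_2x2(m, yates = TRUE),
         fisher = suppressWarnings(fisher_exact_2x2(m)))
}

#' ANCOVA group comparison with Bonferroni family correction
#'
#' Linear model `outcome ~ group + covariates`; reports the group-term
#' p-value and flags significance at the Bonferroni-adjusted level
#' `0.05 / alpha_family` (three volumetric comparisons give the published
#' p < 0.017 threshold).
#'
#' @param data Data frame.
#' @param outcome,group Tidy-eval columns: numeric outcome and binary
#'   group.
#' @param covariates Character vector of covariate column names
#'   (default `c("age_at_mri", "sex", "icv_mm3")`).
#' @param alpha_family Number of comparisons in the family (default 3).
#' @return One-row tibble: `method`, `statistic` (t), `df`, `p_value`,
#'   `alpha_adjusted`, `significant`, `note`.
#' @export
ancova_group_test <- function(data, outcome, group,
                              covariates = c("age_at_mri", "sex", "icv_mm3"),
                              alpha_family = 3) {
  out_q <- rlang::enquo(outcome); grp_q <- rlang::enquo(group)
  d <- tibble::tibble(.outcome = rlang::eval_tidy(out_q, data),
                      .group = rlang::eval_tidy(grp_q, data))
  for (cv in covariates) d[[cv]] <- data[[cv]]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) <= length(covariates) + 2) {
    abort_fcd("too few complete cases for the ANCOVA design", "domain_error")
  }
  fit <- stats::lm(stats::reformulate(c(".group", covariates), ".outcome"),
                   data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort_fcd(paste0("rank-deficient design; collinear term(s): ",
                     paste(bad, collapse = ", ")), "domain_error")
  }
  sm <- summary(fit)$coefficients
  grp_row <- grep("^\\.group", rownames(sm))[1]
  alpha <- 0.05 / alpha_family
  tibble::tibble(method = "ancova",
                 statistic = sm[grp_row, "t value"],
                 df = fit$df.residual,
                 p_value = sm[grp_row, "Pr(>|t|)"],
                 alpha_adjusted = alpha,
                 significant = sm[grp_row, "Pr(>|t|)"] < alpha,
                 note = NA_character_)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the controls, with the t-based two-sided p on
#' `n - k - 2` degrees of freedom (`k` controls). An empty control set
#' reduces to the ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param controls A data frame (or list of vectors) of covariates, or
#'   `NULL`.
#' @return One-row tibble: `method`, `estimate` (r), `statistic` (t),
#'   `df`, `p_value`, `n_controls`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls)) controls <- list()
  ctrl <- if (length(controls)) as.data.frame(controls) else NULL
  keep <- stats::complete.cases(if (is.null(ctrl)) data.frame(x, y)
                                else data.frame(x, y, ctrl))
  x <- x[keep]; y <- y[keep]
  k <- if (is.null(ctrl)) 0L else ncol(ctrl)
  n <- length(x)
  if (n <= k + 2) abort_fcd("need n > controls + 2", "domain_error")
  sx0 <- stats::sd(x); sy0 <- stats::sd(y)
  if (k > 0) {
    ctrl <- ctrl[keep, , drop = FALSE]
    mm <- stats::model.matrix(~ ., data = ctrl)
    x <- stats::lm.fit(mm, x)$residuals
    y <- stats::lm.fit(mm, y)$residuals
  }
  # residual variance at numerical zero (e.g. a variable regressed on
  # itself) leaves the correlation undefined
  if (stats::sd(x) <= 1e-10 * sx0 || stats::sd(y) <= 1e-10 * sy0) {
    abort_fcd("constant residuals: partial correlation undefined",
              "domain_error")
  }
  r <- stats::cor(x, y)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  tibble::tibble(method = "partial_pearson", estimate = r, statistic = tval,
                 df = df, p_value = 2 * stats::pt(-abs(tval), df),
                 n_controls = k)
}

#' Univariate screening for model entry
#'
#' Tests each candidate attribute against a binary outcome and retains
#' those with p below the entry threshold (0.1, the published rule).
#' Binary candidates use the auto-dialect 2x2 test, continuous candidates
#' the Wilcoxon rank-sum test, and multi-level categorical candidates
#' Fisher's exact test on the full contingency table. Untestable
#' candidates (constant, all-missing) are skipped with a warning.
#'
#' @param data Cohort data frame.
#' @param outcome Tidy-eval binary outcome column.
#' @param candidates Character vector of candidate column names.
#' @param threshold Entry p-value threshold (default 0.1).
#' @return Tibble: `candidate`, `type`, `method`, `p_value`, `selected`.
#' @export
select_univariate <- function(data, outcome, candidates, threshold = 0.1) {
  out <- rlang::eval_tidy(rlang::enquo(outcome), data)
  rows <- purrr::map(candidates, function(cand) {
    v <- data[[cand]]
    keep <- !is.na(v) & !is.na(out)
    vv <- v[keep]; oo <- out[keep]
    res <- tryCatch({
      if (is.numeric(vv) && length(unique(vv)) > 2) {
        g <- if (is.logical(oo)) oo else oo == sort(unique(oo))[1]
        r <- wilcoxon_rank_sum(vv[g], vv[!g])
        tibble::tibble(type = "continuous", method = r$method,
                       p_value = r$p_value)
      } else {
        tab <- table(vv, oo)
        if (any(dim(tab) < 2)) stop("constant candidate")
        if (all(dim(tab) == 2)) {
          r <- suppressWarnings(assoc_test_2x2(unclass(tab)[1:2, 1:2]))
          tibble::tibble(type = "binary", method = r$method,
                         p_value = r$p_value)
        } else {
          tibble::tibble(type = "categorical", method = "fisher_exact_rxc",
                         p_value = stats::fisher.test(tab)$p.value)
        }
      }
    }, error = function(e) {
      warning("skipping untestable candidate '", cand, "': ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(candidate = cand), res)
  })
  res <- dplyr::bind_rows(rows)
  res$selected <- res$p_value < threshold
  res
}
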