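# --- multivariable logistic regression with reference coding -----------------

#' Multivariable logistic regression for a binary outcome
#'
#' Maximum-likelihood logistic fit of a binary outcome on a set of
#' predictors, with explicit reference levels for categorical terms (the
#' lesion-location model uses the frontal lobe as reference). Reported
#' effects are exponentiated coefficients (odds ratios) with Wald 95%
#' intervals. Quasi-complete separation (a level with no outcome
#' variation) is detected from inflated standard errors and flagged: the
#' diverging estimate is reported as a diagnostic, not as a valid ratio.
#'
#' @param data Cohort data frame.
#' @param outcome Tidy-eval binary outcome column (logical or two-level).
#' @param predictors Character vector of predictor column names.
#' @param reference Named list/character vector giving the reference level
#'   for categorical predictors, e.g. `c(location = "frontal")`.
#' @return An object of class `fcd_logit` wrapping the `glm` fit.
#'   `tidy()` returns the odds-ratio table (one row per non-intercept
#'   term, with `conf.low`, `conf.high`, `p.value`, `reference`,
#'   `separated`); `glance()` returns fit-level diagnostics.
#' @export
#' @examples
#' fx <- paper_fixture()
#' fx$size <- classify_size(fx$lesion_volume_mm3, 3217)
#' fit <- logistic_fit(fx[!is.na(fx$size), ], sre,
#'                     c("age_at_mri", "sex", "size", "location"),
#'                     reference = c(location = "frontal"))
#' tidy(fit)
logistic_fit <- function(data, outcome, predictors, reference = NULL) {
  out <- rlang::eval_tidy(rlang::enquo(outcome), data)
  if (!is.logical(out)) {
    lev <- sort(unique(stats::na.omit(out)))
    if (length(lev) != 2) abort_fcd("outcome must be binary", "domain_error")
    out <- out == lev[2]
  }
  d <- tibble::tibble(.outcome = out)
  ref_used <- character(0)
  for (p in predictors) {
    v <- data[[p]]
    if (is.null(v)) abort_fcd(paste0("predictor not in data: ", p),
                              "domain_error")
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (!is.null(reference) && p %in% names(reference)) {
        v <- stats::relevel(v, ref = reference[[p]])
      }
      if (nlevels(droplevels(v)) > 1) ref_used[p] <- levels(v)[1]
    }
    d[[p]] <- v
  }
  d <- d[stats::complete.cases(d), ]
  if (length(unique(d$.outcome)) < 2) {
    abort_fcd("outcome has a single class after filtering", "domain_error")
  }
  fit <- stats::glm(stats::reformulate(predictors, ".outcome"),
                    family = stats::binomial(), data = d)
  structure(list(fit = fit, reference = ref_used, n = nrow(d)),
            class = "fcd_logit")
}

#' @exportS3Method generics::tidy
tidy.fcd_logit <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- unname(sm[, "Estimate"]); se <- unname(sm[, "Std. Error"])
  # quasi-separation: Wald SE blows up as the MLE diverges
  separated <- se > 100 | abs(est) > 15
  ref <- rep(NA_character_, nrow(sm))
  for (p in names(x$reference)) {
    ref[startsWith(rownames(sm), p)] <- x$reference[[p]]
  }
  tibble::tibble(term = rownames(sm),
                 estimate = exp(est),
                 conf.low = exp(est - z * se),
                 conf.high = exp(est + z * se),
                 p.value = sm[, "Pr(>|z|)"],
                 reference = ref,
                 separated = separated)
}

#' @exportS3Method generics::glance
glance.fcd_logit <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n = x$n,
                 deviance = x$fit$deviance,
                 null_deviance = x$fit$null.deviance,
                 aic = stats::AIC(x$fit),
                 converged = x$fit$converged,
                 any_separated = any(td$separated))
}

#' @export
print.fcd_logit <- function(x, ...) {
  cat("Logistic regression (", x$n, "complete cases )\n")
  print(tidy(x))
  if (any(tidy(x)$separated)) {
    cat("note: term(s) flagged 'separated' have diverging estimates\n")
  }
  invisible(x)
}
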