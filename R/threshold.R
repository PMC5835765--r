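# --- entropy-based small/large dichotomization -------------------------------

#' Binary (Shannon) entropy
#'
#' Entropy in bits of a Bernoulli(p) label distribution,
#' \eqn{H(p) = -p \log_2 p - (1-p)\log_2(1-p)}, with \eqn{0 \log_2 0 := 0}.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Entropy in bits, same length as `p`.
#' @export
#' @examples
#' binary_entropy(0.5)     # 1
#' binary_entropy(55 / 75) # parent entropy of the 75-lesion report labels
binary_entropy <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort_fcd("p must lie in [0, 1]", "domain_error")
  }
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

gain_components <- function(volume, positive, threshold) {
  below <- volume < threshold
  list(n1 = sum(below), n2 = sum(!below),
       p = mean(positive), p1 = mean(positive[below]),
       p2 = mean(positive[!below]))
}

#' Information gain of a volume split
#'
#' Reduction in label entropy obtained by splitting the lesions at a
#' volume threshold `T` into `D1 = {v < T}` and `D2 = {v >= T}`. The
#' default `"standard"` mode uses the size-weighted child entropy,
#' \deqn{Gain(D,T) = H(D) - \frac{|D_1|}{|D|} H(D_1) - \frac{|D_2|}{|D|} H(D_2),}
#' which is nonnegative and bounded by the parent entropy. The
#' `"literal"` mode computes `H(D) - [H(D1) - H(D2)]`, the unweighted
#' child-entropy difference; it can be negative and is kept only for
#' auditing the published formula, not for analysis.
#'
#' @param volume Positive lesion volumes (mm^3).
#' @param positive Logical MRI-report labels, same length.
#' @param threshold Candidate cutpoint, strictly inside the volume range.
#' @param mode `"standard"` (default) or `"literal"`.
#' @return Gain in bits (scalar).
#' @export
#' @examples
#' information_gain(c(1, 2, 3, 4, 5), c(FALSE, FALSE, TRUE, TRUE, FALSE), 2.5)
information_gain <- function(volume, positive, threshold,
                             mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  stopifnot(length(volume) == length(positive), length(threshold) == 1)
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    abort_fcd("volumes must be finite and positive", "domain_error")
  }
  g <- gain_components(volume, as.logical(positive), threshold)
  if (g$n1 == 0) abort_fcd("empty subset below threshold (D1)", "domain_error")
  if (g$n2 == 0) abort_fcd("empty subset at/above threshold (D2)", "domain_error")
  n <- g$n1 + g$n2
  if (mode == "standard") {
    binary_entropy(g$p) -
      (g$n1 / n * binary_entropy(g$p1) + g$n2 / n * binary_entropy(g$p2))
  } else {
    binary_entropy(g$p) - (binary_entropy(g$p1) - binary_entropy(g$p2))
  }
}

#' Entropy-optimal volume threshold separating small from large lesions
#'
#' Searches for the cutpoint `T` that maximizes the information gain of
#' the MRI-report labels, i.e. that simultaneously maximizes the
#' probabilities of "negative report below T" and "positive report above
#' T". Candidates are the midpoints between consecutive distinct sorted
#' volumes (any value between the same two observations induces the same
#' partition); ties in gain are broken toward the smallest candidate.
#'
#' @param data Data frame with one row per lesion.
#' @param volume,positive Tidy-eval columns: positive volume (mm^3) and
#'   logical report label.
#' @param mode Gain mode, see [information_gain()].
#' @return An object of class `fcd_threshold` with elements `threshold`
#'   (mm^3), `gain`, `parent_entropy`, `p_positive`, `n`, `mode`,
#'   `gain_curve` (tibble of all candidates), and `data` (tibble with the
#'   per-lesion `size` label, small = volume < T). Supports `tidy()`
#'   (gain curve), `glance()` (one-row summary), `autoplot()` and
#'   [classify_size()].
#' @export
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 10, 11, 12),
#'                 pos = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' thr <- find_threshold(d, v, pos)
#' thr$threshold # 6.5; gain 1 bit (perfect separation)
find_threshold <- function(data, volume, positive,
                           mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  v <- rlang::eval_tidy(rlang::enquo(volume), data)
  lab <- as.logical(rlang::eval_tidy(rlang::enquo(positive), data))
  if (anyNA(v) || anyNA(lab)) {
    abort_fcd("volumes and labels must be nonmissing (filter first)",
              "domain_error")
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort_fcd("volumes must be finite and positive", "domain_error")
  }
  if (length(v) < 2) abort_fcd("need at least 2 lesions", "domain_error")
  if (all(lab) || all(!lab)) {
    abort_fcd("no informative split: only one label class present",
              "domain_error")
  }
  sv <- sort(unique(v))
  if (length(sv) < 2) abort_fcd("need at least 2 distinct volumes",
                                "domain_error")
  cand <- (sv[-1] + sv[-length(sv)]) / 2

  # vectorized gain over all candidates via cumulative counts
  ord <- order(v)
  vs <- v[ord]; ls <- lab[ord]
  n <- length(vs)
  cum_pos <- cumsum(ls)
  # index of last observation strictly below each candidate
  k <- findInterval(cand, vs)        # candidates lie between distinct values
  n1 <- k; n2 <- n - k
  p1 <- cum_pos[k] / n1
  p2 <- (cum_pos[n] - cum_pos[k]) / n2
  parent <- binary_entropy(cum_pos[n] / n)
  gain <- if (mode == "standard") {
    parent - (n1 / n * binary_entropy(p1) + n2 / n * binary_entropy(p2))
  } else {
    parent - (binary_entropy(p1) - binary_entropy(p2))
  }
  # ties (within fp tolerance) break toward the smallest candidate
  best <- which(gain > max(gain) - 1e-12)[1]
  threshold <- cand[best]
  structure(
    list(threshold = threshold,
         gain = gain[best],
         parent_entropy = parent,
         p_positive = mean(lab),
         n = n,
         mode = mode,
         gain_curve = tibble::tibble(candidate = cand, gain = gain),
         data = tibble::tibble(volume = v, report_positive = lab,
                               size = classify_size(v, threshold))),
    class = "fcd_threshold")
}

#' Classify lesions as small or large at a threshold
#'
#' Small means volume strictly below `T`; a lesion of exactly `T` mm^3 is
#' large. Missing volumes give `NA` ("unclassifiable": the patient is
#' excluded from size analyses but kept for clinical comparisons).
#'
#' @param volume Numeric volumes (mm^3), `NA` allowed.
#' @param threshold Cutpoint in mm^3, or an `fcd_threshold` object.
#' @return Factor with levels `small`, `large` (small first).
#' @export
#' @examples
#' classify_size(c(3216.62, 3217, 290.69, NA), 3217)
classify_size <- function(volume, threshold) {
  if (inherits(threshold, "fcd_threshold")) threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (any(volume <= 0, na.rm = TRUE)) {
    abort_fcd("volumes must be positive", "domain_error")
  }
  factor(ifelse(volume < threshold, "small", "large"),
         levels = c("small", "large"))
}

#' @export
print.fcd_threshold <- function(x, ...) {
  cat(sprintf(
    "Entropy-optimal volume threshold (%s gain)\n  T = %.2f mm^3, gain = %.4f bits (parent entropy %.4f)\n  n = %d lesions, %d small / %d large, p(positive report) = %.3f\n",
    x$mode, x$threshold, x$gain, x$parent_entropy, x$n,
    sum(x$data$size == "small"), sum(x$data$size == "large"), x$p_positive))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fcd_threshold <- function(x, ...) x$gain_curve

#' @exportS3Method generics::glance
glance.fcd_threshold <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, gain = x$gain,
                 parent_entropy = x$parent_entropy,
                 p_positive = x$p_positive, n = x$n,
                 n_small = sum(x$data$size == "small"),
                 n_large = sum(x$data$size == "large"),
                 mode = x$mode)
}
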