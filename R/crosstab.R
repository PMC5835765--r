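# --- 2x2 cross-tabulation ----------------------------------------------------

binary_levels <- function(v, what) {
  if (is.logical(v)) return(c(TRUE, FALSE))
  if (is.factor(v)) lev <- levels(droplevels(v)) else lev <- sort(unique(v))
  if (length(lev) != 2) {
    abort_fcd(paste0(what, " is not binary (levels: ",
                     paste(lev, collapse = ", "), ")"), "crosstab_error")
  }
  lev
}

#' 2x2 cross-tabulation with printed-style percentages
#'
#' Tabulates two binary attributes of a cohort into a 2x2 table of counts
#' `a, b, c, d` (row 1 = first level of `row`, column 1 = first level of
#' `col`; logical attributes order `TRUE` first, factors follow their
#' level order). Row and column percentages are reported to one decimal,
#' rounded half-up, the convention of the published tables.
#'
#' @param data A cohort data frame.
#' @param row,col Column names (tidy-eval) of the two binary attributes.
#' @param subset Optional tidy-eval predicate restricting the rows
#'   tabulated (e.g. `!is.na(lesion_volume_mm3)`).
#' @return An object of class `fcd_crosstab`: a list with `counts` (2x2
#'   integer matrix with dimnames), `row_pct`, `col_pct` (one-decimal
#'   percentage matrices), `row_label`, `col_label` and `n`.
#'   `tidy()` returns the cell-level tibble.
#' @export
#' @examples
#' fx <- paper_fixture()
#' fx$size <- classify_size(fx$lesion_volume_mm3, 3217)
#' cross_tab(fx, size, sre, subset = !is.na(lesion_volume_mm3))
cross_tab <- function(data, row, col, subset = NULL) {
  row_q <- rlang::enquo(row)
  col_q <- rlang::enquo(col)
  sub_q <- rlang::enquo(subset)
  if (!rlang::quo_is_null(sub_q)) {
    keep <- rlang::eval_tidy(sub_q, data)
    data <- data[keep %in% TRUE, , drop = FALSE]
  }
  rv <- rlang::eval_tidy(row_q, data)
  cv <- rlang::eval_tidy(col_q, data)
  row_label <- rlang::as_label(row_q)
  col_label <- rlang::as_label(col_q)
  if (anyNA(rv) || anyNA(cv)) {
    ids <- if ("patient_id" %in% names(data)) {
      data$patient_id[is.na(rv) | is.na(cv)]
    } else which(is.na(rv) | is.na(cv))
    abort_fcd(paste0("attribute missing for: ", paste(ids, collapse = ", ")),
              "crosstab_error")
  }
  rl <- binary_levels(rv, row_label)
  cl <- binary_levels(cv, col_label)
  counts <- matrix(0L, 2, 2,
                   dimnames = list(as.character(rl), as.character(cl)))
  for (i in 1:2) for (j in 1:2) {
    counts[i, j] <- sum(rv == rl[i] & cv == cl[j])
  }
  structure(
    list(counts = counts,
         row_pct = round_half_up(100 * counts / rowSums(counts), 1),
         col_pct = round_half_up(100 * t(t(counts) / colSums(counts)), 1),
         row_label = row_label, col_label = col_label,
         n = sum(counts)),
    class = "fcd_crosstab")
}

#' Build a 2x2 table directly from counts
#'
#' @param a,b,c,d Nonnegative integer cell counts (row-major).
#' @param row_label,col_label Optional axis labels.
#' @return An `fcd_crosstab` object, as for [cross_tab()].
#' @export
crosstab_counts <- function(a, b, c, d, row_label = "row", col_label = "col") {
  counts <- matrix(as.integer(c(a, b, c, d)), 2, 2, byrow = TRUE,
                   dimnames = list(c("r1", "r2"), c("c1", "c2")))
  if (any(counts < 0) || sum(counts) < 1) {
    abort_fcd("counts must be nonnegative and sum to >= 1", "crosstab_error")
  }
  structure(
    list(counts = counts,
         row_pct = round_half_up(100 * counts / rowSums(counts), 1),
         col_pct = round_half_up(100 * t(t(counts) / colSums(counts)), 1),
         row_label = row_label, col_label = col_label, n = sum(counts)),
    class = "fcd_crosstab")
}

as_counts_matrix <- function(x) {
  if (inherits(x, "fcd_crosstab")) return(x$counts)
  if (is.matrix(x) && all(dim(x) == c(2, 2))) return(x)
  abort_fcd("expected an fcd_crosstab or a 2x2 matrix", "crosstab_error")
}

#' @export
print.fcd_crosstab <- function(x, ...) {
  cat("2x2 table:", x$row_label, "x", x$col_label, " (n =", x$n, ")\n")
  print(x$counts)
  cat("row %:\n"); print(x$row_pct)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fcd_crosstab <- function(x, ...) {
  tibble::tibble(
    !!x$row_label := rep(rownames(x$counts), 2),
    !!x$col_label := rep(colnames(x$counts), each = 2),
    n = as.vector(x$counts),
    row_pct = as.vector(x$row_pct),
    col_pct = as.vector(x$col_pct))
}
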