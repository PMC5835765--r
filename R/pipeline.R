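# --- end-to-end analysis pipeline and published-table-shaped reports ---------

fmt_n_pct <- function(n, den) sprintf("%d (%.1f%%)", n, pct1(n, den))
fmt_mean_range <- function(x) sprintf("%.1f (%.1f-%.1f)", mean(x), min(x),
                                      max(x))
fmt_mean_sd <- function(x) sprintf("%.2f +/- %.2f", mean(x), stats::sd(x))
fmt_center_range <- function(x) sprintf("%.2f (%.2f-%.2f)", stats::median(x),
                                        min(x), max(x))

table1_row_binary <- function(d, col, label, level = TRUE) {
  v <- d[[col]] == level
  tab <- crosstab_counts(sum(v & d$sre), sum(!v & d$sre),
                         sum(v & !d$sre), sum(!v & !d$sre))
  p <- suppressWarnings(assoc_test_2x2(tab))
  tibble::tibble(characteristic = label,
                 sre = fmt_n_pct(sum(v & d$sre), sum(d$sre)),
                 non_sre = fmt_n_pct(sum(v & !d$sre), sum(!d$sre)),
                 p_value = p$p_value, method = p$method)
}

table1_row_cont <- function(d, col, label) {
  x <- d[[col]][d$sre]; y <- d[[col]][!d$sre]
  p <- wilcoxon_rank_sum(x, y)
  tibble::tibble(characteristic = label, sre = fmt_mean_range(x),
                 non_sre = fmt_mean_range(y), p_value = p$p_value,
                 method = p$method)
}

build_table1 <- function(d) {
  dplyr::bind_rows(
    table1_row_binary(d, "sex", "Male", "M"),
    table1_row_cont(d, "age_at_onset", "Age at onset, years"),
    table1_row_cont(d, "age_at_mri", "Age at the MRI, years"),
    table1_row_cont(d, "duration_months", "Duration of epilepsy, months"),
    table1_row_binary(d, "seizure_frequency", "Low seizure frequency", "low"),
    table1_row_binary(d, "mri_report_positive", "MRI findings (positive)"),
    table1_row_binary(d, "side", "Left side of FCD", "left"),
    table1_row_binary(d, "bosd", "BOSD"),
    table1_row_binary(d, "fcd_subtype", "FCD type IIb", "IIb"),
    table1_row_binary(d, "invasive_eeg", "Invasive EEG"),
    table1_row_binary(d, "engel_I", "Seizure-free (Engel I)"))
}

build_table2 <- function(meas, ancova) {
  tibble::tibble(
    measure = c("FCD type II (mm^3), center (range)",
                "Log10 (FCD type II), mean +/- sd",
                "Thalamus ipsilateral (mm^3), mean +/- sd",
                "Thalamus contralateral (mm^3), mean +/- sd"),
    sre = c(fmt_center_range(meas$lesion_norm_mm3[meas$sre]),
            fmt_mean_sd(meas$lesion_log10[meas$sre]),
            fmt_mean_sd(meas$thal_ipsi_norm_mm3[meas$sre]),
            fmt_mean_sd(meas$thal_contra_norm_mm3[meas$sre])),
    non_sre = c(fmt_center_range(meas$lesion_norm_mm3[!meas$sre]),
                fmt_mean_sd(meas$lesion_log10[!meas$sre]),
                fmt_mean_sd(meas$thal_ipsi_norm_mm3[!meas$sre]),
                fmt_mean_sd(meas$thal_contra_norm_mm3[!meas$sre])),
    p_value = c(NA, ancova$lesion$p_value, ancova$thal_ipsi$p_value,
                ancova$thal_contra$p_value),
    significant = c(NA, ancova$lesion$significant,
                    ancova$thal_ipsi$significant,
                    ancova$thal_contra$significant))
}

build_table3 <- function(fit) {
  td <- tidy(fit)
  ref <- tibble::tibble(term = "location: frontal (reference)",
                        estimate = 1, conf.low = NA_real_,
                        conf.high = NA_real_, p.value = NA_real_,
                        reference = NA_character_, separated = FALSE)
  loc_rows <- startsWith(td$term, "location")
  dplyr::bind_rows(td[!loc_rows, ], ref, td[loc_rows, ])
}

build_table4 <- function(meas) {
  one <- function(d, subtype) {
    small_tab <- cross_tab(d, size, sre)
    bosd_tab <- cross_tab(d, bosd, sre)
    p_small <- suppressWarnings(assoc_test_2x2(small_tab))
    p_bosd <- suppressWarnings(assoc_test_2x2(bosd_tab))
    lw <- wilcoxon_rank_sum(d$lesion_log10[d$sre], d$lesion_log10[!d$sre])
    tibble::tibble(
      subtype = subtype,
      measure = c("Lesion volume (mm^3), center (range)",
                  "Log10 (lesion volume)", "Small lesion", "BOSD"),
      sre = c(fmt_center_range(d$lesion_norm_mm3[d$sre]),
              sprintf("%.2f (%.2f-%.2f)", stats::median(d$lesion_log10[d$sre]),
                      min(d$lesion_log10[d$sre]), max(d$lesion_log10[d$sre])),
              fmt_n_pct(sum(d$size == "small" & d$sre), sum(d$sre)),
              fmt_n_pct(sum(d$bosd & d$sre), sum(d$sre))),
      non_sre = c(fmt_center_range(d$lesion_norm_mm3[!d$sre]),
                  sprintf("%.2f (%.2f-%.2f)",
                          stats::median(d$lesion_log10[!d$sre]),
                          min(d$lesion_log10[!d$sre]),
                          max(d$lesion_log10[!d$sre])),
                  fmt_n_pct(sum(d$size == "small" & !d$sre), sum(!d$sre)),
                  fmt_n_pct(sum(d$bosd & !d$sre), sum(!d$sre))),
      p_value = c(NA, lw$p_value, p_small$p_value, p_bosd$p_value))
  }
  dplyr::bind_rows(one(meas[meas$fcd_subtype == "IIa", ], "IIa"),
                   one(meas[meas$fcd_subtype == "IIb", ], "IIb"))
}

#' Run the full lesion-size / SRE analysis pipeline
#'
#' Executes the stages in fixed order on a cohort table: validation;
#' ICV normalization and log transform; entropy threshold search on the
#' measurable lesions' report labels; small/large classification; the
#' clinical comparison table; the 2x2 association battery (size, BOSD,
#' frontal and posterior location vs SRE, every test labeled with its
#' dialect); univariate screening at the 0.1 entry level followed by the
#' multivariable logistic model of SRE on age, sex, lesion size and
#' location (frontal reference); ANCOVAs of log lesion volume and
#' ipsi-/contralateral thalamic volume on group adjusting for age, sex
#' and ICV with a Bonferroni family of 3; and partial correlations of
#' lesion volume with thalamic volumes. The run is fully deterministic:
#' rerunning on the same inputs reproduces identical output.
#'
#' @param cohort A cohort data frame (see [cohort_columns()]).
#' @param volumes_are `"normalized"` (default: stored volumes are already
#'   head-size-corrected, the scale of the published tables) or `"raw"`
#'   (normalize against the cohort mean ICV first).
#' @param mean_icv_scope `"all"` or `"measurable"`, see [cohort_mean_icv()].
#' @param gain_mode Threshold gain mode, see [information_gain()].
#' @param dialect 2x2 test dialect for headline tests (default `"auto"`).
#' @param out_dir Optional directory; when given, writes `volumes.csv`,
#'   `threshold.json` and `tables/table{1..4}.tsv`.
#' @return An object of class `fcd_run`: `cohort` (augmented with
#'   normalized volumes and `size`), `threshold` (`fcd_threshold`),
#'   `counts` (classification counts), `tables` (tibbles shaped like the
#'   published Tables 1-4), `tests` (all test records) and `config`.
#' @export
#' @examples
#' run <- run_pipeline(paper_fixture())
#' run$counts
#' render_table(run, "table3")
run_pipeline <- function(cohort,
                         volumes_are = c("normalized", "raw"),
                         mean_icv_scope = c("all", "measurable"),
                         gain_mode = c("standard", "literal"),
                         dialect = "auto",
                         out_dir = NULL) {
  volumes_are <- match.arg(volumes_are)
  mean_icv_scope <- match.arg(mean_icv_scope)
  gain_mode <- match.arg(gain_mode)
  stage <- "validate"
  res <- tryCatch({
    ch <- validate_cohort(cohort)
    stage <- "normalize"
    ch <- add_volume_norms(ch, volumes_are = volumes_are,
                           mean_icv_scope = mean_icv_scope)
    stage <- "threshold"
    meas <- ch[!is.na(ch$lesion_norm_mm3), ]
    thr <- find_threshold(meas, lesion_norm_mm3, mri_report_positive,
                          mode = gain_mode)
    ch$size <- classify_size(ch$lesion_norm_mm3, thr)
    meas$size <- classify_size(meas$lesion_norm_mm3, thr)
    counts <- c(small = sum(meas$size == "small"),
                large = sum(meas$size == "large"),
                unclassifiable = sum(is.na(ch$size)))
    stage <- "associate"
    size_sre <- cross_tab(meas, size, sre)
    tests <- list(
      size_sre = suppressWarnings(assoc_test_2x2(size_sre, dialect = dialect)),
      size_sre_dialects = assoc_test_2x2(size_sre, verbose = TRUE),
      bosd_size = suppressWarnings(
        assoc_test_2x2(cross_tab(meas, bosd, size), dialect = dialect)),
      frontal_sre = suppressWarnings(assoc_test_2x2(
        cross_tab(dplyr::mutate(ch, frontal = location == "frontal"),
                  frontal, sre), dialect = dialect)),
      posterior_sre = suppressWarnings(assoc_test_2x2(
        cross_tab(dplyr::mutate(ch, posterior =
                                  location == "posterior_quadrant"),
                  posterior, sre), dialect = dialect)))
    stage <- "model"
    screening <- suppressWarnings(select_univariate(
      meas, sre,
      c("sex", "age_at_mri", "duration_months", "seizure_frequency",
        "mri_report_positive", "side", "bosd", "fcd_subtype", "size",
        "location", "invasive_eeg", "engel_I")))
    fit <- logistic_fit(meas, sre, c("age_at_mri", "sex", "size", "location"),
                        reference = c(location = "frontal", size = "large"))
    ancova <- list(
      lesion = ancova_group_test(meas, lesion_log10, sre),
      thal_ipsi = ancova_group_test(meas, thal_ipsi_norm_mm3, sre),
      thal_contra = ancova_group_test(meas, thal_contra_norm_mm3, sre))
    partial <- list(
      lesion_thal_ipsi = partial_correlation(
        meas$lesion_log10, meas$thal_ipsi_norm_mm3,
        controls = meas[, c("age_at_mri", "sex", "icv_mm3")]),
      lesion_thal_contra = partial_correlation(
        meas$lesion_log10, meas$thal_contra_norm_mm3,
        controls = meas[, c("age_at_mri", "sex", "icv_mm3")]))
    stage <- "render"
    tables <- list(table1 = build_table1(ch),
                   table2 = build_table2(meas, ancova),
                   table3 = build_table3(fit),
                   table4 = build_table4(meas))
    structure(
      list(cohort = ch, threshold = thr, counts = counts,
           crosstabs = list(size_sre = size_sre),
           tests = tests, screening = screening, logistic = fit,
           ancova = ancova, partial = partial, tables = tables,
           config = list(volumes_are = volumes_are,
                         mean_icv_scope = mean_icv_scope,
                         gain_mode = gain_mode, dialect = dialect)),
      class = "fcd_run")
  }, error = function(e) {
    abort_fcd(paste0("pipeline failed at stage '", stage, "': ",
                     conditionMessage(e)), "pipeline_error")
  })
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  vols <- run$cohort[, c("patient_id", "lesion_volume_mm3", "lesion_norm_mm3",
                         "lesion_log10", "thal_ipsi_norm_mm3",
                         "thal_contra_norm_mm3")]
  readr::write_csv(vols, file.path(out_dir, "volumes.csv"), na = "")
  jsonlite::write_json(as.list(glance(run$threshold)),
                       file.path(out_dir, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(run$tables)) {
    readr::write_tsv(run$tables[[nm]],
                     file.path(out_dir, "tables", paste0(nm, ".tsv")), na = "NA")
  }
  invisible(out_dir)
}

#' Render a published-table-shaped report
#'
#' Returns (and optionally writes as TSV) one of the four report tables
#' assembled by [run_pipeline()]. Rendering only reads stored results —
#' nothing is recomputed — so rendering twice is idempotent.
#'
#' @param run An `fcd_run` object.
#' @param style One of `"table1"` (clinical comparison), `"table2"`
#'   (volumes), `"table3"` (logistic regression; frontal lobe appears as
#'   the reference row), `"table4"` (subtype subgroups).
#' @param path Optional TSV output path.
#' @return The table as a tibble.
#' @export
render_table <- function(run, style = c("table1", "table2", "table3",
                                        "table4"), path = NULL) {
  stopifnot(inherits(run, "fcd_run"))
  style <- match.arg(style)
  tab <- run$tables[[style]]
  if (!is.null(path)) readr::write_tsv(tab, path, na = "NA")
  tab
}

#' @export
print.fcd_run <- function(x, ...) {
  cat("FCD lesion-size / SRE pipeline run\n")
  cat(sprintf("  threshold: T = %.2f mm^3 (gain %.4f bits, %s mode)\n",
              x$threshold$threshold, x$threshold$gain, x$threshold$mode))
  cat(sprintf("  classification: %d small / %d large / %d unclassifiable\n",
              x$counts["small"], x$counts["large"],
              x$counts["unclassifiable"]))
  cat(sprintf("  size x SRE: p = %.4g (%s)\n",
              x$tests$size_sre$p_value, x$tests$size_sre$method))
  or <- tidy(x$logistic)
  i <- which(or$term == "sizesmall")
  if (length(i) == 1) {
    cat(sprintf("  adjusted small-lesion OR: %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                or$estimate[i], or$conf.low[i], or$conf.high[i],
                or$p.value[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.fcd_run <- function(x, ...) {
  or <- tidy(x$logistic)
  i <- which(or$term == "sizesmall")
  tibble::tibble(
    n = nrow(x$cohort),
    n_measurable = sum(!is.na(x$cohort$lesion_norm_mm3)),
    threshold = x$threshold$threshold,
    gain = x$threshold$gain,
    n_small = unname(x$counts["small"]),
    n_large = unname(x$counts["large"]),
    p_size_sre = x$tests$size_sre$p_value,
    or_small = or$estimate[i],
    or_conf.low = or$conf.low[i],
    or_conf.high = or$conf.high[i],
    p_or_small = or$p.value[i])
}
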