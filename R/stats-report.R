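#' Per-feature mean and SD summaries
#'
#' Summarises each of the 21 features by voxel status (BME vs healthy) or by
#' intervention group over lesion rows. Missing values (only
#' possible for f2) are excluded pairwise with the effective n reported; a
#' single-observation cell reports SD 0 and is flagged as degenerate.
#'
#' @param rows feature table.
#' @param by grouping column, `"status"` or `"group"`.
#' @param lesion_only keep only BME rows first (the by-group summary is over
#'   lesion voxels).
#' @return tibble: `feature`, the grouping level, `n`, `mean`, `sd`,
#'   `degenerate`.
#' @export
summarize_features <- function(rows, by = c("status", "group"),
                               lesion_only = (by[1] == "group")) {
  by <- match.arg(by)
  if (nrow(rows) == 0L) {
    stopf("bmetex_param_error", "empty feature table")
  }
  if (lesion_only) rows <- rows[rows$status == "BME", , drop = FALSE]
  feats <- intersect(feature_names(), names(rows))
  long <- tidyr::pivot_longer(
    rows[, c(by, feats)], dplyr::all_of(feats),
    names_to = "feature", values_to = "value"
  )
  out <- dplyr::group_by(long, .data$feature, .data[[by]]) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) > 1L) sd(.data$value, na.rm = TRUE) else 0,
      degenerate = sum(!is.na(.data$value)) <= 1L,
      .groups = "drop"
    )
  out$feature <- factor(out$feature, levels = feature_names())
  dplyr::arrange(out, .data$feature)
}

#' Build a change-category report with Fisher exact tests
#'
#' Tabulates per-patient change categories (no_change / increased / reduced)
#' by intervention group and tests the group difference with the
#' Freeman-Halton Fisher exact test on the 2x3 table; because printed
#' exact-test p-values in the literature cannot always be attributed to one
#' layout, the 2x2 collapse (any change vs none) is reported alongside.
#'
#' @param categories tibble with one row per patient: `patient_id`, `group`,
#'   `category`.
#' @param source label of the change source, `"radiological"` or `"sparcc"`.
#' @return a `bme_change_report`: list with `counts` tibble, `table` (2x3
#'   matrix), `fisher_p`, `fisher_p_2x2` and `source`.
#' @export
build_change_report <- function(categories, source = "sparcc") {
  stopifnot(all(c("patient_id", "group", "category") %in% names(categories)))
  if (anyDuplicated(categories$patient_id)) {
    stopf("bmetex_param_error", "one category per patient required")
  }
  bad <- setdiff(categories$group, c("HIIT", "control"))
  if (length(bad)) {
    stopf("bmetex_param_error", "unknown group label(s): %s",
          paste(bad, collapse = ", "))
  }
  lv <- c("no_change", "increased", "reduced")
  bad_cat <- setdiff(categories$category, lv)
  if (length(bad_cat)) {
    stopf("bmetex_param_error", "unknown categories: %s",
          paste(bad_cat, collapse = ", "))
  }
  tab <- table(factor(categories$group, levels = c("HIIT", "control")),
               factor(categories$category, levels = lv))
  m <- matrix(as.integer(tab), 2, 3, dimnames = dimnames(tab))
  collapsed <- cbind(no_change = m[, 1], changed = m[, 2] + m[, 3])
  counts <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(counts) <- c("group", "category", "n")
  structure(
    list(counts = counts, table = m,
         fisher_p = fisher_exact(m),
         fisher_p_2x2 = fisher_exact(collapsed),
         source = source),
    class = "bme_change_report"
  )
}

#' @export
print.bme_change_report <- function(x, ...) {
  cat(sprintf("<bme_change_report: %s>\n", x$source))
  print(x$table)
  cat(sprintf("Fisher exact p (2x3): %.4g; collapsed 2x2: %.4g\n",
              x$fisher_p, x$fisher_p_2x2))
  invisible(x)
}
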