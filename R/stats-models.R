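#' Voxel-level mixed model: BME versus healthy voxels
#'
#' Fits, for one feature, the linear mixed model with voxel status (healthy
#' reference vs BME) as fixed effect and random intercepts for patient and
#' for scan within patient, by REML. The reported p-value is the Wald z test
#' of the status coefficient. Perfectly noise-free or otherwise degenerate
#' data yield a singular fit; the fit is then flagged (falling back to
#' ordinary least squares if the mixed fit fails outright) and the p-value is
#' still reported with a warning.
#'
#' @param rows feature table ([extract_feature_table()] shape): needs
#'   `patient_id`, `scan_id`, `status` and the feature column.
#' @param feature feature column name, e.g. `"i2"`.
#' @return a `bme_lmm` object; see [tidy()] and [glance()] methods.
#' @export
lmm_status <- function(rows, feature) {
  need <- c("patient_id", "scan_id", "status", feature)
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stopf("bmetex_param_error", "missing columns: %s",
          paste(miss, collapse = ", "))
  }
  df <- data.frame(
    y = rows[[feature]],
    status = factor(rows$status, levels = c("healthy", "BME")),
    patient_id = factor(rows$patient_id),
    scan_id = factor(rows$scan_id)
  )
  df <- df[complete.cases(df), ]
  if (length(unique(df$patient_id)) < 2L || length(unique(df$status)) < 2L) {
    stopf("bmetex_param_error",
          "need >= 2 patients and both statuses for the voxel model")
  }
  fit_mixed(y ~ status + (1 | patient_id) + (1 | scan_id), df,
            term = "statusBME", feature = feature, model = "voxel_status")
}

#' Longitudinal mixed model: time-by-intervention interaction
#'
#' Fits, for one feature, the change model on per-scan feature means: fixed
#' effects time (reference coded to baseline), intervention (sum coded, HIIT
#' = +1, control = -1) and their interaction, with a random intercept per
#' patient, by REML. The reported p-value is the Wald z test of the
#' interaction. Patients missing a timepoint are dropped (a message reports
#' how many).
#'
#' @param scan_means per-scan feature means ([scan_feature_means()] shape):
#'   `patient_id`, `group`, `timepoint` and the feature column.
#' @param feature feature column name.
#' @return a `bme_lmm` object.
#' @export
lmm_change <- function(scan_means, feature) {
  need <- c("patient_id", "group", "timepoint", feature)
  miss <- setdiff(need, names(scan_means))
  if (length(miss)) {
    stopf("bmetex_param_error", "missing columns: %s",
          paste(miss, collapse = ", "))
  }
  df <- data.frame(
    y = scan_means[[feature]],
    time = factor(scan_means$timepoint, levels = c("baseline", "week11")),
    grp = ifelse(scan_means$group == "HIIT", 1, -1),
    patient_id = factor(scan_means$patient_id)
  )
  df <- df[complete.cases(df), ]
  counts <- table(df$patient_id)
  incomplete <- names(counts)[counts < 2L]
  if (length(incomplete)) {
    message(sprintf("dropped %d patient(s) missing a timepoint",
                    length(incomplete)))
    df <- df[!df$patient_id %in% incomplete, ]
    df$patient_id <- droplevels(df$patient_id)
  }
  if (nlevels(df$patient_id) < 2L) {
    stopf("bmetex_param_error", "need >= 2 complete patients")
  }
  fit_mixed(y ~ time * grp + (1 | patient_id), df,
            term = "timeweek11:grp", feature = feature,
            model = "change_interaction")
}

# Shared REML fit + Wald z extraction with singular-fit flag and OLS
# fallback when lmer cannot fit at all (e.g. zero residual variance).
fit_mixed <- function(formula, df, term, feature, model) {
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(formula, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    )),
    error = function(e) NULL
  )
  co <- NULL
  if (!is.null(fit)) {
    co <- tryCatch(
      suppressWarnings(summary(fit)$coefficients),
      error = function(e) NULL
    )
    if (!is.null(co) && anyNA(co[, 2])) co <- NULL
  }
  if (!is.null(co)) {
    singular <- lme4::isSingular(fit, tol = 1e-4)
    method <- "lmer (REML)"
  } else {
    fixed <- stats::as.formula(paste("y ~",
                                     deparse(lme4::nobars(formula[[3]]))))
    ols <- lm(fixed, data = df)
    co <- summary(ols)$coefficients
    singular <- TRUE
    method <- "ols fallback"
  }
  if (!term %in% rownames(co)) {
    stopf("bmetex_param_error", "term %s not estimable", term)
  }
  est <- co[term, 1]
  se <- co[term, 2]
  z <- if (se > 0) est / se else sign(est) * Inf
  p <- if (se > 0) 2 * pnorm(-abs(z)) else as.numeric(est != 0) * 0
  if (se == 0 && est == 0) p <- 1
  if (singular) {
    rlang::warn(sprintf(
      "singular mixed-model fit for %s (%s); p-value reported anyway",
      feature, model))
  }
  structure(
    list(feature = feature, model = model, term = term, estimate = est,
         std_error = se, statistic = z, p = p, singular = singular,
         n = nrow(df), method = method,
         coefficients = co[, 1:2, drop = FALSE]),
    class = "bme_lmm"
  )
}

#' @export
print.bme_lmm <- function(x, ...) {
  cat(sprintf("<bme_lmm %s> feature %s: %s = %.4g (SE %.3g), p = %.3g%s\n",
              x$model, x$feature, x$term, x$estimate, x$std_error, x$p,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Tidy a fitted voxel or change mixed model
#'
#' @param x a `bme_lmm`.
#' @param ... unused.
#' @return tibble with one row per fixed effect (`term`, `estimate`,
#'   `std.error`) and the Wald statistic / p-value on the tested term.
#' @exportS3Method generics::tidy
#' @export tidy.bme_lmm
tidy.bme_lmm <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, 1],
    std.error = co[, 2],
    statistic = ifelse(rownames(co) == x$term, x$statistic, NA_real_),
    p.value = ifelse(rownames(co) == x$term, x$p, NA_real_)
  )
}

#' @rdname tidy.bme_lmm
#' @exportS3Method generics::glance
#' @export glance.bme_lmm
glance.bme_lmm <- function(x, ...) {
  tibble::tibble(feature = x$feature, model = x$model, nobs = x$n,
                 singular = x$singular, p.value = x$p, method = x$method)
}

#' Per-scan feature means over lesion voxels
#'
#' Averages each feature per scan over rows of the requested status, the
#' response used by the longitudinal change model (lesions cannot be matched
#' between timepoints, so scan means are compared instead).
#'
#' @param rows feature table.
#' @param status which rows to average (default `"BME"`).
#' @return tibble: one row per scan with `patient_id`, `group`, `timepoint`,
#'   `n_voxels` and the 21 feature means (`NA`-aware for `f2`).
#' @export
scan_feature_means <- function(rows, status = "BME") {
  keep <- rows[rows$status %in% status, , drop = FALSE]
  feats <- intersect(feature_names(), names(keep))
  dplyr::group_by(keep, .data$patient_id, .data$group, .data$timepoint,
                  .data$scan_id) |>
    dplyr::summarise(
      n_voxels = dplyr::n(),
      dplyr::across(dplyr::all_of(feats), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Fit a mixed-model family over all features with Bonferroni correction
#'
#' Runs [lmm_status()] (or [lmm_change()]) for every feature column and
#' corrects the family of p-values with `q = min(1, m * p)`, `m` defaulting
#' to the family size (21 features).
#'
#' @param rows feature table (status family) or per-scan means (change
#'   family).
#' @param model `"voxel_status"` or `"change_interaction"`.
#' @param features feature columns to fit.
#' @param m Bonferroni multiplier.
#' @return tibble: `feature`, `estimate`, `std_error`, `statistic`, `p`,
#'   `q`, `singular`, `n`.
#' @export
lmm_family <- function(rows, model = c("voxel_status", "change_interaction"),
                       features = intersect(feature_names(), names(rows)),
                       m = length(features)) {
  model <- match.arg(model)
  fits <- purrr::map(features, function(f) {
    suppressWarnings(
      if (model == "voxel_status") lmm_status(rows, f) else lmm_change(rows, f)
    )
  })
  out <- purrr::map_dfr(fits, function(x) {
    tibble::tibble(feature = x$feature, estimate = x$estimate,
                   std_error = x$std_error, statistic = x$statistic,
                   p = x$p, singular = x$singular, n = x$n)
  })
  out$q <- bonferroni(out$p, m)
  out[, c("feature", "estimate", "std_error", "statistic", "p", "q",
          "singular", "n")]
}
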