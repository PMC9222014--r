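#' Default run configuration
#'
#' A run is fully reproducible from its configuration plus the global seed:
#' stage seeds are derived deterministically from the global seed, and every
#' output is written by deterministic writers.
#'
#' @return nested list with sections `phantom` (see [phantom_spec()]),
#'   `preprocess` (stage toggles + [diffusion_params()] fields + `atlas_scan`,
#'   `"random"` for a seeded random pick), `texture` (`levels`,
#'   `healthy_per_lesion`), `sparcc` (`mic`, `intense_fraction`, `depth_mm`),
#'   `stats` (`m`, `alpha`), and global `seed`.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    phantom = list(
      image_shape = c(96L, 72L, 12L), spacing_mm = c(1.2, 1.2, 3.3),
      n_vertebrae = 7L, marrow_mean = 100, csf_mean = 200, lesion_delta = 60,
      lesion_count_range = c(0L, 4L), lesion_radius_mm_range = c(2, 6),
      bias_amplitude = 0.2, rician_sigma = 5, n_per_group = 19L,
      time_group_effect = 0, background_mean = 10
    ),
    preprocess = list(
      bias = TRUE, match = TRUE, diffuse = TRUE, atlas_scan = "random",
      iterations = 15L, integration_constant = 1 / 7, time_step = 0.01,
      conductance = 1.0
    ),
    texture = list(levels = 8L, healthy_per_lesion = 1),
    sparcc = list(mic = 5L, intense_fraction = 0.75, depth_mm = 10),
    stats = list(m = 21L, alpha = 0.05)
  )
}

#' Load and validate a run configuration from YAML
#'
#' Unknown keys are rejected (every offending key listed), defaults are
#' filled in for absent keys, and value constraints are checked.
#'
#' @param path YAML file path, with top-level keys as in
#'   [default_run_config()].
#' @return the validated, completed configuration list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param config configuration list (possibly partial).
#' @export
validate_config <- function(config) {
  def <- default_run_config()
  bad <- character()
  top_unknown <- setdiff(names(config), names(def))
  bad <- c(bad, top_unknown)
  for (sec in intersect(names(config), names(def))) {
    if (is.list(def[[sec]])) {
      bad <- c(bad, paste(sec, setdiff(names(config[[sec]]),
                                       names(def[[sec]])), sep = "."))
    }
  }
  bad <- bad[!grepl("\\.$", bad)]
  if (length(bad)) {
    stopf("bmetex_config_error", "unknown configuration key(s): %s",
          paste(bad, collapse = ", "))
  }
  cfg <- def
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      cfg[[sec]] <- modifyList(def[[sec]], config[[sec]])
    } else {
      cfg[[sec]] <- config[[sec]]
    }
  }
  if (cfg$sparcc$mic < 0) {
    stopf("bmetex_config_error", "sparcc.mic must be >= 0")
  }
  if (cfg$stats$m < 1) {
    stopf("bmetex_config_error", "stats.m must be >= 1")
  }
  if (cfg$texture$levels < 2) {
    stopf("bmetex_config_error", "texture.levels must be >= 2")
  }
  # constructor-level validation of the numeric sections
  do.call(phantom_spec, c(cfg$phantom, list(seed = cfg$seed)))
  diffusion_params(cfg$preprocess$iterations,
                   cfg$preprocess$integration_constant,
                   cfg$preprocess$time_step, cfg$preprocess$conductance)
  cfg
}

#' Write a configuration to YAML
#' @param config configuration list.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' Run the full pipeline: simulate, preprocess, features, SPARCC, stats
#'
#' Executes every stage in order on a synthetic cohort and writes a report
#' directory: `raw/` (cohort files), `features.csv`, `sparcc.csv`,
#' `table4.csv` (feature summaries by voxel status with voxel-model p/q),
#' `table5.csv` (lesion summaries by group with change-model p/q),
#' `change_tables.json`, `model_diagnostics.json` and `manifest.json`
#' (inputs, outputs, seeds and MD5 checksums). Rerunning with the same
#' configuration reproduces all CSV/JSON outputs byte-identically.
#'
#' @param config configuration (see [default_run_config()]); validated
#'   first.
#' @param out_dir report directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return list with the in-memory results (`features`, `sparcc`,
#'   `table4`, `table5`, `change_reports`, `paths`).
#' @export
run_all <- function(config = default_run_config(), out_dir,
                    overwrite = FALSE) {
  cfg <- validate_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stopf("bmetex_io_error",
          "output directory %s not empty (use overwrite = TRUE)", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  raw_dir <- file.path(out_dir, "raw")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("bmetex_stage_error", "stage '%s' failed: %s", name,
            conditionMessage(e))
    })
  }

  spec <- do.call(phantom_spec, c(cfg$phantom, list(seed = cfg$seed)))
  manifest <- stage("simulate", generate_cohort(spec, raw_dir,
                                                overwrite = overwrite))
  legend <- c("1" = "marrow", "2" = "lesion", "3" = "csf_reference")
  ann <- read_annotation(manifest$annotation[1])

  atlas_id <- cfg$preprocess$atlas_scan
  if (identical(atlas_id, "random")) {
    atlas_id <- with_seed(derive_seed(cfg$seed, "atlas"),
                          sample(manifest$scan_id, 1L))
  }
  atlas_row <- manifest[manifest$scan_id == atlas_id, ]
  if (nrow(atlas_row) != 1L) {
    stopf("bmetex_config_error", "atlas scan '%s' not in cohort", atlas_id)
  }
  atlas <- read_volume(atlas_row$volume, id = atlas_id)
  atlas_masks <- read_labelmap(atlas_row$labels, legend, grid_of = atlas_id)
  dparams <- diffusion_params(cfg$preprocess$iterations,
                              cfg$preprocess$integration_constant,
                              cfg$preprocess$time_step,
                              cfg$preprocess$conductance)
  atlas_pre <- if (cfg$preprocess$bias) {
    correct_bias(atlas, atlas_masks)$volume
  } else {
    atlas
  }

  features <- list()
  sparcc_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    sid <- row$scan_id
    v <- stage("read", read_volume(row$volume, id = sid))
    m <- stage("read", read_labelmap(row$labels, legend, grid_of = sid))
    stage("read", validate_same_grid(v, m))
    pre <- stage("preprocess", preprocess_scan(
      v, m, atlas = atlas_pre, atlas_masks = atlas_masks, params = dparams,
      bias = cfg$preprocess$bias, match = cfg$preprocess$match,
      diffuse = cfg$preprocess$diffuse))
    meta <- list(patient_id = row$patient_id, group = row$group,
                 timepoint = row$timepoint)
    ft <- stage("features", suppressWarnings(extract_matched_features(
      pre, m, meta = meta, levels = cfg$texture$levels,
      healthy_per_lesion = cfg$texture$healthy_per_lesion,
      seed = derive_seed(cfg$seed, "healthy", sid))))
    features[[sid]] <- ft
    sp <- stage("sparcc", sparcc_total(
      m, pre, ann, intense_fraction = cfg$sparcc$intense_fraction,
      depth_mm = cfg$sparcc$depth_mm))
    sparcc_rows[[sid]] <- tibble::tibble(
      patient_id = row$patient_id, group = row$group,
      timepoint = row$timepoint, scan_id = sid, sparcc = sp$total,
      bme_positive = bme_positive(m, ann)
    )
  }
  features <- dplyr::bind_rows(features)
  sparcc_tbl <- dplyr::bind_rows(sparcc_rows)

  wide <- tidyr::pivot_wider(
    sparcc_tbl[, c("patient_id", "group", "timepoint", "sparcc",
                   "bme_positive")],
    names_from = "timepoint",
    values_from = c("sparcc", "bme_positive")
  )
  sparcc_cat <- tibble::tibble(
    patient_id = wide$patient_id, group = wide$group,
    category = mapply(categorize_change, wide$sparcc_baseline,
                      wide$sparcc_week11, MoreArgs = list(mic = cfg$sparcc$mic))
  )
  radio_cat <- tibble::tibble(
    patient_id = wide$patient_id, group = wide$group,
    category = ifelse(wide$bme_positive_week11 == wide$bme_positive_baseline,
                      "no_change",
                      ifelse(wide$bme_positive_week11, "increased", "reduced"))
  )
  change_reports <- stage("stats", list(
    sparcc = build_change_report(sparcc_cat, "sparcc"),
    radiological = build_change_report(radio_cat, "radiological")
  ))

  m_bonf <- cfg$stats$m
  if (nrow(features) > 0) {
    status_fits <- stage("stats", lmm_family(features, "voxel_status",
                                             m = m_bonf))
    means <- scan_feature_means(features)
    change_fits <- stage("stats", lmm_family(means, "change_interaction",
                                             m = m_bonf))
    table4 <- summaries_with_fits(summarize_features(features, "status"),
                                  "status", status_fits)
    table5 <- summaries_with_fits(summarize_features(features, "group"),
                                  "group", change_fits)
  } else {
    message("no lesion voxels in cohort: skipping feature models")
    status_fits <- change_fits <- tibble::tibble()
    table4 <- table5 <- tibble::tibble()
  }

  paths <- list(
    features = file.path(out_dir, "features.csv"),
    sparcc = file.path(out_dir, "sparcc.csv"),
    table4 = file.path(out_dir, "table4.csv"),
    table5 = file.path(out_dir, "table5.csv"),
    changes = file.path(out_dir, "change_tables.json"),
    diagnostics = file.path(out_dir, "model_diagnostics.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(features, paths$features)
  readr::write_csv(sparcc_tbl, paths$sparcc)
  readr::write_csv(table4, paths$table4)
  readr::write_csv(table5, paths$table5)
  jsonlite::write_json(
    list(
      sparcc = change_report_json(change_reports$sparcc),
      radiological = change_report_json(change_reports$radiological)
    ),
    paths$changes, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(
    list(seed = cfg$seed, bonferroni_m = m_bonf, atlas_scan = atlas_id,
         voxel_status = status_fits, change_interaction = change_fits),
    paths$diagnostics, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  out_files <- c(unlist(paths[names(paths) != "manifest"], use.names = FALSE))
  jsonlite::write_json(
    list(seed = cfg$seed, config = cfg,
         inputs = manifest,
         outputs = tibble::tibble(
           path = out_files,
           md5 = unname(tools::md5sum(out_files))
         )),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  list(features = features, sparcc = sparcc_tbl,
       table4 = table4, table5 = table5, change_reports = change_reports,
       config = cfg, atlas_scan = atlas_id, paths = paths)
}

summaries_with_fits <- function(summ, by, fits) {
  wide <- tidyr::pivot_wider(
    summ[, c("feature", by, "n", "mean", "sd")],
    names_from = dplyr::all_of(by), values_from = c("n", "mean", "sd")
  )
  wide$feature <- as.character(wide$feature)
  dplyr::left_join(wide, fits[, c("feature", "estimate", "p", "q")],
                   by = "feature")
}

change_report_json <- function(x) {
  list(source = x$source, counts = x$counts, fisher_p = x$fisher_p,
       fisher_p_2x2 = x$fisher_p_2x2)
}

#' Paired Wilcoxon tests of clinical scores by group
#'
#' Runs the paired signed-rank test on each clinical score column
#' (baseline vs week 11, within group).
#'
#' @param meta study table with `patient_id`, `group`, `timepoint` and
#'   clinical columns.
#' @param scores clinical columns to test.
#' @return tibble: `group`, `score`, `n`, `p`.
#' @export
clinical_wilcoxon <- function(meta,
                              scores = intersect(c("pga", "hscrp", "basdai",
                                                   "das44"), names(meta))) {
  meta <- validate_study_table(meta)
  out <- list()
  for (g in unique(meta$group)) {
    sub <- meta[meta$group == g, ]
    wide <- tidyr::pivot_wider(sub[, c("patient_id", "timepoint", scores)],
                               names_from = "timepoint",
                               values_from = dplyr::all_of(scores))
    for (sc in scores) {
      b <- wide[[paste0(sc, "_baseline")]]
      a <- wide[[paste0(sc, "_week11")]]
      ok <- !is.na(b) & !is.na(a)
      if (sum(ok) < 2) next
      w <- suppressWarnings(suppressMessages(wilcoxon_paired(b[ok], a[ok])))
      out[[paste(g, sc)]] <- tibble::tibble(group = g, score = sc,
                                            n = sum(ok), p = w$p)
    }
  }
  dplyr::bind_rows(out)
}
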