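#' Computerized SPARCC spine scoring of a lesion mask
#'
#' Implements the standard spine scheme: for each disco-vertebral unit, three
#' consecutive sagittal slices are scored; on each slice every one of the
#' four quadrants with at least one lesion voxel scores 1, plus one bonus
#' point per slice for a "deep" lesion (extending at least `depth_mm` from
#' the disc-adjacent vertebral endplate) and one for an "intense" lesion
#' (slice lesion mean at least `intense_fraction` of the median CSF reference
#' intensity), so a unit scores at most 4x3 + 3 + 3 = 18. The six
#' highest-scoring units are summed for the total (0-108).
#'
#' For every unit the consecutive slice triple maximizing the unit score is
#' chosen (ties broken towards the lowest slice index), and ties among units
#' are broken towards the most cranial unit, so scoring is deterministic.
#'
#' @param lesion [labelmask()] with a lesion role (other roles ignored).
#' @param intensity [volume()] on the same grid (used for the intensity
#'   bonus; may be `NULL` to disable it).
#' @param ann a [spine_annotation()].
#' @param intense_fraction fraction of the CSF reference median that counts
#'   as CSF-like brightness (default 0.75).
#' @param depth_mm depth-bonus threshold in mm (default 10, i.e. 1 cm).
#' @return a `bme_sparcc` object: list with `total`, `per_unit` tibble
#'   (unit, slices of the chosen triple, quadrant/depth/intensity points,
#'   unit score, selected flag) and the parameters used.
#' @export
sparcc_total <- function(lesion, intensity = NULL, ann,
                         intense_fraction = 0.75, depth_mm = 10) {
  les <- mask_role(lesion, "lesion")
  d <- dim(les)
  ns <- d[3]
  csf_med <- csf_reference_median(intensity, ann)
  units <- ann$units
  per_unit <- purrr::map_dfr(seq_along(units), function(i) {
    u <- units[[i]]
    best <- NULL
    for (s0 in seq_len(max(1L, ns - 2L))) {
      sl <- s0:min(ns, s0 + 2L)
      parts <- score_unit(les, intensity, u, sl, intense_fraction, depth_mm,
                          csf_med, spacing = lesion$spacing)
      if (is.null(best) || parts$score > best$score) best <- parts
    }
    tibble::tibble(
      unit = u$id, rank = i, slice_start = best$slices[1],
      quadrant_points = best$quadrant, depth_points = best$depth,
      intensity_points = best$intensity, score = best$score
    )
  })
  ord <- order(-per_unit$score, per_unit$rank)
  sel <- ord[seq_len(min(6L, nrow(per_unit)))]
  per_unit$selected <- seq_len(nrow(per_unit)) %in% sel
  total <- sum(per_unit$score[per_unit$selected])
  structure(
    list(total = total, per_unit = per_unit,
         intense_fraction = intense_fraction, depth_mm = depth_mm,
         csf_reference_median = csf_med),
    class = "bme_sparcc"
  )
}

#' @export
print.bme_sparcc <- function(x, ...) {
  cat(sprintf("<bme_sparcc> total %d / 108 over %d units\n",
              x$total, nrow(x$per_unit)))
  print(x$per_unit, n = 10)
  invisible(x)
}

csf_reference_median <- function(intensity, ann) {
  if (is.null(intensity)) return(NA_real_)
  cb <- ann$csf_box
  median(intensity$data[cb$rows[1]:cb$rows[2], cb$cols[1]:cb$cols[2], ])
}

#' Score one disco-vertebral unit on a slice triple
#'
#' @param les logical lesion array.
#' @param intensity [volume()] or `NULL`.
#' @param unit one unit of a [spine_annotation()].
#' @param slices slice indices of the (consecutive) triple.
#' @param intense_fraction,depth_mm see [sparcc_total()].
#' @param csf_med median CSF reference intensity (required when `intensity`
#'   is given).
#' @param spacing voxel spacing in mm.
#' @return list with `quadrant`, `depth`, `intensity` point counts, `score`
#'   and `slices`.
#' @export
score_unit <- function(les, intensity, unit, slices, intense_fraction = 0.75,
                       depth_mm = 10, csf_med = NULL,
                       spacing = c(1, 1, 1)) {
  if (inherits(les, "bme_labelmask")) {
    spacing <- les$spacing
    les <- mask_role(les, "lesion")
  }
  if (!is.null(intensity) && (is.null(csf_med) || is.na(csf_med))) {
    stopf("bmetex_param_error",
          "intensity bonus requires a CSF reference median")
  }
  qpts <- 0L; dpts <- 0L; ipts <- 0L
  for (s in slices) {
    for (q in unit$quadrants) {
      if (any(les[q$rows[1]:q$rows[2], q$cols[1]:q$cols[2], s])) {
        qpts <- qpts + 1L
      }
    }
    if (unit_depth_mm(les, unit, s, spacing) >= depth_mm) dpts <- dpts + 1L
    if (!is.null(intensity)) {
      ules <- unit_lesion_voxels(les, unit, s)
      if (length(ules) > 0 &&
          mean(intensity$data[, , s][ules]) >=
            intense_fraction * csf_med) {
        ipts <- ipts + 1L
      }
    }
  }
  list(quadrant = qpts, depth = dpts, intensity = ipts,
       score = qpts + dpts + ipts, slices = slices)
}

# Linear (within-slice) indices of lesion voxels inside the unit's two
# vertebral bodies on one slice.
unit_lesion_voxels <- function(les, unit, s) {
  sl <- les[, , s]
  keep <- matrix(FALSE, nrow(sl), ncol(sl))
  keep[unit$vert_sup_rows[1]:unit$vert_sup_rows[2],
       unit$cols[1]:unit$cols[2]] <- TRUE
  keep[unit$vert_inf_rows[1]:unit$vert_inf_rows[2],
       unit$cols[1]:unit$cols[2]] <- TRUE
  which(sl & keep)
}

# Maximum lesion extent from the disc-adjacent endplate on one slice, mm.
# A vertebra only contributes when the lesion reaches the unit's
# disc-adjacent half (otherwise it belongs to the neighbouring unit); the
# extent is then measured over the full vertebral body from that endplate.
unit_depth_mm <- function(les, unit, s, spacing) {
  sl <- les[, , s]
  depth <- 0
  half <- (unit$vert_sup_rows[2] - unit$vert_sup_rows[1] + 1L) %/% 2L
  halves <- list(
    list(rows = unit$vert_sup_rows, ep = unit$endplate_rows[1],
         near = c(unit$endplate_rows[1] - half + 1L, unit$endplate_rows[1])),
    list(rows = unit$vert_inf_rows, ep = unit$endplate_rows[2],
         near = c(unit$endplate_rows[2], unit$endplate_rows[2] + half - 1L))
  )
  for (h in halves) {
    touches <- any(sl[h$near[1]:h$near[2], unit$cols[1]:unit$cols[2]])
    if (!touches) next
    sub <- sl[h$rows[1]:h$rows[2], unit$cols[1]:unit$cols[2], drop = FALSE]
    idx <- which(sub, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      rows_abs <- idx[, 1] + h$rows[1] - 1L
      depth <- max(depth, (max(abs(rows_abs - h$ep)) + 1) * spacing[1])
    }
  }
  depth
}

#' Categorize a SPARCC score change at the minimally important change
#'
#' A follow-up score counts as increased (reduced) only when it differs from
#' baseline by at least `mic` points — the minimally important change,
#' 5 by default; smaller differences are `no_change`.
#'
#' @param baseline,followup SPARCC totals in `[0, 108]`.
#' @param mic minimally important change threshold.
#' @return one of `"no_change"`, `"increased"`, `"reduced"`.
#' @examples
#' categorize_change(39, 50)  # "increased"
#' @export
categorize_change <- function(baseline, followup, mic = 5L) {
  if (mic < 0) stopf("bmetex_param_error", "mic must be >= 0")
  for (s in c(baseline, followup)) {
    if (is.na(s) || s < 0 || s > 108) {
      stopf("bmetex_param_error", "scores must be in [0, 108]")
    }
  }
  d <- followup - baseline
  if (d >= mic) "increased" else if (-d >= mic) "reduced" else "no_change"
}

#' Codified radiological BME positivity rule
#'
#' A scan is BME positive when hyperintense lesions occupy two or more
#' distinct disco-vertebral units and/or two or more distinct sagittal
#' slices.
#'
#' @param lesion [labelmask()] with a lesion role.
#' @param ann a [spine_annotation()].
#' @return logical.
#' @export
bme_positive <- function(lesion, ann) {
  les <- mask_role(lesion, "lesion")
  ns <- dim(les)[3]
  n_slices <- sum(vapply(seq_len(ns), function(s) any(les[, , s]), TRUE))
  if (n_slices >= 2L) return(TRUE)
  n_units <- 0L
  for (u in ann$units) {
    hit <- FALSE
    for (q in u$quadrants) {
      if (any(les[q$rows[1]:q$rows[2], q$cols[1]:q$cols[2], ])) {
        hit <- TRUE
        break
      }
    }
    if (hit) n_units <- n_units + 1L
  }
  n_units >= 2L
}
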