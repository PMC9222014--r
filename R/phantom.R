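#' Specification of the synthetic STIR spine phantom
#'
#' The phantom emulates what a sagittal STIR acquisition of the spine looks
#' like after magnitude reconstruction: dark vertebral marrow, bright CSF in
#' the spinal canal, hyperintense bone-marrow-edema lesions seeded at
#' vertebral corners, a smooth multiplicative bias field, and Rician noise.
#' A cohort is two groups (HIIT, control) at two time points (baseline,
#' week11); `time_group_effect` adds extra lesion contrast at week11 in the
#' HIIT group only, giving a known time-by-group interaction for the
#' longitudinal model to recover (zero by default — the null case).
#'
#' Intensity units are arbitrary; the defaults (marrow 100, CSF 200, lesion
#' +60) encode the STIR intensity ordering, not acquired values.
#'
#' @param image_shape integer length-3, grid dimensions (rows, cols, slices).
#' @param spacing_mm voxel size in mm.
#' @param n_vertebrae number of vertebral bodies (units = n_vertebrae - 1).
#' @param marrow_mean,csf_mean,lesion_delta noise-free intensities: marrow
#'   level, CSF level, and the additive lesion hyperintensity.
#' @param lesion_count_range integer pair, lesions per scan (inclusive).
#' @param lesion_radius_mm_range lesion radius range in mm.
#' @param bias_amplitude peak relative deviation of the bias field, in
#'   `[0, 0.5]`.
#' @param rician_sigma noise level of each Gaussian channel.
#' @param n_per_group patients per group.
#' @param time_group_effect extra lesion intensity at week11 in the HIIT
#'   group (0 = no interaction).
#' @param disc_mean intervertebral disc level (STIR-bright nucleus, between
#'   marrow and CSF).
#' @param background_mean paraspinal soft-tissue level (below marrow but far
#'   from zero; air is not modelled).
#' @param seed base seed; every scan's stream is derived from
#'   `(seed, patient_id, timepoint)` so any single scan can be regenerated.
#' @return a `bme_phantom_spec` list.
#' @export
phantom_spec <- function(image_shape = c(96L, 72L, 12L),
                         spacing_mm = c(1.2, 1.2, 3.3),
                         n_vertebrae = 7L,
                         marrow_mean = 100,
                         csf_mean = 200,
                         lesion_delta = 60,
                         lesion_count_range = c(0L, 4L),
                         lesion_radius_mm_range = c(2, 6),
                         bias_amplitude = 0.2,
                         rician_sigma = 5,
                         n_per_group = 19L,
                         time_group_effect = 0,
                         disc_mean = 140,
                         background_mean = 70,
                         seed = 1L) {
  spec <- list(
    image_shape = as.integer(image_shape), spacing_mm = as.double(spacing_mm),
    n_vertebrae = as.integer(n_vertebrae), marrow_mean = marrow_mean,
    csf_mean = csf_mean, lesion_delta = lesion_delta,
    lesion_count_range = as.integer(lesion_count_range),
    lesion_radius_mm_range = as.double(lesion_radius_mm_range),
    bias_amplitude = bias_amplitude, rician_sigma = rician_sigma,
    n_per_group = as.integer(n_per_group),
    time_group_effect = time_group_effect,
    disc_mean = disc_mean,
    background_mean = background_mean, seed = as.integer(seed)
  )
  if (spec$lesion_delta <= 0) {
    stopf("bmetex_spec_error", "lesion_delta must be > 0")
  }
  if (spec$rician_sigma < 0) {
    stopf("bmetex_spec_error", "rician_sigma must be >= 0")
  }
  if (spec$bias_amplitude < 0 || spec$bias_amplitude > 0.5) {
    stopf("bmetex_spec_error", "bias_amplitude must be in [0, 0.5]")
  }
  if (spec$n_vertebrae < 2L) {
    stopf("bmetex_spec_error", "need at least 2 vertebrae")
  }
  layout <- spine_layout(spec)
  if (spec$lesion_radius_mm_range[2] > layout$vheight * spec$spacing_mm[1]) {
    stopf("bmetex_spec_error",
          "max lesion radius %.1f mm exceeds vertebra height %.1f mm",
          spec$lesion_radius_mm_range[2],
          layout$vheight * spec$spacing_mm[1])
  }
  structure(spec, class = "bme_phantom_spec")
}

# Deterministic geometric layout of the phantom spine on the voxel grid.
spine_layout <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  nv <- spec$n_vertebrae
  margin <- 2L
  block <- (nr - 2L * margin) %/% nv
  if (block < 6L) {
    stopf("bmetex_spec_error",
          "image too short for %d vertebrae (%d rows)", nv, nr)
  }
  gap <- 2L
  vheight <- block - gap
  r0 <- margin + 1L + (seq_len(nv) - 1L) * block
  r1 <- r0 + vheight - 1L
  vc0 <- max(2L, as.integer(round(nc * 0.18)))
  vc1 <- min(nc - 2L, vc0 + max(8L, as.integer(round(nc * 0.35))))
  cg0 <- min(nc - 4L, vc1 + 3L)
  cg1 <- min(nc - 1L, cg0 + max(3L, as.integer(round(nc * 0.08))))
  list(vert_rows = unname(cbind(r0, r1)), vcols = c(vc0, vc1),
       csf_cols = c(cg0, cg1), vheight = vheight)
}

# Annotation derived from the layout: one disco-vertebral unit per adjacent
# vertebra pair, quadrants = disc-adjacent vertebral halves split
# anterior/posterior.
phantom_annotation <- function(spec) {
  lay <- spine_layout(spec)
  nv <- spec$n_vertebrae
  vr <- lay$vert_rows
  vc <- lay$vcols
  mc <- (vc[1] + vc[2]) %/% 2L
  half <- lay$vheight %/% 2L
  units <- lapply(seq_len(nv - 1L), function(i) {
    sup <- vr[i, ]; inf <- vr[i + 1L, ]
    sup_half <- c(sup[2] - half + 1L, sup[2])
    inf_half <- c(inf[1], inf[1] + half - 1L)
    list(
      id = sprintf("V%d-V%d", i, i + 1L),
      quadrants = list(
        sa = list(rows = sup_half, cols = c(vc[1], mc)),
        sp = list(rows = sup_half, cols = c(mc + 1L, vc[2])),
        ia = list(rows = inf_half, cols = c(vc[1], mc)),
        ip = list(rows = inf_half, cols = c(mc + 1L, vc[2]))
      ),
      endplate_rows = c(sup[2], inf[1]),
      vert_sup_rows = sup, vert_inf_rows = inf,
      cols = vc
    )
  })
  csf <- list(rows = c(vr[1, 1], vr[nv, 2]), cols = lay$csf_cols)
  spine_annotation(units, csf, spec$image_shape)
}

#' Apply a smooth multiplicative bias field
#'
#' Multiplies a volume by a random smooth field built from a low-order
#' polynomial in normalized coordinates, rescaled so that the field has mean
#' exactly 1 and range within `[1 - amplitude, 1 + amplitude]`. This is the
#' inhomogeneity that bias-field correction later has to undo.
#'
#' @param v a [volume()].
#' @param amplitude peak relative deviation, in `[0, 0.5]`.
#' @param seed RNG seed for the polynomial coefficients.
#' @return list with elements `volume` (biased copy) and `field` (array).
#' @export
apply_bias <- function(v, amplitude, seed = 1L) {
  if (amplitude < 0 || amplitude > 0.5) {
    stopf("bmetex_spec_error", "bias amplitude must be in [0, 0.5]")
  }
  d <- dim(v$data)
  if (amplitude == 0) {
    return(list(volume = v, field = array(1, d)))
  }
  field <- with_seed(seed, {
    co <- rnorm(9L)
    x <- seq(-1, 1, length.out = d[1])
    y <- seq(-1, 1, length.out = d[2])
    z <- seq(-1, 1, length.out = d[3])
    gx <- co[1] * x + co[4] * x^2
    gy <- co[2] * y + co[5] * y^2
    gz <- co[3] * z + co[6] * z^2
    g <- outer(outer(gx, gy, `+`), gz, `+`) +
      co[7] * outer(outer(x, y), rep(1, d[3])) +
      co[8] * outer(outer(x, rep(1, d[2])), z) +
      co[9] * outer(outer(rep(1, d[1]), y), z)
    g <- g - mean(g)
    m <- max(abs(g))
    if (m == 0) array(1, d) else array(1 + amplitude * g / m, d)
  })
  out <- v
  out$data <- v$data * field
  list(volume = out, field = field)
}

#' Add Rician magnitude noise
#'
#' Replaces each voxel `x` by `sqrt((x + n1)^2 + n2^2)` with `n1, n2`
#' independent zero-mean Gaussians of standard deviation `sigma` — the
#' standard noise model for magnitude-reconstructed MR images.
#'
#' @param v a [volume()].
#' @param sigma Gaussian channel standard deviation (>= 0).
#' @param seed RNG seed.
#' @return a [volume()] with noisy intensities.
#' @export
add_rician_noise <- function(v, sigma, seed = 1L) {
  if (sigma < 0) stopf("bmetex_spec_error", "sigma must be >= 0")
  if (sigma == 0) return(v)
  n <- length(v$data)
  out <- v
  out$data <- with_seed(seed, {
    n1 <- rnorm(n, 0, sigma)
    n2 <- rnorm(n, 0, sigma)
    array(sqrt((as.vector(v$data) + n1)^2 + n2^2), dim(v$data))
  })
  out
}

#' Generate one synthetic STIR spine scan with ground truth
#'
#' Builds the noise-free phantom (marrow, CSF, corner lesions), applies the
#' bias field, then Rician noise. Lesion voxels' noise-free intensity is
#' exactly `marrow_mean + lesion_delta`, plus `time_group_effect` when
#' `group == "HIIT"` and `timepoint == "week11"`. The output is fully
#' deterministic given `(seed, patient_id, timepoint)`.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id,timepoint,group scan identity; `timepoint` is
#'   `"baseline"` or `"week11"`, `group` is `"HIIT"` or `"control"`.
#' @param seed base seed (defaults to `spec$seed`).
#' @return list with `volume` (noisy scan) and `truth`: `labelmap` (combined
#'   labels 1=marrow, 2=lesion, 3=csf_reference), logical arrays
#'   `marrow`/`lesion`/`csf` (marrow includes lesion voxels), `true_bias`
#'   field, the `annotation`, a per-lesion tibble (`level`, `quadrant`,
#'   `depth_mm`, `intense`, `n_voxels`) and the noise-free `clean` volume.
#' @export
generate_scan <- function(spec, patient_id, timepoint = "baseline",
                          group = "control", seed = spec$seed) {
  stopifnot(inherits(spec, "bme_phantom_spec"))
  if (!timepoint %in% c("baseline", "week11")) {
    stopf("bmetex_spec_error", "timepoint must be baseline or week11")
  }
  if (!group %in% c("HIIT", "control")) {
    stopf("bmetex_spec_error", "group must be HIIT or control")
  }
  scan_seed <- derive_seed(seed, patient_id, timepoint)
  d <- spec$image_shape
  sp <- spec$spacing_mm
  lay <- spine_layout(spec)
  ann <- phantom_annotation(spec)
  scan_id <- sprintf("%s_%s", patient_id, timepoint)

  marrow <- array(FALSE, d)
  for (i in seq_len(spec$n_vertebrae)) {
    marrow[lay$vert_rows[i, 1]:lay$vert_rows[i, 2],
           lay$vcols[1]:lay$vcols[2], ] <- TRUE
  }
  csf <- array(FALSE, d)
  csf[ann$csf_box$rows[1]:ann$csf_box$rows[2],
      ann$csf_box$cols[1]:ann$csf_box$cols[2], ] <- TRUE

  delta_eff <- spec$lesion_delta +
    if (group == "HIIT" && timepoint == "week11") spec$time_group_effect else 0

  les <- with_seed(derive_seed(scan_seed, "lesions"), {
    k <- sample(seq(spec$lesion_count_range[1], spec$lesion_count_range[2]), 1L)
    place_lesions(spec, lay, ann, k)
  })
  lesion <- les$mask & marrow
  records <- lesion_records(les$params, lesion, ann, sp,
                            delta_eff + spec$marrow_mean,
                            spec$csf_mean)

  img <- array(spec$background_mean, d)
  # intervertebral discs: the gap rows between adjacent vertebral bodies
  for (i in seq_len(spec$n_vertebrae - 1L)) {
    img[(lay$vert_rows[i, 2] + 1L):(lay$vert_rows[i + 1L, 1] - 1L),
        lay$vcols[1]:lay$vcols[2], ] <- spec$disc_mean
  }
  img[marrow] <- spec$marrow_mean
  img[csf] <- spec$csf_mean
  img[lesion] <- spec$marrow_mean + delta_eff
  clean <- volume(img, spacing = sp, id = scan_id)

  biased <- apply_bias(clean, spec$bias_amplitude,
                       seed = derive_seed(scan_seed, "bias"))
  noisy <- add_rician_noise(biased$volume, spec$rician_sigma,
                            seed = derive_seed(scan_seed, "noise"))
  noisy$id <- scan_id

  labels <- array(0L, d)
  labels[marrow] <- 1L
  labels[lesion] <- 2L
  labels[csf] <- 3L
  lm <- labelmask(labels,
                  legend = c("1" = "marrow", "2" = "lesion",
                             "3" = "csf_reference"),
                  spacing = sp, grid_of = scan_id)

  list(
    volume = noisy,
    truth = list(labelmap = lm, marrow = marrow, lesion = lesion, csf = csf,
                 true_bias = biased$field, annotation = ann,
                 lesions = records, clean = clean)
  )
}

# Sample k corner lesions (ellipsoids seeded at disc-adjacent vertebral
# corners). Runs inside the scan's lesion RNG stream.
place_lesions <- function(spec, lay, ann, k) {
  d <- spec$image_shape
  sp <- spec$spacing_mm
  mask <- array(FALSE, d)
  params <- list()
  if (k < 1L) return(list(mask = mask, params = params))
  nu <- length(ann$units)
  for (j in seq_len(k)) {
    ui <- sample.int(nu, 1L)
    qi <- sample.int(4L, 1L)
    u <- ann$units[[ui]]
    radius <- runif(1L, spec$lesion_radius_mm_range[1],
                    spec$lesion_radius_mm_range[2])
    # corner voxel: endplate row x anterior/posterior vertebral edge
    sup <- qi <= 2L
    ant <- qi %in% c(1L, 3L)
    er <- if (sup) u$endplate_rows[1] else u$endplate_rows[2]
    cc <- if (ant) u$cols[1] + 1L else u$cols[2] - 1L
    cr <- if (sup) er - 1L else er + 1L
    cs <- sample(seq(2L, max(2L, d[3] - 1L)), 1L)
    ar <- radius / sp[1]
    ac <- radius / sp[2] * runif(1L, 0.6, 1)
    as_ <- max(0.5, radius / sp[3] * runif(1L, 0.5, 1))
    rr <- seq(max(1L, floor(cr - ar)), min(d[1], ceiling(cr + ar)))
    cc_rng <- seq(max(1L, floor(cc - ac)), min(d[2], ceiling(cc + ac)))
    ss <- seq(max(1L, floor(cs - as_)), min(d[3], ceiling(cs + as_)))
    for (s in ss) {
      dz2 <- ((s - cs) / as_)^2
      if (dz2 > 1) next
      dr <- outer(((rr - cr) / ar)^2, ((cc_rng - cc) / ac)^2, `+`)
      inside <- dr + dz2 <= 1
      sub <- mask[rr, cc_rng, s, drop = FALSE]
      sub[, , 1][inside] <- TRUE
      mask[rr, cc_rng, s] <- sub
    }
    params[[j]] <- list(unit = ui, quadrant = names(u$quadrants)[qi],
                        centre = c(cr, cc, cs), radius_mm = radius,
                        sup = sup)
  }
  list(mask = mask, params = params)
}

# Ground-truth lesion records measured from the realized mask, so they are
# consistent with it by construction.
lesion_records <- function(params, lesion, ann, sp, lesion_level, csf_mean) {
  if (!length(params)) {
    return(tibble::tibble(level = character(), quadrant = character(),
                          depth_mm = double(), intense = logical(),
                          n_voxels = integer()))
  }
  purrr::map_dfr(params, function(p) {
    u <- ann$units[[p$unit]]
    vrows <- if (p$sup) u$vert_sup_rows else u$vert_inf_rows
    er <- if (p$sup) u$endplate_rows[1] else u$endplate_rows[2]
    sub <- lesion[vrows[1]:vrows[2], u$cols[1]:u$cols[2], , drop = FALSE]
    idx <- which(sub, arr.ind = TRUE)
    depth <- if (nrow(idx) == 0) 0 else {
      rows_abs <- idx[, 1] + vrows[1] - 1L
      (max(abs(rows_abs - er)) + 1) * sp[1]
    }
    tibble::tibble(level = u$id, quadrant = p$quadrant, depth_mm = depth,
                   intense = lesion_level >= 0.75 * csf_mean,
                   n_voxels = nrow(idx))
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Writes `2 * n_per_group` patients times two timepoints: a NIfTI volume and
#' an NRRD label map per scan, one annotation JSON, a study metadata CSV
#' (with simple synthetic clinical scores), and a manifest CSV listing every
#' file.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @param overwrite refuse to write into a non-empty directory unless `TRUE`.
#' @return the manifest tibble (one row per scan), invisibly also written to
#'   `manifest.csv`.
#' @export
generate_cohort <- function(spec, out_dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "bme_phantom_spec"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stopf("bmetex_io_error",
          "output directory %s is not empty (use overwrite = TRUE)", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_per_group
  patients <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(2L * n)),
    group = rep(c("HIIT", "control"), each = n)
  )
  ann_path <- file.path(out_dir, "annotation.json")
  rows <- list()
  meta <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    grp <- patients$group[i]
    for (tp in c("baseline", "week11")) {
      scan <- generate_scan(spec, pid, tp, grp)
      sid <- scan$volume$id
      vpath <- file.path(out_dir, paste0(sid, ".nii.gz"))
      lpath <- file.path(out_dir, paste0(sid, "_labels.nrrd"))
      write_volume(scan$volume, vpath)
      write_labelmap(scan$truth$labelmap, lpath)
      if (i == 1L && tp == "baseline") {
        write_annotation(scan$truth$annotation, ann_path)
      }
      rows[[sid]] <- tibble::tibble(
        patient_id = pid, group = grp, timepoint = tp, scan_id = sid,
        volume = vpath, labels = lpath, annotation = ann_path
      )
      clin <- with_seed(derive_seed(spec$seed, pid, tp, "clinical"), {
        c(pga = round(runif(1, 10, 80)),
          hscrp = round(exp(rnorm(1, 0.7, 0.8)), 1),
          basdai = round(runif(1, 0.5, 7), 1),
          das44 = round(runif(1, 0.5, 3.2), 1))
      })
      meta[[sid]] <- tibble::tibble(
        patient_id = pid, group = grp, timepoint = tp,
        pga = clin[["pga"]], hscrp = clin[["hscrp"]],
        basdai = clin[["basdai"]], das44 = clin[["das44"]]
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  readr::write_csv(dplyr::bind_rows(meta), file.path(out_dir, "meta.csv"))
  manifest
}
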