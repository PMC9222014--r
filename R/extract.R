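#' Extract the per-voxel feature table
#'
#' Slides the 3x3 window over every requested centre voxel and computes the
#' 21 texture features (i1-i7, g1-g10, f1-f4) slice by slice. Centres are
#' mask voxels whose in-slice 3x3 window lies fully inside the image; border
#' voxels are excluded (the exclusion count is reported). Window intensities
#' are taken from the image regardless of mask membership, so features at
#' mask edges are always defined. GLCM quantization uses per-scan global
#' min-max scaling.
#'
#' This is a vectorized implementation of exactly the per-window operations
#' [intensity_features()], [gradient_features()] (on [sobel_gradients()]
#' maps) and [glcm_features()].
#'
#' @param v preprocessed [volume()].
#' @param masks [labelmask()] aligned to `v`; lesion-role voxels get status
#'   `"BME"`, other centres `"healthy"`.
#' @param meta optional single-row data frame / list with `patient_id`,
#'   `group`, `timepoint` carried into the table.
#' @param levels GLCM grey levels.
#' @param centres optional logical array selecting centre voxels; default is
#'   all marrow + lesion voxels.
#' @return tibble, one row per evaluated centre: keys (`patient_id`,
#'   `scan_id`, `timepoint`, `group`, `row`, `col`, `slice`, `status`) plus
#'   the 21 feature columns. Attribute `n_excluded_border` counts skipped
#'   border voxels. Only `f2` may be `NA`.
#' @export
extract_feature_table <- function(v, masks, meta = NULL, levels = 8L,
                                  centres = NULL) {
  validate_same_grid(v, masks)
  if (v$slice_axis != 3L) {
    perm <- c(setdiff(1:3, v$slice_axis), v$slice_axis)
    v$data <- aperm(v$data, perm)
    v$spacing <- v$spacing[perm]
    v$slice_axis <- 3L
    masks$labels <- aperm(masks$labels, perm)
    masks$spacing <- masks$spacing[perm]
    if (!is.null(centres)) centres <- aperm(centres, perm)
  }
  lesion <- mask_role(masks, "lesion")
  if (is.null(centres)) {
    centres <- mask_role(masks, "marrow") | lesion
  }
  d <- dim(v$data)
  idx_all <- which(centres)
  if (length(idx_all) == 0L) {
    rlang::warn("empty centre mask: returning empty feature table")
    return(empty_feature_table())
  }
  co <- arrayInd(idx_all, d)
  interior <- co[, 1] >= 2L & co[, 1] <= d[1] - 1L &
    co[, 2] >= 2L & co[, 2] <= d[2] - 1L
  n_excl <- sum(!interior)
  co <- co[interior, , drop = FALSE]
  if (nrow(co) == 0L) {
    rlang::warn("all centre voxels on the image border")
    out <- empty_feature_table()
    attr(out, "n_excluded_border") <- n_excl
    return(out)
  }
  q_all <- quantize_levels(v$data, levels)
  meta <- meta %||% list(patient_id = NA_character_, group = NA_character_,
                         timepoint = NA_character_)

  parts <- list()
  for (s in sort(unique(co[, 3]))) {
    sel <- co[, 3] == s
    rows <- co[sel, 1]; cols <- co[sel, 2]
    sl <- slice_get(v$data, s, v$slice_axis)
    qs <- slice_get(q_all, s, v$slice_axis)
    G <- sobel_gradients(sl)
    feats <- slice_features(sl, qs, G$gx, G$gy, rows, cols, levels)
    parts[[as.character(s)]] <- tibble::tibble(
      patient_id = as.character(meta$patient_id),
      scan_id = v$id,
      timepoint = as.character(meta$timepoint),
      group = as.character(meta$group),
      row = rows, col = cols, slice = s,
      status = ifelse(lesion[cbind(rows, cols, s)], "BME", "healthy")
    ) |> dplyr::bind_cols(tibble::as_tibble(feats))
  }
  out <- dplyr::bind_rows(parts)
  attr(out, "n_excluded_border") <- n_excl
  if (n_excl > 0) {
    message(sprintf("excluded %d border centre voxel(s)", n_excl))
  }
  out
}

empty_feature_table <- function() {
  keys <- tibble::tibble(
    patient_id = character(), scan_id = character(), timepoint = character(),
    group = character(), row = integer(), col = integer(), slice = integer(),
    status = character()
  )
  f <- matrix(numeric(), 0, 21,
              dimnames = list(NULL, feature_names()))
  dplyr::bind_cols(keys, tibble::as_tibble(f))
}

#' Names of the 21 texture features
#' @return character vector `i1..i7, g1..g10, f1..f4`.
#' @export
feature_names <- function() {
  c(paste0("i", 1:7), paste0("g", 1:10), paste0("f", 1:4))
}

# Vectorized per-slice feature computation for given interior centres.
slice_features <- function(sl, qs, gx, gy, rows, cols, levels) {
  n <- length(rows)
  nr <- nrow(sl)
  # column-major window gather: offsets (dc, dr) ordered dc major so the
  # centre is column 5
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  lin <- outer(rows, offs$dr, `+`) + (outer(cols, offs$dc, `+`) - 1L) * nr
  W <- matrix(sl[lin], n, 9L)
  GX <- matrix(gx[lin], n, 9L)
  GY <- matrix(gy[lin], n, 9L)
  QW <- matrix(qs[lin], n, 9L)

  out <- matrix(NA_real_, n, 21L, dimnames = list(NULL, feature_names()))
  S <- apply(W, 1L, sort)               # 9 x n
  m <- rowMeans(W)
  out[, "i1"] <- W[, 5L]
  out[, "i2"] <- m
  out[, "i3"] <- S[5L, ]
  out[, "i4"] <- sqrt(rowSums((W - m)^2) / 8)
  out[, "i5"] <- S[1L, ]
  out[, "i6"] <- S[9L, ]
  out[, "i7"] <- (S[7L, ] - S[3L, ]) / 2

  MW <- sqrt(GX^2 + GY^2)
  SM <- apply(MW, 1L, sort)
  gm <- rowMeans(MW)
  out[, "g1"] <- rowSums(abs(GX) + abs(GY))
  out[, "g2"] <- rowSums(MW)
  out[, "g3"] <- gm
  out[, "g4"] <- SM[5L, ]
  out[, "g5"] <- sqrt(rowSums((MW - gm)^2) / 8)
  out[, "g6"] <- (SM[7L, ] - SM[3L, ]) / 2
  out[, "g7"] <- MW[, 5L]
  out[, "g8"] <- SM[1L, ]
  out[, "g9"] <- SM[9L, ]
  out[, "g10"] <- rowMeans(abs(abs(GX) - abs(GY)))

  glcm <- slice_glcm(QW, levels)
  out[, c("f1", "f2", "f3", "f4")] <- glcm
  out
}

# Window pair index sets per orientation, in column-major 3x3 indexing
# (k = (wc - 1) * 3 + wr). Source pixels whose offset partner stays inside
# the window.
glcm_window_pairs <- local({
  pairs_for <- function(off) {
    src <- integer(); dst <- integer()
    for (wc in 1:3) for (wr in 1:3) {
      r2 <- wr + off[1]; c2 <- wc + off[2]
      if (r2 >= 1 && r2 <= 3 && c2 >= 1 && c2 <= 3) {
        src <- c(src, (wc - 1L) * 3L + wr)
        dst <- c(dst, (c2 - 1L) * 3L + r2)
      }
    }
    list(src = src, dst = dst)
  }
  function() lapply(glcm_offsets, pairs_for)
})

# Vectorized GLCM features over n quantized windows (rows of QW, 0-based
# levels). Mirrors glcm_features().
slice_glcm <- function(QW, levels) {
  n <- nrow(QW)
  pairs <- glcm_window_pairs()
  contr <- matrix(0, n, 4L); ener <- matrix(0, n, 4L)
  homog <- matrix(0, n, 4L); corr <- matrix(NA_real_, n, 4L)
  for (k in seq_along(pairs)) {
    pp <- pairs[[k]]
    A <- QW[, pp$src, drop = FALSE] + 1L
    B <- QW[, pp$dst, drop = FALSE] + 1L
    m <- length(pp$src)
    contr[, k] <- rowMeans((A - B)^2)
    homog[, k] <- rowMeans(1 / (1 + abs(A - B)))
    mu_a <- rowMeans(A); mu_b <- rowMeans(B)
    va <- rowMeans(A^2) - mu_a^2
    vb <- rowMeans(B^2) - mu_b^2
    cv <- rowMeans(A * B) - mu_a * mu_b
    ok <- va > 0 & vb > 0
    corr[ok, k] <- cv[ok] / sqrt(va[ok] * vb[ok])
    code <- A * levels + B
    eq <- matrix(0, n, 1L)
    for (p in seq_len(m)) for (q in seq_len(m)) {
      eq <- eq + (code[, p] == code[, q])
    }
    ener[, k] <- eq / m^2
  }
  f2 <- rowMeans(corr, na.rm = TRUE)
  f2[!is.finite(f2)] <- NA_real_
  cbind(f1 = rowMeans(contr), f2 = f2, f3 = rowMeans(ener),
        f4 = rowMeans(homog))
}

#' Sample healthy reference voxels matched to the lesion count
#'
#' Draws a seeded uniform sample without replacement from marrow voxels that
#' are neither inside a lesion nor adjacent to one (lesions dilated by one
#' voxel, 26-connectivity), the pool used for the "healthy voxels" column of
#' BME-versus-healthy comparisons.
#'
#' @param masks [labelmask()] with marrow and lesion roles.
#' @param n number of voxels requested; capped at the candidate count (with
#'   a warning).
#' @param seed RNG seed.
#' @return logical array marking the sampled voxels.
#' @export
sample_healthy <- function(masks, n, seed = 1L) {
  marrow <- mask_role(masks, "marrow") | mask_role(masks, "lesion")
  lesion <- mask_role(masks, "lesion")
  cand <- marrow & !dilate26(lesion)
  idx <- which(cand)
  if (length(idx) == 0L) {
    stopf("bmetex_roi_error", "no healthy candidate voxels")
  }
  if (n > length(idx)) {
    rlang::warn(sprintf(
      "requested %d healthy voxels but only %d candidates; using all",
      n, length(idx)))
    n <- length(idx)
  }
  sel <- with_seed(seed, sample(idx, n))
  out <- array(FALSE, dim(masks$labels))
  out[sel] <- TRUE
  out
}

# Binary dilation by one voxel, 26-connectivity.
dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) for (ds in -1:1) {
    if (dr == 0 && dc == 0 && ds == 0) next
    rs <- pmin(pmax(seq_len(d[1]) + dr, 1L), d[1])
    cs <- pmin(pmax(seq_len(d[2]) + dc, 1L), d[2])
    ss <- pmin(pmax(seq_len(d[3]) + ds, 1L), d[3])
    out <- out | mask[rs, cs, ss]
  }
  out
}

#' Extract lesion rows plus an equal matched healthy sample
#'
#' Convenience wrapper producing the study-shaped voxel table for one scan:
#' every interior lesion voxel (status `BME`) plus a seeded healthy sample of
#' `healthy_per_lesion` times that count (status `healthy`).
#'
#' @inheritParams extract_feature_table
#' @param healthy_per_lesion healthy voxels drawn per lesion voxel.
#' @param seed RNG seed for the healthy sample.
#' @return tibble as in [extract_feature_table()].
#' @export
extract_matched_features <- function(v, masks, meta = NULL, levels = 8L,
                                     healthy_per_lesion = 1, seed = 1L) {
  lesion <- mask_role(masks, "lesion")
  if (!any(lesion)) {
    rlang::warn("no lesion voxels in scan; returning empty table")
    return(empty_feature_table())
  }
  d <- dim(lesion)
  co <- arrayInd(which(lesion), d)
  n_int <- sum(co[, 1] >= 2 & co[, 1] <= d[1] - 1 &
                 co[, 2] >= 2 & co[, 2] <= d[2] - 1)
  n_healthy <- max(1L, round(healthy_per_lesion * n_int))
  healthy <- sample_healthy(masks, n_healthy, seed = seed)
  centres <- lesion | healthy
  extract_feature_table(v, masks, meta = meta, levels = levels,
                        centres = centres)
}
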