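#' Read and write image volumes (NIfTI / NRRD)
#'
#' `read_volume()` loads a 3D scalar volume from NIfTI (`.nii`, `.nii.gz`)
#' or NRRD (`.nrrd`), taking voxel spacing from the header. `write_volume()`
#' stores a volume as NIfTI (or NRRD when the path ends in `.nrrd`); the
#' round trip is lossless for the stored dtype.
#'
#' @param path file path.
#' @param slice_axis sagittal stacking axis to record on the volume; header
#'   orientation is not interpreted beyond spacing, so override here if your
#'   data stack sagittal slices along a different axis.
#' @param id scan identifier; defaults to the file name without extension.
#' @return a [volume()].
#' @export
read_volume <- function(path, slice_axis = 3L, id = NULL) {
  if (!file.exists(path)) {
    stopf("bmetex_format_error", "no such file: %s", path)
  }
  id <- id %||% sub("\\.(nii(\\.gz)?|nrrd)$", "", basename(path))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    nr <- read_nrrd(path)
    return(volume(nr$data, spacing = nr$spacing, slice_axis = slice_axis,
                  id = id))
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stopf("bmetex_format_error",
                          "cannot read NIfTI file %s: %s",
                          path, conditionMessage(e))
                  })
  arr <- array(as.vector(as.array(img)), dim(img))
  if (length(dim(arr)) != 3L) {
    stopf("bmetex_format_error",
          "expected a 3D volume in %s, got %d dims", path, length(dim(arr)))
  }
  sp <- RNifti::pixdim(img)[1:3]
  volume(arr, spacing = sp, slice_axis = slice_axis, id = id)
}

#' @rdname read_volume
#' @param v a [volume()].
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path))) {
    stopf("bmetex_io_error", "parent directory does not exist: %s",
          dirname(path))
  }
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(v$data, v$spacing, path)
    return(invisible(path))
  }
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write label maps
#'
#' Label maps are integer grids on the same voxel grid as their volume, with
#' an external legend mapping each label to a role (3D Slicer exports vary in
#' numbering, so the legend is never hard-coded). NRRD is the native format
#' (what 3D Slicer emits for segmentations); NIfTI is also accepted.
#'
#' @param path file path (`.nrrd`, `.nii`, `.nii.gz`).
#' @param legend named vector mapping label number to role, e.g.
#'   `c("1" = "marrow", "2" = "lesion", "3" = "csf_reference")`.
#' @param grid_of id of the volume the mask belongs to.
#' @inheritParams read_volume
#' @return a [labelmask()].
#' @export
read_labelmap <- function(path, legend, slice_axis = 3L, grid_of = "scan") {
  v <- read_volume(path, slice_axis = slice_axis)
  if (any(abs(v$data - round(v$data)) > 1e-9)) {
    stopf("bmetex_format_error", "label map %s has non-integer values", path)
  }
  labelmask(round(v$data), legend = legend, spacing = v$spacing,
            slice_axis = slice_axis, grid_of = grid_of)
}

#' @rdname read_labelmap
#' @param m a [labelmask()].
#' @export
write_labelmap <- function(m, path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(m$labels, m$spacing, path, type = "int")
  } else {
    img <- RNifti::asNifti(m$labels)
    RNifti::pixdim(img) <- m$spacing
    RNifti::writeNifti(img, path, datatype = "int32")
  }
  invisible(path)
}

#' Read a per-scan study metadata table
#'
#' CSV with header row and columns `patient_id, group, timepoint` plus
#' optional clinical scores `pga, hscrp, basdai, das44`. Groups must be
#' `HIIT`/`control` and timepoints `baseline`/`week11`; `(patient_id,
#' timepoint)` must be unique and group constant within patient.
#'
#' @param path CSV file path.
#' @return a tibble, one row per scan.
#' @export
read_study_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_study_table(df)
}

validate_study_table <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("patient_id", "group", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("bmetex_format_error", "study table lacks columns: %s",
          paste(miss, collapse = ", "))
  }
  if (!all(df$group %in% c("HIIT", "control"))) {
    stopf("bmetex_format_error", "group must be 'HIIT' or 'control'")
  }
  if (!all(df$timepoint %in% c("baseline", "week11"))) {
    stopf("bmetex_format_error", "timepoint must be 'baseline' or 'week11'")
  }
  if (anyDuplicated(df[c("patient_id", "timepoint")])) {
    stopf("bmetex_format_error", "(patient_id, timepoint) must be unique")
  }
  ngrp <- tapply(df$group, df$patient_id, function(g) length(unique(g)))
  if (any(ngrp > 1)) {
    stopf("bmetex_format_error", "group must be constant within patient")
  }
  df
}

# ---- minimal NRRD raw-encoding IO -----------------------------------------
# Covers the subset needed for label maps and phantom volumes: 3D, raw or
# gzip encoding, little endian, types double/float/int/short/uchar.

nrrd_types <- list(
  double = list(what = "double", size = 8L),
  float = list(what = "double", size = 4L),
  int = list(what = "integer", size = 4L),
  short = list(what = "integer", size = 2L),
  uchar = list(what = "integer", size = 1L)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) {
    stopf("bmetex_format_error", "%s is not a NRRD file", path)
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      stopf("bmetex_format_error", "truncated NRRD header in %s", path)
    }
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":\\s*", perl = TRUE)[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  type <- fields[["type"]]
  if (is.null(type) || !type %in% names(nrrd_types)) {
    stopf("bmetex_format_error", "unsupported NRRD type '%s' in %s",
          type %||% "?", path)
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) {
    stopf("bmetex_format_error", "only 3D NRRD supported, %s has %d dims",
          path, length(sizes))
  }
  spacing <- if (!is.null(fields[["spacings"]])) {
    as.double(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else {
    c(1, 1, 1)
  }
  enc <- fields[["encoding"]] %||% "raw"
  tp <- nrrd_types[[type]]
  n <- prod(sizes)
  raw_data <- if (enc == "raw") {
    readBin(con, "raw", n = n * tp$size)
  } else if (enc %in% c("gzip", "gz")) {
    memDecompress(readBin(con, "raw", n = file.size(path)), type = "gzip")
  } else {
    stopf("bmetex_format_error", "unsupported NRRD encoding '%s'", enc)
  }
  if (length(raw_data) < n * tp$size) {
    stopf("bmetex_format_error", "truncated NRRD data in %s", path)
  }
  vals <- readBin(raw_data, tp$what, n = n, size = tp$size,
                  endian = "little", signed = tp$size > 1L)
  list(data = array(vals, dim = sizes), spacing = spacing, type = type)
}

write_nrrd <- function(data, spacing, path, type = "double") {
  tp <- nrrd_types[[type]]
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# generated by bmetex",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(data), collapse = " ")),
    sprintf("spacings: %s", paste(format(spacing, digits = 15), collapse = " ")),
    "endian: little",
    "encoding: raw",
    ""
  )
  writeLines(hdr, con)
  writeBin(as.vector(data), con, size = tp$size, endian = "little")
  invisible(path)
}
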