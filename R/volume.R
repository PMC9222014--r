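#' Image volume and label-mask containers
#'
#' A `bme_volume` wraps a 3D numeric array together with its voxel spacing in
#' millimetres and the index of the sagittal stacking axis. A `bme_labelmask`
#' wraps an integer label grid aligned to a volume, plus a legend mapping each
#' label to a semantic role (`marrow`, `lesion`, `csf_reference`,
#' `background`).
#'
#' Conventions used throughout the package: voxel indices are addressed as
#' `(row, column, slice)` with slices stacked along `slice_axis` (default 3);
#' within a sagittal slice, rows run superior to inferior and columns anterior
#' to posterior. Intensities are stored as double regardless of on-disk dtype
#' and their scale is arbitrary — derived feature values are scale-dependent.
#'
#' @param data 3D numeric array of voxel intensities (all finite).
#' @param spacing numeric length-3, voxel size in mm along each axis (all > 0).
#' @param slice_axis integer in 1..3, the sagittal stacking axis.
#' @param id scan identifier string.
#' @return `volume()` returns a `bme_volume`; `labelmask()` a `bme_labelmask`.
#' @examples
#' v <- volume(array(0, c(4, 4, 3)), spacing = c(1, 1, 3), id = "demo")
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1), slice_axis = 3L, id = "scan") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stopf("bmetex_format_error", "volume data must be 3D, got %d dims",
          length(dim(data)))
  }
  if (any(dim(data) < 3L)) {
    stopf("bmetex_format_error",
          "volume dimensions must be >= 3 along every axis, got (%s)",
          paste(dim(data), collapse = ", "))
  }
  if (!all(is.finite(data))) {
    stopf("bmetex_format_error", "volume intensities must all be finite")
  }
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("bmetex_format_error", "spacing must be 3 positive values (mm)")
  }
  structure(
    list(data = data + 0.0, spacing = spacing,
         slice_axis = as.integer(slice_axis), id = as.character(id)),
    class = "bme_volume"
  )
}

#' @rdname volume
#' @param labels 3D integer-valued array of labels.
#' @param legend named character vector or list mapping label number (name)
#'   to role; roles are `background`, `marrow`, `lesion`, `csf_reference`.
#' @param grid_of id of the volume this mask is aligned to.
#' @export
labelmask <- function(labels, legend, spacing = c(1, 1, 1), slice_axis = 3L,
                      grid_of = "scan") {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) {
    stopf("bmetex_format_error", "label data must be 3D")
  }
  if (any(abs(labels - round(labels)) > 0)) {
    stopf("bmetex_format_error", "label map must be integer-valued")
  }
  storage.mode(labels) <- "integer"
  legend <- unlist(legend)
  legend <- setNames(as.character(legend), names(legend))
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(as.character(present), names(legend))
  if (length(unknown)) {
    stopf("bmetex_legend_error",
          "labels not in legend: %s", paste(unknown, collapse = ", "))
  }
  roles <- c("background", "marrow", "lesion", "csf_reference")
  bad <- setdiff(legend, roles)
  if (length(bad)) {
    stopf("bmetex_legend_error",
          "unknown legend roles: %s", paste(bad, collapse = ", "))
  }
  structure(
    list(labels = labels, legend = legend, spacing = as.double(spacing),
         slice_axis = as.integer(slice_axis), grid_of = as.character(grid_of)),
    class = "bme_labelmask"
  )
}

#' @export
print.bme_volume <- function(x, ...) {
  cat(sprintf("<bme_volume '%s'> %s voxels, spacing %s mm, slice axis %d\n",
              x$id, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$slice_axis))
  invisible(x)
}

#' @export
print.bme_labelmask <- function(x, ...) {
  cat(sprintf("<bme_labelmask of '%s'> %s voxels; legend: %s\n",
              x$grid_of, paste(dim(x$labels), collapse = "x"),
              paste(names(x$legend), x$legend, sep = "=", collapse = ", ")))
  invisible(x)
}

# Binary array for all labels carrying a given role.
mask_role <- function(m, role) {
  labs <- as.integer(names(m$legend)[m$legend == role])
  array(m$labels %in% labs, dim = dim(m$labels))
}

#' Check that a volume and a label mask share the same grid
#'
#' Passes when dimensions match exactly and per-axis spacing agrees within
#' 1e-6 mm; aborts with a grid error stating both geometries otherwise.
#' The check is symmetric in the two grids.
#'
#' @param v a `bme_volume` (or `bme_labelmask`).
#' @param m a `bme_labelmask` (or `bme_volume`).
#' @return invisibly `TRUE` on success.
#' @export
validate_same_grid <- function(v, m) {
  grid_of <- function(x) {
    if (inherits(x, "bme_volume")) list(dim = dim(x$data), sp = x$spacing)
    else list(dim = dim(x$labels), sp = x$spacing)
  }
  a <- grid_of(v); b <- grid_of(m)
  if (!identical(a$dim, b$dim) || any(abs(a$sp - b$sp) > 1e-6)) {
    stopf("bmetex_grid_error",
          "grids differ: (%s) @ (%s) mm vs (%s) @ (%s) mm",
          paste(a$dim, collapse = ","), paste(format(a$sp), collapse = ","),
          paste(b$dim, collapse = ","), paste(format(b$sp), collapse = ","))
  }
  invisible(TRUE)
}
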