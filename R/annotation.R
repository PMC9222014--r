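#' Spine annotation: disco-vertebral units and CSF reference geometry
#'
#' A `bme_annotation` describes the scoring geometry of a sagittal spine
#' volume: an ordered list of disco-vertebral units (cranial first), each with
#' four quadrant boxes (superior-anterior, superior-posterior,
#' inferior-anterior, inferior-posterior) around the disc, the two
#' disc-adjacent endplate rows, and the row extents of the two adjacent
#' vertebral bodies; plus one CSF reference box used for the SPARCC intensity
#' bonus. Boxes are axis-aligned `(rows, cols)` index ranges applied to every
#' sagittal slice.
#'
#' @param units list of unit descriptions; each a list with elements `id`
#'   (e.g. `"TH9-TH10"`), `quadrants` (list of 4 boxes, each
#'   `list(rows = c(r0, r1), cols = c(c0, c1))` in the order SA, SP, IA, IP),
#'   `endplate_rows` (length-2: inferior endplate row of the superior
#'   vertebra, superior endplate row of the inferior vertebra),
#'   `vert_sup_rows`, `vert_inf_rows` (row ranges of the two vertebral
#'   bodies) and `cols` (column range of the vertebral column at this unit).
#' @param csf_box CSF reference region, `list(rows =, cols =)`.
#' @param dim grid dimensions the geometry refers to.
#' @return a `bme_annotation`.
#' @export
spine_annotation <- function(units, csf_box, dim) {
  if (length(units) < 1L) {
    stopf("bmetex_format_error", "annotation needs at least one unit")
  }
  for (u in units) {
    for (q in u$quadrants) {
      if (q$rows[1] < 1 || q$rows[2] > dim[1] ||
          q$cols[1] < 1 || q$cols[2] > dim[2]) {
        stopf("bmetex_format_error",
              "quadrant box of unit %s outside image bounds", u$id)
      }
    }
  }
  structure(list(units = units, csf_box = csf_box, dim = as.integer(dim)),
            class = "bme_annotation")
}

#' @export
print.bme_annotation <- function(x, ...) {
  cat(sprintf("<bme_annotation> %d disco-vertebral units (%s ... %s)\n",
              length(x$units), x$units[[1]]$id,
              x$units[[length(x$units)]]$id))
  invisible(x)
}

#' @rdname spine_annotation
#' @param ann a `bme_annotation`.
#' @param path JSON file path.
#' @export
write_annotation <- function(ann, path) {
  jsonlite::write_json(
    list(units = ann$units, csf_box = ann$csf_box, dim = ann$dim),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname spine_annotation
#' @export
read_annotation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  units <- lapply(x$units, function(u) {
    u$quadrants <- lapply(u$quadrants, function(q) {
      list(rows = as.integer(q$rows), cols = as.integer(q$cols))
    })
    u$endplate_rows <- as.integer(u$endplate_rows)
    u$vert_sup_rows <- as.integer(u$vert_sup_rows)
    u$vert_inf_rows <- as.integer(u$vert_inf_rows)
    u$cols <- as.integer(u$cols)
    u
  })
  csf <- list(rows = as.integer(x$csf_box$rows),
              cols = as.integer(x$csf_box$cols))
  spine_annotation(units, csf, as.integer(x$dim))
}
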