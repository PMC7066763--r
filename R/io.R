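# Plain-text/binary exchange formats: the JSON contour schema and raw
# grayscale stacks with a JSON sidecar header.

#' Write a contour stack to the JSON exchange schema
#'
#' Schema: `{slices: [{index, phase, label, points: [[x_mm, y_mm], ...]}],
#' geometry: {pixel_spacing, slice_thickness, slice_gap}, papillary_mode}`.
#'
#' @param stack a [contour_stack()].
#' @param path output file.
#' @export
write_contours_json <- function(stack, path) {
  slices <- lapply(stack$contours, function(e)
    list(index = e$slice, phase = e$phase, label = e$label,
         points = unname(apply(e$contour$points, 1, function(r)
           c(r[1], r[2]), simplify = FALSE))))
  obj <- list(slices = slices,
              geometry = stack$geometry,
              papillary_mode = stack$papillary_mode)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a contour stack from the JSON exchange schema
#' @param path JSON file written by [write_contours_json()] or a
#'   schema-compatible tool.
#' @return a [contour_stack()].
#' @export
read_contours_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  contours <- lapply(obj$slices, function(s) {
    pts <- do.call(rbind, lapply(s$points, unlist))
    list(slice = as.integer(s$index), phase = as.integer(s$phase %||% 1),
         label = s$label,
         contour = contour(pts, label = s$label, check_simple = FALSE))
  })
  contour_stack(contours,
                geometry = list(
                  pixel_spacing = unlist(obj$geometry$pixel_spacing),
                  slice_thickness = obj$geometry$slice_thickness,
                  slice_gap = obj$geometry$slice_gap),
                papillary_mode = obj$papillary_mode %||% "in_blood_pool")
}

#' Write an image stack as raw doubles plus a JSON sidecar header
#'
#' @param stack an [image_stack()].
#' @param path output path for the raw data; the header goes to
#'   `<path>.json`.
#' @export
write_image_stack <- function(stack, path) {
  hdr <- list(dim = dim(stack$voxels), dtype = "float64",
              order = "column_major",
              pixel_spacing = stack$pixel_spacing,
              slice_thickness = stack$slice_thickness,
              slice_gap = stack$slice_gap,
              frame_times = stack$frame_times, meta = stack$meta)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(stack$voxels), con, size = 8)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#' @param path raw-data path (header expected at `<path>.json`).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path) {
  hdr <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8)
  image_stack(array(v, dim = hdr$dim),
              pixel_spacing = hdr$pixel_spacing,
              slice_thickness = hdr$slice_thickness,
              slice_gap = hdr$slice_gap,
              frame_times = hdr$frame_times,
              meta = as.list(hdr$meta))
}
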