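#' Grayscale image objects
#'
#' A `gray_image` is a numeric matrix of non-negative finite intensities in
#' arbitrary units with a `pixel_spacing` attribute (mm per pixel). It is the
#' universal currency of the pipeline: phantoms, corrupted images and
#' denoiser outputs are all `gray_image` objects (plain numeric matrices are
#' accepted everywhere and treated as images with the default spacing).
#'
#' @param pixels Numeric matrix of intensities.
#' @param pixel_spacing Pixel size in mm (default 0.4, the voxel size of the
#'   high-resolution vessel-wall protocol the phantoms emulate).
#' @param check If `TRUE`, validate finiteness and minimum size.
#' @return A `gray_image` object (matrix subclass).
#' @export
gray_image <- function(pixels, pixel_spacing = 0.4, check = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    mrd_error("`pixels` must be a numeric matrix", "mrd_type_error")
  if (check) {
    if (nrow(pixels) < 64L || ncol(pixels) < 64L)
      mrd_error("images must be at least 64x64", "mrd_type_error")
    if (!all(is.finite(pixels)))
      mrd_error("image intensities must be finite", "mrd_type_error")
  }
  structure(pixels, pixel_spacing = pixel_spacing,
            class = c("gray_image", class(matrix())))
}

as_pixel_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "pixel_spacing") <- NULL
  y
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, spacing %.3g mm, range [%.4g, %.4g]>\n",
              nrow(x), ncol(x), attr(x, "pixel_spacing") %||% 0.4,
              min(x), max(x)))
  invisible(x)
}

# Rebuild a gray_image around new pixel values, keeping metadata.
reimage <- function(template, pixels) {
  gray_image(pixels, pixel_spacing = attr(template, "pixel_spacing") %||% 0.4,
             check = FALSE)
}

#' Region-of-interest sets
#'
#' An `roi_set` is a named list of logical masks congruent with one image.
#' The canonical region names are `vessel_wall`, `lumen`, `csf`, `parenchyma`
#' and `air` — the five regions every quantitative metric in the pipeline is
#' computed on.
#'
#' @param ... Named logical masks (or a single named list).
#' @param dim Expected image dimension (optional, for validation).
#' @return An `roi_set`.
#' @export
roi_set <- function(..., dim = NULL) {
  regions <- list(...)
  if (length(regions) == 1L && is.list(regions[[1]]) && is.null(dim(regions[[1]])))
    regions <- regions[[1]]
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    mrd_error("all regions must be named", "mrd_roi_error")
  for (nm in names(regions)) {
    m <- regions[[nm]]
    if (!is.matrix(m) || !is.logical(m))
      mrd_error(sprintf("region '%s' is not a logical matrix", nm), "mrd_roi_error")
    if (!any(m))
      mrd_error(sprintf("region '%s' is empty", nm), "mrd_roi_error")
    if (!is.null(dim) && !identical(base::dim(m), as.integer(dim)))
      mrd_error(sprintf("region '%s' does not match image dimensions", nm),
                "mrd_roi_error")
  }
  structure(regions, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %6d px\n", nm, sum(x[[nm]])))
  invisible(x)
}

#' Axis-aligned box mask
#'
#' Builds a logical mask for a half-open, 0-based axis-aligned box, the
#' second ROI representation the pipeline accepts.
#'
#' @param dim Image dimension `c(rows, cols)`.
#' @param row0,col0 0-based top-left corner.
#' @param n_rows,n_cols Box extent in pixels.
#' @return Logical matrix.
#' @export
roi_box <- function(dim, row0, col0, n_rows, n_cols) {
  if (row0 < 0 || col0 < 0 || row0 + n_rows > dim[1] || col0 + n_cols > dim[2])
    mrd_error("box exceeds image bounds", "mrd_roi_error")
  m <- matrix(FALSE, dim[1], dim[2])
  m[(row0 + 1L):(row0 + n_rows), (col0 + 1L):(col0 + n_cols)] <- TRUE
  m
}

roi_pixels <- function(image, roi) {
  as_pixel_matrix(image)[roi]
}
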