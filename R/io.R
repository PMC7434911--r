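#' Read and write pipeline images
#'
#' Images are exchanged as NIfTI (`.nii` / `.nii.gz`, via RNifti, preserving
#' pixel spacing) or 16-bit grayscale PNG (intensities scaled to the stated
#' range). ROI masks use the same containers with 0/1 values.
#'
#' @param image A [gray_image()] or matrix.
#' @param path Output path; format chosen by extension.
#' @param max_intensity Intensity mapped to the top of the 16-bit PNG range
#'   (default: image maximum).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, max_intensity = NULL) {
  px <- as_pixel_matrix(image)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    sp <- attr(image, "pixel_spacing") %||% 0.4
    RNifti::writeNifti(RNifti::asNifti(px, pixdim = c(sp, sp)), path)
  } else if (ext == "png") {
    mx <- max_intensity %||% max(px)
    if (mx <= 0) mx <- 1
    png::writePNG(pmin(pmax(px / mx, 0), 1), path)
  } else {
    mrd_error(sprintf("unsupported image format '%s'", ext), "mrd_io_error")
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    n <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(n)[1]
    gray_image(as.matrix(n[, ]), pixel_spacing = if (is.finite(sp) && sp > 0) sp else 0.4,
               check = FALSE)
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    gray_image(m, check = FALSE)
  } else {
    mrd_error(sprintf("unsupported image format '%s'", ext), "mrd_io_error")
  }
}

#' Write a paired-dataset manifest
#'
#' CSV manifest with one row per pair: `path_clean`, `path_noisy`, `sigma`,
#' `seed`. Images are written as NIfTI alongside.
#'
#' @param pd A `paired_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(pd, dir) {
  stopifnot(inherits(pd, "paired_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(pd$pairs), function(k) {
    pc <- file.path(dir, sprintf("clean_%03d.nii.gz", k))
    pn <- file.path(dir, sprintf("noisy_%03d.nii.gz", k))
    write_image(pd$pairs[[k]]$clean, pc)
    write_image(pd$pairs[[k]]$noisy, pn)
    data.frame(path_clean = pc, path_noisy = pn,
               sigma = pd$pairs[[k]]$sigma, seed = pd$pairs[[k]]$seed)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
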