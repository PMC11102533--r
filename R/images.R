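#' Read a plot image as a grayscale matrix
#'
#' Reads PNG, JPEG or TIFF and converts to a grayscale matrix in `[0, 1]`
#' (rows = image rows, 0 = black). Colour images are converted by Rec. 601
#' luminance, so colour printout schemes binarise the same way as grayscale
#' ones.
#'
#' @param path image file; format inferred from the extension.
#' @return a numeric matrix in `[0, 1]`.
#' @export
read_plot_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the jpeg package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the tiff package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  as_gray(img)
}

#' @rdname read_plot_image
#' @param img a matrix (grayscale) or 3-d array (RGB or RGBA) in `[0, 1]`.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    }
    return(img[, , 1])
  }
  stop("expected a grayscale matrix or RGB array", call. = FALSE)
}

#' Binarise a grayscale image
#'
#' Global Otsu threshold (printouts are near-bilevel, so a single global
#' threshold suffices and needs no per-image tuning). Returns a logical
#' matrix that is TRUE where there is ink (dark pixels).
#'
#' @param gray grayscale matrix in `[0, 1]`.
#' @return logical ink mask, same dimensions.
#' @export
binarize_image <- function(gray) {
  stopifnot(is.matrix(gray))
  rng <- range(gray)
  if (!all(is.finite(rng))) stop("image contains non-finite pixels", call. = FALSE)
  if (diff(rng) < 1e-6) {
    # constant image: no contrast, hence no ink
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  thr <- EBImage::otsu(EBImage::Image(t(gray)), range = c(0, 1))
  gray < thr
}

#' Pad an image with a uniform border
#'
#' @param img grayscale matrix.
#' @param px border width in pixels (may be a vector of 4: top, bottom,
#'   left, right).
#' @param value pixel value of the border (1 = white).
#' @return the padded matrix.
#' @export
pad_image <- function(img, px, value = 1) {
  px <- rep_len(as.integer(px), 4L)
  out <- matrix(value, nrow(img) + px[1] + px[2], ncol(img) + px[3] + px[4])
  out[px[1] + seq_len(nrow(img)), px[3] + seq_len(ncol(img))] <- img
  out
}

#' Rescale an image by a uniform factor
#'
#' Bilinear resize (used by the robustness checks to emulate screenshots and
#' re-saved printouts at different resolutions).
#'
#' @param img grayscale matrix.
#' @param factor scale factor, e.g. 0.75 or 1.5.
#' @return the rescaled matrix, clipped to `[0, 1]`.
#' @export
rescale_image <- function(img, factor) {
  stopifnot(is.matrix(img), factor > 0)
  im <- EBImage::Image(t(img))
  out <- EBImage::resize(im, w = max(2L, round(nrow(im) * factor)))
  pmin(pmax(t(EBImage::imageData(out)), 0), 1)
}

#' Write a grayscale matrix as PNG
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_plot_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
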