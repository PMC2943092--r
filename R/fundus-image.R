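#' Construct a FundusImage from a numeric matrix
#'
#' @param pixels numeric matrix; values are rescaled to [0,1] when
#'   \code{rescale = TRUE}, otherwise they must already lie in [0,1]
#' @param channel channel tag carried as metadata
#' @param rescale rescale intensities linearly to [0,1]
#' @return a \linkS4class{FundusImage}
#' @export
FundusImage <- function(pixels, channel = "gray", rescale = FALSE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (rescale) {
    rg <- range(pixels)
    pixels <- if (diff(rg) > 0) (pixels - rg[1]) / diff(rg) else pixels * 0
  }
  new("FundusImage", pixels = pixels, channel = channel)
}

#' Read a fundus image from PNG/TIFF/JPEG
#'
#' Color images are reduced to a single channel before processing; the green
#' channel is the default for RGB fundus photographs because it carries the
#' highest vessel-to-background contrast.
#'
#' @param path image file
#' @param channel "green", "red", "blue", "gray" (luminance) or an integer
#'   channel index
#' @return a \linkS4class{FundusImage}
#' @export
readFundusImage <- function(path, channel = "green") {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) {
    m <- a
    channel <- "gray"
  } else {
    idx <- switch(as.character(channel),
                  red = 1L, green = 2L, blue = 3L, gray = 0L,
                  as.integer(channel))
    m <- if (identical(idx, 0L)) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else a[, , min(idx, dim(a)[3])]
  }
  # EBImage stores images x-then-y; transpose to [row, col]
  FundusImage(t(m), channel = as.character(channel))
}

#' Write a FundusImage (or matrix) as an image file
#' @param x FundusImage or numeric matrix in [0,1]
#' @param path output file; format follows the extension (png/tiff/jpeg)
#' @return invisibly, the path
#' @export
writeFundusImage <- function(x, path) {
  m <- if (is(x, "FundusImage")) x@pixels else x
  EBImage::writeImage(EBImage::Image(t(m)), path)
  invisible(path)
}

#' Histogram-match an image to a reference intensity profile
#'
#' Maps intensities through the empirical quantile function of the reference.
#' With \code{reference = NULL} the target profile is uniform, i.e. plain
#' histogram equalization.
#'
#' @param image a FundusImage
#' @param reference optional FundusImage (or matrix) providing the target
#'   histogram
#' @return a FundusImage with matched histogram
#' @export
histogramMatch <- function(image, reference = NULL) {
  m <- pixels(image)
  v <- as.vector(m)
  r <- rank(v, ties.method = "average") / length(v)
  out <- if (is.null(reference)) {
    r                                   # uniform target: equalization
  } else {
    ref <- if (is(reference, "FundusImage")) pixels(reference) else reference
    as.vector(stats::quantile(ref, probs = r, names = FALSE, type = 7))
  }
  FundusImage(matrix(clamp01(out), nrow(m), ncol(m)), channel = image@channel)
}

#' Preprocess a fundus image for matched filtering
#'
#' Optional histogram matching followed by median filtering suppresses
#' intensity inconsistencies and impulse noise before vessel enhancement.
#' When a \code{reference} image is supplied the histogram is mapped onto
#' the reference profile (the natural choice for an image pair); with
#' \code{equalize = TRUE} it is mapped to a uniform profile instead.  By
#' default only the median filter is applied: remapping a single image's
#' histogram to a fixed profile amplifies background noise without adding
#' vessel contrast.  Constant images pass through unchanged.
#'
#' @param image a FundusImage
#' @param reference optional histogram reference image
#' @param equalize map the histogram to a uniform profile (ignored when a
#'   reference is given)
#' @param medianRadius radius of the median filter window
#'   (1 gives the default 3 x 3 window)
#' @return a preprocessed FundusImage of identical shape
#' @export
preprocess <- function(image, reference = NULL, equalize = FALSE,
                       medianRadius = 1L) {
  m <- pixels(image)
  if (diff(range(m)) == 0) return(image)   # flat field: nothing to do
  hm <- if (!is.null(reference)) histogramMatch(image, reference)
        else if (equalize) histogramMatch(image, NULL)
        else image
  mf <- if (medianRadius == 1L) median3x3(pixels(hm))
        else EBImage::medianFilter(pixels(hm), medianRadius)
  FundusImage(clamp01(as.matrix(mf)), channel = image@channel)
}
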