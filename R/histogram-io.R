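## Raster input, grayscale conversion, histograms and binary masks.

#' Construct a GrayImage from a matrix
#'
#' @param pixels numeric or integer matrix of gray values in \code{[0, 255]}.
#' @return a [GrayImage-class].
#' @examples
#' grayImage(matrix(c(0, 255, 10, 20), 2, 2))
#' @export
grayImage <- function(pixels) {
    stopifnot(is.matrix(pixels))
    mode(pixels) <- "integer"
    new("GrayImage", pixels = pixels)
}

#' Construct a BinaryMask from a matrix
#'
#' @param labels matrix over \{0, 1\} (logical accepted).
#' @return a [BinaryMask-class].
#' @export
binaryMask <- function(labels) {
    stopifnot(is.matrix(labels))
    mode(labels) <- "integer"
    new("BinaryMask", labels = labels)
}

#' Read an image file as an 8-bit grayscale image
#'
#' Reads a PNG, TIFF or JPEG raster and reduces it to a single 8-bit
#' channel. Multi-channel images are collapsed by the chosen rule:
#' Rec.601 luminance (\code{0.299 R + 0.587 G + 0.114 B}, the default),
#' the unweighted channel mean, or a single channel picked by index.
#' Intensities are mapped to \code{[0, 255]} by rounding the decoded
#' \code{[0, 1]} values times 255, so rasters of any bit depth are
#' rescaled onto the 8-bit gray scale.
#'
#' @param path path to the image file.
#' @param conversion multi-channel reduction rule: \code{"luminance"},
#'   \code{"mean"} or \code{"channel"}.
#' @param channel channel index used when \code{conversion = "channel"}.
#' @return a [GrayImage-class].
#' @export
readGrayImage <- function(path,
                          conversion = c("luminance", "mean", "channel"),
                          channel = 1L) {
    conversion <- match.arg(conversion)
    if (!file.exists(path))
        stop("cannot read image file: ", path)
    img <- EBImage::readImage(path)
    a <- .ebimageToArray(img)
    if (length(dim(a)) == 3L) {
        nc <- dim(a)[3L]
        plane <- function(k) {          # channel k as a matrix
            m <- a[, , k, drop = FALSE]
            dim(m) <- dim(a)[1:2]
            m
        }
        a <- switch(conversion,
            luminance = {
                if (nc < 3L) apply(a, c(1L, 2L), mean)
                else 0.299 * plane(1L) + 0.587 * plane(2L) +
                     0.114 * plane(3L)
            },
            mean = apply(a, c(1L, 2L), mean),
            channel = {
                if (channel < 1L || channel > nc)
                    stop("channel index ", channel,
                         " out of range for a ", nc, "-channel image")
                plane(channel)
            })
    }
    grayImage(round(a * 255))
}

## EBImage stores x (width) as the first dimension; transpose to the
## row-major height x width convention used throughout this package.
.ebimageToArray <- function(img) {
    a <- EBImage::imageData(img)
    d <- dim(a)
    if (length(d) == 2L) t(a)
    else if (length(d) == 3L) aperm(a, c(2L, 1L, 3L))
    else stop("unsupported image dimensionality: ", length(d))
}

#' Compute the 256-bin histogram of a grayscale image
#'
#' @param img a [GrayImage-class].
#' @return a [GrayHistogram-class]; bin \code{i} counts pixels of gray
#'   value \code{i - 1}.
#' @examples
#' computeHistogram(grayImage(matrix(c(5, 5, 7, 5), 1, 4)))
#' @export
computeHistogram <- function(img) {
    stopifnot(is(img, "GrayImage"))
    counts <- tabulate(as.vector(img@pixels) + 1L, nbins = 256L)
    new("GrayHistogram", counts = as.numeric(counts),
        nPixels = length(img@pixels))
}

#' Construct a GrayHistogram from bin counts
#'
#' Mainly useful for working directly in the histogram domain, e.g. with
#' analytically constructed two-delta histograms.
#'
#' @param counts numeric vector of up to 256 non-negative counts; bin
#'   \code{i} corresponds to gray value \code{i - 1}. Shorter vectors are
#'   zero-padded on the right.
#' @return a [GrayHistogram-class].
#' @export
grayHistogram <- function(counts) {
    stopifnot(is.numeric(counts), length(counts) <= 256L)
    full <- numeric(256L)
    full[seq_along(counts)] <- counts
    new("GrayHistogram", counts = full, nPixels = sum(full))
}

#' Threshold a grayscale image into a binary mask
#'
#' Pixels strictly above the threshold become foreground (label 1);
#' \code{invert = TRUE} flips the polarity, for targets darker than their
#' surroundings (e.g. lesions darker than skin).
#'
#' @param img a [GrayImage-class].
#' @param t threshold on the 0--255 gray scale.
#' @param invert flip foreground/background.
#' @return a [BinaryMask-class].
#' @examples
#' applyThreshold(grayImage(matrix(c(5, 5, 7, 5), 1, 4)), 6)
#' @export
applyThreshold <- function(img, t, invert = FALSE) {
    stopifnot(is(img, "GrayImage"))
    if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 255)
        stop("threshold must be a single gray level in [0, 255]")
    fg <- img@pixels > t
    if (invert) fg <- !fg
    binaryMask(matrix(as.integer(fg), nrow(img@pixels), ncol(img@pixels)))
}

#' Read a binary mask file
#'
#' Any nonzero pixel is treated as foreground (a tolerance for the common
#' \{0, 255\} and \{0, 1\} mask dialects). Multi-channel mask files are
#' reduced by their channel mean before binarization.
#'
#' @param path path to the mask raster.
#' @return a [BinaryMask-class].
#' @export
readMask <- function(path) {
    if (!file.exists(path))
        stop("cannot read mask file: ", path)
    a <- .ebimageToArray(EBImage::readImage(path))
    if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
    binaryMask(matrix(as.integer(a > 0), nrow(a), ncol(a)))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground is written as 255, background as 0.
#'
#' @param mask a [BinaryMask-class].
#' @param path output path (PNG, TIFF or JPEG by extension).
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "BinaryMask"))
    EBImage::writeImage(EBImage::Image(t(mask@labels)), path)
    invisible(path)
}

#' Write a grayscale image
#'
#' @param img a [GrayImage-class].
#' @param path output path (PNG, TIFF or JPEG by extension).
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(img, path) {
    stopifnot(is(img, "GrayImage"))
    EBImage::writeImage(EBImage::Image(t(img@pixels) / 255), path)
    invisible(path)
}
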