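#' Read an OCT B-scan image as a grayscale matrix
#'
#' Reads PNG (via \pkg{png}) or TIFF/JPEG (via \pkg{EBImage}, if installed)
#' and returns intensities in `[0, 1]`, rows = image height. RGB input is
#' converted to grayscale by channel averaging.
#'
#' @param path image file path.
#' @return numeric H x W matrix in `[0, 1]`.
#' @export
read_oct_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading ", ext, " images requires the EBImage package: ", path,
           call. = FALSE)
    a <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores x (width) first; transpose back to rows = height
    if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  } else {
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  }
  if (length(dim(img)) == 3) {
    img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# channel statistics of the backbones' pretraining corpus, used to place
# inputs on the scale the architectures expect
.imagenet_mean <- c(0.485, 0.456, 0.406)
.imagenet_sd <- c(0.229, 0.224, 0.225)

#' Preprocess a grayscale image for a backbone
#'
#' Bilinear-resizes to `size x size`, replicates the single channel to
#' three, and standardizes each channel with the ImageNet mean/sd used by
#' all three backbones. This is the full preprocessing chain: the source
#' images receive no denoising or registration.
#'
#' @param img H x W matrix in `[0, 1]` (see [read_oct_image()]).
#' @param size target spatial size (default 224).
#' @return `size x size x 3` array.
#' @export
preprocess_image <- function(img, size = 224L) {
  stopifnot(is.matrix(img))
  r <- bilinear_resize(img, as.integer(size), as.integer(size))
  out <- array(0, dim = c(size, size, 3L))
  for (c in 1:3) out[, , c] <- (r - .imagenet_mean[c]) / .imagenet_sd[c]
  out
}
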