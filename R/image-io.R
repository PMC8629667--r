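#' Read a grayscale image
#'
#' Loads an 8- or 16-bit PNG or TIFF slice as a numeric matrix with
#' intensities linearly rescaled to \[0, 1\] over the format's full dynamic
#' range. Optionally extracts an axial slice from a NIfTI volume.
#'
#' @param path Path to the image file.
#' @param format One of `"auto"`, `"png"`, `"tiff"`, `"nifti"`. With
#'   `"auto"` the format is taken from the file extension.
#' @param slice Axial slice index (1-based) used only for NIfTI volumes.
#' @param convert_rgb If `TRUE`, multi-channel images are converted to
#'   luminance; otherwise they are rejected.
#' @return A numeric matrix (rows x cols) with values in \[0, 1\].
#' @export
read_gray <- function(path, format = "auto", slice = 1L, convert_rgb = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      png = "png", tif = "tiff", tiff = "tiff",
      nii = "nifti", gz = "nifti",
      stop("cannot infer image format from extension: ", ext, call. = FALSE))
  }
  x <- switch(format,
    png  = png::readPNG(path),
    tiff = tiff::readTIFF(path),
    nifti = {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("RNifti is required for NIfTI input", call. = FALSE)
      v <- RNifti::asNifti(RNifti::readNifti(path))
      a <- as.array(v)
      if (length(dim(a)) == 3) a <- a[, , slice]
      rng <- range(a)
      if (diff(rng) > 0) a <- (a - rng[1]) / diff(rng)
      a
    },
    stop("unsupported format: ", format, call. = FALSE))
  if (length(dim(x)) == 3) {
    if (!convert_rgb)
      stop("multi-channel image; pass convert_rgb = TRUE for luminance conversion",
           call. = FALSE)
    ch <- min(3L, dim(x)[3])
    w <- c(0.299, 0.587, 0.114)[seq_len(ch)]; w <- w / sum(w)
    x <- Reduce(`+`, lapply(seq_len(ch), function(i) w[i] * x[, , i]))
  }
  x <- unname(as.matrix(x))
  assert_image(x, "loaded image")
  if (any(x < 0 | x > 1)) x <- clip01(x)
  x
}

#' Write a binary mask as an 8-bit PNG
#'
#' Values are stored as \{0, 255\} and round-trip exactly through
#' [read_gray()].
#'
#' @param mask Binary (0/1) matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_binary(mask)
  png::writePNG(mask, target = path)
  invisible(path)
}

#' Write a grayscale image
#'
#' Writes an 8-bit PNG (`.png`) or a 16-bit TIFF (`.tif`/`.tiff`), chosen by
#' the file extension.
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gray <- function(image, path) {
  assert_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(clip01(image), path, bits.per.sample = 16L)
  } else {
    png::writePNG(clip01(image), target = path)
  }
  invisible(path)
}
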