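# Image I/O and color handling.
#
# Internally images live on the unit interval: grayscale as an H x W matrix,
# RGB as an H x W x 3 array (top-left origin, row-major pixel semantics as in
# the `png`/`tiff` packages). Luminance stays in [0,1]; chroma planes are kept
# on the 8-bit [0,255] scale so the weighted chroma fusion rule with its
# mid-intensity constant tau = 128 applies literally.

# ITU-R BT.601 full-range (JPEG convention) luma/chroma matrix. The method
# only prescribes "YCbCr"; BT.601 full-range is the standard choice for 8-bit
# still images and is pinned here (see the methods vignette).
.ycbcr_fwd <- matrix(c(
   0.299,     0.587,     0.114,
  -0.168736, -0.331264,  0.5,
   0.5,      -0.418688, -0.081312
), nrow = 3, byrow = TRUE)

#' Read an image from PNG or TIFF
#'
#' Reads an 8- or 16-bit grayscale or RGB image and rescales it to the unit
#' interval (by 1/255 or 1/65535 according to the file's bit depth). An alpha
#' channel, if present, is dropped with a warning. The original bit depth is
#' recorded in the `"bit_depth"` attribute so [write_image()] can write
#' symmetrically.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (grayscale) or `H x W x 3` array (RGB) with values
#'   in `[0, 1]` and a `"bit_depth"` attribute.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    depth <- png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  } else {
    stop("unsupported image format: ", ext, " (PNG or TIFF expected)")
  }
  # readPNG/readTIFF already rescale to [0,1] by the file's bit depth
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 2L) {
      warning("dropping alpha channel of gray+alpha image")
      img <- img[, , 1]
    } else if (nc == 4L) {
      warning("dropping alpha channel of RGBA image")
      img <- img[, , 1:3]
    } else if (nc == 3L) {
      # fine
    } else if (nc == 1L) {
      img <- img[, , 1]
    } else {
      stop("unsupported channel count: ", nc)
    }
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "bit_depth") <- as.integer(depth)
  img
}

# PNG bit depth lives in byte 25 of the file (IHDR)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 25L) return(8L)
  as.integer(hdr[25L])
}

#' Write an image to PNG or TIFF
#'
#' @param img Matrix or `H x W x 3` array with values in `[0, 1]`.
#' @param path Output path; the extension selects the format.
#' @param bit_depth 8 or 16. Defaults to the image's `"bit_depth"` attribute
#'   (set by [read_image()]) or 8. PNG output is always 8-bit (the `png`
#'   package cannot write 16-bit); use TIFF for 16-bit output.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = NULL) {
  if (is.null(bit_depth)) bit_depth <- attr(img, "bit_depth")
  if (is.null(bit_depth)) bit_depth <- 8L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  img <- pmin(pmax(unclass(img), 0), 1)
  attributes(img) <- list(dim = dim(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth == 16L) {
      warning("PNG output is written at 8 bits; use TIFF for 16-bit output")
    }
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = bit_depth)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

#' RGB to luma/chroma (BT.601 full range)
#'
#' Decomposes an RGB image into luminance `Y` on `[0, 1]` and chroma planes
#' `Cb`, `Cr` on the 8-bit `[0, 255]` scale centered at `tau = 128`. A pure
#' gray pixel (R = G = B) maps to neutral chroma `Cb = Cr = 128`.
#'
#' @param img `H x W x 3` array on `[0, 1]`.
#' @return List with `Y` (matrix, `[0,1]`), `Cb`, `Cr` (matrices, `[0,255]`)
#'   and `tau = 128`.
#' @export
rgb_to_ycbcr <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("rgb_to_ycbcr expects an H x W x 3 array")
  }
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  m <- .ycbcr_fwd
  list(
    Y  = m[1, 1] * r + m[1, 2] * g + m[1, 3] * b,
    Cb = 128 + 255 * (m[2, 1] * r + m[2, 2] * g + m[2, 3] * b),
    Cr = 128 + 255 * (m[3, 1] * r + m[3, 2] * g + m[3, 3] * b),
    tau = 128
  )
}

#' Luma/chroma back to RGB
#'
#' Exact matrix inverse of [rgb_to_ycbcr()]; the round trip reproduces the
#' input to floating-point precision. Output is clipped to `[0, 1]`.
#'
#' @param lc List with `Y` (`[0,1]`) and `Cb`, `Cr` (`[0,255]`).
#' @return `H x W x 3` array on `[0, 1]`.
#' @export
ycbcr_to_rgb <- function(lc) {
  inv <- solve(.ycbcr_fwd)
  cb <- (lc$Cb - 128) / 255
  cr <- (lc$Cr - 128) / 255
  y <- lc$Y
  r <- inv[1, 1] * y + inv[1, 2] * cb + inv[1, 3] * cr
  g <- inv[2, 1] * y + inv[2, 2] * cb + inv[2, 3] * cr
  b <- inv[3, 1] * y + inv[3, 2] * cb + inv[3, 3] * cr
  out <- array(c(r, g, b), dim = c(dim(y), 3L))
  pmin(pmax(out, 0), 1)
}

#' Weighted chroma fusion
#'
#' Fuses N chroma planes by weighting each pixel's chroma by its own distance
#' from the neutral mid-intensity `tau`:
#' `Cf = sum(Ci * (Ci - tau)) / sum(Ci - tau)` where the denominator is
#' nonzero, and `Cf = tau` otherwise (in particular when every input equals
#' `tau`). Saturated chroma therefore dominates washed-out chroma, and the
#' rule is exactly invariant to the order of the input planes.
#'
#' @param channels List of N chroma matrices on `[0, 255]`, identical shapes.
#' @param tau Mid-intensity constant, 128 for 8-bit chroma.
#' @param tol Values of `|sum(Ci - tau)|` below `tol` count as the zero
#'   denominator branch (guards against float noise).
#' @return Fused chroma matrix on `[0, 255]`.
#' @export
fuse_chroma <- function(channels, tau = 128, tol = 1e-8) {
  if (!is.list(channels) || length(channels) < 1L) {
    stop("channels must be a non-empty list of chroma planes")
  }
  d <- dim(channels[[1]])
  for (ch in channels) {
    if (!identical(dim(ch), d)) stop("chroma planes differ in shape")
  }
  num <- zeros_like(channels[[1]])
  den <- zeros_like(channels[[1]])
  for (ch in channels) {
    w <- ch - tau
    num <- num + ch * w
    den <- den + w
  }
  out <- zeros_like(num) + tau
  ok <- abs(den) > tol
  out[ok] <- num[ok] / den[ok]
  pmin(pmax(out, 0), 255)
}

# luminance plane of any supported image (grayscale passthrough)
as_luma <- function(img) {
  if (length(dim(img)) == 3L) rgb_to_ycbcr(img)$Y else unclass(img)
}
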