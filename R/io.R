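# Image and mask I/O for the formats the DRIVE and STARE archives ship
# (PNG, TIFF, PPM). Intensities are normalised to [0,1] on read by the format's
# maximum value (255 or 65535); all downstream maths is on [0,1].

readRasterFile <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("corrupt or unreadable PNG '", path,
                                            "': ", conditionMessage(e))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("corrupt or unreadable TIFF '", path,
                                             "': ", conditionMessage(e))),
    ppm = ,
    pgm = readPNM(path),
    gif = stop("GIF input is not supported '", path,
               "'; convert to PNG/TIFF/PPM first"),
    stop("unsupported image format '.", ext, "' for '", path, "'")
  )
  # readPNG/readTIFF already divide by the sample maximum (255 or 65535).
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3] # drop alpha
  x
}

# Minimal netpbm reader: P2/P5 (PGM) and P3/P6 (PPM), maxval <= 65535.
readPNM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() { # next whitespace-separated token, skipping '#' comments
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PNM file '", path, "'")
      if (ch == "#") repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in '", path, "'")
  w <- as.integer(tok()); h <- as.integer(tok()); mx <- as.integer(tok())
  if (anyNA(c(w, h, mx)) || w < 1L || h < 1L || mx < 1L)
    stop("corrupt PNM header in '", path, "'")
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    v <- scan(con, what = integer(), n = n, comment.char = "#", quiet = TRUE)
    if (length(v) < n) stop("truncated PNM data in '", path, "'")
    v
  } else if (mx < 256L) {
    as.integer(readBin(con, "raw", n))
  } else {
    readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  }
  # PNM stores row-major, channel-interleaved.
  if (nch == 1L) {
    matrix(vals / mx, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- aperm(array(vals / mx, dim = c(3L, w, h)), c(3L, 2L, 1L))
    a
  }
}

#' Read a fundus photograph
#'
#' Reads PNG, TIFF or PPM/PGM and returns a [FundusImage-class] with
#' intensities normalised to \code{[0,1]} by the format's maximum sample value
#' (255 for 8-bit, 65535 for 16-bit). Grayscale files are replicated to three
#' identical channels with a warning.
#'
#' @param path file to read.
#' @return A [FundusImage-class].
#' @seealso [greenChannel()], [readMask()]
#' @export
readFundus <- function(path) {
  x <- readRasterFile(path)
  if (is.matrix(x)) {
    warning("'", path, "' is grayscale; replicating to 3 channels")
    x <- array(x, dim = c(dim(x), 3L))
  }
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("'", path, "' does not decode to a 3-channel image")
  new("FundusImage", rgb = x, sourcePath = path)
}

#' Extract the green channel
#'
#' The green channel of a colour fundus photograph carries the best
#' vessel/background contrast and is the working image for all enhancement
#' stages. Vessels are darker than the background in this channel.
#'
#' @param img a [FundusImage-class].
#' @param fov optional logical FOV matrix to attach; if \code{NULL} and
#'   \code{estimateFov = TRUE}, a FOV is estimated from the image luminance.
#' @param estimateFov estimate the field of view when no mask is supplied
#'   (default \code{TRUE}; STARE, for instance, ships no FOV masks).
#' @return A [GrayImage-class] with values in \code{[0,1]}.
#' @examples
#' ph <- generatePhantom(phantomSpec(height = 128, width = 128, seed = 1))
#' g <- greenChannel(ph$image, fov = ph$fov)
#' range(pixels(g))
#' @export
greenChannel <- function(img, fov = NULL, estimateFov = TRUE) {
  stopifnot(is(img, "FundusImage"))
  g <- img@rgb[, , 2L]
  if (is.null(fov) && isTRUE(estimateFov)) {
    lum <- 0.299 * img@rgb[, , 1L] + 0.587 * img@rgb[, , 2L] +
      0.114 * img@rgb[, , 3L]
    fov <- estimateFovMask(lum)
  }
  GrayImage(g, fov = fov)
}

#' Estimate a field-of-view mask from luminance
#'
#' Marks pixels brighter than \code{threshold} and applies a morphological
#' closing with a disc structuring element so that dark vessels at the FOV rim
#' are not punched out of the mask.
#'
#' @param lum numeric matrix of luminance in \code{[0,1]}.
#' @param threshold luminance cut (default 0.02).
#' @param radius disc radius in pixels for the closing (default 5).
#' @return logical matrix.
#' @export
estimateFovMask <- function(lum, threshold = 0.02, radius = 5L) {
  m <- lum > threshold
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  closed <- EBImage::closing(matrix(as.numeric(m), nrow(m)), brush)
  closed > 0.5
}

#' Read and write binary masks
#'
#' Masks are stored as single-channel 8-bit PNG with values 0/255; on read any
#' nonzero pixel is taken as TRUE, so 0/1 files work too. \code{writeMask}
#' followed by \code{readMask} is the identity.
#'
#' @param path PNG file.
#' @param mask logical matrix.
#' @return \code{readMask}: logical matrix. \code{writeMask}: \code{path},
#'   invisibly.
#' @export
readMask <- function(path) {
  x <- readRasterFile(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x > 0
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' Write a grayscale image
#'
#' Writes PNG (8-bit, values clamped to \code{[0,1]}) or TIFF (32-bit float,
#' values kept verbatim — used for signed intermediate responses).
#'
#' @param x numeric matrix.
#' @param path output file; format chosen by extension (.png/.tif/.tiff).
#' @return \code{path}, invisibly.
#' @export
writeGray <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    y <- pmin(pmax(x, 0), 1)
    png::writePNG(y, path)
  } else if (ext %in% c("tif", "tiff")) {
    # 32-bit float samples hold signed responses verbatim; writeTIFF warns
    # about values outside [0,1] even though float storage is well-defined
    suppressWarnings(tiff::writeTIFF(x, path, bits.per.sample = 32L,
                                     reduce = FALSE))
  } else stop("unsupported output format '.", ext, "'")
  invisible(path)
}

#' Write a fundus image as PNG
#' @param img a [FundusImage-class].
#' @param path output PNG file.
#' @return \code{path}, invisibly.
#' @export
writeFundus <- function(img, path) {
  stopifnot(is(img, "FundusImage"))
  png::writePNG(img@rgb, path)
  invisible(path)
}
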