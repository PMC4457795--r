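# Internal raster helpers shared by the enhancement stages.

# Reflect-pad a matrix by `h` rows/cols on every side (edge pixel not
# duplicated, i.e. "symmetric" about the border pixel centres is NOT used;
# this is mirror-with-edge-repeat-free: rows 2..h+1 mirror to the top).
reflectPad <- function(x, h) {
  if (h == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (h >= nr || h >= nc)
    stop("padding (", h, ") must be smaller than the image (", nr, " x ", nc, ")")
  ri <- c((h + 1L):2L, 1L:nr, (nr - 1L):(nr - h))
  ci <- c((h + 1L):2L, 1L:nc, (nc - 1L):(nc - h))
  x[ri, ci, drop = FALSE]
}

# Zero-pad a matrix by `h` on every side.
zeroPad <- function(x, h) {
  if (h == 0L) return(x)
  out <- matrix(0, nrow(x) + 2L * h, ncol(x) + 2L * h)
  out[(h + 1L):(h + nrow(x)), (h + 1L):(h + ncol(x))] <- x
  out
}

# Smallest 5-smooth integer >= n (fast FFT length).
nextFastSize <- function(n) {
  if (n <= 2L) return(max(n, 1L))
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

#' Rescale an image to the unit interval
#'
#' Linear rescaling used between pipeline stages so that the multiplicative
#' fusion of enhancement images is meaningful. With \code{mode = "max"} the
#' image is divided by its largest (in-FOV) value — appropriate for
#' non-negative responses such as the Gabor modulus. With \code{mode = "range"}
#' a min-max rescale maps the (in-FOV) range onto \code{[0,1]} — used for
#' signed gray-voting responses.
#'
#' @param x numeric matrix.
#' @param fov optional logical matrix; statistics are computed over in-FOV
#'   pixels only and out-of-FOV pixels are set to 0.
#' @param mode \code{"max"} or \code{"range"}.
#' @return numeric matrix with in-FOV values in \code{[0,1]}.
#' @examples
#' rescale01(matrix(c(-1, 0, 1, 3), 2), mode = "range")
#' @export
rescale01 <- function(x, fov = NULL, mode = c("max", "range")) {
  mode <- match.arg(mode)
  v <- if (is.null(fov)) x else x[fov]
  if (length(v) == 0L) stop("empty FOV")
  if (mode == "max") {
    mx <- max(v)
    out <- if (mx > 0) x / mx else x * 0
    out[out < 0] <- 0
  } else {
    mn <- min(v); mx <- max(v)
    out <- if (mx > mn) (x - mn) / (mx - mn) else x * 0
    out[out < 0] <- 0; out[out > 1] <- 1
  }
  if (!is.null(fov)) out[!fov] <- 0
  out
}

stopifnotSameShape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(what, " must have identical shapes (",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"), ")")
  invisible(TRUE)
}

asMask <- function(x) {
  if (is.logical(x)) return(x)
  m <- x != 0
  storage.mode(m) <- "logical"
  m
}

# Jaccard overlap of two binary masks.
#' Jaccard index of two binary masks
#' @param a,b logical matrices of identical shape.
#' @return |a & b| / |a | b| (1 when both are empty).
#' @export
jaccard <- function(a, b) {
  stopifnotSameShape(a, b, "masks")
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}
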