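# Local gray-voting enhancement. For every pixel, the m x m window around it
# votes: neighbors at or above Center - k count toward Num1, the rest toward
# Num2, and the response is Num1*L + Num2*N where L and N are derived from the
# window's extreme gray values. Small vessels produce characteristic local
# gray-level transitions that this operator amplifies.

#' Gray-voting parameters
#'
#' @param m odd window side in pixels (default 11).
#' @param k gray transition scale on the 0-255 gray scale (default 3 for the
#'   main enhancement pass; the complement pass uses -5). Internally divided
#'   by 255 to match the \code{[0,1]} intensity normalisation.
#' @param lMode weight convention: \code{"max_min"} (main pass;
#'   \eqn{L = M_{max}/(m^2-1)}, \eqn{N = -M_{min}/(m^2-1)}) or
#'   \code{"max_max"} (complement pass; \eqn{N = -M_{max}/(m^2-1)}), where
#'   \eqn{M_{max}}/\eqn{M_{min}} are the window's extreme gray values.
#' @return A validated list of class \code{"grayVoteParams"}.
#' @examples
#' grayVoteParams()                      # main pass
#' grayVoteParams(k = -5, lMode = "max_max")  # complement pass
#' @export
grayVoteParams <- function(m = 11L, k = 3, lMode = c("max_min", "max_max")) {
  lMode <- match.arg(lMode)
  m <- as.integer(m)
  if (m < 3L || m %% 2L == 0L) stop("window side m must be odd and >= 3")
  structure(list(m = m, k = k / 255, kRaw = k, lMode = lMode),
            class = "grayVoteParams")
}

#' Gray-voting enhancement
#'
#' Per pixel, within its \code{m x m} window: \eqn{M_{max}} and \eqn{M_{min}}
#' are the window's maximum and minimum values (centre included);
#' \eqn{L = M_{max}/(m^2-1)}; \eqn{N = -M_{min}/(m^2-1)} (or
#' \eqn{-M_{max}/(m^2-1)} for \code{lMode = "max_max"}). With
#' \eqn{Comparison = Center - k}, \eqn{Num_1} counts neighbours (centre
#' excluded) at or above \eqn{Comparison} and \eqn{Num_2} the rest; the
#' response is \eqn{Num_1 L + Num_2 N}. A constant image is a fixed point for
#' \code{k > 0}.
#'
#' Window borders are reflect-padded. With \code{fovMode = "restrict"} and a
#' FOV mask, out-of-FOV pixels are excluded from the window extremes and the
#' counts, and \eqn{L, N} are renormalised by the actual in-FOV neighbour
#' count.
#'
#' @param img a [GrayImage-class] or numeric matrix.
#' @param params a [grayVoteParams()] list.
#' @param fov optional logical matrix (overrides the [GrayImage-class] FOV).
#' @param fovMode \code{"restrict"} (default) or \code{"full"} (ignore FOV).
#' @return numeric matrix of the input shape (signed response; out-of-FOV
#'   pixels are 0 under \code{"restrict"}).
#' @examples
#' x <- matrix(0.5, 32, 32)
#' all(abs(grayVote(x, grayVoteParams(m = 5)) - 0.5) < 1e-12)
#' @export
grayVote <- function(img, params = grayVoteParams(), fov = NULL,
                     fovMode = c("restrict", "full")) {
  fovMode <- match.arg(fovMode)
  if (is(img, "GrayImage")) {
    if (is.null(fov)) fov <- fov(img)
    img <- pixels(img)
  }
  stopifnot(is.matrix(img), all(is.finite(img)))
  m <- params$m
  hw <- (m - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  if (m > h || m > w) stop("window (", m, ") does not fit in the image")
  useFov <- fovMode == "restrict" && !is.null(fov)
  if (useFov) stopifnotSameShape(img, fov, "image and fov")

  pad <- reflectPad(img, hw)
  fpad <- if (useFov) reflectPad(fov, hw) else NULL
  ctr <- img
  comparison <- ctr - params$k

  wmax <- matrix(-Inf, h, w); wmin <- matrix(Inf, h, w)
  num1 <- matrix(0, h, w); nNb <- matrix(0, h, w)
  rows <- seq_len(h); cols <- seq_len(w)
  for (di in -hw:hw) for (dj in -hw:hw) {
    v <- pad[rows + hw + di, cols + hw + dj, drop = FALSE]
    if (useFov) {
      ok <- fpad[rows + hw + di, cols + hw + dj, drop = FALSE]
      wmax <- pmax(wmax, ifelse(ok, v, -Inf))
      wmin <- pmin(wmin, ifelse(ok, v, Inf))
      if (di != 0L || dj != 0L) {
        num1 <- num1 + (ok & v >= comparison)
        nNb <- nNb + ok
      }
    } else {
      wmax <- pmax(wmax, v)
      wmin <- pmin(wmin, v)
      if (di != 0L || dj != 0L) num1 <- num1 + (v >= comparison)
    }
  }
  if (!useFov) nNb <- matrix(m^2 - 1, h, w)
  num2 <- nNb - num1
  denom <- pmax(nNb, 1)
  L <- wmax / denom
  N <- if (params$lMode == "max_min") -wmin / denom else -wmax / denom
  out <- num1 * L + num2 * N
  if (useFov) {
    out[!fov] <- 0
    # isolated in-FOV pixels with no in-FOV neighbours: response undefined -> 0
    out[fov & nNb == 0] <- 0
  }
  out
}

#' Fuse the Gabor and gray-voting enhancements
#'
#' Multiplicative fusion \eqn{I_{gv} = I_{Gabor} (1 - I_{vessel})} of the two
#' unit-interval enhancement images: the smooth orientation-maximum Gabor
#' response modulated by the complement of the gray-voting response. The fused
#' image keeps the Gabor ridge structure while the gray-vote term sharpens
#' local gray transitions around small vessels.
#'
#' @param gabor,vote numeric matrices in \code{[0,1]} of identical shape.
#' @return numeric matrix in \code{[0,1]}.
#' @examples
#' fuseImages(matrix(0.8, 2, 2), matrix(0.25, 2, 2))  # all 0.6
#' @export
fuseImages <- function(gabor, vote) {
  stopifnotSameShape(gabor, vote, "fusion inputs")
  gabor * (1 - vote)
}

#' Binarise an enhancement image
#'
#' \code{"otsu"} thresholds by Otsu's criterion computed over the in-FOV pixels
#' only (256 bins on the in-FOV range); \code{"zero"} keeps strictly positive
#' pixels. A constant image yields an all-FALSE mask with a warning.
#'
#' @param img numeric matrix.
#' @param method \code{"otsu"} (default) or \code{"zero"}.
#' @param fov optional logical matrix restricting both the threshold estimate
#'   and the resulting mask.
#' @return logical matrix.
#' @examples
#' x <- matrix(c(rep(0.1, 90), rep(0.9, 10)), 10)
#' sum(binarizeImage(x))
#' @export
binarizeImage <- function(img, method = c("otsu", "zero"), fov = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (!is.null(fov)) stopifnotSameShape(img, fov, "image and fov")
  v <- if (is.null(fov)) img else img[fov]
  if (method == "zero") {
    out <- img > 0
  } else {
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("constant image; returning an all-FALSE mask")
      out <- matrix(FALSE, nrow(img), ncol(img))
    } else {
      # Otsu depends only on the histogram, so the in-FOV sample can be
      # reshaped into a 1 x n image for EBImage's estimator.
      thr <- EBImage::otsu(matrix(v, nrow = 1L), range = rng)
      out <- img > thr
    }
  }
  if (!is.null(fov)) out <- out & fov
  out
}
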