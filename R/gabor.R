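# Orientation-maximum 2D Gabor wavelet enhancement. The wavelet is an
# anisotropic Gaussian envelope modulated by a complex plane wave; the dense
# transform over all translations is computed in the frequency domain, and the
# per-pixel maximum modulus over a discrete grid of rotations extracts ridge
# structure (the main vessels) regardless of local orientation.

#' Gabor filter-bank parameters
#'
#' The wavelet at angle \code{theta} and scale \code{a} is
#' \deqn{\psi(x) = \exp(i k_0 \cdot u) \exp(-|Au|^2 / 2), \quad
#'       u = a^{-1} r_{-\theta} x,}
#' with \eqn{A = diag(\epsilon^{-1/2}, 1)}. \eqn{\epsilon \ge 1} elongates the
#' envelope along the first (rotated) axis while the modulation \eqn{k_0}
#' oscillates across it, which makes the modulus respond to line-like ridges
#' aligned with the elongated axis. The normalising constant of the continuous
#' transform is folded into the final unit-interval rescaling of the
#' orientation maximum, since only relative magnitudes feed the fusion.
#'
#' @param a isotropic dilation (default 3, the scale at which fundus vessels
#'   respond best).
#' @param epsilon anisotropy \eqn{\epsilon \ge 1} (default 4).
#' @param k0 length-2 modulation frequency vector (default \code{c(0, 3)}).
#' @param thetaStepDeg,thetaMaxDeg rotation grid: \code{seq(0, thetaMaxDeg,
#'   thetaStepDeg)} degrees (default 0 to 170 in steps of 10).
#' @return A validated list of class \code{"gaborParams"}.
#' @examples
#' gaborParams()
#' @export
gaborParams <- function(a = 3, epsilon = 4, k0 = c(0, 3),
                        thetaStepDeg = 10, thetaMaxDeg = 170) {
  stopifnot(a > 0, epsilon >= 1, length(k0) == 2L,
            thetaStepDeg > 0, thetaStepDeg <= thetaMaxDeg, thetaMaxDeg < 180)
  structure(list(a = a, epsilon = epsilon, k0 = as.numeric(k0),
                 thetaStepDeg = thetaStepDeg, thetaMaxDeg = thetaMaxDeg),
            class = "gaborParams")
}

thetaGrid <- function(params) seq(0, params$thetaMaxDeg, by = params$thetaStepDeg)

# Odd kernel side large enough that the Gaussian envelope decays below 1e-5 at
# the border along its slowest axis: half-width a*sqrt(epsilon)*sqrt(2*ln 1e5).
gaborKernelSide <- function(params) {
  hw <- ceiling(params$a * max(sqrt(params$epsilon), 1) * sqrt(2 * log(1e5)))
  as.integer(2L * hw + 1L)
}

#' Sample a rotated, dilated Gabor kernel
#'
#' Samples \eqn{\psi(a^{-1} r_{-\theta} x)} on an odd-sided pixel grid centred
#' at the origin. Coordinates: \code{x = (dx, dy)} with \code{dx} the column
#' offset and \code{dy} the row offset.
#'
#' @param params a [gaborParams()] list.
#' @param thetaDeg rotation angle in degrees.
#' @return complex matrix of odd side; the centre element is \code{1 + 0i}.
#' @examples
#' k <- gaborKernel(gaborParams(), 40)
#' k[(nrow(k) + 1) / 2, (ncol(k) + 1) / 2]  # 1 at the origin
#' @export
gaborKernel <- function(params, thetaDeg) {
  stopifnot(inherits(params, "gaborParams"))
  side <- gaborKernelSide(params)
  hw <- (side - 1L) / 2L
  th <- thetaDeg * pi / 180
  off <- -hw:hw
  dx <- matrix(off, side, side, byrow = TRUE)   # column offset
  dy <- matrix(off, side, side)                 # row offset
  # u = a^{-1} r_{-theta} x ; r_{-theta} = [[cos, sin], [-sin, cos]]
  u1 <- (cos(th) * dx + sin(th) * dy) / params$a
  u2 <- (-sin(th) * dx + cos(th) * dy) / params$a
  env <- exp(-0.5 * (u1^2 / params$epsilon + u2^2))
  phase <- params$k0[1] * u1 + params$k0[2] * u2
  env * complex(real = cos(phase), imaginary = sin(phase))
}

#' Dense Gabor wavelet transform at one orientation
#'
#' Computes the cross-correlation \eqn{T(b) = \sum_x \psi^*(x - b) f(x)} over
#' all translations \code{b} by frequency-domain multiplication. The image is
#' reflect-padded by the kernel half-width (so the result equals a direct
#' spatial-domain correlation with reflect boundary handling) and then
#' zero-padded to a 5-smooth FFT size.
#'
#' @param img a [GrayImage-class] or numeric matrix.
#' @param params a [gaborParams()] list.
#' @param thetaDeg orientation in degrees.
#' @return complex matrix of the input shape.
#' @examples
#' im <- matrix(0, 64, 64); im[30:34, ] <- 1
#' r <- gaborTransform(im, gaborParams(), 0)
#' dim(r)
#' @export
gaborTransform <- function(img, params, thetaDeg) {
  x <- if (is(img, "GrayImage")) pixels(img) else img
  stopifnot(is.matrix(x), all(is.finite(x)))
  ker <- gaborKernel(params, thetaDeg)
  hw <- (nrow(ker) - 1L) / 2L
  if (nrow(ker) > nrow(x) || nrow(ker) > ncol(x))
    stop("Gabor kernel (", nrow(ker), " px) larger than the image; ",
         "use a smaller scale 'a'")
  h <- nrow(x); w <- ncol(x)
  Ph <- nextFastSize(h + 2L * hw); Pw <- nextFastSize(w + 2L * hw)
  fp <- matrix(0, Ph, Pw)
  fp[seq_len(h + 2L * hw), seq_len(w + 2L * hw)] <- reflectPad(x, hw)
  # Embed the kernel with its origin at (1,1), wrapping negative offsets.
  kb <- matrix(0 + 0i, Ph, Pw)
  idxR <- ((-hw:hw) %% Ph) + 1L
  idxC <- ((-hw:hw) %% Pw) + 1L
  kb[idxR, idxC] <- ker
  Tfull <- stats::fft(stats::fft(fp) * Conj(stats::fft(kb)), inverse = TRUE) /
    (Ph * Pw)
  Tfull[(hw + 1L):(hw + h), (hw + 1L):(hw + w)]
}

#' Orientation-maximum Gabor response
#'
#' Per-pixel maximum modulus of the Gabor transform over the rotation grid,
#' rescaled to \code{[0,1]} by its largest (in-FOV) value. Also records the
#' maximising orientation.
#'
#' @param img a [GrayImage-class] or numeric matrix. When a FOV is present,
#'   out-of-FOV pixels are filled with the in-FOV mean before filtering (to
#'   suppress the artificial rim edge) and zeroed afterwards.
#' @param params a [gaborParams()] list.
#' @return list with \code{response} (numeric matrix in \code{[0,1]}) and
#'   \code{thetaDeg} (numeric matrix; argmax orientation per pixel).
#' @examples
#' im <- matrix(0, 64, 64); im[, 30:32] <- 1
#' r <- orientationMax(im, gaborParams())
#' range(r$response)
#' @export
orientationMax <- function(img, params = gaborParams()) {
  fovm <- if (is(img, "GrayImage")) fov(img) else NULL
  x <- if (is(img, "GrayImage")) pixels(img) else img
  if (!is.null(fovm) && any(fovm)) x[!fovm] <- mean(x[fovm])
  best <- matrix(-Inf, nrow(x), ncol(x))
  bestTh <- matrix(0, nrow(x), ncol(x))
  for (th in thetaGrid(params)) {
    m <- Mod(gaborTransform(x, params, th))
    upd <- m > best
    best[upd] <- m[upd]
    bestTh[upd] <- th
  }
  resp <- rescale01(best, fov = fovm, mode = "max")
  list(response = resp, thetaDeg = bestTh)
}
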