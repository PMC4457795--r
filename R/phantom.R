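# Synthetic fundus phantom: branching dark vessel trees on a textured bright
# background with a bright optic disc and darker fovea inside a circular FOV.
# Ground truth and a per-pixel true-width map are produced alongside, so every
# pipeline stage is testable without the DRIVE/STARE archives.

#' Construct a phantom specification
#'
#' Defaults emulate a DRIVE-sized (584 x 565) fundus photograph: vessels darker
#' than the background in the green channel, width tapering from about 5 px at
#' the disc to 1 px at the tips, a bright optic disc, a darker fovea, and a
#' ground-truth vessel fraction in the range reported for manual segmentations
#' of real fundus images (roughly 10-15 percent of the FOV).
#'
#' @param height,width raster size in pixels.
#' @param nTrees number of vessel trees rooted at the optic disc rim.
#' @param mainWidth,minWidth root and tip vessel widths (px).
#' @param branchProb per-step branching probability of a vessel walker.
#' @param vesselContrast centreline intensity drop in \code{(0,1)}.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param discCenter,discRadius,foveaCenter,foveaRadius geometry; centers are
#'   (row, col) in pixels. \code{NULL} places them at typical fundus positions.
#' @param seed integer RNG seed; generation is bit-for-bit reproducible.
#' @return A [PhantomSpec-class].
#' @examples
#' phantomSpec(height = 128, width = 128, seed = 7)
#' @export
phantomSpec <- function(height = 584L, width = 565L, nTrees = 4L,
                        mainWidth = 6, minWidth = 1, branchProb = 0.03,
                        vesselContrast = 0.35, noiseSd = 0.01,
                        discCenter = NULL, discRadius = NULL,
                        foveaCenter = NULL, foveaRadius = NULL,
                        seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.null(discRadius)) discRadius <- 0.07 * min(height, width)
  if (is.null(discCenter)) discCenter <- c(height / 2, width * 0.72)
  if (is.null(foveaRadius)) foveaRadius <- 0.09 * min(height, width)
  if (is.null(foveaCenter)) foveaCenter <- c(height / 2, width * 0.42)
  new("PhantomSpec",
      height = height, width = width, nTrees = as.integer(nTrees),
      mainWidth = mainWidth, minWidth = minWidth, branchProb = branchProb,
      vesselContrast = vesselContrast, noiseSd = noiseSd,
      discCenter = as.numeric(discCenter), discRadius = as.numeric(discRadius),
      foveaCenter = as.numeric(foveaCenter),
      foveaRadius = as.numeric(foveaRadius), seed = as.integer(seed))
}

# Random branching walk of one vessel tree; returns a matrix of
# (row, col, width) centreline samples. Walkers step ~1 px with angular
# jitter, taper linearly with arc length, and spawn narrower branches.
traceTree <- function(start, angle0, spec, fovCenter, fovRadius) {
  maxLen <- 1.05 * fovRadius * (1.3 + 0.4 * stats::runif(1))
  queue <- list(list(pos = start, ang = angle0, len = 0,
                     w0 = spec@mainWidth * stats::runif(1, 0.8, 1.1), vis = 1))
  pts <- vector("list", 64L); np <- 0L
  nSpawned <- 1L
  while (length(queue) > 0L) {
    wlk <- queue[[1L]]; queue <- queue[-1L]
    pos <- wlk$pos; ang <- wlk$ang; len <- wlk$len; vis <- wlk$vis
    repeat {
      # width tapers with arc length; square-root profile keeps proximal
      # segments near full width, as in real arterio-venous arcades
      wd <- spec@minWidth +
        (wlk$w0 - spec@minWidth) * sqrt(max(0, 1 - len / maxLen))
      if (wd < spec@minWidth - 1e-9) break
      # visibility varies smoothly along the vessel (AR(1), correlation
      # length ~50 px): thin segments fade in and out of detectability — the
      # "broken small vessel" appearance of real fundus photographs — while
      # main arcades stay visible (fading attenuated with width)
      vis <- min(1, max(0.08, 0.98 * vis + 0.02 + stats::rnorm(1, 0, 0.05)))
      thinness <- min(1, max(0, (spec@mainWidth - wd) /
                               max(spec@mainWidth - spec@minWidth, 1e-9)))
      visEff <- vis^(0.3 + 0.7 * thinness)
      np <- np + 1L
      if (np > length(pts)) pts <- c(pts, vector("list", length(pts)))
      pts[[np]] <- c(pos, max(wd, spec@minWidth), visEff)
      ang <- ang + stats::rnorm(1, 0, 0.10)
      pos <- pos + c(sin(ang), cos(ang))
      len <- len + 1
      if (sqrt(sum((pos - fovCenter)^2)) > fovRadius - 2) break
      if (len >= maxLen) break
      if (nSpawned < 40L && stats::runif(1) < spec@branchProb && wd > 1.2) {
        side <- sample(c(-1, 1), 1L)
        queue[[length(queue) + 1L]] <-
          list(pos = pos, ang = ang + side * stats::runif(1, 0.35, 0.8),
               len = len + 0.15 * maxLen,
               w0 = wlk$w0 * stats::runif(1, 0.75, 0.9), vis = vis)
        nSpawned <- nSpawned + 1L
      }
    }
  }
  do.call(rbind, pts[seq_len(np)])
}

#' Generate a synthetic fundus phantom
#'
#' Draws \code{nTrees} branching vessel trees rooted at the optic disc rim.
#' Each centreline sample stamps a Gaussian intensity dip whose FWHM equals the
#' local vessel width; stamps combine by maximum. The ground truth marks pixels
#' where the dip exceeds half the centreline amplitude — i.e. pixels within
#' half the local FWHM of a centreline — so true vessel width in the mask
#' matches the nominal width. A bright disc and a darker fovea are blended
#' into a smooth textured background, Gaussian noise is added, and all planes
#' are quantised to the 8-bit grid so files round-trip exactly.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements \code{image} ([FundusImage-class]),
#'   \code{truth} (logical matrix), \code{fov} (logical matrix),
#'   \code{widthMap} (numeric matrix; local nominal vessel width at truth
#'   pixels, 0 elsewhere), and \code{green} (the exact green plane stored in
#'   \code{image}).
#' @examples
#' ph <- generatePhantom(phantomSpec(height = 128, width = 128, seed = 3))
#' mean(ph$truth[ph$fov])
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  h <- spec@height; w <- spec@width
  if (spec@discRadius > min(h, w) / 2 || spec@foveaRadius > min(h, w) / 2)
    stop("disc/fovea geometry does not fit inside the raster")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec@seed)

  fovCenter <- c((h + 1) / 2, (w + 1) / 2)
  fovRadius <- min(h, w) / 2 - 0.015 * min(h, w)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  dFov <- sqrt((rr - fovCenter[1])^2 + (cc - fovCenter[2])^2)
  fovMask <- dFov <= fovRadius

  # Background: base level, a few broad illumination bumps, plus fine
  # band-limited texture emulating the granular choroidal background of the
  # green channel (present even in noise-free renderings).
  bg <- matrix(0.55, h, w)
  nBumps <- 6L
  for (i in seq_len(nBumps)) {
    ctr <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    sig <- stats::runif(1, 0.2, 0.45) * min(h, w)
    amp <- stats::runif(1, -0.05, 0.05)
    bg <- bg + amp * exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / (2 * sig^2))
  }
  tex <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = 3)
  bg <- bg + 0.012 * tex / stats::sd(tex)
  dDisc <- sqrt((rr - spec@discCenter[1])^2 + (cc - spec@discCenter[2])^2)
  bg <- bg + 0.22 * exp(-(dDisc / spec@discRadius)^4)        # bright disc
  dFv <- sqrt((rr - spec@foveaCenter[1])^2 + (cc - spec@foveaCenter[2])^2)
  bg <- bg - 0.12 * exp(-(dFv / spec@foveaRadius)^2)         # darker fovea

  # Vessel trees rooted on the disc rim, initially heading away from the disc.
  # dipAmp tracks the stamp's contrast scale: thin vessels are fainter than
  # main ones (as in real fundus photographs), scaling linearly from 55% of
  # the nominal contrast at minWidth to 100% at mainWidth.
  dipGain <- matrix(0, h, w)   # max over stamps of exp(-d^2 / (2 sigma^2))
  dipAmp <- matrix(0, h, w)    # amplitude scale of the winning stamp
  widthMap <- matrix(0, h, w)
  ampOfWidth <- function(wd) {
    if (spec@mainWidth <= spec@minWidth) return(rep(1, length(wd)))
    0.40 + 0.60 * pmin(1, (wd - spec@minWidth) /
                          (spec@mainWidth - spec@minWidth))
  }
  if (spec@vesselContrast > 0 && spec@nTrees > 0L) {
    for (tr in seq_len(spec@nTrees)) {
      phi <- 2 * pi * (tr - 1 + stats::runif(1, -0.2, 0.2)) / spec@nTrees
      start <- spec@discCenter + spec@discRadius * c(sin(phi), cos(phi))
      pts <- traceTree(start, phi + stats::rnorm(1, 0, 0.2), spec,
                       fovCenter, fovRadius)
      if (is.null(pts)) next
      for (p in seq_len(nrow(pts))) {
        pr <- pts[p, 1L]; pc <- pts[p, 2L]; wd <- pts[p, 3L]; vis <- pts[p, 4L]
        sigma <- wd / 2.355                      # FWHM = nominal width
        rad <- ceiling(3 * sigma)
        r0 <- max(1L, floor(pr - rad)); r1 <- min(h, ceiling(pr + rad))
        c0 <- max(1L, floor(pc - rad)); c1 <- min(w, ceiling(pc + rad))
        if (r0 > r1 || c0 > c1) next
        ri <- r0:r1; ci <- c0:c1
        d2 <- outer((ri - pr)^2, (ci - pc)^2, "+")
        g <- exp(-d2 / (2 * sigma^2))
        blk <- dipGain[ri, ci, drop = FALSE]
        upd <- g > blk
        if (any(upd)) {
          blk[upd] <- g[upd]
          dipGain[ri, ci] <- blk
          ablk <- dipAmp[ri, ci, drop = FALSE]
          ablk[upd] <- ampOfWidth(wd) * vis
          dipAmp[ri, ci] <- ablk
          wblk <- widthMap[ri, ci, drop = FALSE]
          sel <- upd & g > 0.5
          wblk[sel] <- pmax(wblk[sel], wd)
          widthMap[ri, ci] <- wblk
        }
      }
    }
  }
  truth <- dipGain > 0.5 & fovMask
  widthMap[!truth] <- 0

  green <- bg - spec@vesselContrast * dipAmp * dipGain
  if (spec@noiseSd > 0)
    green <- green + matrix(stats::rnorm(h * w, 0, spec@noiseSd), h, w)
  green[!fovMask] <- 0
  green <- pmin(pmax(green, 0), 1)
  green <- round(green * 255) / 255               # 8-bit grid: exact round-trip
  red <- round(pmin(pmax(green * 1.25 + 0.10, 0), 1) * 255) / 255
  blue <- round(pmin(pmax(green * 0.45, 0), 1) * 255) / 255
  red[!fovMask] <- 0; blue[!fovMask] <- 0
  rgb <- array(c(red, green, blue), dim = c(h, w, 3L))

  list(image = new("FundusImage", rgb = rgb, sourcePath = ""),
       truth = truth, fov = fovMask, widthMap = widthMap, green = green)
}
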