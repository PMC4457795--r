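#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' FundusImage: an RGB fundus photograph
#'
#' Holds a 3-channel raster of a colour fundus photograph with intensities
#' normalised to \code{[0,1]}. Channel order is R, G, B along the third array
#' dimension; pixel \code{[i, j, ]} is row \code{i}, column \code{j}.
#'
#' @slot rgb numeric array \code{height x width x 3}, values in \code{[0,1]}.
#' @slot sourcePath character; file the image was read from ("" if in-memory).
#'
#' @seealso [readFundus()], [greenChannel()]
#' @export
setClass("FundusImage",
  representation(rgb = "array", sourcePath = "character"),
  prototype(sourcePath = "")
)

setValidity("FundusImage", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L)
    return("rgb must be a height x width x 3 array")
  if (d[1] < 16L || d[2] < 16L)
    return("image must be at least 16 x 16 pixels")
  if (anyNA(object@rgb) || min(object@rgb) < 0 || max(object@rgb) > 1)
    return("rgb intensities must lie in [0,1]")
  TRUE
})

#' GrayImage: a single-channel image with an optional field-of-view mask
#'
#' The working representation for all scalar images in the pipeline: the green
#' channel, enhancement responses, fused images. In-FOV intensities of a green
#' channel are in \code{[0,1]}; derived response images may be signed.
#'
#' @slot pixels numeric matrix (rows x cols).
#' @slot fov logical matrix of identical shape marking the imaged retina, or
#'   \code{NULL} when the whole frame is valid.
#'
#' @seealso [GrayImage()], [pixels()], [fov()]
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", fov = "matrixOrNULL"),
  prototype(fov = NULL)
)

setValidity("GrayImage", function(object) {
  if (!is.numeric(object@pixels)) return("pixels must be numeric")
  if (!is.null(object@fov)) {
    if (!is.logical(object@fov)) return("fov must be a logical matrix")
    if (!identical(dim(object@fov), dim(object@pixels)))
      return("fov shape must equal pixels shape")
  }
  if (any(!is.finite(object@pixels))) return("pixels must be finite")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities.
#' @param fov optional logical matrix of the same shape (field of view).
#' @return A [GrayImage-class] object.
#' @examples
#' g <- GrayImage(matrix(runif(32 * 32), 32))
#' dim(pixels(g))
#' @export
GrayImage <- function(pixels, fov = NULL) {
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels, fov = fov)
}

#' GMMFit: a fitted one-dimensional Gaussian mixture
#'
#' Parameters of a K-component univariate Gaussian mixture fitted to pixel
#' intensities by EM, plus the log-likelihood trace of the iterations.
#'
#' @slot K integer; number of components.
#' @slot weights numeric; mixing proportions, sum to 1.
#' @slot means numeric; component means.
#' @slot variances numeric; component variances (floored at the variance floor).
#' @slot loglik numeric; per-iteration log-likelihood (non-decreasing).
#' @slot converged logical; whether the relative tolerance was reached.
#' @slot nobs integer; number of data points fitted.
#'
#' @seealso [emFit()], [assignClusters()]
#' @export
setClass("GMMFit",
  representation(
    K = "integer", weights = "numeric", means = "numeric",
    variances = "numeric", loglik = "numeric", converged = "logical",
    nobs = "integer"
  )
)

setValidity("GMMFit", function(object) {
  K <- object@K
  if (length(object@weights) != K || length(object@means) != K ||
      length(object@variances) != K)
    return("weights, means, variances must all have length K")
  if (abs(sum(object@weights) - 1) > 1e-8 || any(object@weights < -1e-12))
    return("weights must be non-negative and sum to 1")
  if (any(object@variances <= 0)) return("variances must be positive")
  TRUE
})

#' LabeledComponents: a connected-component labeling of a binary mask
#'
#' @slot labels integer matrix; 0 = background, components numbered 1..NUM in
#'   column-major order of first occurrence (as MATLAB's \code{bwlabel}).
#' @slot counts integer; per-component pixel counts.
#' @slot bboxes integer matrix NUM x 4 with columns rowMin, rowMax, colMin,
#'   colMax (1-based, inclusive).
#' @slot connectivity integer; 4 or 8.
#'
#' @seealso [labelComponents()]
#' @export
setClass("LabeledComponents",
  representation(
    labels = "matrix", counts = "integer", bboxes = "matrix",
    connectivity = "integer"
  )
)

setValidity("LabeledComponents", function(object) {
  num <- length(object@counts)
  lab <- object@labels
  if (num > 0 && max(lab) != num) return("labels must be contiguous 1..NUM")
  if (num > 0 && (nrow(object@bboxes) != num || ncol(object@bboxes) != 4L))
    return("bboxes must be NUM x 4")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  TRUE
})

#' PhantomSpec: parameters of the synthetic fundus phantom
#'
#' Describes a fundus-like test image: branching dark vessel trees on a
#' textured bright background with a bright optic disc and a darker fovea,
#' inside a circular field of view. Generation is bit-for-bit reproducible
#' from \code{seed}.
#'
#' @slot height,width image size in pixels.
#' @slot nTrees number of vessel trees rooted at the disc rim.
#' @slot mainWidth,minWidth vessel width (px) at the root and at the tips.
#' @slot branchProb per-step probability that a walker spawns a branch.
#' @slot vesselContrast intensity drop of a vessel centreline, in (0,1).
#' @slot noiseSd standard deviation of additive Gaussian pixel noise.
#' @slot discCenter,discRadius,foveaCenter,foveaRadius geometry (px; centers
#'   are (row, col)).
#' @slot seed integer RNG seed.
#'
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    height = "integer", width = "integer", nTrees = "integer",
    mainWidth = "numeric", minWidth = "numeric", branchProb = "numeric",
    vesselContrast = "numeric", noiseSd = "numeric",
    discCenter = "numeric", discRadius = "numeric",
    foveaCenter = "numeric", foveaRadius = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (object@height < 64L || object@width < 64L)
    return("phantom must be at least 64 x 64")
  if (object@minWidth < 1 || object@mainWidth < object@minWidth)
    return("widths must satisfy mainWidth >= minWidth >= 1")
  if (object@vesselContrast < 0 || object@vesselContrast >= 1)
    return("vesselContrast must be in [0,1)")
  if (object@branchProb < 0 || object@branchProb > 1)
    return("branchProb must be a probability")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  ctrs <- rbind(object@discCenter, object@foveaCenter)
  if (any(ctrs[, 1] < 1 | ctrs[, 1] > object@height |
          ctrs[, 2] < 1 | ctrs[, 2] > object@width))
    return("disc/fovea centers must lie inside the raster")
  TRUE
})

#' VesselSegmentation: the result of a full pipeline run
#'
#' Container for every intermediate of the segmentation pipeline, from the
#' green channel to the final vessel mask.
#'
#' Stage names for [stageImage()]: \code{green}, \code{gabor}, \code{vote},
#' \code{fused}, \code{complementVote}. Mask names for [stageMask()]:
#' \code{gmm} (mixture-model vessel cluster), \code{complementBinary}
#' (binarised second gray-vote), \code{complemented} (after fragment
#' adoption), \code{final}.
#'
#' @slot green [GrayImage-class]; the (normalised) green channel with FOV.
#' @slot stages named list of numeric matrices (intermediate responses).
#' @slot masks named list of logical matrices.
#' @slot fit [GMMFit-class]; the fitted mixture.
#' @slot vesselCluster integer; index of the cluster taken as vessels.
#' @slot config list; the full pipeline configuration used.
#'
#' @seealso [runPipeline()], [finalMask()]
#' @export
setClass("VesselSegmentation",
  representation(
    green = "GrayImage", stages = "list", masks = "list",
    fit = "GMMFit", vesselCluster = "integer", config = "list"
  )
)
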