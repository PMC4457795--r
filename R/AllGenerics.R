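#' Pixel matrix of an image object
#' @param x a [GrayImage-class].
#' @return numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' Field-of-view mask of an image object
#' @param x a [GrayImage-class].
#' @return logical matrix, or \code{NULL} when the whole frame is valid.
#' @export
setGeneric("fov", function(x) standardGeneric("fov"))

#' @rdname fov
#' @export
setMethod("fov", "GrayImage", function(x) x@fov)

#' RGB array of a fundus image
#' @param x a [FundusImage-class].
#' @return numeric array height x width x 3 in \code{[0,1]}.
#' @export
setGeneric("rgbData", function(x) standardGeneric("rgbData"))

#' @rdname rgbData
#' @export
setMethod("rgbData", "FundusImage", function(x) x@rgb)

#' Number of mixture components / labeled components
#' @param x a [GMMFit-class] or [LabeledComponents-class].
#' @return integer count.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname nComponents
#' @export
setMethod("nComponents", "GMMFit", function(x) x@K)

#' @rdname nComponents
#' @export
setMethod("nComponents", "LabeledComponents", function(x) length(x@counts))

#' Mixture parameters of a fitted GMM
#' @param x a [GMMFit-class].
#' @return numeric vector of length K.
#' @export
setGeneric("gmmWeights", function(x) standardGeneric("gmmWeights"))

#' @rdname gmmWeights
#' @export
setMethod("gmmWeights", "GMMFit", function(x) x@weights)

#' @rdname gmmWeights
#' @export
setGeneric("gmmMeans", function(x) standardGeneric("gmmMeans"))

#' @rdname gmmWeights
#' @export
setMethod("gmmMeans", "GMMFit", function(x) x@means)

#' @rdname gmmWeights
#' @export
setGeneric("gmmVariances", function(x) standardGeneric("gmmVariances"))

#' @rdname gmmWeights
#' @export
setMethod("gmmVariances", "GMMFit", function(x) x@variances)

#' Log-likelihood trace of the EM iterations
#' @param x a [GMMFit-class].
#' @return numeric vector, one value per iteration (non-decreasing).
#' @export
setGeneric("loglikTrace", function(x) standardGeneric("loglikTrace"))

#' @rdname loglikTrace
#' @export
setMethod("loglikTrace", "GMMFit", function(x) x@loglik)

#' Label matrix and per-component statistics of a labeling
#' @param x a [LabeledComponents-class].
#' @return \code{labelMatrix}: integer matrix (0 = background);
#'   \code{componentCounts}: integer vector; \code{componentBoxes}: integer
#'   matrix NUM x 4 (rowMin, rowMax, colMin, colMax).
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "LabeledComponents", function(x) x@labels)

#' @rdname labelMatrix
#' @export
setGeneric("componentCounts", function(x) standardGeneric("componentCounts"))

#' @rdname labelMatrix
#' @export
setMethod("componentCounts", "LabeledComponents", function(x) x@counts)

#' @rdname labelMatrix
#' @export
setGeneric("componentBoxes", function(x) standardGeneric("componentBoxes"))

#' @rdname labelMatrix
#' @export
setMethod("componentBoxes", "LabeledComponents", function(x) x@bboxes)

#' Final vessel mask of a pipeline run
#' @param x a [VesselSegmentation-class].
#' @return logical matrix.
#' @export
setGeneric("finalMask", function(x) standardGeneric("finalMask"))

#' @rdname finalMask
#' @export
setMethod("finalMask", "VesselSegmentation", function(x) x@masks$final)

#' Intermediate images and masks of a pipeline run
#'
#' @param x a [VesselSegmentation-class].
#' @param name stage name; see [VesselSegmentation-class] for the available
#'   names.
#' @return numeric matrix (\code{stageImage}) or logical matrix
#'   (\code{stageMask}).
#' @export
setGeneric("stageImage", function(x, name) standardGeneric("stageImage"))

#' @rdname stageImage
#' @export
setMethod("stageImage", "VesselSegmentation", function(x, name) {
  if (identical(name, "green")) return(pixels(x@green))
  if (!name %in% names(x@stages))
    stop("unknown stage '", name, "'; available: green, ",
         paste(names(x@stages), collapse = ", "))
  x@stages[[name]]
})

#' @rdname stageImage
#' @export
setGeneric("stageMask", function(x, name) standardGeneric("stageMask"))

#' @rdname stageImage
#' @export
setMethod("stageMask", "VesselSegmentation", function(x, name) {
  if (!name %in% names(x@masks))
    stop("unknown mask '", name, "'; available: ",
         paste(names(x@masks), collapse = ", "))
  x@masks[[name]]
})

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@rgb)
  cat("FundusImage ", d[1], " x ", d[2], " (RGB)",
      if (nzchar(object@sourcePath)) paste0(" <", object@sourcePath, ">"),
      "\n", sep = "")
})

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  rng <- range(object@pixels)
  cat(sprintf("GrayImage %d x %d, range [%.4g, %.4g]%s\n", d[1], d[2],
              rng[1], rng[2],
              if (is.null(object@fov)) "" else
                sprintf(", FOV %.1f%%", 100 * mean(object@fov))))
})

setMethod("show", "GMMFit", function(object) {
  cat(sprintf("GMMFit: %d components, n = %d, %d EM iterations (%s)\n",
              object@K, object@nobs, length(object@loglik),
              if (object@converged) "converged" else "max iterations"))
  print(data.frame(weight = round(object@weights, 4),
                   mean = round(object@means, 4),
                   sd = round(sqrt(object@variances), 4)))
})

setMethod("show", "LabeledComponents", function(object) {
  cat(sprintf("LabeledComponents: %d components (%d-connected), %d x %d\n",
              length(object@counts), object@connectivity,
              nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %d x %d: %d trees, width %.1f->%.1f px, contrast %.2f, noise sd %.3f, seed %d\n",
    object@height, object@width, object@nTrees, object@mainWidth,
    object@minWidth, object@vesselContrast, object@noiseSd, object@seed))
})

setMethod("show", "VesselSegmentation", function(object) {
  fm <- object@masks$final
  cat(sprintf(
    "VesselSegmentation %d x %d: final vessel pixels %d (%.2f%% of FOV), vessel cluster %d of %d\n",
    nrow(fm), ncol(fm), sum(fm),
    100 * sum(fm) / max(1, sum(if (is.null(fov(object@green)))
      length(fm) else fov(object@green))),
    object@vesselCluster, object@fit@K))
})
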