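# End-to-end orchestration: green channel -> (Gabor, gray-vote) -> fusion ->
# GMM clustering -> complement gray-vote + binarisation -> fragment adoption ->
# squareness elimination.

#' Pipeline configuration
#'
#' Assembles all stage parameters with the method's standard settings:
#' gray-vote window m = 11 with k = 3 (main) and k = -5 (complement, both on
#' the 0-255 scale, complement pass using the max_max weight convention);
#' Gabor scale a = 3 with orientations 0-170 degrees in 10-degree steps;
#' 4-component mixture; adoption thresholds tSeed = 30, tFragment = 100;
#' elimination cuts sizeCut = 14000, squarenessCut = 0.2.
#'
#' @param seed global RNG seed (fans out to the K-means initialisation — the
#'   only stochastic stage).
#' @param gabor list of [gaborParams()] arguments.
#' @param grayvote list with \code{m}, \code{kMain}, \code{kComplement},
#'   \code{binarize} ("otsu" or "zero").
#' @param gmm list with \code{K}, \code{tol}, \code{maxIter},
#'   \code{vesselRule}, \code{weighted}.
#' @param post list with \code{tSeed}, \code{tFragment}, \code{sizeCut},
#'   \code{squarenessCut}, \code{connectivity}, \code{mxMode}.
#' @param fovMode \code{"restrict"} (default) or \code{"full"}.
#' @param invertGreen work on the inverted green channel (vessels bright;
#'   default TRUE). Both enhancement stages see the same polarity, which the
#'   multiplicative fusion requires; set FALSE only for inputs whose vessels
#'   are already brighter than the background.
#' @return nested configuration list of class \code{"pipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(seed = 7)
#' cfg$grayvote$kMain
#' @export
pipelineConfig <- function(seed = 1L,
                           gabor = list(),
                           grayvote = list(),
                           gmm = list(),
                           post = list(),
                           fovMode = c("restrict", "full"),
                           invertGreen = TRUE) {
  fovMode <- match.arg(fovMode)
  gaborDef <- list(a = 3, epsilon = 4, k0 = c(0, 3),
                   thetaStepDeg = 10, thetaMaxDeg = 170)
  voteDef <- list(m = 11L, kMain = 3, kComplement = -5, binarize = "zero")
  gmmDef <- list(K = 4L, tol = 1e-6, maxIter = 500L,
                 vesselRule = "highest", weighted = TRUE)
  postDef <- list(tSeed = 30L, tFragment = 100L, sizeCut = 14000,
                  squarenessCut = 0.2, connectivity = 8L, mxMode = "extent")
  cfg <- list(seed = as.integer(seed),
              gabor = utils::modifyList(gaborDef, gabor),
              grayvote = utils::modifyList(voteDef, grayvote),
              gmm = utils::modifyList(gmmDef, gmm),
              post = utils::modifyList(postDef, post),
              fovMode = fovMode, invertGreen = isTRUE(invertGreen))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read/write a pipeline configuration as YAML
#' @param cfg a [pipelineConfig()] list.
#' @param path YAML file.
#' @return \code{writeConfig}: \code{path}, invisibly; \code{readConfig}: a
#'   \code{pipelineConfig}.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  pipelineConfig(seed = raw$seed %||% 1L,
                 gabor = raw$gabor %||% list(),
                 grayvote = raw$grayvote %||% list(),
                 gmm = raw$gmm %||% list(),
                 post = raw$post %||% list(),
                 fovMode = raw$fovMode %||% "restrict",
                 invertGreen = raw$invertGreen %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

runStage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[retivote] %-16s %6.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full vessel segmentation pipeline
#'
#' Stages, in order: extract and normalise the green channel; compute the
#' orientation-maximum Gabor response (on the inverted green channel by
#' default) and the gray-voting response of the green channel; rescale both to
#' \code{[0,1]} and fuse multiplicatively; cluster the in-FOV fused
#' intensities with a K-means-initialised Gaussian mixture and take the vessel
#' layer; run a second, permissive gray-vote on the fused image and binarise
#' it (positive-vote rule by default, Otsu optional); adopt small complement
#' fragments onto broken vessel seeds; and
#' remove compact non-vessel blobs by squareness rate.
#'
#' @param input a [FundusImage-class], a [GrayImage-class] (already the green
#'   channel), or a path readable by [readFundus()].
#' @param config a [pipelineConfig()] list.
#' @param fov optional logical FOV matrix; if missing and the input is a
#'   colour image, a FOV is estimated (see [estimateFovMask()]).
#' @param outDir optional directory; when given, intermediates and the final
#'   mask are written as image files plus a JSON manifest.
#' @param saveIntermediates write every intermediate (default TRUE when
#'   \code{outDir} is given).
#' @param verbose emit per-stage timing messages (default FALSE).
#' @return A [VesselSegmentation-class].
#' @examples
#' \donttest{
#' ph <- generatePhantom(phantomSpec(height = 160, width = 160, seed = 2))
#' seg <- runPipeline(greenChannel(ph$image, fov = ph$fov),
#'                    pipelineConfig(seed = 2))
#' sum(finalMask(seg))
#' }
#' @export
runPipeline <- function(input, config = pipelineConfig(), fov = NULL,
                        outDir = NULL, saveIntermediates = !is.null(outDir),
                        verbose = FALSE) {
  if (!inherits(config, "pipelineConfig")) stop("config must be a pipelineConfig")
  if (!verbose) {
    mf <- function(expr) suppressMessages(expr)
  } else mf <- identity

  green <- if (is.character(input)) {
    img <- readFundus(input)
    greenChannel(img, fov = fov)
  } else if (is(input, "FundusImage")) {
    greenChannel(input, fov = fov)
  } else if (is(input, "GrayImage")) {
    if (!is.null(fov)) GrayImage(pixels(input), fov = fov) else input
  } else stop("input must be a file path, FundusImage or GrayImage")

  fovm <- if (config$fovMode == "restrict") fov(green) else NULL
  gp <- do.call(gaborParams, config$gabor)
  gvMain <- grayVoteParams(m = config$grayvote$m, k = config$grayvote$kMain,
                           lMode = "max_min")
  gvComp <- grayVoteParams(m = config$grayvote$m,
                           k = config$grayvote$kComplement, lMode = "max_max")

  # Working image: vessels bright. Both enhancement stages see the same
  # polarity, which makes the multiplicative fusion complement the vote
  # response at vessels rather than suppress them.
  working <- if (config$invertGreen) 1 - pixels(green) else pixels(green)
  gab <- mf(runStage("gabor", orientationMax(
    GrayImage(working, fov = fovm), gp)))$response
  vote <- mf(runStage("gray-vote", grayVote(working, gvMain, fov = fovm,
                                            fovMode = config$fovMode)))
  voteR <- rescale01(vote, fov = fovm, mode = "range")
  fused <- mf(runStage("fuse", fuseImages(gab, voteR)))

  seg <- mf(runStage("gmm", gmmSegment(
    fused, fov = fovm, K = config$gmm$K, seed = config$seed,
    rule = config$gmm$vesselRule, weighted = config$gmm$weighted,
    tol = config$gmm$tol, maxIter = config$gmm$maxIter)))

  # The complement gray-vote runs on the dark-vessel rendering of the fused
  # image: with a negative k and max_max weights it then drives vessel pixels
  # toward +Mmax and flat background toward -Mmax, so thresholding recovers
  # small-vessel fragments.
  compVote <- mf(runStage("complement-vote", grayVote(
    1 - fused, gvComp, fov = fovm, fovMode = config$fovMode)))
  iCom <- mf(runStage("binarize", binarizeImage(
    compVote, method = config$grayvote$binarize, fov = fovm)))

  iCGmm <- mf(runStage("complement", complementVessels(
    seg$mask, iCom, tSeed = config$post$tSeed,
    tFragment = config$post$tFragment,
    connectivity = config$post$connectivity)))
  iFinal <- mf(runStage("eliminate", eliminateFragments(
    iCGmm, sizeCut = config$post$sizeCut,
    squarenessCut = config$post$squarenessCut,
    connectivity = config$post$connectivity, mxMode = config$post$mxMode)))

  res <- new("VesselSegmentation",
             green = green,
             stages = list(gabor = gab, vote = voteR, fused = fused,
                           complementVote = compVote),
             masks = list(gmm = seg$mask, complementBinary = iCom,
                          complemented = iCGmm, final = iFinal),
             fit = seg$fit, vesselCluster = as.integer(seg$cluster),
             config = unclass(config))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeMask(iFinal, file.path(outDir, "final.png"))
    if (isTRUE(saveIntermediates)) {
      writeGray(pixels(green), file.path(outDir, "green.png"))
      writeGray(gab, file.path(outDir, "gabor.tif"))
      writeGray(voteR, file.path(outDir, "vote.tif"))
      writeGray(fused, file.path(outDir, "fused.tif"))
      writeGray(compVote, file.path(outDir, "complement_vote.tif"))
      writeMask(seg$mask, file.path(outDir, "gmm.png"))
      writeMask(iCom, file.path(outDir, "complement_binary.png"))
      writeMask(iCGmm, file.path(outDir, "complemented.png"))
      if (!is.null(fovm)) writeMask(fovm, file.path(outDir, "fov.png"))
    }
    manifest <- list(
      package = "retivote",
      version = as.character(utils::packageVersion("retivote")),
      seed = config$seed,
      config = unclass(config),
      configHash = digestConfig(config),
      vesselCluster = seg$cluster,
      pixelCounts = list(gmm = sum(seg$mask), complementBinary = sum(iCom),
                         complemented = sum(iCGmm), final = sum(iFinal))
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

# Stable hash of the configuration (order-independent within lists).
digestConfig <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small FNV-1a over the serialised config; avoids a digest dependency
  bytes <- utf8ToInt(as.character(s))
  hashv <- 2166136261
  for (b in bytes) {
    low8 <- hashv %% 256
    hashv <- hashv - low8 + bitwXor(as.integer(low8), as.integer(b %% 256))
    # multiply by the FNV prime mod 2^32 in 16-bit halves (keeps exact doubles)
    lo <- hashv %% 65536; hi <- hashv %/% 65536
    hashv <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", hashv)
}
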