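# Fragment-level postprocessing: connected-component labeling, adoption of
# small complement fragments onto broken vessel tips of the marker mask, and
# squareness-rate elimination of compact non-vessel blobs.

#' Connected-component labeling
#'
#' Labels the foreground of a binary mask into components numbered 1..NUM in
#' column-major order of first occurrence (the convention of MATLAB's
#' \code{bwlabel}, which the vessel-complementation pseudocode assumes).
#' 4-connected labeling is delegated to \code{EBImage::bwlabel}; 8-connectivity
#' additionally merges labels that touch diagonally (union-find).
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return A [LabeledComponents-class].
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- m[2, 2] <- TRUE
#' nComponents(labelComponents(m, 8))  # 1
#' nComponents(labelComponents(m, 4))  # 2
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  mask <- asMask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    parent <- seq_len(nlab)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    h <- nrow(lab); w <- ncol(lab)
    for (dj in c(-1L, 1L)) {
      a <- lab[-h, , drop = FALSE]
      b <- if (dj == 1L) lab[-1L, -1L, drop = FALSE] else lab[-1L, -w, drop = FALSE]
      a <- if (dj == 1L) a[, -w, drop = FALSE] else a[, -1L, drop = FALSE]
      touch <- which(a > 0L & b > 0L & a != b)
      for (idx in touch) {
        ra <- findRoot(a[idx]); rb <- findRoot(b[idx])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_len(nlab), findRoot, 0L)
    lab[mask] <- roots[lab[mask]]
  }
  # renumber contiguously in column-major order of first occurrence
  fg <- which(mask)
  if (length(fg) == 0L) {
    return(new("LabeledComponents",
               labels = matrix(0L, nrow(mask), ncol(mask)),
               counts = integer(0),
               bboxes = matrix(0L, 0L, 4L,
                               dimnames = list(NULL, c("rowMin", "rowMax",
                                                       "colMin", "colMax"))),
               connectivity = connectivity))
  }
  old <- lab[fg]
  newId <- integer(max(old))
  nxt <- 0L
  for (o in old) if (newId[o] == 0L) { nxt <- nxt + 1L; newId[o] <- nxt }
  lab[fg] <- newId[old]
  counts <- tabulate(lab[fg], nbins = nxt)
  ri <- ((fg - 1L) %% nrow(mask)) + 1L
  ci <- ((fg - 1L) %/% nrow(mask)) + 1L
  ids <- lab[fg]
  bboxes <- cbind(rowMin = as.integer(tapply(ri, ids, min)),
                  rowMax = as.integer(tapply(ri, ids, max)),
                  colMin = as.integer(tapply(ci, ids, min)),
                  colMax = as.integer(tapply(ci, ids, max)))
  new("LabeledComponents", labels = lab, counts = as.integer(counts),
      bboxes = bboxes, connectivity = connectivity)
}

#' Adopt complement fragments onto broken vessel seeds
#'
#' Every marker component with at most \code{tSeed} pixels is treated as a
#' broken-vessel seed: its first pixel (column-major scan order) is looked up
#' in the labeling of the complement mask, and if it lands on a complement
#' component of at most \code{tFragment} pixels, that whole component is added
#' to the output. Seeds landing on complement background are skipped. The
#' output always contains the marker (\code{output >= marker} pixelwise) and
#' adds only complement pixels.
#'
#' @param marker logical matrix — the mixture-model vessel mask.
#' @param complement logical matrix — the binarised second gray-vote mask.
#' @param tSeed maximum pixel count of a broken-vessel seed (default 30).
#' @param tFragment maximum pixel count of an adoptable complement fragment
#'   (default 100).
#' @param connectivity 4 or 8 (default 8).
#' @return logical matrix.
#' @export
complementVessels <- function(marker, complement, tSeed = 30L,
                              tFragment = 100L, connectivity = 8L) {
  stopifnotSameShape(marker, complement, "marker and complement")
  stopifnot(tSeed >= 1L, tFragment >= tSeed)
  marker <- asMask(marker); complement <- asMask(complement)
  lcM <- labelComponents(marker, connectivity)
  lcC <- labelComponents(complement, connectivity)
  out <- marker
  labM <- labelMatrix(lcM); labC <- labelMatrix(lcC)
  seeds <- which(componentCounts(lcM) <= tSeed)
  if (length(seeds) == 0L) return(out)
  # first pixel of each marker component in column-major scan order
  fg <- which(labM > 0L)                        # which() is column-major
  firstPix <- fg[match(seq_len(nComponents(lcM)), labM[fg])]
  cCounts <- componentCounts(lcC)
  cfg <- which(labC > 0L)
  cPixels <- split(cfg, labC[cfg])
  for (s in seeds) {
    t <- labC[firstPix[s]]
    if (t > 0L && cCounts[t] <= tFragment) out[cPixels[[as.character(t)]]] <- TRUE
  }
  out
}

#' Squareness rate of a fragment
#'
#' \eqn{S_{Rcs} = 100 \, F_{Scs} / (1 + mx^2)} where \eqn{F_{Scs}} is the
#' fragment's pixel count and \eqn{mx} the larger of its two axis extents.
#' Compact blobs score near 100; long thin (vessel-like) or very large
#' fragments score low.
#'
#' @param count pixel count of the fragment (\eqn{F_{Scs} \ge 1}).
#' @param mx larger of the fragment's maximum extents along the two axes.
#' @return numeric squareness rate.
#' @examples
#' squarenessRate(100, 10)   # 10x10 square: ~99
#' squarenessRate(100, 100)  # 1-px line of length 100: ~0.01 * 100
#' @export
squarenessRate <- function(count, mx) {
  stopifnot(count >= 1, mx >= 1)
  100 * count / (1 + mx * mx)
}

#' Eliminate non-vessel fragments by squareness rate
#'
#' Each connected component of the mask is removed when it is both smaller
#' than \code{sizeCut} pixels and has squareness rate above
#' \code{squarenessCut}; all other components are kept verbatim. With
#' \code{mxMode = "extent"} (default) \eqn{mx} is the larger of the
#' component's bounding-box height and width — a position-independent shape
#' score; \code{"coordinate"} uses the larger of the component's maximum
#' absolute row/column coordinates instead.
#'
#' @param mask logical matrix.
#' @param sizeCut size threshold in pixels (default 14000).
#' @param squarenessCut squareness threshold (default 0.2).
#' @param connectivity 4 or 8 (default 8).
#' @param mxMode \code{"extent"} or \code{"coordinate"}.
#' @return logical matrix (a subset of the input).
#' @export
eliminateFragments <- function(mask, sizeCut = 14000, squarenessCut = 0.2,
                               connectivity = 8L,
                               mxMode = c("extent", "coordinate")) {
  mxMode <- match.arg(mxMode)
  mask <- asMask(mask)
  lc <- labelComponents(mask, connectivity)
  if (nComponents(lc) == 0L) return(mask)
  bb <- componentBoxes(lc)
  mx <- if (mxMode == "extent") {
    pmax(bb[, "rowMax"] - bb[, "rowMin"] + 1L, bb[, "colMax"] - bb[, "colMin"] + 1L)
  } else {
    pmax(bb[, "rowMax"], bb[, "colMax"])
  }
  sr <- squarenessRate(componentCounts(lc), mx)
  drop <- componentCounts(lc) < sizeCut & sr > squarenessCut
  out <- mask
  if (any(drop)) out[labelMatrix(lc) %in% which(drop)] <- FALSE
  out
}
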