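# Pixel-level evaluation against one or two manual gold standards:
# confusion counts, the three standard metrics, and colour disagreement
# overlays (TP green, FP blue, FN red).

#' Pixel confusion counts
#'
#' Counts true/false positives/negatives of a predicted vessel mask against a
#' gold-standard mask, optionally restricted to a field of view.
#'
#' @param pred,gold logical matrices of identical shape.
#' @param fov optional logical matrix; only in-FOV pixels are counted.
#' @return named integer vector with elements TP, FP, TN, FN summing to the
#'   number of evaluated pixels.
#' @examples
#' g <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2)
#' confusionCounts(g, g)
#' @export
confusionCounts <- function(pred, gold, fov = NULL) {
  stopifnotSameShape(pred, gold, "pred and gold")
  pred <- asMask(pred); gold <- asMask(gold)
  if (!is.null(fov)) {
    stopifnotSameShape(pred, fov, "pred and fov")
    pred <- pred[fov]; gold <- gold[fov]
  }
  c(TP = sum(pred & gold), FP = sum(pred & !gold),
    TN = sum(!pred & !gold), FN = sum(!pred & gold))
}

#' Segmentation metrics from confusion counts
#'
#' sensitivity = TP / (TP + FN); specificity = TN / (TN + FP);
#' accuracy = (TP + TN) / (TP + FP + TN + FN). A metric with zero denominator
#' is reported as NaN with a warning. \code{accuracyAsPrinted = TRUE} computes
#' accuracy with numerator TN only (a formula that scores a perfect
#' segmentation below 1 and is retained purely for literal comparability).
#'
#' @param counts named vector from [confusionCounts()].
#' @param accuracyAsPrinted use the TN-only accuracy numerator (default FALSE).
#' @return named numeric vector: accuracy, sensitivity, specificity.
#' @examples
#' segMetrics(c(TP = 50, FP = 10, TN = 930, FN = 10))
#' @export
segMetrics <- function(counts, accuracyAsPrinted = FALSE) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated pixels")
  sdiv <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NaN }
    else num / den
  }
  accNum <- if (accuracyAsPrinted) tn else tp + tn
  c(accuracy = accNum / total,
    sensitivity = sdiv(tp, tp + fn, "sensitivity"),
    specificity = sdiv(tn, tn + fp, "specificity"))
}

#' Disagreement overlay
#'
#' RGB rendering of prediction vs gold standard: TP pixels green (0,1,0), FP
#' blue (0,0,1), FN red (1,0,0); TN pixels show the grayscale background (or
#' black if none). Out-of-FOV pixels are black.
#'
#' @param pred,gold logical matrices of identical shape.
#' @param fov optional logical matrix.
#' @param background optional numeric matrix in \code{[0,1]} used for TN
#'   pixels.
#' @return numeric array height x width x 3 in \code{[0,1]}.
#' @export
overlayMask <- function(pred, gold, fov = NULL, background = NULL) {
  stopifnotSameShape(pred, gold, "pred and gold")
  pred <- asMask(pred); gold <- asMask(gold)
  inside <- if (is.null(fov)) matrix(TRUE, nrow(pred), ncol(pred)) else fov
  bg <- if (is.null(background)) matrix(0, nrow(pred), ncol(pred))
        else pmin(pmax(background, 0), 1)
  tp <- pred & gold & inside
  fp <- pred & !gold & inside
  fn <- !pred & gold & inside
  marked <- tp | fp | fn
  r <- bg; g <- bg; b <- bg
  r[marked] <- 0; g[marked] <- 0; b[marked] <- 0
  g[tp] <- 1; b[fp] <- 1; r[fn] <- 1
  r[!inside] <- 0; g[!inside] <- 0; b[!inside] <- 0
  array(c(r, g, b), dim = c(nrow(pred), ncol(pred), 3L))
}

#' Metrics against one gold standard as a report row
#'
#' @keywords internal
metricsRow <- function(pred, gold, fov, label) {
  cc <- confusionCounts(pred, gold, fov)
  m <- segMetrics(cc)
  data.frame(gold = label, TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]],
             FN = cc[["FN"]], accuracy = m[["accuracy"]],
             sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
             row.names = NULL)
}

#' Evaluation report against one or two gold standards
#'
#' Computes confusion counts and metrics of a prediction against each supplied
#' gold standard. When a per-pixel vessel-width map is supplied (available for
#' phantoms), additional rows report the sensitivity restricted to small
#' vessels (width <= \code{smallWidth} px) — the regime in which gold
#' standards disagree most.
#'
#' @param pred logical matrix.
#' @param gold1 logical matrix; first gold standard.
#' @param gold2 optional logical matrix; second gold standard.
#' @param fov optional logical matrix.
#' @param widthMap optional numeric matrix of true vessel widths (0 off
#'   vessel); enables small-vessel rows.
#' @param smallWidth width cut in pixels for the small-vessel rows (default 2).
#' @return data.frame, one row per (gold standard x vessel stratum).
#' @export
dualGoldReport <- function(pred, gold1, gold2 = NULL, fov = NULL,
                           widthMap = NULL, smallWidth = 2) {
  out <- metricsRow(pred, gold1, fov, "gold1")
  if (!is.null(gold2)) out <- rbind(out, metricsRow(pred, gold2, fov, "gold2"))
  if (!is.null(widthMap)) {
    golds <- list(gold1 = gold1)
    if (!is.null(gold2)) golds$gold2 <- gold2
    for (nm in names(golds)) {
      g <- asMask(golds[[nm]])
      small <- g & widthMap > 0 & widthMap <= smallWidth
      sens <- smallVesselSensitivity(pred, small, fov)
      out <- rbind(out, data.frame(
        gold = paste0(nm, "_small_w", smallWidth), TP = sum(asMask(pred) & small &
          (if (is.null(fov)) TRUE else fov)),
        FP = NA_integer_, TN = NA_integer_,
        FN = NA_integer_, accuracy = NA_real_, sensitivity = sens,
        specificity = NA_real_, row.names = NULL))
    }
  }
  out
}

#' Sensitivity restricted to small vessels
#'
#' Fraction of small-vessel gold pixels (e.g. true width <= 2 px) recovered by
#' the prediction.
#'
#' @param pred logical matrix.
#' @param smallGold logical matrix of small-vessel gold pixels.
#' @param fov optional logical matrix.
#' @return numeric in \code{[0,1]} (NaN if there are no small-vessel pixels).
#' @export
smallVesselSensitivity <- function(pred, smallGold, fov = NULL) {
  stopifnotSameShape(pred, smallGold, "pred and smallGold")
  pred <- asMask(pred); smallGold <- asMask(smallGold)
  if (!is.null(fov)) { pred <- pred[fov]; smallGold <- smallGold[fov] }
  denom <- sum(smallGold)
  if (denom == 0) return(NaN)
  sum(pred & smallGold) / denom
}
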