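# Univariate Gaussian mixture clustering of fused-image intensities:
# kmeans++-seeded K-means supplies the initial component means, variances and
# weights; EM then iterates the standard responsibility-weighted updates until
# the log-likelihood converges. The cluster whose pixels correspond to vessels
# is extracted as a binary layer.

VAR_FLOOR <- 1e-6

#' K-means initialisation for the mixture
#'
#' kmeans++ seeding followed by Lloyd iterations (via [stats::kmeans()]);
#' per-cluster means, (ML) variances and relative sizes become the initial
#' mixture parameters.
#'
#' @param values numeric vector of intensities (the in-FOV pixels).
#' @param K number of components.
#' @param seed integer seed for the kmeans++ draws.
#' @return list with \code{means}, \code{variances}, \code{weights}, each of
#'   length K, ordered by increasing mean.
#' @examples
#' kmeansInit(c(0, 0, 0, 1, 1, 1), K = 2, seed = 1)
#' @export
kmeansInit <- function(values, K, seed = 1L) {
  stopifnot(is.numeric(values), K >= 1L)
  ux <- unique(values)
  if (length(ux) < K)
    stop("need at least K = ", K, " distinct values, got ", length(ux))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  # kmeans++ seeding on the distinct values
  centers <- numeric(K)
  centers[1] <- ux[sample.int(length(ux), 1L)]
  if (K > 1L) for (i in 2:K) {
    d2 <- vapply(ux, function(u) min((u - centers[seq_len(i - 1L)])^2), 0)
    centers[i] <- if (sum(d2) > 0) ux[sample.int(length(ux), 1L, prob = d2)]
                  else ux[sample.int(length(ux), 1L)]
  }
  cl <- if (K == 1L) {
    list(cluster = rep(1L, length(values)), centers = matrix(mean(values)))
  } else {
    stats::kmeans(values, centers = matrix(centers, ncol = 1L),
                  algorithm = "Lloyd", iter.max = 200L)
  }
  means <- as.numeric(cl$centers)
  sizes <- tabulate(cl$cluster, nbins = K)
  vars <- vapply(seq_len(K), function(i) {
    v <- values[cl$cluster == i]
    if (length(v) == 0L) return(VAR_FLOOR)
    max(mean((v - means[i])^2), VAR_FLOOR)
  }, 0)
  ord <- order(means)
  list(means = means[ord], variances = vars[ord],
       weights = (sizes / length(values))[ord])
}

# log-sum-exp of the K x n matrix of weighted log densities, by column
mixtureLogDens <- function(values, weights, means, variances) {
  K <- length(weights)
  lw <- log(pmax(weights, .Machine$double.xmin))
  ll <- vapply(seq_len(K), function(i)
    lw[i] + stats::dnorm(values, means[i], sqrt(variances[i]), log = TRUE),
    numeric(length(values)))
  if (!is.matrix(ll)) ll <- matrix(ll, nrow = length(values))
  mx <- do.call(pmax, c(as.data.frame(ll), list(na.rm = FALSE)))
  list(logComp = ll, logMix = mx + log(rowSums(exp(ll - mx))))
}

#' Fit a Gaussian mixture by EM
#'
#' Standard univariate EM: responsibilities are the posterior component
#' probabilities; each iteration re-estimates weights (mean responsibility),
#' means (responsibility-weighted averages) and variances
#' (responsibility-weighted squared deviations from the updated means).
#' Iteration stops when the relative log-likelihood change falls below
#' \code{tol} or after \code{maxIter} iterations. Collapsing variances are
#' re-floored at 1e-6 with a warning.
#'
#' @param values numeric vector.
#' @param init initial parameters as returned by [kmeansInit()] (a list with
#'   \code{means}, \code{variances}, \code{weights}).
#' @param tol relative log-likelihood tolerance (default 1e-6).
#' @param maxIter iteration cap (default 500).
#' @return A [GMMFit-class].
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 0.3, 0.05), rnorm(200, 0.7, 0.05))
#' emFit(x, kmeansInit(x, 2, seed = 1))
#' @export
emFit <- function(values, init, tol = 1e-6, maxIter = 500L) {
  stopifnot(is.numeric(values), length(values) > 1L,
            all(c("means", "variances", "weights") %in% names(init)))
  w <- init$weights / sum(init$weights)
  mu <- init$means
  s2 <- pmax(init$variances, VAR_FLOOR)
  K <- length(mu)
  n <- length(values)
  trace <- numeric(0)
  converged <- FALSE
  flooredComp <- integer(0)
  for (it in seq_len(maxIter)) {
    ld <- mixtureLogDens(values, w, mu, s2)
    trace <- c(trace, sum(ld$logMix))
    resp <- exp(ld$logComp - ld$logMix)          # n x K responsibilities
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * values) / nk
    s2 <- vapply(seq_len(K), function(i)
      sum(resp[, i] * (values - mu[i])^2) / nk[i], 0)
    if (any(s2 < VAR_FLOOR)) {
      flooredComp <- unique(c(flooredComp, which(s2 < VAR_FLOOR)))
      s2 <- pmax(s2, VAR_FLOOR)
    }
    if (it > 1L) {
      d <- trace[it] - trace[it - 1L]
      if (abs(d) <= tol * abs(trace[it - 1L])) { converged <- TRUE; break }
    }
  }
  # final log-likelihood under the last parameter update
  trace <- c(trace, sum(mixtureLogDens(values, w, mu, s2)$logMix))
  if (length(flooredComp) > 0L)
    warning("variance floor (1e-6) hit for component(s) ",
            paste(sort(flooredComp), collapse = ", "))
  new("GMMFit", K = as.integer(K), weights = as.numeric(w / sum(w)),
      means = as.numeric(mu), variances = as.numeric(s2),
      loglik = trace, converged = converged, nobs = as.integer(n))
}

#' Assign values to mixture clusters
#'
#' Hard assignment of each value to one of the K components. By default the
#' posterior (weighted) criterion \eqn{\arg\max_i \omega_i p_i(x)} is used;
#' \code{weighted = FALSE} compares unweighted component densities
#' \eqn{\arg\max_i p_i(x)} instead. Ties break toward the lower component
#' index, so the layers always partition the input.
#'
#' @param fit a [GMMFit-class].
#' @param values numeric vector.
#' @param weighted use posterior component probabilities (default TRUE).
#' @return integer vector of cluster indices in \code{1..K}.
#' @examples
#' f <- new("GMMFit", K = 2L, weights = c(.5, .5), means = c(0, 1),
#'          variances = c(.01, .01), loglik = 0, converged = TRUE, nobs = 2L)
#' assignClusters(f, c(0.1, 0.9))
#' @export
assignClusters <- function(fit, values, weighted = TRUE) {
  stopifnot(is(fit, "GMMFit"))
  K <- fit@K
  ll <- vapply(seq_len(K), function(i) {
    base <- stats::dnorm(values, fit@means[i], sqrt(fit@variances[i]), log = TRUE)
    if (weighted) base + log(pmax(fit@weights[i], .Machine$double.xmin)) else base
  }, numeric(length(values)))
  if (!is.matrix(ll)) ll <- matrix(ll, nrow = length(values))
  max.col(ll, ties.method = "first")
}

#' Select the vessel cluster
#'
#' Ranks the K cluster layers by their mean fused-image intensity and returns
#' the index of the layer taken as vessels. In a 4-component fit of a fused
#' fundus enhancement the brightest layer is typically dominated by the optic
#' disc rim and other strong edges, and the vessel layer is the second
#' brightest — hence the default rule.
#'
#' @param fit a [GMMFit-class] (K >= 2).
#' @param labels integer vector of cluster assignments.
#' @param values numeric vector the labels refer to.
#' @param rule \code{"second_highest"} (default), \code{"highest"}, or
#'   \code{"index:i"} to pick layer \code{i} verbatim.
#' @return integer: the selected cluster index.
#' @examples
#' f <- new("GMMFit", K = 2L, weights = c(.5, .5), means = c(0, 1),
#'          variances = c(.01, .01), loglik = 0, converged = TRUE, nobs = 2L)
#' selectVesselCluster(f, c(1L, 2L), c(0.1, 0.9), rule = "highest")
#' @export
selectVesselCluster <- function(fit, labels, values, rule = "second_highest") {
  stopifnot(is(fit, "GMMFit"))
  if (fit@K < 2L) stop("vessel-cluster selection needs K >= 2")
  if (grepl("^index:", rule)) {
    i <- as.integer(sub("^index:", "", rule))
    if (is.na(i) || i < 1L || i > fit@K) stop("invalid cluster index in '", rule, "'")
    return(i)
  }
  layerMeans <- vapply(seq_len(fit@K), function(i) {
    v <- values[labels == i]
    if (length(v) == 0L) -Inf else mean(v)
  }, 0)
  ord <- order(layerMeans, decreasing = TRUE)
  switch(rule,
    highest = ord[1L],
    second_highest = ord[min(2L, fit@K)],
    stop("unknown vessel-cluster rule '", rule, "'")
  )
}

#' Segment an enhancement image with a Gaussian mixture
#'
#' Convenience wrapper: fits a K-component mixture to the in-FOV pixel
#' intensities of \code{img} (K-means init + EM), hard-assigns every in-FOV
#' pixel, and returns the binary layer selected by \code{rule}.
#'
#' @param img numeric matrix (typically the fused enhancement).
#' @param fov optional logical matrix; only in-FOV pixels are modelled.
#' @param K number of mixture components (default 4).
#' @param seed RNG seed for the K-means initialisation.
#' @param rule vessel-layer selection rule; see [selectVesselCluster()].
#' @param weighted posterior (TRUE, default) vs unweighted assignment.
#' @param tol,maxIter EM stopping parameters.
#' @return list with \code{mask} (logical matrix), \code{fit}
#'   ([GMMFit-class]), \code{labels} (integer matrix; 0 out of FOV),
#'   \code{cluster} (selected index).
#' @export
gmmSegment <- function(img, fov = NULL, K = 4L, seed = 1L,
                       rule = "second_highest", weighted = TRUE,
                       tol = 1e-6, maxIter = 500L) {
  stopifnot(is.matrix(img))
  sel <- if (is.null(fov)) rep(TRUE, length(img)) else as.vector(fov)
  values <- img[sel]
  fit <- emFit(values, kmeansInit(values, K, seed = seed),
               tol = tol, maxIter = maxIter)
  lab <- assignClusters(fit, values, weighted = weighted)
  labels <- matrix(0L, nrow(img), ncol(img))
  labels[sel] <- lab
  cl <- selectVesselCluster(fit, lab, values, rule = rule)
  list(mask = labels == cl, fit = fit, labels = labels, cluster = cl)
}
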