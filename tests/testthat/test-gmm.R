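test_that("K-means init separates point masses and reduces to moments at K=1", {
  init <- kmeansInit(c(0, 0, 0, 1, 1, 1), K = 2, seed = 1)
  expect_equal(init$means, c(0, 1))
  expect_equal(init$weights, c(0.5, 0.5))

  x <- c(0.1, 0.4, 0.3, 0.9, 0.25)
  i1 <- kmeansInit(x, K = 1, seed = 1)
  expect_equal(i1$means, mean(x))
  expect_equal(i1$variances, mean((x - mean(x))^2), tolerance = 1e-12)

  expect_error(kmeansInit(c(1, 1, 1), K = 2, seed = 1), "distinct")
})

test_that("K-means init recovers well-separated mixture centres", {
  set.seed(31)
  x <- c(rnorm(5000, 0.2, 0.05), rnorm(5000, 0.8, 0.05))
  init <- kmeansInit(x, K = 2, seed = 31)
  expect_lt(abs(init$means[1] - 0.2), 0.02)
  expect_lt(abs(init$means[2] - 0.8), 0.02)
})

test_that("EM with K=1 equals the sample moments after one iteration", {
  set.seed(32)
  x <- rnorm(500, 0.4, 0.1)
  fit <- emFit(x, list(means = 0, variances = 1, weights = 1), maxIter = 1L)
  expect_equal(gmmMeans(fit), mean(x), tolerance = 1e-12)
  expect_equal(gmmVariances(fit), mean((x - mean(x))^2), tolerance = 1e-12)
})

test_that("the log-likelihood trace is non-decreasing and weights stay normalised", {
  set.seed(33)
  for (rep in 1:10) {
    x <- runif(300)^sample(1:3, 1)
    fit <- emFit(x, kmeansInit(x, 3, seed = rep), maxIter = 60L)
    ll <- loglikTrace(fit)
    expect_true(all(diff(ll) >= -1e-9 * abs(ll[-length(ll)])))
    expect_equal(sum(gmmWeights(fit)), 1, tolerance = 1e-12)
  }
  # weights sum to 1 after every iteration, probed via increasing caps
  x <- c(rnorm(300, 0.3, 0.08), rnorm(200, 0.7, 0.05))
  for (it in 1:5) {
    fit <- suppressWarnings(emFit(x, kmeansInit(x, 2, seed = 1), maxIter = it))
    expect_equal(sum(gmmWeights(fit)), 1, tolerance = 1e-12)
  }
})

test_that("two-component parameters are recovered within 5 percent", {
  set.seed(34)
  n <- 5e4
  z <- runif(n) < 0.7
  x <- ifelse(z, rnorm(n, 0.3, 0.05), rnorm(n, 0.7, 0.05))
  fit <- emFit(x, kmeansInit(x, 2, seed = 34))
  relerr <- function(got, want) abs(got - want) / want
  expect_lt(relerr(gmmWeights(fit)[1], 0.7), 0.05)
  expect_lt(relerr(gmmWeights(fit)[2], 0.3), 0.05)
  expect_lt(relerr(gmmMeans(fit)[1], 0.3), 0.05)
  expect_lt(relerr(gmmMeans(fit)[2], 0.7), 0.05)
  expect_lt(relerr(sqrt(gmmVariances(fit)[1]), 0.05), 0.05)
  expect_lt(relerr(sqrt(gmmVariances(fit)[2]), 0.05), 0.05)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(35)
  x <- c(rnorm(4000, 0.25, 0.06), rnorm(2000, 0.75, 0.04))
  fit <- emFit(x, kmeansInit(x, 2, seed = 35), tol = 1e-9)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(gmmMeans(fit)), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
  expect_equal(sort(gmmWeights(fit)), sort(mc$parameters$pro),
               tolerance = 0.02)
})

test_that("cluster assignment matches the closed-form decision boundary", {
  fit <- new("GMMFit", K = 2L, weights = c(0.6, 0.4), means = c(0.3, 0.7),
             variances = c(0.01, 0.01), loglik = 0, converged = TRUE,
             nobs = 10L)
  # weighted: boundary at midpoint + sigma^2/(mu2-mu1) * log(w1/w2)
  b <- 0.5 + 0.01 / 0.4 * log(0.6 / 0.4)
  eps <- 1e-6
  expect_equal(assignClusters(fit, c(b - eps, b + eps)), c(1L, 2L))
  # unweighted: boundary at the plain midpoint
  expect_equal(assignClusters(fit, c(0.5 - eps, 0.5 + eps), weighted = FALSE),
               c(1L, 2L))
  # every value is assigned to exactly one cluster in 1..K
  set.seed(36)
  lab <- assignClusters(fit, runif(200))
  expect_true(all(lab %in% 1:2))
})

test_that("assignment maximises the per-point posterior (brute force)", {
  set.seed(37)
  fit <- new("GMMFit", K = 3L, weights = c(0.5, 0.3, 0.2),
             means = c(0.2, 0.5, 0.8), variances = c(0.01, 0.04, 0.002),
             loglik = 0, converged = TRUE, nobs = 10L)
  x <- runif(500)
  post <- sapply(1:3, function(i)
    fit@weights[i] * dnorm(x, fit@means[i], sqrt(fit@variances[i])))
  expect_equal(assignClusters(fit, x), max.col(post, ties.method = "first"))
})

test_that("vessel-layer selection rules behave as documented", {
  fit <- new("GMMFit", K = 3L, weights = rep(1/3, 3), means = c(0.1, 0.5, 0.9),
             variances = rep(0.01, 3), loglik = 0, converged = TRUE, nobs = 9L)
  vals <- c(0.1, 0.1, 0.5, 0.5, 0.9, 0.9)
  labs <- c(1L, 1L, 2L, 2L, 3L, 3L)
  expect_equal(selectVesselCluster(fit, labs, vals, rule = "highest"), 3L)
  expect_equal(selectVesselCluster(fit, labs, vals, rule = "second_highest"), 2L)
  expect_equal(selectVesselCluster(fit, labs, vals, rule = "index:2"), 2L)
  expect_error(selectVesselCluster(fit, labs, vals, rule = "index:9"), "index")
})

test_that("gmmSegment is deterministic and partitions the FOV", {
  ph <- testPhantom(seed = 13)
  g <- 1 - ph$green
  s1 <- suppressWarnings(gmmSegment(g, fov = ph$fov, K = 3, seed = 5))
  s2 <- suppressWarnings(gmmSegment(g, fov = ph$fov, K = 3, seed = 5))
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$fit@means, s2$fit@means)
  expect_true(all(s1$labels[ph$fov] %in% 1:3))
  expect_true(all(s1$labels[!ph$fov] == 0L))
})
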