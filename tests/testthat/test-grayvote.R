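test_that("a constant image is a fixed point for positive k", {
  for (m in c(3L, 5L, 11L)) {
    out <- grayVote(matrix(0.37, 24, 24), grayVoteParams(m = m, k = 3))
    expect_equal(out, matrix(0.37, 24, 24), tolerance = 1e-12)
  }
})

test_that("the single-window 3x3 case matches the hand computation", {
  # window [[.1,.2,.3],[.4,.5,.6],[.7,.8,.9]], k = 0.05 (12.75/255):
  # Comparison = 0.45; Num1 = 4, Num2 = 4; L = 0.9/8, N = -0.1/8 -> 0.4
  w <- matrix(c(.1, .4, .7, .2, .5, .8, .3, .6, .9), 3)
  pv <- grayVote(w, grayVoteParams(m = 3, k = 0.05 * 255))
  expect_equal(pv[2, 2], 0.4, tolerance = 1e-12)
})

test_that("production gray-vote equals the per-pixel brute-force oracle", {
  set.seed(21)
  params <- list(
    list(m = 11L, k = 3, lMode = "max_min"),
    list(m = 11L, k = -5, lMode = "max_max"),
    list(m = 5L, k = 3, lMode = "max_max"),
    list(m = 5L, k = -5, lMode = "max_min")
  )
  for (p in params) {
    img <- matrix(runif(32 * 32), 32)
    got <- grayVote(img, grayVoteParams(m = p$m, k = p$k, lMode = p$lMode))
    want <- grayVoteBrute(img, p$m, p$k, p$lMode)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the response is bounded by the window-derived weights", {
  set.seed(22)
  img <- matrix(runif(40 * 40), 40)
  out <- grayVote(img, grayVoteParams(m = 7, k = 3))
  # P_vote within [-Mmin, Mmax] globally for L_mode = max_min
  expect_true(all(out <= max(img) + 1e-12))
  expect_true(all(out >= -max(img) - 1e-12))
})

test_that("raising k drives the response toward the window maximum", {
  # Comparison = Center - k, so a larger k admits more neighbours into Num1
  # and the response rises pointwise toward Mmax; structures are dips, so the
  # count of pixels below any threshold shrinks: "as k increases, the noise
  # (detected structure) decreases".
  set.seed(23)
  img <- matrix(runif(40 * 40), 40)
  ks <- c(0, 3, 5, 10)
  outs <- lapply(ks, function(k) grayVote(img, grayVoteParams(m = 11, k = k)))
  thr <- stats::median(outs[[1]])
  below <- vapply(outs, function(o) sum(o < thr), 0)
  for (i in seq_len(length(ks) - 1)) {
    expect_true(all(outs[[i + 1]] >= outs[[i]] - 1e-12))
    expect_lte(below[i + 1], below[i])
  }
})

test_that("FOV-restricted voting masks outside neighbours and renormalises", {
  set.seed(24)
  img <- matrix(runif(24 * 24), 24)
  fovm <- matrix(TRUE, 24, 24); fovm[1:8, ] <- FALSE
  out <- grayVote(img, grayVoteParams(m = 5, k = 3), fov = fovm)
  expect_true(all(out[!fovm] == 0))
  # interior pixels far from the FOV edge agree with the unrestricted result
  full <- grayVote(img, grayVoteParams(m = 5, k = 3))
  expect_equal(out[12:24, 3:22], full[12:24, 3:22], tolerance = 1e-12)
})

test_that("fusion is the element-wise product of its definition", {
  g <- matrix(0.8, 4, 4); v <- matrix(0.25, 4, 4)
  expect_equal(fuseImages(g, v), matrix(0.6, 4, 4))
  expect_equal(fuseImages(g, matrix(0, 4, 4)), g)
  expect_true(all(fuseImages(g, matrix(1, 4, 4)) == 0))
  expect_error(fuseImages(g, matrix(0, 3, 4)), "shape")
})

test_that("binarisation separates a two-valued image and handles edge cases", {
  set.seed(25)
  v <- matrix(sample(c(rep(0.1, 90), rep(0.9, 10))), 10)
  m <- binarizeImage(v, method = "otsu")
  expect_identical(m, v == 0.9)

  s <- matrix(c(-1, 0, 0.2, 1), 2)
  expect_identical(binarizeImage(s, method = "zero"), s > 0)

  expect_warning(cm <- binarizeImage(matrix(0.5, 8, 8)), "constant")
  expect_true(all(!cm))

  fovm <- matrix(c(TRUE, FALSE), 10, 10)
  mf <- binarizeImage(v, method = "otsu", fov = fovm)
  expect_true(all(!mf[!fovm]))
})
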