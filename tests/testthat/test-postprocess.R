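test_that("labeling handles empty masks and diagonal connectivity", {
  empty <- matrix(FALSE, 8, 8)
  expect_equal(nComponents(labelComponents(empty)), 0L)

  diagm <- matrix(FALSE, 5, 5)
  diagm[2, 2] <- diagm[3, 3] <- TRUE
  expect_equal(nComponents(labelComponents(diagm, 8)), 1L)
  expect_equal(nComponents(labelComponents(diagm, 4)), 2L)
})

test_that("labeling matches the flood-fill oracle on random masks", {
  set.seed(41)
  for (conn in c(4L, 8L)) for (rep in 1:4) {
    m <- matrix(runif(64 * 64) > 0.6, 64)
    lc <- labelComponents(m, conn)
    oracle <- floodLabelOracle(m, conn)
    # identical partitions and identical column-major first-occurrence order
    expect_identical(labelMatrix(lc), oracle)
    expect_equal(componentCounts(lc), as.integer(tabulate(oracle[oracle > 0])))
  }
})

test_that("per-component counts and bounding boxes are correct", {
  m <- matrix(FALSE, 10, 12)
  m[2:4, 3:5] <- TRUE          # 9-px block
  m[8, 7:11] <- TRUE           # 5-px line
  lc <- labelComponents(m, 8)
  expect_equal(nComponents(lc), 2L)
  expect_equal(componentCounts(lc), c(9L, 5L))
  expect_equal(unname(componentBoxes(lc)[1, ]), c(2L, 4L, 3L, 5L))
  expect_equal(unname(componentBoxes(lc)[2, ]), c(8L, 8L, 7L, 11L))
})

test_that("complementation adopts small fragments exactly per the hand trace", {
  # 16x16: a 5-px marker seed sits on a 40-px complement blob -> adopted whole
  marker <- matrix(FALSE, 16, 16)
  marker[8, 3:7] <- TRUE                      # 5-px seed
  marker[12:16, 12:16] <- TRUE                # 25-px blob, also <= T_seed
  complement <- matrix(FALSE, 16, 16)
  complement[6:10, 3:10] <- TRUE              # 40-px blob covering the seed
  out <- complementVessels(marker, complement, tSeed = 30, tFragment = 100)
  expect_true(all(out[complement]))           # whole 40-px blob adopted
  expect_true(all(out[marker]))               # marker never deleted
  expect_equal(sum(out), sum(marker | complement))

  # same geometry, complement blob bigger than T_fragment -> unchanged
  big <- matrix(FALSE, 16, 16)
  big[1:16, 3:15] <- TRUE                     # 208 px > 100
  out2 <- complementVessels(marker, big, tSeed = 30, tFragment = 100)
  expect_identical(out2, marker)

  # marker with no component small enough -> output equals marker
  wide <- matrix(FALSE, 16, 16); wide[1:8, 1:8] <- TRUE   # 64 px > T_seed
  out3 <- complementVessels(wide, complement, tSeed = 30, tFragment = 100)
  expect_identical(out3, wide)

  # seed landing on complement background is skipped
  off <- matrix(FALSE, 16, 16); off[1, 14:16] <- TRUE
  out4 <- complementVessels(off, complement, tSeed = 30, tFragment = 100)
  expect_identical(out4, off)
})

test_that("complementation output is bounded by marker and complement", {
  set.seed(42)
  for (rep in 1:5) {
    marker <- matrix(runif(48 * 48) > 0.92, 48)
    complement <- matrix(runif(48 * 48) > 0.7, 48)
    out <- complementVessels(marker, complement)
    expect_true(all(out[marker]))                 # superset of marker
    expect_true(all(complement[out & !marker]))   # additions from complement
  }
})

test_that("squareness rate follows its defining formula exactly", {
  expect_equal(squarenessRate(100, 10), 100 * 100 / 101)
  expect_equal(squarenessRate(1, 1), 50)
  expect_equal(squarenessRate(100, 100), 10000 / 10001)
  expect_error(squarenessRate(0, 1))
})

test_that("fragment elimination keeps exactly the components the rule keeps", {
  expect_identical(eliminateFragments(matrix(FALSE, 8, 8)), matrix(FALSE, 8, 8))

  # 10x10 square: F=100, S ~ 99 -> removed
  sq <- matrix(FALSE, 20, 20); sq[5:14, 5:14] <- TRUE
  expect_true(all(!eliminateFragments(sq)))

  # a component with >= 14000 px is kept regardless of shape
  big <- matrix(FALSE, 150, 150); big[1:100, 1:140] <- TRUE  # exactly 14000
  expect_identical(eliminateFragments(big), big)

  # a full-width 1-px line of length > 500: S < 0.2 -> kept
  line <- matrix(FALSE, 8, 600); line[4, ] <- TRUE
  expect_identical(eliminateFragments(line), line)

  # mixed suite against the brute-force oracle
  set.seed(43)
  m <- matrix(FALSE, 120, 120)
  m[5:9, 5:9] <- TRUE                          # square
  m[20, 10:60] <- TRUE                         # line
  m[40:60, 40] <- TRUE; m[60, 40:55] <- TRUE   # L-shape
  m[80:119, 70:119] <- TRUE                    # 2000-px block
  got <- eliminateFragments(m)
  expect_identical(got, eliminateOracle(m))
})

test_that("coordinate-mode squareness uses absolute positions", {
  m <- matrix(FALSE, 600, 600)
  m[550:559, 550:559] <- TRUE   # 100-px square at high coordinates
  # extent mode: mx = 10, S ~ 99 -> removed
  expect_true(all(!eliminateFragments(m, mxMode = "extent")))
  # coordinate mode: mx = 559, S = 100*100/(1+559^2) ~ 0.032 -> kept
  expect_identical(eliminateFragments(m, mxMode = "coordinate"), m)
})
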