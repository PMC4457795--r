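# Independent brute-force oracles used to validate the production
# implementations. These are written from the operator definitions directly
# (per-pixel loops, flood fill, direct convolution) and share no code with R/.

# mirror-reflect an out-of-range index into 1..n (no edge duplication)
reflIdx <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 2L - i
    if (i > n) i <- 2L * n - i
  }
  i
}

# Gray-voting, one pixel at a time, straight from the definition:
# window extremes -> L, N; neighbour counts vs Center - k; Num1*L + Num2*N.
grayVoteBrute <- function(img, m, k255, lMode = c("max_min", "max_max")) {
  lMode <- match.arg(lMode)
  k <- k255 / 255
  h <- nrow(img); w <- ncol(img)
  hw <- (m - 1L) %/% 2L
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- numeric(m * m)
    idx <- 0L
    for (di in -hw:hw) for (dj in -hw:hw) {
      idx <- idx + 1L
      vals[idx] <- img[reflIdx(i + di, h), reflIdx(j + dj, w)]
    }
    ctrPos <- (m * m + 1L) %/% 2L
    nb <- vals[-ctrPos]
    comparison <- img[i, j] - k
    num1 <- sum(nb >= comparison)
    num2 <- sum(nb < comparison)
    L <- max(vals) / (m^2 - 1)
    N <- if (lMode == "max_min") -min(vals) / (m^2 - 1) else -max(vals) / (m^2 - 1)
    out[i, j] <- num1 * L + num2 * N
  }
  out
}

# Direct spatial cross-correlation with a complex kernel, reflect boundary.
gaborSpatialOracle <- function(img, ker) {
  h <- nrow(img); w <- ncol(img)
  hw <- (nrow(ker) - 1L) %/% 2L
  ri <- vapply(seq(1L - hw, h + hw), reflIdx, 0L, n = h)
  ci <- vapply(seq(1L - hw, w + hw), reflIdx, 0L, n = w)
  pad <- img[ri, ci]
  out <- matrix(0 + 0i, h, w)
  for (di in -hw:hw) for (dj in -hw:hw) {
    out <- out + Conj(ker[di + hw + 1L, dj + hw + 1L]) *
      pad[(seq_len(h)) + hw + di, (seq_len(w)) + hw + dj]
  }
  out
}

# Connected components by breadth-first flood fill.
floodLabelOracle <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nbr <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (p in which(mask)) {             # column-major scan order
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue) > 0L) {
      q <- queue[[1L]]; queue <- queue[-1L]
      qi <- ((q - 1L) %% h) + 1L; qj <- ((q - 1L) %/% h) + 1L
      for (nn in seq_len(nrow(nbr))) {
        ni <- qi + nbr[nn, 1L]; nj <- qj + nbr[nn, 2L]
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue <- c(queue, (nj - 1L) * h + ni)
        }
      }
    }
  }
  lab
}

# Per-component elimination decision straight from the squareness formula.
eliminateOracle <- function(mask, sizeCut = 14000, squarenessCut = 0.2,
                            connectivity = 8L) {
  lab <- floodLabelOracle(mask, connectivity)
  out <- mask
  if (max(lab) == 0L) return(out)
  for (t in seq_len(max(lab))) {
    px <- which(lab == t)
    f <- length(px)
    ri <- ((px - 1L) %% nrow(mask)) + 1L
    ci <- ((px - 1L) %/% nrow(mask)) + 1L
    mx <- max(max(ri) - min(ri) + 1L, max(ci) - min(ci) + 1L)
    s <- 100 * f / (1 + mx * mx)
    if (f < sizeCut && s > squarenessCut) out[px] <- FALSE
  }
  out
}

# small phantom spec used across tests (fast to generate)
testPhantom <- function(seed = 3L, ...) {
  generatePhantom(phantomSpec(height = 192L, width = 192L, seed = seed, ...))
}

# write a tiny binary PPM (P6) for I/O tests
writeP6 <- function(rgb8, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", ncol(rgb8), nrow(rgb8)), con,
            eos = NULL)
  # channel-interleaved, row-major
  arr <- aperm(rgb8, c(3, 2, 1))
  writeBin(as.raw(as.integer(arr)), con)
}
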