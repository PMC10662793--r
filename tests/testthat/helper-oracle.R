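# Independent oracles, deliberately naive: a sweep-until-stable flood
# fill and an exhaustive-cut Otsu.  These share no code with the package
# internals they check.

# Connected-component flood fill under |I(p) - I(seed)| <= thr, full
# 8/26 neighbourhood, by repeated whole-array dilation sweeps.
brute_flood_fill <- function(A, seed, thr) {
  dm <- dim(A)
  d <- length(dm)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  ok <- abs(A - A[matrix(seed, 1)]) <= thr
  mask <- array(FALSE, dm)
  mask[matrix(seed, 1)] <- TRUE
  repeat {
    changed <- FALSE
    idx <- which(mask)
    co <- arrayInd(idx, dm)
    for (r in seq_len(nrow(offs))) {
      nb <- co + matrix(offs[r, ], nrow(co), d, byrow = TRUE)
      keep <- rep(TRUE, nrow(nb))
      for (a in seq_len(d)) keep <- keep & nb[, a] >= 1 & nb[, a] <= dm[a]
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) == 0) next
      lin <- nb[, 1]
      mult <- 1
      for (a in seq_len(d - 1)) {
        mult <- mult * dm[a]
        lin <- lin + (nb[, a + 1] - 1) * mult
      }
      new <- lin[ok[lin] & !mask[lin]]
      if (length(new)) { mask[new] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  mask
}

# Otsu by exhaustive maximization of between-class variance over the
# 255 interior cuts of a 256-bin histogram on [0, 1].
brute_otsu <- function(values) {
  nb <- 256
  bin <- pmin(floor(values * nb) + 1, nb)
  counts <- tabulate(bin, nbins = nb)
  centers <- (seq_len(nb) - 0.5) / nb
  n <- sum(counts)
  best <- -Inf; best_k <- integer(0)
  for (k in 1:(nb - 1)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * centers[1:k]) / n0
    mu1 <- sum(counts[(k + 1):nb] * centers[(k + 1):nb]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best + 1e-15) { best <- v; best_k <- k }
    else if (abs(v - best) <= 1e-15) best_k <- c(best_k, k)
  }
  mean(best_k) / nb
}

# A small test scene reused across files: bright block on dark field.
block_image <- function() {
  a <- matrix(0.1, 7, 7)
  a[2:6, 2:6] <- 0.5
  a[3:5, 3:5] <- 0.9
  a
}
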