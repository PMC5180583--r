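# Independent oracles and small fixture builders shared across tests.

# mirror (edge-duplicating) reflection of a 1-based index into 1..n,
# matching the entropy filter's border handling
reflect1 <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j[j < 0] <- j[j < 0] + 2L * n
  ifelse(j < n, j + 1L, 2L * n - j)
}

# brute-force per-pixel histogram entropy, independent of the package's
# sliding implementation
naiveLocalEntropy <- function(img, offs, excl = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(excl)) excl <- matrix(FALSE, nr, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (excl[i, j]) next
      vals <- integer(0)
      for (k in seq_len(nrow(offs))) {
        ii <- reflect1(i + offs[k, 1], nr)
        jj <- reflect1(j + offs[k, 2], nc)
        if (!excl[ii, jj]) vals <- c(vals, img[ii, jj])
      }
      if (!length(vals)) next
      p <- as.vector(table(vals)) / length(vals)
      out[i, j] <- -sum(p * log2(p))
    }
  }
  out
}

# logical disk mask with continuum centre (cx, cy) in 0-based pixel coords
diskMask <- function(h, w, cx, cy, r) {
  px <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
  py <- matrix(seq_len(h) - 0.5, h, w)
  (px - cx)^2 + (py - cy)^2 <= r^2
}

# constant-colour RGB array
flatRGB <- function(h, w, rgb) {
  out <- array(0L, c(h, w, 3L))
  for (ch in 1:3) out[, , ch] <- as.integer(rgb[ch])
  out
}

# random simple (convex) polygon as an n x 2 (x, y) vertex matrix
randomConvexPolygon <- function(n, xlim, ylim) {
  pts <- cbind(runif(n, xlim[1], xlim[2]), runif(n, ylim[1], ylim[2]))
  hull <- chull(pts)
  pts[hull, , drop = FALSE]
}
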