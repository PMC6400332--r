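# Independent brute-force oracles, deliberately written as plain loops /
# direct formulas so they share no code with the package implementation.

# trilinear interpolation of volume array `a` (slice, row, col) at one
# continuous 1-based index position
oracle_trilinear <- function(a, iz, iy, ix) {
  z0 <- floor(iz); y0 <- floor(iy); x0 <- floor(ix)
  z0 <- min(max(z0, 1), dim(a)[1] - 1)
  y0 <- min(max(y0, 1), dim(a)[2] - 1)
  x0 <- min(max(x0, 1), dim(a)[3] - 1)
  fz <- iz - z0; fy <- iy - y0; fx <- ix - x0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) fz else 1 - fz) * (if (dy) fy else 1 - fy) *
      (if (dx) fx else 1 - fx)
    acc <- acc + w * a[z0 + dz, y0 + dy, x0 + dx]
  }
  acc
}

oracle_confusion <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && gt[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

oracle_dsc <- function(pred, gt) {
  inter <- 0L
  for (i in seq_along(pred)) if (pred[i] == 1 && gt[i] == 1) inter <- inter + 1L
  den <- sum(pred == 1) + sum(gt == 1)
  if (den == 0) return(NA_real_)
  2 * inter / den
}

oracle_directed_hd <- function(A, B) {
  worst <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
    if (best > worst) worst <- best
  }
  worst
}

oracle_hd <- function(A, B) max(oracle_directed_hd(A, B), oracle_directed_hd(B, A))

# standard same-padded dilated cross-correlation, plain loops
oracle_conv2d <- function(x, k, rate = 1L) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- rate * (kh - 1) / 2; pw <- rate * (kw - 1) / 2
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    acc <- 0
    for (u in seq_len(kh)) for (v in seq_len(kw)) {
      ii <- i + (u - 1) * rate - ph
      jj <- j + (v - 1) * rate - pw
      if (ii >= 1 && ii <= nrow(x) && jj >= 1 && jj <= ncol(x)) {
        acc <- acc + k[u, v] * x[ii, jj]
      }
    }
    out[i, j] <- acc
  }
  out
}

# direct bilinear interpolation matching the half-pixel-centre convention:
# output pixel i samples the input at (i - 0.5)/f + 0.5 (1-based)
oracle_bilinear_upsample <- function(x, f) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr * f, nc * f)
  for (i in seq_len(nr * f)) for (j in seq_len(nc * f)) {
    si <- (i - 0.5) / f + 0.5
    sj <- (j - 0.5) / f + 0.5
    i0 <- min(max(floor(si), 1), nr - 1); j0 <- min(max(floor(sj), 1), nc - 1)
    fi <- si - i0; fj <- sj - j0
    out[i, j] <- x[i0, j0] * (1 - fi) * (1 - fj) +
      x[i0 + 1, j0] * fi * (1 - fj) +
      x[i0, j0 + 1] * (1 - fi) * fj +
      x[i0 + 1, j0 + 1] * fi * fj
  }
  out
}

random_mask <- function(nr, nc, p = 0.3) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}
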