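# Independent brute-force oracles used to cross-check the production
# implementations.  These deliberately share no code with the package paths
# they verify.

# Upper concave envelope of scattered 3D points, evaluated at the points
# themselves: the minimum over all dominating planes through point triples
# (a piecewise-linear concave majorant equals the pointwise infimum of its
# affine majorants), floored at the data.
brute_upper_envelope <- function(x, y, z, tol = 1e-7) {
  n <- length(x)
  tri <- t(utils::combn(n, 3))
  p1 <- tri[, 1]; p2 <- tri[, 2]; p3 <- tri[, 3]
  ux <- x[p2] - x[p1]; uy <- y[p2] - y[p1]; uz <- z[p2] - z[p1]
  vx <- x[p3] - x[p1]; vy <- y[p3] - y[p1]; vz <- z[p3] - z[p1]
  nx <- uy * vz - uz * vy
  ny <- uz * vx - ux * vz
  nz <- ux * vy - uy * vx
  keep <- abs(nz) > 1e-12
  a <- -nx[keep] / nz[keep]
  b <- -ny[keep] / nz[keep]
  cc <- z[p1[keep]] - a * x[p1[keep]] - b * y[p1[keep]]
  zhat <- a %o% x + b %o% y + cc           # K x n plane evaluations
  dom <- rowSums(zhat < matrix(z, nrow(zhat), n, byrow = TRUE) - tol) == 0
  env <- if (any(dom)) apply(zhat[dom, , drop = FALSE], 2, min) else rep(Inf, n)
  pmax(env, z)
}

# 1D upper concave majorant (for collinear footprints): max over all pairwise
# chords spanning the query, floored at the data.
brute_envelope_1d <- function(t, z) {
  n <- length(t)
  env <- z
  for (q in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (t[i] <= t[q] && t[q] <= t[j] && t[j] > t[i]) {
          lam <- (t[q] - t[i]) / (t[j] - t[i])
          env[q] <- max(env[q], (1 - lam) * z[i] + lam * z[j])
        }
      }
    }
  }
  env
}

# Double-loop mask-aware window mean (blur oracle).
brute_blur <- function(g, mask, size, mask_aware = TRUE) {
  h <- nrow(g); w <- ncol(g)
  lo <- -((size - 1L) %/% 2L); hi <- size %/% 2L
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    rr <- max(1, r + lo):min(h, r + hi)
    cc <- max(1, c + lo):min(w, c + hi)
    win_g <- g[rr, cc, drop = FALSE]
    if (mask_aware) {
      win_m <- mask[rr, cc, drop = FALSE]
      out[r, c] <- sum(win_g[win_m]) / sum(win_m)
    } else {
      out[r, c] <- mean(win_g)
    }
  }
  out
}

# Double-loop mask-aware grayscale opening with a disk element.
brute_opening <- function(g, mask, radius) {
  h <- nrow(g); w <- ncol(g)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  ext <- function(src, op) {
    out <- matrix(NA_real_, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      if (!mask[r, c]) next
      vals <- c()
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dy[k]; cc <- c + offs$dx[k]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc])
          vals <- c(vals, src[rr, cc])
      }
      out[r, c] <- op(vals)
    }
    out
  }
  op <- ext(ext(g, min), max)
  op[!mask] <- 0
  op
}

# Random masked brightness grid with a 2D-spanning footprint.
random_masked_grid <- function(h, w, density = 0.7) {
  repeat {
    mask <- matrix(runif(h * w) < density, h, w)
    if (sum(mask) < max(6, 0.3 * h * w)) next
    rc <- which(mask, arr.ind = TRUE)
    if (length(unique(rc[, 1])) > 1 && length(unique(rc[, 2])) > 1) {
      s <- svd(cbind(rc[, 1] - mean(rc[, 1]), rc[, 2] - mean(rc[, 2])))$d
      if (s[2] > 1e-6) return(mask)
    }
  }
}
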