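# Brute-force reference implementations, kept deliberately independent of
# the package's C++ code paths: plain R loops, no shared helpers.

# symmetric (edge-including) reflection for 1-based indices
reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# direct O(N^2) non-local means
nlm_oracle <- function(img, patch_radius, search_radius, h) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  pr <- -patch_radius:patch_radius
  npatch <- length(pr)^2
  getpx <- function(r, c) img[reflect1(r, nr), reflect1(c, nc)]
  patch_of <- function(r, c) {
    v <- numeric(npatch)
    k <- 0L
    for (i in pr) for (j in pr) {
      k <- k + 1L
      v[k] <- getpx(r + i, c + j)
    }
    v
  }
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      p0 <- patch_of(r, c)
      wsum <- 0; vsum <- 0
      for (dr in -search_radius:search_radius) {
        for (dc in -search_radius:search_radius) {
          p1 <- patch_of(r + dr, c + dc)
          d2 <- mean((p0 - p1)^2)
          w <- exp(-d2 / h^2)
          wsum <- wsum + w
          vsum <- vsum + w * getpx(r + dr, c + dc)
        }
      }
      out[r, c] <- vsum / wsum
    }
  }
  out
}

# sliding-window Phansalkar threshold, one pixel at a time
phansalkar_oracle <- function(img, radius, k, r, p, q) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(FALSE, nr, nc)
  for (rr in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      vals <- numeric(0)
      for (i in -radius:radius) for (j in -radius:radius)
        vals <- c(vals, img[reflect1(rr + i, nr), reflect1(cc + j, nc)])
      m <- mean(vals)
      s <- sqrt(mean((vals - m)^2))
      t <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
      out[rr, cc] <- img[rr, cc] > t
    }
  }
  out
}

# triple-loop box counter for one box size
boxcount_oracle <- function(mask, s) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- 0L
  for (r0 in seq(1, nr, by = s)) {
    for (c0 in seq(1, nc, by = s)) {
      blk <- mask[r0:min(nr, r0 + s - 1), c0:min(nc, c0 + s - 1)]
      if (any(blk)) n <- n + 1L
    }
  }
  n
}

# BFS connected-component labelling in plain R
label_oracle <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  moves <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r, c), ncol = 2)
    lab[r, c] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (m in seq_len(nrow(moves))) {
        r2 <- p[1] + moves[m, 1]; c2 <- p[2] + moves[m, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue <- rbind(queue, c(r2, c2))
        }
      }
    }
  }
  lab
}

# convenience: binary disk mask
disk_mask <- function(n, center, radius) {
  d2 <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+")
  d2 <= radius^2
}

n_components <- function(mask, connectivity = 8) {
  max(label_oracle(mask, connectivity))
}
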