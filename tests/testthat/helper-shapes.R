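# Rasterized reference shapes and brute-force geometry oracles.

make_disk_mask <- function(r, pad = 11) {
  n <- 2 * r + 2 * pad
  cx <- r + pad
  xy <- as.matrix(expand.grid(row = 1:n, col = 1:n))
  m <- matrix(FALSE, n, n)
  m[xy[(xy[, 1] - cx)^2 + (xy[, 2] - cx)^2 <= r^2, ]] <- TRUE
  m
}

# axis-aligned a x b (length x width) filled rectangle
make_rect_mask <- function(a, b, pad = 10) {
  m <- matrix(FALSE, b + 2 * pad, a + 2 * pad)
  m[(pad + 1):(pad + b), (pad + 1):(pad + a)] <- TRUE
  m
}

# the same rectangle rotated 45 degrees before rasterization
make_rot_rect_mask <- function(a, b) {
  n <- ceiling((a + b) / sqrt(2)) + 28
  c0 <- n / 2
  xy <- as.matrix(expand.grid(row = 1:n, col = 1:n))
  u <- (xy[, 2] - c0 + xy[, 1] - c0) / sqrt(2)
  v <- (xy[, 2] - c0 - (xy[, 1] - c0)) / sqrt(2)
  m <- matrix(FALSE, n, n)
  m[xy[abs(u) <= a / 2 & abs(v) <= b / 2, ]] <- TRUE
  m
}

# seeded random 4-connected polyomino grown cell by cell
random_polyomino <- function(n_px, seed, field = 64) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, field, field)
    r <- field %/% 2; c <- field %/% 2
    m[r, c] <- TRUE
    frontier <- matrix(c(r, c), ncol = 2)
    while (sum(m) < n_px) {
      i <- sample.int(nrow(frontier), 1)
      p <- frontier[i, ]
      moves <- matrix(c(-1, 0, 1, 0, 0, -1, 0, 1), ncol = 2, byrow = TRUE)
      q <- p + moves[sample.int(4, 1), ]
      if (q[1] < 2 || q[1] > field - 1 || q[2] < 2 || q[2] > field - 1) next
      if (!m[q[1], q[2]]) {
        m[q[1], q[2]] <- TRUE
        frontier <- rbind(frontier, q)
      }
    }
    m
  })
}

# Exhaustive inscribed-radius oracle: for every foreground pixel the exact
# minimum Euclidean distance to any background pixel center (image padded
# by one background ring), maximized over foreground pixels.
brute_inner_radius <- function(mask) {
  padded <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  fg <- which(padded, arr.ind = TRUE)
  bg <- which(!padded, arr.ind = TRUE)
  best <- 0
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    best <- max(best, sqrt(min(d2)))
  }
  best
}

# relative error helper
rel_err <- function(x, ref) abs(x - ref) / abs(ref)
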