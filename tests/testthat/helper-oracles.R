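# Independent brute-force oracles and fixture builders. These deliberately
# use explicit loops / first-principles formulas rather than the package's
# vectorized code paths.

# element-wise loop count of pixels strictly above a threshold
oracle_threshold_count <- function(m, thr) {
  count <- 0L
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > thr) count <- count + 1L
    }
  }
  count
}

# loop-over-frames union count of ever-exceeding pixels
oracle_union_count <- function(mats, thr) {
  ever <- matrix(FALSE, nrow(mats[[1]]), ncol(mats[[1]]))
  for (m in mats) {
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        if (m[i, j] > thr) ever[i, j] <- TRUE
      }
    }
  }
  sum(ever)
}

# brute-force flood fill: size of the largest 4-connected TRUE component
oracle_largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  best <- 0L
  for (i0 in seq_len(nr)) {
    for (j0 in seq_len(nc)) {
      if (!mask[i0, j0] || seen[i0, j0]) next
      stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE; size <- 0L
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              mask[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
      best <- max(best, size)
    }
  }
  best
}

# complete-enumeration two-sided rank-sum p-value
oracle_ranksum_p <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  n1 <- length(x); n <- length(r)
  mu <- n1 * (n + 1) / 2
  obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(n, n1)
  sums <- apply(idx, 2, function(j) sum(r[j]))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# random thermogram sequence within the plausible range
random_sequence <- function(seed, n_frames = 5, nr = 12, nc = 15,
                            lo = 30, hi = 80, frame_rate = 10) {
  set.seed(seed)
  mats <- replicate(n_frames, matrix(runif(nr * nc, lo, hi), nr, nc),
                    simplify = FALSE)
  thermogram_sequence(mats, frame_rate_hz = frame_rate)
}

# small, fast default scenario for simulation-backed tests
tiny_tissue <- function(...) tissue_model(size_mm = c(12, 12, 8), voxel_mm = 1, ...)

float32 <- function(x) thermospread:::as_float32(x)
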