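# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# brute-force O(L^2) pairwise distances
brute_dmap <- function(xyz) {
  L <- nrow(xyz)
  m <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    m[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  m
}

# exhaustive scan of in-band pairs for restraint selection
brute_restraint_count <- function(pred, min_sep, band = c(4, 16)) {
  L <- nrow(pred); n <- 0L
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    if (j - i >= min_sep && pred[i, j] >= band[1] && pred[i, j] <= band[2]) n <- n + 1L
  }
  n
}

# brute-force Neff: pairwise identity loops, then sum of 1/S_i
brute_neff <- function(seqs, threshold = 0.75) {
  N <- length(seqs)
  ch <- strsplit(seqs, "")
  s <- numeric(N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (mean(ch[[i]] == ch[[j]]) >= threshold) s[i] <- s[i] + 1
    }
  }
  sum(1 / s)
}

# gradient-probe receptive field: a linear convolution stack with random
# weights, backpropagated from one interior output unit; the RF is the row
# extent of the nonzero input gradient
probe_receptive_field <- function(kernels, strides) {
  jumps <- cumprod(c(1, strides[-length(strides)]))
  rf_expect_margin <- 1 + sum((kernels - 1) * jumps) + 2 * prod(strides)
  L <- rf_expect_margin + sum(kernels)   # comfortably larger than any RF here
  layers <- lapply(seq_along(kernels), function(i)
    distgan:::nn_conv2d(1L, 1L, kernels[i], stride = strides[i],
                        pad = as.integer(kernels[i] - 1L)))
  x <- array(rnorm(L * L), c(L, L, 1))
  h <- x
  for (ly in layers) h <- ly$forward(h, train = TRUE)
  d <- dim(h)
  g <- array(0, d)
  g[ceiling(d[1] / 2), ceiling(d[2] / 2), 1] <- 1
  for (ly in rev(layers)) g <- ly$backward(g)
  rows <- which(apply(abs(g) > 1e-12, 1, any))
  max(rows) - min(rows) + 1L
}

# histogram-binned mutual information estimate between two matrices
binned_mi <- function(a, b, bins = 8) {
  qa <- cut(as.vector(a), breaks = unique(quantile(a, 0:bins / bins)),
            include.lowest = TRUE)
  qb <- cut(as.vector(b), breaks = unique(quantile(b, 0:bins / bins)),
            include.lowest = TRUE)
  p <- table(qa, qb) / length(qa)
  px <- rowSums(p); py <- colSums(p)
  keep <- p > 0
  sum((p * log(p / outer(px, py)))[keep])
}

# exhaustive rotation-grid superposition: coarse Euler-angle scan refined
# around the best cell
grid_superpose_rmsd <- function(a, b) {
  a <- scale(a, scale = FALSE); b <- scale(b, scale = FALSE)
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Rz %*% Ry %*% Rx
  }
  eval_rmsd <- function(ang) sqrt(mean(rowSums((a - b %*% t(rot(ang)))^2)))
  best <- c(0, 0, 0); best_v <- Inf
  gr <- seq(-pi, pi, by = 10 * pi / 180)
  for (z in gr) for (y in seq(-pi / 2, pi / 2, by = 10 * pi / 180)) for (x in gr) {
    v <- eval_rmsd(c(z, y, x))
    if (v < best_v) { best_v <- v; best <- c(z, y, x) }
  }
  for (step in c(2, 0.4, 0.08) * pi / 180) {
    repeat {
      improved <- FALSE
      for (k in 1:3) for (s in c(-step, step)) {
        cand <- best; cand[k] <- cand[k] + s
        v <- eval_rmsd(cand)
        if (v < best_v - 1e-12) { best_v <- v; best <- cand; improved <- TRUE }
      }
      if (!improved) break
    }
  }
  best_v
}

# small simulated dataset shared by training-loop tests (built once per run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(4, length = 24, seed = 42,
                                 total_steps = 20000, save_every = 5000)
    }
    cache
  }
})

tiny_gen_cfg <- function(attention = FALSE) {
  generator_config(n_conv_layers = 5L, block_size = 3L, kernel = 3L,
                   channels = 8L, attention = attention)
}

tiny_disc_cfg <- function() {
  patch_disc_config(n_layers = 3L, first_width = 8L)
}
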