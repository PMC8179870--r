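# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorised/compiled code paths: boundaries by explicit
# neighbour loops, distances by all-pairs arithmetic, Dice by index-set
# operations.

rand_mask <- function(dims, p = 0.2, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  repeat {
    v <- array(as.integer(stats::runif(prod(dims)) < p), dims)
    if (sum(v) > 0) break
  }
  label_volume(v, spacing)
}

sphere_mask <- function(dims, center, radius, spacing = c(1, 1, 1)) {
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  d2 <- ((idx[, 1] - center[1]) * spacing[1])^2 +
    ((idx[, 2] - center[2]) * spacing[2])^2 +
    ((idx[, 3] - center[3]) * spacing[3])^2
  label_volume(array(as.integer(d2 <= radius^2), dims), spacing)
}

brute_dice <- function(a, b) {
  ia <- which(as.vector(a$voxels) == 1L)
  ib <- which(as.vector(b$voxels) == 1L)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# explicit-loop 6-neighbour boundary; outside the array counts background
brute_boundary_coords <- function(vol) {
  v <- vol$voxels
  d <- dim(v)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (v[i, j, k] != 1L) next
    nb <- c(
      if (i > 1) v[i - 1, j, k] else 0L, if (i < d[1]) v[i + 1, j, k] else 0L,
      if (j > 1) v[i, j - 1, k] else 0L, if (j < d[2]) v[i, j + 1, k] else 0L,
      if (k > 1) v[i, j, k - 1] else 0L, if (k < d[3]) v[i, j, k + 1] else 0L)
    # degenerate axes (extent 1) contribute no neighbours
    keep <- c(rep(d[1] > 1, 2), rep(d[2] > 1, 2), rep(d[3] > 1, 2))
    if (any(nb[keep] == 0L)) out <- rbind(out, c(i, j, k))
  }
  out
}

brute_directed <- function(ca, cb, spacing) {
  apply(ca, 1, function(p) {
    sqrt(min(colSums((t(cb) - p)^2 * spacing^2)))
  })
}

brute_hd <- function(a, b, spacing = c(1, 1, 1)) {
  ca <- brute_boundary_coords(a)
  cb <- brute_boundary_coords(b)
  max(max(brute_directed(ca, cb, spacing)),
      max(brute_directed(cb, ca, spacing)))
}

brute_ahd <- function(a, b, spacing = c(1, 1, 1)) {
  ca <- brute_boundary_coords(a)
  cb <- brute_boundary_coords(b)
  max(mean(brute_directed(ca, cb, spacing)),
      mean(brute_directed(cb, ca, spacing)))
}

# one-voxel 6-neighbour dilation, loop-based
dilate1 <- function(vol) {
  v <- vol$voxels
  d <- dim(v)
  out <- v
  idx <- which(v == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    if (i > 1) out[i - 1, j, k] <- 1L
    if (i < d[1]) out[i + 1, j, k] <- 1L
    if (j > 1) out[i, j - 1, k] <- 1L
    if (j < d[2]) out[i, j + 1, k] <- 1L
    if (k > 1) out[i, j, k - 1] <- 1L
    if (k < d[3]) out[i, j, k + 1] <- 1L
  }
  label_volume(out, vol$spacing)
}

# independent hand implementation of Holm's step-down rule
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    adj[o[i]] <- running <- min(1, max(running, (m - i + 1) * p[o[i]]))
  }
  adj
}

# scaled-down cohort spec used throughout the tests; coarse anisotropic
# grid keeps per-case volumes ~1e5 voxels
test_spec <- function(n_cases = 2, seed = 7, ...) {
  cohort_spec(n_cases = n_cases, spacing_mm = c(1.5, 1.5, 3),
              seed = seed, ...)
}

uniform_raters <- function(noise_mm = 1, n = 7) {
  r <- default_raters()[seq_len(n), ]
  r$boundary_noise_mm <- noise_mm
  r
}
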