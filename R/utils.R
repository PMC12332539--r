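# Small shared helpers.

# Evaluate `code` with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library functions never perturb user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic scale of a point cloud: median nonzero pairwise distance
# over an evenly spaced subset of rows. Used as the lengthscale prior
# before enough observations exist to fit one.
cloud_scale <- function(coords, max_points = 512L) {
  n <- nrow(coords)
  rows <- if (n > max_points)
    unique(round(seq(1L, n, length.out = max_points)))
  else seq_len(n)
  d <- sqrt(cross_dist2(coords[rows, , drop = FALSE],
                        coords[rows, , drop = FALSE]))
  v <- d[upper.tri(d)]
  v <- v[v > 0]
  if (!length(v)) return(1)
  stats::median(v)
}

# Squared Euclidean cross-distances between rows of A (n x d) and B (m x d).
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A * A); b2 <- rowSums(B * B)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}
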