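# Independent oracles and tiny fixture builders shared across tests.

# Horn's quaternion method for the optimal superposition RMSD: an
# implementation independent of the SVD-based Kabsch code under test.
quaternion_fit_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(X, Y)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(X^2) + sum(Y^2) - 2 * lambda) / n))
}

# Exhaustive double-loop minimum pairwise distance.
brute_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# A small hand-built system: one protein chain with hydrogens plus one
# glycan residue, at explicit coordinates.
make_toy_system <- function() {
  atoms <- data.frame(
    serial = 1:8,
    name = c("N", "CA", "C", "HA", "CA", "O5", "C1", "C2"),
    element = c("N", "C", "C", "H", "C", "O", "C", "C"),
    chain_id = c("A", "A", "A", "A", "A", "A", "A", "A"),
    residue_number = c(295L, 295L, 295L, 295L, 296L, 1L, 1L, 1L),
    insert = "",
    residue_name = c("GLN", "GLN", "GLN", "GLN", "TYR",
                     "NAG", "NAG", "NAG"),
    x = c(0, 1.5, 2.5, 0.5, 4.0, 8.0, 9.0, 10.0),
    y = c(0, 0, 1.0, 1.0, 0, 0, 0, 1.0),
    z = 0,
    stringsAsFactors = FALSE
  )
  molecular_system(atoms)
}

# Random rigid transform (proper rotation + translation).
random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), nrow = 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(coords, rt) {
  sweep(coords %*% t(rt$R), 2, rt$t, `+`)
}

# Small synthetic run shared by several test files (memoised per session).
small_man8_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_trajectory(synthetic_spec(seed = 42,
                                                   n_frames = 120))
    cache
  }
})
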