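# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain loops/sums so they share no code with the
# implementation they check.

# --- tiny structure fixtures ---------------------------------------------

make_structure <- function(xyz, names = NULL, elements = NULL, chain = "A",
                           resno = NULL, resname = "GLY", hetatm = FALSE) {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  structure_model(data.frame(
    serial = seq_len(n),
    name = if (is.null(names)) paste0("C", seq_len(n)) else names,
    element = if (is.null(elements)) rep("C", n) else elements,
    resno = if (is.null(resno)) rep(1L, n) else resno,
    resname = resname, chain = chain, insert = "", hetatm = hetatm,
    stringsAsFactors = FALSE), xyz)
}

random_rotation <- function() {
  # Haar-distributed via QR of a Gaussian matrix
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  d <- diag(qr.R(qr_d))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# --- brute-force geometric oracles ---------------------------------------

oracle_centroid <- function(xyz) {
  out <- numeric(3)
  for (a in 1:3) {
    s <- 0
    for (i in seq_len(nrow(xyz))) s <- s + xyz[i, a]
    out[a] <- s / nrow(xyz)
  }
  out
}

oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

oracle_rmsd <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) s <- s + sum((A[i, ] - B[i, ])^2)
  sqrt(s / nrow(A))
}

# exact per-cell canonical masses of a 1D potential on a q surface binning
oracle_cell_masses <- function(potential, grid, bins) {
  rt <- rt_kcal(potential$temperature)
  out <- matrix(0, grid$n_zones, bins)
  for (z in seq_len(grid$n_zones)) {
    e <- grid$axes[[1L]]$edges[z, ]
    ed <- seq(e[1L], e[2L], length.out = bins + 1L)
    for (i in seq_len(bins)) {
      out[z, i] <- stats::integrate(function(x) {
        exp(-potential$energy(cbind(x)) / rt)
      }, ed[i], ed[i + 1L])$value
    }
  }
  out
}

# --- cached synthetic ensembles ------------------------------------------

.fixture_env <- new.env(parent = emptyenv())

cached_ensemble <- function(n, seed = 401L, key = paste0("ens", n, "_", seed)) {
  if (is.null(.fixture_env[[key]])) {
    gen <- generate_binding_ensemble(
      synthetic_ensemble_spec(n_snapshots = n, seed = seed))
    gen$ensemble <- align_ensemble(gen$ensemble)
    .fixture_env[[key]] <- gen
  }
  .fixture_env[[key]]
}

runit_test <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# weighted mean oracle over an arbitrary per-snapshot statistic
oracle_weighted_mean <- function(x, w) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * x[i]
    den <- den + w[i]
  }
  num / den
}
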