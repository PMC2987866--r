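# shared fixtures and independent oracles for the test suite

# random non-degenerate configuration
rand_config <- function(k, seed, id = paste0("r", seed)) {
  set.seed(seed)
  landmark_config(matrix(rnorm(2 * k), k, 2), id)
}

# apply an arbitrary similarity transform (rotation theta, scale s,
# translation tr) to a configuration's coordinates
similarity_transform <- function(config, theta, s, tr) {
  m <- if (inherits(config, "landmark_config")) config$coords else config
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  out <- s * m %*% R + rep(tr, each = nrow(m))
  dimnames(out) <- list(NULL, c("x", "y"))
  if (inherits(config, "landmark_config")) { config$coords <- out; config } else out
}

# exhaustive grid search over rotation angles for the optimal partial
# Procrustes distance between two configurations (independent of the SVD
# route used by the package)
opa_grid_oracle <- function(a, b, step = 1e-4) {
  Ap <- preshape(if (inherits(a, "landmark_config")) a$coords else a)
  Bp <- preshape(if (inherits(b, "landmark_config")) b$coords else b)
  th <- seq(0, 2 * pi, by = step)
  # ||Ap - Bp R(theta)||^2 = 2 - 2 (c1 cos + c2 sin) for unit preshapes
  M <- crossprod(Bp, Ap)
  c1 <- M[1, 1] + M[2, 2]; c2 <- M[1, 2] - M[2, 1]
  d2 <- 2 - 2 * (c1 * cos(th) + c2 * sin(th))
  i <- which.min(d2)
  list(distance = sqrt(max(0, min(d2))), angle = th[i])
}

# independently assembled thin-plate-spline bordered system, inverted with
# qr.solve rather than solve()
bending_assembly_oracle <- function(P) {
  k <- nrow(P)
  K <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    r2 <- sum((P[i, ] - P[j, ])^2)
    K[i, j] <- if (r2 > 0) r2 * log(r2) else 0
  }
  Q <- cbind(rep(1, k), P[, 1], P[, 2])
  L <- matrix(0, k + 3, k + 3)
  L[1:k, 1:k] <- K
  L[1:k, (k + 1):(k + 3)] <- Q
  L[(k + 1):(k + 3), 1:k] <- t(Q)
  Li <- qr.solve(L)
  Li[1:k, 1:k]
}

# bending energy of heights h over reference P via the TPS interpolation
# fit: solve L [w; a] = [h; 0], energy = w' K h ( = w' K w )
tps_energy_oracle <- function(P, h) {
  k <- nrow(P)
  K <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    r2 <- sum((P[i, ] - P[j, ])^2)
    K[i, j] <- if (r2 > 0) r2 * log(r2) else 0
  }
  Q <- cbind(rep(1, k), P[, 1], P[, 2])
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  wa <- solve(L, c(h, 0, 0, 0))
  w <- wa[1:k]
  as.numeric(t(w) %*% K %*% w)
}

# Mahalanobis distance via an explicitly formed inverse (the package uses
# triangular solves on a Cholesky factor)
mahal_inverse_oracle <- function(W, x, mu) {
  d <- x - mu
  sqrt(as.numeric(t(d) %*% solve(W) %*% d))
}

# a labelled two-species wing dataset with controllable overlap
make_two_species <- function(n_per_species, separation, sigma, seed,
                             k = 11) {
  tpl <- make_template(k, "wing")
  means <- simulate_species_means(tpl, 2, separation, seed = seed)
  d <- simulate_specimens(means, n_per_species, sigma, seed = seed + 1L)
  attr(d, "mean_distance") <- attr(means, "truth")$pairwise_distances[1, 2]
  d
}

# shape_variables stand-in built directly from a score matrix, for testing
# the discriminant machinery in isolation from GPA
fake_shape_variables <- function(scores, kind = "relative_warps") {
  structure(list(scores = scores, basis = NULL,
                 score_center = numeric(ncol(scores)),
                 eigenvalues = apply(scores, 2, stats::var),
                 reference_consensus = NULL,
                 consensus_signature = "fake",
                 kind = kind, keys = rownames(scores) %||% as.character(seq_len(nrow(scores)))),
            class = "shape_variables")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# centroid size of a bare coordinate matrix
.cs_test <- function(m) sqrt(sum(sweep(m, 2, colMeans(m))^2))
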