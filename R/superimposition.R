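#' Centroid size of a configuration
#'
#' The centroid size (CS) is the square root of the summed squared distances
#' from each landmark to the configuration centroid.  It is the standard
#' geometric size measure: translation- and rotation-invariant, and scaling
#' all coordinates by c multiplies CS by c.  CS is expressed in pixels
#' unless `apply_scale = TRUE` and the configuration carries a
#' pixel-to-length scale factor.
#'
#' @param config a [landmark_config()] or a k x 2 coordinate matrix.
#' @param apply_scale multiply by the configuration's `scale_factor`
#'   (default FALSE, i.e. pixel units).
#' @return positive scalar; 0 (with a warning) for a degenerate
#'   configuration whose landmarks all coincide.
#' @examples
#' sq <- landmark_config(cbind(c(1, 1, -1, -1), c(1, -1, -1, 1)), "sq")
#' centroid_size(sq)  # 2 * sqrt(2)
#' @export
centroid_size <- function(config, apply_scale = FALSE) {
  m <- .coords(config)
  cs <- .cs(m)
  if (cs == 0) .warnf("degenerate configuration: all landmarks coincide")
  if (apply_scale && inherits(config, "landmark_config") && !is.null(config$scale_factor))
    cs <- cs * config$scale_factor
  cs
}

#' Preshape of a configuration
#'
#' Centers a configuration at the origin and scales it to unit centroid
#' size, removing position and size while leaving shape (and orientation)
#' untouched.  Idempotent.
#'
#' @inheritParams centroid_size
#' @return for a `landmark_config`, the same object with transformed
#'   coordinates; for a matrix, a matrix.
#' @export
preshape <- function(config) {
  m <- .coords(config)
  cm <- .center(m)
  cs <- sqrt(sum(cm^2))
  if (cs == 0) .stopf("degenerate configuration: centroid size is 0")
  p <- cm / cs
  if (inherits(config, "landmark_config")) { config$coords <- p; config } else p
}

# optimal rotation matrix (det +1, reflections excluded) aligning moving
# preshape B onto target preshape A by right multiplication B %*% R,
# plus the cosine of the Procrustes angle rho
.opt_rotation <- function(A, B) {
  M <- crossprod(B, A)
  sv <- svd(M)
  s <- sign(det(sv$u) * det(sv$v))
  if (s == 0) s <- 1
  R <- sv$u %*% diag(c(1, s)) %*% t(sv$v)
  list(R = R, cos_rho = min(1, max(-1, sv$d[1] + s * sv$d[2])))
}

#' Ordinary Procrustes analysis of two configurations
#'
#' Finds the least-squares optimal similarity transform (rotation,
#' translation and optionally scaling; reflections excluded) mapping
#' `moving` onto `target`.  The reported `distance` is always the partial
#' Procrustes distance between the two unit-size preshapes, i.e. the
#' residual norm after optimal rotation.
#'
#' @param target,moving configurations with the same landmark count.
#' @param allow_scaling estimate the least-squares scale (default FALSE,
#'   in which case `scale` is 1 and `moving` keeps its size).
#' @return a list of class `opa_fit` with elements `rotation` (2 x 2,
#'   det +1), `angle` (radians, counter-clockwise), `scale`, `translation`
#'   (length-2), `aligned` (the transformed `moving`) and `distance`.
#' @export
opa <- function(target, moving, allow_scaling = FALSE) {
  A0 <- .coords(target); B0 <- .coords(moving)
  if (nrow(A0) != nrow(B0))
    .stopf("landmark count mismatch: %d vs %d", nrow(A0), nrow(B0))
  ca <- colMeans(A0); cb <- colMeans(B0)
  Ac <- sweep(A0, 2, ca); Bc <- sweep(B0, 2, cb)
  csa <- sqrt(sum(Ac^2)); csb <- sqrt(sum(Bc^2))
  if (csa == 0 || csb == 0) .stopf("degenerate configuration in opa()")
  Ap <- Ac / csa; Bp <- Bc / csb
  fit <- .opt_rotation(Ap, Bp)
  beta <- if (allow_scaling) fit$cos_rho * csa / csb else 1
  aligned_m <- beta * Bc %*% fit$R + rep(ca, each = nrow(B0))
  dimnames(aligned_m) <- list(NULL, c("x", "y"))
  aligned <- if (inherits(moving, "landmark_config")) {
    moving$coords <- aligned_m; moving
  } else aligned_m
  structure(list(
    rotation = fit$R,
    angle = atan2(fit$R[1, 2], fit$R[1, 1]),
    scale = beta,
    translation = as.vector(ca - beta * cb %*% fit$R),
    aligned = aligned,
    distance = sqrt(sum((Ap - Bp %*% fit$R)^2)),
    cos_rho = fit$cos_rho
  ), class = "opa_fit")
}

#' Generalized Procrustes Analysis
#'
#' Iteratively superimposes all configurations of a dataset: every specimen
#' is reduced to its unit-size preshape, rotated onto the current consensus,
#' and the consensus is re-estimated as the coordinate-wise mean rescaled to
#' unit centroid size, until the consensus change falls below `tol`.  The
#' fixed unit-size convention ("partial Procrustes" fitting) keeps size and
#' shape cleanly separated; `scaling = "full"` instead shrinks each aligned
#' specimen by the cosine of its Procrustes angle to the consensus
#' (full-Procrustes fitting).
#'
#' The iteration is initialized from the preshape of the configuration with
#' the lexicographically smallest digitization key, which makes the fitted
#' orientation deterministic and invariant to input order.
#'
#' @param dataset a [landmark_dataset()] with n >= 2 configurations.
#' @param tol convergence tolerance on the Frobenius change of the
#'   consensus (default 1e-10).
#' @param max_iter maximum number of iterations (default 100).
#' @param scaling `"unit"` (default) or `"full"`.
#' @return an object of class `gpa_fit`: list with `aligned` (k x 2 x n
#'   array of superimposed preshapes), `consensus` (k x 2, centered, unit
#'   CS), `centroid_sizes` (original CS of each specimen, pixel units),
#'   `iterations`, `objective_trace` (nonincreasing sums of squared
#'   deviations from the consensus), `converged`, `keys` and the input
#'   `dataset`.
#' @examples
#' d <- simulate_specimens(list(make_template(6, "polygon")), 10, 0.02, seed = 1)
#' fit <- gpa(d)
#' fit$iterations
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L, scaling = c("unit", "full")) {
  scaling <- match.arg(scaling)
  n <- n_specimens(dataset)
  if (n < 2L) .stopf("gpa needs at least 2 configurations")
  k <- landmark_count(dataset)
  keys <- specimen_keys(dataset)
  cs <- numeric(n)
  P <- vector("list", n)  # unit preshapes, rotated in place
  for (i in seq_len(n)) {
    m <- .center(dataset$configurations[[i]]$coords)
    cs[i] <- sqrt(sum(m^2))
    if (cs[i] == 0) .stopf("degenerate configuration '%s'", keys[i])
    P[[i]] <- m / cs[i]
  }
  beta <- rep(1, n)
  C <- P[[order(keys)[1]]]
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n)) {
      f <- .opt_rotation(C, P[[i]])
      P[[i]] <- P[[i]] %*% f$R
      if (scaling == "full") beta[i] <- max(f$cos_rho, .Machine$double.eps)
    }
    S <- matrix(0, k, 2L)
    for (i in seq_len(n)) S <- S + beta[i] * P[[i]]
    S <- S / n
    csS <- sqrt(sum(.center(S)^2))
    if (csS == 0) .stopf("degenerate consensus (shapes cancel out)")
    Cnew <- .center(S) / csS
    obj <- 0
    for (i in seq_len(n)) obj <- obj + sum((beta[i] * P[[i]] - Cnew)^2)
    trace <- c(trace, obj)
    delta <- sqrt(sum((Cnew - C)^2))
    C <- Cnew
    if (delta < tol) { converged <- TRUE; break }
  }
  # canonical orientation: rotate the whole solution so the consensus
  # principal axis lies along x with a deterministic sign, making the fitted
  # frame independent of how the inputs happened to be oriented (only
  # meaningful for shapes without rotational symmetry; a symmetric shape has
  # no intrinsic orientation)
  svC <- svd(C)
  Vc <- svC$v
  if (det(Vc) < 0) Vc[, 2] <- -Vc[, 2]
  Cs <- C %*% Vc
  f <- sum(Cs[, 1]^3)
  if (abs(f) < 1e-12) f <- sum(Cs[, 2]^3)
  if (f < 0) Vc <- -Vc  # rotate by pi, keeping det +1
  C <- C %*% Vc
  dimnames(C) <- list(NULL, c("x", "y"))
  for (i in seq_len(n)) P[[i]] <- P[[i]] %*% Vc
  # final pass: align every preshape exactly to the converged consensus so
  # the tangency constraints hold to machine precision
  for (i in seq_len(n)) {
    f <- .opt_rotation(C, P[[i]])
    P[[i]] <- P[[i]] %*% f$R
    if (scaling == "full") beta[i] <- max(f$cos_rho, .Machine$double.eps)
  }
  aligned <- array(NA_real_, c(k, 2L, n), dimnames = list(NULL, c("x", "y"), keys))
  for (i in seq_len(n)) aligned[, , i] <- beta[i] * P[[i]]
  if (!converged)
    .warnf("gpa did not converge in %d iterations (last consensus change above tol)", max_iter)
  structure(list(
    aligned = aligned, consensus = C, centroid_sizes = cs,
    iterations = it, objective_trace = trace, converged = converged,
    keys = keys, scaling = scaling, dataset = dataset
  ), class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("<gpa_fit> n = %d, k = %d, %d iteration(s), %sconverged\n",
              dim(x$aligned)[3], nrow(x$consensus), x$iterations,
              if (x$converged) "" else "NOT "))
  cat(sprintf("  final sum of squared deviations: %.6g\n",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Consensus configuration of a GPA fit
#'
#' @param fit a `gpa_fit`.
#' @param id specimen id to give the returned configuration.
#' @return a [landmark_config()] holding the consensus (mean shape).
#' @export
consensus_config <- function(fit, id = "consensus") {
  landmark_config(fit$consensus, id)
}

#' Tangent-space coordinates
#'
#' Residual coordinates produced by GPA lie on a curved manifold (the
#' preshape sphere modulo rotation); for classical multivariate statistics
#' they are orthogonally projected onto the linear tangent plane at the
#' consensus.  Row i is the 2k-vector (x-block then y-block) of specimen i's
#' aligned preshape minus its component along the consensus.  Because
#' alignment also removes position and rotation, the rows span at most
#' 2k - 4 dimensions.
#'
#' @param fit a `gpa_fit`.
#' @return an n x 2k matrix with specimen keys as row names and the
#'   consensus attached as attribute `"consensus"`.
#' @export
tangent_coordinates <- function(fit) {
  n <- dim(fit$aligned)[3]; k <- nrow(fit$consensus)
  cvec <- .vec2(fit$consensus)
  TT <- matrix(NA_real_, n, 2L * k, dimnames = list(fit$keys, NULL))
  for (i in seq_len(n)) {
    x <- .vec2(fit$aligned[, , i])
    x <- x / sqrt(sum(x^2))  # unit preshape (identical to aligned under "unit" scaling)
    TT[i, ] <- x - sum(x * cvec) * cvec
  }
  attr(TT, "consensus") <- fit$consensus
  TT
}

#' Procrustes distance between two configurations
#'
#' Shape distance after removal of position, size and orientation
#' (reflections excluded).  Writing rho for the Procrustes angle between
#' the two unit-size preshapes after optimal rotation: `partial` =
#' 2 sin(rho / 2) (chord on the preshape sphere, the default and the
#' tangent-space-compatible variant), `full` = sin(rho) (residual after
#' additionally shrinking one preshape), `geodesic` = rho.
#'
#' @param a,b configurations with the same landmark count.
#' @param variant `"partial"`, `"full"` or `"geodesic"`.
#' @return nonnegative scalar; 0 iff the shapes are identical.
#' @export
procrustes_distance <- function(a, b, variant = c("partial", "full", "geodesic")) {
  variant <- match.arg(variant)
  A <- .coords(a); B <- .coords(b)
  if (nrow(A) != nrow(B))
    .stopf("landmark count mismatch: %d vs %d", nrow(A), nrow(B))
  Ap <- .center(A); Bp <- .center(B)
  csa <- sqrt(sum(Ap^2)); csb <- sqrt(sum(Bp^2))
  if (csa == 0 || csb == 0) .stopf("degenerate configuration in procrustes_distance()")
  .pdist(Ap / csa, Bp / csb, variant)
}

# distance between unit preshapes; the partial distance is the direct
# residual norm after optimal rotation (numerically exact near zero, unlike
# the sqrt(2 - 2 cos rho) route), and the other variants derive from it:
# geodesic rho = 2 asin(partial / 2), full = sin(rho) = partial cos(rho / 2)
.pdist <- function(Ap, Bp, variant) {
  R <- .opt_rotation(Ap, Bp)$R
  dp <- sqrt(sum((Ap - Bp %*% R)^2))
  switch(variant,
         partial = dp,
         full = dp * sqrt(max(0, 1 - (dp / 2)^2)),
         geodesic = 2 * asin(min(1, dp / 2)))
}

#' Pairwise Procrustes distance matrix
#'
#' All n(n-1)/2 pairwise [procrustes_distance()] values of a dataset.
#'
#' @param dataset a [landmark_dataset()] with n >= 2.
#' @inheritParams procrustes_distance
#' @return a symmetric n x n matrix with zero diagonal, digitization keys
#'   as dimnames, `variant` attached as an attribute, class
#'   `procrustes_dist`.
#' @export
distance_matrix <- function(dataset, variant = c("partial", "full", "geodesic")) {
  variant <- match.arg(variant)
  n <- n_specimens(dataset)
  if (n < 2L) .stopf("distance_matrix needs at least 2 configurations")
  keys <- specimen_keys(dataset)
  P <- lapply(dataset$configurations, function(c) preshape(c$coords))
  D <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d <- .pdist(P[[i]], P[[j]], variant)
    D[i, j] <- d; D[j, i] <- d
  }
  attr(D, "variant") <- variant
  class(D) <- c("procrustes_dist", "matrix")
  D
}

#' Export a distance matrix
#'
#' @param dm a matrix from [distance_matrix()].
#' @param path output path.
#' @param format `"csv"` (square, with header ids) or `"phylip"`
#'   (square PHYLIP-style text).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  m <- unclass(dm); attr(m, "variant") <- NULL
  if (format == "csv") {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- c(sprintf("%d", nrow(m)),
               vapply(seq_len(nrow(m)), function(i)
                 paste(formatC(rownames(m)[i], width = -10),
                       paste(sprintf("%.10f", m[i, ]), collapse = " ")),
                 character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
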