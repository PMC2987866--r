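#' Thin-plate-spline bending-energy basis of a reference configuration
#'
#' Builds the bending-energy matrix of the thin-plate spline anchored on a
#' reference configuration: with kernel U(r) = r^2 log(r^2) (U(0) = 0),
#' the bordered system L = [[K, Q], [Q', 0]] (Q = [1, x, y]) is inverted
#' and the upper k x k block of the inverse is the bending matrix.  Its
#' eigenvectors with positive eigenvalue are the principal warps; the
#' 3-dimensional null space corresponds to affine (zero-bending)
#' deformations, so a triangle (k = 3) has no warp space at all.
#'
#' @param reference a [landmark_config()] or k x 2 matrix; landmarks must
#'   not be collinear.
#' @return an object of class `bending_basis`: list with `bending_matrix`
#'   (k x k symmetric PSD), `principal_warps` (k x (k - 3) orthonormal
#'   eigenvectors, by decreasing eigenvalue), `eigenvalues`,
#'   `zero_space_dim` (3) and `reference`.
#' @export
bending_energy <- function(reference) {
  P <- .coords(reference)
  k <- nrow(P)
  Q <- cbind(1, P)
  if (qr(Q)$rank < 3L)
    .stopf("collinear reference configuration: thin-plate spline system is singular")
  D2 <- as.matrix(dist(P))^2
  K <- matrix(0, k, k)
  pos <- D2 > 0
  K[pos] <- D2[pos] * log(D2[pos])
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Li <- tryCatch(solve(L), error = function(e)
    .stopf("singular thin-plate spline system (coincident or collinear landmarks): %s",
           conditionMessage(e)))
  Be <- Li[seq_len(k), seq_len(k), drop = FALSE]
  Be <- (Be + t(Be)) / 2
  dimnames(Be) <- NULL
  eg <- eigen(Be, symmetric = TRUE)
  vals <- eg$values
  npos <- if (max(vals) < 1e-10) 0L else sum(vals > 1e-8 * max(vals))
  structure(list(
    bending_matrix = Be,
    principal_warps = eg$vectors[, seq_len(npos), drop = FALSE],
    eigenvalues = vals[seq_len(npos)],
    zero_space_dim = k - npos,
    reference = P
  ), class = "bending_basis")
}

#' @export
print.bending_basis <- function(x, ...) {
  cat(sprintf("<bending_basis> k = %d: %d principal warps, null space dim %d\n",
              nrow(x$reference), length(x$eigenvalues), x$zero_space_dim))
  invisible(x)
}

# orthonormal basis (rows, m x 2k) of the tangent space at the consensus,
# split into non-uniform (principal warp) and uniform (affine) parts
.pw_basis <- function(consensus, be) {
  k <- nrow(consensus)
  cx <- consensus[, 1]; cy <- consensus[, 2]
  cvec <- c(cx, cy)
  avec <- c(-cy, cx)  # in-plane rotation generator at the consensus
  zer <- numeric(k)
  E <- be$principal_warps
  nw <- ncol(E)
  B_nu <- matrix(0, 2L * nw, 2L * k)
  if (nw > 0L) for (j in seq_len(nw)) {
    B_nu[2L * j - 1L, ] <- c(E[, j], zer)
    B_nu[2L * j, ] <- c(zer, E[, j])
  }
  # uniform component: orthonormal complement of {consensus, rotation}
  # within the (centered) affine coordinate subspace
  Qo <- qr.Q(qr(cbind(1, cx, cy)))
  qx <- Qo[, 2]; qy <- Qo[, 3]
  U4 <- cbind(c(qx, zer), c(zer, qx), c(qy, zer), c(zer, qy))
  Pm <- cbind(cvec, avec)
  U4r <- U4 - Pm %*% crossprod(Pm, U4)
  sv <- svd(U4r)
  Ub <- sv$u[, sv$d > 1e-8, drop = FALSE]
  if (ncol(Ub) != 2L)
    .stopf("unexpected uniform-subspace dimension %d (degenerate consensus?)", ncol(Ub))
  list(nonuniform = B_nu, uniform = t(Ub), n_warps = nw)
}

#' Partial-warp scores
#'
#' Decomposes the tangent-space residuals of a GPA fit onto the
#' thin-plate-spline principal warps of the consensus (one x and one y
#' score per warp) plus the two-dimensional uniform (affine) component
#' estimated in the orthogonal complement of the bending space.  No
#' bending-energy weighting is applied (weight exponent alpha = 0), so the
#' full score space is an orthonormal rotation of the tangent space:
#' pairwise Euclidean distances between score rows equal tangent-space
#' distances, and downstream Mahalanobis classification is unaffected by
#' the basis choice.
#'
#' With the uniform component included the score matrix has exactly
#' 2k - 4 columns.
#'
#' @param fit a converged `gpa_fit`.
#' @param include_uniform include the 2 uniform scores (default TRUE).
#' @return an object of class `shape_variables` with fields `scores`
#'   (n x m), `basis` (m x 2k orthonormal rows), `score_center` (m zeros
#'   for partial warps), `eigenvalues` (bending eigenvalue of each warp
#'   pair, 0 for the uniform pair), `reference_consensus`, `kind`
#'   (`"partial_warps"`) and `keys`.
#' @export
partial_warps <- function(fit, include_uniform = TRUE) {
  if (!inherits(fit, "gpa_fit")) .stopf("fit must be a gpa_fit")
  C <- fit$consensus
  k <- nrow(C)
  be <- bending_energy(C)
  bas <- .pw_basis(C, be)
  if (!include_uniform && bas$n_warps == 0L)
    .stopf("k = %d leaves no non-uniform warp space; need include_uniform = TRUE or k >= 4", k)
  B <- if (include_uniform) rbind(bas$nonuniform, bas$uniform) else bas$nonuniform
  TT <- tangent_coordinates(fit)
  scores <- TT %*% t(B)
  cn <- if (bas$n_warps > 0L)
    as.vector(rbind(paste0("pw", seq_len(bas$n_warps), "x"),
                    paste0("pw", seq_len(bas$n_warps), "y")))
  else character(0)
  if (include_uniform) cn <- c(cn, "uniX", "uniY")
  dimnames(scores) <- list(fit$keys, cn)
  ev <- rep(be$eigenvalues, each = 2L)
  if (include_uniform) ev <- c(ev, 0, 0)
  structure(list(
    scores = scores, basis = B, score_center = numeric(nrow(B)),
    eigenvalues = ev, reference_consensus = C,
    consensus_signature = .consensus_signature(C),
    kind = "partial_warps", include_uniform = include_uniform,
    keys = fit$keys
  ), class = "shape_variables")
}

#' Relative warps (principal components of partial-warp scores)
#'
#' Principal components of the partial-warp scores (covariance matrix, no
#' bending-energy weighting), ordered by decreasing eigenvalue.  With all
#' axes retained the relative warps are an orthogonal rotation (about the
#' sample mean) of the partial warps, so pairwise distances are preserved.
#'
#' @param pw a `shape_variables` of kind `"partial_warps"`.
#' @param retain number of axes to keep (integer >= 1), or a variance
#'   fraction in (0, 1) meaning "the smallest number of axes explaining at
#'   least this fraction of total variance"; default keeps the full rank.
#' @return a `shape_variables` of kind `"relative_warps"`; `eigenvalues`
#'   are the per-axis variances, with `variance_explained` attached.
#' @export
relative_warps <- function(pw, retain = NULL) {
  if (!inherits(pw, "shape_variables") || pw$kind != "partial_warps")
    .stopf("relative_warps expects partial-warp shape variables")
  S <- pw$scores
  n <- nrow(S)
  ctr <- colMeans(S)
  Sc <- sweep(S, 2L, ctr)
  sv <- svd(Sc)
  rank <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10)
  evals <- sv$d^2 / max(1L, n - 1L)
  r <- if (is.null(retain)) rank
  else if (length(retain) == 1L && retain > 0 && retain < 1)
    which(cumsum(evals) / sum(evals) >= retain)[1]
  else as.integer(retain)
  if (r > rank)
    .stopf("retain = %d exceeds the score-matrix rank %d", r, rank)
  if (r < 1L) .stopf("retain must keep at least one axis")
  V <- sv$v[, seq_len(r), drop = FALSE]
  scores <- Sc %*% V
  dimnames(scores) <- list(pw$keys, paste0("rw", seq_len(r)))
  basis <- t(V) %*% pw$basis
  structure(list(
    scores = scores, basis = basis,
    score_center = as.vector(ctr %*% V),
    eigenvalues = evals[seq_len(r)],
    variance_explained = sum(evals[seq_len(r)]) / sum(evals),
    reference_consensus = pw$reference_consensus,
    consensus_signature = pw$consensus_signature,
    kind = "relative_warps", keys = pw$keys
  ), class = "shape_variables")
}

#' @export
print.shape_variables <- function(x, ...) {
  cat(sprintf("<shape_variables> %s: %d specimens x %d variables\n",
              x$kind, nrow(x$scores), ncol(x$scores)))
  if (x$kind == "relative_warps")
    cat(sprintf("  variance explained: %.1f%%\n", 100 * x$variance_explained))
  invisible(x)
}

#' Subset shape variables by specimen
#'
#' @param x a `shape_variables`.
#' @param i row (specimen) index.
#' @param ... ignored.
#' @return a `shape_variables` restricted to the selected specimens; the
#'   basis and reference consensus are unchanged.
#' @export
`[.shape_variables` <- function(x, i, ...) {
  x$scores <- x$scores[i, , drop = FALSE]
  x$keys <- x$keys[i]
  x
}

#' Combine shape variables computed from the same consensus
#'
#' Shape variables are only comparable when computed relative to the same
#' consensus configuration: adding specimens to an analysis changes the
#' consensus and therefore every score.  Combining score matrices built
#' from different consensuses is a hard error.
#'
#' @param ... `shape_variables` objects sharing kind, basis and consensus.
#' @return a `shape_variables` with the rows concatenated.
#' @export
combine_shape_variables <- function(...) {
  xs <- list(...)
  ref <- xs[[1]]
  for (x in xs[-1]) {
    if (!identical(x$kind, ref$kind))
      .stopf("cannot combine %s with %s scores", x$kind, ref$kind)
    if (!identical(x$consensus_signature, ref$consensus_signature))
      .stopf(paste("cannot combine shape variables computed relative to different",
                   "consensus configurations; re-run GPA on the pooled dataset"))
  }
  ref$scores <- do.call(rbind, lapply(xs, function(x) x$scores))
  ref$keys <- unlist(lapply(xs, function(x) x$keys))
  ref
}

#' Export shape-variable scores
#'
#' Writes the score matrix as CSV (rows = specimens) and, optionally, the
#' basis and eigenvalues as a JSON sidecar.
#'
#' @param sv a `shape_variables`.
#' @param path CSV output path.
#' @param sidecar optional path for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_scores <- function(sv, path, sidecar = NULL) {
  df <- data.frame(specimen = sv$keys, sv$scores, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    jsonlite::write_json(list(kind = sv$kind,
                              eigenvalues = sv$eigenvalues,
                              basis = sv$basis,
                              reference_consensus = sv$reference_consensus),
                         sidecar, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
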