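`%||%` <- function(a, b) if (is.null(a)) b else a

# coordinate matrix of a configuration or a bare matrix
.coords <- function(x) {
  if (inherits(x, "landmark_config")) return(x$coords)
  if (is.matrix(x) && ncol(x) == 2L) return(x)
  stop("expected a landmark_config or a k x 2 coordinate matrix", call. = FALSE)
}

# vec layout used throughout: c(x_1..x_k, y_1..y_k) (column-major)
.vec2 <- function(m) as.vector(m)
.unvec2 <- function(v) matrix(v, ncol = 2L)

.center <- function(m) sweep(m, 2L, colMeans(m), "-")

# centroid size of an already-extracted coordinate matrix
.cs <- function(m) sqrt(sum(.center(m)^2))

# deterministic sub-seed derivation, kept below 2^31
.derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647) + 1L
}

# exact text signature of a consensus configuration, used to guard against
# mixing shape variables computed relative to different consensuses
.consensus_signature <- function(consensus) {
  paste(sprintf("%.15e", consensus), collapse = ",")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
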