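# Internal numeric helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `theta` radians about the (not necessarily unit)
#' 3-vector `axis`, right-handed.
#'
#' @param axis numeric length-3 axis vector.
#' @param theta rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @keywords internal
#' @noRd
rotation_about_axis <- function(axis, theta) {
  u <- unit(axis)
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# Squared Euclidean cross-distance matrix between the rows of A and B.
crossdist2 <- function(A, B) {
  d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# Fold an angular difference (degrees) into the symmetric fundamental
# domain [0, period/2] of a cyclic symmetry.
fold_angle <- function(delta, period) {
  m <- delta %% period
  pmin(m, period - m)
}

# Chain identifier pool: single characters first, then two-character codes.
chain_id_pool <- function(n) {
  singles <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(singles)) return(singles[seq_len(n)])
  doubles <- as.vector(t(outer(singles, singles, paste0)))
  ids <- c(singles, doubles)
  if (n > length(ids)) stop("too many chains requested")
  ids[seq_len(n)]
}
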