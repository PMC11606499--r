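# Shell geometry: capsomere plane fitting, inter-capsomere bend/twist
# angles, cyclic-symmetry-aware superposition RMSD, and shell diameter.

#' Capsomere container
#'
#' One hexamer or pentamer treated as a rigid unit: an ordered set of
#' subunits, each a block of points.  Subunits are kept in cyclic
#' order around the capsomere axis.
#'
#' @param subunit_points list of per-subunit coordinate matrices
#'   (equal row counts).
#' @param chains character vector of subunit chain identifiers.
#' @param kind `"pentamer"`, `"hexamer"`, or `"unknown"` (default:
#'   inferred from the subunit count).
#' @return an object of class `"capsomere"`: list with `kind`,
#'   `chains`, `subunit_count`, `points` (m x 3), `subunit` (integer
#'   block index per row), `centroid`, `subunit_centroids`.
#' @export
capsomere <- function(subunit_points, chains = NULL, kind = NULL) {
  ns <- length(subunit_points)
  if (is.null(kind))
    kind <- switch(as.character(ns), "5" = "pentamer", "6" = "hexamer",
                   "unknown")
  pts <- do.call(rbind, subunit_points)
  sub <- rep(seq_len(ns), vapply(subunit_points, nrow, 0L))
  sc <- t(vapply(subunit_points, colMeans, numeric(3L)))
  structure(list(kind = kind,
                 chains = chains %||% as.character(seq_len(ns)),
                 subunit_count = ns,
                 points = unname(pts), subunit = sub,
                 centroid = colMeans(pts),
                 subunit_centroids = unname(sc)),
            class = "capsomere")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.capsomere <- function(x, ...) {
  cat(sprintf("Capsomere (%s): %d subunits [%s], %d points\n",
              x$kind, x$subunit_count, paste(x$chains, collapse = ","),
              nrow(x$points)))
  invisible(x)
}

#' Least-squares plane through a point set
#'
#' The fitted plane passes through the centroid with normal along the
#' smallest principal component of the centred points.  When a shell
#' centroid is supplied the normal is oriented outward (away from it).
#'
#' @param points m x 3 coordinate matrix (or a [capsomere()], whose
#'   points are used).
#' @param shell_centroid optional length-3 reference for outward
#'   orientation.
#' @return object of class `"fitted_plane"`: list with `point` (the
#'   centroid), `normal` (unit 3-vector) and `rms_residual`
#'   (root-mean-square out-of-plane distance).
#' @examples
#' hexagon <- cbind(cos(0:5 * pi / 3), sin(0:5 * pi / 3), 0)
#' fit_plane(hexagon)$normal
#' @export
fit_plane <- function(points, shell_centroid = NULL) {
  if (inherits(points, "capsomere")) points <- points$points
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("plane fitting needs at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  X <- sweep(points, 2L, ctr)
  sv <- svd(X)
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1e-12))
    stop("degenerate (collinear) point set", call. = FALSE)
  nrm <- sv$v[, 3L]
  if (!is.null(shell_centroid) && sum(nrm * (ctr - shell_centroid)) < 0)
    nrm <- -nrm
  structure(list(point = ctr, normal = nrm,
                 rms_residual = sv$d[3L] / sqrt(nrow(points))),
            class = "fitted_plane")
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a * b %/% gcd2(a, b)

cyclic_phase <- function(V, e1, e2, nsym) {
  th <- atan2(V %*% e2, V %*% e1)
  Arg(sum(exp(1i * nsym * th))) / nsym
}

#' Bend and twist angles between two adjacent capsomeres
#'
#' The bend (alpha) is the angle between the outward fitted-plane
#' normals of the two capsomeres.  The twist (beta) is the residual
#' in-plane rotation of capsomere B's subunit directions after the
#' bend is removed (B's plane rotated onto A's about the interface
#' axis, the normal cross product), measured against the interface
#' direction and folded into the joint rotational-symmetry fundamental
#' domain (period `360 / lcm(nA, nB)` degrees, reported in
#' `[0, period/2]`).  On ideal lattices beta is zero.
#'
#' @param capA,capB [capsomere()] objects.
#' @param shell_centroid optional length-3 shell centre used to orient
#'   both normals outward; without it, B's normal is flipped into A's
#'   hemisphere.
#' @param max_distance optional adjacency check: error when the
#'   centroid distance exceeds it.
#' @return list with `alpha` and `beta` in degrees.
#' @examples
#' fx <- generate_two_capsomere_fixture(alpha = 30, beta = 0)
#' interface_angles(fx$A, fx$B)
#' @export
interface_angles <- function(capA, capB, shell_centroid = NULL,
                             max_distance = NULL) {
  stopifnot(inherits(capA, "capsomere"), inherits(capB, "capsomere"))
  sep <- vnorm(capB$centroid - capA$centroid)
  if (!is.null(max_distance) && sep > max_distance)
    stop(sprintf("capsomeres are not adjacent (centroid distance %.1f > %.1f)",
                 sep, max_distance), call. = FALSE)
  pA <- fit_plane(capA$points, shell_centroid)
  pB <- fit_plane(capB$points, shell_centroid)
  nA <- pA$normal; nB <- pB$normal
  if (is.null(shell_centroid) && sum(nA * nB) < 0) nB <- -nB
  # atan2 form: stable for near-parallel normals (acos amplifies rounding)
  alpha <- rad2deg(atan2(vnorm(cross3(nA, nB)), sum(nA * nB)))

  # interface direction in A's plane
  w <- capB$centroid - capA$centroid
  w_in <- w - sum(w * nA) * nA
  e1 <- unit(w_in)
  e2 <- cross3(nA, e1)

  vA <- sweep(capA$subunit_centroids, 2L, capA$centroid)
  vB <- sweep(capB$subunit_centroids, 2L, capB$centroid)
  if (alpha > 1e-9) {
    axis <- cross3(nB, nA)
    if (vnorm(axis) > 1e-12) {
      Rb <- rotation_about_axis(axis, deg2rad(alpha))
      vB <- vB %*% t(Rb)
    }
  }
  nsA <- capA$subunit_count; nsB <- capB$subunit_count
  phA <- cyclic_phase(vA, e1, e2, nsA)
  phB <- cyclic_phase(vB, e1, e2, nsB)
  period <- 360 / lcm2(nsA, nsB)
  beta <- fold_angle(rad2deg(phB - phA), period)
  list(alpha = alpha, beta = beta)
}

kabsch_rmsd <- function(P, Q) {
  P <- sweep(P, 2L, colMeans(P))
  Q <- sweep(Q, 2L, colMeans(Q))
  H <- crossprod(P, Q)
  sv <- svd(H)
  s <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  sqrt(sum((P %*% R - Q)^2) / nrow(P))
}

#' Superposition RMSD between two capsomeres
#'
#' Least-squares rigid-body (Kabsch, proper rotations only — proteins
#' are chiral) root-mean-square deviation, minimised over the cyclic
#' subunit correspondence: capsomere B's subunit blocks are rotated by
#' every cyclic shift and the best superposition is reported.
#'
#' @param capA,capB [capsomere()] objects with equal subunit counts
#'   and equal points per subunit.
#' @return RMSD in Angstroms.
#' @export
superpose_rmsd <- function(capA, capB) {
  stopifnot(inherits(capA, "capsomere"), inherits(capB, "capsomere"))
  ns <- capA$subunit_count
  if (ns != capB$subunit_count ||
      nrow(capA$points) != nrow(capB$points))
    stop("capsomeres have mismatched point counts", call. = FALSE)
  m <- nrow(capA$points) / ns
  ordB <- order(capB$subunit)
  best <- Inf
  for (t in 0:(ns - 1L)) {
    shifted <- ((capA$subunit - 1L + t) %% ns) + 1L
    idx <- order(shifted)  # stable: preserves intra-subunit point order
    r <- kabsch_rmsd(capA$points[idx, , drop = FALSE],
                     capB$points[ordB, , drop = FALSE])
    best <- min(best, r)
  }
  best
}

#' Shell diameter from capsomere centroids
#'
#' Three measurement conventions: `"diagonal_average"` emulates the
#' micrograph procedure of drawing three diagonals through the centre
#' at 60-degree increments in a (seeded) random projection and
#' averaging their extents; `"circumsphere"` and `"insphere"` return
#' twice the maximal / minimal centroid radius.
#'
#' @param centroids m x 3 matrix of capsomere centroids (m >= 12).
#' @param mode measurement convention.
#' @param seed seed for the random projection of
#'   `"diagonal_average"`; fixed default for reproducibility.
#' @return diameter in the input units.
#' @export
measure_diameter <- function(centroids,
                             mode = c("diagonal_average", "circumsphere",
                                      "insphere"),
                             seed = 42) {
  mode <- match.arg(mode)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 12L)
    stop("diameter measurement needs at least 12 centroids", call. = FALSE)
  ctr <- colMeans(centroids)
  X <- sweep(centroids, 2L, ctr)
  r <- sqrt(rowSums(X^2))
  switch(mode,
    circumsphere = 2 * max(r),
    insphere = 2 * min(r),
    diagonal_average = with_seed(seed, {
      M <- matrix(stats::rnorm(9L), 3L)
      e <- qr.Q(qr(M))[, 1:2]
      th0 <- stats::runif(1L, 0, 2 * pi)
      mean(vapply(th0 + c(0, 2, 4) * pi / 6, function(th) {
        u <- cos(th) * e[, 1L] + sin(th) * e[, 2L]
        p <- X %*% u
        max(p) - min(p)
      }, 0))
    }))
}

#' Adjacency between segmented capsomeres
#'
#' Two capsomeres are neighbours when their centroid distance is at
#' most `factor x spacing`; by default `spacing` is the smallest
#' nearest-neighbour centroid distance of the set, so the rule matches
#' the lattice adjacency rule on ideal shells.
#'
#' @param caps list of [capsomere()] objects.
#' @param spacing reference spacing; default inferred.
#' @param factor cutoff multiplier (default 1.2).
#' @return two-column matrix of capsomere index pairs (`i < j`).
#' @export
capsomere_adjacency <- function(caps, spacing = NULL, factor = 1.2) {
  ctr <- t(vapply(caps, `[[`, numeric(3L), "centroid"))
  d2 <- crossdist2(ctr, ctr)
  diag(d2) <- Inf
  if (is.null(spacing)) spacing <- sqrt(min(d2))
  adj <- which(d2 <= (factor * spacing)^2 & upper.tri(d2), arr.ind = TRUE)
  adj <- adj[order(adj[, 1L], adj[, 2L]), , drop = FALSE]
  colnames(adj) <- c("i", "j")
  adj
}

#' Classify interfaces of segmented capsomeres by symmetry
#'
#' Detects the point group of the capsomere centroid set and partitions
#' the adjacency edges into orbits, exactly as
#' [classify_interfaces()] does for ideal lattices.  With
#' `merge_mirror = NULL` (default) every detected operation is used —
#' improper operations exist only when the arrangement is achiral, so
#' this reproduces the lattice rule.
#'
#' @param caps list of [capsomere()] objects.
#' @param adjacency matrix from [capsomere_adjacency()].
#' @param merge_mirror `NULL` (use all detected operations), `TRUE`
#'   (require improper merging) or `FALSE` (proper rotations only).
#' @param tol positional tolerance for symmetry detection.
#' @return an `"interface_classes"` object (see
#'   [classify_interfaces()]).
#' @export
classify_capsomere_interfaces <- function(caps, adjacency,
                                          merge_mirror = NULL,
                                          tol = NULL) {
  ctr <- t(vapply(caps, `[[`, numeric(3L), "centroid"))
  kind <- vapply(caps, `[[`, "", "kind")
  if (is.null(tol)) {
    d2 <- crossdist2(ctr, ctr); diag(d2) <- Inf
    tol <- 1e-6 * sqrt(min(d2))
  }
  sym <- detect_point_symmetry(ctr, kind, tol)
  use <- if (isFALSE(merge_mirror)) sym$proper
         else rep(TRUE, length(sym$proper))
  build_interface_classes(kind, adjacency, sym$perms[use, , drop = FALSE],
                          merge_mirror %||% any(!sym$proper))
}

#' Per-interface-class angle statistics
#'
#' Computes bend/twist angles for every adjacency edge and aggregates
#' them per interface class (classes ordered as produced by the
#' classification).
#'
#' @param caps list of [capsomere()] objects.
#' @param adjacency two-column edge matrix.
#' @param classes optional `"interface_classes"` object; without it
#'   all edges form one class.
#' @param shell_centroid shell centre for outward normal orientation
#'   (default: mean capsomere centroid).
#' @return list with `edges` (per-edge data frame: `i`, `j`, `class`,
#'   `alpha`, `beta`) and `classes` (per-class data frame with
#'   mean/min/max of both angles).
#' @export
angle_survey <- function(caps, adjacency, classes = NULL,
                         shell_centroid = NULL) {
  if (is.null(shell_centroid))
    shell_centroid <- colMeans(t(vapply(caps, `[[`, numeric(3L), "centroid")))
  lab <- if (is.null(classes)) rep(1L, nrow(adjacency)) else classes$edge_class
  ang <- t(vapply(seq_len(nrow(adjacency)), function(e) {
    ia <- interface_angles(caps[[adjacency[e, 1L]]], caps[[adjacency[e, 2L]]],
                           shell_centroid = shell_centroid)
    c(ia$alpha, ia$beta)
  }, numeric(2L)))
  edges <- data.frame(i = adjacency[, 1L], j = adjacency[, 2L],
                      class = lab, alpha = ang[, 1L], beta = ang[, 2L])
  agg <- do.call(rbind, lapply(sort(unique(lab)), function(l) {
    a <- edges$alpha[lab == l]; b <- edges$beta[lab == l]
    data.frame(class = l, n_edges = sum(lab == l),
               alpha_mean = mean(a), alpha_min = min(a), alpha_max = max(a),
               beta_mean = mean(b), beta_min = min(b), beta_max = max(b))
  }))
  if (!is.null(classes))
    agg$kind <- classes$classes$kind[match(agg$class, classes$classes$label)]
  list(edges = edges, classes = agg)
}
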