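# Caspar-Klug lattice construction.
#
# An icosahedral (h, k) lattice is built by laying a planar hexagonal
# lattice, cutting 20 triangular facets whose corners sit (h, k) lattice
# steps apart, and folding them onto an icosahedron.  A prolate lattice
# inserts a tube of 10 elongated facets, defined by the body indices
# (h', k'), between two pentagonal caps.  The canonical embedding is the
# faceted polyhedron (flat triangular faces); `spherize` optionally
# projects sites onto the circumscribed sphere.

hex_basis <- function(s) {
  cbind(c(s, 0), c(s / 2, s * sqrt(3) / 2))
}

# All hexagonal-lattice points inside (or on the border of) the 2D
# triangle (P1, P2, P3); returns barycentric weights w.r.t. (P2-P1, P3-P1).
hex_points_in_triangle <- function(P1, P2, P3, basis, tol = 1e-9) {
  Binv <- solve(basis)
  lc <- Binv %*% cbind(P1, P2, P3)
  is <- floor(min(lc[1L, ]) - 1):ceiling(max(lc[1L, ]) + 1)
  js <- floor(min(lc[2L, ]) - 1):ceiling(max(lc[2L, ]) + 1)
  ij <- as.matrix(expand.grid(i = is, j = js))
  pts <- t(basis %*% t(ij))                       # n x 2 cartesian
  M <- cbind(P2 - P1, P3 - P1)
  lam <- t(solve(M, t(pts) - P1))                 # n x 2 barycentric
  keep <- lam[, 1L] >= -tol & lam[, 2L] >= -tol &
    (lam[, 1L] + lam[, 2L]) <= 1 + tol
  lam[keep, , drop = FALSE]
}

icosahedron_vertices <- function(edge) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
    c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v * edge / 2
}

icosahedron_faces <- function(verts) {
  edge <- min(dist(verts))
  n <- nrow(verts)
  faces <- list()
  d <- as.matrix(dist(verts))
  adj <- abs(d - edge) < 1e-6 * edge
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (adj[i, j] && adj[j, k] && adj[i, k]) faces[[length(faces) + 1L]] <- c(i, j, k)
  }
  # orient each face counterclockwise as seen from outside
  lapply(faces, function(f) {
    v1 <- verts[f[1L], ]; v2 <- verts[f[2L], ]; v3 <- verts[f[3L], ]
    nrm <- cross3(v2 - v1, v3 - v1)
    if (sum(nrm * (v1 + v2 + v3)) < 0) f <- f[c(1L, 3L, 2L)]
    f
  })
}

# Accumulate per-face lattice points into a deduplicated site list,
# averaging contributing face normals.
collect_sites <- function(face_points, face_normals, tol) {
  pos <- NULL
  nrm <- list()
  for (fi in seq_along(face_points)) {
    P <- face_points[[fi]]
    fn <- face_normals[[fi]]
    for (r in seq_len(nrow(P))) {
      p <- P[r, ]
      idx <- NA_integer_
      if (!is.null(pos)) {
        d2 <- colSums((t(pos) - p)^2)
        m <- which.min(d2)
        if (d2[m] < tol^2) idx <- m
      }
      if (is.na(idx)) {
        pos <- rbind(pos, p)
        nrm[[nrow(pos)]] <- fn
      } else {
        nrm[[idx]] <- rbind(nrm[[idx]], fn)
      }
    }
  }
  normals <- t(vapply(nrm, function(m) {
    if (is.null(dim(m))) unit(m) else unit(colMeans(m))
  }, numeric(3L)))
  list(pos = unname(pos), normals = normals)
}

#' Build a Caspar-Klug shell lattice
#'
#' Constructs the faceted polyhedral embedding of an icosahedral `(h, k)`
#' lattice, or of a prolate `(h, k) / (h', k')` lattice, with one site
#' per capsomere.  Sites coinciding with the 12 polyhedron vertices are
#' pentamers; all others hexamers.  Adjacency connects sites whose
#' centre distance is at most `1.2 x edge_spacing` (separating first
#' from second neighbour shells with a wide margin on ideal lattices).
#' The point-symmetry group of the site set (rotations, plus improper
#' operations when the lattice is achiral) is detected numerically and
#' stored for interface classification.
#'
#' @inheritParams shell_class
#' @param edge_spacing centre-to-centre spacing of adjacent capsomeres
#'   in model units (Angstroms by convention); default 65.
#' @param spherize project sites radially onto the circumscribed sphere
#'   (icosahedral lattices only) instead of keeping the faceted
#'   embedding.  Default `FALSE`.
#' @return an object of class `"shell_lattice"`: a list with `params`
#'   (a [shell_class()]), `edge_spacing`, `sites` (data frame with
#'   columns `site`, `kind`, `x`, `y`, `z`, `nx`, `ny`, `nz`),
#'   `adjacency` (two-column matrix of site index pairs, `i < j`),
#'   `vertices` (the 12 polyhedron vertices), and `symmetry`
#'   (detected operations; see [classify_interfaces()]).
#' @examples
#' lat <- build_lattice(1, 0)
#' nrow(lat$sites)  # 12 pentamers
#' @export
build_lattice <- function(h, k, h_prime = NULL, k_prime = NULL,
                          edge_spacing = 65, spherize = FALSE) {
  sc <- shell_class(h, k, h_prime, k_prime)
  if (!is.numeric(edge_spacing) || edge_spacing <= 0)
    stop("edge_spacing must be positive", call. = FALSE)
  s <- edge_spacing
  tol <- 1e-6 * s

  if (sc$is_prolate) {
    if (spherize)
      stop("spherize is only defined for icosahedral lattices", call. = FALSE)
    geom <- prolate_geometry(sc, s)
  } else {
    geom <- icosahedral_geometry(sc, s)
  }

  got <- collect_sites(geom$face_points, geom$face_normals, tol)
  pos <- got$pos
  normals <- got$normals

  # pentamer = site at a polyhedron vertex
  dv <- crossdist2(pos, geom$vertices)
  kind <- ifelse(apply(dv, 1L, min) < tol^2, "pentamer", "hexamer")

  comp <- predict_composition(sc)
  if (sum(kind == "pentamer") != 12L ||
      sum(kind == "hexamer") != comp$n_hexamers)
    stop(sprintf(
      "lattice construction inconsistent: got %d pentamers / %d hexamers, expected 12 / %d",
      sum(kind == "pentamer"), sum(kind == "hexamer"), comp$n_hexamers))

  # centre at the symmetry centre
  ctr <- colMeans(pos)
  pos <- sweep(pos, 2L, ctr)

  if (spherize) {
    rc <- max(sqrt(rowSums(pos^2)))
    rr <- sqrt(rowSums(pos^2))
    pos <- pos * (rc / rr)
    normals <- pos / rc
  }

  d2 <- crossdist2(pos, pos)
  cut2 <- (1.2 * s)^2
  adj <- which(d2 <= cut2 & upper.tri(d2), arr.ind = TRUE)
  adj <- adj[order(adj[, 1L], adj[, 2L]), , drop = FALSE]
  colnames(adj) <- c("i", "j")

  deg <- tabulate(c(adj), nbins = nrow(pos))
  want <- ifelse(kind == "pentamer", 5L, 6L)
  if (!all(deg == want))
    stop("lattice adjacency inconsistent: site degrees do not match kinds")

  sym <- detect_point_symmetry(pos, kind, tol = tol)

  sites <- data.frame(site = seq_len(nrow(pos)), kind = kind,
                      x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                      nx = normals[, 1L], ny = normals[, 2L],
                      nz = normals[, 3L])
  structure(list(params = sc, edge_spacing = s, spherize = spherize,
                 sites = sites, adjacency = adj,
                 vertices = sweep(geom$vertices, 2L, ctr),
                 symmetry = sym),
            class = "shell_lattice")
}

icosahedral_geometry <- function(sc, s) {
  B2 <- hex_basis(s)
  Cv <- as.vector(B2 %*% c(sc$h, sc$k))
  C3 <- as.vector(rot2(pi / 3) %*% Cv)
  lam <- hex_points_in_triangle(c(0, 0), Cv, C3, B2)
  a <- sqrt(sc$T) * s
  verts <- icosahedron_vertices(a)
  faces <- icosahedron_faces(verts)
  face_points <- vector("list", length(faces))
  face_normals <- vector("list", length(faces))
  for (fi in seq_along(faces)) {
    f <- faces[[fi]]
    V1 <- verts[f[1L], ]; V2 <- verts[f[2L], ]; V3 <- verts[f[3L], ]
    P <- matrix(rep(V1, each = nrow(lam)), ncol = 3L) +
      lam[, 1L] %o% (V2 - V1) + lam[, 2L] %o% (V3 - V1)
    face_points[[fi]] <- P
    face_normals[[fi]] <- unit(cross3(V2 - V1, V3 - V1))
  }
  list(face_points = face_points, face_normals = face_normals,
       vertices = verts)
}

# Prolate body: two regular pentagonal caps joined by a band of 10
# elongated triangles.  The band triangle has one edge equal to the cap
# edge (length |C| = sqrt(T) s) and slant edges |D| and |C - D| where
# D is the 60-degree rotation of the (h', k') lattice vector; its area is
# (sqrt(3)/4) Q s^2.  The two pentamer rings are offset by an azimuthal
# screw angle phi and an axial rise solved from the slant lengths.
prolate_geometry <- function(sc, s) {
  B2 <- hex_basis(s)
  Cv <- as.vector(B2 %*% c(sc$h, sc$k))
  C3 <- as.vector(rot2(pi / 3) %*% Cv)
  Dv <- as.vector(rot2(pi / 3) %*% (B2 %*% c(sc$h_prime, sc$k_prime)))

  a <- sqrt(sc$T) * s
  R5 <- a / (2 * sin(deg2rad(36)))
  dD <- vnorm(Dv); dCD <- vnorm(Cv - Dv)

  # solve (cos72 - 1) cos(phi) + sin72 sin(phi) = K for the screw angle
  A1 <- cos(deg2rad(72)) - 1
  B1 <- sin(deg2rad(72))
  K <- (dD^2 - dCD^2) / (2 * R5^2)
  Rc <- sqrt(A1^2 + B1^2)
  if (abs(K) > Rc)
    stop(sprintf(
      "no prolate embedding exists for (h',k') = (%d,%d): tube shear too large",
      sc$h_prime, sc$k_prime), call. = FALSE)
  delta <- atan2(B1, A1)
  cand <- c(delta + acos(K / Rc), delta - acos(K / Rc)) %% (2 * pi)
  phi <- cand[cand > 1e-9 & cand < deg2rad(72) - 1e-9][1L]
  if (is.na(phi))
    stop("no valid screw angle for the requested prolate lattice", call. = FALSE)
  dz2 <- dD^2 - 2 * R5^2 * (1 - cos(phi))
  if (dz2 <= 0)
    stop(sprintf(
      "no prolate embedding exists for (h',k') = (%d,%d): negative axial rise",
      sc$h_prime, sc$k_prime), call. = FALSE)
  dz <- sqrt(dz2)
  hcap <- sqrt(a^2 - R5^2)

  ang <- function(i) deg2rad(72) * i
  U <- t(vapply(0:4, function(i)
    c(R5 * cos(ang(i)), R5 * sin(ang(i)), dz), numeric(3L)))
  L <- t(vapply(0:4, function(i)
    c(R5 * cos(ang(i) + phi), R5 * sin(ang(i) + phi), 0), numeric(3L)))
  Vt <- c(0, 0, dz + hcap)
  Vb <- c(0, 0, -hcap)
  verts <- rbind(Vt, U, L, Vb)
  axis_mid <- c(0, 0, dz / 2)

  lam_cap <- hex_points_in_triangle(c(0, 0), Cv, C3, B2)
  lam_dn <- hex_points_in_triangle(c(0, 0), Cv, Dv, B2)
  lam_up <- hex_points_in_triangle(Dv, Cv + Dv, Cv, B2)

  face_points <- list()
  face_normals <- list()
  put <- function(V1, V2, V3, lam) {
    P <- matrix(rep(V1, each = nrow(lam)), ncol = 3L) +
      lam[, 1L] %o% (V2 - V1) + lam[, 2L] %o% (V3 - V1)
    nrm <- unit(cross3(V2 - V1, V3 - V1))
    fc <- (V1 + V2 + V3) / 3
    if (sum(nrm * (fc - axis_mid)) < 0) nrm <- -nrm
    face_points[[length(face_points) + 1L]] <<- P
    face_normals[[length(face_normals) + 1L]] <<- nrm
  }
  nxt <- function(i) (i %% 5L) + 1L
  for (i in 1:5) {
    put(Vt, U[i, ], U[nxt(i), ], lam_cap)            # top cap
    put(Vb, L[nxt(i), ], L[i, ], lam_cap)            # bottom cap
    put(U[i, ], U[nxt(i), ], L[i, ], lam_dn)         # band, apex down
    put(L[i, ], L[nxt(i), ], U[nxt(i), ], lam_up)    # band, apex up
  }
  list(face_points = face_points, face_normals = face_normals,
       vertices = verts)
}

#' @export
print.shell_lattice <- function(x, ...) {
  sc <- x$params
  cat(sprintf(
    "Shell lattice T = %d%s: %d sites (%d pentamers, %d hexamers), %d edges\n",
    sc$T, if (!is.null(sc$Q) && sc$is_prolate) sprintf(" Q = %d", sc$Q) else "",
    nrow(x$sites), sum(x$sites$kind == "pentamer"),
    sum(x$sites$kind == "hexamer"), nrow(x$adjacency)))
  cat(sprintf("  edge spacing %.3g, %s embedding, symmetry order %d (%d proper)\n",
              x$edge_spacing, if (x$spherize) "spherized" else "faceted",
              length(x$symmetry$ops), sum(x$symmetry$proper)))
  invisible(x)
}
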