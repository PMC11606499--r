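# Point-group detection and symmetry-orbit classification of interfaces.
#
# The point group of a site set is recovered numerically: an orthogonal
# candidate operation is determined by the images of three affinely
# independent reference sites, with candidates pruned by conserved
# invariants (site kind, distance from the centre, pairwise distances),
# then accepted only if it permutes the full site set kind-preservingly.
# This recovers the 60 proper icosahedral rotations, the 120-element
# full group on achiral lattices (improper operations included), and
# the smaller dihedral groups of prolate lattices, without assuming any
# particular group in advance.

#' Detect the point-symmetry group of a labelled point set
#'
#' @param pos n x 3 matrix of positions (centred internally).
#' @param kind character vector of site kinds, length n.
#' @param tol positional tolerance in the same units as `pos`.
#' @return a list with `ops` (list of 3x3 orthogonal matrices), `perms`
#'   (matrix, one row per op, the induced site permutation), and
#'   `proper` (logical, `det > 0`).
#' @keywords internal
detect_point_symmetry <- function(pos, kind, tol) {
  n <- nrow(pos)
  ctr <- colMeans(pos)
  P <- sweep(pos, 2L, ctr)
  r <- sqrt(rowSums(P^2))

  same_shell <- function(i) which(kind == kind[i] & abs(r - r[i]) < 4 * tol)

  # reference triple: prefer the rarest (kind, radius) shells to keep the
  # candidate count small; require linear independence.
  ord <- order(vapply(seq_len(n), function(i) length(same_shell(i)), 0L))
  s1 <- ord[1L]
  s2 <- NA_integer_; s3 <- NA_integer_
  for (i in ord[-1L]) {
    if (vnorm(cross3(P[s1, ], P[i, ])) > 0.05 * r[s1] * r[i]) { s2 <- i; break }
  }
  for (i in ord) {
    if (i %in% c(s1, s2)) next
    if (abs(det(cbind(P[s1, ], P[s2, ], P[i, ]))) >
        0.02 * r[s1] * r[s2] * r[i]) { s3 <- i; break }
  }
  if (is.na(s2) || is.na(s3))
    stop("degenerate site set: no independent reference triple")

  d12 <- vnorm(P[s1, ] - P[s2, ]); d13 <- vnorm(P[s1, ] - P[s3, ])
  d23 <- vnorm(P[s2, ] - P[s3, ])
  S <- cbind(P[s1, ], P[s2, ], P[s3, ])
  Sinv <- solve(S)

  ops <- list(); perms <- NULL; proper <- logical(0)
  seen <- character(0)
  c1 <- same_shell(s1)
  for (t1 in c1) {
    c2 <- same_shell(s2)
    c2 <- c2[abs(sqrt(colSums((t(P[c2, , drop = FALSE]) - P[t1, ])^2)) - d12) < 4 * tol]
    for (t2 in c2) {
      c3 <- same_shell(s3)
      keep <- abs(sqrt(colSums((t(P[c3, , drop = FALSE]) - P[t1, ])^2)) - d13) < 4 * tol &
        abs(sqrt(colSums((t(P[c3, , drop = FALSE]) - P[t2, ])^2)) - d23) < 4 * tol
      for (t3 in c3[keep]) {
        M <- cbind(P[t1, ], P[t2, ], P[t3, ]) %*% Sinv
        if (max(abs(crossprod(M) - diag(3L))) > 1e-6) next
        key <- paste(round(M * 1e6), collapse = ",")
        if (key %in% seen) next
        # does M permute the site set, preserving kinds?
        Q <- P %*% t(M)
        D2 <- crossdist2(Q, P)
        pm <- max.col(-D2)
        ok <- all(D2[cbind(seq_len(n), pm)] < (4 * tol)^2) &&
          !anyDuplicated(pm) && all(kind[pm] == kind)
        if (!ok) next
        seen <- c(seen, key)
        ops[[length(ops) + 1L]] <- M
        perms <- rbind(perms, pm)
        proper <- c(proper, det(M) > 0)
      }
    }
  }
  rownames(perms) <- NULL
  list(ops = ops, perms = perms, proper = proper, centre = ctr)
}

# Union-find over edge orbits induced by site permutations.
edge_orbits <- function(adjacency, perms) {
  ne <- nrow(adjacency)
  key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  idx <- structure(seq_len(ne), names = key(adjacency[, 1L], adjacency[, 2L]))
  parent <- seq_len(ne)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (p in seq_len(nrow(perms))) {
    pm <- perms[p, ]
    mi <- pm[adjacency[, 1L]]; mj <- pm[adjacency[, 2L]]
    tgt <- idx[key(mi, mj)]
    if (anyNA(tgt))
      stop("symmetry operation does not permute the adjacency set; lattice inconsistent")
    for (e in seq_len(ne)) {
      a <- find(e); b <- find(tgt[e])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(ne), find, 0L)
}

#' Classify capsomere-capsomere interfaces into symmetry orbits
#'
#' Partitions the adjacency edges of a lattice into orbits under the
#' detected point group.  With `merge_mirror = TRUE` improper
#' operations (available only when the site set is achiral) are used as
#' well, merging mirror-related orbits.  The default follows the
#' lattice chirality: mirror merging on for achiral lattices
#' (`k = 0` or `h = k`), off for chiral ones.
#'
#' Classes are ordered pentamer-involving first, then hexamer-hexamer,
#' by decreasing orbit size, ties broken by the lexicographically
#' smallest representative edge.
#'
#' @param lattice a [build_lattice()] result.
#' @param merge_mirror logical; merge mirror-related orbits.  Default
#'   `NULL` = follow lattice chirality.
#' @return an object of class `"interface_classes"`: list with
#'   `classes` (data frame: `label`, `kind`, `orbit_size`, `rep_i`,
#'   `rep_j`), `edge_class` (integer class label per adjacency row),
#'   `n_ops` (group order used), and `merge_mirror`.
#' @examples
#' cls <- classify_interfaces(build_lattice(1, 0))
#' nrow(cls$classes)  # 1: all 30 pentamer-pentamer edges equivalent
#' @export
classify_interfaces <- function(lattice, merge_mirror = NULL) {
  stopifnot(inherits(lattice, "shell_lattice"))
  if (is.null(merge_mirror)) merge_mirror <- lattice$params$achiral
  sym <- lattice$symmetry
  use <- if (merge_mirror) rep(TRUE, length(sym$proper)) else sym$proper
  perms <- sym$perms[use, , drop = FALSE]
  build_interface_classes(lattice$sites$kind, lattice$adjacency, perms,
                          merge_mirror)
}

build_interface_classes <- function(kind, adjacency, perms, merge_mirror) {
  rep_orbit <- edge_orbits(adjacency, perms)
  labs <- unique(rep_orbit)
  ka <- kind[adjacency[, 1L]]; kb <- kind[adjacency[, 2L]]
  ekind <- ifelse(ka == "hexamer" & kb == "hexamer", "hexamer-hexamer",
                  ifelse(ka == "pentamer" & kb == "pentamer",
                         "pentamer-pentamer", "pentamer-hexamer"))
  cls <- lapply(labs, function(l) {
    rows <- which(rep_orbit == l)
    reps <- adjacency[rows, , drop = FALSE]
    reps <- reps[order(reps[, 1L], reps[, 2L]), , drop = FALSE]
    list(kind = ekind[rows[1L]], orbit_size = length(rows),
         rep_i = reps[1L, 1L], rep_j = reps[1L, 2L], orbit = l)
  })
  kind_rank <- vapply(cls, function(x)
    if (x$kind == "hexamer-hexamer") 2L else 1L, 0L)
  o <- order(kind_rank,
             -vapply(cls, `[[`, 0L, "orbit_size"),
             vapply(cls, `[[`, 0L, "rep_i"),
             vapply(cls, `[[`, 0L, "rep_j"))
  cls <- cls[o]
  classes <- data.frame(
    label = seq_along(cls),
    kind = vapply(cls, `[[`, "", "kind"),
    orbit_size = vapply(cls, `[[`, 0L, "orbit_size"),
    rep_i = vapply(cls, `[[`, 0L, "rep_i"),
    rep_j = vapply(cls, `[[`, 0L, "rep_j"))
  relab <- integer(max(rep_orbit))
  relab[vapply(cls, `[[`, 0L, "orbit")] <- seq_along(cls)
  structure(list(classes = classes, edge_class = relab[rep_orbit],
                 n_ops = nrow(perms), merge_mirror = merge_mirror),
            class = "interface_classes")
}

#' @export
print.interface_classes <- function(x, ...) {
  cat(sprintf("%d interface class(es) under a %d-operation group%s\n",
              nrow(x$classes), x$n_ops,
              if (x$merge_mirror) " (mirror-merged)" else ""))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Asymmetric unit of an icosahedral lattice
#'
#' Returns one representative site per orbit of the 60-element rotation
#' group, with fractional occupancy `orbit_size / 60`.  The pentamer
#' orbit (12 sites, occupancy 1/5) corresponds to one pentamer subunit
#' per asymmetric unit; hexamer occupancies sum to `10(T - 1) / 60`
#' hexamer equivalents (whole hexamers when T is of the 60-site-orbit
#' kind, e.g. 3 for T = 19; fractional otherwise, e.g. 2.5 for T = 16).
#'
#' @param lattice an icosahedral [build_lattice()] result.
#' @return data frame of representative sites (`site`, `kind`,
#'   `orbit_size`, `occupancy`) with attributes
#'   `n_hexamer_equivalents` and `n_pentamer_subunits`.
#' @export
asymmetric_unit <- function(lattice) {
  stopifnot(inherits(lattice, "shell_lattice"))
  if (lattice$params$is_prolate)
    stop("asymmetric_unit is defined for icosahedral lattices", call. = FALSE)
  sym <- lattice$symmetry
  perms <- sym$perms[sym$proper, , drop = FALSE]
  g <- nrow(perms)
  n <- ncol(perms)
  orbit <- integer(n)
  nextlab <- 0L
  for (i in seq_len(n)) {
    if (orbit[i] == 0L) {
      nextlab <- nextlab + 1L
      orbit[unique(perms[, i])] <- nextlab
    }
  }
  reps <- vapply(seq_len(nextlab), function(l) min(which(orbit == l)), 0L)
  sizes <- tabulate(orbit, nextlab)
  out <- data.frame(site = reps, kind = lattice$sites$kind[reps],
                    orbit_size = sizes, occupancy = sizes / g)
  out <- out[order(out$kind, out$site), ]
  rownames(out) <- NULL
  attr(out, "n_hexamer_equivalents") <-
    sum(out$occupancy[out$kind == "hexamer"])
  attr(out, "n_pentamer_subunits") <-
    sum(out$occupancy[out$kind == "pentamer"]) * 5
  out
}
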