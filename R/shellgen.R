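# Synthetic-data generator: pseudo-atomic shells on Caspar-Klug
# lattices and linker sequences with planted [IV][TS]G motifs, each
# with a ground-truth manifest so downstream stages are testable
# without deposited structures.

#' Pseudo-atomic capsomere template
#'
#' A hexamer or pentamer built from `n` identical wedge-shaped subunits
#' of 7 pseudo-atoms each: one inner point, two mid-ring points, three
#' outer-ring points and one slightly out-of-plane apex.  The wedge is
#' wide enough that adjacent subunits come within ~2 Angstroms of each
#' other (so subunit clustering sees one connected capsomere) while
#' remaining well inside the capsomere footprint.
#'
#' @param kind `"pentamer"` or `"hexamer"`.
#' @param ring_radius outer capsomere radius in Angstroms.
#' @return list of per-subunit 7 x 3 coordinate matrices in the local
#'   frame (capsomere centre at the origin, outward normal +z, subunit 1
#'   centred on +x).
#' @export
capsomere_template <- function(kind = c("hexamer", "pentamer"),
                               ring_radius = 24) {
  kind <- match.arg(kind)
  n <- if (kind == "hexamer") 6L else 5L
  w <- 2 * pi / n
  r <- ring_radius
  lapply(seq_len(n) - 1L, function(s) {
    g <- s * w
    polar <- rbind(
      c(0.30, 0, 0),
      c(0.65, -0.30, 0), c(0.65, 0.30, 0),
      c(0.95, -0.46, 0), c(0.95, 0.46, 0),
      c(0.95, 0, 0),
      c(0.55, 0, 0.15))
    ang <- g + polar[, 2L] * w
    cbind(r * polar[, 1L] * cos(ang),
          r * polar[, 1L] * sin(ang),
          r * polar[, 3L])
  })
}

# Canonical in-plane reference direction of a lattice site: the
# C_n-phase mean of its (projected) neighbour directions.  This choice
# commutes with every lattice symmetry operation, so capsomere
# orientations placed along it are symmetry-covariant and per-class
# angle dispersion on ideal shells is zero to machine precision.
site_phase_direction <- function(p, nrm, neighbours, nsym) {
  e1 <- if (abs(nrm[3L]) < 0.9) unit(cross3(nrm, c(0, 0, 1)))
        else unit(cross3(nrm, c(1, 0, 0)))
  e2 <- cross3(nrm, e1)
  th <- apply(neighbours, 1L, function(q) {
    d <- q - p
    atan2(sum(d * e2), sum(d * e1))
  })
  psi <- Arg(sum(exp(1i * nsym * th))) / nsym
  unit(cos(psi) * e1 + sin(psi) * e2)
}

#' Generate a synthetic shell model with ground truth
#'
#' Places a pseudo-atomic capsomere template on every site of the
#' requested Caspar-Klug lattice, one chain per subunit, orients each
#' capsomere along the symmetry-covariant phase of its neighbour
#' directions, and (optionally) perturbs every coordinate with
#' isotropic Gaussian noise.  The returned manifest records the true
#' capsomere membership, kinds, interface classes and per-interface
#' bend/twist angles, making the model a self-oracle for segmentation
#' and geometry code.
#'
#' @inheritParams build_lattice
#' @param noise_sigma isotropic coordinate noise (Angstroms).  A value
#'   above `0.1 x edge_spacing` warns; above `0.25 x edge_spacing`
#'   errors (adjacency would become ambiguous).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param ring_radius outer capsomere radius; default
#'   `0.38 x edge_spacing`.
#' @param pentamer_scale radius scale of pentamers relative to
#'   hexamers; default 0.85.
#' @param merge_mirror passed to [classify_interfaces()] for the
#'   manifest classes.
#' @return an object of class `"synthetic_shell"`: list with `atoms`
#'   (atom-record data frame, see [read_structure()]), `manifest`
#'   (list: `sites`, `edges`, `classes`, `seed`, `spec`), and
#'   `lattice`.
#' @examples
#' sh <- generate_shell(1, 0, seed = 7)
#' length(unique(sh$atoms$chain))  # 60 subunit chains
#' @export
generate_shell <- function(h, k, h_prime = NULL, k_prime = NULL,
                           edge_spacing = 65, noise_sigma = 0, seed = 1,
                           ring_radius = 0.38 * edge_spacing,
                           pentamer_scale = 0.85, spherize = FALSE,
                           merge_mirror = NULL) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (noise_sigma > 0.25 * edge_spacing)
    stop("noise_sigma > 0.25 x edge_spacing: adjacency would be ambiguous",
         call. = FALSE)
  if (noise_sigma > 0.10 * edge_spacing)
    warning("noise_sigma > 0.1 x edge_spacing: segmentation may be unreliable")

  lat <- build_lattice(h, k, h_prime, k_prime, edge_spacing, spherize)
  sites <- lat$sites
  pos <- as.matrix(sites[, c("x", "y", "z")])
  nrm <- as.matrix(sites[, c("nx", "ny", "nz")])
  nsite <- nrow(sites)
  nsub_site <- ifelse(sites$kind == "pentamer", 5L, 6L)
  chains <- chain_id_pool(sum(nsub_site))

  tmpl <- list(hexamer = capsomere_template("hexamer", ring_radius),
               pentamer = capsomere_template("pentamer",
                                             ring_radius * pentamer_scale))

  caps <- vector("list", nsite)
  atom_list <- vector("list", nsite)
  chain_of_site <- vector("list", nsite)
  ci <- 0L
  for (i in seq_len(nsite)) {
    kind <- sites$kind[i]
    nsym <- nsub_site[i]
    nb <- lat$adjacency[lat$adjacency[, 1L] == i | lat$adjacency[, 2L] == i, ,
                        drop = FALSE]
    nb_idx <- setdiff(as.vector(nb), i)
    e1 <- site_phase_direction(pos[i, ], nrm[i, ], pos[nb_idx, , drop = FALSE],
                               nsym)
    e2 <- cross3(nrm[i, ], e1)
    Rf <- cbind(e1, e2, nrm[i, ])
    sub_pts <- lapply(tmpl[[kind]], function(m)
      sweep(m %*% t(Rf), 2L, pos[i, ], "+"))
    sub_chains <- chains[ci + seq_len(nsym)]
    ci <- ci + nsym
    chain_of_site[[i]] <- sub_chains
    caps[[i]] <- capsomere(sub_pts, chains = sub_chains, kind = kind)
    atom_list[[i]] <- do.call(rbind, lapply(seq_len(nsym), function(s) {
      m <- sub_pts[[s]]
      data.frame(chain = sub_chains[s], resid = seq_len(nrow(m)),
                 resname = "UNK", atom = "CA", element = "C",
                 x = m[, 1L], y = m[, 2L], z = m[, 3L],
                 occ = 1, b = 0)
    }))
  }
  atoms <- do.call(rbind, atom_list)
  rownames(atoms) <- NULL

  cls <- classify_interfaces(lat, merge_mirror)
  edges <- as.data.frame(lat$adjacency)
  edges$class <- cls$edge_class
  ang <- t(vapply(seq_len(nrow(edges)), function(e) {
    ia <- interface_angles(caps[[edges$i[e]]], caps[[edges$j[e]]],
                           shell_centroid = c(0, 0, 0))
    c(ia$alpha, ia$beta)
  }, numeric(2L)))
  edges$alpha_true <- ang[, 1L]
  edges$beta_true <- ang[, 2L]

  if (noise_sigma > 0) {
    atoms[, c("x", "y", "z")] <- with_seed(seed, {
      as.matrix(atoms[, c("x", "y", "z")]) +
        matrix(stats::rnorm(3L * nrow(atoms), sd = noise_sigma),
               ncol = 3L)
    })
  }

  manifest <- list(
    sites = data.frame(site = sites$site, kind = sites$kind,
                       x = sites$x, y = sites$y, z = sites$z,
                       chains = vapply(chain_of_site, paste, "",
                                       collapse = ",")),
    edges = edges,
    classes = cls$classes,
    seed = seed,
    spec = list(h = lat$params$h, k = lat$params$k,
                h_prime = lat$params$h_prime, k_prime = lat$params$k_prime,
                edge_spacing = edge_spacing, noise_sigma = noise_sigma,
                ring_radius = ring_radius, pentamer_scale = pentamer_scale,
                spherize = spherize))
  structure(list(atoms = atoms, manifest = manifest, lattice = lat),
            class = "synthetic_shell")
}

#' @export
print.synthetic_shell <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "Synthetic shell: %d capsomeres (%d pentamers, %d hexamers), %d atoms, noise %.3g A, seed %d\n",
    nrow(m$sites), sum(m$sites$kind == "pentamer"),
    sum(m$sites$kind == "hexamer"), nrow(x$atoms), m$spec$noise_sigma,
    m$seed))
  invisible(x)
}

#' Two-capsomere fixture with known bend and twist
#'
#' Builds a pair of capsomeres whose fitted-plane bend (alpha) and
#' in-plane twist (beta) equal the requested values by construction:
#' capsomere A lies in the z = 0 plane with subunit 1 pointing along
#' the interface direction (+x); capsomere B is twisted by `beta`
#' about its normal, bent by `alpha` about the interface axis (y), and
#' placed `spacing` Angstroms along +x.
#'
#' @param kindA,kindB capsomere kinds.
#' @param alpha bend angle in degrees, `0 <= alpha < 90`.
#' @param beta twist angle in degrees (recovered in the symmetry
#'   fundamental domain).
#' @param spacing centre-to-centre distance in Angstroms.
#' @param ring_radius capsomere radius.
#' @param noise_sigma optional isotropic coordinate noise.
#' @param seed seed for the noise stream.
#' @return list with capsomeres `A` and `B` and an `atoms` data frame.
#' @examples
#' fx <- generate_two_capsomere_fixture(alpha = 30)
#' interface_angles(fx$A, fx$B)$alpha
#' @export
generate_two_capsomere_fixture <- function(kindA = "hexamer",
                                           kindB = "hexamer",
                                           alpha = 0, beta = 0,
                                           spacing = 65, ring_radius = 24,
                                           noise_sigma = 0, seed = 1) {
  if (alpha < 0 || alpha >= 90)
    stop("alpha must satisfy 0 <= alpha < 90", call. = FALSE)
  tA <- capsomere_template(kindA, ring_radius)
  tB <- capsomere_template(kindB, ring_radius)
  Rtwist <- rotation_about_axis(c(0, 0, 1), deg2rad(beta))
  Rbend <- rotation_about_axis(c(0, 1, 0), deg2rad(alpha))
  shift <- c(spacing, 0, 0)
  ptsA <- tA
  ptsB <- lapply(tB, function(m)
    sweep(m %*% t(Rtwist) %*% t(Rbend), 2L, shift, "+"))
  if (noise_sigma > 0) {
    pts <- with_seed(seed, {
      lapply(c(ptsA, ptsB), function(m)
        m + matrix(stats::rnorm(length(m), sd = noise_sigma), ncol = 3L))
    })
    ptsA <- pts[seq_along(ptsA)]
    ptsB <- pts[length(ptsA) + seq_along(ptsB)]
  }
  nA <- length(ptsA)
  chA <- chain_id_pool(nA + length(ptsB))
  A <- capsomere(ptsA, chains = chA[seq_len(nA)], kind = kindA)
  B <- capsomere(ptsB, chains = chA[nA + seq_along(ptsB)], kind = kindB)
  atoms <- rbind(capsomere_atoms(A), capsomere_atoms(B))
  list(A = A, B = B, atoms = atoms,
       truth = list(alpha = alpha, beta = beta, spacing = spacing))
}

capsomere_atoms <- function(cap) {
  do.call(rbind, lapply(seq_len(cap$subunit_count), function(s) {
    m <- cap$points[cap$subunit == s, , drop = FALSE]
    data.frame(chain = cap$chains[s], resid = seq_len(nrow(m)),
               resname = "UNK", atom = "CA", element = "C",
               x = m[, 1L], y = m[, 2L], z = m[, 3L], occ = 1, b = 0)
  }))
}

aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Generate a synthetic linker sequence with planted [IV][TS]G motifs
#'
#' Draws a random amino-acid background, plants tripeptide motifs
#' matching `[IV][TS]G` at the requested 1-based positions, and then
#' removes any accidental matches elsewhere by rejection resampling of
#' background residues, so the planted positions are exactly the true
#' motif positions.
#'
#' @param length sequence length in residues.
#' @param motif_positions integer vector of 1-based start positions;
#'   planted motifs must not overlap and must fit within `length`.
#' @param motif_choices optional character vector (recycled) of
#'   triplets to plant; each must match `[IV][TS]G`.  Default: random
#'   draws from the 4 matching triplets.
#' @param seed integer seed.
#' @return list with `sequence` (single string) and `manifest`
#'   (positions, triplets, seed).
#' @examples
#' lk <- generate_linker(60, c(5, 20, 41), seed = 3)
#' scan_motifs(lk$sequence)
#' @export
generate_linker <- function(length, motif_positions = integer(0),
                            motif_choices = NULL, seed = 1) {
  length <- check_count(length, "length", min = 1L)
  pos <- sort(as.integer(motif_positions))
  if (any(pos < 1L | pos + 2L > length))
    stop("motif positions must fit within the sequence", call. = FALSE)
  if (any(diff(pos) < 3L))
    stop("planted motifs must not overlap", call. = FALSE)
  all_triplets <- as.vector(outer(c("I", "V"),
                                  paste0(c("T", "S"), "G"), paste0))
  if (!is.null(motif_choices)) {
    if (!all(motif_choices %in% all_triplets))
      stop("every planted triplet must match [IV][TS]G", call. = FALSE)
    triplets <- rep_len(motif_choices, base::length(pos))
  }
  with_seed(seed, {
    if (is.null(motif_choices))
      triplets <- sample(all_triplets, base::length(pos), replace = TRUE)
    sq <- sample(aa_alphabet(), length, replace = TRUE)
    planted <- logical(length)
    for (m in seq_along(pos)) {
      sq[pos[m] + 0:2] <- strsplit(triplets[m], "")[[1L]]
      planted[pos[m] + 0:2] <- TRUE
    }
    repeat {
      hits <- motif_positions_in(paste(sq, collapse = ""))
      bad <- setdiff(hits, pos)
      if (!base::length(bad)) break
      for (b in bad) {
        free <- (b + 0:2)[!planted[b + 0:2]]
        j <- free[1L]
        cls <- switch(as.character(j - b + 1L),
                      "1" = c("I", "V"), "2" = c("T", "S"), "3" = "G")
        sq[j] <- sample(setdiff(aa_alphabet(), cls), 1L)
      }
    }
    list(sequence = paste(sq, collapse = ""),
         manifest = list(length = length, positions = pos,
                         triplets = triplets, seed = seed))
  })
}
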