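# Independent oracles and fixture builders used across the suite.

# Quadratic all-pairs enumeration: the reference for any accelerated
# neighbour search.
brute_force_pairs <- function(A, B, cutoff) {
  A <- as.matrix(A); B <- as.matrix(B)
  out <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d <= cutoff) out <- rbind(out, c(i, j, d))
  }
  if (is.null(out))
    return(data.frame(i = integer(0), j = integer(0), distance = numeric(0)))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  data.frame(i = as.integer(out[, 1]), j = as.integer(out[, 2]),
             distance = out[, 3])
}

# Character-by-character sliding window: the reference motif scanner.
naive_motif_scan <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(ch)
  if (n < 3) return(integer(0))
  which(vapply(seq_len(n - 2), function(i) {
    ch[i] %in% c("I", "V") && ch[i + 1] %in% c("T", "S") && ch[i + 2] == "G"
  }, TRUE))
}

# Closed-form buried area of two overlapping solvent spheres
# (spherical caps), radii R1/R2 = vdw + probe, centre distance d.
two_sphere_buried_analytic <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(0)
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  2 * pi * R1 * (R1 - x1) + 2 * pi * R2 * (R2 - x2)
}

# Quick builder for atom-record rows.
mk_atoms <- function(chain, resid, resname, atom, element, x, y = 0, z = 0) {
  data.frame(chain = chain, resid = resid, resname = resname, atom = atom,
             element = element, x = x, y = y, z = z, occ = 1, b = 0)
}

# Two-subunit micro-fixture with exactly 2 planted hydrogen bonds and
# 1 planted salt bridge across chains A/B (the salt bridge is placed
# beyond the hydrogen-bond cutoff so the two record types are
# disjoint); all other atoms are beyond contact range.
contact_microfixture <- function() {
  a <- rbind(
    mk_atoms("A", 29, "LYS", "NZ", "N", 0, 0, 0),       # hbond 1 donor
    mk_atoms("A", 83, "ARG", "NE", "N", 20, 0, 0),      # hbond 2 donor
    mk_atoms("A", 83, "ARG", "NH1", "N", 40, 0, 0),     # salt bridge basic
    mk_atoms("A", 50, "ALA", "CB", "C", 60, 0, 0),      # spectator
    mk_atoms("A", 51, "GLY", "CA", "C", 0, 20, 0))      # spectator
  b <- rbind(
    mk_atoms("B", 43, "GLY", "O", "O", 2.9, 0, 0),      # hbond 1 acceptor
    mk_atoms("B", 10, "SER", "OG", "O", 20, 3.2, 0),    # hbond 2 acceptor
    mk_atoms("B", 48, "ASP", "OD1", "O", 43.7, 0, 0),   # salt bridge acidic
    mk_atoms("B", 60, "VAL", "CG1", "C", 60, 20, 0),    # spectator
    mk_atoms("B", 61, "ALA", "CA", "C", 20, -20, 0))    # spectator
  list(A = a, B = b,
       truth = list(n_hbonds = 2L, n_salt = 1L))
}
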