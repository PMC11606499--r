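# Residue-level interface chemistry: hydrogen bonds, salt bridges,
# and a grid-accelerated neighbour search.
#
# Contact criteria are purely distance-based (heavy-atom cutoffs,
# no angle term), matching how interface contacts are reported for
# shell assemblies: hydrogen bonds as N/O donor-acceptor pairs within
# 3.5 A, salt bridges as Asp/Glu carboxylate oxygens within 4.0 A of
# Arg/Lys (optionally His) basic nitrogens.  Cutoffs are arguments
# everywhere.

MAINCHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                    HIS = c("ND1", "NE2"))

#' Grid-accelerated cross-group neighbour search
#'
#' Returns all pairs (one atom from each group) within `cutoff`, using
#' spatial binning at the cutoff length; results are identical to the
#' quadratic all-pairs enumeration.
#'
#' @param A,B m x 3 / n x 3 coordinate matrices.
#' @param cutoff distance cutoff.
#' @return data frame with columns `i` (row in A), `j` (row in B),
#'   `distance`, ordered by `i` then `j`.
#' @export
find_contact_pairs <- function(A, B, cutoff) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(data.frame(i = integer(0), j = integer(0), distance = numeric(0)))
  org <- pmin(apply(A, 2L, min), apply(B, 2L, min))
  cellB <- floor(sweep(B, 2L, org) / cutoff)
  keyB <- paste(cellB[, 1L], cellB[, 2L], cellB[, 3L])
  binB <- split(seq_len(nrow(B)), keyB)
  cellA <- floor(sweep(A, 2L, org) / cutoff)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (i in seq_len(nrow(A))) {
    nb <- paste(cellA[i, 1L] + off[, 1L], cellA[i, 2L] + off[, 2L],
                cellA[i, 3L] + off[, 3L])
    js <- unlist(binB[nb], use.names = FALSE)
    if (!length(js)) next
    d2 <- colSums((t(B[js, , drop = FALSE]) - A[i, ])^2)
    hit <- d2 <= cutoff^2
    if (any(hit)) {
      out_i <- c(out_i, rep.int(i, sum(hit)))
      out_j <- c(out_j, js[hit])
      out_d <- c(out_d, sqrt(d2[hit]))
    }
  }
  o <- order(out_i, out_j)
  data.frame(i = out_i[o], j = out_j[o], distance = out_d[o])
}

contact_record <- function(kind, a, b, distance) {
  data.frame(kind = rep_len(kind, length(distance)),
             chain_a = a$chain, resname_a = a$resname, resid_a = a$resid,
             atom_a = a$atom, provenance_a =
               ifelse(a$atom %in% MAINCHAIN_ATOMS, "main-chain", "side-chain"),
             chain_b = b$chain, resname_b = b$resname, resid_b = b$resid,
             atom_b = b$atom, provenance_b =
               ifelse(b$atom %in% MAINCHAIN_ATOMS, "main-chain", "side-chain"),
             distance = distance)
}

check_elements <- function(atoms) {
  if (any(is.na(atoms$element) | atoms$element == ""))
    stop("atoms are missing element labels", call. = FALSE)
}

#' Hydrogen bonds between two atom groups
#'
#' Nitrogen/oxygen heavy-atom pairs (one atom from each group) within
#' the cutoff, excluding clash-range pairs that would be covalent
#' (default below 2.0 A).  At least one partner must be a nitrogen or
#' both oxygens; the nitrogen (or the group-A atom) is reported as the
#' donor.  Main-chain / side-chain provenance is recorded per atom.
#'
#' @param groupA,groupB atom-record data frames.
#' @param cutoff heavy-atom distance cutoff, default 3.5 Angstroms.
#' @param min_distance lower bound excluding covalent/clashing pairs.
#' @return data frame of contact records (columns `kind`, donor
#'   `*_a`, acceptor `*_b`, `distance`).
#' @export
find_hbonds <- function(groupA, groupB, cutoff = 3.5, min_distance = 2.0) {
  validate_atoms(groupA); validate_atoms(groupB)
  check_elements(groupA); check_elements(groupB)
  selA <- which(toupper(groupA$element) %in% c("N", "O"))
  selB <- which(toupper(groupB$element) %in% c("N", "O"))
  pr <- find_contact_pairs(groupA[selA, c("x", "y", "z")],
                           groupB[selB, c("x", "y", "z")], cutoff)
  pr <- pr[pr$distance >= min_distance, , drop = FALSE]
  if (!nrow(pr))
    return(contact_record("hbond", groupA[0, ], groupB[0, ], numeric(0)))
  a <- groupA[selA[pr$i], ]
  b <- groupB[selB[pr$j], ]
  swap <- toupper(a$element) == "O" & toupper(b$element) == "N"
  rec <- contact_record("hbond",
                        rbind(a[!swap, ], b[swap, ]),
                        rbind(b[!swap, ], a[swap, ]),
                        c(pr$distance[!swap], pr$distance[swap]))
  rec[order(rec$chain_a, rec$resid_a, rec$atom_a, rec$distance), ]
}

#' Salt bridges between two atom groups
#'
#' Asp/Glu carboxylate oxygens within the cutoff of Arg/Lys (and
#' optionally His) basic nitrogens, in either group order.  Atom-level
#' records are returned; `summarize_salt_bridges()` collapses them to
#' unique residue pairs.
#'
#' @inheritParams find_hbonds
#' @param cutoff distance cutoff, default 4.0 Angstroms.
#' @param include_his count histidine nitrogens as basic (default
#'   `TRUE`).
#' @return data frame of contact records (acidic partner as `*_a`).
#' @export
find_salt_bridges <- function(groupA, groupB, cutoff = 4.0,
                              include_his = TRUE) {
  validate_atoms(groupA); validate_atoms(groupB)
  check_elements(groupA); check_elements(groupB)
  basic <- BASIC_ATOMS
  if (!include_his) basic$HIS <- NULL
  sel <- function(g, table) {
    which(mapply(function(rn, an) an %in% (table[[rn]] %||% character(0)),
                 toupper(g$resname), toupper(g$atom)))
  }
  one_way <- function(acid_g, base_g, flip) {
    ia <- sel(acid_g, ACIDIC_ATOMS); ib <- sel(base_g, basic)
    if (!length(ia) || !length(ib)) return(NULL)
    pr <- find_contact_pairs(acid_g[ia, c("x", "y", "z")],
                             base_g[ib, c("x", "y", "z")], cutoff)
    if (!nrow(pr)) return(NULL)
    contact_record("salt_bridge", acid_g[ia[pr$i], ], base_g[ib[pr$j], ],
                   pr$distance)
  }
  rec <- rbind(one_way(groupA, groupB), one_way(groupB, groupA))
  if (is.null(rec))
    return(contact_record("salt_bridge", groupA[0, ], groupB[0, ],
                          numeric(0)))
  rec <- unique(rec)
  rec[order(rec$chain_a, rec$resid_a, rec$atom_a, rec$distance), ]
}

#' Collapse atom-level salt-bridge records to residue pairs
#'
#' @param records output of [find_salt_bridges()].
#' @return data frame with one row per interacting residue pair and
#'   the minimal atom distance.
#' @export
summarize_salt_bridges <- function(records) {
  if (!nrow(records))
    return(data.frame(chain_a = character(0), resid_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resid_b = integer(0), resname_b = character(0),
                      n_atom_pairs = integer(0), min_distance = numeric(0)))
  key <- paste(records$chain_a, records$resid_a, records$chain_b,
               records$resid_b)
  do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(chain_a = g$chain_a[1L], resid_a = g$resid_a[1L],
               resname_a = g$resname_a[1L], chain_b = g$chain_b[1L],
               resid_b = g$resid_b[1L], resname_b = g$resname_b[1L],
               n_atom_pairs = nrow(g), min_distance = min(g$distance))
  }))
}

#' Residue-level report for one interface
#'
#' Hydrogen bonds, salt bridges, buried surface area and the
#' participating residues (ranked by contact count) for the interface
#' between two chain groups of a full-side-chain model.  Pseudo-atomic
#' synthetic shells carry no chemistry and are rejected; use the
#' purpose-built contact micro-fixtures instead.
#'
#' @param atoms atom-record data frame.
#' @param chainsA,chainsB chain identifiers of the two sides.
#' @param cutoff_hbond,cutoff_salt contact cutoffs (Angstroms).
#' @param probe SASA probe radius for the buried area.
#' @return list with `contacts` (combined record table), `buried`
#'   (see [buried_area()]), and `residues` (participation ranking).
#' @export
interface_report <- function(atoms, chainsA, chainsB, cutoff_hbond = 3.5,
                             cutoff_salt = 4.0, probe = 1.4) {
  validate_atoms(atoms)
  if (mean(atoms$resname == "UNK") > 0.5)
    stop(paste("this looks like a pseudo-atomic synthetic shell, which has",
               "no side-chain chemistry; use contact micro-fixtures for",
               "chemistry tests"), call. = FALSE)
  ga <- atoms[atoms$chain %in% chainsA, , drop = FALSE]
  gb <- atoms[atoms$chain %in% chainsB, , drop = FALSE]
  if (!nrow(ga) || !nrow(gb))
    stop("empty chain selection", call. = FALSE)
  hb <- find_hbonds(ga, gb, cutoff_hbond)
  sb <- find_salt_bridges(ga, gb, cutoff_salt)
  contacts <- rbind(hb, sb)
  buried <- if (min(crossdist2(as.matrix(ga[, c("x", "y", "z")]),
                               as.matrix(gb[, c("x", "y", "z")]))) >
                (2 * (max(vdw_radius(c(ga$element, gb$element))) + probe))^2) {
    list(total = 0, per_side = 0, convention = "total = SASA(A) + SASA(B) - SASA(AB)")
  } else {
    buried_area(ga, gb, probe = probe)
  }
  res_tab <- if (nrow(contacts)) {
    keys <- c(paste(contacts$chain_a, contacts$resname_a, contacts$resid_a),
              paste(contacts$chain_b, contacts$resname_b, contacts$resid_b))
    tab <- sort(table(keys), decreasing = TRUE)
    data.frame(residue = names(tab), n_contacts = as.integer(tab))
  } else {
    data.frame(residue = character(0), n_contacts = integer(0))
  }
  list(contacts = contacts, buried = buried, residues = res_tab)
}
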