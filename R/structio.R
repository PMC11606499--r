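# Structure and sequence I/O plus capsomere segmentation.
#
# Atom records are plain data frames with columns
#   chain, resid, resname, atom, element, x, y, z, occ, b
# Residue numbering is preserved verbatim from the source file; all
# coordinates are Angstroms.  PDB reading/writing goes through bio3d;
# the PDB format's single-character chain field limits it to 62
# chains, so larger assemblies (synthetic shells above T = 1) are
# written as mmCIF, whose auth_asym_id has no such limit.

ATOM_COLS <- c("chain", "resid", "resname", "atom", "element",
               "x", "y", "z", "occ", "b")

validate_atoms <- function(atoms) {
  if (!is.data.frame(atoms) || !all(ATOM_COLS %in% names(atoms)))
    stop("atom records need columns: ", paste(ATOM_COLS, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates", call. = FALSE)
  invisible(atoms)
}

#' Read a structure file into atom records
#'
#' PDB files are parsed with `bio3d::read.pdb`, mmCIF files with
#' `bio3d::read.cif`.  Only the first model of a multi-model file is
#' accepted unless `model` selects one explicitly.  The first
#' alternate location is kept; residue numbering is preserved
#' verbatim.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @param model model number to extract from a multi-model file.
#' @return a data frame of atom records (columns `chain`, `resid`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `occ`, `b`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop(sprintf("failed to parse %s as %s: %s",
                                     path, format, conditionMessage(e)),
                             call. = FALSE))
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (nmod > 1L && is.null(model))
    stop(sprintf("file has %d models; pass `model` to pick one", nmod),
         call. = FALSE)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model %||% 1L, ] else pdb$xyz
  a <- pdb$atom
  # keep first altloc
  if (!is.null(a$alt)) {
    keep <- is.na(a$alt) | a$alt == "" | a$alt == "A"
    a <- a[keep, , drop = FALSE]
    xyz <- xyz[as.vector(t(cbind(3 * (which(keep)) - 2, 3 * which(keep) - 1,
                                 3 * which(keep))))]
  }
  m <- matrix(xyz, ncol = 3L, byrow = TRUE)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- substr(trimws(a$elety), 1L, 1L)
  out <- data.frame(chain = as.character(a$chain), resid = a$resno,
                    resname = trimws(a$resid), atom = trimws(a$elety),
                    element = trimws(elem),
                    x = m[, 1L], y = m[, 2L], z = m[, 3L],
                    occ = a$o %||% 1, b = a$b %||% 0)
  out$occ[is.na(out$occ)] <- 1
  out$b[is.na(out$b)] <- 0
  validate_atoms(out)
  out
}

#' Write atom records to PDB or mmCIF
#'
#' @param atoms atom-record data frame.
#' @param path output path.
#' @param format `"pdb"` (through `bio3d::write.pdb`; at most 62
#'   chains), `"mmcif"`, or `"auto"` by extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path, format = c("auto", "pdb", "mmcif")) {
  validate_atoms(atoms)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "pdb") {
    nch <- length(unique(atoms$chain))
    if (nch > 62L || any(nchar(atoms$chain) > 1L))
      stop(sprintf(
        "PDB chain ids are single characters (%d chains here); write mmCIF instead",
        nch), call. = FALSE)
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
                     resno = atoms$resid, resid = atoms$resname,
                     eleno = seq_len(nrow(atoms)), elety = atoms$atom,
                     chain = atoms$chain, o = atoms$occ, b = atoms$b,
                     elesy = atoms$element)
  } else {
    write_mmcif(atoms, path)
  }
  invisible(path)
}

# Minimal mmCIF atom_site writer (multi-character chain ids supported).
write_mmcif <- function(atoms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_model",
               "#",
               "loop_",
               "_atom_site.group_PDB",
               "_atom_site.id",
               "_atom_site.type_symbol",
               "_atom_site.label_atom_id",
               "_atom_site.label_alt_id",
               "_atom_site.label_comp_id",
               "_atom_site.label_asym_id",
               "_atom_site.label_entity_id",
               "_atom_site.label_seq_id",
               "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x",
               "_atom_site.Cartn_y",
               "_atom_site.Cartn_z",
               "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv",
               "_atom_site.pdbx_formal_charge",
               "_atom_site.auth_seq_id",
               "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id",
               "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    seq_len(nrow(atoms)), atoms$element, atoms$atom, atoms$resname,
    atoms$chain, atoms$resid, atoms$x, atoms$y, atoms$z, atoms$occ,
    atoms$b, atoms$resid, atoms$resname, atoms$chain, atoms$atom)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}

#' Segment a multi-chain assembly into capsomeres
#'
#' Chains are grouped by a two-level rule.  First, chains touching
#' under a tight heavy-atom contact cutoff (default 5 Angstroms) are
#' linked; second, chains whose centroids lie within
#' `link_factor x median nearest-neighbour centroid distance` are
#' linked (adjacent subunits of one capsomere are each other's nearest
#' neighbours, so the median estimates the intra-capsomere subunit
#' spacing; the factor keeps the rule below typical inter-capsomere
#' spacings while tolerating coordinate noise that breaks individual
#' atom contacts).  Connected components of the combined graph are
#' capsomeres; any component larger than six subunits — e.g. a whole
#' shell fused through dense inter-capsomere atom contacts — is
#' re-split using the centroid links alone.  Component subunits are
#' put in cyclic order around the fitted capsomere axis.  Components
#' with 5 subunits are pentamers, 6 hexamers; anything else is
#' labelled `"unknown"` and kept, never dropped.
#'
#' @param atoms atom-record data frame (hydrogens are ignored).
#' @param contact_cutoff inter-chain heavy-atom distance defining
#'   "touching", Angstroms.
#' @param link_factor multiplier for the centroid-linkage cutoff;
#'   `NA` disables centroid linking.
#' @return list of [capsomere()] objects.
#' @examples
#' sh <- generate_shell(1, 0)
#' caps <- segment_capsomeres(sh$atoms)
#' table(vapply(caps, `[[`, "", "kind"))
#' @export
segment_capsomeres <- function(atoms, contact_cutoff = 5,
                               link_factor = 1.4) {
  validate_atoms(atoms)
  atoms <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
  chains <- unique(atoms$chain)
  if (length(chains) < 2L)
    stop("segmentation needs at least 2 chains", call. = FALSE)
  idx <- split(seq_len(nrow(atoms)), factor(atoms$chain, levels = chains))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- t(vapply(idx, function(i) colMeans(xyz[i, , drop = FALSE]),
                  numeric(3L)))
  rad <- vapply(seq_along(idx), function(ci) {
    sqrt(max(rowSums(sweep(xyz[idx[[ci]], , drop = FALSE], 2L,
                           ctr[ci, ])^2)))
  }, 0)
  nc <- length(chains)
  d2 <- crossdist2(ctr, ctr)
  diag(d2) <- Inf
  lim <- outer(rad, rad, "+") + contact_cutoff
  cand <- which(d2 <= lim^2 & upper.tri(d2), arr.ind = TRUE)
  touching <- cand[vapply(seq_len(nrow(cand)), function(r) {
    min(crossdist2(xyz[idx[[cand[r, 1L]]], , drop = FALSE],
                   xyz[idx[[cand[r, 2L]]], , drop = FALSE])) <=
      contact_cutoff^2
  }, TRUE), , drop = FALSE]

  centroid_links <- NULL
  if (!is.na(link_factor) && nc > 1L) {
    link_cutoff <- link_factor * stats::median(sqrt(apply(d2, 1L, min)))
    centroid_links <- which(d2 <= link_cutoff^2 & upper.tri(d2),
                            arr.ind = TRUE)
  }

  comp_of <- function(edges) {
    g <- igraph::make_empty_graph(n = nc, directed = FALSE)
    if (!is.null(edges) && nrow(edges))
      g <- igraph::add_edges(g, as.vector(t(edges)))
    igraph::components(g)$membership
  }
  comp <- comp_of(rbind(touching, centroid_links))
  # re-split fused super-components with the centroid links alone
  if (any(tabulate(comp) > 6L) && !is.null(centroid_links)) {
    sub <- comp_of(centroid_links)
    big <- which(tabulate(comp) > 6L)
    comp <- ifelse(comp %in% big, max(comp) + sub, comp)
    comp <- match(comp, unique(comp))
  }

  lapply(seq_len(max(comp)), function(cc) {
    members <- which(comp == cc)
    # cyclic subunit order around the component axis
    if (length(members) >= 3L) {
      pl <- fit_plane(ctr[members, , drop = FALSE])
      e1 <- if (abs(pl$normal[3L]) < 0.9)
        unit(cross3(pl$normal, c(0, 0, 1)))
      else unit(cross3(pl$normal, c(1, 0, 0)))
      e2 <- cross3(pl$normal, e1)
      v <- sweep(ctr[members, , drop = FALSE], 2L, pl$point)
      members <- members[order(atan2(v %*% e2, v %*% e1))]
    }
    capsomere(lapply(members, function(ci) xyz[idx[[ci]], , drop = FALSE]),
              chains = chains[members])
  })
}

#' Full geometric analysis of a shell model
#'
#' Segments the model into capsomeres, builds capsomere adjacency,
#' classifies interfaces by the detected point symmetry, surveys
#' bend/twist angles per class, and measures the shell diameter —
#' the standard pipeline applied to a (synthetic or user-supplied)
#' multi-capsomere structure.
#'
#' @param atoms atom-record data frame, or a `"synthetic_shell"`.
#' @param contact_cutoff subunit-clustering cutoff (Angstroms).
#' @param merge_mirror see [classify_capsomere_interfaces()].
#' @param diameter_seed seed for the averaged-diagonal diameter.
#' @return object of class `"shell_analysis"`: list with
#'   `capsomeres`, `composition`, `adjacency`, `classes`, `angles`,
#'   `diameters` (all three conventions).
#' @export
analyze_shell <- function(atoms, contact_cutoff = 5, merge_mirror = NULL,
                          diameter_seed = 42) {
  if (inherits(atoms, "synthetic_shell")) atoms <- atoms$atoms
  caps <- segment_capsomeres(atoms, contact_cutoff)
  kinds <- vapply(caps, `[[`, "", "kind")
  adj <- capsomere_adjacency(caps)
  cls <- classify_capsomere_interfaces(caps, adj, merge_mirror)
  ang <- angle_survey(caps, adj, cls)
  ctr <- t(vapply(caps, `[[`, numeric(3L), "centroid"))
  dia <- c(diagonal_average = measure_diameter(ctr, "diagonal_average",
                                               seed = diameter_seed),
           circumsphere = measure_diameter(ctr, "circumsphere"),
           insphere = measure_diameter(ctr, "insphere"))
  structure(list(capsomeres = caps,
                 composition = list(
                   n_pentamers = sum(kinds == "pentamer"),
                   n_hexamers = sum(kinds == "hexamer"),
                   n_unknown = sum(kinds == "unknown")),
                 adjacency = adj, classes = cls, angles = ang,
                 diameters = dia),
            class = "shell_analysis")
}

#' @export
print.shell_analysis <- function(x, ...) {
  cat(sprintf(
    "Shell analysis: %d pentamers, %d hexamers%s; %d edges in %d interface class(es)\n",
    x$composition$n_pentamers, x$composition$n_hexamers,
    if (x$composition$n_unknown)
      sprintf(", %d unknown", x$composition$n_unknown) else "",
    nrow(x$adjacency), nrow(x$classes$classes)))
  cat(sprintf("  diameter (diagonal avg / circum / in): %.1f / %.1f / %.1f\n",
              x$diameters[["diagonal_average"]],
              x$diameters[["circumsphere"]], x$diameters[["insphere"]]))
  invisible(x)
}

#' Export a lattice as JSON
#'
#' Writes sites (1-based ordinals, kinds, positions, normals),
#' adjacency, and (optionally) interface classes.
#'
#' @param lattice a [build_lattice()] result.
#' @param path output path.
#' @param classes optional `"interface_classes"` object.
#' @return `path`, invisibly.
#' @export
export_lattice_json <- function(lattice, path, classes = NULL) {
  stopifnot(inherits(lattice, "shell_lattice"))
  obj <- list(
    params = lattice$params[c("h", "k", "h_prime", "k_prime", "T", "Q")],
    edge_spacing = lattice$edge_spacing,
    sites = lattice$sites,
    adjacency = as.data.frame(lattice$adjacency))
  if (!is.null(classes)) {
    obj$classes <- classes$classes
    obj$adjacency$class <- classes$edge_class
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Export a lattice as a pseudo-atom PDB
#'
#' One HETATM pseudo-atom (element X) per lattice site; the B-factor
#' column carries the interface-free site class: 1 for pentamers, 2
#' for hexamers, or the site's interface-class-free label.
#'
#' @inheritParams export_lattice_json
#' @return `path`, invisibly.
#' @export
export_lattice_pdb <- function(lattice, path) {
  stopifnot(inherits(lattice, "shell_lattice"))
  s <- lattice$sites
  lines <- sprintf(
    "HETATM%5d  X   SIT A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           X",
    s$site %% 100000L, s$site %% 10000L, s$x, s$y, s$z, 1,
    ifelse(s$kind == "pentamer", 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
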