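# Linker-motif scanning: the Ile/Val - Thr/Ser - Gly ([IV][TS]G)
# tripeptide repeats through which the disordered scaffold protein's
# C-terminal region anchors to shell hexamers, plus the standard
# C-terminal fragment annotations and their overlap arithmetic.

MOTIF_REGEX <- "(?=[IV][TS]G)"

motif_positions_in <- function(sequence) {
  m <- gregexpr(MOTIF_REGEX, sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Scan a sequence for [IV][TS]G motifs
#'
#' Reports every (possibly overlapping) occurrence of the
#' Ile/Val-Thr/Ser-Gly anchor motif, in order, with 1-based start
#' positions and flanking context.
#'
#' @param sequence amino-acid sequence (single string; canonicalized
#'   to upper case).  Non-amino-acid characters are rejected with
#'   their position.
#' @param context number of flanking residues to include on each side.
#' @return data frame with columns `position`, `triplet`, `context`.
#' @examples
#' scan_motifs("AAITGAA")   # one hit at position 3
#' scan_motifs("VTGVSG")    # hits at 1 and 4
#' @export
scan_motifs <- function(sequence, context = 3) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sq <- toupper(gsub("\\s", "", sequence))
  chars <- strsplit(sq, "")[[1L]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad))
    stop(sprintf("non-amino-acid character '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  pos <- motif_positions_in(sq)
  data.frame(
    position = pos,
    triplet = substr(rep(sq, length(pos)), pos, pos + 2L),
    context = substr(rep(sq, length(pos)),
                     pmax(1L, pos - context),
                     pmin(nchar(sq), pos + 2L + context)))
}

#' Default C-terminal fragment annotations
#'
#' The five scaffold-protein C-terminal fragments in full-length
#' residue numbering: F1 607-647, F2 685-700, F3 712-731, F4 702-735,
#' F5 770-869.
#'
#' @return data frame with columns `name`, `start`, `end`.
#' @export
fragment_annotations <- function() {
  data.frame(name = paste0("F", 1:5),
             start = c(607L, 685L, 712L, 702L, 770L),
             end = c(647L, 700L, 731L, 735L, 869L))
}

#' Pairwise overlap of fragment annotations
#'
#' Interval arithmetic over 1-based inclusive residue ranges: for each
#' fragment pair the overlapping interval (if any) and its length.
#'
#' @param fragments data frame with `name`, `start`, `end`; default
#'   [fragment_annotations()].
#' @return data frame with `frag_a`, `frag_b`, `overlap_start`,
#'   `overlap_end`, `overlap_length` (0 when disjoint, with NA
#'   bounds).
#' @examples
#' ov <- fragment_overlap()
#' subset(ov, frag_a == "F3" & frag_b == "F4")  # 712-731, length 20
#' @export
fragment_overlap <- function(fragments = fragment_annotations()) {
  stopifnot(nrow(fragments) >= 2L, all(fragments$start <= fragments$end))
  pairs <- utils::combn(seq_len(nrow(fragments)), 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    a <- fragments[pairs[1L, p], ]; b <- fragments[pairs[2L, p], ]
    s <- max(a$start, b$start); e <- min(a$end, b$end)
    data.frame(frag_a = a$name, frag_b = b$name,
               overlap_start = if (s <= e) s else NA_integer_,
               overlap_end = if (s <= e) e else NA_integer_,
               overlap_length = max(0L, e - s + 1L))
  }))
}

#' Register shift between two motif series
#'
#' Two overlapping linker windows bind the shell with their motif
#' series offset by an integer number of motifs.  The best offset(s)
#' maximise the number of exact position agreements between series A
#' and series B shifted by `o` motifs (positive: B lags A by `o`).
#'
#' @param hitsA,hitsB motif hit tables from [scan_motifs()] (or
#'   integer position vectors).
#' @return list with `offset` (best offset; ties give a vector),
#'   `n_matched`, and `scores` (per-offset match counts).
#' @examples
#' a <- c(10, 20, 30); b <- c(20, 30)      # B dropped A's first motif
#' motif_register_shift(a, b)$offset        # 1
#' @export
motif_register_shift <- function(hitsA, hitsB) {
  posA <- if (is.data.frame(hitsA)) hitsA$position else as.integer(hitsA)
  posB <- if (is.data.frame(hitsB)) hitsB$position else as.integer(hitsB)
  if (!length(posA) || !length(posB))
    stop("empty motif series", call. = FALSE)
  offs <- seq(-(length(posB) - 1L), length(posA) - 1L)
  scores <- vapply(offs, function(o) {
    i <- seq_along(posA)
    jb <- i - o
    ok <- jb >= 1L & jb <= length(posB)
    sum(posA[i[ok]] == posB[jb[ok]])
  }, 0L)
  best <- offs[scores == max(scores)]
  list(offset = best, n_matched = max(scores),
       scores = data.frame(offset = offs, n_matched = scores))
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet` returning plain
#' named character strings.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_linker_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA input", call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_linker_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA output", call. = FALSE)
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
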