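# [IV][TS]G motif scanning and fragment annotations.

test_that("the scanner reports all, and only, matching triplets", {
  h <- scan_motifs("AAITGAA")
  expect_identical(h$position, 3L)
  expect_identical(h$triplet, "ITG")

  h2 <- scan_motifs("VTGVSG")
  expect_identical(h2$position, c(1L, 4L))
  expect_identical(h2$triplet, c("VTG", "VSG"))

  expect_identical(nrow(scan_motifs("ITAISA")), 0L)
  # consecutive repeats are all reported, no greedy consumption
  expect_identical(scan_motifs("ITGITGITG")$position, c(1L, 4L, 7L))

  expect_error(scan_motifs("AAITGXZA"), "position 6")
})

test_that("the scanner equals the sliding-window oracle on random sequences", {
  set.seed(13)
  for (rep in 1:200) {
    sq <- paste(sample(bmcshell:::aa_alphabet(), sample(3:80, 1),
                       replace = TRUE), collapse = "")
    expect_identical(scan_motifs(sq)$position, naive_motif_scan(sq))
  }
})

test_that("hit count is invariant under appending non-matching suffixes", {
  lk <- generate_linker(50, c(4, 30), seed = 6)
  base <- scan_motifs(lk$sequence)$position
  for (suffix in c("AAAA", "PPPPPP", "ITAIS")) {
    expect_identical(scan_motifs(paste0(lk$sequence, suffix))$position, base)
  }
})

test_that("fragment overlap arithmetic matches the annotated endpoints", {
  ov <- fragment_overlap()
  f34 <- ov[ov$frag_a == "F3" & ov$frag_b == "F4", ]
  expect_identical(f34$overlap_start, 712L)
  expect_identical(f34$overlap_end, 731L)
  expect_identical(f34$overlap_length, 20L)

  f12 <- ov[ov$frag_a == "F1" & ov$frag_b == "F2", ]
  expect_identical(f12$overlap_length, 0L)
  expect_true(is.na(f12$overlap_start))

  fr <- fragment_annotations()
  self <- fragment_overlap(fr[c(1, 1), ])
  expect_identical(self$overlap_length, fr$end[1] - fr$start[1] + 1L)
})

test_that("register shift recovers constructed offsets", {
  expect_identical(motif_register_shift(c(5, 15, 25), c(5, 15, 25))$offset, 0L)
  expect_identical(motif_register_shift(c(10, 20, 30), c(20, 30))$offset, 1L)

  # synthetic overlapping windows sharing three planted motifs with a
  # one-register shift, as for the overlapping C-terminal fragments
  lk <- generate_linker(60, c(10, 22, 34, 46), seed = 8)
  hitsA <- scan_motifs(substr(lk$sequence, 1, 40))          # motifs 1-3
  winB <- substr(lk$sequence, 13, 60)                       # motifs 2-4
  hitsB <- scan_motifs(winB)
  hitsB$position <- hitsB$position + 12L                    # back to full numbering
  expect_identical(motif_register_shift(hitsA, hitsB)$offset, 1L)

  expect_error(motif_register_shift(integer(0), 5L), "empty")
})

test_that("FASTA round trip preserves linker sequences", {
  skip_if_not_installed("Biostrings")
  lk <- generate_linker(40, c(5, 30), seed = 2)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_linker_fasta(c(linker1 = lk$sequence), f)
  back <- read_linker_fasta(f)
  expect_identical(unname(back["linker1"]), lk$sequence)
})
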