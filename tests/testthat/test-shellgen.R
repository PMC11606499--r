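# Synthetic shell and linker generation.

test_that("generated shells carry the predicted capsomere census", {
  sh1 <- cached_shell("T9")$shell
  expect_identical(nrow(sh1$manifest$sites), 92L)
  expect_identical(sum(sh1$manifest$sites$kind == "hexamer"), 80L)
  expect_identical(sum(sh1$manifest$sites$kind == "pentamer"), 12L)

  sh0 <- generate_shell(1, 0, seed = 7)
  expect_identical(length(unique(sh0$atoms$chain)), 60L)  # 12 x 5 subunits
  expect_identical(nrow(sh0$manifest$sites), 12L)
})

test_that("generation is deterministic under a fixed seed", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(generate_shell(1, 0, noise_sigma = 1, seed = 42)$atoms, f1)
  write_structure(generate_shell(1, 0, noise_sigma = 1, seed = 42)$atoms, f2)
  expect_identical(readLines(f1), readLines(f2))
  sh_a <- generate_shell(1, 0, noise_sigma = 1, seed = 42)
  sh_b <- generate_shell(1, 0, noise_sigma = 1, seed = 43)
  expect_false(identical(sh_a$atoms$x, sh_b$atoms$x))
})

test_that("excessive coordinate noise is refused", {
  expect_error(generate_shell(1, 0, noise_sigma = 0.3 * 65), "ambiguous")
  expect_warning(generate_shell(1, 0, noise_sigma = 0.15 * 65), "segmentation")
})

test_that("two-capsomere fixtures reproduce their construction angles", {
  for (tr in list(c(0, 0), c(10, 0), c(30, 0), c(45, 20))) {
    fx <- generate_two_capsomere_fixture(alpha = tr[1], beta = tr[2])
    ia <- interface_angles(fx$A, fx$B)
    expect_equal(ia$alpha, tr[1], tolerance = 1e-6)
    expect_equal(ia$beta, tr[2], tolerance = 1e-6)
  }
  expect_error(generate_two_capsomere_fixture(alpha = 95), "alpha")
})

test_that("fixture angle recovery survives coordinate noise", {
  err <- vapply(1:20, function(s) {
    fx <- generate_two_capsomere_fixture(alpha = 30, noise_sigma = 0.2,
                                         seed = s)
    abs(interface_angles(fx$A, fx$B)$alpha - 30)
  }, 0)
  expect_lt(mean(err), 1)
})

test_that("segmentation of noisy shells stays correct at 5% spacing noise", {
  for (s in 1:6) {
    sh <- generate_shell(1, 1, noise_sigma = 0.05 * 65, seed = s)
    kinds <- vapply(segment_capsomeres(sh$atoms), `[[`, "", "kind")
    expect_identical(sum(kinds == "pentamer"), 12L)
    expect_identical(sum(kinds == "hexamer"), 20L)
  }
})

test_that("synthetic linkers plant exactly the manifest motifs", {
  lk <- generate_linker(60, c(5, 20, 41), seed = 3)
  hits <- scan_motifs(lk$sequence)
  expect_identical(hits$position, c(5L, 20L, 41L))
  expect_identical(nchar(lk$sequence), 60L)

  expect_identical(nrow(scan_motifs(generate_linker(10, seed = 2)$sequence)),
                   0L)

  lk2 <- generate_linker(30, 5, motif_choices = "VTG", seed = 9)
  h2 <- scan_motifs(lk2$sequence)
  expect_identical(h2$position, 5L)
  expect_identical(h2$triplet, "VTG")

  expect_error(generate_linker(20, c(5, 6)), "overlap")
  expect_error(generate_linker(10, 9), "fit")
  expect_error(generate_linker(30, 5, motif_choices = "ATG"), "match")
  expect_identical(generate_linker(80, c(3, 40), seed = 5)$sequence,
                   generate_linker(80, c(3, 40), seed = 5)$sequence)
})

test_that("planted linker motifs resist accidental background matches", {
  # property: over many seeds, the scanner finds the planted set exactly
  for (s in 1:25) {
    lk <- generate_linker(120, c(10, 50, 90), seed = s)
    expect_identical(scan_motifs(lk$sequence)$position, c(10L, 50L, 90L))
  }
})
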