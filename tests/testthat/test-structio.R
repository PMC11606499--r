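# Structure I/O and capsomere segmentation.

test_that("PDB round trip preserves coordinates to format precision", {
  sh <- generate_shell(1, 0, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sh$atoms, f)
  back <- read_structure(f)
  expect_identical(length(unique(back$chain)), 60L)
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                    as.matrix(sh$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_identical(back$resid, sh$atoms$resid)
})

test_that("mmCIF holds assemblies beyond the PDB chain-id limit", {
  sh <- cached_shell("T9")$shell
  expect_error(write_structure(sh$atoms, withr::local_tempfile(fileext = ".pdb")),
               "chain")
  f <- withr::local_tempfile(fileext = ".cif")
  write_structure(sh$atoms, f)
  back <- suppressWarnings(read_structure(f))
  expect_identical(length(unique(back$chain)), 540L)
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                    as.matrix(sh$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("malformed input is reported as a parse failure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM  garbage record that is far too short"), f)
  expect_error(read_structure(f), "parse|PDB")
  expect_error(read_structure("no/such/file.pdb"), "no such file")
})

test_that("zero-noise segmentation reproduces the generation manifest", {
  got <- cached_shell("T9")
  kinds <- vapply(got$analysis$capsomeres, `[[`, "", "kind")
  expect_identical(sum(kinds == "pentamer"), 12L)
  expect_identical(sum(kinds == "hexamer"), 80L)

  sh3 <- generate_shell(1, 1, seed = 4)
  caps3 <- segment_capsomeres(sh3$atoms)
  expect_identical(length(caps3), 32L)
  site_of <- map_caps_to_sites(caps3, sh3$manifest$sites)
  expect_identical(vapply(caps3, `[[`, "", "kind"),
                   sh3$manifest$sites$kind[site_of])
})

test_that("segmentation is invariant to chain order and rigid motion", {
  sh <- generate_shell(1, 0, seed = 6)
  base <- segment_capsomeres(sh$atoms)

  set.seed(3)
  perm <- sample(nrow(sh$atoms))
  shuffled <- sh$atoms[perm, ]
  caps_p <- segment_capsomeres(shuffled)
  expect_identical(length(caps_p), length(base))
  expect_setequal(
    vapply(caps_p, function(cp) paste(sort(cp$chains), collapse = ","), ""),
    vapply(base, function(cp) paste(sort(cp$chains), collapse = ","), ""))

  R <- bmcshell:::rotation_about_axis(c(1, 2, 3), 1.1)
  moved <- sh$atoms
  moved[, c("x", "y", "z")] <-
    sweep(as.matrix(sh$atoms[, c("x", "y", "z")]) %*% t(R), 2,
          c(100, -50, 30), "+")
  caps_r <- segment_capsomeres(moved)
  expect_setequal(
    vapply(caps_r, function(cp) paste(sort(cp$chains), collapse = ","), ""),
    vapply(base, function(cp) paste(sort(cp$chains), collapse = ","), ""))
})

test_that("every chain lands in exactly one capsomere; oddballs are kept", {
  tmpl <- capsomere_template("hexamer", 24)
  # a full hexamer plus an isolated 3-subunit fragment far away
  frag <- lapply(tmpl[1:3], function(m) sweep(m, 2, c(500, 0, 0), "+"))
  atoms <- rbind(
    bmcshell:::capsomere_atoms(capsomere(tmpl, chains = paste0("H", 1:6))),
    bmcshell:::capsomere_atoms(capsomere(frag, chains = paste0("F", 1:3))))
  caps <- segment_capsomeres(atoms)
  kinds <- vapply(caps, `[[`, "", "kind")
  expect_setequal(kinds, c("hexamer", "unknown"))
  all_chains <- sort(unlist(lapply(caps, `[[`, "chains")))
  expect_identical(all_chains, sort(unique(atoms$chain)))
})

test_that("two isolated capsomere templates segment as two capsomeres", {
  t1 <- capsomere_template("hexamer", 24)
  t2 <- lapply(t1, function(m) sweep(m, 2, c(200, 0, 0), "+"))
  atoms <- rbind(
    bmcshell:::capsomere_atoms(capsomere(t1, chains = paste0("A", 1:6))),
    bmcshell:::capsomere_atoms(capsomere(t2, chains = paste0("B", 1:6))))
  caps <- segment_capsomeres(atoms)
  expect_identical(length(caps), 2L)
  expect_true(all(vapply(caps, `[[`, "", "kind") == "hexamer"))
})
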