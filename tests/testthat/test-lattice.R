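# Lattice arithmetic, construction, and counting.

test_that("triangulation and elongation numbers follow the index formulas", {
  expect_identical(triangulation_number(3, 0), 9L)
  expect_identical(triangulation_number(1, 0), 1L)
  expect_identical(triangulation_number(3, 2), 19L)   # 9 + 6 + 4
  expect_error(triangulation_number(0, 0), "degenerate")
  expect_error(triangulation_number(-1, 2), "integer")

  expect_identical(elongation_number(3, 0, 4, 0), 12L)
  expect_identical(elongation_number(1, 0, 1, 0), 1L)  # Q = T, icosahedral
  expect_identical(elongation_number(2, 1, 2, 1), 7L)  # 4 + 2 + 1
  expect_error(elongation_number(3, 0, 1, 0), "oblate")
})

test_that("T, Q and chirality behave under the (h,k) mirror swap", {
  for (hk in list(c(2, 1), c(3, 1), c(3, 2), c(4, 1))) {
    expect_identical(triangulation_number(hk[1], hk[2]),
                     triangulation_number(hk[2], hk[1]))
    expect_false(shell_class(hk[1], hk[2])$achiral)
    expect_false(shell_class(hk[2], hk[1])$achiral)
  }
  for (hk in list(c(3, 0), c(2, 2), c(1, 1), c(4, 0))) {
    expect_true(shell_class(hk[1], hk[2])$achiral)
  }
})

test_that("composition prediction matches the closed forms", {
  expect_identical(predict_composition(shell_class(3, 0))$n_hexamers, 80L)
  expect_identical(predict_composition(shell_class(1, 0))$n_hexamers, 0L)
  expect_identical(predict_composition(shell_class(3, 0, 4, 0))$n_hexamers, 95L)
  expect_identical(predict_composition(shell_class(3, 1))$n_hexamers, 120L)
  expect_identical(predict_composition(shell_class(4, 0))$n_hexamers, 150L)
  expect_identical(predict_composition(shell_class(3, 2))$n_hexamers, 180L)
  comp <- predict_composition(13, conformers_per_au = 2)
  expect_identical(comp$n_pentamers, 12L)
  expect_identical(comp$n_linker_sites, 120L)
})

test_that("built lattices reproduce the composition formulas by site counting", {
  # every icosahedral index pair with T <= 25, and two lattice-compatible
  # prolate bodies
  index_pairs <- list(c(1, 0), c(1, 1), c(2, 0), c(2, 1), c(3, 0), c(2, 2),
                      c(3, 1), c(4, 0), c(3, 2), c(4, 1), c(5, 0))
  for (hk in index_pairs) {
    lat <- build_lattice(hk[1], hk[2])
    comp <- predict_composition(lat$params)
    expect_identical(sum(lat$sites$kind == "pentamer"), 12L)
    expect_identical(sum(lat$sites$kind == "hexamer"), comp$n_hexamers)
    # Euler consistency: pentamer degree 5, hexamer degree 6
    deg <- tabulate(c(lat$adjacency), nbins = nrow(lat$sites))
    expect_identical(deg, ifelse(lat$sites$kind == "pentamer", 5L, 6L))
  }
  for (q in list(c(4, 0), c(5, 0))) {           # Q = 12, 15 on (3, 0)
    lat <- build_lattice(3, 0, q[1], q[2])
    comp <- predict_composition(lat$params)
    expect_identical(sum(lat$sites$kind == "hexamer"), comp$n_hexamers)
    expect_identical(sum(lat$sites$kind == "pentamer"), 12L)
  }
})

test_that("adjacency equals brute-force pair enumeration at the cutoff", {
  lat <- build_lattice(3, 0)
  pos <- as.matrix(lat$sites[, c("x", "y", "z")])
  bf <- brute_force_pairs(pos, pos, 1.2 * lat$edge_spacing)
  bf <- bf[bf$i < bf$j, ]
  expect_identical(nrow(lat$adjacency), nrow(bf))          # 270 for T = 9
  expect_identical(nrow(lat$adjacency), 270L)
  expect_equal(unname(lat$adjacency[, 1]), bf$i)
  expect_equal(unname(lat$adjacency[, 2]), bf$j)
})

test_that("small lattices have the expected shapes", {
  lat3 <- build_lattice(1, 1)
  expect_identical(nrow(lat3$sites), 32L)                  # T = 3
  lat1 <- build_lattice(1, 0)
  expect_identical(nrow(lat1$sites), 12L)
  expect_true(all(tabulate(c(lat1$adjacency), 12) == 5L))
  expect_error(build_lattice(3, 0, 1, 0), "oblate")
  expect_error(build_lattice(3, 0, 0, 4), "prolate|embedding")
  expect_error(build_lattice(3, 0, edge_spacing = -1), "positive")
})

test_that("asymmetric unit contents scale as site count / 60", {
  au19 <- asymmetric_unit(build_lattice(3, 2))
  expect_equal(attr(au19, "n_hexamer_equivalents"), 3)     # 180 / 60
  expect_equal(attr(au19, "n_pentamer_subunits"), 1)
  expect_identical(sum(au19$kind == "hexamer" & au19$occupancy == 1), 3L)

  au16 <- asymmetric_unit(build_lattice(4, 0))
  expect_equal(attr(au16, "n_hexamer_equivalents"), 2.5)   # 150 / 60

  au1 <- asymmetric_unit(build_lattice(1, 0))
  expect_equal(attr(au1, "n_hexamer_equivalents"), 0)
  expect_equal(attr(au1, "n_pentamer_subunits"), 1)
  expect_error(asymmetric_unit(build_lattice(3, 0, 4, 0)), "icosahedral")
})

test_that("lattice exports are well formed", {
  lat <- build_lattice(1, 1)
  cls <- classify_interfaces(lat)
  jf <- withr::local_tempfile(fileext = ".json")
  export_lattice_json(lat, jf, classes = cls)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_identical(back$params$T, 3L)
  expect_identical(length(back$sites$site), 32L)
  expect_identical(length(back$adjacency$class), nrow(lat$adjacency))

  pf <- withr::local_tempfile(fileext = ".pdb")
  export_lattice_pdb(lat, pf)
  lines <- readLines(pf)
  expect_identical(sum(startsWith(lines, "HETATM")), 32L)
})
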