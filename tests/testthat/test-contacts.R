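# Hydrogen bonds, salt bridges, neighbour search.

test_that("hydrogen bonds are detected at, and only at, contact range", {
  don <- mk_atoms("A", 1, "LYS", "NZ", "N", 0)
  acc <- mk_atoms("B", 5, "GLY", "O", "O", 2.9)
  expect_identical(nrow(find_hbonds(don, acc)), 1L)
  hb <- find_hbonds(don, acc)
  expect_identical(hb$provenance_a, "side-chain")
  expect_identical(hb$provenance_b, "main-chain")
  expect_equal(hb$distance, 2.9)

  expect_identical(nrow(find_hbonds(don, mk_atoms("B", 5, "GLY", "O", "O", 3.8))),
                   0L)
  # clash-range pair excluded as covalent
  expect_identical(nrow(find_hbonds(don, mk_atoms("B", 5, "GLY", "O", "O", 1.2))),
                   0L)
  noel <- don; noel$element <- ""
  expect_error(find_hbonds(noel, acc), "element")
})

test_that("k donors around one acceptor give k records (enumeration oracle)", {
  set.seed(2)
  for (k in c(1L, 4L, 9L)) {
    th <- seq(0, 2 * pi, length.out = k + 1)[-1]
    donors <- mk_atoms("A", seq_len(k), "LYS", "NZ", "N",
                       3 * cos(th), 3 * sin(th))
    acc <- mk_atoms("B", 1, "SER", "OG", "O", 0)
    got <- find_hbonds(donors, acc)
    bf <- brute_force_pairs(donors[, c("x", "y", "z")],
                            acc[, c("x", "y", "z")], 3.5)
    bf <- bf[bf$distance >= 2, ]
    expect_identical(nrow(got), nrow(bf))
    expect_identical(nrow(got), k)
  }
})

test_that("salt bridges require an acidic/basic pair and deduplicate by residue", {
  asp <- mk_atoms("A", 48, "ASP", c("OD1", "OD2"), "O", c(0, 1))
  arg <- mk_atoms("B", 83, "ARG", c("NH1", "NH2"), "N", c(3.2, 3.5))
  rec <- find_salt_bridges(asp, arg)
  expect_identical(nrow(rec), 4L)
  smry <- summarize_salt_bridges(rec)
  expect_identical(nrow(smry), 1L)
  expect_equal(smry$min_distance, 2.2)   # OD2 (x=1) to NH1 (x=3.2)

  ser <- mk_atoms("B", 7, "SER", "OG", "O", 3.2)
  expect_identical(nrow(find_salt_bridges(asp, ser)), 0L)

  his <- mk_atoms("B", 9, "HIS", "NE2", "N", 3.2)
  expect_identical(nrow(find_salt_bridges(asp, his)), 2L)
  expect_identical(nrow(find_salt_bridges(asp, his, include_his = FALSE)), 0L)

  # argument order: acidic partner always reported on the a-side
  rev <- find_salt_bridges(arg, asp)
  expect_identical(rev$resname_a, rec$resname_a)
  expect_identical(nrow(rev), 4L)
})

test_that("grid neighbour search equals brute force on random configurations", {
  set.seed(21)
  for (rep in 1:60) {
    nA <- sample(5:25, 1); nB <- sample(5:25, 1)
    A <- matrix(runif(3 * nA, 0, 12), ncol = 3)
    B <- matrix(runif(3 * nB, 0, 12), ncol = 3)
    cutoff <- runif(1, 1, 6)
    expect_identical(find_contact_pairs(A, B, cutoff),
                     brute_force_pairs(A, B, cutoff))
  }
})

test_that("the interface report lists exactly the planted contacts", {
  fx <- contact_microfixture()
  atoms <- rbind(fx$A, fx$B)
  rep <- interface_report(atoms, "A", "B")
  expect_identical(nrow(rep$contacts), 3L)
  expect_identical(sum(rep$contacts$kind == "hbond"), fx$truth$n_hbonds)
  expect_identical(sum(rep$contacts$kind == "salt_bridge"), fx$truth$n_salt)
  expect_true(rep$buried$total > 0)

  # argument order swap: identical records (donor / acidic partner is
  # always normalised onto the a-side)
  rep2 <- interface_report(atoms, "B", "A")
  expect_identical(nrow(rep2$contacts), 3L)
  expect_setequal(
    paste(rep$contacts$kind, rep$contacts$resid_a, rep$contacts$resid_b),
    paste(rep2$contacts$kind, rep2$contacts$resid_a, rep2$contacts$resid_b))

  # empty interface: capsomeres beyond contact range
  far <- fx$B; far$x <- far$x + 500
  rep0 <- interface_report(rbind(fx$A, far), "A", "B")
  expect_identical(nrow(rep0$contacts), 0L)
  expect_identical(rep0$buried$total, 0)

  # pseudo-atomic synthetic shells carry no chemistry
  sh <- generate_shell(1, 0, seed = 1)
  expect_error(interface_report(sh$atoms, "A", "B"), "fixtures")
})
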