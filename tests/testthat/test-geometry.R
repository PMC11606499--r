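# Plane fitting, interface angles, superposition RMSD, diameter.

test_that("plane fitting recovers exact and noisy planes", {
  hexagon <- cbind(cos(0:5 * pi / 3), sin(0:5 * pi / 3), 0)
  pl <- fit_plane(hexagon)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$rms_residual, 0, tolerance = 1e-12)

  tri <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
  expect_equal(abs(fit_plane(tri)$normal[3]), 1, tolerance = 1e-12)

  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
  expect_error(fit_plane(hexagon[1:2, ]), "3 points")

  # Monte-Carlo: sigma = 0.1 noise tilts the hexagon normal < 2 degrees
  set.seed(5)
  tilt <- vapply(1:100, function(s) {
    noisy <- hexagon * 24 + matrix(rnorm(18, sd = 0.1), ncol = 3)
    n <- fit_plane(noisy)$normal
    bmcshell:::rad2deg(acos(abs(n[3])))
  }, 0)
  expect_true(all(tilt < 2))
})

test_that("interface angles are symmetric and rigid-motion invariant", {
  fx <- generate_two_capsomere_fixture(alpha = 25, beta = 10, seed = 1)
  ab <- interface_angles(fx$A, fx$B)
  ba <- interface_angles(fx$B, fx$A)
  expect_equal(ab$alpha, ba$alpha, tolerance = 1e-9)
  expect_equal(ab$beta, ba$beta, tolerance = 1e-9)

  R <- bmcshell:::rotation_about_axis(c(2, -1, 1), 0.8)
  move <- function(cp) {
    pts <- split.data.frame(sweep(cp$points %*% t(R), 2, c(30, 40, -10), "+"),
                            cp$subunit)
    capsomere(pts, chains = cp$chains, kind = cp$kind)
  }
  moved <- interface_angles(move(fx$A), move(fx$B))
  expect_equal(moved$alpha, ab$alpha, tolerance = 1e-9)
  expect_equal(moved$beta, ab$beta, tolerance = 1e-9)

  expect_error(interface_angles(fx$A, fx$B, max_distance = 10),
               "not adjacent")
})

test_that("superposition RMSD honours rigid motion, cyclic symmetry, and noise", {
  tmpl <- capsomere_template("hexamer", 24)
  A <- capsomere(tmpl)
  R <- bmcshell:::rotation_about_axis(c(1, 0, 2), 2.2)
  B <- capsomere(lapply(tmpl, function(m) sweep(m %*% t(R), 2, c(9, 8, 7), "+")))
  expect_equal(superpose_rmsd(A, B), 0, tolerance = 1e-9)

  # rotation by one subunit step is absorbed by the cyclic correspondence
  C <- capsomere(tmpl[c(2:6, 1)])
  expect_equal(superpose_rmsd(A, C), 0, tolerance = 1e-9)

  expect_error(superpose_rmsd(A, capsomere(capsomere_template("pentamer"))),
               "mismatch")

  # isotropic noise: E[RMSD] ~ sigma * sqrt(3) * sqrt(1 - 2/n) after the
  # 6-parameter fit, n = 42 points
  set.seed(8)
  sigma <- 0.5
  rmsds <- vapply(1:50, function(s) {
    noisy <- lapply(tmpl, function(m)
      m + matrix(rnorm(length(m), sd = sigma), ncol = 3))
    superpose_rmsd(A, capsomere(noisy))
  }, 0)
  expected <- sigma * sqrt(3) * sqrt(1 - 2 / 42)
  expect_lt(abs(mean(rmsds) - expected) / expected, 0.2)
})

test_that("diameter conventions agree with closed-form geometry", {
  set.seed(4)
  X <- matrix(rnorm(1500), ncol = 3)
  X <- 10 * X / sqrt(rowSums(X^2))
  X <- rbind(X, -X)        # dense sphere, radius 10, centroid exactly 0
  expect_equal(measure_diameter(X, "circumsphere"), 20, tolerance = 1e-6)
  for (s in c(1, 7, 99))
    expect_equal(measure_diameter(X, "diagonal_average", seed = s), 20,
                 tolerance = 0.01)

  # faceted T = 9: circumsphere / insphere = icosahedron circumradius /
  # inradius (vertex pentamers vs face-centre hexamers)
  lat <- build_lattice(3, 0)
  a <- sqrt(9) * lat$edge_spacing
  circ <- (a / 4) * sqrt(10 + 2 * sqrt(5))
  inr <- a * sqrt(3) / 12 * (3 + sqrt(5))
  pos <- as.matrix(lat$sites[, c("x", "y", "z")])
  expect_equal(measure_diameter(pos, "circumsphere") /
                 measure_diameter(pos, "insphere"),
               circ / inr, tolerance = 1e-9)
  expect_error(measure_diameter(pos[1:5, ]), "12")
})

test_that("angle survey on ideal shells shows facet-flatness and symmetry", {
  got <- cached_shell("T9")
  an <- got$analysis
  cls <- an$classes$classes
  ph <- cls$label[cls$kind == "pentamer-hexamer"]
  edges <- an$angles$edges

  # all 60 pentamer-hexamer edges share one bend angle
  expect_lt(diff(range(edges$alpha[edges$class %in% ph])), 1e-6)
  # faceted icosahedron bound: every bend within [0, 45] degrees
  expect_true(all(edges$alpha >= 0 & edges$alpha <= 45))
  # intra-facet hexamer-hexamer interfaces are flat
  flat <- cls$label[cls$kind == "hexamer-hexamer"][
    which.min(an$angles$classes$alpha_mean[cls$kind == "hexamer-hexamer"])]
  expect_lt(max(edges$alpha[edges$class == flat]), 1e-6)

  # spherized embedding: curvature everywhere, no flat interfaces
  shs <- generate_shell(1, 1, spherize = TRUE, seed = 2)
  ans <- analyze_shell(shs)
  hex_pairs <- with(ans$angles$edges,
                    class %in% ans$classes$classes$label[
                      ans$classes$classes$kind == "hexamer-hexamer"])
  expect_true(all(ans$angles$edges$alpha[hex_pairs] > 0.1))
})
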