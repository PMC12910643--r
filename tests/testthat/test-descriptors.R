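# Radius of gyration, SASA and SA 3D PSA.

test_that("radius of gyration matches hand-evaluated cases and is rigid-invariant", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3), 12), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 1)), 0.5)
  sq <- rbind(c(0.5, 0.5, 0), c(0.5, -0.5, 0), c(-0.5, 0.5, 0),
              c(-0.5, -0.5, 0))
  expect_equal(radius_of_gyration(sq, rep(1, 4)), sqrt(0.5))

  # mass weighting moves the centre: unequal masses give a different value
  expect_false(isTRUE(all.equal(
    radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 15)),
    0.5)))

  set.seed(21)
  xyz <- matrix(rnorm(30), 10, 3)
  m <- runif(10, 1, 16)
  r0 <- radius_of_gyration(xyz, m)
  moved <- sweep(xyz %*% t(random_rotation_matrix()), 2, c(4, -2, 7), "+")
  expect_equal(radius_of_gyration(moved, m), r0, tolerance = 1e-9)

  expect_error(radius_of_gyration(matrix(numeric(), 0, 3)), "empty")
  expect_error(radius_of_gyration(xyz, rep(-1, 10)), "positive")
})

test_that("SASA matches closed forms, is additive at separation, and scales", {
  topo_o <- chameleonics:::minimal_topology(tibble::tibble(element = "O"))
  a <- sasa(matrix(0, 1, 3), topo_o)
  expect_equal(a, 4 * pi * (1.52 + 1.4)^2, tolerance = 1e-6)

  # two identical atoms far apart: exactly twice the isolated value
  topo2 <- chameleonics:::minimal_topology(tibble::tibble(element = c("O", "O")))
  a2 <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), topo2)
  expect_equal(sum(a2), 2 * a, tolerance = 1e-9)

  # doubling radii and probe scales the isolated-atom area by 4
  custom <- tibble::tibble(element = "O", vdw_A = 2 * 1.52,
                           covalent_A = 0.66, mass = 16)
  a4 <- sasa(matrix(0, 1, 3), topo_o,
             sasa_params(probe_A = 2.8, radii = custom))
  expect_equal(a4 / a, 4, tolerance = 1e-9)

  # full 26-neighbour cage buries the central atom completely
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * 1.8
  topo_cage <- chameleonics:::minimal_topology(
    tibble::tibble(element = rep("C", nrow(g))))
  centre <- which(rowSums(g^2) == 0)
  a_cage <- sasa(g, topo_cage)
  expect_equal(a_cage[centre], 0)
})

test_that("SASA point-count convergence is within 2% on the toy molecule", {
  toy <- build_toy_molecule()
  xyz <- toy$reference
  s960 <- sum(sasa(xyz, toy$topology, sasa_params(n_points = 960)))
  s4000 <- sum(sasa(xyz, toy$topology, sasa_params(n_points = 4000)))
  expect_lt(abs(s4000 - s960) / s4000, 0.02)
})

test_that("SASA and SA 3D PSA are invariant under rigid motion within lattice tolerance", {
  toy <- build_toy_molecule()
  xyz <- toy$reference
  set.seed(22)
  moved <- sweep(xyz %*% t(random_rotation_matrix()), 2, c(3, 1, -2), "+")
  s0 <- sum(sasa(xyz, toy$topology)); s1 <- sum(sasa(moved, toy$topology))
  expect_lt(abs(s1 - s0) / s0, 0.005)
  p0 <- sa_3d_psa(xyz, toy$topology); p1 <- sa_3d_psa(moved, toy$topology)
  expect_lt(abs(p1 - p0) / p0, 0.01)
})

test_that("SA 3D PSA is bounded by total SASA and zero without polar atoms", {
  toy <- build_toy_molecule()
  ens <- generate_ensemble(toy, "mixed", n_frames = 10, seed = 23)
  tab <- descriptor_table(ens)
  expect_true(all(tab$sa3dpsa_A2 >= 0))
  expect_true(all(tab$sa3dpsa_A2 <= tab$sasa_A2))
  expect_true(all(tab$rgyr_A >= 0))
  expect_equal(tab$frame, 1:10)

  # apolar molecule: zero polar surface
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0), c(4.5, 0, 0))
  ens2 <- annotate_frame(xyz, rep("C", 4))
  expect_equal(sa_3d_psa(xyz, ens2$topology), 0)
})

test_that("folded conformers expose less polar surface than extended ones", {
  toy <- build_toy_molecule()
  folded <- generate_ensemble(toy, "folded", n_frames = 25, seed = 24)
  extended <- generate_ensemble(toy, "extended", n_frames = 25, seed = 25)
  tf <- descriptor_table(folded); te <- descriptor_table(extended)
  expect_gt(mean(te$sa3dpsa_A2) - mean(tf$sa3dpsa_A2), 20)
  expect_lt(median(tf$rgyr_A), median(te$rgyr_A))
})

test_that("duplicate frames give identical descriptor rows", {
  toy <- build_toy_molecule()
  ens <- make_ensemble(list(toy$reference, toy$reference),
                       toy$topology$atoms$element)
  ens$topology <- toy$topology
  tab <- descriptor_table(ens)
  expect_equal(tab[1, -1], tab[2, -1])
})
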