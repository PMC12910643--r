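# Hydrogen bonds, Burgi-Dunitz approaches, pi-stacking, C-H/pi.

# a spaced donor...acceptor system: hydroxyl on one end of a long chain,
# carbonyl O on the other, with the H-bond geometry set per test
hb_system <- function(o_o_dist, angle_dev_deg = 0) {
  # chain of 5 C keeps the donor-acceptor bond-path separation >= 4
  chain <- cbind(seq(0, 6, length.out = 5), 0, 0)
  o_d <- c(-1.2, 0.8, 0)                      # O bonded to C1
  o_a <- chain[5, ] + c(1.23, 0, 0)           # carbonyl O on C5
  # place H on the O_d -> O_a line at 0.97 A, then tilt by angle_dev
  u <- (o_a - o_d) / sqrt(sum((o_a - o_d)^2))
  perp <- c(-u[2], u[1], 0); perp <- perp / sqrt(sum(perp^2))
  th <- angle_dev_deg * pi / 180
  h <- o_d + 0.97 * (cos(th) * u + sin(th) * perp)
  xyz <- rbind(chain, o_d, h, o_a)
  # rescale O_d...O_a to the requested distance by moving the acceptor O
  scale <- o_o_dist / sqrt(sum((o_a - o_d)^2))
  xyz[8, ] <- o_d + (o_a - o_d) * scale
  elements <- c(rep("C", 5), "O", "H", "O")
  list(xyz = xyz, elements = elements)
}

annotate_hb <- function(sys) {
  # bonds perceived on an ideal geometry, then the acceptor is moved; use
  # explicit bonds so the topology stays fixed while geometry varies
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 6), c(6, 7),
                 c(5, 8))
  annotate_topology(tibble::tibble(element = sys$elements), bonds)
}

test_that("IMHB detection honours distance, angle and bond-path criteria", {
  sys <- hb_system(2.9)
  topo <- annotate_hb(sys)
  ev <- detect_imhb(sys$xyz, topo)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$donor, 6L); expect_equal(ev$acceptor, 8L)
  expect_equal(ev$distance_A, 2.9, tolerance = 1e-9)
  expect_gt(ev$angle_deg, 160)

  # distance failure at 4.2 A
  sys2 <- hb_system(4.2)
  expect_equal(nrow(detect_imhb(sys2$xyz, topo)), 0)

  # angle failure: D-H...A = 150 deg
  sys3 <- hb_system(2.9, angle_dev_deg = 30)
  expect_equal(nrow(detect_imhb(sys3$xyz, topo)), 0)

  # no donors annotated -> declared condition
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  topo_nd <- annotate_frame(xyz, c("C", "C"))$topology
  expect_error(detect_imhb(xyz, topo_nd), "no donors",
               class = "chameleonics_no_donors")
})

test_that("IMHB detection agrees with the brute-force triple-loop oracle", {
  toy <- build_toy_molecule()
  ens <- generate_ensemble(toy, "mixed", n_frames = 30, seed = 31)
  for (f in seq_len(n_frames(ens))) {
    ours <- nrow(detect_imhb(ens$frames[[f]], ens$topology))
    brute <- brute_imhb_count(ens$frames[[f]], ens$topology)
    expect_equal(ours, brute)
  }
})

test_that("tightening criteria never increases IMHB counts and events are rigid-invariant", {
  toy <- build_toy_molecule()
  ens <- generate_ensemble(toy, "folded", n_frames = 15, seed = 32)
  for (f in seq_len(n_frames(ens))) {
    n_loose <- nrow(detect_imhb(ens$frames[[f]], ens$topology,
                                hbond_criteria(4.0, 20)))
    n_tight_d <- nrow(detect_imhb(ens$frames[[f]], ens$topology,
                                  hbond_criteria(3.0, 20)))
    n_tight_a <- nrow(detect_imhb(ens$frames[[f]], ens$topology,
                                  hbond_criteria(4.0, 10)))
    expect_lte(n_tight_d, n_loose)
    expect_lte(n_tight_a, n_loose)
  }
  set.seed(33)
  fr <- ens$frames[[1]]
  moved <- sweep(fr %*% t(random_rotation_matrix()), 2, c(1, 2, 3), "+")
  ev0 <- detect_imhb(fr, ens$topology)
  ev1 <- detect_imhb(moved, ens$topology)
  expect_equal(ev0$donor, ev1$donor)
  expect_equal(ev0$distance_A, ev1$distance_A, tolerance = 1e-9)
})

test_that("IMHB frequency counts planted occupancy and concatenation conserves it", {
  toy <- build_toy_molecule()
  folded <- generate_ensemble(toy, "folded", n_frames = 40, seed = 34)
  extended <- generate_ensemble(toy, "extended", n_frames = 40, seed = 35)
  expect_equal(imhb_frequency(folded)$freq_ge1, 1.0)
  expect_equal(imhb_frequency(folded)$freq_ge2, 0.0)
  expect_equal(imhb_frequency(extended)$freq_ge1, 0.0)

  # planted half-occupancy, exactly
  mixed <- generate_ensemble(toy, "mixed", n_frames = 200,
                             fraction_folded = 0.5, seed = 36)
  fr <- imhb_frequency(mixed)
  expect_equal(fr$freq_ge1, 0.5)
  expect_equal(fr$freq_ge2, 0.0)

  # concatenation = frame-count-weighted mean of the parts
  both <- folded; both$frames <- c(folded$frames, extended$frames)
  expect_equal(imhb_frequency(both)$freq_ge1,
               (40 * 1.0 + 40 * 0.0) / 80)
})

test_that("Burgi-Dunitz window classifies textbook geometries", {
  # carbonyl C at origin, O along +x; N placed at given distance/angle in xy
  place_n <- function(dist, angle_deg) {
    th <- angle_deg * pi / 180
    c(dist * cos(th), dist * sin(th), 0)
  }
  mk <- function(nu_pos) {
    xyz <- rbind(c(0, 0, 0), c(1.23, 0, 0), nu_pos)
    bonds <- rbind(c(1, 2))
    topo <- annotate_topology(tibble::tibble(element = c("C", "O", "N")),
                              bonds)
    burgi_dunitz_scan(xyz, topo, nucleophiles = 3L)
  }
  expect_true(mk(place_n(3.0, 107))$satisfied)
  expect_false(mk(place_n(3.0, 90))$satisfied)
  expect_false(mk(place_n(5.0, 107))$satisfied)
  expect_equal(mk(place_n(3.0, 107))$angle_deg, 107, tolerance = 1e-9)

  # no carbonyls -> empty scan
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  topo2 <- annotate_frame(xyz, c("C", "N"))$topology
  expect_equal(nrow(burgi_dunitz_scan(xyz, topo2, 2L)), 0)
})

test_that("pi-stacking separates parallel, T-shaped and unstacked rings", {
  th <- (0:5) * pi / 3
  hex <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  stacked <- cbind(hex[, 1], hex[, 2], 3.5)
  perp <- t(apply(hex, 1, function(p) c(p[1], 5.0 + p[3], p[2])))
  far <- cbind(hex[, 1] + 8, hex[, 2], 0)

  xyz <- rbind(hex, stacked)
  topo <- annotate_frame(xyz, rep("C", 12))$topology
  expect_equal(pi_stacking(xyz, topo, 1:6, 7:12)$kind, "pi_parallel")

  xyz2 <- rbind(hex, perp)
  expect_equal(pi_stacking(xyz2, topo, 1:6, 7:12)$kind, "pi_tshaped")

  xyz3 <- rbind(hex, far)
  expect_equal(pi_stacking(xyz3, topo, 1:6, 7:12)$kind, "none")

  expect_error(pi_stacking(xyz, topo, 1:6, 5:10), "disjoint")
  expect_error(pi_stacking(xyz, topo, 1:2, 7:12), "at least 3")
})

test_that("C-H/pi detection requires the H above the ring face", {
  th <- (0:5) * pi / 3
  hex <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  mk <- function(hpos) {
    xyz <- rbind(hex, hpos)
    topo <- annotate_frame(rbind(hex, c(0, 0, 9)), c(rep("C", 6), "H"))$topology
    ch_pi(xyz, topo, ring = 1:6, hydrogens = 7L)
  }
  expect_equal(nrow(mk(c(0, 0, 2.6))), 1)     # above centroid
  expect_equal(nrow(mk(c(2.6, 0, 0))), 0)     # in-plane, beside the rim
  expect_equal(nrow(mk(c(0, 0, 5))), 0)       # too far
})
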