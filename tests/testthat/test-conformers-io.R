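# Structure I/O, bond perception and topology annotation.

test_that("multi-model PDB and multi-frame XYZ round-trip within format precision", {
  set.seed(11)
  frames <- lapply(1:3, function(i) matrix(rnorm(15, sd = 3), 5, 3))
  ens <- make_ensemble(frames, c("C", "C", "O", "N", "H"))
  expect_equal(n_frames(ens), 3)
  expect_equal(n_atoms(ens), 5)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, pdb)
  back <- read_ensemble(pdb)
  expect_equal(n_frames(back), 3)
  expect_equal(back$topology$atoms$element, ens$topology$atoms$element)
  for (i in 1:3)
    expect_lt(max(abs(back$frames[[i]] - ens$frames[[i]])), 1e-3)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_ensemble(ens, xyz)
  expect_equal(length(readLines(xyz)), 3 * (5 + 2))
  back2 <- read_ensemble(xyz)
  for (i in 1:3)
    expect_lt(max(abs(back2$frames[[i]] - ens$frames[[i]])), 1e-6)
})

test_that("parse errors name the offending model and bad inputs are rejected", {
  ens <- make_ensemble(list(matrix(0:8, 3, 3) * 1.0), c("C", "O", "N"))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, pdb, frames = c(1, 1))
  lines <- readLines(pdb)
  # drop one atom from MODEL 2
  atom2 <- which(startsWith(lines, "ATOM"))[4]
  writeLines(lines[-atom2], pdb)
  expect_error(read_ensemble(pdb), "MODEL 2",
               class = "chameleonics_parse_error")

  bad_xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "frame", "C 0 0 0", "O 1 0 0"), bad_xyz)
  expect_error(read_ensemble(bad_xyz), "truncated",
               class = "chameleonics_parse_error")

  unk <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "frame", "Xx 0 0 0"), unk)
  expect_error(read_ensemble(unk), "unknown element")

  expect_error(conformer_ensemble(list(), tibble::tibble(element = "C")))
})

test_that("cross-check: bio3d reads our multi-model PDB identically", {
  skip_if_not_installed("bio3d")
  set.seed(12)
  frames <- lapply(1:2, function(i) matrix(round(rnorm(12, sd = 2), 3), 4, 3))
  ens <- make_ensemble(frames, c("C", "N", "O", "C"))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, pdb)
  ref <- bio3d::read.pdb(pdb, multi = TRUE)
  expect_equal(dim(ref$xyz), c(2, 12))
  expect_equal(matrix(ref$xyz[1, ], 4, 3, byrow = TRUE), frames[[1]],
               tolerance = 1e-6)
  expect_equal(matrix(ref$xyz[2, ], 4, 3, byrow = TRUE), frames[[2]],
               tolerance = 1e-6)
})

test_that("bond perception follows covalent-radius sums and is symmetric", {
  # C-C at 1.5 A bonded; 3.0 A not; O-H at 0.96 bonded
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(4.5, 0, 0), c(4.5, 0.96, 0))
  ens <- make_ensemble(list(xyz), c("C", "C", "O", "H"))
  b <- perceive_bonds(ens)
  expect_equal(unname(b), rbind(c(1L, 2L), c(3L, 4L)), ignore_attr = TRUE)

  # permutation covariance: relabeling atoms relabels bonds
  perm <- c(3L, 1L, 4L, 2L)
  ens2 <- make_ensemble(list(xyz[perm, ]), c("C", "C", "O", "H")[perm])
  b2 <- perceive_bonds(ens2)
  remapped <- apply(b, 1, function(r) sort(match(r, perm)))
  expect_setequal(paste(b2[, 1], b2[, 2]),
                  paste(remapped[1, ], remapped[2, ]))
})

test_that("annotation identifies donors, acceptors, polar set, rings and carbonyls", {
  # hydroxyl: O with H -> donor pair, acceptor, polar (both O and H)
  xyz <- rbind(c(0, 0, 0), c(1.43, 0, 0), c(1.76, 0.9, 0))
  ens <- annotate_frame(xyz, c("C", "O", "H"))
  topo <- ens$topology
  expect_equal(topo$donor_h, tibble::tibble(heavy = 2L, h = 3L))
  expect_true(2L %in% topo$acceptors)
  expect_equal(topo$atoms$polar, c(FALSE, TRUE, TRUE))

  # carbonyl O (terminal, no H): acceptor, not donor
  xyz2 <- rbind(c(0, 0, 0), c(1.23, 0, 0))
  topo2 <- annotate_frame(xyz2, c("C", "O"))$topology
  expect_equal(nrow(topo2$donor_h), 0)
  expect_equal(topo2$acceptors, 2L)
  expect_equal(topo2$carbonyls, tibble::tibble(c = 1L, o = 2L))

  # benzene bond graph: one planar aromatic 6-ring
  th <- (0:5) * pi / 3
  hex <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  topo3 <- annotate_frame(hex, rep("C", 6))$topology
  expect_length(topo3$rings, 1)
  expect_setequal(topo3$rings[[1]]$atoms, 1:6)
  expect_true(topo3$rings[[1]]$aromatic)

  # annotation is idempotent/deterministic for a fixed bond graph
  b <- perceive_bonds(annotate_frame(hex, rep("C", 6)))
  t_a <- annotate_topology(tibble::tibble(element = rep("C", 6)), b, frame = hex)
  t_b <- annotate_topology(tibble::tibble(element = rep("C", 6)), b, frame = hex)
  expect_identical(t_a, t_b)
})

test_that("annotation overrides win and invalid overrides error", {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0))
  ov <- tibble::tibble(atom_index = 2L, role = "polar")
  topo <- annotate_frame(xyz, c("C", "C", "C"), overrides = ov)$topology
  expect_true(topo$atoms$polar[2])
  expect_error(
    annotate_frame(xyz, c("C", "C", "C"),
                   overrides = tibble::tibble(atom_index = 9L, role = "polar")),
    "outside")
})
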