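# Superposed RMSD, pairwise matrices, clustering, congruent search,
# property summaries.

test_that("superposed RMSD is zero under rigid motion and matches the grid oracle", {
  set.seed(41)
  a <- matrix(rnorm(12, sd = 2), 4, 3)
  expect_equal(superposed_rmsd(a, a), 0, tolerance = 1e-9)

  moved <- sweep(a %*% t(random_rotation_matrix()), 2, c(5, -3, 2), "+")
  expect_lt(superposed_rmsd(a, moved), 1e-6)

  # 4-atom toy with one displaced atom: agree with the independent
  # rotation-grid oracle
  for (rep in 1:3) {
    b <- a
    b[rep, ] <- b[rep, ] + c(1, 0, 0)
    b <- sweep(b %*% t(random_rotation_matrix()), 2, rnorm(3), "+")
    expect_equal(superposed_rmsd(a, b), grid_rmsd_oracle(a, b),
                 tolerance = 1e-3)
  }

  expect_error(superposed_rmsd(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("superposed RMSD is a pseudo-metric on random toy triples", {
  set.seed(42)
  for (i in 1:25) {
    x <- matrix(rnorm(15), 5, 3)
    y <- matrix(rnorm(15), 5, 3)
    z <- matrix(rnorm(15), 5, 3)
    dxy <- superposed_rmsd(x, y)
    dyx <- superposed_rmsd(y, x)
    dxz <- superposed_rmsd(x, z)
    dzy <- superposed_rmsd(z, y)
    expect_equal(dxy, dyx, tolerance = 1e-6)
    expect_lte(dxy, dxz + dzy + 1e-6)
  }
})

test_that("pairwise RMSD matrix is symmetric with zero diagonal; mismatches error", {
  toy <- build_toy_molecule()
  ens <- generate_ensemble(toy, "mixed", n_frames = 12, seed = 43)
  m <- pairwise_rmsd(ens)
  expect_equal(diag(m), rep(0, 12))
  expect_lt(max(abs(m - t(m))), 1e-9)
  expect_true(all(m >= 0))

  # duplicated frame gives a duplicate row
  dup <- ens; dup$frames <- c(ens$frames, ens$frames[1])
  md <- pairwise_rmsd(dup)
  expect_equal(md[13, ], md[1, ], tolerance = 1e-9)

  other <- generate_ensemble(build_toy_molecule(chain_length = 9),
                             "extended", n_frames = 3, seed = 44)
  expect_error(pairwise_rmsd(ens, other), "topology")
})

test_that("k-means on the RMSD matrix recovers planted groups and is deterministic", {
  toy <- build_toy_molecule()
  set.seed(45)
  base_a <- generate_ensemble(toy, "folded", n_frames = 1, seed = 46)$frames[[1]]
  base_b <- generate_ensemble(toy, "extended", n_frames = 1, seed = 47)$frames[[1]]
  jitterer <- function(x) x + matrix(rnorm(length(x), sd = 0.01), nrow(x), 3)
  frames <- c(replicate(10, jitterer(base_a), simplify = FALSE),
              replicate(10, jitterer(base_b), simplify = FALSE))
  ens <- make_ensemble(frames, toy$topology$atoms$element)
  ens$topology <- toy$topology
  m <- pairwise_rmsd(ens)
  truth <- rep(1:2, each = 10)

  # perfect partition across 100 random seeds
  ok <- vapply(1:100, function(s) {
    cl <- cluster_frames(m, k = 2, seed = s)
    length(unique(paste(cl$labels, truth))) == 2
  }, logical(1))
  expect_true(all(ok))

  # determinism: same seed, same labels; k = n gives singleton clusters
  expect_identical(cluster_frames(m, k = 2, seed = 7)$labels,
                   cluster_frames(m, k = 2, seed = 7)$labels)
  cl_n <- cluster_frames(m, k = 20, seed = 1)
  expect_equal(sort(cl_n$representatives), 1:20)
  expect_equal(cl_n$populations, rep(1 / 20, 20))

  cl <- cluster_frames(m, k = 2, seed = 1)
  expect_equal(sum(cl$populations), 1)
  expect_true(all(vapply(seq_len(cl$k), function(i)
    cl$labels[cl$representatives[i]] == i, logical(1))))
  expect_error(cluster_frames(m, k = 21), "exceeds")
  expect_error(cluster_frames(m, k = 0), "positive")
})

test_that("congruent search finds identity, separation, and monotone thresholds", {
  toy <- build_toy_molecule()
  a <- generate_ensemble(toy, "extended", n_frames = 15, seed = 48)
  # identical ensembles of distinct conformers: both fractions 1
  rep_id <- congruent_search(a, a)
  expect_equal(rep_id$fraction_a, 1)
  expect_equal(rep_id$fraction_b, 1)

  # disjoint regimes: no matches
  b <- generate_ensemble(toy, "folded", n_frames = 15, seed = 49)
  rep_disj <- congruent_search(a, b)
  expect_equal(rep_disj$fraction_a, 0)
  expect_equal(nrow(rep_disj$pairs), 0)

  # monotone non-decreasing in threshold
  f_at <- vapply(c(0.5, 1, 2, 5), function(th)
    congruent_search(a, b, threshold_A = th)$fraction_a, numeric(1))
  expect_true(all(diff(f_at) >= 0))
})

test_that("exclusion predicate drops leading frames and high-Rgyr outliers", {
  toy <- build_toy_molecule()
  a <- generate_ensemble(toy, "extended", n_frames = 40, seed = 50)
  b <- generate_ensemble(toy, "folded", n_frames = 40, seed = 51)
  keep <- exclude_linear()(b, b)          # self-opposing: only head trimmed
  expect_false(any(keep[1:2]))
  keep_ab <- exclude_linear()(a, b)       # extended vs folded: Rgyr cut bites
  expect_lt(mean(keep_ab), mean(keep))
  drop_all <- function(ensemble, opposing) rep(FALSE, n_frames(ensemble))
  expect_error(congruent_search(a, b, exclude = drop_all), "empty")
})

test_that("property-space summary computes fractions and type-7 quartiles", {
  tab <- tibble::tibble(frame = 1:4, sa3dpsa_A2 = c(100, 200, 300, 400))
  s <- property_space_summary(tab, c(sa3dpsa_A2 = 215))
  expect_equal(s$fraction_below, 0.5)

  tab2 <- tibble::tibble(frame = 1:8, rgyr_A = as.numeric(1:8))
  s2 <- property_space_summary(tab2)
  expect_equal(c(s2$q1, s2$median, s2$q3), c(2.75, 4.5, 6.25))

  expect_equal(property_space_summary(
    tab, c(sa3dpsa_A2 = 50))$fraction_below, 0)
  expect_error(property_space_summary(tab, c(nope = 1)), "unknown")
  expect_error(property_space_summary(tab[0, ]), "empty")
})
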