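# Shared fixtures, built in code.

# minimal ensemble from a list of coordinate matrices and element symbols
make_ensemble <- function(frames, elements, environment = "test") {
  conformer_ensemble(frames, tibble::tibble(element = elements),
                     environment = environment)
}

# annotated single-frame system for interaction tests: coordinates chosen
# per test, elements fixed
annotate_frame <- function(xyz, elements, tolerance = 0.4, overrides = NULL) {
  ens <- make_ensemble(list(xyz), elements)
  annotate_ensemble(ens, tolerance = tolerance, overrides = overrides)
}

# independent rotation-grid + local-refinement RMSD oracle (no Kabsch):
# coarse scan over Euler angles, then Nelder-Mead refinement
euler_rot <- function(a, b, g) {
  rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  rz1 %*% ry %*% rz2
}

grid_rmsd_oracle <- function(xa, xb) {
  a <- sweep(xa, 2, colMeans(xa))
  b <- sweep(xb, 2, colMeans(xb))
  f <- function(p) {
    r <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((b %*% t(r) - a)^2)))
  }
  step <- pi / 9
  grid <- expand.grid(a = seq(0, 2 * pi - step, step),
                      b = seq(0, pi, step),
                      g = seq(0, 2 * pi - step, step))
  vals <- apply(grid, 1, f)
  p0 <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(p0, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# brute-force IMHB oracle: explicit triple loop over (donor heavy, H,
# acceptor) with its own geometry code and bond-path search
brute_imhb_count <- function(xyz, topology, dist_max = 4, angle_tol = 20,
                             min_sep = 4) {
  el <- topology$atoms$element
  bonds <- topology$bonds
  n <- nrow(topology$atoms)
  adj <- lapply(seq_len(n), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  bfs_dist <- function(from, to) {
    seen <- rep(Inf, n); seen[from] <- 0; q <- from
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (seen[w] > seen[v] + 1) {
        seen[w] <- seen[v] + 1; q <- c(q, w)
      }
    }
    seen[to]
  }
  events <- 0
  for (d in which(el %in% c("N", "O"))) for (h in adj[[d]]) {
    if (el[h] != "H") next
    for (a in which(el %in% c("N", "O", "S"))) {
      if (a == d || a == h) next
      if (bfs_dist(d, a) < min_sep) next
      if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) > dist_max) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= 180 - angle_tol) events <- events + 1
    }
  }
  events
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
    2 * (q[2] * q[4] + q[3] * q[1]),
    2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[2] * q[1]),
    2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}
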