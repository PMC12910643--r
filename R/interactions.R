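# Per-conformer intramolecular contacts: hydrogen bonds under geometric
# criteria, Burgi-Dunitz n->pi* approach geometry, pi-stacking and C-H/pi
# classification, and ensemble-level frequencies.

#' Hydrogen-bond detection criteria
#'
#' Geometric criteria for an intramolecular hydrogen bond: donor-heavy to
#' acceptor distance at most `dist_max_A`, the D-H...A angle within
#' `angle_tol_deg` of linear (i.e. at least `180 - angle_tol_deg` degrees),
#' and at least `min_bond_sep` bonds between donor heavy atom and acceptor
#' so that covalent neighbours are never counted.
#'
#' @param dist_max_A Maximum donor-acceptor distance (Angstrom, default 4).
#' @param angle_tol_deg Maximum deviation of D-H...A from 180 degrees
#'   (default 20).
#' @param min_bond_sep Minimum bond-path separation between donor heavy atom
#'   and acceptor (default 4).
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(dist_max_A = 4.0, angle_tol_deg = 20,
                           min_bond_sep = 4L) {
  stopifnot(dist_max_A > 0, angle_tol_deg > 0, angle_tol_deg < 90)
  structure(list(dist_max_A = dist_max_A, angle_tol_deg = angle_tol_deg,
                 min_bond_sep = as.integer(min_bond_sep)),
            class = "hbond_criteria")
}

#' Burgi-Dunitz parameters
#'
#' Geometry window for an n->pi* nucleophile-to-carbonyl approach: N...C
#' distance cutoff and an angular window on the N...C=O angle around the
#' canonical 107 degrees.
#'
#' @param dist_max_A Maximum nucleophile-carbonyl-carbon distance
#'   (Angstrom, default 3.6).
#' @param angle_window_deg Two-element inclusive window on the N...C=O angle
#'   (degrees, default `c(95, 125)`).
#' @return A list of class `bd_params`.
#' @export
bd_params <- function(dist_max_A = 3.6, angle_window_deg = c(95, 125)) {
  stopifnot(dist_max_A > 0, length(angle_window_deg) == 2,
            angle_window_deg[1] > 0, angle_window_deg[2] < 180,
            angle_window_deg[1] < angle_window_deg[2])
  structure(list(dist_max_A = dist_max_A, angle_window_deg = angle_window_deg),
            class = "bd_params")
}

vec_angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect intramolecular hydrogen bonds in one frame
#'
#' Emits one event per (donor H, acceptor) pair satisfying
#' [hbond_criteria()]. Self pairs (donor heavy == acceptor) and short
#' bond-path pairs are excluded.
#'
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param topology Annotated topology with donor and acceptor annotations.
#' @param criteria An [hbond_criteria()] object.
#' @return Tibble with columns `kind`, `donor`, `h`, `acceptor`,
#'   `distance_A` (D...A), `angle_deg` (D-H...A).
#' @export
detect_imhb <- function(xyz, topology, criteria = hbond_criteria()) {
  if (!isTRUE(topology$annotated))
    abort("topology is not annotated")
  if (nrow(topology$donor_h) == 0)
    abort("no donors annotated: topology has no H bound to N or O",
          class = "chameleonics_no_donors")
  xyz <- as.matrix(xyz)
  # bond-path distances from each donor heavy atom to all atoms, once
  g <- igraph::graph_from_edgelist(topology$bonds, directed = FALSE)
  if (igraph::vcount(g) < nrow(topology$atoms))
    g <- igraph::add_vertices(g, nrow(topology$atoms) - igraph::vcount(g))
  sep <- suppressWarnings(
    igraph::distances(g, v = topology$donor_h$heavy, to = topology$acceptors))
  out <- purrr::map_dfr(seq_len(nrow(topology$donor_h)), function(k) {
    d_heavy <- topology$donor_h$heavy[k]
    h <- topology$donor_h$h[k]
    purrr::map_dfr(seq_along(topology$acceptors), function(ai) {
      a <- topology$acceptors[ai]
      if (a == d_heavy || a == h) return(NULL)
      if (sep[k, ai] < criteria$min_bond_sep) return(NULL)
      da <- sqrt(sum((xyz[d_heavy, ] - xyz[a, ])^2))
      if (da > criteria$dist_max_A) return(NULL)
      ang <- vec_angle_deg(xyz[d_heavy, ] - xyz[h, ], xyz[a, ] - xyz[h, ])
      if (ang < 180 - criteria$angle_tol_deg) return(NULL)
      tibble(kind = "imhb", donor = d_heavy, h = h, acceptor = a,
             distance_A = da, angle_deg = ang)
    })
  })
  if (nrow(out) == 0)
    out <- tibble(kind = character(), donor = integer(), h = integer(),
                  acceptor = integer(), distance_A = numeric(),
                  angle_deg = numeric())
  out
}

#' Intramolecular hydrogen-bond frequency over an ensemble
#'
#' Counts distinct donor-acceptor events per frame and reports the fraction
#' of frames with at least one and at least two IMHBs (an occupancy table
#' for comparing solvent environments).
#'
#' @param ensemble Annotated [conformer_ensemble].
#' @param criteria An [hbond_criteria()] object.
#' @return Tibble with columns `environment`, `n_frames`, `freq_ge1`,
#'   `freq_ge2`, `mean_per_frame`.
#' @export
imhb_frequency <- function(ensemble, criteria = hbond_criteria()) {
  stopifnot(inherits(ensemble, "conformer_ensemble"), n_frames(ensemble) >= 1)
  counts <- vapply(ensemble$frames, function(fr) {
    ev <- detect_imhb(fr, ensemble$topology, criteria)
    nrow(dplyr::distinct(ev, .data$donor, .data$acceptor))
  }, 1L)
  tibble(environment = ensemble$environment, n_frames = length(counts),
         freq_ge1 = mean(counts >= 1), freq_ge2 = mean(counts >= 2),
         mean_per_frame = mean(counts))
}

#' Burgi-Dunitz scan of nucleophile-to-carbonyl approaches
#'
#' For every (nucleophile, carbonyl C=O) pair, reports the N...C distance,
#' the N...C=O angle, and whether the pair falls inside the Burgi-Dunitz
#' window of [bd_params()].
#'
#' @param xyz N x 3 coordinate matrix.
#' @param topology Annotated topology (uses its `carbonyls`).
#' @param nucleophiles Atom indices of the attacking lone-pair atoms
#'   (e.g. basic ring nitrogens).
#' @param params A [bd_params()] object.
#' @return Tibble with columns `nucleophile`, `carbonyl_c`, `carbonyl_o`,
#'   `distance_A`, `angle_deg`, `satisfied`. Empty if no carbonyls are
#'   annotated.
#' @export
burgi_dunitz_scan <- function(xyz, topology, nucleophiles,
                              params = bd_params()) {
  xyz <- as.matrix(xyz)
  cb <- topology$carbonyls
  if (nrow(cb) == 0)
    return(tibble(nucleophile = integer(), carbonyl_c = integer(),
                  carbonyl_o = integer(), distance_A = numeric(),
                  angle_deg = numeric(), satisfied = logical()))
  purrr::map_dfr(nucleophiles, function(nu) {
    purrr::map_dfr(seq_len(nrow(cb)), function(k) {
      ci <- cb$c[k]; oi <- cb$o[k]
      if (nu %in% c(ci, oi)) return(NULL)
      dist <- sqrt(sum((xyz[nu, ] - xyz[ci, ])^2))
      ang <- vec_angle_deg(xyz[nu, ] - xyz[ci, ], xyz[oi, ] - xyz[ci, ])
      tibble(nucleophile = nu, carbonyl_c = ci, carbonyl_o = oi,
             distance_A = dist, angle_deg = ang,
             satisfied = dist <= params$dist_max_A &
               ang >= params$angle_window_deg[1] &
               ang <= params$angle_window_deg[2])
    })
  })
}

ring_geometry <- function(xyz, ring_atoms) {
  if (length(ring_atoms) < 3) abort("ring must have at least 3 atoms")
  pts <- xyz[ring_atoms, , drop = FALSE]
  centroid <- colMeans(pts)
  c0 <- sweep(pts, 2, centroid)
  normal <- svd(c0)$v[, 3]
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

#' Classify pi-stacking geometry between two aromatic rings
#'
#' Parallel stacking: centroid distance at most `par_dist_A` and acute
#' interplanar angle at most `par_angle_deg`. T-shaped stacking: centroid
#' distance at most `t_dist_A` and interplanar angle at least `t_angle_deg`.
#'
#' @param xyz N x 3 coordinate matrix.
#' @param topology Annotated topology.
#' @param ring_a,ring_b Atom-index vectors of two disjoint aromatic rings.
#' @param par_dist_A,par_angle_deg,t_dist_A,t_angle_deg Classification
#'   thresholds (defaults 4.4 Angstrom / 30 deg and 5.5 Angstrom / 60 deg).
#' @return Tibble with `kind` in `"pi_parallel"`, `"pi_tshaped"`, `"none"`,
#'   plus `distance_A` (centroid-centroid) and `angle_deg` (acute
#'   interplanar angle).
#' @export
pi_stacking <- function(xyz, topology, ring_a, ring_b,
                        par_dist_A = 4.4, par_angle_deg = 30,
                        t_dist_A = 5.5, t_angle_deg = 60) {
  if (length(intersect(ring_a, ring_b)) > 0) abort("rings must be disjoint")
  xyz <- as.matrix(xyz)
  ga <- ring_geometry(xyz, ring_a)
  gb <- ring_geometry(xyz, ring_b)
  d <- sqrt(sum((ga$centroid - gb$centroid)^2))
  ang <- vec_angle_deg(ga$normal, gb$normal)
  ang <- min(ang, 180 - ang)  # acute interplanar angle
  kind <- if (d <= par_dist_A && ang <= par_angle_deg) "pi_parallel"
  else if (d <= t_dist_A && ang >= t_angle_deg) "pi_tshaped"
  else "none"
  tibble(kind = kind, distance_A = d, angle_deg = ang)
}

#' Detect C-H/pi contacts with an aromatic ring
#'
#' A hydrogen forms a C-H/pi contact when it sits within `dist_max_A` of the
#' ring centroid and its projection onto the ring plane falls inside a disc
#' of radius `proj_max_A` around the centroid (i.e. it is above the ring
#' face, not beside the rim).
#'
#' @param xyz N x 3 coordinate matrix.
#' @param topology Annotated topology.
#' @param ring Atom-index vector of an aromatic ring.
#' @param hydrogens Candidate H atom indices.
#' @param dist_max_A H-to-centroid cutoff (default 3.0).
#' @param proj_max_A In-plane projection radius (default 1.6).
#' @return Tibble of events: `kind`, `h`, `distance_A`, `offset_A`.
#' @export
ch_pi <- function(xyz, topology, ring, hydrogens,
                  dist_max_A = 3.0, proj_max_A = 1.6) {
  xyz <- as.matrix(xyz)
  g <- ring_geometry(xyz, ring)
  out <- purrr::map_dfr(hydrogens, function(h) {
    v <- xyz[h, ] - g$centroid
    d <- sqrt(sum(v^2))
    perp <- sum(v * g$normal)
    offset <- sqrt(max(0, d^2 - perp^2))
    if (d <= dist_max_A && offset <= proj_max_A)
      tibble(kind = "ch_pi", h = h, distance_A = d, offset_A = offset)
    else NULL
  })
  if (nrow(out) == 0)
    out <- tibble(kind = character(), h = integer(), distance_A = numeric(),
                  offset_A = numeric())
  out
}
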