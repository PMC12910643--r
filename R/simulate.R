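# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth. Purely geometric (no force field): the generators realise
# the statistical structure the analysis assumes -- two conformational
# regimes (folded/low-polarity vs extended/high-polarity), planted
# intramolecular hydrogen bonds, planted congruent subsets -- plus
# dose-response, PAMPA, microsome and NMR-shift fixtures.

#' Build a toy chameleonic molecule
#'
#' A linear carbon backbone decorated with a hydroxyl donor (O-H) near one
#' end, a carbonyl acceptor (C=O) at the other, and optionally one aromatic
#' six-ring. The extended zigzag reference frame keeps donor and acceptor
#' far apart; hinge-folding brings them into hydrogen-bond contact. The
#' returned topology is annotated exactly as bond perception on the
#' reference frame yields it.
#'
#' @param chain_length Number of backbone carbons (default 12, minimum 8).
#' @param donor_atom Backbone atom carrying the hydroxyl (default 1).
#' @param acceptor_atom Backbone carbon of the carbonyl (default: chain
#'   end).
#' @param ring_atom Optional backbone atom carrying an aromatic six-ring.
#' @param bond_length_A Backbone bond length (default 1.5).
#' @return Object of class `toy_molecule`: list with `topology`
#'   (annotated), `reference` (extended N x 3 frame), and index bookkeeping
#'   (`o_donor`, `h_donor`, `o_acceptor`, `chain`, `hinge`).
#' @export
build_toy_molecule <- function(chain_length = 12L, donor_atom = 1L,
                               acceptor_atom = NULL, ring_atom = NULL,
                               bond_length_A = 1.5) {
  L <- as.integer(chain_length)
  if (L < 8) abort("chain_length must be at least 8")
  acceptor_atom <- acceptor_atom %||% L
  if (donor_atom < 1 || donor_atom > L || acceptor_atom < 1 ||
      acceptor_atom > L || donor_atom == acceptor_atom)
    abort("donor/acceptor positions must be distinct backbone atoms")
  if (!is.null(ring_atom) && (ring_atom < 1 || ring_atom > L))
    abort("ring_atom outside the backbone")

  # extended zigzag in the xy-plane, bond angle ~114 deg
  dx <- 1.26 * bond_length_A / 1.5
  dy <- 0.82 * bond_length_A / 1.5
  bb <- cbind((seq_len(L) - 1) * dx, (seq_len(L) %% 2) * dy, 0)
  el <- rep("C", L)
  nm <- paste0("C", seq_len(L))

  # hydroxyl: O on donor_atom, pointing -x/+y; H beyond it
  od_dir <- c(-1, 1, 0) / sqrt(2)
  o_d <- bb[donor_atom, ] + 1.43 * od_dir
  h_d <- o_d + 0.97 * od_dir
  xyz <- rbind(bb, o_d, h_d)
  el <- c(el, "O", "H"); nm <- c(nm, "OD", "HD")
  i_od <- L + 1L; i_hd <- L + 2L

  # carbonyl O beyond the acceptor carbon along +x
  oa_dir <- if (acceptor_atom == L) c(1, 0, 0) else c(0, -1, 0)
  o_a <- bb[acceptor_atom, ] + 1.23 * oa_dir
  xyz <- rbind(xyz, o_a)
  el <- c(el, "O"); nm <- c(nm, "OA")
  i_oa <- nrow(xyz)

  ring_idx <- integer()
  if (!is.null(ring_atom)) {
    centre <- bb[ring_atom, ] + c(0, 0, 1.5 + 1.39)
    th <- -pi / 2 + (0:5) * pi / 3
    ring <- t(vapply(th, function(a)
      centre + 1.39 * c(cos(a), 0, sin(a)), numeric(3)))
    xyz <- rbind(xyz, ring)
    el <- c(el, rep("C", 6)); nm <- c(nm, paste0("CR", 1:6))
    ring_idx <- (nrow(xyz) - 5L):nrow(xyz)
  }

  ens <- conformer_ensemble(list(unname(xyz)), tibble(element = el, name = nm),
                            environment = "reference")
  ens <- annotate_ensemble(ens)
  topo <- ens$topology

  hinge <- floor(L / 2)
  structure(
    list(topology = topo, reference = unname(xyz), chain = seq_len(L),
         o_donor = i_od, h_donor = i_hd, o_acceptor = i_oa,
         ring = ring_idx, hinge = hinge,
         rotatable = setdiff(2:(L - 1), NULL)),
    class = "toy_molecule")
}

#' @export
print.toy_molecule <- function(x, ...) {
  cat(sprintf("<toy_molecule> %d backbone C, %d atoms total%s\n",
              length(x$chain), nrow(x$topology$atoms),
              if (length(x$ring)) ", 1 aromatic ring" else ""))
  invisible(x)
}

# rotate `points` (matrix) about the axis through `origin` along unit `axis`
rotate_about_axis <- function(points, origin, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  p <- sweep(points, 2, origin)
  cosang <- cos(angle); sinang <- sin(angle)
  dot <- as.numeric(p %*% axis)
  crossp <- cbind(axis[2] * p[, 3] - axis[3] * p[, 2],
                  axis[3] * p[, 1] - axis[1] * p[, 3],
                  axis[1] * p[, 2] - axis[2] * p[, 1])
  rot <- p * cosang + crossp * sinang +
    outer(dot * (1 - cosang), axis)
  sweep(rot, 2, origin, "+")
}

# atoms distal to backbone bond (i, i+1): everything reachable from i+1
# with that bond removed (precomputed per bond from the topology graph)
distal_sets <- function(topology, chain) {
  g <- igraph::graph_from_edgelist(topology$bonds, directed = FALSE)
  if (igraph::vcount(g) < nrow(topology$atoms))
    g <- igraph::add_vertices(g, nrow(topology$atoms) - igraph::vcount(g))
  lapply(seq_len(length(chain) - 1), function(i) {
    eid <- igraph::get_edge_ids(g, c(chain[i], chain[i + 1]))
    g2 <- igraph::delete_edges(g, eid)
    comp <- igraph::components(g2)$membership
    which(comp == comp[chain[i + 1]])
  })
}

apply_torsion_noise <- function(xyz, toy, distal, sd_deg, bonds_idx,
                                gauche_prob = 0) {
  for (b in bonds_idx) {
    flip <- if (gauche_prob > 0)
      sample(c(-120, 0, 120), 1,
             prob = c(gauche_prob / 2, 1 - gauche_prob, gauche_prob / 2))
    else 0
    ang <- (stats::rnorm(1, 0, sd_deg) + flip) * pi / 180
    axis <- xyz[toy$chain[b + 1], ] - xyz[toy$chain[b], ]
    ds <- distal[[b]]
    xyz[ds, ] <- rotate_about_axis(xyz[ds, , drop = FALSE],
                                   xyz[toy$chain[b], ], axis, ang)
  }
  xyz
}

# pairs within two bonds (and self) are geometry-constrained, not clashes;
# the mask is computed once per topology and reused across frames
bonded_exclusion_mask <- function(topology) {
  n <- nrow(topology$atoms)
  g <- igraph::graph_from_edgelist(topology$bonds, directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  sp <- igraph::distances(g)
  sp <= 2
}

min_nonbonded_dist <- function(xyz, excl) {
  d <- as.matrix(stats::dist(xyz))
  d[excl] <- Inf
  min(d)
}

random_rigid_motion <- function(xyz) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  r <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
    2 * (q[2] * q[4] + q[3] * q[1]),
    2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[2] * q[1]),
    2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  sweep(xyz %*% t(r), 2, stats::runif(3, -5, 5), "+")
}

# one folded frame: torsion noise, hinge fold bringing the donor O within
# hydrogen-bond reach of the carbonyl O, donor H re-aimed along O_d -> O_a
folded_frame <- function(toy, distal, excl, torsion_sd, gauche_prob = 0.1,
                         max_retry = 400) {
  for (attempt in seq_len(max_retry)) {
    xyz <- apply_torsion_noise(toy$reference, toy, distal, torsion_sd,
                               setdiff(seq_along(distal), toy$hinge),
                               gauche_prob)
    d_ha <- stats::runif(1, 1.8, 2.2)
    target <- d_ha + 0.97
    ds <- distal[[toy$hinge]]
    origin <- xyz[toy$chain[toy$hinge], ]
    # hinge axis: out-of-plane with a random tilt, so successive frames fold
    # along different directions and the folded strands avoid coplanarity
    tilt <- stats::runif(2, -0.35, 0.35)
    axis <- c(sin(tilt[1]), sin(tilt[2]),
              sqrt(max(0.1, 1 - sum(sin(tilt)^2))))
    objective <- function(th) {
      moved <- rotate_about_axis(xyz[toy$o_acceptor, , drop = FALSE],
                                 origin, axis, th)
      abs(sqrt(sum((moved[1, ] - xyz[toy$o_donor, ])^2)) - target)
    }
    grid <- seq(0, 2 * pi, length.out = 73)[-73]
    ob <- vapply(grid, objective, numeric(1))
    # refine every local minimum of the hinge scan and try each solution
    loc <- which(ob < c(ob[-1], ob[1]) & ob < c(ob[length(ob)], ob[-length(ob)]))
    loc <- loc[order(ob[loc])]
    done <- FALSE
    for (l in loc) {
      opt <- stats::optimize(objective, grid[l] + c(-0.2, 0.2))
      if (opt$objective > 0.05) next
      cand <- xyz
      cand[ds, ] <- rotate_about_axis(xyz[ds, , drop = FALSE], origin, axis,
                                      opt$minimum)
      u <- cand[toy$o_acceptor, ] - cand[toy$o_donor, ]
      cand[toy$h_donor, ] <- cand[toy$o_donor, ] + 0.97 * u / sqrt(sum(u^2))
      if (min_nonbonded_dist(cand, excl) < 0.8) next
      xyz <- cand; done <- TRUE; break
    }
    if (!done) next
    return(random_rigid_motion(xyz))
  }
  abort("could not build a clash-free folded conformer; geometry infeasible")
}

# one extended frame: near-trans torsion noise, donor and acceptor kept apart
extended_frame <- function(toy, distal, excl, torsion_sd, gauche_prob = 0.4,
                           max_retry = 60) {
  for (attempt in seq_len(max_retry)) {
    xyz <- apply_torsion_noise(toy$reference, toy, distal, torsion_sd,
                               seq_along(distal), gauche_prob)
    dda <- sqrt(sum((xyz[toy$o_donor, ] - xyz[toy$o_acceptor, ])^2))
    if (dda < 6) next
    if (min_nonbonded_dist(xyz, excl) < 0.8) next
    return(random_rigid_motion(xyz))
  }
  abort("could not build a clash-free extended conformer; geometry infeasible")
}

#' Generate a synthetic conformer ensemble
#'
#' Folded frames carry a planted intramolecular hydrogen bond (donor H
#' within 1.8-2.2 Angstrom of the acceptor O, near-linear D-H...A), so the
#' default detection criteria find one IMHB in every folded frame. Extended
#' frames keep donor and acceptor more than 6 Angstrom apart (no IMHB, high
#' exposed polar surface). `mixed` interleaves folded frames evenly at the
#' requested fraction. Every frame receives a random rigid motion;
#' generation is fully determined by `seed`.
#'
#' @param toy A [build_toy_molecule()] object.
#' @param mode `"folded"`, `"extended"` or `"mixed"`.
#' @param n_frames Number of conformers (default 200).
#' @param fraction_folded Folded fraction for `mixed` (default 0.5).
#' @param torsion_noise_deg SD of the continuous backbone torsion noise;
#'   defaults to 10 (folded) or 30 (extended).
#' @param gauche_prob Per-bond probability of an additional discrete
#'   +/-120 degree rotamer flip, the main source of conformational
#'   diversity; defaults to 0.1 (folded) or 0.4 (extended).
#' @param environment Environment label (default: the mode).
#' @param seed Integer seed (default 0).
#' @return An annotated [conformer_ensemble] with attribute `folded`
#'   (logical per frame, the planted ground truth).
#' @export
generate_ensemble <- function(toy, mode = c("folded", "extended", "mixed"),
                              n_frames = 200L, fraction_folded = 0.5,
                              torsion_noise_deg = NULL, gauche_prob = NULL,
                              environment = NULL, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(toy, "toy_molecule"), n_frames >= 1,
            fraction_folded >= 0, fraction_folded <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  distal <- distal_sets(toy$topology, toy$chain)
  excl <- bonded_exclusion_mask(toy$topology)
  folded <- switch(mode,
    folded = rep(TRUE, n_frames),
    extended = rep(FALSE, n_frames),
    mixed = {
      k <- round(fraction_folded * n_frames)
      f <- rep(FALSE, n_frames)
      if (k > 0) f[floor((seq_len(k) - 0.5) * n_frames / k) + 1L] <- TRUE
      f
    })
  sd_fold <- torsion_noise_deg %||% 10
  sd_ext <- torsion_noise_deg %||% 30
  pg_fold <- gauche_prob %||% 0.1
  pg_ext <- gauche_prob %||% 0.4
  frames <- lapply(seq_len(n_frames), function(i) {
    if (folded[i]) folded_frame(toy, distal, excl, sd_fold, pg_fold)
    else extended_frame(toy, distal, excl, sd_ext, pg_ext)
  })
  ens <- conformer_ensemble(frames, toy$topology,
                            environment = environment %||% mode,
                            source = sprintf("synthetic seed=%d", seed))
  attr(ens, "folded") <- folded
  ens
}

#' Generate a paired two-environment ensemble with a planted congruent subset
#'
#' Emulates a polar-environment ensemble (extended regime, `a`) and a
#' nonpolar one (folded regime, `b`), then copies `ceiling(f * n)` randomly
#' chosen frames of `a` into random positions of `b` with at most 0.2
#' Angstrom coordinate jitter — a ground-truth congruent subset recoverable
#' by [congruent_search()].
#'
#' @param toy A [build_toy_molecule()] object.
#' @param n_frames Frames per ensemble (default 400).
#' @param congruent_fraction Planted fraction `f` (default 0.05).
#' @param environment_a,environment_b Labels (defaults `"water"`,
#'   `"toluene"`).
#' @param seed Integer seed.
#' @return List with `a`, `b` (ensembles), `planted_a` (frame ids of `a`
#'   that were copied) and `planted_b` (their positions in `b`).
#' @export
generate_ensemble_pair <- function(toy, n_frames = 400L,
                                   congruent_fraction = 0.05,
                                   environment_a = "water",
                                   environment_b = "toluene",
                                   seed = 0L) {
  stopifnot(congruent_fraction >= 0, congruent_fraction <= 1)
  a <- generate_ensemble(toy, "extended", n_frames,
                         environment = environment_a, seed = seed)
  b <- generate_ensemble(toy, "folded", n_frames,
                         environment = environment_b, seed = seed + 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 2L)
  k <- ceiling(congruent_fraction * n_frames)
  planted_a <- integer(0); planted_b <- integer(0)
  if (k > 0) {
    planted_a <- sort(sample.int(n_frames, k))
    planted_b <- sort(sample.int(n_frames, k))
    for (j in seq_len(k)) {
      fr <- a$frames[[planted_a[j]]]
      jit <- matrix(stats::runif(length(fr), -0.1, 0.1), nrow(fr), 3)
      b$frames[[planted_b[j]]] <- fr + jit
    }
  }
  list(a = a, b = b, planted_a = planted_a, planted_b = planted_b)
}

#' Generate a dose-response series with an optional hook effect
#'
#' Four-parameter logistic decay plus a multiplicative hook term rising
#' beyond a hook-onset concentration, plus Gaussian noise:
#' `y = 4PL(c) + hook_amplitude * (top - bottom) * S(c)` with
#' `S(c) = (c/onset)^hook_hill / (1 + (c/onset)^hook_hill)`.
#'
#' @param dc50_nM,hill,top,bottom 4PL ground truth (defaults 50, 1, 100,
#'   10).
#' @param hook_amplitude Hook size relative to the dynamic range (0 = no
#'   hook).
#' @param hook_onset_nM Concentration of half-maximal hook rise (default
#'   3000).
#' @param hook_hill Hook steepness (default 2).
#' @param noise_sd Additive Gaussian noise SD in response units (default
#'   0).
#' @param noise_cv Proportional Gaussian noise: each response is multiplied
#'   by `1 + N(0, noise_cv)` (default 0). Both noise terms may be combined.
#' @param concentrations_nM Concentration ladder (default the 7-point
#'   half-log design 10...10000 nM).
#' @param seed Integer seed.
#' @return Tibble `conc_nM`, `response_pct` with attribute `truth` (the
#'   generating parameters).
#' @export
generate_dose_response <- function(dc50_nM = 50, hill = 1, top = 100,
                                   bottom = 10, hook_amplitude = 0,
                                   hook_onset_nM = 3000, hook_hill = 2,
                                   noise_sd = 0, noise_cv = 0,
                                   concentrations_nM = c(10, 30, 100, 300,
                                                         1000, 3000, 10000),
                                   seed = 0L) {
  stopifnot(!is.unsorted(concentrations_nM, strictly = TRUE))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cc <- concentrations_nM
  y <- four_pl(cc, bottom, top, dc50_nM, hill)
  if (hook_amplitude > 0) {
    s <- (cc / hook_onset_nM)^hook_hill /
      (1 + (cc / hook_onset_nM)^hook_hill)
    y <- y + hook_amplitude * (top - bottom) * s
  }
  if (noise_cv > 0) y <- y * (1 + stats::rnorm(length(cc), 0, noise_cv))
  if (noise_sd > 0) y <- y + stats::rnorm(length(cc), 0, noise_sd)
  out <- tibble(conc_nM = cc, response_pct = y)
  attr(out, "truth") <- list(dc50_nM = dc50_nM, hill = hill, top = top,
                             bottom = bottom, hook_amplitude = hook_amplitude,
                             hook_onset_nM = hook_onset_nM,
                             hook_hill = hook_hill, noise_sd = noise_sd,
                             noise_cv = noise_cv)
  out
}

# two-compartment PAMPA ODE: donor/acceptor concentrations under passive
# permeation with permeability p (cm/s); the independent oracle for papp()
pampa_ode_acceptor <- function(p_cm_s, c_donor0, area_cm2, v_donor_ml,
                               v_acceptor_ml, time_h) {
  times <- seq(0, time_h * 3600, length.out = 2001)
  out <- deSolve::ode(
    y = c(cd = c_donor0, ca = 0), times = times,
    func = function(t, y, parms) {
      flux <- p_cm_s * area_cm2 * (y["cd"] - y["ca"])
      list(c(-flux / v_donor_ml, flux / v_acceptor_ml))
    }, parms = NULL, method = "lsoda",
    rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), "ca"])
}

#' Generate assay fixtures with known ground truth
#'
#' Produces (i) a PAMPA run whose acceptor concentration comes from
#' numerically integrating the two-compartment permeation ODE at a known
#' permeability, (ii) a microsome record whose percent remaining is the
#' clearance formula inverted at a chosen true CLint, and (iii) an NMR
#' shift table realising chosen delta-delta values.
#'
#' @param p_cm_s True PAMPA permeability (cm/s, default 1e-6).
#' @param area_cm2 Membrane area (default 0.3).
#' @param clint_true True scaled CLint (mL/min/kg, default 1785).
#' @param dd_ppm Named vector of true delta-delta values (ppm).
#' @param seed Integer seed (reserved; the fixtures are deterministic).
#' @return List `pampa` (inputs for [papp()]), `microsome` (inputs for
#'   [clint_scaled()]), `nmr` (tibble for [nmr_shift_table()]), each with
#'   the ground truth alongside.
#' @export
generate_assay_fixtures <- function(p_cm_s = 1e-6, area_cm2 = 0.3,
                                    clint_true = 1785,
                                    dd_ppm = c(nh_linker = 0.64,
                                               nh_aryl = 1.1),
                                    seed = 0L) {
  v_d <- 0.3; v_a <- 0.2; t_h <- 4; c0 <- 10
  ca <- pampa_ode_acceptor(p_cm_s, c0, area_cm2, v_d, v_a, t_h)
  pct <- 100 * exp(-clint_true / (45.4 * 87.5) * 0.2 * 30)
  base_cdcl3 <- 8.36
  nmr <- tibble(proton_label = names(dd_ppm),
                delta_dmso_ppm = base_cdcl3 + unname(dd_ppm),
                delta_cdcl3_ppm = base_cdcl3)
  list(
    pampa = list(c_donor0 = c0, c_acceptor_t = ca, area_cm2 = area_cm2,
                 v_donor_ml = v_d, v_acceptor_ml = v_a, time_h = t_h,
                 p_true_cm_s = p_cm_s),
    microsome = list(percent_remaining = pct, time_min = 30,
                     protein_mg_ml = 0.2, clint_true = clint_true),
    nmr = nmr, dd_true_ppm = dd_ppm)
}
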