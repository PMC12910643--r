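# Annotated topology: the static chemistry of one molecule -- atoms, bonds,
# polar/donor/acceptor flags, rings, carbonyls. All atom indices are 1-based.

#' Construct a conformer ensemble
#'
#' An ensemble is an ordered set of conformers (coordinate frames in
#' Angstrom) sharing one molecular topology, tagged with an environment
#' label such as `"water"` or `"toluene"`.
#'
#' @param frames List of N x 3 numeric matrices (Angstrom), one per
#'   conformer, all with the same atom count and ordering.
#' @param topology An [annotated_topology] object, or a bare atom tibble
#'   with at least an `element` column (annotations can be added later with
#'   [annotate_topology()]).
#' @param environment Free-text environment label (e.g. `"water"`).
#' @param source Free-text provenance string.
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(frames, topology, environment = "unlabelled",
                               source = "") {
  if (!is.list(frames) || length(frames) == 0)
    abort("`frames` must be a non-empty list of N x 3 matrices")
  if (inherits(topology, "annotated_topology")) {
    topo <- topology
  } else {
    topo <- minimal_topology(topology)
  }
  n <- nrow(topo$atoms)
  frames <- lapply(seq_along(frames), function(i) {
    fr <- as.matrix(frames[[i]])
    if (!is.numeric(fr) || ncol(fr) != 3)
      abort(sprintf("frame %d is not an N x 3 numeric matrix", i))
    if (nrow(fr) != n)
      abort(sprintf("frame %d has %d atoms; topology has %d", i, nrow(fr), n))
    if (!all(is.finite(fr)))
      abort(sprintf("frame %d contains non-finite coordinates", i))
    dimnames(fr) <- NULL
    fr
  })
  structure(
    list(topology = topo, frames = frames,
         environment = environment, source = source),
    class = "conformer_ensemble"
  )
}

# Bare topology: atoms known, no perception run yet.
minimal_topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  if (!"element" %in% names(atoms)) abort("atom table needs an `element` column")
  props <- element_properties(atoms$element)
  out <- tibble(
    index = seq_len(nrow(atoms)),
    element = atoms$element,
    name = if ("name" %in% names(atoms)) atoms$name else atoms$element,
    vdw_A = props$vdw_A,
    mass = props$mass,
    polar = FALSE
  )
  structure(
    list(atoms = out, bonds = matrix(integer(), 0, 2),
         donor_h = tibble(heavy = integer(), h = integer()),
         acceptors = integer(), rings = list(),
         carbonyls = tibble(c = integer(), o = integer()),
         annotated = FALSE),
    class = "annotated_topology"
  )
}

#' Number of frames / atoms in an ensemble
#' @param x A `conformer_ensemble`.
#' @return Integer count.
#' @export
n_frames <- function(x) length(x$frames)

#' @rdname n_frames
#' @export
n_atoms <- function(x) nrow(x$topology$atoms)

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d frames x %d atoms, environment = \"%s\"\n",
              n_frames(x), n_atoms(x), x$environment))
  invisible(x)
}

#' @export
print.annotated_topology <- function(x, ...) {
  cat(sprintf(
    "<annotated_topology> %d atoms, %d bonds, %d donor H, %d acceptors, %d rings\n",
    nrow(x$atoms), nrow(x$bonds), nrow(x$donor_h), length(x$acceptors),
    length(x$rings)))
  invisible(x)
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed the sum of their
#' covalent radii plus a tolerance. Bonds are symmetric and self-bonds are
#' never produced; isolated atoms are allowed.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param frame Frame index used for the distance test (default 1).
#' @param tolerance Slack added to the covalent-radius sum (Angstrom,
#'   default 0.4).
#' @param radii Optional element-property override table
#'   (see [element_properties()]).
#' @return Integer matrix with two columns `i`, `j` (`i < j`), one row per
#'   bond.
#' @export
perceive_bonds <- function(ensemble, frame = 1L, tolerance = 0.4,
                           radii = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (frame < 1 || frame > n_frames(ensemble))
    abort(sprintf("frame %d out of range (ensemble has %d frames)",
                  frame, n_frames(ensemble)))
  xyz <- ensemble$frames[[frame]]
  rcov <- element_properties(ensemble$topology$atoms$element, radii)$covalent_A
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(rcov, rcov, "+") + tolerance
  hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  out <- cbind(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Smallest set of smallest cycles, greedily: one shortest cycle through each
# non-tree edge, kept smallest-first until the cycle space is covered.
perceive_rings <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0) return(list())
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n_atoms)
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  n_cycles <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::components(g)$no
  if (n_cycles <= 0) return(list())
  tree <- igraph::mst(g)
  tree_ids <- igraph::get_edge_ids(g, t(igraph::ends(tree, igraph::E(tree))))
  chords <- setdiff(seq_len(igraph::ecount(g)), tree_ids)
  cycles <- lapply(chords, function(eid) {
    uv <- as.integer(igraph::ends(g, eid))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = uv[1], to = uv[2])$vpath[[1]])
    if (length(sp) == 0) return(NULL)
    as.integer(sp)
  })
  cycles <- Filter(Negate(is.null), cycles)
  cycles <- cycles[order(vapply(cycles, length, 1L))]
  # keep cycles contributing a new edge until the basis is full
  seen_edge <- character()
  kept <- list()
  for (cy in cycles) {
    e <- paste(pmin(cy, c(cy[-1], cy[1])), pmax(cy, c(cy[-1], cy[1])), sep = "-")
    if (any(!e %in% seen_edge)) {
      kept[[length(kept) + 1]] <- cy
      seen_edge <- union(seen_edge, e)
    }
    if (length(kept) >= n_cycles) break
  }
  kept
}

# RMS deviation of ring atoms from their best-fit plane (Angstrom).
ring_planarity <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(c0)
  sqrt(mean((c0 %*% sv$v[, 3])^2))
}

#' Annotate a molecular topology
#'
#' Builds the full annotation a chameleonicity analysis needs: the polar-atom
#' set used for solvent-accessible 3D polar surface area (N, O, and H bound
#' to N or O; S is excluded from the polar set but allowed as an acceptor),
#' hydrogen-bond donor pairs (H on N or O), acceptors (N, O, S), smallest
#' rings of the bond graph with a geometric aromaticity flag, and carbonyl
#' C=O pairs (terminal O bonded to a C).
#'
#' Explicit overrides always win over perception. Overrides are a tibble with
#' columns `atom_index`, `role` (one of `"polar"`, `"donor_h"`, `"acceptor"`,
#' `"aromatic_ring"`) and, for ring members, `ring_id` grouping the atoms of
#' one aromatic ring.
#'
#' @param atoms Tibble with an `element` column (optionally `name`), or an
#'   existing topology whose atoms are reused.
#' @param bonds Two-column integer matrix of bonded pairs
#'   (from [perceive_bonds()]).
#' @param overrides Optional override tibble; see Details.
#' @param frame Optional N x 3 coordinate matrix used for the planarity part
#'   of aromaticity perception. Without it (and without overrides) rings are
#'   kept but not flagged aromatic.
#' @param radii Optional element-property override table.
#' @return An `annotated_topology`.
#' @export
annotate_topology <- function(atoms, bonds, overrides = NULL, frame = NULL,
                              radii = NULL) {
  topo <- if (inherits(atoms, "annotated_topology")) {
    minimal_topology(atoms$atoms[c("element", "name")])
  } else minimal_topology(atoms)
  at <- topo$atoms
  n <- nrow(at)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && (min(bonds) < 1 || max(bonds) > n))
    abort("bond refers to an atom index outside 1..N")
  if (any(bonds[, 1] == bonds[, 2])) abort("self-bonds are not allowed")
  bonds <- cbind(i = pmin(bonds[, 1], bonds[, 2]),
                 j = pmax(bonds[, 1], bonds[, 2]))
  bonds <- unique(bonds)
  if (!is.null(overrides)) {
    overrides <- as_tibble(overrides)
    if (nrow(overrides) > 0 &&
        (min(overrides$atom_index) < 1 || max(overrides$atom_index) > n))
      abort("override refers to an atom index outside 1..N")
  }

  nbr <- lapply(seq_len(n), function(i)
    unname(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])))
  el <- at$element

  # donors: H bonded to N or O
  h_idx <- which(el == "H")
  donor_h <- purrr::map_dfr(h_idx, function(h) {
    heavy <- nbr[[h]][el[nbr[[h]]] %in% c("N", "O")]
    if (length(heavy) == 0) return(NULL)
    tibble(heavy = heavy[1], h = h)
  })
  if (nrow(donor_h) == 0) donor_h <- tibble(heavy = integer(), h = integer())

  acceptors <- which(el %in% c("N", "O", "S"))

  polar <- el %in% c("N", "O")
  polar[donor_h$h] <- TRUE

  rings_raw <- perceive_rings(n, bonds)
  rings <- lapply(rings_raw, function(cy) {
    arom <- FALSE
    if (!is.null(frame) && length(cy) %in% 5:6 &&
        all(el[cy] %in% c("C", "N", "S", "O"))) {
      arom <- ring_planarity(frame[cy, , drop = FALSE]) <= 0.1
    }
    list(atoms = cy, aromatic = arom)
  })

  # carbonyls: terminal O (degree 1) bonded to a C
  o_term <- which(el == "O" & vapply(nbr, length, 1L) == 1)
  carbonyls <- purrr::map_dfr(o_term, function(o) {
    ci <- nbr[[o]]
    if (el[ci] != "C") return(NULL)
    tibble(c = ci, o = o)
  })
  if (nrow(carbonyls) == 0) carbonyls <- tibble(c = integer(), o = integer())

  # overrides win
  if (!is.null(overrides) && nrow(overrides) > 0) {
    ov_polar <- overrides$atom_index[overrides$role == "polar"]
    polar[ov_polar] <- TRUE
    ov_dh <- overrides$atom_index[overrides$role == "donor_h"]
    for (h in ov_dh) {
      heavy <- nbr[[h]][el[nbr[[h]]] %in% c("N", "O")]
      if (length(heavy) == 0) heavy <- nbr[[h]]
      if (length(heavy) == 0)
        abort(sprintf("donor_h override atom %d has no bonded heavy atom", h))
      if (!h %in% donor_h$h)
        donor_h <- bind_rows(donor_h, tibble(heavy = heavy[1], h = as.integer(h)))
    }
    acceptors <- sort(union(
      acceptors, overrides$atom_index[overrides$role == "acceptor"]))
    ov_ring <- overrides[overrides$role == "aromatic_ring", , drop = FALSE]
    if (nrow(ov_ring) > 0) {
      ids <- if ("ring_id" %in% names(ov_ring)) ov_ring$ring_id else 1L
      for (rid in unique(ids)) {
        members <- sort(ov_ring$atom_index[ids == rid])
        hit <- FALSE
        for (k in seq_along(rings)) {
          if (setequal(rings[[k]]$atoms, members)) {
            rings[[k]]$aromatic <- TRUE; hit <- TRUE
          }
        }
        if (!hit)
          rings[[length(rings) + 1]] <- list(atoms = members, aromatic = TRUE)
      }
    }
  }

  at$polar <- polar
  structure(
    list(atoms = at, bonds = bonds, donor_h = donor_h,
         acceptors = as.integer(acceptors), rings = rings,
         carbonyls = carbonyls, annotated = TRUE),
    class = "annotated_topology"
  )
}

#' Annotate an ensemble's topology in place
#'
#' Convenience wrapper: perceives bonds on one frame, annotates, and returns
#' the ensemble with its topology replaced.
#'
#' @inheritParams perceive_bonds
#' @param overrides Passed to [annotate_topology()].
#' @return The ensemble with an annotated topology.
#' @export
annotate_ensemble <- function(ensemble, frame = 1L, overrides = NULL,
                              tolerance = 0.4, radii = NULL) {
  bonds <- perceive_bonds(ensemble, frame, tolerance, radii)
  ensemble$topology <- annotate_topology(
    ensemble$topology$atoms[c("element", "name")], bonds,
    overrides = overrides, frame = ensemble$frames[[frame]], radii = radii)
  ensemble
}

#' Heavy-atom indices of a topology
#' @param topology An `annotated_topology`.
#' @return Integer vector of non-hydrogen atom indices.
#' @export
heavy_atoms <- function(topology) which(topology$atoms$element != "H")

# bond-graph distance (number of bonds) between two atoms; Inf if disconnected
bond_path_length <- function(topology, from, to) {
  if (nrow(topology$bonds) == 0) return(Inf)
  g <- igraph::graph_from_edgelist(topology$bonds, directed = FALSE)
  if (igraph::vcount(g) < nrow(topology$atoms))
    g <- igraph::add_vertices(g, nrow(topology$atoms) - igraph::vcount(g))
  suppressWarnings(igraph::distances(g, v = from, to = to))[1, 1]
}
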