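# Per-conformer compactness and polarity descriptors: radius of gyration,
# numeric solvent-accessible surface area (Shrake-Rupley on a deterministic
# Fibonacci lattice), and its restriction to the polar-atom set (SA 3D PSA).

#' SASA parameters
#'
#' @param probe_A Solvent probe radius in Angstrom (default 1.4, a water
#'   probe).
#' @param n_points Quasi-uniform sample points per atomic sphere
#'   (default 960; minimum 92).
#' @param radii Optional element-property override table.
#' @return A list of class `sasa_params`.
#' @export
sasa_params <- function(probe_A = 1.4, n_points = 960L, radii = NULL) {
  stopifnot(probe_A >= 0, n_points >= 92)
  structure(list(probe_A = probe_A, n_points = as.integer(n_points),
                 radii = radii), class = "sasa_params")
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1) * (seq_len(n) - 1)  # golden-angle increments
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of atoms from the centre of
#' mass: `sqrt(sum(m_i |r_i - r_cm|^2) / sum(m_i))`. Translation- and
#' rotation-invariant. With `weighted = FALSE` all masses are taken equal
#' (geometric Rgyr).
#'
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param masses Positive numeric vector of atomic masses, or `NULL` to use
#'   equal weights.
#' @param weighted Use the supplied masses (default `TRUE`).
#' @return Radius of gyration in Angstrom.
#' @export
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 1))  # 0.5
radius_of_gyration <- function(xyz, masses = NULL, weighted = TRUE) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) abort("empty frame: no atoms")
  m <- if (weighted && !is.null(masses)) masses else rep(1, nrow(xyz))
  if (length(m) != nrow(xyz) || any(m <= 0))
    abort("`masses` must be positive, one per atom")
  cm <- colSums(xyz * m) / sum(m)
  d2 <- rowSums(sweep(xyz, 2, cm)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, quasi-uniform points are placed on the sphere of radius
#' `r_vdw + probe`; the accessible fraction is the share of points not inside
#' any neighbouring atom's expanded sphere, scaled by the sphere area
#' `4*pi*(r_vdw + probe)^2`. The point set is a fixed Fibonacci lattice, so
#' results are deterministic.
#'
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param topology An `annotated_topology` (for elements and vdW radii).
#' @param params A [sasa_params()] object.
#' @return Numeric vector of per-atom areas (Angstrom^2); `sum()` gives the
#'   total SASA.
#' @export
sasa <- function(xyz, topology, params = sasa_params()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(n == nrow(topology$atoms))
  rv <- element_properties(topology$atoms$element, params$radii)$vdw_A
  re <- rv + params$probe_A
  pts <- fibonacci_sphere(params$n_points)
  area <- numeric(n)
  if (n == 1) return(4 * pi * re^2)
  d <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    nbr <- which(d[i, ] < re[i] + re & seq_len(n) != i)
    sph <- sweep(pts * re[i], 2, xyz[i, ], "+")
    if (length(nbr) == 0) {
      area[i] <- 4 * pi * re[i]^2
      next
    }
    buried <- rep(FALSE, nrow(sph))
    for (j in nbr) {
      if (all(buried)) break
      free <- which(!buried)
      dj2 <- (sph[free, 1] - xyz[j, 1])^2 + (sph[free, 2] - xyz[j, 2])^2 +
        (sph[free, 3] - xyz[j, 3])^2
      buried[free[dj2 < re[j]^2]] <- TRUE
    }
    area[i] <- 4 * pi * re[i]^2 * mean(!buried)
  }
  area
}

#' Solvent-accessible 3D polar surface area
#'
#' SASA summed over the polar-atom set of one specific conformer (N, O, and
#' H bound to N or O by default annotation). Conformation-dependent, unlike
#' topological PSA: folding polar groups into contact buries their surface.
#'
#' @inheritParams sasa
#' @return SA 3D PSA in Angstrom^2.
#' @export
sa_3d_psa <- function(xyz, topology, params = sasa_params()) {
  if (!isTRUE(topology$annotated))
    abort("topology has no polar annotations; run annotate_topology() first")
  pol <- which(topology$atoms$polar)
  if (length(pol) == 0) return(0)
  sum(sasa(xyz, topology, params)[pol])
}

#' Per-conformer descriptor table
#'
#' One row per frame, in frame order: radius of gyration, total SASA and
#' SA 3D PSA (the data behind compactness-vs-polarity density plots).
#'
#' @param ensemble An annotated [conformer_ensemble].
#' @param params A [sasa_params()] object.
#' @param weighted Mass-weight the radius of gyration (default `TRUE`).
#' @return A tibble with columns `frame`, `rgyr_A`, `sasa_A2`, `sa3dpsa_A2`
#'   and attribute `environment`.
#' @export
descriptor_table <- function(ensemble, params = sasa_params(),
                             weighted = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  topo <- ensemble$topology
  if (!isTRUE(topo$annotated))
    abort("ensemble topology is not annotated; run annotate_ensemble() first")
  pol <- which(topo$atoms$polar)
  rows <- purrr::map_dfr(seq_len(n_frames(ensemble)), function(f) {
    fr <- ensemble$frames[[f]]
    a <- sasa(fr, topo, params)
    tibble(
      frame = f,
      rgyr_A = radius_of_gyration(fr, topo$atoms$mass, weighted),
      sasa_A2 = sum(a),
      sa3dpsa_A2 = if (length(pol)) sum(a[pol]) else 0
    )
  })
  attr(rows, "environment") <- ensemble$environment
  rows
}
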