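# Pairwise heavy-atom RMSD with optimal (Kabsch) superposition, k-means
# clustering of the RMSD matrix, cross-ensemble congruent-conformation
# search, and property-space summaries.

# Kabsch minimum RMSD between two pre-centred coordinate sets, using the
# singular values of the cross-covariance with proper-rotation correction:
# msd = (|A|^2 + |B|^2 - 2 * (d1 + d2 +/- d3)) / N.
kabsch_rmsd_centred <- function(a, b, ga, gb) {
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sv$d
  if (det(sv$u) * det(sv$v) < 0) d[3] <- -d[3]
  msd <- (ga + gb - 2 * sum(d)) / nrow(a)
  sqrt(max(0, msd))
}

#' Minimum RMSD between two conformers under optimal superposition
#'
#' Least-squares rigid superposition (Kabsch, via SVD with proper-rotation
#' correction) of the selected atoms, returning the minimised RMSD over all
#' rotations and translations.
#'
#' @param frame_a,frame_b N x 3 coordinate matrices sharing atom ordering.
#' @param selection Atom indices used for the comparison (default: all rows;
#'   typically `heavy_atoms(topology)`). At least 3 atoms.
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(frame_a, frame_b, selection = NULL) {
  frame_a <- as.matrix(frame_a); frame_b <- as.matrix(frame_b)
  sel <- selection %||% seq_len(nrow(frame_a))
  if (length(sel) < 3)
    abort("superposition needs at least 3 selected atoms")
  if (nrow(frame_a) != nrow(frame_b))
    abort("frames have different atom counts")
  a <- frame_a[sel, , drop = FALSE]
  b <- frame_b[sel, , drop = FALSE]
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  kabsch_rmsd_centred(a, b, sum(a^2), sum(b^2))
}

# Pre-centre the selected atoms of every frame once.
centred_selection <- function(frames, sel) {
  lapply(frames, function(fr) {
    a <- fr[sel, , drop = FALSE]
    a <- sweep(a, 2, colMeans(a))
    list(xyz = a, g = sum(a^2))
  })
}

#' Pairwise superposed-RMSD matrix
#'
#' Heavy-atom (by default) RMSD between every pair of frames, within one
#' ensemble (symmetric, zero diagonal) or across two ensembles sharing a
#' topology.
#'
#' @param ensemble_a A [conformer_ensemble].
#' @param ensemble_b Optional second ensemble; `NULL` for self-mode.
#' @param selection `"heavy"` (all non-hydrogen atoms), `"all"`, or an
#'   integer index vector.
#' @return Numeric matrix (rows = frames of `ensemble_a`) with attribute
#'   `selection`.
#' @export
pairwise_rmsd <- function(ensemble_a, ensemble_b = NULL,
                          selection = "heavy") {
  stopifnot(inherits(ensemble_a, "conformer_ensemble"))
  sel <- resolve_selection(ensemble_a$topology, selection)
  self <- is.null(ensemble_b)
  if (!self) {
    if (n_atoms(ensemble_b) != n_atoms(ensemble_a) ||
        !identical(ensemble_b$topology$atoms$element,
                   ensemble_a$topology$atoms$element))
      abort("ensembles do not share a topology (atom count/order mismatch)")
  }
  ca <- centred_selection(ensemble_a$frames, sel)
  cb <- if (self) ca else centred_selection(ensemble_b$frames, sel)
  na <- length(ca); nb <- length(cb)
  m <- matrix(0, na, nb)
  if (self) {
    for (i in seq_len(na - 1)) for (j in (i + 1):na) {
      m[i, j] <- m[j, i] <- kabsch_rmsd_centred(
        ca[[i]]$xyz, ca[[j]]$xyz, ca[[i]]$g, ca[[j]]$g)
    }
  } else {
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      m[i, j] <- kabsch_rmsd_centred(
        ca[[i]]$xyz, cb[[j]]$xyz, ca[[i]]$g, cb[[j]]$g)
    }
  }
  attr(m, "selection") <- if (is.character(selection)) selection else "custom"
  m
}

resolve_selection <- function(topology, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  switch(selection,
         heavy = heavy_atoms(topology),
         all = seq_len(nrow(topology$atoms)),
         abort("`selection` must be \"heavy\", \"all\" or an index vector"))
}

#' Cluster conformers on the pairwise RMSD matrix
#'
#' Treats each row of the (self-mode) RMSD matrix as the frame's feature
#' vector and applies k-means with many random restarts; the representative
#' of each cluster is the member frame nearest the cluster centroid in that
#' feature space (ties broken by lowest frame id). Deterministic for a fixed
#' seed.
#'
#' @param rmsd_matrix Square symmetric matrix from [pairwise_rmsd()].
#' @param k Number of clusters (default 10).
#' @param seed Integer RNG seed (default 0).
#' @param nstart Random restarts passed to [stats::kmeans()] (default 50).
#' @return An object of class `cluster_result`: list with `k`, `labels`
#'   (1..k per frame), `representatives`, `populations`, `seed`. `tidy()`
#'   gives the per-cluster table.
#' @export
cluster_frames <- function(rmsd_matrix, k = 10L, seed = 0L, nstart = 50L) {
  n <- nrow(rmsd_matrix)
  if (k <= 0) abort("k must be positive")
  if (k > n) abort(sprintf("k = %d exceeds the number of frames (%d)", k, n))
  if (k == n) {
    # every frame its own cluster: zero within-cluster scatter
    return(structure(
      list(k = k, labels = seq_len(n), representatives = seq_len(n),
           populations = rep(1 / n, n), seed = seed),
      class = "cluster_result"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- kmeans(rmsd_matrix, centers = k, nstart = nstart, iter.max = 100)
  labels <- km$cluster
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    d2 <- rowSums((rmsd_matrix[members, , drop = FALSE] -
                     matrix(km$centers[cl, ], length(members), n,
                            byrow = TRUE))^2)
    members[which.min(d2)]  # which.min takes the first == lowest frame id
  }, 1L)
  structure(
    list(k = k, labels = labels, representatives = reps,
         populations = as.numeric(table(factor(labels, levels = 1:k))) / n,
         seed = seed),
    class = "cluster_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, populations: %s\n", x$k,
              paste(sprintf("%.2f", x$populations), collapse = " ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) {
  tibble(cluster = seq_len(x$k), representative = x$representatives,
         population = x$populations)
}

#' @exportS3Method generics::glance
glance.cluster_result <- function(x, ...) {
  tibble(k = x$k, n_frames = length(x$labels), seed = x$seed,
         max_population = max(x$populations))
}

#' Exclusion predicate for initial linear conformations
#'
#' Returns a predicate (used by [congruent_search()]) that drops frames
#' whose radius of gyration exceeds the given quantile of the *opposing*
#' ensemble's Rgyr, or that fall within the leading fraction of trajectory
#' order — the operational reading of "excluding the initial linear
#' conformations" for steered unfolding trajectories.
#'
#' @param rgyr_quantile Quantile of the opposing ensemble's Rgyr above which
#'   a frame is excluded (default 0.95).
#' @param head_fraction Leading fraction of trajectory order to exclude
#'   (default 0.05).
#' @return A function `(ensemble, opposing)` returning a logical keep-mask.
#' @export
exclude_linear <- function(rgyr_quantile = 0.95, head_fraction = 0.05) {
  force(rgyr_quantile); force(head_fraction)
  function(ensemble, opposing) {
    rg_self <- vapply(ensemble$frames, radius_of_gyration,
                      numeric(1), masses = ensemble$topology$atoms$mass)
    rg_opp <- vapply(opposing$frames, radius_of_gyration,
                     numeric(1), masses = opposing$topology$atoms$mass)
    cut <- quantile(rg_opp, rgyr_quantile, names = FALSE)
    n <- n_frames(ensemble)
    keep <- rg_self <= cut & seq_len(n) > floor(head_fraction * n)
    keep
  }
}

#' Search for congruent conformations across two environments
#'
#' A frame of ensemble A is *congruent* when its minimum superposed RMSD to
#' any frame of ensemble B (after optional exclusion filtering of both
#' sides) is at most `threshold_A`. Matching is nearest-neighbour: each
#' matched A-frame is paired with its minimum-RMSD B-frame. Fractions are
#' reported relative to the post-exclusion frame counts, in both directions.
#'
#' @param ensemble_a,ensemble_b Ensembles sharing one topology (e.g. water
#'   and toluene).
#' @param threshold_A RMSD threshold in Angstrom (default 1.0).
#' @param selection Atom selection as in [pairwise_rmsd()].
#' @param exclude `NULL` for no exclusion, or a predicate such as
#'   [exclude_linear()].
#' @return An object of class `congruent_report`: list with `threshold_A`,
#'   `pairs` (tibble `frame_a`, `frame_b`, `rmsd_A`), `fraction_a`,
#'   `fraction_b`, `n_a`, `n_b`, `exclusion`.
#' @export
congruent_search <- function(ensemble_a, ensemble_b, threshold_A = 1.0,
                             selection = "heavy", exclude = NULL) {
  keep_a <- rep(TRUE, n_frames(ensemble_a))
  keep_b <- rep(TRUE, n_frames(ensemble_b))
  if (!is.null(exclude)) {
    keep_a <- exclude(ensemble_a, ensemble_b)
    keep_b <- exclude(ensemble_b, ensemble_a)
  }
  if (!any(keep_a)) abort("ensemble A is empty after exclusion filtering")
  if (!any(keep_b)) abort("ensemble B is empty after exclusion filtering")
  ia <- which(keep_a); ib <- which(keep_b)
  sub_a <- ensemble_a; sub_a$frames <- ensemble_a$frames[ia]
  sub_b <- ensemble_b; sub_b$frames <- ensemble_b$frames[ib]
  m <- pairwise_rmsd(sub_a, sub_b, selection)
  min_a <- apply(m, 1, min); arg_a <- apply(m, 1, which.min)
  min_b <- apply(m, 2, min)
  hit <- which(min_a <= threshold_A)
  pairs <- tibble(frame_a = ia[hit], frame_b = ib[arg_a[hit]],
                  rmsd_A = min_a[hit])
  structure(
    list(threshold_A = threshold_A, pairs = pairs,
         fraction_a = mean(min_a <= threshold_A),
         fraction_b = mean(min_b <= threshold_A),
         n_a = length(ia), n_b = length(ib),
         exclusion = if (is.null(exclude)) "none" else "custom"),
    class = "congruent_report")
}

#' @export
print.congruent_report <- function(x, ...) {
  cat(sprintf(
    "<congruent_report> threshold %.2f A: %.1f%% of A (n=%d), %.1f%% of B (n=%d) matched\n",
    x$threshold_A, 100 * x$fraction_a, x$n_a, 100 * x$fraction_b, x$n_b))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.congruent_report <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.congruent_report <- function(x, ...) {
  tibble(threshold_A = x$threshold_A, fraction_a = x$fraction_a,
         fraction_b = x$fraction_b, n_a = x$n_a, n_b = x$n_b,
         n_pairs = nrow(x$pairs))
}

#' Property-space summary of a descriptor table
#'
#' Empirical fractions below declared cutoffs plus type-7 quartiles for each
#' descriptor column (the numbers read off polarity/compactness violin
#' plots).
#'
#' @param table Descriptor tibble from [descriptor_table()].
#' @param cutoffs Named list/vector: descriptor column -> cutoff value
#'   (e.g. `c(sa3dpsa_A2 = 215)`).
#' @return Tibble with one row per descriptor: `descriptor`, `cutoff`,
#'   `fraction_below`, `q1`, `median`, `q3`.
#' @export
property_space_summary <- function(table, cutoffs = NULL) {
  if (nrow(table) == 0) abort("empty descriptor table")
  descs <- setdiff(names(table), "frame")
  if (!is.null(cutoffs)) {
    bad <- setdiff(names(cutoffs), descs)
    if (length(bad) > 0)
      abort(paste0("unknown descriptor(s): ", paste(bad, collapse = ", ")))
  }
  purrr::map_dfr(descs, function(d) {
    v <- table[[d]]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    cut <- if (!is.null(cutoffs) && d %in% names(cutoffs))
      as.numeric(cutoffs[[d]]) else NA_real_
    tibble(descriptor = d, cutoff = cut,
           fraction_below = if (is.na(cut)) NA_real_ else mean(v < cut),
           q1 = q[1], median = q[2], q3 = q[3])
  })
}
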