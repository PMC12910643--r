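# Orchestration: descriptors -> interactions -> clustering -> congruent
# search -> machine-readable report, driven by one config object.

#' Default chameleonicity run configuration
#'
#' All thresholds in one versioned block so reports are self-describing:
#' 1.4 Angstrom solvent probe, 4 Angstrom / 20 degree hydrogen-bond
#' criteria, Burgi-Dunitz window 3.6 Angstrom / 95-125 degrees, k = 10
#' clusters, 1.0 Angstrom congruent threshold, report cutoffs 215 Angstrom^2
#' (SA 3D PSA) and 5.5 Angstrom (Rgyr).
#'
#' @param ... Named overrides of any default.
#' @return A list of class `chameleonicity_config`.
#' @export
chameleonicity_config <- function(...) {
  cfg <- list(
    config_version = "1.0",
    probe_A = 1.4, sasa_points = 960L,
    hbond = list(dist_max_A = 4.0, angle_tol_deg = 20, min_bond_sep = 4L),
    bd = list(dist_max_A = 3.6, angle_window_deg = c(95, 125)),
    k = 10L, congruent_threshold_A = 1.0,
    exclusion = "none",           # or "linear"
    cutoffs = c(sa3dpsa_A2 = 215, rgyr_A = 5.5),
    seed = 0L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0)
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  for (nm in names(over)) {
    cfg[[nm]] <- over[[nm]]
    warn(sprintf("config default '%s' overridden", nm),
         class = "chameleonics_config_override")
  }
  structure(cfg, class = "chameleonicity_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys override
#'   [chameleonicity_config()] defaults.
#' @return A `chameleonicity_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  do.call(chameleonicity_config, vals)
}

#' Run the full chameleonicity analysis
#'
#' For each environment-labelled ensemble: per-frame descriptor table,
#' property-space summary against the configured cutoffs, IMHB frequency,
#' and an optional Burgi-Dunitz scan; per ensemble a k-means clustering of
#' the pairwise heavy-atom RMSD matrix with representatives; and, when two
#' or more ensembles are given, a congruent-conformation search between the
#' first pair. Artifacts (CSV/JSON) are written when `out_dir` is given.
#' Identical config + seed gives identical reports.
#'
#' @param ensembles Named list of annotated [conformer_ensemble]s sharing
#'   one topology (names are environment labels; unnamed ensembles use
#'   their own label).
#' @param config A [chameleonicity_config()].
#' @param nucleophiles Optional atom indices for the Burgi-Dunitz scan.
#' @param out_dir Optional output directory for artifacts.
#' @return Object of class `chameleonicity_report`: list with
#'   `descriptors` (tibble over all environments), `summaries`,
#'   `imhb`, `burgi_dunitz`, `clusters`, `congruent`, `config`.
#' @export
run_chameleonicity <- function(ensembles, config = chameleonicity_config(),
                               nucleophiles = NULL, out_dir = NULL) {
  if (inherits(ensembles, "conformer_ensemble"))
    ensembles <- list(ensembles)
  if (length(ensembles) == 0) abort("at least one ensemble is required")
  labs <- names(ensembles) %||% rep("", length(ensembles))
  labs <- ifelse(labs == "",
                 vapply(ensembles, function(e) e$environment, ""), labs)
  names(ensembles) <- labs
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("[%s] %s", name, conditionMessage(e)),
            class = "chameleonics_stage_error"))
  }
  params <- sasa_params(config$probe_A, config$sasa_points)
  crit <- do.call(hbond_criteria, config$hbond)
  bdp <- do.call(bd_params, config$bd)

  desc <- stage("descriptors", purrr::map_dfr(labs, function(l)
    mutate(descriptor_table(ensembles[[l]], params), environment = l,
           .before = 1)))
  summaries <- stage("summary", purrr::map_dfr(labs, function(l)
    mutate(property_space_summary(
      select(filter(desc, .data$environment == l), -"environment"),
      config$cutoffs), environment = l, .before = 1)))
  imhb <- stage("imhb", purrr::map_dfr(ensembles, imhb_frequency,
                                       criteria = crit))
  bd <- NULL
  if (!is.null(nucleophiles)) {
    bd <- stage("burgi_dunitz", purrr::map_dfr(labs, function(l) {
      ens <- ensembles[[l]]
      purrr::map_dfr(seq_len(n_frames(ens)), function(f)
        mutate(burgi_dunitz_scan(ens$frames[[f]], ens$topology,
                                 nucleophiles, bdp),
               environment = l, frame = f, .before = 1))
    }))
  }
  clusters <- stage("clustering", purrr::map(ensembles, function(ens) {
    m <- pairwise_rmsd(ens)
    cluster_frames(m, k = min(config$k, n_frames(ens)), seed = config$seed)
  }))
  congruent <- NULL
  if (length(ensembles) >= 2) {
    excl <- if (identical(config$exclusion, "linear")) exclude_linear()
    else NULL
    congruent <- stage("congruent", congruent_search(
      ensembles[[1]], ensembles[[2]],
      threshold_A = config$congruent_threshold_A, exclude = excl))
  }
  report <- structure(
    list(descriptors = desc, summaries = summaries, imhb = imhb,
         burgi_dunitz = bd, clusters = clusters, congruent = congruent,
         config = config,
         provenance = list(package_version =
                             as.character(utils::packageVersion("chameleonics")),
                           seed = config$seed)),
    class = "chameleonicity_report")
  if (!is.null(out_dir)) write_report(report, ensembles, out_dir)
  report
}

write_report <- function(report, ensembles, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$descriptors,
                   file.path(out_dir, "descriptors.csv"), row.names = FALSE)
  utils::write.csv(report$summaries,
                   file.path(out_dir, "summaries.csv"), row.names = FALSE)
  utils::write.csv(report$imhb, file.path(out_dir, "imhb_frequency.csv"),
                   row.names = FALSE)
  if (!is.null(report$burgi_dunitz))
    utils::write.csv(report$burgi_dunitz,
                     file.path(out_dir, "burgi_dunitz.csv"),
                     row.names = FALSE)
  js <- list(
    config = unclass(report$config),
    clusters = lapply(report$clusters, function(cl)
      list(k = cl$k, representatives = cl$representatives,
           populations = cl$populations, labels = cl$labels,
           seed = cl$seed)),
    congruent = if (!is.null(report$congruent))
      list(threshold_A = report$congruent$threshold_A,
           fraction_a = report$congruent$fraction_a,
           fraction_b = report$congruent$fraction_b,
           n_a = report$congruent$n_a, n_b = report$congruent$n_b,
           pairs = report$congruent$pairs),
    provenance = report$provenance)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  # representative conformers as multi-model PDB, one file per environment
  for (l in names(report$clusters)) {
    reps <- report$clusters[[l]]$representatives
    write_ensemble(ensembles[[l]],
                   file.path(out_dir, paste0("representatives_", l, ".pdb")),
                   format = "pdb", frames = reps)
  }
  invisible(out_dir)
}

#' @export
print.chameleonicity_report <- function(x, ...) {
  envs <- unique(x$descriptors$environment)
  cat(sprintf("<chameleonicity_report> %d environment(s): %s\n",
              length(envs), paste(envs, collapse = ", ")))
  print(x$summaries)
  if (!is.null(x$congruent)) print(x$congruent)
  invisible(x)
}
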