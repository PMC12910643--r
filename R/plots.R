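# ggplot2 views of the result types.

#' Compactness-polarity density plot
#'
#' Rgyr against SA 3D PSA per conformer, coloured by environment — the
#' standard view for spotting chameleonic behaviour (a low-Rgyr,
#' low-polar-surface lobe in the nonpolar environment).
#'
#' @param descriptors Tibble from [descriptor_table()] or the
#'   `descriptors` element of a report (with an `environment` column).
#' @return A ggplot object.
#' @export
plot_property_space <- function(descriptors) {
  df <- as_tibble(descriptors)
  if (!"environment" %in% names(df))
    df$environment <- attr(descriptors, "environment") %||% "ensemble"
  ggplot2::ggplot(df, ggplot2::aes(.data$rgyr_A, .data$sa3dpsa_A2,
                                   colour = .data$environment)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_density_2d(linewidth = 0.3) +
    ggplot2::labs(x = "radius of gyration (Å)",
                  y = "SA 3D PSA (Å²)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Violin plot of a descriptor across environments
#'
#' @param descriptors Descriptor tibble with an `environment` column.
#' @param descriptor Column to plot (default `"sa3dpsa_A2"`).
#' @return A ggplot object with quartile lines inside the violins.
#' @export
plot_descriptor_violin <- function(descriptors, descriptor = "sa3dpsa_A2") {
  df <- as_tibble(descriptors)
  if (!descriptor %in% names(df))
    abort(paste0("unknown descriptor: ", descriptor))
  ggplot2::ggplot(df, ggplot2::aes(.data$environment,
                                   .data[[descriptor]],
                                   fill = .data$environment)) +
    ggplot2::geom_violin(draw_quantiles = c(0.25, 0.5, 0.75),
                         alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = descriptor) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.dose_response_fit <- function(object, ...) {
  grid <- tibble(conc_nM = exp(seq(log(min(object$data$conc_nM)),
                                   log(max(object$data$conc_nM)),
                                   length.out = 200)))
  grid$fit <- predict(object, grid)
  pts <- mutate(object$data,
                region = ifelse(dplyr::row_number() %in% object$hook_region,
                                "hook (excluded)", "fitted"))
  ggplot2::ggplot(pts, ggplot2::aes(.data$conc_nM, .data$response_pct)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$region), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "response (% of vehicle)",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.congruent_report <- function(object, ...) {
  if (nrow(object$pairs) == 0)
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no congruent pairs") +
             ggplot2::theme_void())
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$frame_a, .data$frame_b,
                               colour = .data$rmsd_A)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "frame (ensemble A)", y = "matched frame (ensemble B)",
                  colour = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' Burgi-Dunitz angle-distance scatter
#'
#' @param scan Tibble from [burgi_dunitz_scan()] (possibly over many
#'   frames).
#' @param params The [bd_params()] used, drawn as the acceptance window.
#' @return A ggplot object.
#' @export
plot_burgi_dunitz <- function(scan, params = bd_params()) {
  ggplot2::ggplot(scan, ggplot2::aes(.data$distance_A, .data$angle_deg,
                                     colour = .data$satisfied)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::annotate("rect", xmin = 0, xmax = params$dist_max_A,
                      ymin = params$angle_window_deg[1],
                      ymax = params$angle_window_deg[2],
                      alpha = 0.1, fill = "steelblue") +
    ggplot2::labs(x = "N···C distance (Å)",
                  y = "N···C=O angle (°)") +
    ggplot2::theme_minimal()
}
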