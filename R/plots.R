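# ggplot2 presentations of the analysis results.  Plotting is never
# load-bearing: every figure draws from the same tibbles the TSV writers
# emit.

#' @export
autoplot.pp_contact_series <- function(object, ...) {
  totals <- total_contact_series(object)
  ggplot2::ggplot(totals, ggplot2::aes(x = .data$time, y = .data$total)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (ns)", y = "protein-membrane contacts",
                  title = "Total weighted contacts over time")
}

#' @export
autoplot.pp_contact_profile <- function(object, ...) {
  df <- cumulative_profile(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$global_index)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$mean_contact), fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "firebrick") +
    ggplot2::labs(x = "residue (global index)", y = "contacts",
                  title = "Window-mean and cumulative contact profile")
}

#' @export
autoplot.pp_depth_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$global_index,
                               y = (.data$bin_left + .data$bin_right) / 2,
                               fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "residue (global index)", y = "depth (Angstrom)",
                  fill = "relative\nprobability",
                  title = "Per-residue insertion depth distribution")
}

#' @export
autoplot.pp_pose_profile <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$dg))
  kT <- attr(object, "kT") %||% 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$dg)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "tilt angle (degrees)",
                  y = sprintf("free energy (%s)", if (kT == 1) "kT" else "kcal/mol"),
                  title = "Pose free-energy profile")
}

#' @export
autoplot.pp_tilt_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$angle_deg)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (ns)", y = "tilt angle (degrees)",
                  title = "Tilt-angle time series")
}
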