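#' Heatmap of the heterochromatin fraction of a field
#'
#' @param object A `composition_field`.
#' @param ... Unused.
#' @return A ggplot object (phi_h raster, euchromatin blue to
#'   heterochromatin red, as density renderings are conventionally
#'   displayed).
#' @method autoplot composition_field
#' @export
autoplot.composition_field <- function(object, ...) {
  ph <- phi_h(object)
  nx <- nrow(ph); ny <- ncol(ph)
  df <- tibble::tibble(
    x = rep(seq_len(nx), ny) * object$h,
    y = rep(seq_len(ny), each = nx) * object$h,
    phi_h = as.vector(ph)
  )
  ggplot2::ggplot(df[!is.na(df$phi_h), ],
                  ggplot2::aes(.data$x, .data$y, fill = .data$phi_h)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b",
                                  midpoint = max(df$phi_h, na.rm = TRUE) / 2,
                                  name = expression(phi[h])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' @method autoplot steady_state
#' @export
autoplot.steady_state <- function(object, ...) {
  autoplot.composition_field(object$field) +
    ggplot2::ggtitle(sprintf("steady state after %d steps", object$steps))
}

#' LAD thickness around the nuclear boundary
#'
#' @param object A `lad_profile`.
#' @param ... Unused.
#' @return A ggplot of thickness versus boundary arc position.
#' @method autoplot lad_profile
#' @export
autoplot.lad_profile <- function(object, ...) {
  df <- object$profile
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$arc_start + .data$arc_end) / 2e3,
    y = .data$thickness_nm)) +
    ggplot2::geom_col(width = diff(range(df$arc_end)) / nrow(df) / 1e3,
                      fill = "#b2182b") +
    ggplot2::geom_hline(yintercept = object$mean_T_LAD,
                        linetype = "dashed") +
    ggplot2::labs(x = "boundary arc position (µm)",
                  y = expression(T[LAD] ~ "(nm)")) +
    ggplot2::theme_minimal()
}

#' Response surface of LAD thickness
#'
#' @param object A `response_surface`.
#' @param ... Unused.
#' @return A ggplot: one T_LAD(V_LAD) curve per methylation level.
#' @method autoplot response_surface
#' @export
autoplot.response_surface <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(
    .data$V_LAD, .data$T_LAD,
    colour = factor(signif(.data$Gamma_me, 3)),
    group = .data$Gamma_me)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(V[LAD] ~ "(pN·nm/nm²)"),
                  y = expression(T[LAD] ~ "(nm)"),
                  colour = expression(Gamma[me] ~ "(1/s)")) +
    ggplot2::theme_minimal()
}

#' Extracted parameter distributions
#'
#' @param object An `extraction_result`.
#' @param ... Unused.
#' @return A ggplot with the methylation-rate and affinity histograms.
#' @method autoplot extraction_result
#' @export
autoplot.extraction_result <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(metric = "Gamma_me (1/s)",
                   value = object$gamma_me$Gamma_me),
    tibble::tibble(metric = "V_LAD", value = object$vlad$V_LAD)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2166ac") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' Domain-size distributions across conditions
#'
#' @param object A `size_distributions` object.
#' @param ... Unused.
#' @return A ggplot of the smoothed density curves per condition.
#' @method autoplot size_distributions
#' @export
autoplot.size_distributions <- function(object, ...) {
  dens <- object$density[is.finite(object$density$y), ]
  ggplot2::ggplot(dens, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "size (nm)", y = "density") +
    ggplot2::theme_minimal()
}

#' Localization cloud coloured by density class
#'
#' @param object A density-classified `localization_table`.
#' @param ... Unused.
#' @return A ggplot scatter of the localizations.
#' @export
plot_localizations <- function(object, ...) {
  has_cls <- "density_class" %in% names(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x_nm, .data$y_nm))
  if (has_cls) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$density_class),
                                 size = 0.3) +
      ggplot2::scale_colour_manual(values = c(
        sparse = "#92c5de", dense = "#f4a582", ultradense = "#b2182b",
        edge = "grey70"))
  } else {
    p <- p + ggplot2::geom_point(size = 0.3)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
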