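#' Plot a binned photon time trace
#'
#' @param object A [bin_stream()] trace.
#' @param ... Unused.
#' @return A ggplot: counts per bin, one facet per detection channel.
#' @method autoplot binned_trace
#' @export
autoplot.binned_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
    dplyr::any_of(fret_channels()), names_to = "channel",
    values_to = "counts")
  ggplot2::ggplot(long, ggplot2::aes(.data$start_ms, .data$counts)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = "counts per bin")
}

#' Red-green and lifetime-FRET projections of level signatures
#'
#' The two standard projections of the 3D signature space: red vs green
#' brightness, and donor lifetime vs FRET value. Points are coloured by
#' `colour_by` when present (e.g. truth `label` or `assigned`).
#'
#' @param signatures A `level_signatures` table.
#' @param colour_by Optional column name for the point colour.
#' @return A list of two ggplots: `red_green`, `lifetime_fret`.
#' @export
plot_signatures <- function(signatures, colour_by = NULL) {
  s <- tibble::as_tibble(signatures)
  use_col <- !is.null(colour_by) && colour_by %in% names(s)
  pt <- function(p) {
    if (use_col)
      p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
        alpha = 0.6, size = 0.8, na.rm = TRUE)
    else p + ggplot2::geom_point(alpha = 0.6, size = 0.8, na.rm = TRUE)
  }
  p1 <- pt(ggplot2::ggplot(s, ggplot2::aes(.data$green_b, .data$red_b))) +
    ggplot2::labs(x = "green brightness (counts/ms/uW)",
      y = "red brightness (counts/ms/uW)", colour = colour_by)
  p2 <- pt(ggplot2::ggplot(s, ggplot2::aes(.data$fret_E, .data$tau_ns))) +
    ggplot2::labs(x = "FRET value", y = "donor lifetime (ns)",
      colour = colour_by)
  list(red_green = p1, lifetime_fret = p2)
}

#' Heat map of a misclassification confusion matrix
#'
#' Off-diagonal cells show the pairwise misclassification probability,
#' capped at `cap` (default 2.5%) so rare unfavourable pairs stand out.
#'
#' @param object A [confusion_matrix()] result.
#' @param cap Colour-scale cap.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fret_confusion
#' @export
autoplot.fret_confusion <- function(object, cap = 0.025, ...) {
  d <- tidy(object)
  d$p_capped <- pmin(d$p_mis, cap)
  d$p_capped[d$true == d$assigned] <- NA
  ggplot2::ggplot(d, ggplot2::aes(.data$assigned, .data$true,
    fill = .data$p_capped)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "black", limits = c(0, cap)) +
    ggplot2::labs(x = "assigned identity", y = "true identity",
      fill = "p(mis)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
      vjust = 0.5, hjust = 1))
}

#' Confinement scatter of a bound/unbound split
#'
#' @param object A [split_bound_unbound()] result.
#' @param ... Unused.
#' @return A ggplot of sigma_x vs sigma_y coloured by call state.
#' @method autoplot binding_split
#' @export
autoplot.binding_split <- function(object, ...) {
  ggplot2::ggplot(object$calls, ggplot2::aes(.data$sigma_x, .data$sigma_y,
    colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::labs(x = expression(sigma[x] ~ "(nm)"),
      y = expression(sigma[y] ~ "(nm)"), colour = NULL)
}
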