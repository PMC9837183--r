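#' Plot the three channels and tumor mask of one slice
#'
#' @param case A `patient_case`.
#' @param slice Slice index (default: slice with the most tumor voxels).
#' @return A ggplot object (faceted rasters with mask overlay).
#' @export
plot_case <- function(case, slice = NULL) {
  if (is.null(slice)) {
    per_slice <- apply(case$reference_mask$voxels, 3, sum)
    slice <- which.max(per_slice)
  }
  grab <- function(vol, nm) {
    m <- vol[, , slice]
    tibble::tibble(
      x = rep(seq_len(nrow(m)), ncol(m)),
      y = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.numeric(scale(as.numeric(m))),
      channel = nm
    )
  }
  df <- dplyr::bind_rows(grab(case$b0, "b0"), grab(case$b1000, "b1000"),
                         grab(case$adc, "ADC"))
  mk <- case$reference_mask$voxels[, , slice]
  mdf <- tibble::tibble(
    x = rep(seq_len(nrow(mk)), ncol(mk)),
    y = rep(seq_len(ncol(mk)), each = nrow(mk)),
    mask = as.numeric(mk)
  ) |> dplyr::filter(.data$mask > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_tile(data = mdf, ggplot2::aes(.data$x, .data$y),
                       fill = NA, colour = "red", linewidth = 0.1,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, slice %d", case$case_id, slice),
                  fill = "z-score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.unet_model <- function(object, ...) {
  if (nrow(object$history) == 0) {
    abort("Model has no training history to plot.")
  }
  df <- tidyr::pivot_longer(object$history, -"epoch", names_to = "set",
                            values_to = "dice_loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$dice_loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "Dice loss", title = "Training history") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dsc_report <- function(object, ...) {
  agg <- attr(object, "aggregate")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$dsc)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Dice similarity coefficient", y = "cases") +
    ggplot2::theme_minimal()
  centre <- if (!is.null(agg$median_dsc)) agg$median_dsc else agg$mean_dsc
  p + ggplot2::geom_vline(xintercept = centre, linetype = 2)
}

#' ICC profile by feature family
#'
#' Dot plot of per-feature ICC estimates grouped by family with the
#' good-reproducibility threshold (0.75) marked.
#'
#' @param icc_table Output of [feature_icc()].
#' @return A ggplot object.
#' @export
plot_icc_profile <- function(icc_table) {
  ggplot2::ggplot(icc_table,
                  ggplot2::aes(.data$family, .data$icc,
                               colour = .data$category)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = 2, colour = "orange") +
    ggplot2::labs(x = NULL, y = "ICC(2,1)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
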