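# ggplot2 visualisations for the main result types.

#' Plot spectra
#'
#' One line per sample, optionally coloured by a metadata column or by the
#' reference value.
#'
#' @param object A `spectra_set`.
#' @param colour_by Name of a metadata column, `"hu"` for the reference
#'   value, or `NULL` (default) for no colour mapping.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectra_set <- function(object, colour_by = NULL, ...) {
  long <- tidy(object)
  if (!is.null(colour_by) && colour_by != "hu" && !is.null(object$meta)) {
    key <- tibble(sample_id = object$sample_ids,
                  .colour = object$meta[[colour_by]])
    long <- dplyr::left_join(long, key, by = "sample_id")
  } else if (identical(colour_by, "hu") && "hu" %in% names(long)) {
    long$.colour <- long$hu
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$wavelength,
                                          .data$transmittance,
                                          group = .data$sample_id))
  if (".colour" %in% names(long)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$.colour),
                                linewidth = 0.3) +
      ggplot2::labs(colour = colour_by)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.3, alpha = 0.5)
  }
  p + ggplot2::labs(x = "Wavelength (nm)", y = "Transmittance (%T)")
}

#' Plot the division sweep
#'
#' RMSECV and RMSEP against the number of spectral intervals, with the
#' recommended division marked.
#'
#' @param object An `ipls_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipls_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("n", "rmsecv", "rmsep")],
                              -"n", names_to = "stage", values_to = "rmse")
  long$stage <- toupper(long$stage)
  ggplot2::ggplot(long, ggplot2::aes(.data$n, .data$rmse,
                                     colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = attr(object, "best_n"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Number of spectral intervals", y = "RMSE (HU)",
                  colour = NULL)
}

#' Plot interval members
#'
#' Bar of per-interval RMSECV with the full-spectrum PLS RMSECV as a dashed
#' reference line; selected members (when a fusion model is supplied) are
#' highlighted.
#'
#' @param object An `ipls_model_set`.
#' @param fusion Optional `fusion_model` fitted on `object`.
#' @param pls_rmsecv Optional full-spectrum PLS RMSECV reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipls_model_set <- function(object, fusion = NULL,
                                    pls_rmsecv = NULL, ...) {
  tab <- tidy(object)
  tab$selected <- if (!is.null(fusion)) {
    tab$interval %in% fusion$selected
  } else {
    tab$best
  }
  p <- ggplot2::ggplot(tab, ggplot2::aes(.data$interval, .data$rmsecv,
                                         fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "Spectral interval", y = "RMSECV (HU)",
                  fill = "Selected")
  if (!is.null(pls_rmsecv)) {
    p <- p + ggplot2::geom_hline(yintercept = pls_rmsecv, linetype = "dashed")
  }
  p
}

#' Measured-versus-predicted scatter plot
#'
#' @param object A fitted `fusion_model` or `pls_model`.
#' @param newdata A `spectra_set` with reference values.
#' @return A ggplot object with the identity line.
#' @export
plot_predictions <- function(object, newdata) {
  stopifnot(inherits(newdata, "spectra_set"), !is.null(newdata$y))
  tab <- tibble(measured = newdata$y, predicted = predict(object, newdata))
  ggplot2::ggplot(tab, ggplot2::aes(.data$measured, .data$predicted)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Measured HU", y = "Predicted HU")
}
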