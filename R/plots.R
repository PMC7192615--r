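# Diagnostic figures, one autoplot method per result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a global CSP fit
#'
#' Observed combined CSPs per residue against added ligand, overlaid with
#' the shared-Kd model curves.
#'
#' @param object A `csp_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot csp_fit
#' @export
autoplot.csp_fit <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ligand_uM)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$dobs), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$residue), scales = "free_y") +
    ggplot2::labs(
      x = "RNA added (µM)", y = "combined CSP (ppm)",
      title = sprintf("Global fit: Kd = %.3g ± %.2g µM",
        object$kd_uM, object$kd_se)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a one-site ITC fit
#'
#' Normalized per-injection heats against molar ratio with the fitted
#' isotherm.
#'
#' @param object An `itc_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed, shape = .data$used)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
      guide = "none") +
    ggplot2::labs(
      x = "molar ratio (titrant / macromolecule)",
      y = "heat (kcal/mol of injectant)",
      title = sprintf("One-site fit: n = %.2f, Kd = %.3g µM, dH = %.3g kcal/mol",
        object$n, object$kd_uM, object$dh)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a two-state melting fit
#'
#' @param object A `melt_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot melt_fit
#' @export
autoplot.melt_fit <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature_C)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.6,
      alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$tm_C, linetype = "dashed") +
    ggplot2::labs(
      x = "temperature (°C)", y = "ellipticity",
      title = sprintf("Two-state melt: Tm = %.1f ± %.2g °C",
        object$tm_C, object$tm_se)
    ) +
    ggplot2::theme_minimal()
}

#' Plot foldedness versus titrant concentration
#'
#' @param curve A [foldedness_curve()], or a named list of them to compare
#'   constructs.
#' @return A ggplot.
#' @export
plot_foldedness <- function(curve) {
  if (!inherits(curve, "foldedness_curve") && is.list(curve)) {
    df <- purrr::imap(curve, function(cv, nm) {
      dplyr::mutate(tibble::as_tibble(cv), series = nm)
    }) |>
      purrr::list_rbind()
  } else {
    df <- dplyr::mutate(tibble::as_tibble(curve), series = "series")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$titrant_uM, y = .data$foldedness,
    colour = .data$series)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "protein (µM)", y = "relative foldedness") +
    ggplot2::theme_minimal()
}
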