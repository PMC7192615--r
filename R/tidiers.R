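# broom-style accessors for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a global CSP fit
#'
#' One row per parameter: the shared Kd followed by each residue's
#' saturation shift.
#'
#' @param x A `csp_fit` object.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`.
#' @method tidy csp_fit
#' @export
tidy.csp_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "kd_uM", estimate = x$kd_uM, std.error = x$kd_se),
    tibble::tibble(
      term = paste0("ddmax[", x$per_residue$residue, "]"),
      estimate = x$per_residue$ddmax, std.error = x$per_residue$ddmax_se
    )
  )
}

#' Glance at a global CSP fit
#'
#' @param x A `csp_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `kd_uM`, `kd_se`, `kd_se_boot`, `n_residues`,
#'   `rss`, `df.residual`, `converged`, `flag`.
#' @method glance csp_fit
#' @export
glance.csp_fit <- function(x, ...) {
  tibble::tibble(
    kd_uM = x$kd_uM, kd_se = x$kd_se, kd_se_boot = x$kd_se_boot,
    n_residues = nrow(x$per_residue), rss = x$rss,
    df.residual = x$df_residual, converged = x$converged, flag = x$flag
  )
}

#' Tidy a one-site ITC fit
#'
#' @param x An `itc_fit` object.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`.
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("n", "kd_uM", "dh", "baseline"),
    estimate = c(x$n, x$kd_uM, x$dh, x$baseline),
    std.error = c(x$n_se, x$kd_se, x$dh_se, x$baseline_se)
  )
}

#' Glance at a one-site ITC fit
#'
#' @param x An `itc_fit` object.
#' @param ... Unused.
#' @return A one-row tibble including the Wiseman c-value and flags.
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, kd_uM = x$kd_uM, dh = x$dh, baseline = x$baseline,
    c_value = x$c_value, rss = x$rss, df.residual = x$df_residual,
    converged = x$converged, flag = x$flag
  )
}

#' Tidy a two-state melting fit
#'
#' @param x A `melt_fit` object.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`.
#' @method tidy melt_fit
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tm_C", "dh_vh", "theta_f", "slope_f", "theta_u", "slope_u"),
    estimate = c(x$tm_C, x$dh_vh, x$theta_f, x$slope_f, x$theta_u, x$slope_u),
    std.error = c(x$tm_se, x$dh_vh_se, rep(NA_real_, 4))
  )
}

#' Glance at a two-state melting fit
#'
#' @param x A `melt_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `tm_C`, `tm_se`, `dh_vh`, `rss`, `converged`,
#'   `flag`.
#' @method glance melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  tibble::tibble(
    tm_C = x$tm_C, tm_se = x$tm_se, dh_vh = x$dh_vh, rss = x$rss,
    converged = x$converged, flag = x$flag
  )
}
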