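#' Tidy a rate fit
#'
#' One row per (bin, parameter) with broom-style column names.
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return A tibble: `time`, `term`, `channel`, `estimate`.
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble::tibble(time = x$time, term = x$term, channel = x$channel,
                 estimate = x$rate)
}

#' Summarise a rate fit
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return One row: `n_bins`, `n_terms`, `mean_residual`, `max_residual`,
#'   `frac_degenerate`, `any_clamped`, `dt`, `bath_temperature`.
#' @export
glance.rate_fit <- function(x, ...) {
  per_bin <- dplyr::distinct(tibble::as_tibble(x)[, c("time", "residual_norm",
                                                      "degenerate",
                                                      "solvent_clamped")])
  tibble::tibble(
    n_bins = nrow(per_bin),
    n_terms = dplyr::n_distinct(x$term),
    mean_residual = mean(per_bin$residual_norm),
    max_residual = max(per_bin$residual_norm),
    frac_degenerate = mean(per_bin$degenerate),
    any_clamped = any(per_bin$solvent_clamped),
    dt = attr(x, "dt"),
    bath_temperature = attr(x, "bath_temperature")
  )
}

#' Tidy a regime fit
#'
#' Long format: one row per (region, parameter).
#'
#' @param x A `regime_fit`.
#' @param ... Unused.
#' @return A tibble: `label`, `term`, `estimate`, `std.error`.
#' @export
tidy.regime_fit <- function(x, ...) {
  df <- tibble::as_tibble(x)
  long <- lapply(seq_len(nrow(df)), function(r) {
    tibble::tibble(
      label = df$label[r],
      term = c("kappa_eff", "d_eff", "intercept"),
      estimate = c(df$kappa_eff[r], df$d_eff[r], df$intercept[r]),
      std.error = c(df$kappa_sem[r], df$d_sem[r], df$intercept_sem[r])
    )
  })
  dplyr::bind_rows(long)
}

#' Summarise a regime fit
#'
#' @param x A `regime_fit`.
#' @param ... Unused.
#' @return One row: `n_regions`, `n_converged`, `spacing`, `heat_capacity`.
#' @export
glance.regime_fit <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    n_converged = sum(x$converged),
    spacing = attr(x, "spacing"),
    heat_capacity = attr(x, "heat_capacity")
  )
}
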