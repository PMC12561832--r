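#' Tidy a fitted concentration-response curve
#'
#' @param x A `crc_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy crc_fit
#' @export
tidy.crc_fit <- function(x, ...) {
  se <- if (all(is.finite(x$vcov))) sqrt(diag(x$vcov)) else rep(NA_real_, 2)
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = unname(se)
  )
}

#' One-row fit summary for a concentration-response curve
#'
#' @param x A `crc_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `r2_adj`, `r2`, `rmse`, `n_obs`,
#'   `ec50_ugL`, `conc_scale`.
#' @method glance crc_fit
#' @export
glance.crc_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    r2_adj = x$r2_adj,
    r2 = x$r2,
    rmse = x$rmse,
    n_obs = x$n_obs,
    ec50_ugL = ecx(x, 0.5),
    conc_scale = x$conc_scale
  )
}
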