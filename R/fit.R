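#' Goodness-of-fit statistics for a concentration-response fit
#'
#' The adjusted coefficient reported here penalises by parameter count:
#' `R2_adj = 1 - ((n - 1) * sum((y - yhat)^2)) / ((n - m) * sum((y - ybar)^2))`
#' and `RMSE = sqrt(sum((y - yhat)^2) / n)`. The plain (unadjusted) `R2`
#' is also returned for transparency.
#'
#' @param observed,fitted Numeric vectors of equal length.
#' @param n_params Number of fitted parameters `m` (`n > m` required).
#' @return A one-row tibble with `r2_adj`, `r2`, `rmse`.
#' @export
goodness_of_fit <- function(observed, fitted, n_params) {
  if (length(observed) != length(fitted)) {
    stop("observed and fitted must have equal length", call. = FALSE)
  }
  n <- length(observed)
  m <- n_params
  if (n <= m) stop("need more observations than parameters", call. = FALSE)
  sse <- sum((observed - fitted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("undefined R2: observed effects have zero variance", call. = FALSE)
  tibble::tibble(
    r2_adj = 1 - ((n - 1) * sse) / ((n - m) * sst),
    r2 = 1 - sse / sst,
    rmse = sqrt(sse / n)
  )
}

# linearised-transform starting values; effects clipped away from {0,1}
crc_start <- function(model, x, e) {
  eps <- 1e-3
  ec <- pmin(pmax(e, eps), 1 - eps)
  z <- switch(model, Logit = stats::qlogis(ec), Weibull = log(-log(1 - ec)))
  co <- stats::coef(stats::lm(z ~ x))
  list(alpha = unname(co[1]), beta = max(unname(co[2]), 1e-3))
}

crc_grid_starts <- function(x, e) {
  x_mid <- x[which.min(abs(e - 0.5))]
  betas <- c(0.5, 1, 2, 4, 8)
  purrr::map(betas, \(b) list(alpha = -b * x_mid, beta = b))
}

#' Fit a two-parameter sigmoid concentration-response curve
#'
#' Minimises the residual sum of squares of mean inhibition effects against
#' the Logit or Weibull model on `log10` concentration, by
#' Levenberg-Marquardt least squares with a linearised-transform start plus
#' a coarse multi-start grid (objective tolerance 1e-10). Parameters are on
#' the canonical convention (`alpha_sign = +1`, see [crc()]).
#'
#' @param effect_table Output of [build_effect_table()], or any data frame
#'   with columns `conc_total_ugL` and `effect_mean` (one row per
#'   concentration point).
#' @param model `"Logit"` or `"Weibull"`.
#' @param conc_scale Scale on which to take `log10(c)`: `"ugL"` (default)
#'   or `"gL"`.
#' @param min_points Minimum number of distinct concentrations; default 10,
#'   the chemometric rule of five observations per parameter.
#' @return A `crc_fit` object (inherits `crc`): parameters, parameter
#'   covariance, `r2_adj`/`r2`/`rmse`, the data fitted, and fitted values.
#' @export
fit_crc <- function(effect_table, model = c("Logit", "Weibull"),
                    conc_scale = c("ugL", "gL"), min_points = 10) {
  model <- match.arg(model)
  conc_scale <- match.arg(conc_scale)
  stopifnot(is.data.frame(effect_table))
  conc <- effect_table$conc_total_ugL
  e <- effect_table$effect_mean
  if (is.null(conc) || is.null(e)) {
    stop("effect_table must have columns conc_total_ugL and effect_mean",
         call. = FALSE)
  }
  keep <- is.finite(conc) & conc > 0 & is.finite(e)
  conc <- conc[keep]; e <- e[keep]
  if (length(unique(conc)) < min_points) {
    stop("too few distinct concentrations for a reliable 2-parameter fit (need ",
         min_points, ")", call. = FALSE)
  }
  if (max(e) - min(e) < 1e-12) {
    stop("degenerate data: effects are constant across concentrations",
         call. = FALSE)
  }
  x <- log10(conc) - scale_offset_ugL(conc_scale)
  dat <- data.frame(x = x, e = e)
  form <- switch(model,
    Logit = e ~ 1 / (1 + exp(-alpha - beta * x)),
    Weibull = e ~ 1 - exp(-exp(alpha + beta * x))
  )
  starts <- c(list(crc_start(model, x, e)), crc_grid_starts(x, e))
  fits <- purrr::map(starts, function(s) {
    tryCatch(
      minpack.lm::nlsLM(
        form, data = dat, start = s,
        lower = c(alpha = -Inf, beta = 1e-8),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-10, maxiter = 200
        )
      ),
      error = function(err) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    stop("fit failure: nonlinear least squares did not converge from any start",
         call. = FALSE)
  }
  sse <- purrr::map_dbl(fits, \(f) sum(stats::residuals(f)^2))
  best <- fits[[which.min(sse)]]
  co <- stats::coef(best)
  vc <- tryCatch(stats::vcov(best), error = function(err) matrix(NA_real_, 2, 2))
  fitted_vals <- model_effect(model, co[["alpha"]], co[["beta"]], x)
  gof <- goodness_of_fit(e, fitted_vals, n_params = 2)
  obj <- crc(model, co[["alpha"]], co[["beta"]], conc_scale = conc_scale,
             alpha_sign = 1)
  obj$vcov <- vc
  obj$r2_adj <- gof$r2_adj
  obj$r2 <- gof$r2
  obj$rmse <- gof$rmse
  obj$n_obs <- length(e)
  obj$n_params <- 2L
  obj$data <- tibble::tibble(conc_ugL = conc, x = x, effect = e,
                             fitted = fitted_vals)
  class(obj) <- c("crc_fit", class(obj))
  obj
}

#' @export
print.crc_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  n = %d, R2_adj = %.4f, RMSE = %.4f, EC50 = %.4g ug/L\n",
              x$n_obs, x$r2_adj, x$rmse, ecx(x, 0.5)))
  invisible(x)
}

#' Select the best fit among candidate models
#'
#' Largest adjusted R2 wins; ties (difference < 1e-6) are broken by the
#' smaller RMSE, then by model order (Logit before Weibull).
#'
#' @param fits A list of `crc_fit` objects.
#' @return The selected `crc_fit`.
#' @export
select_best <- function(fits) {
  fits <- purrr::compact(fits)
  if (length(fits) == 0) stop("no successful fits to select from", call. = FALSE)
  model_rank <- function(f) match(f$model, c("Logit", "Weibull"))
  best <- fits[[1]]
  for (f in fits[-1]) {
    d <- f$r2_adj - best$r2_adj
    if (d > 1e-6) {
      best <- f
    } else if (abs(d) <= 1e-6) {
      if (f$rmse < best$rmse - 1e-12 ||
          (abs(f$rmse - best$rmse) <= 1e-12 && model_rank(f) < model_rank(best))) {
        best <- f
      }
    }
  }
  best
}

#' Function-based confidence bands (FCIs) for a fitted curve
#'
#' Delta-method bands on the effect scale: the linear predictor variance is
#' propagated through the inverse link, with a t-quantile on
#' `n - m` degrees of freedom.
#'
#' @param fit A `crc_fit` object with finite parameter covariance.
#' @param conc_ugL Concentration grid (µg/L); defaults to 200 log-spaced
#'   points across the fitted range.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `conc_ugL`, `fit`, `fci_lwr`, `fci_upr`. If the
#'   covariance is singular or non-finite, bands are `NA` with a warning.
#' @export
confidence_bands <- function(fit, conc_ugL = NULL, level = 0.95) {
  stopifnot(inherits(fit, "crc_fit"))
  if (level <= 0 || level >= 1) stop("level must lie strictly inside (0, 1)", call. = FALSE)
  if (is.null(conc_ugL)) {
    rng <- range(fit$data$conc_ugL)
    conc_ugL <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200)
  }
  x <- log10(conc_ugL) - scale_offset_ugL(fit$conc_scale)
  eta <- fit$alpha + fit$beta * x
  e_hat <- model_effect(fit$model, fit$alpha, fit$beta, x)
  v <- fit$vcov
  if (any(!is.finite(v))) {
    warning("parameter covariance unavailable; confidence bands omitted", call. = FALSE)
    return(tibble::tibble(conc_ugL = conc_ugL, fit = e_hat,
                          fci_lwr = NA_real_, fci_upr = NA_real_))
  }
  var_eta <- v[1, 1] + 2 * x * v[1, 2] + x^2 * v[2, 2]
  var_eta <- pmax(var_eta, 0)
  dmu <- switch(fit$model,
    Logit = e_hat * (1 - e_hat),
    Weibull = exp(eta - exp(eta))
  )
  se <- abs(dmu) * sqrt(var_eta)
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n_obs - fit$n_params)
  tibble::tibble(
    conc_ugL = conc_ugL,
    fit = e_hat,
    fci_lwr = e_hat - tq * se,
    fci_upr = e_hat + tq * se
  )
}

#' NOEC and LOEC estimation
#'
#' Two methods are available:
#' * `"dunnett"` (default): one-sided Dunnett many-to-one comparison of
#'   per-replicate effects against the blank control at significance 0.05;
#'   the NOEC is the highest tested concentration whose mean effect is not
#'   significantly above control, the LOEC the next concentration up.
#' * `"threshold"`: the LOEC is the lowest tested concentration whose mean
#'   effect exceeds `threshold` (default 0.01, the "effect at most 1%"
#'   minimum-effect rule); the NOEC is the next concentration down.
#'
#' Sentinels: when every concentration shows an effect the NOEC is `-Inf`
#' (below tested range) and the LOEC the lowest tested concentration; when
#' none does, the NOEC is the highest tested concentration and the LOEC
#' `+Inf`.
#'
#' @param effect_table Output of [build_effect_table()] for a single
#'   concentration series (the Dunnett method needs the per-replicate
#'   `effects` list-column and the `control_effects` attribute).
#' @param method `"dunnett"` or `"threshold"`.
#' @param threshold Mean-effect cutoff for the threshold method.
#' @param sig_level Significance level for the Dunnett test.
#' @return A one-row tibble: `method`, `noec_ugL`, `loec_ugL`.
#' @export
noec_loec <- function(effect_table, method = c("dunnett", "threshold"),
                      threshold = 0.01, sig_level = 0.05) {
  method <- match.arg(method)
  tab <- dplyr::arrange(effect_table, .data$conc_total_ugL)
  conc <- tab$conc_total_ugL
  if (method == "threshold") {
    exceeds <- tab$effect_mean > threshold
  } else {
    ctrl <- attr(effect_table, "control_effects")
    if (is.null(ctrl) || length(ctrl) < 2) {
      stop("Dunnett method needs >= 2 control replicates (control_effects attribute)",
           call. = FALSE)
    }
    if (any(tab$n_reps < 2)) {
      stop("Dunnett method needs >= 2 replicates per concentration", call. = FALSE)
    }
    long <- tibble::tibble(
      effect = c(ctrl, unlist(tab$effects)),
      group = factor(
        c(rep("control", length(ctrl)),
          rep(sprintf("c%02d", seq_along(conc)), tab$n_reps)),
        levels = c("control", sprintf("c%02d", seq_along(conc)))
      )
    )
    fit <- stats::aov(effect ~ group, data = long)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"),
                         alternative = "greater")
    pvals <- summary(gl)$test$pvalues
    exceeds <- as.numeric(pvals) < sig_level
  }
  not_exceeding <- which(!exceeds)
  if (length(not_exceeding) == 0) {
    noec <- -Inf
    loec <- conc[1]
  } else {
    noec_idx <- max(not_exceeding)
    noec <- conc[noec_idx]
    loec <- if (noec_idx < length(conc)) conc[noec_idx + 1] else Inf
  }
  tibble::tibble(method = method, noec_ugL = noec, loec_ugL = loec)
}
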