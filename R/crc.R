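#' Two-parameter sigmoid concentration-response functions
#'
#' Evaluates the inhibition effect at `x = log10(concentration)`:
#' * Logit: `E = 1 / (1 + exp(-alpha - beta * x))`
#' * Weibull: `E = 1 - exp(-exp(alpha + beta * x))`
#'
#' @param model `"Logit"` or `"Weibull"`.
#' @param alpha Location parameter.
#' @param beta Slope parameter (per log10 concentration unit).
#' @param log10_c `log10` of concentration, in whatever unit the parameters
#'   were fitted on.
#' @return Effect value(s) in `[0, 1]` (vectorised over `log10_c`).
#' @examples
#' model_effect("Logit", -6, 2.5, 2.4)  # midpoint at log10(c) = 2.4
#' @export
model_effect <- function(model, alpha, beta, log10_c) {
  model <- match.arg(model, c("Logit", "Weibull"))
  eta <- alpha + beta * log10_c
  switch(model,
    Logit = stats::plogis(eta),
    Weibull = 1 - exp(-exp(eta))
  )
}

#' Construct a concentration-response curve object
#'
#' A CRC stores the canonical sigmoid (see [model_effect()]) together with
#' the concentration scale the parameters were fitted on and a sign flag on
#' the location parameter. The effective location is
#' `alpha_sign * alpha`: published single-compound tables in this assay
#' family sometimes report the mirrored convention in which the EC50 is
#' `10^(+alpha/beta)` rather than the canonical `10^(-alpha/beta)`; setting
#' `alpha_sign = -1` reproduces such parameters without re-deriving them.
#'
#' @param model `"Logit"` or `"Weibull"`.
#' @param alpha,beta Location and slope; `beta` must be positive so effect
#'   increases with concentration.
#' @param conc_scale Unit in which `log10(c)` was taken: `"ugL"` or `"gL"`.
#' @param alpha_sign `+1` (canonical) or `-1` (mirrored location).
#' @return An object of class `crc`.
#' @examples
#' as_tab <- crc("Logit", 6.4033, 2.4878, conc_scale = "ugL", alpha_sign = -1)
#' ecx(as_tab, 0.5)  # EC50 in ug/L
#' @export
crc <- function(model, alpha, beta, conc_scale = c("ugL", "gL"),
                alpha_sign = 1) {
  model <- match.arg(model, c("Logit", "Weibull"))
  conc_scale <- match.arg(conc_scale)
  if (!is.finite(alpha) || !is.finite(beta)) {
    stop("alpha and beta must be finite", call. = FALSE)
  }
  if (beta <= 0) stop("beta must be positive (effect increases with concentration)",
                      call. = FALSE)
  if (!alpha_sign %in% c(-1, 1)) stop("alpha_sign must be +1 or -1", call. = FALSE)
  structure(
    list(model = model, alpha = alpha, beta = beta,
         conc_scale = conc_scale, alpha_sign = alpha_sign),
    class = "crc"
  )
}

#' @export
print.crc <- function(x, ...) {
  cat(sprintf("<crc> %s: alpha = %.6g (sign %+d), beta = %.6g, log10(c) in %s\n",
              x$model, x$alpha, x$alpha_sign, x$beta,
              if (x$conc_scale == "ugL") "ug/L" else "g/L"))
  invisible(x)
}

# log10 unit offset from the crc's scale to ug/L
scale_offset_ugL <- function(conc_scale) {
  switch(conc_scale, ugL = 0, gL = 6,
         stop("unknown conc_scale", call. = FALSE))
}

#' Evaluate a CRC at concentrations in ug/L
#'
#' @param object A [crc()] or fitted `crc_fit` object.
#' @param conc_ugL Concentration(s) in µg/L.
#' @return Predicted effect(s).
#' @export
crc_effect <- function(object, conc_ugL) {
  stopifnot(inherits(object, "crc"))
  x <- log10(conc_ugL) - scale_offset_ugL(object$conc_scale)
  model_effect(object$model, object$alpha_sign * object$alpha, object$beta, x)
}

#' Construct a CRC from an EC50 and a slope
#'
#' Convenience constructor for simulation truths and worked examples: the
#' location parameter is derived so that the curve passes through 50%
#' effect at `ec50_ugL`.
#'
#' @param ec50_ugL Median effect concentration in µg/L.
#' @param beta Positive slope per log10 concentration unit.
#' @param model `"Logit"` or `"Weibull"`.
#' @param conc_scale Scale for `log10(c)` (default `"ugL"`).
#' @return A [crc()] object (canonical sign convention).
#' @export
crc_from_ec50 <- function(ec50_ugL, beta, model = c("Logit", "Weibull"),
                          conc_scale = c("ugL", "gL")) {
  model <- match.arg(model)
  conc_scale <- match.arg(conc_scale)
  if (!is.finite(ec50_ugL) || ec50_ugL <= 0) {
    stop("ec50_ugL must be finite and positive", call. = FALSE)
  }
  x50 <- log10(ec50_ugL) - scale_offset_ugL(conc_scale)
  target <- switch(model, Logit = 0, Weibull = log(log(2)))
  crc(model, alpha = target - beta * x50, beta = beta,
      conc_scale = conc_scale, alpha_sign = 1)
}

#' Effect concentration ECx
#'
#' Closed-form inversion of a CRC at effect level `x`:
#' Logit `c = 10^((logit(x) - alpha_eff)/beta)`, Weibull
#' `c = 10^((log(-log(1 - x)) - alpha_eff)/beta)` on the fit's
#' concentration scale, converted to µg/L; `alpha_eff = alpha_sign * alpha`.
#'
#' @param object A [crc()] or `crc_fit` object.
#' @param x Effect level strictly inside `(0, 1)` (vectorised).
#' @return Concentration(s) in µg/L.
#' @export
ecx <- function(object, x) {
  stopifnot(inherits(object, "crc"))
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop("effect level x must lie strictly inside (0, 1)", call. = FALSE)
  }
  alpha_eff <- object$alpha_sign * object$alpha
  target <- switch(object$model,
    Logit = stats::qlogis(x),
    Weibull = log(-log(1 - x))
  )
  log10_c <- (target - alpha_eff) / object$beta
  10^(log10_c + scale_offset_ugL(object$conc_scale))
}
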