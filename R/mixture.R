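ray_fractions <- function(ray) {
  stopifnot(is.data.frame(ray), nrow(ray) == 1)
  p <- c(ray$p_A, ray$p_B)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1) ||
      abs(sum(p) - 1) > 1e-12) {
    stop("ray fractions must lie in (0,1) and sum to 1", call. = FALSE)
  }
  p
}

#' Concentration Addition (Loewe additivity) mixture ECx
#'
#' Under CA the components act as dilutions of one another, so the total
#' mixture concentration producing effect `x` is the weighted harmonic
#' combination of the component ECx values:
#' `EC_x,mix = (sum_i p_i / EC_x,i)^-1`, all in µg/L.
#'
#' @param ray One-row ray tibble ([equray_rays()] / [fixed_ratio_ray()]).
#' @param crcs List of two component CRCs (`crc` or `crc_fit`), in the ray's
#'   component order (A, B).
#' @param x Effect level(s) strictly inside `(0, 1)`.
#' @return Total mixture concentration(s) in µg/L.
#' @examples
#' ray <- fixed_ratio_ray(1, 1)
#' crcs <- list(crc_from_ec50(100, 2), crc_from_ec50(1000, 2))
#' ca_ecx(ray, crcs, 0.5)
#' @export
ca_ecx <- function(ray, crcs, x) {
  p <- ray_fractions(ray)
  stopifnot(length(crcs) == 2)
  ec_a <- ecx(crcs[[1]], x)
  ec_b <- ecx(crcs[[2]], x)
  1 / (p[1] / ec_a + p[2] / ec_b)
}

#' Independent Action (Bliss independence) mixture effect
#'
#' Under IA the components act on independent targets and the mixture
#' effect is the probabilistic union of the component effects:
#' `E = 1 - prod_i (1 - f_i(p_i * c_total))`, each component evaluated at
#' its own partial concentration.
#'
#' @inheritParams ca_ecx
#' @param total_conc_ugL Total mixture concentration(s) in µg/L.
#' @return Predicted effect(s).
#' @export
ia_effect <- function(ray, crcs, total_conc_ugL) {
  p <- ray_fractions(ray)
  stopifnot(length(crcs) == 2)
  if (any(total_conc_ugL <= 0)) {
    stop("total concentration must be positive", call. = FALSE)
  }
  e_a <- crc_effect(crcs[[1]], p[1] * total_conc_ugL)
  e_b <- crc_effect(crcs[[2]], p[2] * total_conc_ugL)
  1 - (1 - e_a) * (1 - e_b)
}

#' CA-predicted effect at a total concentration
#'
#' Converts the CA curve to the effect axis by numerical inversion:
#' bisection on the effect level `x` such that [ca_ecx()] equals the given
#' total concentration (tolerance 1e-10 on `x`). Concentrations outside the
#' invertible range collapse to effects of ~0 or ~1.
#'
#' @inheritParams ia_effect
#' @return Predicted effect(s) under Concentration Addition.
#' @export
ca_effect <- function(ray, crcs, total_conc_ugL) {
  vapply(total_conc_ugL, function(ct) {
    lo <- 1e-12
    hi <- 1 - 1e-12
    # ca_ecx is strictly increasing in x for positive-slope CRCs
    if (ca_ecx(ray, crcs, hi) <= ct) return(1)
    if (ca_ecx(ray, crcs, lo) >= ct) return(0)
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (ca_ecx(ray, crcs, mid) < ct) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Mixture prediction curves for a ray
#'
#' Tabulates both reference models over grids: the CA curve as
#' `EC_x,mix` per effect level, and the IA curve as predicted effect per
#' total concentration.
#'
#' @inheritParams ca_ecx
#' @param x_grid Effect levels for the CA curve.
#' @param conc_grid_ugL Total concentrations for the IA (and effect-axis CA)
#'   curve; defaults to 200 log-spaced points over the union of the
#'   component fitted ranges, when available.
#' @return A list of class `mixture_prediction` with elements `ray`, `crcs`,
#'   `ca` (tibble `x`, `conc_ugL`) and `ia` (tibble `conc_ugL`, `effect_ia`,
#'   `effect_ca`).
#' @export
mixture_prediction <- function(ray, crcs, x_grid = seq(0.01, 0.99, by = 0.01),
                               conc_grid_ugL = NULL) {
  p <- ray_fractions(ray)
  if (is.null(conc_grid_ugL)) {
    rng <- range(unlist(purrr::map(crcs, function(f) {
      if (!is.null(f$data)) range(f$data$conc_ugL) else ecx(f, c(0.01, 0.99))
    })))
    conc_grid_ugL <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200)
  }
  structure(
    list(
      ray = ray,
      crcs = crcs,
      ca = tibble::tibble(x = x_grid, conc_ugL = ca_ecx(ray, crcs, x_grid)),
      ia = tibble::tibble(
        conc_ugL = conc_grid_ugL,
        effect_ia = ia_effect(ray, crcs, conc_grid_ugL),
        effect_ca = ca_effect(ray, crcs, conc_grid_ugL)
      )
    ),
    class = "mixture_prediction"
  )
}

#' Classify observed mixture points against a reference model
#'
#' At each tested total concentration the reference prediction (CA or IA,
#' on the effect axis) is compared with the observation-based confidence
#' interval around the observed mean effect. With the default toxicological
#' orientation, a prediction inside the OCI is `additive`; a prediction
#' below the OCI (observed toxicity exceeds the prediction) is
#' `synergistic`; above it, `antagonistic`. `orientation = "flipped"`
#' swaps the synergism/antagonism labels.
#'
#' @param effect_table Effect table for the mixture ray
#'   ([build_effect_table()] output).
#' @param ray,crcs The ray and its two component CRCs.
#' @param reference `"CA"`, `"IA"`, or `"both"` (default).
#' @param level OCI confidence level.
#' @param orientation `"effect"` (default, observed effect above prediction
#'   means synergism) or `"flipped"`.
#' @return A tibble with one row per tested concentration:
#'   `conc_total_ugL`, `effect_mean`, `oci_lwr`, `oci_upr`, `pred_ca`,
#'   `pred_ia`, `label_ca`, `label_ia` (label columns only for the chosen
#'   references). Points lacking an OCI are dropped with a warning.
#' @export
classify_points <- function(effect_table, ray, crcs,
                            reference = c("both", "CA", "IA"),
                            level = 0.95,
                            orientation = c("effect", "flipped")) {
  reference <- match.arg(reference)
  orientation <- match.arg(orientation)
  tab <- oci(effect_table, level = level)
  usable <- is.finite(tab$oci_lwr) & is.finite(tab$oci_upr)
  if (any(!usable)) {
    warning(sum(!usable), " point(s) without an OCI skipped", call. = FALSE)
    tab <- tab[usable, ]
  }
  if (nrow(tab) == 0) stop("no points with OCIs to classify", call. = FALSE)
  label_against <- function(pred) {
    lab <- dplyr::case_when(
      pred < tab$oci_lwr ~ "synergistic",
      pred > tab$oci_upr ~ "antagonistic",
      TRUE ~ "additive"
    )
    if (orientation == "flipped") {
      lab <- dplyr::recode(lab, synergistic = "antagonistic",
                           antagonistic = "synergistic")
    }
    lab
  }
  out <- tibble::tibble(
    conc_total_ugL = tab$conc_total_ugL,
    effect_mean = tab$effect_mean,
    oci_lwr = tab$oci_lwr,
    oci_upr = tab$oci_upr,
    pred_ca = ca_effect(ray, crcs, tab$conc_total_ugL),
    pred_ia = ia_effect(ray, crcs, tab$conc_total_ugL)
  )
  if (reference %in% c("both", "CA")) out$label_ca <- label_against(out$pred_ca)
  if (reference %in% c("both", "IA")) out$label_ia <- label_against(out$pred_ia)
  out
}

majority_label <- function(labels) {
  if (length(labels) == 0) return(NA_character_)
  counts <- sort(table(labels), decreasing = TRUE)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) "additive" else top[1]
}

#' Ray-level interaction label and concentration-region summary
#'
#' The ray label is the majority point label among points whose effect
#' (the mixture fit's value if supplied, else the observed mean) lies in
#' the mid-effect window `[0.2, 0.8]`; ties are resolved conservatively to
#' `additive`. Points are also summarised over low / medium / high
#' concentration regions (default band edges 1e3 and 2e4 µg/L).
#'
#' @param points Output of [classify_points()].
#' @param mix_fit Optional `crc_fit` of the mixture ray itself, used to
#'   compute the windowing effect.
#' @param window Mid-effect window for the ray label.
#' @param band_edges_ugL Two increasing edges splitting low / medium / high
#'   concentration regions.
#' @return A list of class `ray_summary`: `label` (named character, one per
#'   reference model present) and `regions` (tibble of majority labels per
#'   region and reference).
#' @export
summarize_ray <- function(points, mix_fit = NULL, window = c(0.2, 0.8),
                          band_edges_ugL = c(1e3, 2e4)) {
  stopifnot(is.data.frame(points), nrow(points) >= 1)
  if (length(band_edges_ugL) != 2 || diff(band_edges_ugL) <= 0) {
    stop("band_edges_ugL must be two strictly increasing values", call. = FALSE)
  }
  eff <- if (!is.null(mix_fit)) {
    crc_effect(mix_fit, points$conc_total_ugL)
  } else {
    points$effect_mean
  }
  in_window <- eff >= window[1] & eff <= window[2]
  if (!any(in_window)) {
    warning("no points in the mid-effect window; ray label uses all points",
            call. = FALSE)
    in_window <- rep(TRUE, length(eff))
  }
  refs <- intersect(c("label_ca", "label_ia"), names(points))
  label <- purrr::map_chr(refs, function(col) {
    majority_label(points[[col]][in_window])
  })
  names(label) <- sub("^label_", "", refs)
  region_fac <- cut(points$conc_total_ugL,
                    breaks = c(0, band_edges_ugL, Inf),
                    labels = c("low", "medium", "high"))
  regions <- purrr::map_dfr(refs, function(col) {
    tibble::tibble(
      reference = sub("^label_", "", col),
      region = levels(region_fac),
      label = vapply(levels(region_fac), function(r) {
        majority_label(points[[col]][region_fac == r])
      }, character(1)),
      n_points = as.integer(table(region_fac))
    )
  })
  structure(list(label = label, regions = regions), class = "ray_summary")
}

#' @export
print.ray_summary <- function(x, ...) {
  cat("<ray_summary>\n")
  for (ref in names(x$label)) {
    cat(sprintf("  %s: %s\n", toupper(ref), x$label[[ref]]))
  }
  print(x$regions)
  invisible(x)
}
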