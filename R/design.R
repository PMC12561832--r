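#' Geometric dilution factor
#'
#' Computes the constant factor `F` that maps the maximum-effect
#' concentration `c_high` onto the minimum-effect concentration `c_low`
#' in `n_points - 1` multiplicative steps:
#' `F = (c_low / c_high)^(1 / (n_points - 1))`.
#'
#' @param c_high Maximum-effect concentration (µg/L), `C_H`.
#' @param c_low Minimum-effect concentration (µg/L), `C_L`.
#' @param n_points Number of gradient points (>= 2).
#' @return The dimensionless dilution factor, in `(0, 1]`.
#' @examples
#' dilution_factor(10000, 10, 12)
#' @export
dilution_factor <- function(c_high, c_low, n_points) {
  if (!is.numeric(c_high) || !is.numeric(c_low) || length(c_high) != 1L ||
      length(c_low) != 1L || !is.finite(c_high) || !is.finite(c_low) ||
      c_high <= 0 || c_low <= 0) {
    stop("invalid design: concentrations must be finite and positive", call. = FALSE)
  }
  if (c_low > c_high) {
    stop("invalid design: c_low must not exceed c_high", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) {
    stop("invalid design: n_points must be at least 2", call. = FALSE)
  }
  (c_low / c_high)^(1 / (n_points - 1))
}

#' Geometric concentration series
#'
#' Builds the descending gradient `C_k = C_H * F^(k-1)`, `k = 1..n_points`,
#' with `C_1 = c_high` and `C_n = c_low` (the endpoints are pinned exactly).
#'
#' @inheritParams dilution_factor
#' @return A tibble of class `dilution_series` with columns `point`
#'   (1-based index, descending concentration) and `conc_ugL`. The design
#'   parameters are stored as attributes `c_high`, `c_low`, `factor`.
#' @examples
#' concentration_series(10000, 10, 12)
#' @export
concentration_series <- function(c_high, c_low, n_points) {
  if (n_points < 3) stop("invalid design: a series needs at least 3 points", call. = FALSE)
  f <- dilution_factor(c_high, c_low, n_points)
  conc <- c_high * f^(seq_len(n_points) - 1)
  conc[1] <- c_high
  conc[n_points] <- c_low
  out <- tibble::tibble(point = seq_len(n_points), conc_ugL = conc)
  attr(out, "c_high") <- c_high
  attr(out, "c_low") <- c_low
  attr(out, "factor") <- f
  class(out) <- c("dilution_series", class(out))
  out
}

new_ray <- function(ray_id, component_ids, p_a, basis, basis_detail) {
  tibble::tibble(
    ray_id = ray_id,
    component_a = component_ids[[1]],
    component_b = component_ids[[2]],
    p_A = p_a,
    p_B = 1 - p_a,
    basis = basis,
    basis_detail = basis_detail
  )
}

#' Direct equipartition ray (EquRay) mixture design
#'
#' Constructs `n_rays` fixed-ratio binary mixture rays from the two
#' components' EC50s. Ray `k` mixes `k` toxic units of component A with
#' `n_rays + 1 - k` toxic units of component B, one toxic unit being that
#' component's EC50 in mass concentration, so the A mass fraction is
#' `p_A(k) = k * EC50_A / (k * EC50_A + (n_rays + 1 - k) * EC50_B)`.
#' Rays are returned in increasing `p_A` and labelled `R1 .. Rn`.
#'
#' @param ec50_a,ec50_b Component EC50s on the same mass-concentration
#'   scale (any common unit; fractions are scale-invariant).
#' @param n_rays Number of rays (default 5).
#' @param component_ids Character pair naming the components.
#' @return A tibble with one row per ray: `ray_id`, `component_a`,
#'   `component_b`, `p_A`, `p_B`, `basis`, `basis_detail`.
#' @examples
#' equray_rays(374.87, 19988.75)
#' @export
equray_rays <- function(ec50_a, ec50_b, n_rays = 5,
                        component_ids = c("A", "B")) {
  if (!is.finite(ec50_a) || !is.finite(ec50_b) || ec50_a <= 0 || ec50_b <= 0) {
    stop("invalid design: EC50s must be finite and positive", call. = FALSE)
  }
  n_rays <- as.integer(n_rays)
  if (is.na(n_rays) || n_rays < 1L) {
    stop("invalid design: n_rays must be a positive integer", call. = FALSE)
  }
  k <- seq_len(n_rays)
  k_b <- n_rays + 1L - k
  p_a <- k * ec50_a / (k * ec50_a + k_b * ec50_b)
  purrr::map_dfr(k, function(i) {
    new_ray(
      ray_id = paste0("R", i),
      component_ids = component_ids,
      p_a = p_a[i],
      basis = "ec50_multiples",
      basis_detail = sprintf("%dEC50_A:%dEC50_B", i, k_b[i])
    )
  })
}

#' Fixed-ratio mixture ray
#'
#' A single ray at a stated mass-concentration ratio `ratio_a : ratio_b`
#' (for example the environmentally observed As:Pb = 1:10 ratio).
#'
#' @param ratio_a,ratio_b Positive ratio parts for the two components.
#' @param ray_id Label for the ray (default `"Rf"`).
#' @param component_ids Character pair naming the components.
#' @return A one-row ray tibble (see [equray_rays()]).
#' @examples
#' fixed_ratio_ray(1, 10)
#' @export
fixed_ratio_ray <- function(ratio_a, ratio_b, ray_id = "Rf",
                            component_ids = c("A", "B")) {
  if (!is.finite(ratio_a) || !is.finite(ratio_b) || ratio_a <= 0 || ratio_b <= 0) {
    stop("invalid design: both ratio parts must be positive", call. = FALSE)
  }
  new_ray(
    ray_id = ray_id,
    component_ids = component_ids,
    p_a = ratio_a / (ratio_a + ratio_b),
    basis = "fixed_ratio",
    basis_detail = sprintf("%g:%g", ratio_a, ratio_b)
  )
}

#' Expand rays over a dilution series into a plate design
#'
#' @param rays Ray tibble from [equray_rays()] / [fixed_ratio_ray()]
#'   (rows may be combined with [dplyr::bind_rows()]).
#' @param series A [concentration_series()] of total mixture concentrations.
#' @return A tibble with columns `ray_id`, `point_index`, `total_conc_ugL`,
#'   `conc_A_ugL`, `conc_B_ugL`, `p_A`, ready for CSV export.
#' @export
design_table <- function(rays, series) {
  stopifnot(is.data.frame(rays), is.data.frame(series))
  tidyr::crossing(
    dplyr::select(rays, "ray_id", "p_A"),
    dplyr::select(series, point_index = "point", total_conc_ugL = "conc_ugL")
  ) |>
    dplyr::mutate(
      conc_A_ugL = .data$p_A * .data$total_conc_ugL,
      conc_B_ugL = (1 - .data$p_A) * .data$total_conc_ugL
    ) |>
    dplyr::select(
      "ray_id", "point_index", "total_conc_ugL",
      "conc_A_ugL", "conc_B_ugL", "p_A"
    ) |>
    dplyr::arrange(.data$ray_id, .data$point_index)
}
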