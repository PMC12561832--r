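plate_columns <- c(
  "treatment_id", "ray_id", "conc_A_ugL", "conc_B_ugL",
  "replicate", "od680", "is_control"
)

#' Read a plate-style CSV of optical-density readings
#'
#' The expected header is
#' `treatment_id,ray_id,conc_A_ugL,conc_B_ugL,replicate,od680,is_control`
#' (UTF-8, `.` decimal). `ray_id` is `"single"` for single-compound
#' treatments; control rows carry `is_control = TRUE` and zero
#' concentrations.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of plate readings.
#' @export
read_plate <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE))
  missing <- setdiff(plate_columns, header)
  if (length(missing) > 0) {
    stop("plate format error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    treatment_id = readr::col_character(),
    ray_id = readr::col_character(),
    conc_A_ugL = readr::col_double(),
    conc_B_ugL = readr::col_double(),
    replicate = readr::col_integer(),
    od680 = readr::col_double(),
    is_control = readr::col_logical()
  ), progress = FALSE)
  validate_plate(raw)
}

validate_plate <- function(readings) {
  readings <- tibble::as_tibble(readings)[plate_columns]
  bad <- which(!is.finite(readings$od680) | readings$od680 < 0)
  if (length(bad) > 0) {
    stop("plate format error: negative or non-finite od680 at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad_conc <- which(readings$is_control &
                      (readings$conc_A_ugL != 0 | readings$conc_B_ugL != 0))
  if (length(bad_conc) > 0) {
    stop("plate format error: control row(s) with non-zero concentration at data row(s) ",
         paste(utils::head(bad_conc, 5), collapse = ", "), call. = FALSE)
  }
  if (!any(readings$is_control)) {
    stop("plate format error: no control rows present", call. = FALSE)
  }
  readings
}

#' Growth-inhibition rate from optical densities
#'
#' `E = (I0 - Ii) / I0`, where `I0` is the blank-control mean OD680 and
#' `Ii` the treatment OD680. The result is not clamped: growth stimulation
#' yields `E < 0` and is reported with a warning.
#'
#' @param control_mean Mean OD680 of the blank controls (must be > 0).
#' @param treatment_mean Treatment OD680 (vectorised).
#' @return Inhibition effect(s) `E`, dimensionless.
#' @examples
#' inhibition(0.4, 0.1)
#' @export
inhibition <- function(control_mean, treatment_mean) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    stop("invalid control: blank-control mean OD must be positive", call. = FALSE)
  }
  e <- (control_mean - treatment_mean) / control_mean
  if (any(e < 0, na.rm = TRUE)) {
    warning("negative inhibition (growth stimulation) observed; values not clamped",
            call. = FALSE)
  }
  e
}

#' Build per-concentration effect table from plate readings
#'
#' Converts each reading to an inhibition effect against the pooled
#' blank-control mean within the plate, then summarises replicates per
#' treatment series and concentration point.
#'
#' @param readings A plate tibble from [read_plate()] or the simulator.
#' @return A tibble with one row per (`treatment_id`, concentration point):
#'   `treatment_id`, `ray_id`, `conc_A_ugL`, `conc_B_ugL`, `conc_total_ugL`,
#'   `n_reps`, `effects` (list of replicate effects), `effect_mean`,
#'   `effect_se` (`NA` when a single replicate). The per-replicate control
#'   effects are attached as attribute `"control_effects"` and the pooled
#'   control mean as `"control_mean"` for downstream hypothesis tests.
#' @export
build_effect_table <- function(readings) {
  readings <- validate_plate(readings)
  controls <- readings[readings$is_control, ]
  i0 <- mean(controls$od680)
  if (!is.finite(i0) || i0 <= 0) {
    stop("invalid control: pooled blank-control mean OD must be positive", call. = FALSE)
  }
  trt <- readings[!readings$is_control, ]
  dup <- duplicated(trt[c("treatment_id", "conc_A_ugL", "conc_B_ugL", "replicate")])
  if (any(dup)) {
    stop("ambiguous plate: duplicate (treatment, concentration, replicate) keys",
         call. = FALSE)
  }
  out <- trt |>
    dplyr::mutate(effect = suppressWarnings(inhibition(i0, .data$od680))) |>
    dplyr::group_by(
      .data$treatment_id, .data$ray_id, .data$conc_A_ugL, .data$conc_B_ugL
    ) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      effects = list(.data$effect),
      effect_mean = mean(.data$effect),
      effect_se = if (dplyr::n() > 1) {
        stats::sd(.data$effect) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      conc_total_ugL = .data$conc_A_ugL + .data$conc_B_ugL,
      .after = "conc_B_ugL"
    ) |>
    dplyr::arrange(.data$treatment_id, .data$conc_total_ugL)
  attr(out, "control_mean") <- i0
  attr(out, "control_effects") <- suppressWarnings(inhibition(i0, controls$od680))
  out
}

#' Observation-based confidence intervals (OCIs) on mean effects
#'
#' At each tested concentration the interval is the per-concentration
#' t-interval on the replicate mean:
#' `mean(E) +/- t(df = n - 1, 1 - (1 - level)/2) * SE`.
#'
#' @param effect_table Output of [build_effect_table()].
#' @param level Confidence level (default 0.95).
#' @return `effect_table` with added columns `oci_lwr`, `oci_upr`
#'   (`NA` where only one replicate exists).
#' @export
oci <- function(effect_table, level = 0.95) {
  stopifnot(is.data.frame(effect_table))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  tq <- ifelse(effect_table$n_reps > 1,
               stats::qt(1 - (1 - level) / 2, df = effect_table$n_reps - 1),
               NA_real_)
  dplyr::mutate(effect_table,
    oci_lwr = .data$effect_mean - tq * .data$effect_se,
    oci_upr = .data$effect_mean + tq * .data$effect_se
  )
}
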