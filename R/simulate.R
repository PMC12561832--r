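#' Define a simulation scenario
#'
#' Bundles the generative truths and noise model for a synthetic
#' growth-inhibition study: per-component true CRCs, the geometric plate
#' design, replicate-level optical-density noise, and the mixture truth
#' (Concentration Addition, Independent Action, or either with a
#' dose-modification factor `kappa` applied to the effective total
#' concentration: `kappa > 1` builds in synergy, `kappa < 1` antagonism).
#'
#' @param truth_a,truth_b True component CRCs ([crc()] or
#'   [crc_from_ec50()]); `truth_b` may be `NULL` for single-compound work.
#' @param c_high_a,c_low_a,c_high_b,c_low_b Per-component ladder endpoints
#'   (µg/L): the maximum-effect and minimum-effect concentrations.
#' @param n_points Gradient points per ladder (default 12).
#' @param replicates Replicates per treatment (default 3).
#' @param sigma Noise standard deviation (default 0.02).
#' @param noise_scale `"od"` (default; noise on the measured absorbance) or
#'   `"effect"` (noise added directly to the inhibition effect).
#' @param control_od Mean blank-control OD680 (default 0.5).
#' @param background_od Constant background absorbance added to treatment
#'   wells only (default 0), so both blank-handling conventions can be
#'   exercised.
#' @param interaction Mixture truth: `"CA_truth"`, `"IA_truth"` or
#'   `"dose_modifier"`.
#' @param base_model Reference model the dose modifier perturbs
#'   (`"CA"` or `"IA"`).
#' @param kappa Dose-modification factor (> 0; 1 leaves the base truth
#'   unchanged).
#' @param seed Integer seed; simulation draws use Mersenne-Twister with
#'   inversion normals for cross-platform determinism.
#' @return A list of class `sim_scenario`.
#' @export
simulation_scenario <- function(truth_a, truth_b = NULL,
                                c_high_a, c_low_a,
                                c_high_b = NULL, c_low_b = NULL,
                                n_points = 12, replicates = 3,
                                sigma = 0.02,
                                noise_scale = c("od", "effect"),
                                control_od = 0.5, background_od = 0,
                                interaction = c("CA_truth", "IA_truth",
                                                "dose_modifier"),
                                base_model = c("CA", "IA"),
                                kappa = 1, seed = 1L) {
  noise_scale <- match.arg(noise_scale)
  interaction <- match.arg(interaction)
  base_model <- match.arg(base_model)
  stopifnot(inherits(truth_a, "crc"))
  if (!is.null(truth_b)) stopifnot(inherits(truth_b, "crc"))
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (!is.finite(control_od) || control_od <= 0) {
    stop("control_od must be positive", call. = FALSE)
  }
  structure(
    list(truth_a = truth_a, truth_b = truth_b,
         c_high_a = c_high_a, c_low_a = c_low_a,
         c_high_b = c_high_b, c_low_b = c_low_b,
         n_points = as.integer(n_points), replicates = as.integer(replicates),
         sigma = sigma, noise_scale = noise_scale,
         control_od = control_od, background_od = background_od,
         interaction = interaction, base_model = base_model,
         kappa = kappa, seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Reference scenario emulating a 96 h As(V)/Pb(II) algal assay
#'
#' Logit truths centred on the published single-compound EC50s
#' (374.87 and 19,988.75 µg/L) with slopes steep enough that the ladder
#' endpoints meet the design rule (effect at most 1% at the lowest and at
#' least 98% at the highest tested concentration); 12 geometric points
#' times 3 replicates per treatment.
#'
#' @param ... Overrides passed on to [simulation_scenario()].
#' @return A `sim_scenario`.
#' @export
scenario_as_pb <- function(...) {
  defaults <- list(
    truth_a = crc_from_ec50(374.87, 3.2, model = "Logit"),
    truth_b = crc_from_ec50(19988.75, 2.6, model = "Logit"),
    c_high_a = 10000, c_low_a = 10,
    c_high_b = 1.3e6, c_low_b = 300,
    interaction = "CA_truth"
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_scenario, args)
}

sim_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# noisy plate rows for one treatment series
sim_readings <- function(scenario, treatment_id, ray_id, conc_a, conc_b,
                         e_true) {
  reps <- scenario$replicates
  n <- length(e_true)
  ctrl <- scenario$control_od
  sig <- scenario$sigma
  trt_rows <- tidyr::crossing(point = seq_len(n), replicate = seq_len(reps))
  e_point <- e_true[trt_rows$point]
  if (scenario$noise_scale == "od") {
    od <- ctrl * (1 - e_point) + scenario$background_od +
      stats::rnorm(nrow(trt_rows), 0, sig)
  } else {
    od <- ctrl * (1 - (e_point + stats::rnorm(nrow(trt_rows), 0, sig))) +
      scenario$background_od
  }
  control_od <- stats::rnorm(reps, ctrl, sig)
  tibble::tibble(
    treatment_id = c(rep(treatment_id, nrow(trt_rows)), rep("control", reps)),
    ray_id = c(rep(ray_id, nrow(trt_rows)), rep("control", reps)),
    conc_A_ugL = c(conc_a[trt_rows$point], rep(0, reps)),
    conc_B_ugL = c(conc_b[trt_rows$point], rep(0, reps)),
    replicate = c(trt_rows$replicate, seq_len(reps)),
    od680 = pmax(c(od, control_od), 0),
    is_control = c(rep(FALSE, nrow(trt_rows)), rep(TRUE, reps))
  )
}

#' Simulate a single-compound plate
#'
#' Draws a geometric ladder for the chosen component, evaluates its true
#' CRC, and generates replicate OD680 readings: control OD is
#' `Normal(control_od, sigma)` and treatment OD is
#' `control_od * (1 - E_true) + background + Normal(0, sigma)`, both
#' truncated at zero. Deterministic for a fixed seed.
#'
#' @param scenario A [simulation_scenario()].
#' @param component `"A"` or `"B"`.
#' @param seed Seed for this draw (defaults to the scenario seed).
#' @return A plate-readings tibble (see [read_plate()]).
#' @export
simulate_single <- function(scenario, component = c("A", "B"),
                            seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  component <- match.arg(component)
  truth <- if (component == "A") scenario$truth_a else scenario$truth_b
  if (is.null(truth)) stop("scenario has no truth for component ", component,
                           call. = FALSE)
  c_high <- if (component == "A") scenario$c_high_a else scenario$c_high_b
  c_low <- if (component == "A") scenario$c_low_a else scenario$c_low_b
  series <- concentration_series(c_high, c_low, scenario$n_points)
  e_true <- crc_effect(truth, series$conc_ugL)
  conc_a <- if (component == "A") series$conc_ugL else rep(0, nrow(series))
  conc_b <- if (component == "B") series$conc_ugL else rep(0, nrow(series))
  sim_rng(seed, sim_readings(scenario, component, "single",
                             conc_a, conc_b, e_true))
}

#' True mixture effect for a ray under the scenario's interaction mode
#'
#' @param scenario A [simulation_scenario()] with both truths set.
#' @param ray One-row ray tibble.
#' @param total_conc_ugL Total mixture concentration(s) in µg/L.
#' @return True effect(s) at each total concentration.
#' @export
ray_truth_effect <- function(scenario, ray, total_conc_ugL) {
  crcs <- list(scenario$truth_a, scenario$truth_b)
  mode <- scenario$interaction
  kappa <- if (mode == "dose_modifier") scenario$kappa else 1
  base <- if (mode == "IA_truth" ||
              (mode == "dose_modifier" && scenario$base_model == "IA")) {
    "IA"
  } else {
    "CA"
  }
  c_eff <- kappa * total_conc_ugL
  if (base == "CA") {
    ca_effect(ray, crcs, c_eff)
  } else {
    ia_effect(ray, crcs, c_eff)
  }
}

# total concentration at which the ray truth reaches effect x
ray_truth_ecx <- function(scenario, ray, x) {
  lo <- log10(min(ecx(scenario$truth_a, 1e-4), ecx(scenario$truth_b, 1e-4))) - 6
  hi <- log10(max(ecx(scenario$truth_a, 1 - 1e-4),
                  ecx(scenario$truth_b, 1 - 1e-4))) + 6
  vapply(x, function(xx) {
    10^stats::uniroot(
      function(lc) ray_truth_effect(scenario, ray, 10^lc) - xx,
      lower = lo, upper = hi, tol = 1e-12
    )$root
  }, numeric(1))
}

#' Simulate a mixture-ray plate
#'
#' As [simulate_single()], but the truth is the scenario's mixture model
#' (CA inversion, IA composition, or either at the dose-modified
#' concentration `kappa * c`). The ladder endpoints default to the
#' range-finding rule used for real assays: the total concentrations where
#' the true mixture effect reaches 98% and 1%.
#'
#' @param scenario A [simulation_scenario()] with both component truths.
#' @param ray One-row ray tibble ([equray_rays()] / [fixed_ratio_ray()]).
#' @param seed Seed for this draw (defaults to the scenario seed).
#' @param c_high,c_low Optional explicit ladder endpoints (µg/L).
#' @return A plate-readings tibble.
#' @export
simulate_ray <- function(scenario, ray, seed = scenario$seed,
                         c_high = NULL, c_low = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(scenario$truth_b)) {
    stop("ray simulation needs both component truths", call. = FALSE)
  }
  if (is.null(c_high)) c_high <- ray_truth_ecx(scenario, ray, 0.98)
  if (is.null(c_low)) c_low <- ray_truth_ecx(scenario, ray, 0.01)
  series <- concentration_series(c_high, c_low, scenario$n_points)
  e_true <- ray_truth_effect(scenario, ray, series$conc_ugL)
  sim_rng(seed, sim_readings(
    scenario, ray$ray_id, ray$ray_id,
    conc_a = ray$p_A * series$conc_ugL,
    conc_b = ray$p_B * series$conc_ugL,
    e_true = e_true
  ))
}

#' Write plate readings to the package CSV dialect
#'
#' Emits exactly the columns [read_plate()] expects; a zero-row tibble
#' produces a header-only file. `write_fixture()` is an alias.
#'
#' @param readings Plate-readings tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(readings, path) {
  readings <- tibble::as_tibble(readings)
  missing <- setdiff(plate_columns, names(readings))
  if (length(missing) > 0) {
    stop("cannot write plate: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(readings[plate_columns], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
write_fixture <- write_plate
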