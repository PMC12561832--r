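# Noiseless effect table from a truth curve over a dilution series
noiseless_table <- function(truth, c_high, c_low, n_points = 12) {
  s <- concentration_series(c_high, c_low, n_points)
  tibble::tibble(
    treatment_id = "t",
    ray_id = "single",
    conc_A_ugL = s$conc_ugL,
    conc_B_ugL = 0,
    conc_total_ugL = s$conc_ugL,
    n_reps = 1L,
    effects = as.list(crc_effect(truth, s$conc_ugL)),
    effect_mean = crc_effect(truth, s$conc_ugL),
    effect_se = NA_real_
  )
}

# Independent brute-force evaluation of the printed fit statistics:
# adjusted R2 and RMSE computed term by term with explicit loops.
gof_oracle <- function(y, yhat, m) {
  n <- length(y)
  sse <- 0
  for (i in seq_len(n)) sse <- sse + (y[i] - yhat[i])^2
  ybar <- sum(y) / n
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (y[i] - ybar)^2
  list(r2_adj = 1 - ((n - 1) * sse) / ((n - m) * sst),
       rmse = sqrt(sse / n))
}

# Minimal valid plate tibble: one treatment series plus controls
toy_plate <- function(control_od = c(0.5, 0.5, 0.5),
                      treatment_od = c(0.25, 0.30, 0.20),
                      conc = 100) {
  tibble::tibble(
    treatment_id = c(rep("t", length(treatment_od)),
                     rep("control", length(control_od))),
    ray_id = c(rep("single", length(treatment_od)),
               rep("control", length(control_od))),
    conc_A_ugL = c(rep(conc, length(treatment_od)), rep(0, length(control_od))),
    conc_B_ugL = 0,
    replicate = c(seq_along(treatment_od), seq_along(control_od)),
    od680 = c(treatment_od, control_od),
    is_control = c(rep(FALSE, length(treatment_od)),
                   rep(TRUE, length(control_od)))
  )
}
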