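#' Pharmacokinetic parameter set
#'
#' Parameters of the two-compartment (subcutaneous skin depot -> blood)
#' model: first-order absorption from the depot at rate `ka`, first-order
#' elimination from the central compartment at rate `kel`. Rates are per
#' day, volumes in litres. `ka == kel` is a removable singularity of the
#' closed form and is perturbed by 1e-9.
#'
#' @param ka Absorption rate constant (/day).
#' @param kel Elimination rate constant (/day).
#' @param v_blood Central (blood) volume, L.
#' @param v_skin Depot (skin) volume, L (bookkeeping only; absorption is
#'   amount-based).
#' @param f_bio Bioavailability fraction in `(0, 1]`.
#' @return An object of class `pk_parameters`.
#' @examples
#' pk_parameters(ka = absorption_constant(tmax = 3), kel = 0.05)
#' @export
pk_parameters <- function(ka, kel, v_blood = 5, v_skin = 3, f_bio = 1) {
  stopifnot(ka > 0, kel > 0, v_blood > 0, v_skin > 0,
            f_bio > 0, f_bio <= 1)
  if (ka == kel) ka <- ka + 1e-9
  structure(list(ka = ka, kel = kel, v_blood = v_blood,
                 v_skin = v_skin, f_bio = f_bio),
            class = "pk_parameters")
}

#' Absorption rate constant from Tmax
#'
#' First-order absorption constant `ka = ln 2 / T_1/2a`, with the
#' absorption half-life approximated as one third of the time to peak
#' concentration: `ka = ln 2 / (tmax / 3)`.
#'
#' @param tmax Time to peak concentration, days (> 0).
#' @return `ka` in /day.
#' @export
absorption_constant <- function(tmax) {
  if (!is.numeric(tmax) || any(tmax <= 0)) {
    stop("absorption_constant: tmax must be > 0")
  }
  log(2) / (tmax / 3)
}

#' Dosing regimen
#'
#' An ordered table of dose events. Routes: `sc` (into the skin depot,
#' scaled by bioavailability), `iv` (bolus into blood) and `oral`
#' (first-order absorption, same depot machinery, used for the oral
#' reference drug with liver-clearance labeling).
#'
#' @param times Days from first dose (>= 0).
#' @param amounts mg (>= 0).
#' @param routes Character vector in `c("sc", "iv", "oral")`.
#' @param label Regimen label.
#' @return An object of class `regimen` (data.frame `time_day, amount_mg,
#'   route` plus label attribute).
#' @export
regimen <- function(times, amounts, routes = "sc", label = "regimen") {
  stopifnot(all(times >= 0), all(amounts >= 0),
            all(routes %in% c("sc", "iv", "oral")))
  df <- data.frame(time_day = times, amount_mg = amounts,
                   route = rep_len(routes, length(times)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time_day), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, class = c("regimen", "data.frame"))
}

#' Approved certolizumab pegol regimens
#'
#' Both arms receive a 400 mg subcutaneous loading dose at weeks 0, 2 and
#' 4, followed by the maintenance dose (200 or 400 mg) every two weeks
#' through week 16: nine dose events at days 0, 14, ..., 112.
#'
#' @param maintenance_mg Maintenance dose, 200 or 400 (other values are
#'   rejected unless `allow_any = TRUE`).
#' @param allow_any Allow non-approved maintenance doses.
#' @return A [regimen()] labelled `czp200` / `czp400`.
#' @examples
#' czp_regimen(200)
#' @export
czp_regimen <- function(maintenance_mg, allow_any = FALSE) {
  if (!allow_any && !maintenance_mg %in% c(200, 400)) {
    stop("czp_regimen: approved maintenance doses are 200 or 400 mg ",
         "(use allow_any = TRUE to override)")
  }
  regimen(times = seq(0, 112, by = 14),
          amounts = c(rep(400, 3), rep(maintenance_mg, 6)),
          routes = "sc",
          label = paste0("czp", maintenance_mg))
}

# dose input per event: list(depot = mg added to depot, central = mg/L added)
dose_inputs <- function(event_amount, route, params) {
  if (route == "iv") {
    list(depot = 0, central = event_amount / params$v_blood)
  } else {
    list(depot = params$f_bio * event_amount, central = 0)
  }
}

#' Simulate a concentration-time profile
#'
#' Integrates the linear two-compartment system
#' `dA_skin/dt = -ka * A_skin`, `dC/dt = ka * A_skin / v_blood - kel * C`,
#' with dose events adding mass to the depot (sc/oral, scaled by `f_bio`)
#' or directly to blood (iv). Two equivalent paths are available: a
#' fixed-step fourth-order Runge-Kutta integrator (`method = "rk4"`,
#' sub-stepped so that `max(ka, kel) * h <= 0.01`) and the exact
#' closed-form Bateman superposition (`method = "closed"`). The system is
#' linear, so superposition is exact and the closed form serves as an
#' independent oracle for the integrator.
#'
#' @param params A [pk_parameters()].
#' @param reg A [regimen()]; every dose time must coincide with a grid
#'   point (within 1e-9), otherwise the offending event is named.
#' @param grid Strictly increasing time grid in days (default 0 to 16
#'   weeks, step 0.1 d).
#' @param method `"rk4"` or `"closed"`.
#' @param patient_id,label Identifiers carried in the output.
#' @return A `concentration_profile`: data.frame `time_day,
#'   conc_mg_per_L` with attributes `params`, `patient_id`, `regimen`.
#' @export
simulate_pk <- function(params, reg, grid = seq(0, 112 + 14, by = 0.1),
                        method = c("rk4", "closed"),
                        patient_id = "patient", label = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(params, "pk_parameters"), all(diff(grid) > 0))
  label <- label %||% attr(reg, "label") %||% "regimen"
  events <- as.data.frame(reg)
  if (nrow(events) > 0) {
    idx <- vapply(events$time_day, function(td) {
      j <- which(abs(grid - td) < 1e-9)
      if (length(j) == 0) {
        stop("simulate_pk: dose event at day ", td,
             " does not fall on the time grid")
      }
      j[1]
    }, integer(1))
    events$grid_index <- idx
  }
  conc <- if (method == "closed") {
    closed_form_conc(params, events, grid)
  } else {
    rk4_conc(params, events, grid)
  }
  prof <- data.frame(time_day = grid, conc_mg_per_L = pmax(conc, 0))
  structure(prof, params = params, patient_id = patient_id,
            regimen = label, class = c("concentration_profile", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

closed_form_conc <- function(params, events, grid) {
  conc <- numeric(length(grid))
  if (nrow(events) == 0) return(conc)
  ka <- params$ka; kel <- params$kel
  if (ka == kel) ka <- ka + 1e-9
  for (i in seq_len(nrow(events))) {
    td <- events$time_day[i]
    inp <- dose_inputs(events$amount_mg[i], events$route[i], params)
    dt <- grid - td
    on <- dt >= 0
    if (inp$depot > 0) {
      conc[on] <- conc[on] + inp$depot * ka /
        (params$v_blood * (ka - kel)) * (exp(-kel * dt[on]) - exp(-ka * dt[on]))
    }
    if (inp$central > 0) {
      conc[on] <- conc[on] + inp$central * exp(-kel * dt[on])
    }
  }
  conc
}

rk4_conc <- function(params, events, grid) {
  ka <- params$ka; kel <- params$kel; V <- params$v_blood
  deriv <- function(s) c(-ka * s[1], ka * s[1] / V - kel * s[2])
  state <- c(A = 0, C = 0)
  conc <- numeric(length(grid))
  ev_at <- split(seq_len(nrow(events)), events$grid_index)
  apply_doses <- function(state, gi) {
    for (i in ev_at[[as.character(gi)]]) {
      inp <- dose_inputs(events$amount_mg[i], events$route[i], params)
      state[1] <- state[1] + inp$depot
      state[2] <- state[2] + inp$central
    }
    state
  }
  if (nrow(events) > 0 && !is.null(ev_at[["1"]])) state <- apply_doses(state, 1L)
  conc[1] <- state[2]
  for (g in seq_len(length(grid) - 1)) {
    h_tot <- grid[g + 1] - grid[g]
    n_sub <- max(1L, ceiling(h_tot * max(ka, kel) / 0.01))
    h <- h_tot / n_sub
    for (s in seq_len(n_sub)) {
      k1 <- deriv(state)
      k2 <- deriv(state + h / 2 * k1)
      k3 <- deriv(state + h / 2 * k2)
      k4 <- deriv(state + h * k3)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (nrow(events) > 0 && !is.null(ev_at[[as.character(g + 1)]])) {
      state <- apply_doses(state, g + 1L)
    }
    conc[g + 1] <- state[2]
  }
  conc
}

#' Fit the elimination (and optionally absorption) constant
#'
#' Least-squares fit of the two-compartment model to observed
#' concentration-time points, minimizing the sum of squared residuals over
#' `kel` (1-D golden-section search) or over `(ka, kel)` jointly
#' (Nelder-Mead on the log scale). Reports residuals and the coefficient
#' of determination against the observed points.
#'
#' @param points data.frame `time_day, conc_mg_per_L` (>= 3 points,
#'   positive times, at least two distinct times).
#' @param params A [pk_parameters()] providing the fixed parameters and
#'   starting values.
#' @param reg The [regimen()] that produced the points.
#' @param free Character: `"kel"` or `c("ka", "kel")`.
#' @param interval Search interval for `kel` (/day).
#' @return List of class `pk_fit`: `ka`, `kel`, `residuals`, `r_squared`,
#'   `fitted`.
#' @export
fit_clearance <- function(points, params, reg, free = "kel",
                          interval = c(1e-4, 2)) {
  stopifnot(nrow(points) >= 3, all(points$time_day >= 0))
  if (length(unique(points$time_day)) < 2) {
    stop("fit_clearance: all points share one time; kel is not identifiable")
  }
  obs <- points$conc_mg_per_L
  predict_at <- function(ka, kel) {
    p <- pk_parameters(ka, kel, params$v_blood, params$v_skin, params$f_bio)
    grid <- sort(unique(c(as.data.frame(reg)$time_day, points$time_day)))
    prof <- simulate_pk(p, reg, grid = grid, method = "closed")
    prof$conc_mg_per_L[match(points$time_day, prof$time_day)]
  }
  if (identical(free, "kel")) {
    sse <- function(kel) sum((predict_at(params$ka, kel) - obs)^2)
    opt <- stats::optimize(sse, interval = interval, tol = 1e-10)
    ka_hat <- params$ka; kel_hat <- opt$minimum
  } else {
    sse <- function(par) {
      sum((predict_at(exp(par[1]), exp(par[2])) - obs)^2)
    }
    opt <- stats::optim(log(c(params$ka, params$kel)), sse,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    ka_hat <- exp(opt$par[1]); kel_hat <- exp(opt$par[2])
  }
  fitted <- predict_at(ka_hat, kel_hat)
  res <- obs - fitted
  r2 <- 1 - sum(res^2) / sum((obs - mean(obs))^2)
  structure(list(ka = ka_hat, kel = kel_hat, residuals = res,
                 fitted = fitted, r_squared = r2),
            class = "pk_fit")
}

#' Individualize pharmacokinetic parameters
#'
#' Scales the reference volumes to a patient's covariates: the central
#' volume follows a sex-specific allometric blood-volume formula
#' (male `0.3669 h^3 + 0.03219 w + 0.6041`, female
#' `0.3561 h^3 + 0.03308 w + 0.1833`; h in m, w in kg), multiplied by a
#' configurable distribution-volume adjustment factor; the depot volume
#' scales with body surface area (Du Bois). Rate constants and
#' bioavailability are unchanged by default.
#'
#' @param patient One row of a `virtual_population` (fields `sex`,
#'   `height_cm`, `weight_kg`).
#' @param reference A [pk_parameters()] for the reference patient.
#' @param v_adjust Distribution-volume adjustment factor applied to the
#'   allometric blood volume (default 1).
#' @param reference_patient List with `height_cm`, `weight_kg`, `sex` for
#'   the reference subject (default 170 cm, 75 kg, male).
#' @return A [pk_parameters()] for the patient.
#' @export
individualize <- function(patient, reference,
                          v_adjust = 1,
                          reference_patient = list(height_cm = 170,
                                                   weight_kg = 75,
                                                   sex = "male")) {
  stopifnot(patient$height_cm > 0, patient$weight_kg > 0)
  blood_vol <- function(sex, h_cm, w_kg) {
    h <- h_cm / 100
    if (sex == "female") 0.3561 * h^3 + 0.03308 * w_kg + 0.1833
    else 0.3669 * h^3 + 0.03219 * w_kg + 0.6041
  }
  bsa <- function(h_cm, w_kg) 0.007184 * w_kg^0.425 * h_cm^0.725
  ref_bv <- blood_vol(reference_patient$sex, reference_patient$height_cm,
                      reference_patient$weight_kg)
  ref_bsa <- bsa(reference_patient$height_cm, reference_patient$weight_kg)
  pat_bv <- blood_vol(patient$sex, patient$height_cm, patient$weight_kg)
  pat_bsa <- bsa(patient$height_cm, patient$weight_kg)
  pk_parameters(ka = reference$ka, kel = reference$kel,
                v_blood = reference$v_blood * v_adjust * pat_bv / ref_bv,
                v_skin = reference$v_skin * pat_bsa / ref_bsa,
                f_bio = reference$f_bio)
}

#' Extract pharmacokinetic metrics from a profile
#'
#' Peak concentration and its time, trapezoidal AUC, elimination
#' half-life (from `ln 2 / kel` when the profile carries parameters,
#' otherwise from the terminal log-linear slope), and the steady-state
#' trough (concentration immediately before the last dose).
#'
#' @param profile A `concentration_profile`.
#' @param reg Optional [regimen()] for trough localization.
#' @return List of class `pk_metrics`: `cmax`, `tmax`, `auc`,
#'   `half_life`, `trough_ss`. `half_life` is `NA` when no decreasing
#'   terminal phase exists.
#' @export
pk_metrics <- function(profile, reg = NULL) {
  stopifnot(nrow(profile) > 0)
  conc <- profile$conc_mg_per_L
  tt <- profile$time_day
  imax <- which.max(conc)
  cmax <- conc[imax]; tmax <- tt[imax]
  auc <- trapz(tt, conc)
  params <- attr(profile, "params")
  if (!is.null(params)) {
    half_life <- log(2) / params$kel
  } else {
    tail_idx <- which(tt > tmax & conc > 0)
    if (length(tail_idx) >= 3 && conc[tail_idx[length(tail_idx)]] <
        conc[tail_idx[1]]) {
      fit <- stats::lm(log(conc[tail_idx]) ~ tt[tail_idx])
      slope <- unname(stats::coef(fit)[2])
      half_life <- if (slope < 0) -log(2) / slope else NA_real_
    } else {
      half_life <- NA_real_
    }
  }
  trough_ss <- 0
  if (!is.null(reg) && nrow(reg) > 0) {
    last_dose <- max(as.data.frame(reg)$time_day)
    before <- which(tt < last_dose - 1e-9)
    if (length(before) > 0) trough_ss <- conc[max(before)]
  } else if (cmax == 0) {
    trough_ss <- 0
  }
  structure(list(cmax = cmax, tmax = tmax, auc = auc,
                 half_life = half_life, trough_ss = trough_ss),
            class = "pk_metrics")
}

#' Mass balance of a simulated profile
#'
#' For a subcutaneous regimen, bioavailable dosed mass must equal depot
#' remainder plus central amount plus the eliminated integral
#' `kel * v_blood * AUC(0, t_end)`.
#'
#' @param params A [pk_parameters()].
#' @param reg A [regimen()].
#' @param grid Time grid.
#' @return List with `input`, `accounted`, `relative_error`.
#' @export
mass_balance <- function(params, reg, grid = seq(0, 126, by = 0.1)) {
  prof <- simulate_pk(params, reg, grid = grid, method = "closed")
  events <- as.data.frame(reg)
  t_end <- max(grid)
  input <- 0; depot <- 0
  for (i in seq_len(nrow(events))) {
    inp <- dose_inputs(events$amount_mg[i], events$route[i], params)
    dt <- t_end - events$time_day[i]
    if (dt < 0) next
    input <- input + inp$depot + inp$central * params$v_blood
    depot <- depot + inp$depot * exp(-params$ka * dt)
  }
  # eliminated mass on a fine grid for an accurate integral
  fine <- seq(0, t_end, by = min(0.01, diff(range(grid)) / 1000))
  fine <- sort(unique(c(fine, events$time_day)))
  pf <- simulate_pk(params, reg, grid = fine, method = "closed")
  eliminated <- params$kel * params$v_blood * trapz(pf$time_day, pf$conc_mg_per_L)
  central <- prof$conc_mg_per_L[nrow(prof)] * params$v_blood
  accounted <- depot + central + eliminated
  list(input = input, accounted = accounted,
       relative_error = if (input > 0) abs(accounted - input) / input else 0)
}
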