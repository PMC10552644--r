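test_that("absorption constant follows the Tmax/3 half-life rule", {
  expect_equal(absorption_constant(3), log(2), tolerance = 1e-12)
  expect_equal(absorption_constant(6), 3 * log(2) / 6, tolerance = 1e-12)
  # strictly decreasing in tmax
  tm <- c(1, 2, 5, 10, 20)
  expect_true(all(diff(absorption_constant(tm)) < 0))
  expect_error(absorption_constant(0), "tmax")
  expect_error(absorption_constant(-1), "tmax")
})

test_that("approved CZP regimens carry the printed schedule", {
  r200 <- czp_regimen(200)
  expect_equal(r200$time_day, seq(0, 112, by = 14))
  expect_equal(r200$amount_mg, c(400, 400, 400, rep(200, 6)))
  expect_equal(sum(r200$amount_mg), 2400)
  r400 <- czp_regimen(400)
  expect_equal(r400$amount_mg, rep(400, 9))
  expect_error(czp_regimen(300), "approved")
  expect_s3_class(czp_regimen(300, allow_any = TRUE), "regimen")
})

test_that("single-dose profile matches the Bateman closed form", {
  p <- pk_parameters(ka = 0.35, kel = 0.05, v_blood = 5, f_bio = 1)
  grid <- seq(0, 60, by = 0.1)
  prof <- simulate_pk(p, regimen(0, 200), grid = grid, method = "rk4")
  bateman <- 200 * 0.35 / (5 * (0.35 - 0.05)) *
    (exp(-0.05 * grid) - exp(-0.35 * grid))
  expect_equal(prof$conc_mg_per_L, bateman, tolerance = 1e-6)
})

test_that("RK4 integrator agrees with closed-form superposition on a
           multi-dose regimen", {
  p <- pk_parameters(ka = 0.42, kel = 0.05, v_blood = 5)
  reg <- czp_regimen(200)
  grid <- seq(0, 126, by = 0.1)
  a <- simulate_pk(p, reg, grid = grid, method = "rk4")$conc_mg_per_L
  b <- simulate_pk(p, reg, grid = grid, method = "closed")$conc_mg_per_L
  expect_lt(max(abs(a - b)) / max(b), 1e-6)
})

test_that("the PK system is linear and empty regimens give zero", {
  p <- pk_parameters(ka = 0.3, kel = 0.07, v_blood = 4)
  grid <- seq(0, 40, by = 0.2)
  empty <- simulate_pk(p, regimen(numeric(0), numeric(0)), grid = grid)
  expect_true(all(empty$conc_mg_per_L == 0))
  one <- simulate_pk(p, regimen(c(0, 14), c(100, 50)), grid = grid,
                     method = "closed")
  two <- simulate_pk(p, regimen(c(0, 14), c(200, 100)), grid = grid,
                     method = "closed")
  expect_equal(two$conc_mg_per_L, 2 * one$conc_mg_per_L, tolerance = 1e-12)
  # superposition of two regimens equals the sum of their profiles
  ra <- simulate_pk(p, regimen(0, 100), grid = grid, method = "closed")
  rb <- simulate_pk(p, regimen(14, 50), grid = grid, method = "closed")
  expect_equal(one$conc_mg_per_L,
               ra$conc_mg_per_L + rb$conc_mg_per_L, tolerance = 1e-12)
})

test_that("dose events off the grid are rejected by name", {
  p <- pk_parameters(0.3, 0.05)
  expect_error(simulate_pk(p, regimen(3.05, 100), grid = seq(0, 10, 0.1)),
               "3.05")
})

test_that("mass balance closes within 0.1%", {
  p <- pk_parameters(ka = 0.42, kel = log(2) / 14, v_blood = 5,
                     f_bio = 0.8)
  mb <- mass_balance(p, czp_regimen(200))
  expect_lt(mb$relative_error, 1e-3)
})

test_that("iv bolus route bypasses the depot", {
  p <- pk_parameters(ka = 0.3, kel = 0.1, v_blood = 5)
  grid <- seq(0, 30, by = 0.1)
  prof <- simulate_pk(p, regimen(0, 100, "iv"), grid = grid,
                      method = "closed")
  expect_equal(prof$conc_mg_per_L, 100 / 5 * exp(-0.1 * grid),
               tolerance = 1e-9)
  rk <- simulate_pk(p, regimen(0, 100, "iv"), grid = grid)
  expect_equal(rk$conc_mg_per_L, prof$conc_mg_per_L, tolerance = 1e-6)
})

test_that("kel fitting recovers truth and matches a grid-search oracle", {
  p_true <- pk_parameters(ka = 0.35, kel = 0.08, v_blood = 5)
  reg <- regimen(0, 200)
  times <- c(1, 2, 4, 7, 10, 14, 21, 28)
  prof <- simulate_pk(p_true, reg, grid = c(0, times), method = "closed")
  obs <- prof$conc_mg_per_L[match(times, prof$time_day)]
  points <- data.frame(time_day = times, conc_mg_per_L = obs)
  p0 <- pk_parameters(ka = 0.35, kel = 0.05, v_blood = 5)
  fit <- fit_clearance(points, p0, reg)
  expect_equal(fit$kel, 0.08, tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.999999)
  # brute-force grid oracle
  sse <- vapply(seq(1e-3, 1, by = 1e-4), function(k) {
    pk <- pk_parameters(0.35, k, 5)
    pr <- simulate_pk(pk, reg, grid = c(0, times), method = "closed")
    sum((pr$conc_mg_per_L[match(times, pr$time_day)] - obs)^2)
  }, numeric(1))
  kel_grid <- seq(1e-3, 1, by = 1e-4)[which.min(sse)]
  expect_equal(fit$kel, kel_grid, tolerance = 1e-4)
})

test_that("joint ka/kel fit recovers noise-free truth within 0.1%", {
  p_true <- pk_parameters(ka = 0.42, kel = 0.0495, v_blood = 5)
  reg <- czp_regimen(200)
  times <- c(1, 3, 5, 8, 14, 20, 28, 42, 60, 84, 100, 112, 120)
  obs <- simulate_pk(p_true, reg, grid = sort(unique(c(times, reg$time_day))),
                     method = "closed")
  points <- data.frame(time_day = times,
                       conc_mg_per_L = obs$conc_mg_per_L[
                         match(times, obs$time_day)])
  p0 <- pk_parameters(ka = 0.3, kel = 0.08, v_blood = 5)
  fit <- fit_clearance(points, p0, reg, free = c("ka", "kel"))
  expect_lt(abs(fit$ka - 0.42) / 0.42, 1e-3)
  expect_lt(abs(fit$kel - 0.0495) / 0.0495, 1e-3)
})

test_that("fit to 5%-noise synthetic points keeps R^2 at least 0.95", {
  p_true <- pk_parameters(ka = 0.42, kel = 0.0495, v_blood = 5)
  reg <- regimen(0, 400)
  times <- seq(1, 28, by = 1)
  prof <- simulate_pk(p_true, reg, grid = c(0, times), method = "closed")
  clean <- prof$conc_mg_per_L[match(times, prof$time_day)]
  set.seed(42)
  noisy <- clean * (1 + rnorm(length(clean), 0, 0.05))
  fit <- fit_clearance(data.frame(time_day = times, conc_mg_per_L = noisy),
                       pk_parameters(0.42, 0.03, 5), reg)
  expect_gte(fit$r_squared, 0.95)
})

test_that("non-identifiable fit input fails with a diagnostic", {
  pts <- data.frame(time_day = c(5, 5, 5), conc_mg_per_L = c(1, 2, 3))
  expect_error(fit_clearance(pts, pk_parameters(0.3, 0.05), regimen(0, 100)),
               "identifiable")
})

test_that("PK metrics match closed-form single-dose theory", {
  p <- pk_parameters(ka = 0.35, kel = 0.05, v_blood = 5, f_bio = 1)
  grid <- seq(0, 400, by = 0.05)
  prof <- simulate_pk(p, regimen(0, 200), grid = grid, method = "closed")
  m <- pk_metrics(prof)
  expect_equal(m$tmax, log(0.35 / 0.05) / (0.35 - 0.05), tolerance = 0.05)
  expect_equal(m$auc, 200 / (5 * 0.05), tolerance = 0.01 * 800)
  expect_equal(m$half_life, log(2) / 0.05, tolerance = 1e-9)
  zero <- simulate_pk(p, regimen(numeric(0), numeric(0)),
                      grid = seq(0, 10, 1))
  mz <- pk_metrics(zero)
  expect_equal(mz$cmax, 0)
  expect_equal(mz$auc, 0)
})

test_that("terminal-slope half-life matches ln2/kel without parameters", {
  p <- pk_parameters(ka = 0.6, kel = 0.06, v_blood = 5)
  grid <- seq(0, 200, by = 0.5)
  prof <- simulate_pk(p, regimen(0, 100), grid = grid, method = "closed")
  attr(prof, "params") <- NULL
  m <- pk_metrics(prof)
  expect_equal(m$half_life, log(2) / 0.06, tolerance = 0.02 * log(2) / 0.06)
})

test_that("Q2W troughs stabilize after five half-lives of dosing", {
  p <- pk_parameters(ka = 0.42, kel = log(2) / 14, v_blood = 5)
  reg <- regimen(seq(0, 14 * 11, by = 14), 200)
  grid <- seq(0, 14 * 12, by = 0.1)
  prof <- simulate_pk(p, reg, grid = grid, method = "closed")
  trough_at <- function(n) {  # concentration just before dose n (1-based)
    prof$conc_mg_per_L[which.max(prof$time_day >= 14 * (n - 1)) - 1]
  }
  n_ss <- ceiling(5 * 14 / 14) + 1
  t1 <- trough_at(n_ss + 1); t2 <- trough_at(n_ss + 2)
  expect_lt(abs(t2 - t1) / t1, 0.01)
})

test_that("individualization scales volumes with covariates", {
  ref <- pk_parameters(ka = 0.42, kel = 0.05, v_blood = 5, v_skin = 3)
  ref_pat <- data.frame(id = "R", sex = "male", age = 40, height_cm = 170,
                        weight_kg = 75, bmi = 75 / 1.7^2,
                        comorbidities = "")
  ind <- individualize(ref_pat, ref)
  expect_equal(ind$v_blood, ref$v_blood, tolerance = 1e-12)
  expect_equal(ind$v_skin, ref$v_skin, tolerance = 1e-12)
  # strictly increasing in weight at fixed height and sex
  ws <- seq(50, 130, by = 10)
  vb <- vapply(ws, function(w) {
    pat <- ref_pat; pat$weight_kg <- w
    individualize(pat, ref)$v_blood
  }, numeric(1))
  expect_true(all(diff(vb) > 0))
  # two patients differing only in weight get different Cmax
  light <- ref_pat; light$weight_kg <- 60
  heavy <- ref_pat; heavy$weight_kg <- 120
  grid <- seq(0, 126, by = 0.5)
  cm <- vapply(list(light, heavy), function(pat) {
    pk_metrics(simulate_pk(individualize(pat, ref), czp_regimen(200),
                           grid = grid, method = "closed"))$cmax
  }, numeric(1))
  expect_gt(abs(diff(cm)), 0)
  expect_gt(cm[1], cm[2])  # smaller volume, higher concentration
})
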