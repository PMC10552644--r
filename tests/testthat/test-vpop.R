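test_that("moment-matched truncated normal reproduces target moments", {
  par <- truncnorm_match(45.53, 13.23, 18, 90)
  set.seed(1)
  x <- rtruncnorm(2e5, par$mean, par$sd, 18, 90)
  expect_equal(mean(x), 45.53, tolerance = 0.005)
  expect_equal(sd(x), 13.23, tolerance = 0.005)
  expect_true(all(x >= 18 & x <= 90))
})

test_that("generated population matches the reference marginals", {
  spec <- ref_population_spec(500)
  pop <- generate_population(spec, height_model(), seed = 11)
  expect_equal(nrow(pop), 500)
  # every marginal mean within 3 standard errors of its target
  for (v in list(c("weight_kg", "weight"), c("bmi", "bmi"),
                 c("age", "age"))) {
    se <- spec[[v[2]]][["sd"]] / sqrt(500)
    expect_lt(abs(mean(pop[[v[1]]]) - spec[[v[2]]][["mean"]]), 3 * se)
  }
  # BMI-weight-height identity for every patient
  expect_equal(pop$weight_kg, pop$bmi * (pop$height_cm / 100)^2,
               tolerance = 1e-6)
  expect_true(all(pop$age > 0 & pop$height_cm > 0 & pop$weight_kg > 0))
})

test_that("population generation is deterministic under a fixed seed", {
  spec <- ref_population_spec(80)
  p1 <- generate_population(spec, height_model(), seed = 5)
  p2 <- generate_population(spec, height_model(), seed = 5)
  expect_identical(p1, p2)
  p3 <- generate_population(spec, height_model(), seed = 6)
  expect_false(identical(p1$weight_kg, p3$weight_kg))
})

test_that("degenerate marginals force weight deterministically", {
  spec <- population_spec(25, female_fraction = 0.5,
                          age = c(45, 10), weight = c(30 * 1.7^2, 0),
                          bmi = c(30, 0))
  hm <- height_model(male = c(170, 0), female = c(170, 0))
  pop <- generate_population(spec, hm, seed = 3)
  expect_equal(pop$weight_kg, rep(30 * 1.7^2, 25), tolerance = 1e-12)
})

test_that("unsatisfiable weight marginal fails with a named marginal", {
  spec <- population_spec(200, female_fraction = 0.5, age = c(45, 13),
                          weight = c(40, 5), bmi = c(30.48, 7.07))
  expect_error(generate_population(spec, height_model(), seed = 1,
                                   max_iter = 50),
               "weight marginal")
})

test_that("generated BMI agrees with direct truncated-normal draws (KS)", {
  spec <- ref_population_spec(500)
  par <- truncnorm_match(spec$bmi[["mean"]], spec$bmi[["sd"]], 15, 60)
  pass <- vapply(1:20, function(s) {
    pop <- generate_population(spec, height_model(), seed = s)
    set.seed(stage_seed(s, "ks_oracle"))
    oracle <- rtruncnorm(500, par$mean, par$sd, 15, 60)
    suppressWarnings(stats::ks.test(pop$bmi, oracle)$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 18)
})

test_that("comorbidity tagging respects frequency and eligibility", {
  spec <- ref_population_spec(10000)
  # wide weight tolerance: this test targets tag frequencies, and the
  # 0.5-SE acceptance window is impractically narrow at n = 10,000
  pop <- generate_population(spec, height_model(), seed = 21, tol_se = 5)
  specs <- list(comorbidity_spec("none_tag", 0),
                comorbidity_spec("all_tag", 1),
                comorbidity_spec("diabetes", 0.0438),
                comorbidity_spec("obesity", NA, "bmi_gt_30"))
  tagged <- assign_comorbidities(pop, specs, seed = 2)
  expect_false(any(has_tag(tagged, "none_tag")))
  expect_true(all(has_tag(tagged, "all_tag")))
  # binomial oracle: 438 +/- 3 * sqrt(n p (1-p))
  n_diab <- sum(has_tag(tagged, "diabetes"))
  expect_lt(abs(n_diab - 438), 3 * sqrt(10000 * 0.0438 * 0.9562))
  # obesity strictly confined to BMI > 30 (exhaustive)
  expect_true(all(tagged$bmi[has_tag(tagged, "obesity")] > 30))
  expect_true(all(has_tag(tagged, "obesity")[tagged$bmi > 30]))
})

test_that("fixed-frequency obesity never tags ineligible patients", {
  spec <- ref_population_spec(400)
  pop <- generate_population(spec, height_model(), seed = 8)
  for (s in 1:5) {
    tagged <- assign_comorbidities(
      pop, list(comorbidity_spec("obesity", 0.2, "bmi_gt_30")), seed = s)
    expect_true(all(tagged$bmi[has_tag(tagged, "obesity")] > 30))
  }
  expect_error(
    assign_comorbidities(pop, list(comorbidity_spec("obesity", 0.99,
                                                    "bmi_gt_30")), 1),
    "eligible fraction")
})

test_that("validate_population behaves as a t-test against the reference", {
  spec <- ref_population_spec(300)
  pop <- generate_population(spec, height_model(), seed = 13)
  # identity: a population against its own summary
  self_spec <- population_spec(300, mean(pop$sex == "female"),
                               age = c(mean(pop$age), sd(pop$age)),
                               weight = c(mean(pop$weight_kg), sd(pop$weight_kg)),
                               bmi = c(mean(pop$bmi), sd(pop$bmi)),
                               reference_n = 300)
  tab <- validate_population(pop, self_spec)
  expect_equal(tab$statistic, rep(0, 3), tolerance = 1e-12)
  expect_equal(tab$p, rep(1, 3), tolerance = 1e-12)
  # power: a +5 SE weight shift is detected
  shifted <- pop
  shifted$weight_kg <- shifted$weight_kg +
    5 * spec$weight[["sd"]] / sqrt(300)
  tab2 <- validate_population(shifted, spec)
  expect_lt(tab2$p[tab2$variable == "weight"], 0.05)
})

test_that("t-tests against the reference are null-behaved across seeds", {
  spec <- ref_population_spec(500)
  ok <- vapply(1:50, function(s) {
    pop <- generate_population(spec, height_model(), seed = 100 + s)
    all(validate_population(pop, spec)$p > 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("population round-trips through CSV", {
  pop <- assign_comorbidities(
    generate_population(ref_population_spec(30), height_model(), 4),
    default_comorbidities(), 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_patients(pop, path)
  back <- read_patients(path)
  expect_equal(back$id, pop$id)
  expect_equal(back$comorbidities, pop$comorbidities)
  expect_equal(back$weight_kg, pop$weight_kg, tolerance = 1e-12)
})
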