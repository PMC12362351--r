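test_that("model-1 parameters are recovered from noise-free data", {
  truth <- quick_params(rho0 = 0.5, gamma = 0.15, delta = 0.25, E0 = 2e8)
  fit <- fit_individual(1, model1_obs(truth),
                        init = quick_params(),  # generic start
                        control = fit_control(restarts = 3))
  for (pn in c("rho0", "gamma", "delta", "E0"))
    expect_lt(abs(fit$flat[[pn]] - flatten_parameters(truth)[[pn]]) /
                flatten_parameters(truth)[[pn]], 0.01)
  expect_lt(fit$objective, 1e-4)
  # accepted objective improvements are monotone by construction
  expect_true(all(diff(fit$obj_trace) <= 0))
})

test_that("frozen parameters are returned untouched, bit for bit", {
  truth <- quick_params(rho0 = 0.5, gamma = 0.15, delta = 0.25, E0 = 2e8)
  init <- quick_params(delta = 0.25)
  fit <- fit_individual(1, model1_obs(truth), init = init,
                        frozen = "delta",
                        control = fit_control(restarts = 2))
  expect_identical(fit$flat[["delta"]], 0.25)
  expect_false("delta" %in% fit$free)
})

test_that("constant counts drive the fit onto the zero-net-growth ridge", {
  obs <- data.frame(time_day = seq(0, 28, 2), observable = "E_blood",
                    value = 1e8)
  fit <- fit_individual(1, obs, init = quick_params(rho0 = 1e-6, E0 = 1e8),
                        control = fit_control(restarts = 2))
  expect_lt(fit$objective, 0.01)
  pred <- simulate_model(1, fit$params, seq(0, 28, 2))$E_b
  expect_lt(max(abs(pred - 1e8) / 1e8), 0.05)
})

test_that("irrelevant and missing observables are handled", {
  obs <- rbind(model1_obs(quick_params()),
               data.frame(time_day = 0, observable = "LDH", value = 210))
  expect_silent(fit <- fit_individual(1, obs,
                                      control = fit_control(restarts = 1)))
  expect_error(fit_individual(3, data.frame(time_day = 0,
                                            observable = "IL7",
                                            value = 1)),
               "no usable observations")
  expect_warning(fit_individual(2, model1_obs(quick_params()),
                                control = fit_control(restarts = 1)),
                 "C_blood")
})

test_that("sequential fit freezes layer-1 parameters exactly", {
  ds <- local_cohort(2, seed = 42, noise = FALSE)
  obs <- patient_observations(ds, "P001")
  ctrl <- fit_control(restarts = 2)
  seq_fit <- fit_sequential(obs, control = ctrl)
  solo <- fit_individual(1, obs, control = ctrl)
  for (pn in c("rho0", "gamma", "delta", "E0"))
    expect_identical(flatten_parameters(seq_fit$params)[[pn]],
                     solo$flat[[pn]])
  expect_identical(unname(seq_fit$provenance[c("rho0", "delta")]),
                   rep("model1", 2))
  expect_length(seq_fit$skipped, 0)
})

test_that("missing lesion data skips the lesion layers", {
  ds <- local_cohort(2, seed = 42, noise = FALSE)
  obs <- patient_observations(ds, "P001")
  obs <- obs[!obs$observable %in% c("spd", "LDH"), ]
  fit <- fit_sequential(obs, control = fit_control(restarts = 1))
  expect_setequal(fit$skipped, c("3", "5"))
  expect_setequal(names(fit$fits), c("1", "2", "4"))
  expect_error(fit_sequential(obs[obs$observable != "E_blood", ]),
               "endogenous")
})

test_that("population fitting recovers a known lognormal location", {
  set.seed(31)
  e0 <- stats::rlnorm(64, log(1000), 0.5)
  cohort <- lapply(e0, function(v) quick_params(E0 = v))
  pop <- fit_population(cohort, parameters = "E0")
  row <- pop$params[pop$params$parameter == "E0", ]
  expect_equal(row$family, "lognormal")
  expect_lt(abs(row$location - log(1000)), 3 * row$se)
  expect_lt(abs(row$scale - 0.5), 0.15)
})

test_that("population fitting flags degenerate parameters", {
  cohort <- list(quick_params(), quick_params())
  expect_warning(pop <- fit_population(cohort, parameters = "rho0"),
                 "degenerate")
  expect_equal(pop$params$scale, 0)
  expect_equal(pop$params$location, log(quick_params()$rho0))
})

test_that("latent correlation is recovered from a correlated cohort", {
  set.seed(17)
  z1 <- stats::rnorm(200)
  z2 <- 0.9 * z1 + sqrt(1 - 0.81) * stats::rnorm(200)
  cohort <- lapply(seq_len(200), function(i)
    quick_params(rho0 = exp(log(0.6) + 0.3 * z1[i]),
                 C0 = exp(log(7e7) + 0.5 * z2[i])))
  pop <- fit_population(cohort, parameters = c("rho0", "C0"),
                        correlation = TRUE)
  expect_lt(abs(pop$correlation["rho0", "C0"] - 0.9), 0.1)
})

test_that("error models are pooled from fit residuals", {
  ds <- local_cohort(6, seed = 3, noise = TRUE)
  ids <- unique(ds$observations$patient_id)[1:3]
  fits <- lapply(ids, function(id)
    fit_individual(1, patient_observations(ds, id),
                   control = fit_control(restarts = 1)))
  pop <- fit_population(fits)
  expect_equal(pop$error_model$E_blood$family, "proportional")
  expect_lt(abs(pop$error_model$E_blood$sd - 0.2), 0.15)
})

test_that("proliferation decomposition splits the two sources", {
  p <- quick_params()
  tr <- simulate_model(5, p, 0:30)
  d <- decompose_proliferation(p, tr)
  expect_equal(d$endogenous[1], p$rho0)
  expect_equal(d$endogenous,
               endogenous_proliferation_rate(p, 0:30))
  expect_equal(d$antigen_blood, rep(0, 31))
  expect_true(all(d$antigen_lesion >= 0))
  # saturation limit: B >> K_half pins the antigen series at rho_a
  psat <- quick_params(K_half = 1e4, kappa_p = c(0, 0, 0, 0),
                       g_tumour = 0)
  dsat <- decompose_proliferation(psat, simulate_model(3, psat, 0:30))
  expect_lt(max(abs(dsat$antigen_lesion - psat$rho_a)) / psat$rho_a, 0.01)
  # no tumour, no antigen drive
  p0 <- quick_params(B0 = 0)
  d0 <- decompose_proliferation(p0, simulate_model(3, p0, 0:10))
  expect_equal(d0$antigen_lesion, rep(0, 11))
  expect_error(decompose_proliferation(p, simulate_model(1, p, 0:5)),
               "model 3 or 5")
})

test_that("responder ranking is tiered, stable, and halved", {
  out <- data.frame(patient_id = c("a", "b"), month1 = c(1, 1),
                    month3 = c(2, 2), month6 = c(3, 1))
  r <- rank_responders(out)
  expect_equal(r$patient_id, c("b", "a"))
  expect_equal(r$group, c("good", "poor"))
  ties <- data.frame(patient_id = letters[1:4], month1 = 1, month3 = 1,
                     month6 = 1)
  expect_equal(rank_responders(ties)$patient_id, letters[1:4])
  m1 <- data.frame(patient_id = c("w", "x", "y", "z"),
                   month1 = c(3, 0, 2, 1), month3 = 0, month6 = 0)
  expect_equal(rank_responders(m1)$patient_id, c("x", "z", "y", "w"))
  odd <- data.frame(patient_id = letters[1:3], month1 = 1:3, month3 = 1,
                    month6 = 1)
  expect_warning(ro <- rank_responders(odd), "odd")
  expect_equal(sum(ro$group == "poor"), 2)
})

test_that("covariate correlation is computed per patient", {
  rate <- data.frame(patient_id = "p1", time_day = c(0, 5, 10),
                     value = c(3, 1, 2))
  self <- correlate_covariate(rate, transform(rate, value = value))
  expect_equal(self$per_patient$rho, 1)
  neg <- correlate_covariate(rate, transform(rate, value = -value))
  expect_equal(neg$per_patient$rho, -1)
  scaled <- correlate_covariate(rate, transform(rate, value = value * 10))
  expect_equal(scaled$median_rho, 1)
  # fewer than three shared points: patient skipped
  short <- data.frame(patient_id = "p1", time_day = c(0, 5), value = 1:2)
  expect_true(is.na(correlate_covariate(short, short)$median_rho))
})

test_that("LDH interpolation maps endpoints exactly", {
  ldh <- data.frame(time_day = c(0, 7, 14, 28),
                    value = c(100, 80, 60, 20))
  sp <- interpolate_tumour_burden(10, 2, ldh)
  expect_equal(sp$spd, c(10, 8, 6, 2))
  # LDH linear in time gives SPD linear in time
  lin <- data.frame(time_day = c(0, 10, 20, 30),
                    value = c(300, 250, 200, 150))
  sl <- interpolate_tumour_burden(12, 3, lin)
  expect_equal(sl$spd, seq(12, 3, length.out = 4))
  expect_warning(
    fl <- interpolate_tumour_burden(10, 2, data.frame(
      time_day = c(0, 10, 30), value = c(50, 90, 50))),
    "linear-in-time")
  expect_equal(fl$spd[c(1, 3)], c(10, 2))
  # the volume-scale variant still hits the endpoints exactly
  sv <- interpolate_tumour_burden(10, 2, ldh, scale = "volume")
  expect_equal(sv$spd[c(1, 4)], c(10, 2))
  expect_true(all(diff(sv$spd) < 0))
})
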