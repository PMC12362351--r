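test_that("antigen-independent proliferation decays exponentially", {
  p <- quick_params(rho0 = 0.5, gamma = 0.1)
  expect_equal(endogenous_proliferation_rate(p, 0), 0.5)
  expect_equal(endogenous_proliferation_rate(quick_params(rho0 = 0.5,
                                                          gamma = 0), 100),
               0.5)
  expect_equal(endogenous_proliferation_rate(p, 10), 0.5 * exp(-1))
  r <- endogenous_proliferation_rate(p, seq(0, 30, 0.5))
  expect_true(all(diff(r) < 0))
  expect_error(endogenous_proliferation_rate(p, -1), ">= 0")
})

test_that("model-1 closed form matches high-accuracy integration", {
  p <- quick_params(E0 = 1e9, rho0 = 0.4, gamma = 0.15, delta = 0.1)
  expect_equal(model1_closed_form(p, 0), 1e9)
  p0 <- quick_params(E0 = 5e8, rho0 = 0, delta = 0)
  expect_equal(model1_closed_form(p0, c(0, 10, 30)), rep(5e8, 3))
  # independent oracle: adaptive solve at two tolerance levels
  rhs <- function(t, y, q) list((q$rho0 * exp(-q$gamma * t) - q$delta) * y)
  for (tol in c(1e-10, 1e-12)) {
    num <- deSolve::ode(c(E = p$E0), c(0, 30), rhs, p,
                        rtol = tol, atol = 1e-4)[2, "E"]
    expect_equal(model1_closed_form(p, 30), unname(num),
                 tolerance = 1e-8)
  }
  # gamma = 0 falls back to the plain exponential
  pg <- quick_params(rho0 = 0.2, gamma = 0, delta = 0.05, E0 = 1e8)
  expect_equal(model1_closed_form(pg, 10), 1e8 * exp(0.15 * 10))
})

test_that("simulated model 1 agrees with the analytic oracle", {
  p <- quick_params()
  tr <- simulate_model(1, p, 0:30)
  exact <- model1_closed_form(p, 0:30)
  expect_lt(max(abs(tr$E_b - exact) / exact), 1e-6)
  flat <- simulate_model(1, quick_params(rho0 = 0, delta = 0), 0:10)
  expect_equal(flat$E_b, rep(quick_params()$E0, 11), tolerance = 1e-9)
})

test_that("trajectory invariants hold across the hierarchy", {
  p <- quick_params()
  tr5 <- simulate_model(5, p, 0:30)
  tr3 <- simulate_model(3, p, 0:30)
  tr1 <- simulate_model(1, p, 0:30)
  tr4 <- simulate_model(4, p, 0:30)
  # endogenous totals conserved across layers
  expect_lt(max(abs(tr4$E_b - tr1$E_b) / tr1$E_b), 1e-6)
  expect_lt(max(abs(tr5$E_b - tr1$E_b) / tr1$E_b), 1e-6)
  # CAR totals conserved between layers 3 and 5
  expect_lt(max(abs(tr5$C_b - tr3$C_b) / tr3$C_b), 1e-6)
  # constant partition ratio and volume identity
  expect_equal(tr5$C_l, p$phi * tr5$C_b)
  expect_equal(tr5$lesion_volume, tr5$B_l * p$v_cell)
  # phenotype proportions on the simplex at every grid point
  expect_lt(max(abs(rowSums(tr5$C_pheno_prop) - 1)), 1e-8)
  expect_true(all(tr5$C_pheno_prop >= 0 & tr5$C_pheno_prop <= 1))
  # model 2 equals model 3 when the antigen channel is off
  tr2 <- simulate_model(2, p, 0:30)
  tr3b <- simulate_model(3, quick_params(rho_a = 0), 0:30)
  expect_lt(max(abs(tr2$C_b - tr3b$C_b) / tr2$C_b), 1e-6)
})

test_that("no differentiation flux leaves phenotype proportions fixed", {
  p <- quick_params(alpha = c(0, 0, 0), pi_car0 = c(1, 0, 0, 0),
                    pi_endo0 = c(1, 0, 0, 0), kappa_p = c(1e-8, 0, 0, 0))
  tr5 <- simulate_model(5, p, 0:30)
  expect_equal(unname(tr5$C_pheno_prop[, "naive"]), rep(1, 31),
               tolerance = 1e-8)
  tr3 <- simulate_model(3, p, 0:30)
  expect_lt(max(abs(tr5$C_b - tr3$C_b) / tr3$C_b), 1e-6)
})

test_that("without killing the lesion grows exponentially", {
  p <- quick_params(kappa_p = c(0, 0, 0, 0), g_tumour = 0.05)
  tr <- simulate_model(3, p, 0:30)
  expect_equal(tr$B_l, p$B0 * exp(0.05 * (0:30)), tolerance = 1e-6)
})

test_that("stronger killing never grows the day-30 lesion", {
  vols <- sapply(c(0.5, 1, 2, 4) * 1e-8, function(k) {
    tr <- simulate_model(5, quick_params(kappa_p = c(0, 0, 0, k)), 0:30)
    tr$lesion_volume[31]
  })
  expect_true(all(diff(vols) <= 0))
})

test_that("naive CAR proportions forget their initial value", {
  t_grid <- 0:30
  base <- quick_params(pi_car0 = c(0.10, 0.50, 0.30, 0.10))
  high <- quick_params(pi_car0 = c(0.40, 0.20, 0.30, 0.10))
  n1 <- simulate_model(5, base, t_grid)$C_pheno_prop[, "naive"]
  n2 <- simulate_model(5, high, t_grid)$C_pheno_prop[, "naive"]
  expect_lt(abs(n1[31] - n2[31]), abs(n1[1] - n2[1]))
})

test_that("simulate rejects malformed inputs", {
  expect_error(simulate_model(6, quick_params()), "model_id")
  expect_error(simulate_model(1, quick_params(), c(1, 0, 2)), "t_grid")
  expect_error(simulate_model(1, quick_params(), c(1, 2, 3)), "t_grid")
})

test_that("lesion geometry inverts the sphere formula", {
  expect_equal(spd_from_cells(0, 1e-9), list(diameter = 0, spd = 0))
  g <- spd_from_cells(pi / 6 * 1e9, 1e-9, 1)
  expect_equal(g$diameter, 1)
  expect_equal(g$spd, 1)
  g2 <- spd_from_cells(8 * pi / 6 * 1e9, 1e-9, 1)
  expect_equal(g2$diameter, 2)
  expect_equal(g2$spd, 4)
  # splitting over n lesions conserves volume and round-trips
  for (n in c(1L, 3L)) {
    g3 <- spd_from_cells(4e10, 1e-9, n)
    expect_equal(cells_from_spd(g3$spd, 1e-9, n), 4e10)
    expect_equal(n * pi / 6 * g3$diameter^3, 4e10 * 1e-9)
  }
})

test_that("derived outputs: peak, timing, trapezoid AUC, response", {
  fake <- structure(list(t = c(0, 1, 2), model_id = 2,
                         C_b = c(0, 5, 3), n_lesions = 1L),
                    class = "car_trajectory")
  d <- derived_outputs(fake)
  expect_equal(d$cmax, 5)
  expect_equal(d$tmax, 1)
  expect_equal(d$auc, 6.5)
  expect_true(is.na(d$prop_tumour_size_change))

  mono <- structure(list(t = 0:3, model_id = 2, C_b = c(1, 2, 3, 4),
                         n_lesions = 1L), class = "car_trajectory")
  expect_equal(derived_outputs(mono)$tmax, 3)

  flat <- structure(list(t = 0:2, model_id = 3, C_b = c(1, 1, 1),
                         B_l = rep(1e9, 3), lesion_volume = rep(1, 3),
                         lesion_diameter = rep(1.24, 3),
                         spd = rep(1.54, 3), n_lesions = 1L),
                    class = "car_trajectory")
  df <- derived_outputs(flat)
  expect_equal(df$prop_tumour_size_change, 0)
  expect_equal(df$lugano_response, "SD")

  tr <- simulate_model(5, quick_params(), 0:30)
  d5 <- derived_outputs(tr)
  expect_gte(d5$auc, 0)
  expect_true(d5$tmax >= 0 && d5$tmax <= 30)
  expect_gte(d5$prop_tumour_size_change, -1)
  expect_true(d5$lugano_response %in% c("CR", "PR", "SD", "PD"))
})

test_that("trajectory CSV export round-trips the series", {
  tr <- simulate_model(5, quick_params(), 0:10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$t, tr$t)
  expect_equal(back$C_b, unname(tr$C_b))
  expect_equal(back$spd, unname(tr$spd))
  expect_equal(unname(back$C_pheno_prop), unname(tr$C_pheno_prop))
  df <- utils::read.csv(path)
  expect_named(df, c("time_day", "variable", "value", "unit", "model_id"))
})
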