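unit_bounds <- function(k, names = letters[seq_len(k)])
  stats::setNames(lapply(seq_len(k), function(i) c(0, 1)), names)

test_that("eFAST design has N x D x M rows inside the bounds", {
  b <- list(a = c(0, 2), b = c(-1, 1), c = c(10, 20))
  d <- efast_design(b, 65, resamplings = 2, include_dummy = TRUE, seed = 8)
  expect_equal(nrow(d$X), 65 * 4 * 2)
  expect_named(d$X, c("a", "b", "c", "dummy"))
  for (f in names(b)) {
    expect_gte(min(d$X[[f]]), b[[f]][1])
    expect_lte(max(d$X[[f]]), b[[f]][2])
  }
  expect_true(all(d$X$dummy >= 0 & d$X$dummy <= 1))
  expect_error(efast_design(list(a = c(1, 0)), 65), "lower bound")
  expect_error(efast_design(unit_bounds(2), 64),
               "minimum valid N is 65")
})

test_that("eFAST indices recover analytic variance fractions", {
  d <- efast_design(unit_bounds(2, c("a", "b")), 1000, 4, seed = 3)
  add <- efast_indices(d, d$X$a + d$X$b)[[1]]
  si <- stats::setNames(add$SI, add$parameter)
  tsi <- stats::setNames(add$TSI, add$parameter)
  expect_lt(abs(si[["a"]] - 0.5), 0.05)
  expect_lt(abs(si[["b"]] - 0.5), 0.05)
  # the dummy sits below both influential parameters
  expect_lt(si[["dummy"]] + 0.02, min(si[["a"]], si[["b"]]))
  expect_true(all(tsi >= add$SI - 0.02))
  # pure interaction: total indices far exceed first-order ones
  int <- efast_indices(d, (d$X$a - 0.5) * (d$X$b - 0.5))[[1]]
  expect_gt(int$TSI[int$parameter == "a"],
            int$SI[int$parameter == "a"] + 0.3)
  # a null parameter stays at the dummy's level
  one <- efast_indices(d, d$X$a)[[1]]
  expect_lt(one$SI[one$parameter == "b"],
            one$SI[one$parameter == "dummy"] + 0.02)
})

test_that("eFAST failure handling: imputation below 5%, abort above", {
  d <- efast_design(unit_bounds(2, c("a", "b")), 129, 1, seed = 1)
  y <- d$X$a + d$X$b
  y[seq_len(floor(0.04 * length(y)))] <- NA
  res <- efast_indices(d, y)
  expect_equal(unname(attr(res, "n_imputed")), floor(0.04 * length(y)))
  y[seq_len(floor(0.08 * length(y)))] <- NaN
  expect_error(efast_indices(d, y), "5%")
  expect_warning(out <- efast_indices(d, rep(1, nrow(d$X))), "constant")
  expect_true(all(out[[1]]$SI == 0))
})

test_that("random-forest importances isolate the driving parameter", {
  set.seed(12)
  X <- as.data.frame(matrix(stats::runif(500 * 5), 500,
                            dimnames = list(NULL, paste0("x", 1:5))))
  imp <- rf_importance(X, X$x3, n_trees = 100, seed = 2)
  expect_equal(sum(imp), 1)
  expect_true(all(imp >= 0))
  expect_gt(imp[["x3"]], 0.9)
  expect_error(rf_importance(X[1:10, ], X$x1[1:10]), "nrow")
  expect_warning(u <- rf_importance(X, rep(2, 500)), "constant")
  expect_equal(unname(u), rep(0.2, 5))
})

test_that("pure-noise forests spread importance near uniformity", {
  set.seed(5)
  X <- as.data.frame(matrix(stats::runif(2000 * 5), 2000,
                            dimnames = list(NULL, paste0("x", 1:5))))
  imp <- rf_importance(X, stats::rnorm(2000), seed = 3)
  expect_lt(max(imp), 2 / ncol(X))
})

test_that("Spearman sensitivity handles monotone, null and tied cases", {
  set.seed(6)
  X <- data.frame(a = stats::runif(100), b = stats::runif(100))
  expect_equal(unname(spearman_sensitivity(X, exp(3 * X$a))["a"]), 1)
  expect_equal(unname(spearman_sensitivity(data.frame(a = c(3, 1, 2)),
                                           c(9, 1, 4))["a"]), 1)
  X1000 <- data.frame(a = stats::runif(1000), b = stats::runif(1000))
  expect_lt(abs(spearman_sensitivity(X1000, stats::rnorm(1000))[["b"]]),
            0.1)
  expect_equal(unname(spearman_sensitivity(data.frame(a = rep(1, 5),
                                                      b = 1:5), 1:5)),
               c(0, 1))
})

test_that("local sensitivity matches exact linear responses", {
  lin_fn <- function(p) c(lin = 3 * p$rho0, flat = 42)
  sc <- local_sensitivity(list(quick_params(), quick_params(rho0 = 0.9)),
                          output_fn = lin_fn,
                          parameters = c("rho0", "delta"))
  expect_equal(sc["lin", "rho0"], 0.01, tolerance = 1e-10)
  expect_equal(sc["lin", "delta"], 0)
  expect_equal(sc["flat", "rho0"], 0)
})

test_that("local sensitivity agrees with a central finite difference", {
  cmax_fn <- function(p) c(cmax = max(simulate_model(2, p, 0:30)$C_b))
  p <- quick_params()
  sc <- local_sensitivity(list(p), output_fn = cmax_fn,
                          parameters = "delta")
  h <- 1e-4
  up <- cmax_fn(quick_params(delta = p$delta * (1 + h)))
  dn <- cmax_fn(quick_params(delta = p$delta * (1 - h)))
  fd <- abs((up - dn) / (2 * h)) / cmax_fn(p) * 0.01
  expect_lt(abs(sc["cmax", "delta"] - fd) / fd, 0.05)
})

test_that("heatmap normalization subtracts the dummy and rescales rows", {
  r1 <- sensitivity_result("eFAST-SI",
                           matrix(c(0.5, 0.3), 1,
                                  dimnames = list("cmax", c("p1", "p2"))),
                           dummy = c(cmax = 0.1))
  out <- normalize_heatmap(list(r1))
  expect_equal(unname(out["eFAST-SI.cmax", ]), c(1.0, 0.5))
  # row equal to the dummy collapses to zero
  r2 <- sensitivity_result("SRC-vpop",
                           matrix(c(0.2, 0.2), 1,
                                  dimnames = list("tmax", c("p1", "p2"))),
                           dummy = c(tmax = 0.2))
  expect_equal(unname(normalize_heatmap(list(r2))["SRC-vpop.tmax", ]),
               c(0, 0))
  # methods without a dummy are only rescaled
  r3 <- sensitivity_result("local",
                           matrix(c(0.04, 0.02), 1,
                                  dimnames = list("auc", c("p1", "p2"))))
  expect_equal(unname(normalize_heatmap(list(r3))["local.auc", ]),
               c(1, 0.5))
  expect_error(sensitivity_result("x", matrix(1, 1, 1), dummy = c(1, 2)),
               "one entry per output row")
})

test_that("population-derived bounds honour families and validity", {
  pop <- default_truth_population()
  b <- sensitivity_bounds(pop, k = 3)
  expect_false("phi" %in% names(b))  # structural, zero spread
  expect_equal(unname(b$rho0),
               exp(log(quick_params()$rho0) + c(-3, 3) * 0.25))
  expect_true(all(vapply(b, function(x) x[1] < x[2], logical(1))))
  pr <- b$pi_car0_naive
  expect_true(pr[1] > 0 && pr[2] < 1)
})

test_that("design evaluation feeds the estimators end to end", {
  pop <- default_truth_population()
  b <- sensitivity_bounds(pop)[c("rho0", "delta", "C0")]
  d <- efast_design(b, 65, 1, include_dummy = TRUE, seed = 4)
  Y <- evaluate_design(d$X, model_id = 2, t_grid = 0:14)
  expect_equal(dim(Y), c(nrow(d$X), 5))
  expect_true(all(is.finite(Y[, "cmax"])))
  rho <- spearman_sensitivity(d$X, Y[, "cmax"])
  expect_gt(rho[["rho0"]], 0.3)
  expect_lt(rho[["delta"]], 0)
  # search-curve samples are structured, not iid: allow a generous null
  # band (~5 x the iid standard error at n = 260)
  expect_lt(abs(rho[["dummy"]]), 0.3)
})
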