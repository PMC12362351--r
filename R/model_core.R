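#' Antigen-independent T-cell proliferation rate
#'
#' The lymphodepletion-driven proliferation rate shared by endogenous and
#' CAR T-cells decays exponentially from its post-conditioning peak:
#' `rho0 * exp(-gamma * t)`.
#'
#' @param params A [patient_parameters()] object.
#' @param t Time since infusion, days (scalar or vector, all >= 0).
#' @return Proliferation rate(s), 1/day.
#' @examples
#' endogenous_proliferation_rate(patient_parameters(rho0 = 0.5, gamma = 0.1), 10)
#' @export
endogenous_proliferation_rate <- function(params, t) {
  if (any(t < 0)) stop("t must be >= 0")
  params$rho0 * exp(-params$gamma * t)
}

#' Closed-form solution of the blood endogenous T-cell model
#'
#' Analytic solution of `dE/dt = (rho0 exp(-gamma t) - delta) E`:
#' `E0 * exp((rho0/gamma) (1 - exp(-gamma t)) - delta t)` for `gamma > 0`,
#' reducing to simple exponential growth/decay `E0 exp((rho0 - delta) t)`
#' at `gamma = 0`.  Serves as the exact oracle for the numerical solver.
#'
#' @inheritParams endogenous_proliferation_rate
#' @return Endogenous blood T-cell count(s), cells per 5.3 L.
#' @export
model1_closed_form <- function(params, t) {
  if (any(t < 0)) stop("t must be >= 0")
  if (params$gamma == 0)
    return(params$E0 * exp((params$rho0 - params$delta) * t))
  params$E0 * exp(params$rho0 / params$gamma * (1 - exp(-params$gamma * t)) -
                    params$delta * t)
}

# differentiation chain flux for the 4-stage naive->CM->EM->EFF cascade
chain_flux <- function(x, alpha) {
  c(-alpha[1] * x[1],
    alpha[1] * x[1] - alpha[2] * x[2],
    alpha[2] * x[2] - alpha[3] * x[3],
    alpha[3] * x[3])
}

# right-hand sides ------------------------------------------------------

rhs_model1 <- function(t, y, p) {
  list(( p$rho0 * exp(-p$gamma * t) - p$delta) * y[1])
}

rhs_model2 <- function(t, y, p) {
  r <- p$rho0 * exp(-p$gamma * t) - p$delta
  list(c(r * y[1], r * y[2]))
}

# model 3 carries the CAR phenotype-proportion chain internally: the
# lesion killing rate is the phenotype-weighted kappa, which keeps model 3
# CAR totals identical to model 5's (proportions evolve independently of
# totals because proliferation and death are phenotype-uniform)
rhs_model3 <- function(t, y, p) {
  E <- y[1]; CT <- y[2]; B <- max(y[3], 0); pi_c <- y[4:7]
  rho_e <- p$rho0 * exp(-p$gamma * t)
  pf <- p$phi / (1 + p$phi)
  a <- p$rho_a * B / (B + p$K_half) * pf
  Cl <- pf * CT
  kill <- sum(p$kappa_p * pi_c) * Cl
  list(c((rho_e - p$delta) * E,
         (rho_e - p$delta + a) * CT,
         p$g_tumour * B - kill * B,
         chain_flux(pi_c, p$alpha)))
}

rhs_model4 <- function(t, y, p) {
  r <- p$rho0 * exp(-p$gamma * t) - p$delta
  list(r * y + chain_flux(y, p$alpha))
}

rhs_model5 <- function(t, y, p) {
  Ep <- y[1:4]; Cp <- y[5:8]; B <- max(y[9], 0)
  rho_e <- p$rho0 * exp(-p$gamma * t)
  CT <- sum(Cp)
  pi_c <- if (CT > 0) Cp / CT else rep(0.25, 4)
  pf <- p$phi / (1 + p$phi)
  a <- p$rho_a * B / (B + p$K_half) * pf
  Cl <- pf * CT
  kill <- sum(p$kappa_p * pi_c) * Cl
  list(c((rho_e - p$delta) * Ep + chain_flux(Ep, p$alpha),
         (rho_e - p$delta + a) * Cp + chain_flux(Cp, p$alpha),
         p$g_tumour * B - kill * B))
}

#' Simulate one of the five hierarchical models
#'
#' Model layers: (1) blood endogenous T-cells; (2) adds blood CAR T-cells;
#' (3) adds the lesion compartment (CD19+ target cells, CAR partitioning
#' and killing); (4) endogenous phenotypes in blood; (5) the full model —
#' endogenous and CAR phenotypes plus the lesion.  Each layer extends the
#' previous ones without altering them, so endogenous totals agree across
#' all models and CAR totals agree between models 3 and 5.
#'
#' The lesion and blood CAR pools are in fast-exchange quasi-equilibrium:
#' the lesion CAR count is always `phi` times the blood count, so one total
#' CAR state is integrated and partitioned algebraically.
#'
#' @param model_id Integer 1..5.
#' @param params A [patient_parameters()] object.
#' @param t_grid Sorted time grid in days starting at 0 (default daily to 30).
#' @param n_lesions Number of (equal-size, spherical) lesions used to map
#'   lesion cell counts to diameters; default 1.
#' @param rtol,atol Solver tolerances (adaptive stiff-capable `lsoda`).
#' @return A `car_trajectory` object: time grid plus, as available for the
#'   layer, `E_b`, `E_b_pheno`, `C_b`, `C_l`, `C_pheno_prop`, `B_l`,
#'   `lesion_volume`, `lesion_diameter`, `spd`.
#' @examples
#' tr <- simulate_model(5, patient_parameters(), t_grid = 0:30)
#' max(tr$C_b)
#' @export
simulate_model <- function(model_id, params, t_grid = 0:30, n_lesions = 1L,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(model_id %in% 1:5)
  validate_parameters(params)
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] != 0)
    stop("t_grid must be strictly increasing and start at 0")
  p <- params
  CT0 <- p$C0 * (1 + p$phi)   # total (blood + lesion) CAR cells
  init <- switch(model_id,
    `1` = c(E = p$E0),
    `2` = c(E = p$E0, CT = CT0),
    `3` = c(E = p$E0, CT = CT0, B = p$B0, pi = p$pi_car0),
    `4` = c(Ep = p$E0 * p$pi_endo0),
    `5` = c(Ep = p$E0 * p$pi_endo0, Cp = CT0 * p$pi_car0, B = p$B0))
  rhs <- list(rhs_model1, rhs_model2, rhs_model3, rhs_model4,
              rhs_model5)[[model_id]]
  sol <- try(deSolve::ode(y = init, times = t_grid, func = rhs, parms = p,
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(t_grid))
    stop("ODE integration failed for model ", model_id, " with parameters: ",
         paste(sprintf("%s=%.3g", parameter_names(),
                       flatten_parameters(p)), collapse = ", "))
  sol <- as.matrix(sol)
  # tiny solver-noise negatives are clamped; larger ones are a real failure
  states <- sol[, -1, drop = FALSE]
  clamp_tol <- max(1e-12, 100 * atol)
  if (any(states < -clamp_tol))
    stop("negative state beyond tolerance in model ", model_id)
  states[states < 0] <- 0
  sol[, -1] <- states

  tr <- list(t = t_grid, model_id = model_id, params = p,
             n_lesions = as.integer(n_lesions))
  pf <- p$phi / (1 + p$phi)
  if (model_id == 1) {
    tr$E_b <- sol[, "E"]
  } else if (model_id == 2) {
    tr$E_b <- sol[, "E"]; tr$C_b <- sol[, "CT"] / (1 + p$phi)
  } else if (model_id == 3) {
    tr$E_b <- sol[, "E"]
    tr$C_b <- sol[, "CT"] / (1 + p$phi)
    tr$C_l <- p$phi * tr$C_b
    tr$C_pheno_prop <- sol[, paste0("pi", 1:4), drop = FALSE]
    tr$B_l <- sol[, "B"]
  } else if (model_id == 4) {
    Ep <- sol[, paste0("Ep", 1:4), drop = FALSE]
    tr$E_b_pheno <- Ep; tr$E_b <- rowSums(Ep)
  } else {
    Ep <- sol[, paste0("Ep", 1:4), drop = FALSE]
    Cp <- sol[, paste0("Cp", 1:4), drop = FALSE]
    tr$E_b_pheno <- Ep; tr$E_b <- rowSums(Ep)
    CT <- rowSums(Cp)
    tr$C_b <- CT / (1 + p$phi); tr$C_l <- p$phi * tr$C_b
    tr$C_pheno_prop <- sweep(Cp, 1, ifelse(CT > 0, CT, 1), "/")
    tr$B_l <- sol[, "B"]
  }
  if (!is.null(tr$E_b_pheno))
    colnames(tr$E_b_pheno) <- PHENO_NAMES
  if (!is.null(tr$C_pheno_prop))
    colnames(tr$C_pheno_prop) <- PHENO_NAMES
  if (!is.null(tr$B_l)) {
    geom <- spd_from_cells(tr$B_l, p$v_cell, n_lesions)
    tr$lesion_volume <- tr$B_l * p$v_cell
    tr$lesion_diameter <- geom$diameter
    tr$spd <- geom$spd
  }
  class(tr) <- "car_trajectory"
  tr
}

#' @export
print.car_trajectory <- function(x, ...) {
  cat(sprintf("<car_trajectory> model %d, %d time points over [%g, %g] days\n",
              x$model_id, length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' Lesion diameter and sum-of-product-of-diameters from a cell count
#'
#' Total tumour volume `B_l * v_cell` is split evenly across `n_lesions`
#' identical spherical lesions (elimination is assumed even across
#' lesions), giving per-lesion diameter `d = (6 V / (n pi))^(1/3)` and
#' `SPD = n d^2` (equal-diameter lesions).  T-cells do not contribute to
#' lesion volume.
#'
#' @param B_l Lesion CD19+ cell count(s), >= 0.
#' @param v_cell Volume per tumour cell, cm^3.
#' @param n_lesions Number of lesions, >= 1.
#' @return List with `diameter` (cm, per lesion) and `spd` (cm^2, total).
#' @examples
#' spd_from_cells(pi / 6 * 1e9, 1e-9, 1)  # 1 cm sphere -> spd 1 cm^2
#' @export
spd_from_cells <- function(B_l, v_cell, n_lesions = 1L) {
  stopifnot(all(B_l >= 0), n_lesions >= 1)
  V <- B_l * v_cell
  d <- (6 * V / (n_lesions * pi))^(1 / 3)
  list(diameter = d, spd = n_lesions * d^2)
}

#' Inverse of [spd_from_cells()]: lesion cell count from an SPD
#' @param spd Sum of product of diameters, cm^2.
#' @param v_cell Volume per tumour cell, cm^3.
#' @param n_lesions Number of equal-diameter lesions.
#' @return Lesion CD19+ cell count.
#' @export
cells_from_spd <- function(spd, v_cell, n_lesions = 1L) {
  d <- sqrt(spd / n_lesions)
  n_lesions * pi / 6 * d^3 / v_cell
}

#' Scalar outcomes derived from a simulated trajectory
#'
#' Computes the peak blood CAR T-cell count (Cmax), its timing (tmax, the
#' earliest grid time attaining the peak), the trapezoid-rule area under
#' the blood CAR curve (AUC), the relative change in lesion volume from
#' start to end, and the simplified Lugano response class obtained from
#' the trajectory's lesion-diameter history (baseline at the first grid
#' point, nadir the running minimum).
#'
#' @param traj A `car_trajectory` from [simulate_model()].
#' @return List with `cmax`, `tmax`, `auc`, `prop_tumour_size_change`,
#'   `lugano_response` (the latter two `NA` for layers without a lesion).
#' @export
derived_outputs <- function(traj) {
  stopifnot(inherits(traj, "car_trajectory"), length(traj$t) > 0)
  out <- list(cmax = NA_real_, tmax = NA_real_, auc = NA_real_,
              prop_tumour_size_change = NA_real_,
              lugano_response = NA_character_)
  if (!is.null(traj$C_b)) {
    out$cmax <- max(traj$C_b)
    out$tmax <- traj$t[which.max(traj$C_b)]
    out$auc <- trapz(traj$t, traj$C_b)
  }
  if (!is.null(traj$lesion_volume)) {
    V <- traj$lesion_volume
    out$prop_tumour_size_change <-
      if (V[1] > 0) (V[length(V)] - V[1]) / V[1] else NA_real_
    d <- traj$lesion_diameter
    n <- length(d)
    h <- lesion_history(baseline_d = rep(d[1], traj$n_lesions),
                        nadir_d = rep(min(d), traj$n_lesions),
                        current_d = rep(d[n], traj$n_lesions),
                        baseline_spd = traj$spd[1],
                        current_spd = traj$spd[n])
    out$lugano_response <- if (traj$spd[1] > 0) classify_lesions(h)
                           else NA_character_
  }
  out
}

#' Export a trajectory as a tidy long CSV
#'
#' Columns `time_day, variable, value, unit, model_id`; the inverse of
#' [read_trajectory()].
#'
#' @param traj A `car_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  rows <- list()
  add <- function(var, val, unit) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time_day = traj$t, variable = var, value = as.numeric(val),
      unit = unit, model_id = traj$model_id)
  }
  if (!is.null(traj$E_b)) add("E_blood", traj$E_b, "cells_per_5.3L")
  if (!is.null(traj$E_b_pheno))
    for (ph in PHENO_NAMES)
      add(paste0("E_blood_", ph), traj$E_b_pheno[, ph], "cells_per_5.3L")
  if (!is.null(traj$C_b)) add("C_blood", traj$C_b, "cells_per_5.3L")
  if (!is.null(traj$C_l)) add("C_lesion", traj$C_l, "cells")
  if (!is.null(traj$C_pheno_prop))
    for (ph in PHENO_NAMES)
      add(paste0("car_prop_", ph), traj$C_pheno_prop[, ph], "proportion")
  if (!is.null(traj$B_l)) {
    add("B_lesion", traj$B_l, "cells")
    add("lesion_volume", traj$lesion_volume, "cm3")
    add("lesion_diameter", traj$lesion_diameter, "cm")
    add("spd", traj$spd, "cm2")
  }
  df <- do.call(rbind, rows)
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy trajectory CSV written by [write_trajectory()]
#' @param path CSV path.
#' @return A `car_trajectory` (series only; parameters are not stored).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  t_grid <- sort(unique(df$time_day))
  tr <- list(t = t_grid, model_id = df$model_id[1], n_lesions = 1L)
  get <- function(var) {
    sub <- df[df$variable == var, ]
    if (!nrow(sub)) return(NULL)
    sub$value[order(sub$time_day)]
  }
  tr$E_b <- get("E_blood")
  tr$C_b <- get("C_blood"); tr$C_l <- get("C_lesion")
  tr$B_l <- get("B_lesion")
  tr$lesion_volume <- get("lesion_volume")
  tr$lesion_diameter <- get("lesion_diameter")
  tr$spd <- get("spd")
  ep <- lapply(paste0("E_blood_", PHENO_NAMES), get)
  if (!is.null(ep[[1]])) {
    tr$E_b_pheno <- do.call(cbind, ep); colnames(tr$E_b_pheno) <- PHENO_NAMES
  }
  cp <- lapply(paste0("car_prop_", PHENO_NAMES), get)
  if (!is.null(cp[[1]])) {
    tr$C_pheno_prop <- do.call(cbind, cp)
    colnames(tr$C_pheno_prop) <- PHENO_NAMES
  }
  tr[vapply(tr, is.null, logical(1))] <- NULL
  class(tr) <- "car_trajectory"
  tr
}
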