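#' Control settings for individual model fits
#'
#' @param restarts Number of jittered optimizer restarts (bounded local
#'   search; the best optimum is kept).
#' @param seed Seed for the restart jitter.
#' @param weights Optional named vector of per-observable objective
#'   weights (default 1 each).
#' @param maxit Iteration cap per `nlminb` run.
#' @param fit_kappa_em Also free the effector-memory killing rate in the
#'   lesion layer (off by default: EM and terminal-effector proportions
#'   are nearly collinear over one month, making the pair weakly
#'   identifiable).
#' @param use_ldh Use LDH-interpolated SPD series (between the first and
#'   last imaging visits) as lesion observations in sequential fits.
#' @param ridge Weak quadratic penalty (on the transformed scale) pulling
#'   free parameters toward their starting values.  It is orders of
#'   magnitude below the data term for identified parameters and exists
#'   only to break flat likelihood ridges (e.g. `rho0 - delta` when
#'   `gamma` collapses to 0) deterministically.  Set 0 to disable.
#' @return A list of control settings.
#' @export
fit_control <- function(restarts = 5L, seed = 1L, weights = NULL,
                        maxit = 400L, fit_kappa_em = FALSE,
                        use_ldh = TRUE, ridge = 1e-4) {
  list(restarts = restarts, seed = seed, weights = weights, maxit = maxit,
       fit_kappa_em = fit_kappa_em, use_ldh = use_ldh, ridge = ridge)
}

# free-parameter sets per model layer (cumulative); phi, the blood CD19
# constant and the cell volume are structural constants, never fitted
free_params_for_model <- function(model_id, control = fit_control()) {
  l1 <- c("rho0", "gamma", "delta", "E0")
  l2 <- "C0"
  l3 <- c("rho_a", "K_half", "g_tumour", "kappa_eff", "B0",
          if (isTRUE(control$fit_kappa_em)) "kappa_em")
  l4 <- c(paste0("alpha_", 1:3), paste0("pi_endo0_", PHENO_NAMES))
  l5 <- paste0("pi_car0_", PHENO_NAMES)
  switch(model_id,
         `1` = l1, `2` = c(l1, l2), `3` = c(l1, l2, l3),
         `4` = c(l1, l4), `5` = c(l1, l2, l3, l4, l5))
}

# observables each model layer can predict
observables_for_model <- function(model_id) {
  switch(model_id,
    `1` = "E_blood",
    `2` = c("E_blood", "C_blood"),
    `3` = c("E_blood", "C_blood", "spd"),
    `4` = c("E_blood", paste0("endo_prop_", PHENO_NAMES)),
    `5` = c("E_blood", "C_blood", "spd", paste0("endo_prop_", PHENO_NAMES),
            paste0("car_prop_", PHENO_NAMES)))
}

is_proportion_obs <- function(obs) grepl("_prop_", obs)

# optimizer box bounds on the transformed (log / logit) scale
transform_bounds <- function(name) {
  if (grepl("^pi_", name)) return(c(logit(1e-4), logit(1 - 1e-4)))
  if (name %in% c("E0", "C0", "B0")) return(log(c(1, 1e14)))
  if (name == "K_half") return(log(c(1e3, 1e13)))
  if (grepl("^kappa_", name)) return(log(c(1e-14, 1e-4)))
  log(c(1e-6, 20))  # rates
}

transform_param <- function(name, v) {
  if (grepl("^pi_", name)) logit(pmin(pmax(v, 1e-4), 1 - 1e-4))
  else log(pmax(v, 1e-12))
}

untransform_param <- function(name, x) {
  if (grepl("^pi_", name)) inv_logit(x) else exp(x)
}

# predicted value of each observation row given a trajectory
predict_observable <- function(tr, obs_name, idx) {
  y <- switch(obs_name,
    E_blood = tr$E_b, C_blood = tr$C_b, spd = tr$spd,
    endo_prop_naive = tr$E_b_pheno[, "naive"] / tr$E_b,
    endo_prop_cm = tr$E_b_pheno[, "cm"] / tr$E_b,
    endo_prop_em = tr$E_b_pheno[, "em"] / tr$E_b,
    endo_prop_eff = tr$E_b_pheno[, "eff"] / tr$E_b,
    car_prop_naive = tr$C_pheno_prop[, "naive"],
    car_prop_cm = tr$C_pheno_prop[, "cm"],
    car_prop_em = tr$C_pheno_prop[, "em"],
    car_prop_eff = tr$C_pheno_prop[, "eff"],
    stop("unfittable observable: ", obs_name))
  y[idx]
}

# residual on the transformed scale: log for magnitudes, logit for
# proportions
obs_residual <- function(obs_name, pred, value) {
  if (is_proportion_obs(obs_name)) {
    logit(pmin(pmax(pred, 1e-6), 1 - 1e-6)) -
      logit(pmin(pmax(value, 1e-6), 1 - 1e-6))
  } else {
    log(pmax(pred, 1e-12)) - log(pmax(value, 1e-12))
  }
}

#' Fit one model layer to a single patient's observations
#'
#' Minimizes a weighted least-squares objective on transformed scales
#' (log for counts and SPD, logit for proportions) over the layer's free
#' parameters, holding `frozen` parameters at their values in `init`.
#' Optimization is a bounded local search (`nlminb` on log/logit-scaled
#' parameters) from the supplied initial values with jittered restarts.
#'
#' @param model_id Model layer 1..5.
#' @param obs Data frame with columns `time_day, observable, value`
#'   (a single patient).  Observables outside the layer's scope are
#'   ignored; observables with no usable rows are dropped with a warning.
#' @param init A [patient_parameters()] object supplying starting values
#'   and the values of frozen/structural parameters.
#' @param frozen Character vector of flat parameter names to hold fixed.
#' @param control A [fit_control()] list.
#' @return A `car_fit` object: `params` (optimum), `flat`, `objective`,
#'   `free`, `frozen`, `residual_summary`, `residuals`, `obj_trace`
#'   (best-so-far objective at each accepted improvement), `convergence`.
#' @export
fit_individual <- function(model_id, obs, init = patient_parameters(),
                           frozen = character(), control = fit_control()) {
  stopifnot(model_id %in% 1:5)
  relevant <- observables_for_model(model_id)
  obs <- obs[obs$observable %in% relevant & is.finite(obs$value), ]
  present <- intersect(relevant, unique(obs$observable))
  dropped <- setdiff(relevant, present)
  if (length(dropped) && length(present))
    warning("no usable observations for: ", paste(dropped, collapse = ", "))
  if (!nrow(obs))
    stop("no usable observations for any observable of model ", model_id)

  free <- setdiff(free_params_for_model(model_id, control), frozen)
  base <- flatten_parameters(init)
  w <- stats::setNames(rep(1, length(present)), present)
  if (!is.null(control$weights))
    w[names(control$weights)] <- control$weights

  t_obs <- sort(unique(obs$time_day))
  t_grid <- sort(unique(c(0, t_obs)))
  idx <- match(obs$time_day, t_grid)

  trace_env <- new.env()
  trace_env$best <- Inf
  trace_env$trace <- numeric()

  eval_at <- function(vals) {
    v <- base
    v[free] <- vals
    p <- try(unflatten_parameters(v, renormalize = TRUE), silent = TRUE)
    if (inherits(p, "try-error")) return(NULL)
    tr <- try(simulate_model(model_id, p, t_grid), silent = TRUE)
    if (inherits(tr, "try-error")) return(NULL)
    tr
  }
  objective_nat <- function(vals) {
    tr <- eval_at(vals)
    if (is.null(tr)) return(1e10)
    total <- 0
    for (o in present) {
      rows <- obs$observable == o
      pred <- predict_observable(tr, o, idx[rows])
      r <- obs_residual(o, pred, obs$value[rows])
      total <- total + w[[o]] * sum(r^2)
    }
    if (!is.finite(total)) return(1e10)
    if (total < trace_env$best) {
      trace_env$best <- total
      trace_env$trace <- c(trace_env$trace, total)
    }
    total
  }
  start <- vapply(free, function(nm) transform_param(nm, base[[nm]]),
                  numeric(1))
  objective <- function(x) {
    objective_nat(vapply(seq_along(free),
                         function(k) untransform_param(free[k], x[k]),
                         numeric(1))) +
      (control$ridge %||% 0) * sum((x - start)^2)
  }

  if (length(free) == 0L) {
    obj0 <- objective_nat(numeric(0))
    fit_vals <- numeric(0)
    conv <- 0L
  } else {
    bounds <- vapply(free, transform_bounds, numeric(2))
    start <- pmin(pmax(start, bounds[1, ]), bounds[2, ])
    best <- NULL
    set.seed(derive_seed(control$seed, "restart"))
    starts <- list(start)
    for (k in seq_len(max(control$restarts - 1L, 0L)))
      starts[[k + 1L]] <- pmin(pmax(start + stats::rnorm(length(start),
                                                         0, 0.4),
                                    bounds[1, ]), bounds[2, ])
    for (s in starts) {
      ans <- try(stats::nlminb(s, objective, lower = bounds[1, ],
                               upper = bounds[2, ],
                               control = list(iter.max = control$maxit,
                                              eval.max = 4L * control$maxit)),
                 silent = TRUE)
      if (inherits(ans, "try-error")) next
      if (is.null(best) || ans$objective < best$objective) best <- ans
    }
    if (is.null(best)) stop("all optimizer restarts failed")
    fit_vals <- vapply(seq_along(free),
                       function(k) untransform_param(free[k], best$par[k]),
                       numeric(1))
    obj0 <- best$objective
    conv <- best$convergence
    if (conv != 0)
      warning("optimizer did not report convergence (code ", conv,
              "); best objective so far returned")
  }

  v <- base
  v[free] <- fit_vals
  p_opt <- unflatten_parameters(v, renormalize = TRUE)
  tr <- simulate_model(model_id, p_opt, t_grid)
  resid <- lapply(present, function(o) {
    rows <- obs$observable == o
    r <- obs_residual(o, predict_observable(tr, o, idx[rows]),
                      obs$value[rows])
    data.frame(observable = o, time_day = obs$time_day[rows], residual = r)
  })
  resid <- do.call(rbind, resid)
  rs <- do.call(rbind, lapply(split(resid, resid$observable), function(d)
    data.frame(observable = d$observable[1], n = nrow(d),
               rmse = sqrt(mean(d$residual^2)))))
  rownames(rs) <- NULL
  # the reported objective is the data term alone (no ridge penalty)
  obj0 <- sum(w[resid$observable] * resid$residual^2)

  out <- list(model_id = model_id, params = p_opt,
              flat = flatten_parameters(p_opt), objective = obj0,
              free = free, frozen = frozen,
              residual_summary = rs, residuals = resid,
              obj_trace = trace_env$trace, convergence = conv)
  class(out) <- "car_fit"
  out
}

#' @export
print.car_fit <- function(x, ...) {
  cat(sprintf("<car_fit> model %d, objective %.4g, %d free parameter(s)\n",
              x$model_id, x$objective, length(x$free)))
  invisible(x)
}

# anchor value helpers used by the sequential pipeline ------------------

baseline_value <- function(obs, observable) {
  sub <- obs[obs$observable == observable & is.finite(obs$value), ]
  if (!nrow(sub)) return(NULL)
  sub <- sub[order(sub$time_day), ]
  if (sub$time_day[1] > 1) return(NULL)  # no baseline visit
  sub$value[1]
}

#' Sequential ("Russian doll") fit of the model hierarchy
#'
#' Fits the layers in the order 1 (blood endogenous kinetics), 2 (blood
#' CAR initial count), 4 (endogenous phenotype chain), 3 (lesion layer),
#' 5 (full assembly), each layer freezing every parameter fixed by its
#' predecessors.  The phenotype layer is fitted before the lesion layer
#' because the differentiation chain is independent of tumour dynamics
#' while lesion killing is phenotype-weighted, so the lesion layer can use
#' the already-estimated chain.
#'
#' Initial conditions are anchored at baseline measurements when a visit
#' at day <= 1 exists: `C0` at the baseline blood CAR count, `B0` at the
#' baseline SPD (via [cells_from_spd()]), and both phenotype proportion
#' vectors at the baseline flow observations; otherwise they are fitted.
#' SPD observations may be densified between the first and last imaging
#' visits by LDH interpolation ([interpolate_tumour_burden()]).
#'
#' Layers whose observables are entirely missing are skipped (a missing
#' lesion stream skips layers 3 and 5); a layer failure halts subsequent
#' layers and earlier results are returned.
#'
#' @param obs Single-patient observation data frame
#'   (`time_day, observable, value`).
#' @param init Starting [patient_parameters()].
#' @param control A [fit_control()] list.
#' @return List with `fits` (per fitted layer, named by model id),
#'   `params` (final parameter set), `provenance` (named vector: which
#'   layer fixed each parameter), and `skipped`.
#' @export
fit_sequential <- function(obs, init = patient_parameters(),
                           control = fit_control()) {
  if (!any(obs$observable == "E_blood"))
    stop("blood endogenous T-cell counts are required")
  fits <- list()
  skipped <- character()
  provenance <- character()
  cur <- init
  frozen <- character()

  run_layer <- function(model_id, obs_layer) {
    fit_individual(model_id, obs_layer, init = cur, frozen = frozen,
                   control = control)
  }
  freeze <- function(fit, layer) {
    cur <<- fit$params
    provenance[fit$free] <<- layer
    frozen <<- union(frozen, fit$free)
  }

  # layer 1: endogenous blood kinetics
  f1 <- run_layer(1, obs)
  fits[["1"]] <- f1
  freeze(f1, "model1")

  # layer 2: blood CAR initial count (anchored at the baseline count when
  # observed; the expansion kinetics are inherited from layer 1 and the
  # antigen layer above)
  if (any(obs$observable == "C_blood")) {
    c0 <- baseline_value(obs, "C_blood")
    if (!is.null(c0)) {
      v <- flatten_parameters(cur); v["C0"] <- c0
      cur <- unflatten_parameters(v)
      f2 <- fit_individual(2, obs, init = cur,
                           frozen = union(frozen, "C0"), control = control)
      f2$free <- "C0"; f2$flat <- flatten_parameters(cur)
      f2$params <- cur
      provenance["C0"] <- "model2(anchored)"
      frozen <- union(frozen, "C0")
      fits[["2"]] <- f2
    } else {
      f2 <- run_layer(2, obs)
      fits[["2"]] <- f2
      freeze(f2, "model2")
    }
  } else skipped <- c(skipped, "2")

  # layer 4: phenotype differentiation chain
  if (any(grepl("^endo_prop_", obs$observable))) {
    pe <- vapply(paste0("endo_prop_", PHENO_NAMES), function(o)
      baseline_value(obs, o) %||% NA_real_, numeric(1))
    anchored <- character()
    if (all(is.finite(pe))) {
      v <- flatten_parameters(cur)
      v[paste0("pi_endo0_", PHENO_NAMES)] <- pe / sum(pe)
      cur <- unflatten_parameters(v, renormalize = TRUE)
      anchored <- paste0("pi_endo0_", PHENO_NAMES)
      provenance[anchored] <- "model4(anchored)"
    }
    f4 <- fit_individual(4, obs, init = cur,
                         frozen = union(frozen, anchored),
                         control = control)
    fits[["4"]] <- f4
    freeze(f4, "model4")
    frozen <- union(frozen, anchored)
  } else skipped <- c(skipped, "4")

  # layer 3: lesion layer (needs a tumour-burden stream)
  obs3 <- obs
  if (isTRUE(control$use_ldh)) {
    spd_obs <- obs[obs$observable == "spd", ]
    ldh_obs <- obs[obs$observable == "LDH", ]
    if (nrow(spd_obs) >= 2 && nrow(ldh_obs) >= 2) {
      spd_obs <- spd_obs[order(spd_obs$time_day), ]
      interp <- interpolate_tumour_burden(
        spd_obs$value[1], spd_obs$value[nrow(spd_obs)],
        ldh_obs[order(ldh_obs$time_day), c("time_day", "value")],
        scale = "volume")
      obs3 <- rbind(obs[obs$observable != "spd",
                        c("time_day", "observable", "value")],
                    data.frame(time_day = interp$time_day,
                               observable = "spd", value = interp$spd))
    }
  }
  if (any(obs3$observable == "spd") && any(obs3$observable == "C_blood")) {
    anchored <- character()
    spd0 <- baseline_value(obs3, "spd")
    v <- flatten_parameters(cur)
    if (!is.null(spd0)) {
      v["B0"] <- cells_from_spd(spd0, cur$v_cell)
      anchored <- "B0"
      provenance["B0"] <- "model3(anchored)"
    }
    pc <- vapply(paste0("car_prop_", PHENO_NAMES), function(o)
      baseline_value(obs, o) %||% NA_real_, numeric(1))
    if (all(is.finite(pc))) {
      v[paste0("pi_car0_", PHENO_NAMES)] <- pc / sum(pc)
      anchored <- c(anchored, paste0("pi_car0_", PHENO_NAMES))
      provenance[paste0("pi_car0_", PHENO_NAMES)] <- "model5(anchored)"
    }
    cur <- unflatten_parameters(v, renormalize = TRUE)
    f3 <- try(fit_individual(3, obs3, init = cur,
                             frozen = union(frozen, anchored),
                             control = control), silent = TRUE)
    if (inherits(f3, "try-error")) {
      warning("lesion layer failed; later layers halted: ",
              attr(f3, "condition")$message)
      skipped <- c(skipped, "3", "5")
    } else {
      fits[["3"]] <- f3
      freeze(f3, "model3")
      frozen <- union(frozen, anchored)
      # layer 5: full model assembly; any remaining free parameters
      f5 <- fit_individual(5, obs, init = cur, frozen = frozen,
                           control = control)
      fits[["5"]] <- f5
      freeze(f5, "model5")
    }
  } else skipped <- c(skipped, "3", "5")

  list(fits = fits, params = cur, provenance = provenance,
       skipped = unique(skipped))
}

default_family_map <- function() {
  fam <- stats::setNames(rep("lognormal", length(parameter_names())),
                         parameter_names())
  fam["delta"] <- "normal"
  fam[grepl("^pi_", names(fam))] <- "logitnormal"
  fam
}

#' Estimate a population model from individual fits (two-stage approach)
#'
#' Stage two of two-stage population estimation: per-parameter Gaussian
#' maximum likelihood on the family's latent scale (identity, log, or
#' logit) across the individual optima, latent-scale correlations for
#' parameters with non-zero spread, and pooled-residual error models per
#' observable.  Parameters with (numerically) zero spread across patients
#' get scale 0 with a warning.
#'
#' @param fits List of `car_fit` objects (or of [patient_parameters()]),
#'   length >= 2.
#' @param family_map Named character vector parameter -> family; defaults
#'   to lognormal for positive parameters, normal for the death rate,
#'   logit-normal for proportions.
#' @param parameters Which flat parameters to model (default: those that
#'   vary across fits).
#' @param correlation Estimate the latent-scale correlation matrix.
#' @return A [population_model()]; the `params` data frame carries an
#'   extra `se` column (standard error of the location).
#' @export
fit_population <- function(fits, family_map = default_family_map(),
                           parameters = NULL, correlation = FALSE) {
  stopifnot(length(fits) >= 2)
  mat <- t(vapply(fits, function(f) {
    if (inherits(f, "car_fit")) f$flat
    else flatten_parameters(f)
  }, numeric(length(parameter_names()))))
  colnames(mat) <- parameter_names()
  if (is.null(parameters)) {
    spread <- apply(mat, 2, function(x) diff(range(x)))
    parameters <- colnames(mat)[spread > 0]
  }
  n <- nrow(mat)
  to_latent <- function(pn) {
    fam <- family_map[[pn]]
    x <- mat[, pn]
    if (fam == "logitnormal") x <- pmin(pmax(x, 1e-8), 1 - 1e-8)
    if (fam == "lognormal") x <- pmax(x, 1e-300)
    natural_to_latent(fam, x)
  }
  rows <- lapply(parameters, function(pn) {
    fam <- family_map[[pn]]
    lat <- to_latent(pn)
    loc <- mean(lat)
    sc <- stats::sd(lat)
    if (!is.finite(sc) || sc < 1e-12) {
      warning("parameter ", pn, " is degenerate across fits; scale set to 0")
      sc <- 0
    }
    data.frame(parameter = pn, family = fam, location = loc, scale = sc,
               se = sc / sqrt(n))
  })
  params <- do.call(rbind, rows)
  corr <- NULL
  if (correlation) {
    keep <- params$parameter[params$scale > 0]
    if (length(keep) >= 2)
      corr <- stats::cor(sapply(keep, to_latent))
  }
  # pooled residual spread per observable -> error model
  err <- NULL
  if (all(vapply(fits, inherits, logical(1), "car_fit"))) {
    res <- do.call(rbind, lapply(fits, function(f) f$residuals))
    if (!is.null(res) && nrow(res)) {
      err <- lapply(split(res, res$observable), function(d) {
        fam <- if (is_proportion_obs(d$observable[1])) "logit_additive"
               else "proportional"
        list(family = fam, sd = sqrt(mean(d$residual^2)))
      })
    }
  }
  population_model(params, correlation = corr, error_model = err)
}

#' Decompose the CAR T-cell proliferation rate by source
#'
#' Splits the per-capita CAR proliferation rate into its
#' antigen-independent (lymphodepletion-driven) component
#' `rho0 exp(-gamma t)`, shared by both compartments and independent of
#' tumour state, and its antigen-driven component
#' `rho_a B(t) / (B(t) + K_half)` in the lesion.  Blood CD19+ cells are
#' pinned at the limit of quantitation and do not stimulate CAR T-cells,
#' so the blood antigen-driven series is identically zero.
#'
#' @param params A [patient_parameters()].
#' @param traj A trajectory from model 3 or 5 (needs the lesion state).
#' @return Data frame `time_day, endogenous, antigen_lesion, antigen_blood`.
#' @export
decompose_proliferation <- function(params, traj) {
  stopifnot(inherits(traj, "car_trajectory"))
  if (is.null(traj$B_l))
    stop("lesion decomposition requires a trajectory from model 3 or 5")
  B <- traj$B_l
  data.frame(
    time_day = traj$t,
    endogenous = endogenous_proliferation_rate(params, traj$t),
    antigen_lesion = params$rho_a * B / (B + params$K_half),
    antigen_blood = 0)
}

#' Tiered responder ranking and half-cohort split
#'
#' Orders patients lexicographically by their month-1 response grade,
#' breaking ties by month 3 and then month 6 (smaller grade = better
#' response; see [response_ordinal()]).  Full ties preserve input order
#' (stable sort).  The first half is labelled `good`, the second `poor`;
#' with an odd cohort the extra patient goes to the poor half (warning).
#'
#' @param outcomes Data frame with columns `patient_id, month1, month3,
#'   month6` (ordinal response grades).
#' @return `outcomes` reordered, with added `rank` and `group` columns.
#' @export
rank_responders <- function(outcomes) {
  stopifnot(all(c("patient_id", "month1", "month3", "month6") %in%
                  names(outcomes)))
  n <- nrow(outcomes)
  ord <- order(outcomes$month1, outcomes$month3, outcomes$month6,
               method = "radix")
  out <- outcomes[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  n_good <- n %/% 2
  if (n %% 2 == 1)
    warning("odd cohort size: the extra patient is assigned to the poor half")
  out$group <- rep(c("good", "poor"), c(n_good, n - n_good))
  rownames(out) <- NULL
  out
}

#' Per-patient Spearman correlation between a rate and a covariate
#'
#' Interpolates each patient's covariate series onto that patient's rate
#' time grid and computes the Spearman rank correlation; patients with
#' fewer than 3 shared time points are skipped.
#'
#' @param rate_df,covariate_df Data frames `patient_id, time_day, value`.
#' @return List with `per_patient` (data frame `patient_id, rho, n`) and
#'   `median_rho`.
#' @export
correlate_covariate <- function(rate_df, covariate_df) {
  ids <- intersect(unique(rate_df$patient_id),
                   unique(covariate_df$patient_id))
  rows <- lapply(ids, function(id) {
    r <- rate_df[rate_df$patient_id == id, ]
    cv <- covariate_df[covariate_df$patient_id == id, ]
    if (nrow(cv) < 2) return(NULL)
    ci <- stats::approx(cv$time_day, cv$value, xout = r$time_day,
                        rule = 1)$y
    ok <- is.finite(ci) & is.finite(r$value)
    if (sum(ok) < 3) return(NULL)
    data.frame(patient_id = id,
               rho = stats::cor(r$value[ok], ci[ok], method = "spearman"),
               n = sum(ok))
  })
  per <- do.call(rbind, rows)
  list(per_patient = per,
       median_rho = if (is.null(per)) NA_real_ else stats::median(per$rho))
}

#' Interpolate tumour burden between imaging visits using LDH
#'
#' Maps the LDH series affinely so that the first and last LDH times hit
#' the measured start and end SPD exactly:
#' `spd(t) = spd_start + (spd_end - spd_start) *
#' (LDH(t) - LDH(t0)) / (LDH(t_end) - LDH(t0))`.  If LDH is flat between
#' the endpoints the interpolation falls back to linear-in-time, with a
#' warning.  Interior values are floored at zero.
#'
#' @param spd_start,spd_end SPD (cm^2) at the first and last imaging
#'   visits, >= 0.
#' @param ldh_series Data frame `time_day, value` with >= 2 points; the
#'   first/last rows define the start/end times.
#' @param scale Interpolate affinely on the SPD scale (`"spd"`, the
#'   default) or on the volume scale (`"volume"`: the SPD endpoints are
#'   converted to volumes of equal spheres, the volume is interpolated
#'   affinely in LDH — the natural scale when LDH tracks total burden —
#'   and converted back, so interior SPD values vary as volume^(2/3)).
#' @return Data frame `time_day, spd`.
#' @export
interpolate_tumour_burden <- function(spd_start, spd_end, ldh_series,
                                      scale = c("spd", "volume")) {
  scale <- match.arg(scale)
  stopifnot(spd_start >= 0, spd_end >= 0, nrow(ldh_series) >= 2)
  ldh_series <- ldh_series[order(ldh_series$time_day), ]
  t <- ldh_series$time_day
  L <- ldh_series$value
  n <- length(L)
  denom <- L[n] - L[1]
  if (denom == 0) {
    warning("LDH unchanged between endpoints; using linear-in-time ",
            "interpolation")
    frac <- (t - t[1]) / (t[n] - t[1])
  } else {
    frac <- (L - L[1]) / denom
  }
  if (scale == "spd") {
    spd <- pmax(spd_start + (spd_end - spd_start) * frac, 0)
  } else {
    v0 <- spd_start^(3 / 2)   # volume of a sphere scales as spd^(3/2)
    v1 <- spd_end^(3 / 2)
    spd <- pmax(v0 + (v1 - v0) * frac, 0)^(2 / 3)
  }
  data.frame(time_day = t, spd = spd)
}
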