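#' Population distribution model over patient parameters
#'
#' Describes, for each flat parameter (see [parameter_names()]), a marginal
#' distribution family (`normal`, `lognormal`, or `logitnormal`) with a
#' location and scale on the latent Gaussian scale, an optional correlation
#' matrix between latent variables, and per-observable observation-error
#' models.  `lognormal` locations are log-medians; `logitnormal` locations
#' are logit-medians.  Phenotype-proportion parameters must use
#' `logitnormal`.
#'
#' @param params Data frame with columns `parameter, family, location,
#'   scale`.  Parameters not listed are held at the [patient_parameters()]
#'   defaults when drawing virtual patients.
#' @param correlation Optional correlation matrix (latent scale) whose
#'   dimnames are a subset of `params$parameter`; must be symmetric
#'   positive semi-definite with unit diagonal.
#' @param error_model Optional named list, one entry per observable, each a
#'   list with `family` (`additive`, `proportional`, or `combined`) and
#'   `sd` (and `sd_prop` for `combined`).  Proportional errors act
#'   multiplicatively as `exp(sd * z)` on positive observables.
#' @return A `population_model` object.
#' @examples
#' pm <- population_model(data.frame(
#'   parameter = c("rho0", "delta"), family = c("lognormal", "normal"),
#'   location = c(log(0.6), 0.3), scale = c(0.25, 0.05)))
#' @export
population_model <- function(params, correlation = NULL, error_model = NULL) {
  stopifnot(is.data.frame(params),
            all(c("parameter", "family", "location", "scale") %in%
                  names(params)))
  if (any(!params$family %in% c("normal", "lognormal", "logitnormal")))
    stop("family must be normal, lognormal or logitnormal")
  if (any(params$scale < 0)) stop("scales must be >= 0")
  unknown <- setdiff(params$parameter, parameter_names())
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  is_prop <- grepl("^pi_", params$parameter)
  if (any(is_prop & params$family != "logitnormal"))
    stop("proportion-type parameters must use the logitnormal family")
  if (!is.null(correlation)) {
    cn <- colnames(correlation)
    if (is.null(cn) || !all(cn %in% params$parameter) ||
        !isTRUE(all.equal(correlation, t(correlation))) ||
        any(abs(diag(correlation) - 1) > 1e-12))
      stop("invalid correlation matrix")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  }
  pm <- list(params = params, correlation = correlation,
             error_model = error_model)
  class(pm) <- "population_model"
  pm
}

latent_to_natural <- function(family, x) {
  switch(family, normal = x, lognormal = exp(x), logitnormal = inv_logit(x))
}

natural_to_latent <- function(family, v) {
  switch(family, normal = v, lognormal = log(v), logitnormal = logit(v))
}

#' Draw a virtual-patient population
#'
#' Samples `n` parameter sets from a [population_model()]: iid standard
#' normal latents (correlated through the Cholesky factor where a
#' correlation matrix is given) are scaled, shifted and transformed per
#' family.  Draws are deterministic under a fixed seed.  Phenotype
#' proportion vectors are renormalized onto the simplex after the marginal
#' draws, and `normal`-family rates are floored at zero so every returned
#' set satisfies the parameter invariants.
#'
#' @param pop A [population_model()].
#' @param n Number of virtual patients (>= 0).
#' @param seed Integer seed.
#' @return List of `n` [patient_parameters()] objects.
#' @export
draw_vpop <- function(pop, n, seed = 1L) {
  stopifnot(inherits(pop, "population_model"), n >= 0)
  if (n == 0) return(list())
  prm <- pop$params
  set.seed(seed)
  z <- matrix(stats::rnorm(n * nrow(prm)), nrow = n,
              dimnames = list(NULL, prm$parameter))
  if (!is.null(pop$correlation)) {
    cn <- colnames(pop$correlation)
    L <- chol(pop$correlation, pivot = FALSE)
    z[, cn] <- z[, cn, drop = FALSE] %*% L
  }
  base <- flatten_parameters(patient_parameters())
  lapply(seq_len(n), function(i) {
    v <- base
    for (j in seq_len(nrow(prm))) {
      x <- prm$location[j] + prm$scale[j] * z[i, j]
      val <- latent_to_natural(prm$family[j], x)
      if (prm$family[j] == "normal") val <- max(val, 0)
      v[prm$parameter[j]] <- val
    }
    unflatten_parameters(v, renormalize = TRUE)
  })
}

#' Alter one parameter across a virtual population
#'
#' Applies a multiplicative or additive change to a named flat parameter
#' in every patient of a virtual population.  Altered phenotype
#' proportions are capped at 1 and the proportion vector renormalized;
#' every altered set is re-validated.
#'
#' @param vpop List of [patient_parameters()] objects.
#' @param parameter_name One of [parameter_names()].
#' @param factor Finite numeric constant.
#' @param mode `"multiply"` or `"add"`.
#' @return The altered list of parameter sets.
#' @examples
#' vp <- list(patient_parameters())
#' vp2 <- alter_parameters(vp, "rho0", 1.5, "multiply")
#' vp2[[1]]$rho0
#' @export
alter_parameters <- function(vpop, parameter_name, factor,
                             mode = c("multiply", "add")) {
  mode <- match.arg(mode)
  if (!parameter_name %in% parameter_names())
    stop("unknown parameter: ", parameter_name)
  if (!is.finite(factor)) stop("factor must be finite")
  is_prop <- grepl("^pi_", parameter_name)
  lapply(vpop, function(p) {
    v <- flatten_parameters(p)
    v[parameter_name] <- if (mode == "multiply")
      v[parameter_name] * factor else v[parameter_name] + factor
    unflatten_parameters(v, renormalize = is_prop)
  })
}

# observable series extracted from a trajectory by name
trajectory_observable <- function(tr, obs) {
  switch(obs,
    E_blood = tr$E_b, C_blood = tr$C_b, C_lesion = tr$C_l,
    B_lesion = tr$B_l, lesion_volume = tr$lesion_volume,
    lesion_diameter = tr$lesion_diameter, spd = tr$spd,
    car_prop_naive = tr$C_pheno_prop[, "naive"],
    car_prop_cm = tr$C_pheno_prop[, "cm"],
    car_prop_em = tr$C_pheno_prop[, "em"],
    car_prop_eff = tr$C_pheno_prop[, "eff"],
    endo_prop_naive = tr$E_b_pheno[, "naive"] / tr$E_b,
    endo_prop_cm = tr$E_b_pheno[, "cm"] / tr$E_b,
    endo_prop_em = tr$E_b_pheno[, "em"] / tr$E_b,
    endo_prop_eff = tr$E_b_pheno[, "eff"] / tr$E_b,
    stop("unknown observable: ", obs))
}

#' Cohort quartile bands of simulated observables
#'
#' Simulates every virtual patient, optionally perturbs each patient's
#' series with the population observation-error model, and summarizes the
#' cohort per time point by the median, interquartile range and 5th-95th
#' percentile band.  Quantiles use linear interpolation between order
#' statistics (R type 7).  Per-patient simulation failures are collected
#' (attribute `"failures"`) rather than aborting the cohort.
#'
#' @param vpop Non-empty list of [patient_parameters()] objects.
#' @param model_id Model layer to simulate (default 5).
#' @param t_grid Time grid, days.
#' @param observables Character vector of observable names (see
#'   [generate_cohort()] for the vocabulary).
#' @param error_model Optional error model (as in [population_model()]) to
#'   add observation noise per patient.
#' @param seed Seed for the observation noise.
#' @return A data frame of class `quartile_bands` with columns
#'   `observable, time_day, q05, q25, q50, q75, q95`.
#' @export
vpop_outputs <- function(vpop, model_id = 5, t_grid = 0:30,
                         observables = c("C_blood", "E_blood",
                                         "lesion_volume"),
                         error_model = NULL, seed = 1L) {
  stopifnot(length(vpop) >= 1)
  set.seed(derive_seed(seed, "noise"))
  failures <- character()
  series <- vector("list", length(vpop))
  for (i in seq_along(vpop)) {
    tr <- tryCatch(simulate_model(model_id, vpop[[i]], t_grid),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      failures <- c(failures, sprintf("patient %d: %s", i,
                                      conditionMessage(tr)))
      next
    }
    mat <- sapply(observables, function(o) {
      y <- trajectory_observable(tr, o)
      if (!is.null(error_model) && !is.null(error_model[[o]]))
        y <- apply_error_model(y, error_model[[o]])
      y
    })
    series[[i]] <- mat
  }
  series <- series[!vapply(series, is.null, logical(1))]
  if (!length(series)) stop("all patient simulations failed")
  bands <- do.call(rbind, lapply(seq_along(observables), function(k) {
    m <- sapply(series, function(s) s[, k])   # time x patients
    q <- t(apply(m, 1, band_quantiles))
    data.frame(observable = observables[k], time_day = t_grid,
               q05 = q[, 1], q25 = q[, 2], q50 = q[, 3], q75 = q[, 4],
               q95 = q[, 5])
  }))
  attr(bands, "failures") <- failures
  class(bands) <- c("quartile_bands", class(bands))
  bands
}

# draw observation noise on one series under an error-model entry
apply_error_model <- function(y, em) {
  n <- length(y)
  switch(em$family,
    additive = y + stats::rnorm(n, 0, em$sd),
    proportional = y * exp(stats::rnorm(n, 0, em$sd)),
    logit_additive = inv_logit(logit(pmin(pmax(y, 1e-12), 1 - 1e-12)) +
                               stats::rnorm(n, 0, em$sd)),
    combined = y * exp(stats::rnorm(n, 0, em$sd_prop)) +
               stats::rnorm(n, 0, em$sd),
    stop("unknown error family: ", em$family))
}

#' Plot cohort quartile bands
#' @param x A `quartile_bands` data frame.
#' @param observable Which observable to draw (default the first).
#' @param log Use a log y-axis.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.quartile_bands <- function(x, observable = x$observable[1],
                                log = FALSE, ...) {
  b <- x[x$observable == observable, ]
  graphics::plot(b$time_day, b$q50, type = "l", lwd = 2,
                 log = if (log) "y" else "",
                 xlab = "time (days)", ylab = observable, ...)
  graphics::lines(b$time_day, b$q25, lty = 2)
  graphics::lines(b$time_day, b$q75, lty = 2)
  graphics::lines(b$time_day, b$q05, lty = 3)
  graphics::lines(b$time_day, b$q95, lty = 3)
  invisible(x)
}
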