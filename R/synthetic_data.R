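#' Default ground-truth population for synthetic cohorts
#'
#' The cohort-level distribution the synthetic generator draws patients
#' from.  Marginals follow the modelling conventions used throughout:
#' log-normal for positive rates, counts and constants (locations are
#' log-medians), Gaussian for the death rate, logit-normal for phenotype
#' proportions.  The lesion:blood partition ratio, the cell volume, the
#' blood CD19+ limit-of-quantitation count and the non-effector killing
#' rates are structural constants (not listed, hence held at the
#' [patient_parameters()] defaults with zero spread).
#'
#' @return A [population_model()] with observation-error models for every
#'   generated observable.
#' @export
default_truth_population <- function() {
  base <- flatten_parameters(patient_parameters())
  prm <- rbind(
    data.frame(parameter = "rho0", family = "lognormal",
               location = log(base[["rho0"]]), scale = 0.25),
    data.frame(parameter = "gamma", family = "lognormal",
               location = log(base[["gamma"]]), scale = 0.30),
    data.frame(parameter = "delta", family = "normal",
               location = base[["delta"]], scale = 0.04),
    data.frame(parameter = "rho_a", family = "lognormal",
               location = log(base[["rho_a"]]), scale = 0.40),
    data.frame(parameter = "K_half", family = "lognormal",
               location = log(base[["K_half"]]), scale = 0.50),
    data.frame(parameter = "g_tumour", family = "lognormal",
               location = log(base[["g_tumour"]]), scale = 0.40),
    data.frame(parameter = "kappa_eff", family = "lognormal",
               location = log(base[["kappa_eff"]]), scale = 0.50),
    data.frame(parameter = paste0("alpha_", 1:3), family = "lognormal",
               location = log(base[paste0("alpha_", 1:3)]), scale = 0.30),
    data.frame(parameter = "E0", family = "lognormal",
               location = log(base[["E0"]]), scale = 0.50),
    data.frame(parameter = "C0", family = "lognormal",
               location = log(base[["C0"]]), scale = 0.60),
    data.frame(parameter = "B0", family = "lognormal",
               location = log(base[["B0"]]), scale = 0.70),
    data.frame(parameter = paste0("pi_endo0_", PHENO_NAMES),
               family = "logitnormal",
               location = logit(base[paste0("pi_endo0_", PHENO_NAMES)]),
               scale = 0.30),
    data.frame(parameter = paste0("pi_car0_", PHENO_NAMES),
               family = "logitnormal",
               location = logit(base[paste0("pi_car0_", PHENO_NAMES)]),
               scale = 0.30))
  rownames(prm) <- NULL
  err <- list(
    E_blood = list(family = "proportional", sd = 0.20),
    C_blood = list(family = "proportional", sd = 0.20),
    spd = list(family = "proportional", sd = 0.15),
    LDH = list(family = "additive", sd = 10),
    IL7 = list(family = "additive", sd = 0.05),
    IL15 = list(family = "additive", sd = 0.05))
  for (o in c(paste0("endo_prop_", PHENO_NAMES),
              paste0("car_prop_", PHENO_NAMES)))
    err[[o]] <- list(family = "logit_additive", sd = 0.15)
  population_model(prm, error_model = err)
}

#' Default trial-like observation schedule
#'
#' Blood counts on days 0, 1, 3, 5, 7, 10, 14, 21, 28; phenotype flow
#' panels weekly; lesion imaging (SPD) only at the first and last visits;
#' LDH twice weekly; cytokines with the blood draws.
#'
#' @return Named list of visit-day vectors (`blood`, `phenotype`,
#'   `lesion`, `ldh`, `cytokine`).
#' @export
default_schedule <- function() {
  list(blood = c(0, 1, 3, 5, 7, 10, 14, 21, 28),
       phenotype = c(0, 7, 14, 21, 28),
       lesion = c(0, 28),
       ldh = c(0, 3, 7, 10, 14, 17, 21, 24, 28),
       cytokine = c(0, 1, 3, 5, 7, 10, 14, 21, 28))
}

# cytokine surrogate: a * exp(-gamma_patient * t) + b, matching the decay
# of the antigen-independent proliferation rate by construction
CYTOKINE_SHAPE <- list(IL7 = c(a = 0.7, b = 0.3),
                       IL15 = c(a = 0.8, b = 0.2))

# LDH surrogate: affine in lesion volume
LDH_COEF <- c(c0 = 200, c1 = 8)  # units; per cm^3

#' Generate a fully synthetic trial-like cohort with known ground truth
#'
#' Draws per-patient parameters from `truth_pop`, simulates the full
#' model (layer 5), and samples sparse noisy observations on the visit
#' schedule: blood endogenous/CAR counts, phenotype proportions
#' (renormalized after noise, as flow panels are), SPD at the first and
#' last imaging visits only, blood CD19+ pinned constant at the limit of
#' quantitation, LDH as an affine function of lesion volume plus noise,
#' and IL-7/IL-15 as noisy decaying exponentials sharing each patient's
#' proliferation-decay rate (so the cytokine-proliferation correlation
#' exists by construction).
#'
#' @param truth_pop Ground-truth [population_model()] (default
#'   [default_truth_population()]).
#' @param n_patients Cohort size (default 64).
#' @param schedule Visit schedule list (see [default_schedule()]); all
#'   times must lie in \[0, 30\].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param noise Apply the observation-error models (set `FALSE` for
#'   noise-free data equal to the model outputs).
#' @param responder_mode Split the cohort into good/poor halves by
#'   multiplying the antigen-driven proliferation rate `rho_a` of the
#'   good half by `responder_factor`.
#' @param responder_factor Multiplier for the good half (default 1.6).
#' @return A `cohort_dataset`: `observations` (patient_id, time_day,
#'   observable, value, unit), `lesions` (patient_id, lesion_id,
#'   baseline_d, final_d), `covariates` (patient_id, time_day, covariate,
#'   value), `truth` (patient_id, parameter, value), `groups`,
#'   `truth_population`, `schedule`.
#' @export
generate_cohort <- function(truth_pop = default_truth_population(),
                            n_patients = 64L,
                            schedule = default_schedule(), seed = 1L,
                            noise = TRUE, responder_mode = FALSE,
                            responder_factor = 1.6) {
  stopifnot(n_patients >= 1)
  all_times <- unlist(schedule)
  if (any(all_times < 0 | all_times > 30))
    stop("schedule times must lie within [0, 30] days")
  vpop <- draw_vpop(truth_pop, n_patients, derive_seed(seed, "draw"))
  groups <- rep(NA_character_, n_patients)
  if (responder_mode) {
    good <- seq_len(n_patients) <= n_patients %/% 2
    groups <- ifelse(good, "good", "poor")
    vpop[good] <- alter_parameters(vpop[good], "rho_a", responder_factor,
                                   "multiply")
  }
  em <- truth_pop$error_model
  set.seed(derive_seed(seed, "noise"))
  maybe_noise <- function(y, obs) {
    if (!noise || is.null(em[[obs]])) return(y)
    apply_error_model(y, em[[obs]])
  }

  obs_rows <- list(); cov_rows <- list(); les_rows <- list()
  tru_rows <- list()
  t_grid <- sort(unique(c(0:30, all_times)))
  for (i in seq_len(n_patients)) {
    id <- sprintf("P%03d", i)
    p <- vpop[[i]]
    tr <- simulate_model(5, p, t_grid)
    at <- function(series, times) series[match(times, t_grid)]
    add_obs <- function(times, observable, values, unit) {
      obs_rows[[length(obs_rows) + 1L]] <<- data.frame(
        patient_id = id, time_day = times, observable = observable,
        value = values, unit = unit)
    }
    add_obs(schedule$blood, "E_blood",
            maybe_noise(at(tr$E_b, schedule$blood), "E_blood"),
            "cells_per_5.3L")
    add_obs(schedule$blood, "C_blood",
            maybe_noise(at(tr$C_b, schedule$blood), "C_blood"),
            "cells_per_5.3L")
    add_obs(schedule$blood, "B_blood",
            rep(p$B_blood_loq, length(schedule$blood)), "cells_per_5.3L")
    # flow panels: noise per channel, then renormalized to sum to 1
    for (kind in c("endo", "car")) {
      raw <- sapply(PHENO_NAMES, function(ph) {
        o <- paste0(kind, "_prop_", ph)
        y <- if (kind == "endo")
          at(tr$E_b_pheno[, ph], schedule$phenotype) /
            at(tr$E_b, schedule$phenotype)
        else at(tr$C_pheno_prop[, ph], schedule$phenotype)
        maybe_noise(y, o)
      })
      raw <- raw / rowSums(raw)
      for (ph in PHENO_NAMES)
        add_obs(schedule$phenotype, paste0(kind, "_prop_", ph),
                raw[, ph], "proportion")
    }
    spd_obs <- maybe_noise(at(tr$spd, schedule$lesion), "spd")
    add_obs(schedule$lesion, "spd", spd_obs, "cm2")
    les_rows[[i]] <- data.frame(
      patient_id = id, lesion_id = 1L,
      baseline_d = sqrt(spd_obs[1]),
      final_d = sqrt(spd_obs[length(spd_obs)]))
    add_cov <- function(times, covariate, values) {
      cov_rows[[length(cov_rows) + 1L]] <<- data.frame(
        patient_id = id, time_day = times, covariate = covariate,
        value = values)
    }
    ldh <- LDH_COEF[["c0"]] +
      LDH_COEF[["c1"]] * at(tr$lesion_volume, schedule$ldh)
    add_cov(schedule$ldh, "LDH", maybe_noise(ldh, "LDH"))
    for (cy in names(CYTOKINE_SHAPE)) {
      sh <- CYTOKINE_SHAPE[[cy]]
      y <- sh[["a"]] * exp(-p$gamma * schedule$cytokine) + sh[["b"]]
      add_cov(schedule$cytokine, cy, maybe_noise(y, cy))
    }
    fl <- flatten_parameters(p)
    tru_rows[[i]] <- data.frame(patient_id = id, parameter = names(fl),
                                value = unname(fl))
  }
  ds <- list(observations = do.call(rbind, obs_rows),
             lesions = do.call(rbind, les_rows),
             covariates = do.call(rbind, cov_rows),
             truth = do.call(rbind, tru_rows),
             groups = data.frame(patient_id = sprintf("P%03d",
                                                      seq_len(n_patients)),
                                 group = groups),
             truth_population = truth_pop,
             schedule = schedule)
  class(ds) <- "cohort_dataset"
  ds
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(paste0("<cohort_dataset> %d patients, %d observation rows, ",
                     "%d covariate rows\n"),
              length(unique(x$observations$patient_id)),
              nrow(x$observations), nrow(x$covariates)))
  invisible(x)
}

#' One patient's observations merged with covariates
#'
#' Returns the long observation table (`time_day, observable, value`) for
#' one patient, with the covariate series appended as observables
#' (`LDH`, `IL7`, `IL15`) — the form [fit_sequential()] consumes.
#'
#' @param ds A `cohort_dataset`.
#' @param patient_id Patient identifier.
#' @return Data frame `time_day, observable, value`.
#' @export
patient_observations <- function(ds, patient_id) {
  o <- ds$observations[ds$observations$patient_id == patient_id,
                       c("time_day", "observable", "value")]
  cv <- ds$covariates[ds$covariates$patient_id == patient_id, ]
  if (nrow(cv))
    o <- rbind(o, data.frame(time_day = cv$time_day,
                             observable = cv$covariate, value = cv$value))
  o[order(o$observable, o$time_day), ]
}

#' True parameter set of one synthetic patient
#' @param ds A `cohort_dataset`.
#' @param patient_id Patient identifier.
#' @return A [patient_parameters()] object.
#' @export
patient_truth <- function(ds, patient_id) {
  tt <- ds$truth[ds$truth$patient_id == patient_id, ]
  unflatten_parameters(stats::setNames(tt$value, tt$parameter))
}

#' Thin a cohort by random missingness
#'
#' Drops observation rows independently at `rate`, never dropping a
#' baseline (day-0) visit; lesion, covariate and truth tables are
#' untouched.
#'
#' @param ds A `cohort_dataset`.
#' @param rate Missingness rate in \[0, 1).
#' @param seed Integer seed.
#' @return The thinned `cohort_dataset`.
#' @export
degrade <- function(ds, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(ds)
  set.seed(seed)
  o <- ds$observations
  drop <- stats::runif(nrow(o)) < rate & o$time_day > 0
  ds$observations <- o[!drop, ]
  ds
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a cohort dataset to a directory of plain-text files
#'
#' Four CSV tables (`observations`, `lesions`, `covariates`, `truth`,
#' plus `groups`) and the ground-truth population model as YAML; the
#' exact inverse of [read_cohort()] (values round-trip at full double
#' precision).
#'
#' @param ds A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, quote = TRUE)
  }
  wr(ds$observations, "observations")
  wr(ds$lesions, "lesions")
  wr(ds$covariates, "covariates")
  wr(ds$truth, "truth")
  wr(ds$groups, "groups")
  write_population_model(ds$truth_population,
                         file.path(dir, "population.yaml"))
  yaml::write_yaml(ds$schedule, file.path(dir, "schedule.yaml"))
  invisible(dir)
}

#' Read a cohort dataset written by [write_cohort()]
#' @param dir Directory path.
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  rd <- function(name)
    utils::read.csv(file.path(dir, paste0(name, ".csv")),
                    stringsAsFactors = FALSE)
  ds <- list(observations = rd("observations"), lesions = rd("lesions"),
             covariates = rd("covariates"), truth = rd("truth"),
             groups = rd("groups"),
             truth_population =
               read_population_model(file.path(dir, "population.yaml")),
             schedule = yaml::read_yaml(file.path(dir, "schedule.yaml")))
  class(ds) <- "cohort_dataset"
  ds
}

#' Write a population model as structured text (YAML)
#' @param pop A [population_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_model <- function(pop, path) {
  obj <- list(
    params = lapply(seq_len(nrow(pop$params)), function(j)
      list(parameter = pop$params$parameter[j],
           family = pop$params$family[j],
           location = fmt_num(pop$params$location[j]),
           scale = fmt_num(pop$params$scale[j]))),
    correlation = if (!is.null(pop$correlation))
      list(parameters = colnames(pop$correlation),
           values = apply(pop$correlation, 1, fmt_num, simplify = FALSE)),
    error_model = if (!is.null(pop$error_model))
      lapply(pop$error_model, function(e) {
        e$sd <- fmt_num(e$sd)
        if (!is.null(e$sd_prop)) e$sd_prop <- fmt_num(e$sd_prop)
        e
      }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a population model written by [write_population_model()]
#' @param path YAML path.
#' @return A [population_model()].
#' @export
read_population_model <- function(path) {
  obj <- yaml::read_yaml(path)
  params <- do.call(rbind, lapply(obj$params, function(e)
    data.frame(parameter = e$parameter, family = e$family,
               location = as.numeric(e$location),
               scale = as.numeric(e$scale))))
  corr <- NULL
  if (!is.null(obj$correlation)) {
    pn <- obj$correlation$parameters
    corr <- t(vapply(obj$correlation$values,
                     function(r) as.numeric(unlist(r)),
                     numeric(length(pn))))
    dimnames(corr) <- list(pn, pn)
    corr <- (corr + t(corr)) / 2
  }
  em <- obj$error_model
  if (!is.null(em))
    em <- lapply(em, function(e) {
      e$sd <- as.numeric(e$sd)
      if (!is.null(e$sd_prop)) e$sd_prop <- as.numeric(e$sd_prop)
      e
    })
  population_model(params, correlation = corr, error_model = em)
}
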