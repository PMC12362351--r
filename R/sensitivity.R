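#' eFAST sampling design
#'
#' Builds the search-curve sample matrix for the extended Fourier
#' Amplitude Sensitivity Test.  For each factor of interest (each
#' parameter, plus an optional dummy parameter used as a noise-floor
#' reference) and each of `resamplings` independent curves with random
#' phase shifts, `samples_per_param` points are taken along the
#' space-filling curve
#' `x_j(s) = 0.5 + (1/pi) asin(sin(omega_j s + phi_j))`,
#' with the factor of interest driven at the maximal frequency
#' `omega_max = floor((N - 1) / (2 Mi))` (interference factor `Mi`) and
#' the complementary factors at low frequencies.  The design therefore
#' has `N * D * M` rows.
#'
#' @param bounds Named list (or two-row matrix with column names) of
#'   `c(lower, upper)` per parameter, `lower < upper`.
#' @param samples_per_param Points per search curve, `N`.
#' @param resamplings Number of random-phase resample curves per factor,
#'   `M`.
#' @param include_dummy Append a non-influential `dummy` factor with
#'   bounds \[0, 1\].
#' @param seed Integer seed for the phase shifts.
#' @param interference Interference factor `Mi` (harmonics retained when
#'   estimating first-order variance), default 4.
#' @return An `efast_design` object whose `$X` is the sample data frame
#'   (one column per factor); metadata needed by [efast_indices()] is
#'   stored alongside.
#' @examples
#' d <- efast_design(list(a = c(0, 1), b = c(0, 1)), 65, 1,
#'                   include_dummy = FALSE)
#' nrow(d$X)  # 65 * 2 * 1
#' @export
efast_design <- function(bounds, samples_per_param, resamplings = 4L,
                         include_dummy = TRUE, seed = 1L,
                         interference = 4L) {
  if (is.matrix(bounds))
    bounds <- stats::setNames(lapply(seq_len(ncol(bounds)),
                                     function(j) bounds[, j]),
                              colnames(bounds))
  if (include_dummy) bounds$dummy <- c(0, 1)
  factors <- names(bounds)
  D <- length(factors)
  N <- as.integer(samples_per_param)
  M <- as.integer(resamplings)
  Mi <- as.integer(interference)
  for (f in factors)
    if (bounds[[f]][1] >= bounds[[f]][2])
      stop("lower bound must be below upper bound for ", f)
  omega_max <- floor((N - 1) / (2 * Mi))
  m_comp <- floor(omega_max / (2 * Mi))
  if (m_comp < 1) {
    n_min <- 2L * Mi * (2L * Mi) + 1L
    stop("samples_per_param too small for frequency selection; ",
         "minimum valid N is ", n_min)
  }
  # complementary-set frequencies, assigned as in the standard estimator
  omega_c <- if (m_comp >= D - 1 && D > 1)
    floor(seq(1, m_comp, length.out = D - 1))
  else if (D > 1) ((seq_len(D - 1) - 1L) %% m_comp) + 1L
  else integer(0)

  s <- 2 * pi * (seq_len(N) - 1) / N
  set.seed(seed)
  blocks <- vector("list", D * M)
  k <- 0L
  for (i in seq_len(D)) {
    omega <- numeric(D)
    omega[i] <- omega_max
    omega[-i] <- omega_c
    for (r in seq_len(M)) {
      phase <- stats::runif(D, 0, 2 * pi)
      x <- vapply(seq_len(D), function(j) {
        g <- 0.5 + (1 / pi) * asin(sin(omega[j] * s + phase[j]))
        bounds[[j]][1] + g * (bounds[[j]][2] - bounds[[j]][1])
      }, numeric(N))
      colnames(x) <- factors
      k <- k + 1L
      blocks[[k]] <- x
    }
  }
  X <- as.data.frame(do.call(rbind, blocks))
  out <- list(X = X, factors = factors, N = N, M = M, Mi = Mi, D = D,
              omega_max = omega_max, m_comp = m_comp, bounds = bounds)
  class(out) <- "efast_design"
  out
}

# spectrum-based indices for one factor's curve of model outputs
efast_curve_indices <- function(y, N, Mi, omega_max, m_comp) {
  f <- stats::fft(y)
  half <- floor((N - 1) / 2)
  Sp <- (Mod(f[2:(half + 1)]) / N)^2
  V <- 2 * sum(Sp)
  if (V <= 0) return(c(NA_real_, NA_real_))
  D1 <- 2 * sum(Sp[omega_max * seq_len(Mi)])
  Dc <- 2 * sum(Sp[seq_len(m_comp)])
  c(SI = D1 / V, TSI = 1 - Dc / V)
}

#' eFAST first-order and total sensitivity indices
#'
#' Computes first-order (`SI`) and total (`TSI`) variance-based indices
#' from model outputs evaluated on an [efast_design()] (averaging over the
#' design's resample curves).  Non-finite outputs are imputed with the
#' output median; the run aborts if more than 5\% of rows failed.
#'
#' @param design An `efast_design`.
#' @param outputs Numeric vector (or matrix/data frame with one column
#'   per model output) of length/`nrow` equal to `nrow(design$X)`.
#' @return List of data frames, one per output, each with columns
#'   `parameter, SI, TSI`.
#' @export
efast_indices <- function(design, outputs) {
  stopifnot(inherits(design, "efast_design"))
  Y <- as.matrix(outputs)
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("output", seq_len(ncol(Y)))
  if (nrow(Y) != nrow(design$X))
    stop("outputs must have one row per design row")
  bad <- !is.finite(Y)
  if (any(colMeans(bad) > 0.05))
    stop("more than 5% of model evaluations failed")
  for (j in seq_len(ncol(Y)))
    Y[bad[, j], j] <- stats::median(Y[, j], na.rm = TRUE)
  n_imputed <- colSums(bad)

  N <- design$N; M <- design$M; D <- design$D
  res <- lapply(seq_len(ncol(Y)), function(jout) {
    y <- Y[, jout]
    si <- tsi <- numeric(D)
    if (stats::sd(y) == 0) {
      warning("output ", colnames(Y)[jout],
              " is constant; all indices set to 0")
      return(data.frame(parameter = design$factors, SI = si, TSI = tsi))
    }
    constant <- TRUE
    for (i in seq_len(D)) {
      vals <- sapply(seq_len(M), function(r) {
        off <- ((i - 1) * M + (r - 1)) * N
        efast_curve_indices(y[(off + 1):(off + N)], N, design$Mi,
                            design$omega_max, design$m_comp)
      })
      if (any(is.finite(vals))) constant <- FALSE
      si[i] <- mean(vals[1, ], na.rm = TRUE)
      tsi[i] <- mean(vals[2, ], na.rm = TRUE)
    }
    if (constant) {
      warning("output ", colnames(Y)[jout],
              " is constant; all indices set to 0")
      si[] <- 0; tsi[] <- 0
    }
    si[!is.finite(si)] <- 0; tsi[!is.finite(tsi)] <- 0
    data.frame(parameter = design$factors,
               SI = pmin(pmax(si, 0), 1), TSI = pmin(pmax(tsi, 0), 1))
  })
  names(res) <- colnames(Y)
  attr(res, "n_imputed") <- n_imputed
  res
}

#' Random-forest importance as sensitivity indices
#'
#' Grows a regression random forest of `n_trees` trees on all rows (the
#' forest is not used for prediction, so no held-out split is taken) and
#' returns the node-impurity importance of each parameter, normalized to
#' sum to 1.  Every feature is considered at every split (`mtry =
#' ncol(X)`) so that impurity importance concentrates on the parameters
#' that actually drive the output rather than being diluted over random
#' split candidates.
#'
#' @param X Data frame or matrix of parameter values (>= 50 rows).
#' @param y Numeric output vector.
#' @param n_trees Trees per forest (default 100).
#' @param seed Integer seed.
#' @return Named importance vector (>= 0, sums to 1).
#' @export
rf_importance <- function(X, y, n_trees = 100L, seed = 1L) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) >= 50, length(y) == nrow(X))
  if (stats::sd(y) == 0) {
    warning("constant output; returning uniform importances")
    return(stats::setNames(rep(1 / ncol(X), ncol(X)), colnames(X)))
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   mtry = ncol(X))
  imp <- rf$importance[, "IncNodePurity"]
  if (sum(imp) <= 0) {
    warning("zero total importance; returning uniform importances")
    return(stats::setNames(rep(1 / ncol(X), ncol(X)), colnames(X)))
  }
  imp / sum(imp)
}

#' Spearman rank correlation between parameters and an output
#'
#' @param X Data frame or matrix of parameter values (>= 3 rows).
#' @param y Numeric output vector.
#' @return Named vector of Spearman correlations (mid-ranks for ties);
#'   constant parameters get 0.
#' @export
spearman_sensitivity <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 3, length(y) == nrow(X))
  rho <- suppressWarnings(
    apply(X, 2, function(x) stats::cor(x, y, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  rho
}

#' Local (one-at-a-time 1\%) sensitivity around fitted optima
#'
#' Each parameter of each optimum is increased and decreased by
#' `perturbation` (relative); the score for a parameter-output pair is
#' the mean over patients and both directions of the absolute relative
#' output change.  Patient-output pairs whose baseline output is zero are
#' skipped (recorded in the `"skipped"` attribute).
#'
#' @param optima List of [patient_parameters()] objects (fitted optima).
#' @param output_fn Function mapping a parameter set to a named numeric
#'   vector of outputs; defaults to [model_outputs()] on model 5.
#' @param parameters Flat parameter names to perturb (default: all
#'   non-structural parameters).
#' @param perturbation Relative perturbation (default 0.01).
#' @return Matrix outputs x parameters of mean absolute relative changes.
#' @export
local_sensitivity <- function(optima, output_fn = model_outputs,
                              parameters = NULL, perturbation = 0.01) {
  if (is.null(parameters))
    parameters <- setdiff(parameter_names(),
                          c("B_blood_loq", "v_cell"))
  base_out <- lapply(optima, output_fn)
  out_names <- names(base_out[[1]])
  acc <- array(0, dim = c(length(out_names), length(parameters)),
               dimnames = list(out_names, parameters))
  cnt <- acc
  skipped <- character()
  for (i in seq_along(optima)) {
    v0 <- flatten_parameters(optima[[i]])
    y0 <- base_out[[i]]
    for (pn in parameters) {
      for (dir in c(1 + perturbation, 1 - perturbation)) {
        v <- v0
        v[pn] <- v0[pn] * dir
        p <- try(unflatten_parameters(v, renormalize = grepl("^pi_", pn)),
                 silent = TRUE)
        if (inherits(p, "try-error")) next
        y <- try(output_fn(p), silent = TRUE)
        if (inherits(y, "try-error")) next
        for (o in out_names) {
          if (!is.finite(y0[[o]]) || y0[[o]] == 0) {
            skipped <- c(skipped, sprintf("patient %d, %s", i, o))
            next
          }
          acc[o, pn] <- acc[o, pn] + abs((y[[o]] - y0[[o]]) / y0[[o]])
          cnt[o, pn] <- cnt[o, pn] + 1
        }
      }
    }
  }
  score <- ifelse(cnt > 0, acc / cnt, 0)
  attr(score, "skipped") <- unique(skipped)
  score
}

#' Scalar model outputs used by the sensitivity analyses
#'
#' Simulates model `model_id` and returns the Fig-5-style output set:
#' `cmax`, `tmax`, `auc`, `luganoResponse` (ordinal CR=0 .. PD=3) and
#' `propTmrSizeChange`.
#'
#' @param params A [patient_parameters()].
#' @param model_id Model layer (default 5).
#' @param t_grid Time grid, days.
#' @return Named numeric vector.
#' @export
model_outputs <- function(params, model_id = 5, t_grid = 0:30) {
  tr <- simulate_model(model_id, params, t_grid)
  d <- derived_outputs(tr)
  c(cmax = d$cmax, tmax = d$tmax, auc = d$auc,
    luganoResponse = if (is.na(d$lugano_response)) NA_real_
                     else as.numeric(response_ordinal(d$lugano_response)),
    propTmrSizeChange = d$prop_tumour_size_change)
}

#' Evaluate model outputs over a parameter sample matrix
#'
#' Each row's named columns override the corresponding flat parameters of
#' `base` (a `dummy` column, if present, is ignored by the model); rows
#' whose simulation fails yield `NA` outputs (the downstream estimators
#' impute them).
#'
#' @param X Data frame of flat parameter values (columns named as in
#'   [parameter_names()], optionally plus `dummy`).
#' @param base Baseline [patient_parameters()] for unvaried parameters.
#' @param model_id,t_grid Passed to [model_outputs()].
#' @return Matrix `nrow(X)` x 5 of outputs.
#' @export
evaluate_design <- function(X, base = patient_parameters(), model_id = 5,
                            t_grid = 0:30) {
  v0 <- flatten_parameters(base)
  pcols <- intersect(colnames(X), parameter_names())
  out <- matrix(NA_real_, nrow(X), 5,
                dimnames = list(NULL, c("cmax", "tmax", "auc",
                                        "luganoResponse",
                                        "propTmrSizeChange")))
  for (i in seq_len(nrow(X))) {
    v <- v0
    v[pcols] <- as.numeric(X[i, pcols])
    p <- try(unflatten_parameters(v, renormalize = TRUE), silent = TRUE)
    if (inherits(p, "try-error")) next
    y <- try(model_outputs(p, model_id, t_grid), silent = TRUE)
    if (!inherits(y, "try-error")) out[i, ] <- y
  }
  out
}

#' Parameter bounds for global sensitivity from a population model
#'
#' Mean +/- `k` standard deviations on each parameter's latent
#' (transform) scale, mapped back to the natural scale; proportion-type
#' parameters are truncated to (0, 1).  Zero-scale (structural)
#' parameters are dropped.
#'
#' @param pop A [population_model()].
#' @param k Number of latent standard deviations (default 3).
#' @return Named list of `c(lower, upper)` bounds.
#' @export
sensitivity_bounds <- function(pop, k = 3) {
  prm <- pop$params[pop$params$scale > 0, ]
  b <- lapply(seq_len(nrow(prm)), function(j) {
    lo <- latent_to_natural(prm$family[j],
                            prm$location[j] - k * prm$scale[j])
    hi <- latent_to_natural(prm$family[j],
                            prm$location[j] + k * prm$scale[j])
    if (prm$family[j] == "normal") lo <- max(lo, 0)
    c(lo, hi)
  })
  stats::setNames(b, prm$parameter)
}

#' Bundle one method's sensitivity values
#'
#' @param method Label, e.g. `"eFAST-SI"`, `"RF-vpop"`, `"SRC-optima"`,
#'   `"local"`.
#' @param values Matrix outputs x parameters of raw sensitivity values
#'   (absolute values are taken for correlation-type methods before
#'   normalization).
#' @param dummy Optional named numeric vector (one entry per output row)
#'   of the dummy parameter's value; `NULL` for methods without a dummy.
#' @return A `sensitivity_result` object.
#' @export
sensitivity_result <- function(method, values, dummy = NULL) {
  values <- as.matrix(values)
  if (!is.null(dummy) && length(dummy) != nrow(values))
    stop("dummy must have one entry per output row")
  out <- list(method = method, values = values, dummy = dummy)
  class(out) <- "sensitivity_result"
  out
}

#' Normalize sensitivity results into a comparable heatmap matrix
#'
#' For each method-output row: subtract the dummy parameter's apparent
#' sensitivity (where the method has one), floor at 0, and divide by the
#' row maximum (an all-zero row stays zero).  Rows are labelled
#' `method.output`.
#'
#' @param results List of [sensitivity_result()] objects sharing the same
#'   parameter columns.
#' @return Matrix of normalized sensitivities in \[0, 1\].
#' @export
normalize_heatmap <- function(results) {
  rows <- list()
  for (res in results) {
    vals <- abs(res$values)
    for (r in seq_len(nrow(vals))) {
      v <- vals[r, ]
      if (!is.null(res$dummy)) v <- pmax(v - res$dummy[r], 0)
      mx <- max(v)
      if (mx > 0) v <- v / mx
      rows[[paste(res$method, rownames(vals)[r] %||% r, sep = ".")]] <- v
    }
  }
  do.call(rbind, rows)
}
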