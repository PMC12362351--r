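default_config <- function() {
  list(
    seed = 1L,
    outdir = "cartpop_run",
    stages = c("generate", "fit", "vpop", "classify"),
    generate = list(n_patients = 8L, noise = TRUE, responder_mode = FALSE,
                    responder_factor = 1.6, missingness = 0),
    fit = list(max_patients = NULL, restarts = 2L, use_ldh = TRUE),
    vpop = list(n = 100L, observables = c("C_blood", "E_blood"),
                alteration = NULL, model_id = 5L),
    sensitivity = list(methods = c("SRC-vpop", "RF-vpop"), n_vpop = 100L,
                       samples_per_param = 65L, resamplings = 1L),
    classify = list())
}

check_scalar <- function(x, name, type = "numeric", positive = FALSE) {
  if (length(x) != 1L || !is.finite(as.numeric(x)))
    stop("config key ", name, " must be a single finite ", type)
  if (positive && as.numeric(x) <= 0)
    stop("config key ", name, " must be > 0")
  invisible(x)
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML string, a YAML file path, or a plain list; fills
#' defaults, rejects unknown keys (with the offending key path), and
#' enforces cross-field constraints.
#'
#' @param raw Configuration as YAML text, YAML file path, or list.
#' @return A completed `run_config` list.
#' @examples
#' cfg <- validate_config(list(seed = 7, generate = list(n_patients = 4)))
#' cfg$generate$n_patients
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1L)
    raw <- if (file.exists(raw)) yaml::read_yaml(raw)
           else yaml::yaml.load(raw)
  if (is.null(raw)) raw <- list()
  stopifnot(is.list(raw))
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, raw, keep.null = TRUE)
  for (blk in c("generate", "fit", "vpop", "sensitivity", "classify")) {
    if (!is.null(raw[[blk]])) {
      bad <- setdiff(names(raw[[blk]]), names(def[[blk]]))
      if (length(bad))
        stop("unknown config key(s): ",
             paste(paste0(blk, ".", bad), collapse = ", "))
    }
  }
  check_scalar(cfg$seed, "seed", "integer")
  bad_stage <- setdiff(cfg$stages, names(def)[-(1:3)])
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  check_scalar(cfg$generate$n_patients, "generate.n_patients",
               positive = TRUE)
  if (cfg$generate$missingness < 0 || cfg$generate$missingness >= 1)
    stop("config key generate.missingness must lie in [0, 1)")
  check_scalar(cfg$vpop$n, "vpop.n", positive = TRUE)
  if (!is.null(cfg$vpop$alteration)) {
    alt <- cfg$vpop$alteration
    if (!all(c("parameter", "mode", "factor") %in% names(alt)))
      stop("config key vpop.alteration needs parameter, mode, factor")
    if (!alt$parameter %in% parameter_names())
      stop("config key vpop.alteration.parameter is unknown: ",
           alt$parameter)
  }
  if ("vpop" %in% cfg$stages && !"fit" %in% cfg$stages &&
      !"generate" %in% cfg$stages)
    stop("stage vpop needs a population model: include fit or generate")
  class(cfg) <- c("run_config", "list")
  cfg
}

manifest_row <- function(stage, file, status = "ok") {
  data.frame(stage = stage, file = file, status = status)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the canned end-to-end experiment
#'
#' Chains the configured stages in order generate -> fit -> vpop ->
#' sensitivity -> classify, each stage consuming the previous stage's
#' outputs, writing all artifacts under `config$outdir` together with a
#' manifest and a provenance record (config hash, seed, package
#' version).  A stage failure aborts the downstream stages; the manifest
#' marks partial completion.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @return List with `status` (`"ok"` or `"partial"`), `manifest` (data
#'   frame of files written) and `outdir`, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  status <- "ok"
  ds <- NULL
  pop <- NULL
  vp <- NULL

  stages <- intersect(c("generate", "fit", "vpop", "sensitivity",
                        "classify"), cfg$stages)
  for (stage in stages) {
    res <- tryCatch({
      if (stage == "generate") {
        g <- cfg$generate
        ds <- generate_cohort(n_patients = g$n_patients,
                               seed = derive_seed(cfg$seed, "generate"),
                               noise = g$noise,
                               responder_mode = g$responder_mode,
                               responder_factor = g$responder_factor)
        if (g$missingness > 0)
          ds <- degrade(ds, g$missingness,
                         derive_seed(cfg$seed, "generate"))
        ddir <- file.path(cfg$outdir, "data")
        write_cohort(ds, ddir)
        manifest[[length(manifest) + 1L]] <-
          manifest_row("generate", file.path(ddir, paste0(
            c("observations", "lesions", "covariates", "truth", "groups"),
            ".csv")))
        pop <- ds$truth_population
      } else if (stage == "fit") {
        if (is.null(ds)) stop("fit stage needs generated data")
        ids <- unique(ds$observations$patient_id)
        if (!is.null(cfg$fit$max_patients))
          ids <- utils::head(ids, cfg$fit$max_patients)
        ctrl <- fit_control(restarts = cfg$fit$restarts,
                            seed = derive_seed(cfg$seed, "fit"),
                            use_ldh = cfg$fit$use_ldh)
        fits <- lapply(ids, function(id)
          fit_sequential(patient_observations(ds, id), control = ctrl))
        flat <- do.call(rbind, lapply(seq_along(ids), function(i)
          data.frame(patient_id = ids[i],
                     parameter = parameter_names(),
                     value = unname(flatten_parameters(fits[[i]]$params)))))
        fpath <- file.path(cfg$outdir, "individual_parameters.csv")
        utils::write.csv(flat, fpath, row.names = FALSE)
        pop <- fit_population(lapply(fits, function(f) f$params))
        ppath <- file.path(cfg$outdir, "population_model.yaml")
        write_population_model(pop, ppath)
        manifest[[length(manifest) + 1L]] <-
          manifest_row("fit", c(fpath, ppath))
      } else if (stage == "vpop") {
        if (is.null(pop)) stop("vpop stage needs a population model")
        vcfg <- cfg$vpop
        vp <- draw_vpop(pop, vcfg$n, derive_seed(cfg$seed, "vpop"))
        bands <- vpop_outputs(vp, model_id = vcfg$model_id,
                              observables = vcfg$observables,
                              seed = derive_seed(cfg$seed, "vpop"))
        paths <- file.path(cfg$outdir, "vpop_bands.csv")
        utils::write.csv(bands, paths[1], row.names = FALSE)
        if (!is.null(vcfg$alteration)) {
          alt <- vcfg$alteration
          vp2 <- alter_parameters(vp, alt$parameter, alt$factor, alt$mode)
          bands2 <- vpop_outputs(vp2, model_id = vcfg$model_id,
                                 observables = vcfg$observables,
                                 seed = derive_seed(cfg$seed, "vpop"))
          p2 <- file.path(cfg$outdir, "vpop_bands_altered.csv")
          utils::write.csv(bands2, p2, row.names = FALSE)
          paths <- c(paths, p2)
        }
        manifest[[length(manifest) + 1L]] <- manifest_row("vpop", paths)
      } else if (stage == "sensitivity") {
        if (is.null(pop)) stop("sensitivity stage needs a population model")
        scfg <- cfg$sensitivity
        seed_s <- derive_seed(cfg$seed, "sensitivity")
        vps <- draw_vpop(pop, scfg$n_vpop, seed_s)
        Xv <- t(vapply(vps, flatten_parameters,
                       numeric(length(parameter_names()))))
        keep <- apply(Xv, 2, function(x) diff(range(x)) > 0)
        Xv <- as.data.frame(Xv[, keep, drop = FALSE])
        set.seed(seed_s)
        Xv$dummy <- stats::runif(nrow(Xv))
        Yv <- evaluate_design(Xv, model_id = 5)
        rows <- list()
        for (m in scfg$methods) {
          vals <- switch(m,
            `SRC-vpop` = sapply(colnames(Xv), function(pn)
              sapply(colnames(Yv), function(o)
                abs(spearman_sensitivity(Xv[, pn, drop = FALSE],
                                         Yv[, o])))),
            `RF-vpop` = t(sapply(colnames(Yv), function(o)
              rf_importance(Xv, Yv[, o], seed = seed_s))),
            stop("pipeline sensitivity method not supported: ", m))
          if (m == "SRC-vpop") {
            vals <- matrix(vals, nrow = ncol(Yv),
                           dimnames = list(colnames(Yv), colnames(Xv)))
          }
          for (o in rownames(vals))
            rows[[length(rows) + 1L]] <- data.frame(
              method = m, output = o,
              parameter = colnames(vals),
              raw_value = unname(vals[o, ]))
        }
        sens <- do.call(rbind, rows)
        spath <- file.path(cfg$outdir, "sensitivity.csv")
        utils::write.csv(sens, spath, row.names = FALSE)
        manifest[[length(manifest) + 1L]] <-
          manifest_row("sensitivity", spath)
      } else if (stage == "classify") {
        if (is.null(ds)) stop("classify stage needs generated data")
        les <- ds$lesions
        cls <- classify_cohort(data.frame(
          patient_id = les$patient_id, lesion_id = les$lesion_id,
          baseline_d = les$baseline_d,
          nadir_d = pmin(les$baseline_d, les$final_d),
          current_d = les$final_d, new_lesion = FALSE))
        cpath <- file.path(cfg$outdir, "response.csv")
        utils::write.csv(cls, cpath, row.names = FALSE)
        manifest[[length(manifest) + 1L]] <-
          manifest_row("classify", cpath)
      }
      NULL
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status <- "partial"
      manifest[[length(manifest) + 1L]] <-
        manifest_row(stage, NA_character_,
                     paste0("failed: ", conditionMessage(res)))
      warning("stage ", stage, " failed (downstream stages aborted): ",
              conditionMessage(res))
      break
    }
  }
  man <- do.call(rbind, manifest)
  prov <- data.frame(config_hash = config_hash(cfg), seed = cfg$seed,
                     package_version =
                       as.character(utils::packageVersion("cartpop")))
  utils::write.csv(man, file.path(cfg$outdir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(prov, file.path(cfg$outdir, "provenance.csv"),
                   row.names = FALSE)
  invisible(list(status = status, manifest = man, outdir = cfg$outdir))
}
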