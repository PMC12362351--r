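#' Patient parameter sets for the hierarchical CAR T-cell models
#'
#' A `patient_parameters` object holds every rate, partition constant and
#' initial condition needed by the five model layers.  Units follow the
#' conventions used throughout the package: times in days, cell counts per
#' 5.3 L of blood (average adult blood volume) for blood compartments and
#' absolute cells for the lesion, lesion geometry in cm.
#'
#' Phenotype order is always naive, central memory (CM), effector memory
#' (EM), terminal effector (EFF): the irreversible differentiation chain.
#'
#' @param rho0 Initial antigen-independent (lymphodepletion-driven)
#'   proliferation rate, 1/day.  Shared by endogenous and CAR T-cells.
#' @param gamma Exponential decay rate of the antigen-independent
#'   proliferation rate, 1/day.
#' @param delta T-cell death rate (shared endogenous/CAR), 1/day.
#' @param rho_a Maximal antigen-driven CAR proliferation rate, 1/day.
#' @param K_half CD19+ lesion cell count at half-maximal antigen
#'   stimulation, cells.
#' @param g_tumour Net lesion B-cell growth rate, 1/day.
#' @param kappa_p Length-4 vector of per-phenotype killing rate constants
#'   (naive, CM, EM, EFF), 1/(cell day).  By default only effector-lineage
#'   cells kill.
#' @param phi Lesion:blood CAR T-cell partition ratio (dimensionless);
#'   the lesion CAR count is always `phi` times the blood count.
#' @param alpha Length-3 vector of differentiation rates
#'   naive->CM->EM->EFF, 1/day, shared by endogenous and CAR cells.
#' @param E0 Initial blood endogenous T-cell count, cells per 5.3 L.
#' @param C0 Initial blood CAR T-cell count, cells per 5.3 L.
#' @param B0 Initial lesion CD19+ cell count, cells.
#' @param pi_endo0,pi_car0 Length-4 initial phenotype proportion vectors
#'   (sum to 1) for endogenous and CAR T-cells.
#' @param B_blood_loq Constant blood CD19+ count pinned at the assay limit
#'   of quantitation, cells per 5.3 L.
#' @param v_cell Volume per tumour cell, cm^3.
#'
#' @return An object of class `patient_parameters` (a validated list).
#' @examples
#' p <- patient_parameters()
#' p$rho0
#' @export
patient_parameters <- function(rho0 = 0.6, gamma = 0.12, delta = 0.3,
                               rho_a = 0.4, K_half = 1e10, g_tumour = 0.02,
                               kappa_p = c(0, 0, 0, 1e-8),
                               phi = 0.5,
                               alpha = c(0.03, 0.05, 0.08),
                               E0 = 3e8, C0 = 7e7, B0 = 5e10,
                               pi_endo0 = c(0.30, 0.35, 0.25, 0.10),
                               pi_car0 = c(0.25, 0.40, 0.25, 0.10),
                               B_blood_loq = 5.3e6, v_cell = 1e-9) {
  p <- list(rho0 = rho0, gamma = gamma, delta = delta, rho_a = rho_a,
            K_half = K_half, g_tumour = g_tumour,
            kappa_p = as.numeric(kappa_p), phi = phi,
            alpha = as.numeric(alpha),
            E0 = E0, C0 = C0, B0 = B0,
            pi_endo0 = as.numeric(pi_endo0), pi_car0 = as.numeric(pi_car0),
            B_blood_loq = B_blood_loq, v_cell = v_cell)
  class(p) <- "patient_parameters"
  validate_parameters(p)
  p
}

#' Validate a patient parameter set
#'
#' Checks non-negativity of all rates and counts, strict positivity of
#' `phi`, `K_half` and `v_cell`, and that both phenotype proportion vectors
#' lie on the unit simplex (entries in \[0, 1\] summing to 1 within 1e-9).
#'
#' @param p A `patient_parameters` object or plain list with the same fields.
#' @return `p`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_parameters <- function(p) {
  rates <- c(p$rho0, p$gamma, p$delta, p$rho_a, p$g_tumour, p$kappa_p,
             p$alpha)
  counts <- c(p$E0, p$C0, p$B0, p$B_blood_loq)
  if (any(!is.finite(unlist(p[PARAM_SCALARS], use.names = FALSE))))
    stop("non-finite parameter value")
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (p$phi <= 0) stop("phi must be > 0")
  if (p$K_half <= 0) stop("K_half must be > 0")
  if (p$v_cell <= 0) stop("v_cell must be > 0")
  if (length(p$kappa_p) != 4L) stop("kappa_p must have 4 entries")
  if (length(p$alpha) != 3L) stop("alpha must have 3 entries")
  for (nm in c("pi_endo0", "pi_car0")) {
    v <- p[[nm]]
    if (length(v) != 4L) stop(nm, " must have 4 entries")
    if (any(v < 0) || any(v > 1)) stop(nm, " entries must lie in [0, 1]")
    if (abs(sum(v) - 1) > 1e-9) stop(nm, " must sum to 1 (within 1e-9)")
  }
  invisible(p)
}

# fields that are scalar or numeric-vector valued (all of them)
PARAM_SCALARS <- c("rho0", "gamma", "delta", "rho_a", "K_half", "g_tumour",
                   "kappa_p", "phi", "alpha", "E0", "C0", "B0",
                   "pi_endo0", "pi_car0", "B_blood_loq", "v_cell")

# canonical flat (scalar-per-entry) parameter names, the vocabulary used by
# population models, alteration experiments, sensitivity analyses and fits
PHENO_NAMES <- c("naive", "cm", "em", "eff")

#' Flat parameter name vocabulary
#'
#' Vector-valued fields of [patient_parameters()] are expanded into scalar
#' entries (`kappa_naive` ... `kappa_eff`, `alpha_1..3`,
#' `pi_endo0_naive` ... `pi_car0_eff`) so that population distributions,
#' alterations and sensitivity methods can address every scalar by name.
#'
#' @return Character vector of the 27 flat parameter names.
#' @export
parameter_names <- function() {
  c("rho0", "gamma", "delta", "rho_a", "K_half", "g_tumour",
    paste0("kappa_", PHENO_NAMES), "phi",
    paste0("alpha_", 1:3), "E0", "C0", "B0",
    paste0("pi_endo0_", PHENO_NAMES), paste0("pi_car0_", PHENO_NAMES),
    "B_blood_loq", "v_cell")
}

#' Flatten a patient parameter set to a named numeric vector
#' @param p A `patient_parameters` object.
#' @return Named numeric vector over [parameter_names()].
#' @export
flatten_parameters <- function(p) {
  v <- c(p$rho0, p$gamma, p$delta, p$rho_a, p$K_half, p$g_tumour,
         p$kappa_p, p$phi, p$alpha, p$E0, p$C0, p$B0,
         p$pi_endo0, p$pi_car0, p$B_blood_loq, p$v_cell)
  names(v) <- parameter_names()
  v
}

#' Rebuild a patient parameter set from a named flat vector
#'
#' @param v Named numeric vector over [parameter_names()].
#' @param renormalize Renormalize each phenotype proportion vector to sum
#'   to 1 (after capping entries at 1) before validation.  Used after
#'   parameter alterations that push a proportion off the simplex.
#' @return A validated `patient_parameters` object.
#' @export
unflatten_parameters <- function(v, renormalize = FALSE) {
  need <- setdiff(parameter_names(), names(v))
  if (length(need)) stop("missing parameters: ", paste(need, collapse = ", "))
  pe <- unname(v[paste0("pi_endo0_", PHENO_NAMES)])
  pc <- unname(v[paste0("pi_car0_", PHENO_NAMES)])
  if (renormalize) {
    pe <- pmin(pmax(pe, 0), 1); pe <- pe / sum(pe)
    pc <- pmin(pmax(pc, 0), 1); pc <- pc / sum(pc)
  }
  patient_parameters(
    rho0 = v[["rho0"]], gamma = v[["gamma"]], delta = v[["delta"]],
    rho_a = v[["rho_a"]], K_half = v[["K_half"]],
    g_tumour = v[["g_tumour"]],
    kappa_p = unname(v[paste0("kappa_", PHENO_NAMES)]),
    phi = v[["phi"]],
    alpha = unname(v[paste0("alpha_", 1:3)]),
    E0 = v[["E0"]], C0 = v[["C0"]], B0 = v[["B0"]],
    pi_endo0 = pe, pi_car0 = pc,
    B_blood_loq = v[["B_blood_loq"]], v_cell = v[["v_cell"]])
}

#' @export
print.patient_parameters <- function(x, ...) {
  cat("<patient_parameters>\n")
  v <- flatten_parameters(x)
  print(signif(v, 4))
  invisible(x)
}
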