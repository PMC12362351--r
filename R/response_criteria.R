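#' Lesion history for response classification
#'
#' Per-lesion longest-diameter records (baseline, nadir, current) plus
#' total sum-of-product-of-diameters (SPD) at baseline and at the current
#' evaluation.  The SPDs default to the sums of squared diameters but may
#' be supplied independently (e.g. when the SPD comes from imaging and the
#' diameters from a model).
#'
#' @param baseline_d,nadir_d,current_d Numeric vectors (one entry per
#'   lesion) of longest diameters in cm; the nadir is the smallest
#'   diameter observed at any earlier evaluation.
#' @param new_lesion Has any new lesion appeared since baseline?
#' @param baseline_spd,current_spd Total SPD in cm^2.
#' @return A `lesion_history` object.
#' @examples
#' lesion_history(baseline_d = 3, nadir_d = 1, current_d = 1.2)
#' @export
lesion_history <- function(baseline_d, nadir_d, current_d,
                           new_lesion = FALSE,
                           baseline_spd = sum(baseline_d^2),
                           current_spd = sum(current_d^2)) {
  n <- length(baseline_d)
  stopifnot(length(nadir_d) == n, length(current_d) == n,
            all(baseline_d >= 0), all(nadir_d >= 0), all(current_d >= 0),
            baseline_spd >= 0, current_spd >= 0)
  if (any(nadir_d > baseline_d + 1e-12))
    stop("nadir diameter cannot exceed the baseline diameter")
  h <- list(baseline_d = baseline_d, nadir_d = nadir_d,
            current_d = current_d, new_lesion = isTRUE(new_lesion),
            baseline_spd = baseline_spd, current_spd = current_spd)
  class(h) <- "lesion_history"
  h
}

# the PD test for one lesion: spd_change is the relative change of the
# SPD measure the test applies to (total SPD for single-lesion patients,
# the lesion's own d^2 for per-lesion evaluation in multi-lesion patients)
pd_single <- function(spd_change, current_d, growth_from_nadir) {
  grow_thr <- if (current_d < 2) 0.5 else 1.0
  spd_change >= 0.5 && current_d > 1.5 && growth_from_nadir >= grow_thr
}

#' Simplified 2014 Lugano classification, single lesion
#'
#' Classifies a single-lesion history as CR, PR, SD or PD using the
#' simplified diameter-based rules:
#' \itemize{
#'   \item PD if the SPD has increased by at least 50\% from baseline, the
#'     longest diameter is greater than 1.5 cm, and the diameter has grown
#'     from nadir by at least 0.5 cm (when the current diameter is below
#'     2 cm) or 1.0 cm (otherwise);
#'   \item CR if the SPD has fallen by at least 50\% and the longest
#'     diameter is less than 1.5 cm;
#'   \item PR if the SPD has fallen by at least 50\%;
#'   \item SD otherwise.
#' }
#' PD is evaluated first, then CR, then PR; SD is the residual class.
#'
#' @param h A [lesion_history()] with exactly one lesion and
#'   `baseline_spd > 0`.
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @examples
#' classify_single(lesion_history(3, 1, 1.0))   # CR
#' classify_single(lesion_history(3, 1, 2.0, baseline_spd = 10,
#'                                current_spd = 4))  # PR
#' @export
classify_single <- function(h) {
  stopifnot(inherits(h, "lesion_history"), length(h$baseline_d) == 1L)
  if (h$baseline_spd <= 0)
    stop("baseline SPD must be > 0 (relative change undefined)")
  spd_change <- (h$current_spd - h$baseline_spd) / h$baseline_spd
  growth <- h$current_d - h$nadir_d
  if (pd_single(spd_change, h$current_d, growth)) return("PD")
  if (spd_change <= -0.5 && h$current_d < 1.5) return("CR")
  if (spd_change <= -0.5) return("PR")
  "SD"
}

#' Simplified 2014 Lugano classification, multiple lesions
#'
#' PD if a new lesion has appeared or any single lesion satisfies the PD
#' conditions (evaluated on that lesion's own product of diameters);
#' CR requires the total SPD to have fallen by at least 50\% and every
#' lesion's longest diameter to be below 1.5 cm; PR requires the total
#' SPD reduction alone; SD otherwise.
#'
#' @param h A [lesion_history()] with two or more lesions and
#'   `baseline_spd > 0`.
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
classify_multi <- function(h) {
  stopifnot(inherits(h, "lesion_history"), length(h$baseline_d) >= 2L)
  if (h$baseline_spd <= 0)
    stop("baseline SPD must be > 0 (relative change undefined)")
  if (h$new_lesion) return("PD")
  per_lesion_pd <- mapply(function(b, nd, cd) {
    if (b <= 0) return(FALSE)
    pd_single((cd^2 - b^2) / b^2, cd, cd - nd)
  }, h$baseline_d, h$nadir_d, h$current_d)
  if (any(per_lesion_pd)) return("PD")
  spd_change <- (h$current_spd - h$baseline_spd) / h$baseline_spd
  if (spd_change <= -0.5 && all(h$current_d < 1.5)) return("CR")
  if (spd_change <= -0.5) return("PR")
  "SD"
}

#' Classify a lesion history (dispatching on the number of lesions)
#' @param h A [lesion_history()].
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
classify_lesions <- function(h) {
  if (length(h$baseline_d) == 1L) classify_single(h) else classify_multi(h)
}

#' Ordinal coding of response classes
#'
#' CR = 0 < PR = 1 < SD = 2 < PD = 3; used when a numeric response target
#' is needed (sensitivity analyses, responder ranking).
#'
#' @param class Character vector of response classes.
#' @return Integer vector.
#' @export
response_ordinal <- function(class) {
  codes <- c(CR = 0L, PR = 1L, SD = 2L, PD = 3L)
  unname(codes[class])
}

#' Classify many patients from a lesion-history table
#'
#' @param df Data frame with columns `patient_id, lesion_id, baseline_d,
#'   nadir_d, current_d, new_lesion`.
#' @return Data frame `patient_id, response`.
#' @export
classify_cohort <- function(df) {
  need <- c("patient_id", "lesion_id", "baseline_d", "nadir_d",
            "current_d", "new_lesion")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ids <- unique(df$patient_id)
  res <- vapply(ids, function(id) {
    sub <- df[df$patient_id == id, ]
    classify_lesions(lesion_history(sub$baseline_d, sub$nadir_d,
                                    sub$current_d,
                                    new_lesion = any(sub$new_lesion)))
  }, character(1))
  data.frame(patient_id = ids, response = res)
}
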