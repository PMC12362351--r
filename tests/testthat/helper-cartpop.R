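# shared fixtures, built in code

# a patient with gentle dynamics (fast to integrate, nothing degenerate)
quick_params <- function(...) {
  patient_parameters(...)
}

# single-lesion history with independently specified SPD change and
# diameter geometry, as used throughout the classifier tests
single_history <- function(spd_change, current_d, growth_from_nadir = 0,
                           baseline_spd = 10) {
  nadir <- max(current_d - growth_from_nadir, 0)
  lesion_history(baseline_d = max(current_d, nadir, 5),
                 nadir_d = nadir, current_d = current_d,
                 baseline_spd = baseline_spd,
                 current_spd = baseline_spd * (1 + spd_change))
}

# noise-free model-1 observation table from the analytic solution
model1_obs <- function(p, times = 0:30) {
  data.frame(time_day = times, observable = "E_blood",
             value = model1_closed_form(p, times))
}

# tiny cohorts are expensive to regenerate; cache per test run
local_cohort <- local({
  cache <- list()
  function(n, seed, noise = TRUE, ...) {
    key <- paste(n, seed, noise, ...)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_cohort(n_patients = n, seed = seed,
                                       noise = noise, ...)
    cache[[key]]
  }
})
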