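# Heavier simulated cohorts shared between acceptance checks, built once
# per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .cohort_cache))
    assign(name, build(), envir = .cohort_cache)
  get(name, envir = .cohort_cache)
}

# control / KCl / recovery design at the study scale (30 cells per group)
treatment_cohort <- function() cached("treatment", function() {
  cfg <- cohort_config(n_per_group = 30,
                       groups = c("control", "kcl", "kcl_recovery"),
                       seed = 20260901,
                       families = c("cc_zero", "cc_ramp", "cc_step"),
                       compute_truth = FALSE)
  out <- cohort_profiles(cfg)
  out$cells <- out$cells[!is.na(out$cells$included) & out$cells$included, ]
  out
})

# 30 control cells with the 1 pA fine-grid ground truth
truth_cohort <- function() cached("truth", function() {
  cfg <- cohort_config(n_per_group = 30, groups = "control",
                       seed = 20260902,
                       families = c("cc_ramp", "cc_step"),
                       compute_truth = TRUE)
  cohort_profiles(cfg)
})
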