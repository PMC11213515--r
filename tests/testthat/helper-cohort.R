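# Shared synthetic cohorts, generated once per test run. Seed 7 for the
# full CF-piglet scenario is fixed as part of the study conditions.

.cohort_cache <- new.env(parent = emptyenv())

cf_cohort <- function() {
  if (is.null(.cohort_cache$cf)) {
    truth <- synthetic_truth("cf_piglet")
    .cohort_cache$cf <- generate_cohort(truth, n_pairs = 8, seed = 7)
  }
  .cohort_cache$cf
}

cf_results <- function() {
  if (is.null(.cohort_cache$cf_res))
    .cohort_cache$cf_res <- analyze_cohort(cf_cohort())
  .cohort_cache$cf_res
}

demo_cohort <- function(seed = 11) {
  generate_cohort(synthetic_truth("demo"), n_pairs = 4, seed = seed)
}

withr_like_tempdir <- function() {
  d <- tempfile("avflux-test-")
  dir.create(d)
  d
}

# collapsed single-replicate abundance table from a named site -> value map,
# for one animal and metabolite
tiny_table <- function(values, animal = "a1", metabolite = "m1") {
  data.frame(animal_id = animal, site_id = names(values),
             metabolite_id = metabolite, ion_count = unname(values))
}
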