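test_that("cohort generation is deterministic given the seed", {
  truth <- synthetic_truth("demo")
  a <- generate_cohort(truth, n_pairs = 3, seed = 99)
  b <- generate_cohort(truth, n_pairs = 3, seed = 99)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$qc, b$qc)
  expect_identical(a$tracer, b$tracer)
  c_ <- generate_cohort(truth, n_pairs = 3, seed = 100)
  expect_false(identical(a$abundance$ion_count, c_$abundance$ion_count))
})

test_that("invalid truth parameters refuse to generate", {
  truth <- synthetic_truth("demo")
  truth$reabsorption$efficiency_cf[1] <- 1.5
  expect_error(generate_cohort(truth, n_pairs = 3, seed = 1),
               "invariants violated")
  truth2 <- synthetic_truth("demo")
  expect_error(generate_cohort(truth2, n_pairs = 3), "seed is mandatory")
})

test_that("noise-free cohorts round-trip per-animal fluxes to machine precision", {
  truth <- synthetic_truth("recovery", measurement_cv = 0)
  cohort <- generate_cohort(truth, n_pairs = 4, seed = 5)
  tab <- collapse_replicates(
    normalize_internal_standard(cohort$abundance,
                                truth$internal_standard))
  fit <- avflux(tab, cohort$design, cohort$map,
                metabolites = unique(truth$metabolites$metabolite_id))
  s <- fit$samples
  key <- paste(s$organ, s$metabolite_id, s$animal_id)
  rf <- cohort$realized_flux
  truth_key <- paste(rf$organ, rf$metabolite_id, rf$animal_id)
  expect_equal(s$log2_va, rf$log2_flux[match(key, truth_key)],
               tolerance = 1e-9)
})

test_that("QC injections reproduce the programmed technical CV", {
  truth <- synthetic_truth("null")
  cohort <- generate_cohort(truth, n_pairs = 4, seed = 19)
  qc <- cohort$qc
  cvs <- vapply(split(qc$ion_count, qc$metabolite_id),
                function(v) sd(v) / mean(v), numeric(1))
  # per-metabolite estimates at 10 injections are noisy; the panel median
  # must sit within 20% of the programmed value
  expect_equal(unname(stats::median(cvs)), truth$measurement_cv,
               tolerance = 0.2)
})

test_that("deliberately noisy metabolites are excluded by the QC filter", {
  qc_res <- cf_results()$qc
  bad <- sprintf("filler_%02d", 46:50)
  expect_true(all(qc_res$dropped %in% bad))
  expect_gte(length(qc_res$dropped), 3)
  expect_false(any(c("glucose", "alanine", "C20:4") %in% qc_res$dropped))
})

test_that("recovery scoring refuses mismatched truth", {
  res <- cf_results()
  truth <- cf_cohort()$truth
  rec <- evaluate_recovery(res, truth)
  expect_gte(rec$flux_sign_accuracy, 0.95)
  shuffled <- truth
  shuffled$flux$log2_flux <- rev(shuffled$flux$log2_flux)
  expect_error(evaluate_recovery(res, shuffled), "refusing to score")
  other <- synthetic_truth("demo")
  expect_error(evaluate_recovery(res, other), "refusing to score")
})

test_that("recovery degrades monotonically with measurement noise", {
  accs <- vapply(c(0, 0.05, 0.20, 0.50), function(cv) {
    truth <- synthetic_truth("recovery", measurement_cv = cv)
    cohort <- generate_cohort(truth, n_pairs = 8, seed = 29)
    tab <- collapse_replicates(
      normalize_internal_standard(cohort$abundance,
                                  truth$internal_standard))
    fit <- avflux(tab, cohort$design, cohort$map,
                  metabolites = unique(truth$metabolites$metabolite_id))
    res <- list(fit = fit, graph = exchange_graph(fit),
                truth_uid = cohort$truth$uid)
    evaluate_recovery(res, truth)$flux_sign_accuracy
  }, numeric(1))
  expect_equal(accs[1], 1)  # noise-free: perfect
  expect_true(all(diff(accs) <= 0.02))  # non-increasing up to sampling noise
})
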