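test_that("urine/artery ratio formula and invariances", {
  expect_equal(urine_artery_ratio(10, 10, 1), 1)
  expect_equal(urine_artery_ratio(100, 50, 10), 0.2)
  # doubling urine and creatinine together changes nothing
  expect_equal(urine_artery_ratio(20, 20, 1), urine_artery_ratio(10, 10, 1))
  # nonpositive inputs are missing, not infinite
  expect_true(is.na(urine_artery_ratio(0, 10, 1)))
  expect_true(is.na(urine_artery_ratio(10, 0, 1)))
  expect_true(is.na(urine_artery_ratio(10, 10, 0)))
})

test_that("reabsorption contrast flags programmed genotype differences", {
  set.seed(61)
  mk <- function(g, ratios) data.frame(
    animal_id = paste0(g, seq_along(ratios)), genotype = g,
    metabolite_id = "m1", ratio = ratios)
  same <- rbind(mk("WT", rep(0.1, 8)), mk("CF", rep(0.1, 8)))
  r <- reabsorption_contrast(same)
  expect_equal(r$direction, "none")
  expect_equal(r$p, 1)
  shifted <- rbind(mk("WT", 0.1 * exp(rnorm(8, 0, 0.05))),
                   mk("CF", 0.4 * exp(rnorm(8, 0, 0.05))))
  r <- reabsorption_contrast(shifted)
  expect_equal(r$direction, "CF_higher")
  expect_lt(r$p, 0.01)
  expect_equal(r$geomean_cf / r$geomean_wt, 4, tolerance = 0.2)
})

test_that("permuted genotype labels reject at about the nominal rate", {
  set.seed(67)
  ratios <- 0.2 * exp(rnorm(16, 0, 0.3))
  hits <- 0L; n_perm <- 200L
  for (i in seq_len(n_perm)) {
    g <- sample(rep(c("WT", "CF"), each = 8))
    d <- data.frame(animal_id = paste0("a", 1:16), genotype = g,
                    metabolite_id = "m1", ratio = ratios)
    if (reabsorption_contrast(d)$direction != "none") hits <- hits + 1L
  }
  expect_gt(hits / n_perm, 0.005)
  expect_lt(hits / n_perm, 0.12)
})

test_that("tracer leakage index is a pure ratio with sensible edge cases", {
  expect_equal(tracer_leakage_index(100, 50, 10), 0.2)
  expect_equal(tracer_leakage_index(0, 50, 10), 0)  # complete reabsorption
  expect_true(is.na(tracer_leakage_index(10, 50, 0)))
  # the urine concentration factor cancels out of the index
  expect_equal(tracer_leakage_index(100 * 7, 50 * 7, 10),
               tracer_leakage_index(100, 50, 10))
})

test_that("programmed 5x CF tracer leakage appears in the cohort summary", {
  tr <- cf_results()$tracer
  m <- tr$means
  expect_equal(unique(m$n), 2)           # descriptive n = 2 per genotype
  for (t_ in unique(m$tracer_id)) {
    ratio <- m$index[m$tracer_id == t_ & m$genotype == "CF"] /
      m$index[m$tracer_id == t_ & m$genotype == "WT"]
    expect_gt(ratio, 2.5)
    expect_lt(ratio, 10)
  }
})

test_that("full-cohort reabsorption analysis flags amino acids as CF-elevated", {
  rc <- cf_results()$reabsorption_contrast
  aa <- rc[rc$metabolite_id %in% c("alanine", "glycine", "proline",
                                   "leucine", "lysine"), ]
  expect_true(all(aa$direction == "CF_higher"))
  lac <- rc[rc$metabolite_id == "lactate", ]
  expect_equal(lac$direction, "CF_higher")
  glc <- rc[rc$metabolite_id == "glucose", ]
  expect_equal(glc$direction, "none")    # glucose reabsorption unimpaired
})
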