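test_that("flux classification respects the call invariants", {
  r <- classify_flux(c(0.5, 0.6, 0.55, 0.52, 0.58, 0.61, 0.57, 0.54))
  expect_equal(r$call, "release")
  expect_lt(r$p, 0.001)
  r <- classify_flux(c(-0.3, 0.3, -0.2, 0.2, -0.1, 0.1))
  expect_equal(r$call, "none")
  set.seed(17)
  r <- classify_flux(-abs(rnorm(8, 1, 0.1)))
  expect_equal(r$call, "uptake")
  r <- classify_flux(c(0.4, 0.5))  # below min_n
  expect_equal(r$call, "none")
  expect_true(is.na(r$p))
  # never release with nonpositive mean, never uptake with nonnegative mean
  set.seed(23)
  for (i in 1:200) {
    v <- rnorm(sample(3:10, 1), sample(c(-1, 0, 1), 1), runif(1, 0.01, 2))
    r <- classify_flux(v)
    if (r$call == "release") expect_gt(r$mean_log2_va, 0)
    if (r$call == "uptake") expect_lt(r$mean_log2_va, 0)
    if (r$call != "none") expect_lt(r$p, 0.05)
  }
})

test_that("avflux records are internally consistent on a synthetic cohort", {
  fit <- cf_results()$fit
  r <- fit$records
  expect_true(all(r$q >= r$p - 1e-12, na.rm = TRUE))
  rel <- r[r$call == "release", ]
  upt <- r[r$call == "uptake", ]
  expect_true(all(rel$mean_log2_va > 0 & rel$p < fit$alpha))
  expect_true(all(upt$mean_log2_va < 0 & upt$p < fit$alpha))
  expect_true(all(r$test[!is.na(r$p)] %in%
                    c("one_sample_t", "wilcoxon_signed_rank")))
  # summary counts agree with the records
  s <- summary(fit)
  i <- s$organ == "liver" & s$genotype == "WT"
  expect_equal(s$n_release[i],
               sum(r$call == "release" & r$organ == "liver" &
                     r$genotype == "WT"))
})

test_that("concentration differences use calibration and sign conventions", {
  map <- default_organ_map()
  cal <- c(m1 = 1)
  tab <- tiny_table(c(right_ventricle = 0.10, aorta = 0.27))
  expect_equal(
    flux_concentration_difference(tab, map, "lung", "a1", "m1", cal), 0.17)
  tab <- tiny_table(c(right_ventricle = 10, aorta = 2.5))
  expect_equal(
    flux_concentration_difference(tab, map, "lung", "a1", "m1", cal,
                                  as_uptake = TRUE), 7.5)
  tab <- tiny_table(c(right_ventricle = 4, aorta = 4))
  expect_equal(
    flux_concentration_difference(tab, map, "lung", "a1", "m1", cal), 0)
  expect_error(
    flux_concentration_difference(tab, map, "lung", "a1", "m2", cal),
    "no absolute calibration")
})

test_that("arterial contrast recovers paired fold changes", {
  animals <- data.frame(
    animal_id = c(sprintf("w%d", 1:8), sprintf("c%d", 1:8)),
    genotype = rep(c("WT", "CF"), each = 8),
    litter_id = rep(sprintf("l%d", 1:8), 2),
    pair_id = rep(sprintf("p%d", 1:8), 2), sex = "F")
  design <- study_design(animals, default_sites())
  set.seed(31)
  base <- runif(8, 50, 150)
  mk <- function(vals, met) data.frame(
    animal_id = animals$animal_id, site_id = "aorta", metabolite_id = met,
    ion_count = vals)
  tab <- rbind(
    mk(c(base, base), "flat"),
    mk(c(base, 2 * base * exp(rnorm(8, 0, 0.01))), "up"))
  res <- arterial_contrast(tab, design)
  expect_equal(res$mean_log2fc[res$metabolite_id == "flat"], 0)
  expect_equal(res$direction[res$metabolite_id == "flat"], "none")
  expect_equal(res$mean_log2fc[res$metabolite_id == "up"], 1,
               tolerance = 0.05)
  expect_equal(res$direction[res$metabolite_id == "up"], "increased")
  expect_lt(res$p[res$metabolite_id == "up"], 0.01)
})

test_that("programmed CF arterial shifts are recovered from the full cohort", {
  res <- cf_results()
  ct <- res$contrast
  tyr <- ct[ct$metabolite_id == "tyrosine", ]
  glu <- ct[ct$metabolite_id == "glutamate", ]
  expect_equal(tyr$direction, "decreased")
  expect_equal(tyr$mean_log2fc, log2(1 / 3), tolerance = 0.35)
  expect_equal(glu$direction, "increased")
  expect_equal(glu$mean_log2fc, 1, tolerance = 0.35)
  # tyrosine among the most decreased metabolites
  dec <- ct[order(ct$mean_log2fc), "metabolite_id"]
  expect_true("tyrosine" %in% utils::head(dec, 3))
})
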