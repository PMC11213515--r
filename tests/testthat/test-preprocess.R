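long_row <- function(animal, site, met, rep_, count)
  data.frame(animal_id = animal, site_id = site, metabolite_id = met,
             replicate = rep_, ion_count = count)

test_that("internal-standard normalization divides by the same-sample standard", {
  tab <- rbind(long_row("a1", "aorta", "m1", 1, 100),
               long_row("a1", "aorta", "std", 1, 50),
               long_row("a2", "aorta", "m1", 1, 200),
               long_row("a2", "aorta", "std", 1, 100))
  out <- normalize_internal_standard(tab, "std")
  expect_equal(out$ion_count[out$metabolite_id == "m1"], c(2, 2))
  expect_equal(out$ion_count[out$metabolite_id == "std"], c(1, 1))

  # zero standard: that sample is dropped, with a message
  tab2 <- rbind(tab, long_row("a3", "aorta", "m1", 1, 5),
                long_row("a3", "aorta", "std", 1, 0))
  expect_message(out2 <- normalize_internal_standard(tab2, "std"),
                 "dropping 1 sample")
  expect_false("a3" %in% out2$animal_id)
})

test_that("replicate collapsing takes the median with midpoint convention", {
  tab <- rbind(long_row("a1", "aorta", "m1", 1:3, c(1, 2, 10)),
               long_row("a1", "aorta", "m2", 1, 7),
               long_row("a1", "aorta", "m3", 1:2, c(4, 6)))
  out <- collapse_replicates(tab)
  val <- function(m) out$ion_count[out$metabolite_id == m]
  expect_equal(val("m1"), 2)
  expect_equal(val("m2"), 7)
  expect_equal(val("m3"), 5)
  expect_false("replicate" %in% names(out))
})

test_that("normalization and collapsing commute with global rescaling", {
  set.seed(21)
  tab <- do.call(rbind, lapply(c("a1", "a2"), function(a)
    rbind(long_row(a, "aorta", "m1", 1:3, runif(3, 50, 150)),
          long_row(a, "aorta", "std", 1:3, runif(3, 40, 60)))))
  ref <- collapse_replicates(normalize_internal_standard(tab, "std"))
  tab2 <- tab; tab2$ion_count <- tab2$ion_count * 37.5
  scaled <- collapse_replicates(normalize_internal_standard(tab2, "std"))
  expect_equal(scaled$ion_count, ref$ion_count)
})

test_that("QC CV filter computes sample CV and applies a strict threshold", {
  qc <- data.frame(
    metabolite_id = rep(c("flat", "edge", "noisy", "lonely", "zero"),
                        times = c(3, 3, 3, 1, 3)),
    injection = c(1:3, 1:3, 1:3, 1, 1:3),
    ion_count = c(10, 10, 10, 5, 10, 15, 1, 10, 19, 8, 0, 0, 0))
  expect_warning(res <- qc_cv_filter(qc), "cannot be assessed")
  rep_ <- res$report
  cv <- function(m) rep_$cv[rep_$metabolite_id == m]
  expect_equal(cv("flat"), 0)
  expect_equal(cv("edge"), 50)   # sample SD 5, mean 10; kept (strict >)
  expect_equal(cv("noisy"), 90)  # sample SD 9, mean 10; dropped
  expect_setequal(res$kept, c("flat", "edge"))
  expect_equal(res$dropped, c("noisy", "zero"))
  expect_equal(res$unassessable, "lonely")
  # the three groups partition the metabolite set
  expect_setequal(c(res$kept, res$dropped, res$unassessable),
                  unique(qc$metabolite_id))
})
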