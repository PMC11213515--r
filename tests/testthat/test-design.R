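test_that("inflow resolution applies mixture weights and stays within bounds", {
  map <- default_organ_map()
  # single-inflow organ returns the site value unchanged
  tab <- tiny_table(c(right_ventricle = 5, aorta = 9))
  expect_equal(resolve_inflow_abundance(tab, map, "lung", "a1", "m1"), 5)
  # hepatic artery 22% / portal vein 78%
  tab <- tiny_table(c(hepatic_artery = 10, portal_vein = 20))
  expect_equal(resolve_inflow_abundance(tab, map, "liver", "a1", "m1"), 17.8)
  set.seed(2)
  for (i in 1:20) {
    v <- runif(2, 0, 100)
    tab <- tiny_table(c(hepatic_artery = v[1], portal_vein = v[2]))
    r <- resolve_inflow_abundance(tab, map, "liver", "a1", "m1")
    expect_equal(r, 0.22 * v[1] + 0.78 * v[2])   # linear
    expect_gte(r, min(v)); expect_lte(r, max(v)) # convex combination
  }
  # equal inflow values collapse to that value
  tab <- tiny_table(c(hepatic_artery = 7.3, portal_vein = 7.3))
  expect_equal(resolve_inflow_abundance(tab, map, "liver", "a1", "m1"), 7.3)
})

test_that("redundant arterial references renormalize over measured sites; true mixtures do not", {
  map <- default_organ_map()
  tab <- tiny_table(c(aorta = 12))  # femoral artery unmeasured
  expect_equal(resolve_inflow_abundance(tab, map, "kidney", "a1", "m1"), 12)
  tab <- tiny_table(c(portal_vein = 20))  # hepatic artery missing: no liver value
  expect_true(is.na(resolve_inflow_abundance(tab, map, "liver", "a1", "m1")))
})

test_that("design validation reports each invariant breach and passes clean designs", {
  d <- demo_cohort()
  expect_equal(nrow(validate_design(d$design, d$map)), 0)

  animals <- data.frame(animal_id = c("a", "b"), genotype = c("WT", "WT"),
                        litter_id = "l1", pair_id = "p1", sex = "M")
  bad <- study_design(animals, default_sites())
  v <- validate_design(bad)
  expect_true(any(grepl("one WT and one CF", v$problem)))

  m <- as.data.frame(default_organ_map())
  m$weight[m$organ == "liver"] <- c(0.22, 0.68)  # sums to 0.9
  v <- validate_design(bad, organ_map(m))
  expect_true(any(grepl("sum to 1", v$problem)))

  m <- as.data.frame(default_organ_map())
  m$outflow_site[m$organ == "lung"] <- "right_ventricle"
  v <- validate_design(d$design, organ_map(m))
  expect_true(any(grepl("equals an inflow site", v$problem)))

  m <- as.data.frame(default_organ_map())
  m$outflow_site[m$organ == "kidney"] <- "no_such_vein"
  v <- validate_design(d$design, organ_map(m))
  expect_true(any(grepl("undeclared site", v$problem)))
})

test_that("log2(V/A) is antisymmetric, scale invariant and NA on nonpositive input", {
  map <- default_organ_map()
  t0 <- tiny_table(c(right_ventricle = 10, aorta = 10))
  expect_equal(compute_log2_va(t0, map, "lung", "a1", "m1"), 0)
  t1 <- tiny_table(c(right_ventricle = 10, aorta = 20))
  expect_equal(compute_log2_va(t1, map, "lung", "a1", "m1"), 1)
  # liver example: inflow resolves to 17.8
  t2 <- tiny_table(c(hepatic_artery = 10, portal_vein = 20,
                     hepatic_vein = 18.8))
  expect_equal(compute_log2_va(t2, map, "liver", "a1", "m1"),
               log2(18.8 / 17.8))
  set.seed(8)
  for (i in 1:20) {
    v <- runif(2, 1, 50)
    fwd <- compute_log2_va(tiny_table(c(right_ventricle = v[1],
                                        aorta = v[2])),
                           map, "lung", "a1", "m1")
    rev <- compute_log2_va(tiny_table(c(right_ventricle = v[2],
                                        aorta = v[1])),
                           map, "lung", "a1", "m1")
    expect_equal(fwd, -rev)                      # antisymmetry
    c_ <- runif(1, 0.1, 100)                     # per-animal scaling cancels
    sc <- compute_log2_va(tiny_table(c(right_ventricle = c_ * v[1],
                                       aorta = c_ * v[2])),
                          map, "lung", "a1", "m1")
    expect_equal(sc, fwd)
  }
  t3 <- tiny_table(c(right_ventricle = 0, aorta = 5))
  expect_true(is.na(compute_log2_va(t3, map, "lung", "a1", "m1")))
})
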