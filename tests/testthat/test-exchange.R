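# hand-built flux records for rule-level tests
rec <- function(organ, met, mean_, p, genotype = "WT")
  data.frame(organ = organ, metabolite_id = met, genotype = genotype,
             n = 8, mean_log2_va = mean_, test = "one_sample_t", p = p,
             call = ifelse(p < 0.05, ifelse(mean_ > 0, "release", "uptake"),
                           "none"), q = p)

test_that("edges require dual significance with matched signs", {
  records <- rbind(rec("liver", "m1", 0.8, 0.01),
                   rec("lung", "m1", -0.5, 0.02),
                   rec("heart", "m1", -0.2, 0.30),
                   rec("liver", "m2", 0.9, 0.001))  # release, no sink
  g <- exchange_graph(records, alpha = 0.05)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$source_organ, "liver")
  expect_equal(g$edges$sink_organ, "lung")
  expect_false("m2" %in% g$edges$metabolite_id)
})

test_that("multiple sources and sinks produce the full cross product", {
  records <- rbind(rec(c("liver", "kidney"), "m1", 0.7, 0.01),
                   rec(c("lung", "heart", "leg"), "m1", -0.7, 0.01))
  g <- exchange_graph(records, alpha = 0.05)
  expect_equal(nrow(g$edges), 6)
  expect_equal(unname(organ_exchange_counts(g, "liver")),
               c(3, 0, 3))
  expect_equal(unname(organ_exchange_counts(g, "lung")),
               c(0, 2, 2))
  m <- as.matrix(g)
  expect_equal(sum(m), 6)                       # conservation
  expect_equal(m["liver", "lung"], 1L)
  expect_warning(organ_exchange_counts(g, "gallbladder"), "not present")
})

test_that("graph construction is monotone in alpha and empty input is safe", {
  set.seed(41)
  records <- do.call(rbind, lapply(1:30, function(i)
    rec(sample(c("liver", "lung", "heart", "kidney", "leg"), 1),
        paste0("m", sample(1:8, 1)), rnorm(1), runif(1))))
  records <- unique(records[, ])
  ek <- function(g) paste(g$edges$metabolite_id, g$edges$source_organ,
                          g$edges$sink_organ)
  e01 <- ek(exchange_graph(records, alpha = 0.01))
  e05 <- ek(exchange_graph(records, alpha = 0.05))
  expect_true(all(e01 %in% e05))
  g0 <- exchange_graph(records[0, ])
  expect_equal(nrow(g0$edges), 0)
  expect_equal(sum(as.matrix(g0)), 0)
})

test_that("every emitted edge satisfies the matching rule on real fits", {
  g <- cf_results()$graph
  e <- g$edges
  expect_true(all(e$source_mean > 0 & e$source_p < g$alpha))
  expect_true(all(e$sink_mean < 0 & e$sink_p < g$alpha))
  expect_true(all(e$source_organ != e$sink_organ))
  # outgoing and incoming totals both count every edge once
  orgs <- g$organs
  for (gt in c("WT", "CF")) {
    cnt <- vapply(orgs, function(o)
      organ_exchange_counts(g, o, genotype = gt), numeric(3))
    n_edges <- sum(e$genotype == gt)
    expect_equal(sum(cnt["outgoing", ]), n_edges)
    expect_equal(sum(cnt["incoming", ]), n_edges)
  }
})
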