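#' Per-animal log2 venous/arterial ratio
#'
#' The elementary flux statistic: log2(outflow abundance / resolved inflow
#' abundance) for one organ, animal and metabolite. Positive values mean net
#' release by the organ, negative values net uptake.
#'
#' @inheritParams resolve_inflow_abundance
#' @return the log2 ratio, or `NA` when either side is missing or
#'   nonpositive (nonpositive ion counts carry no usable gradient
#'   information and the animal is excluded from that cell).
#' @export
compute_log2_va <- function(collapsed, map, organ, animal_id, metabolite_id) {
  inflow <- resolve_inflow_abundance(collapsed, map, organ, animal_id,
                                     metabolite_id)
  out_site <- outflow_site_of(map, organ)
  rows <- collapsed$animal_id == animal_id &
    collapsed$metabolite_id == metabolite_id &
    collapsed$site_id == out_site
  outflow <- if (any(rows)) collapsed$ion_count[rows][1] else NA_real_
  if (is.na(inflow) || is.na(outflow) || inflow <= 0 || outflow <= 0)
    return(NA_real_)
  log2(outflow / inflow)
}

# value[site, animal, metabolite] array from a collapsed table
abundance_array <- function(collapsed) {
  tapply(collapsed$ion_count,
         list(site_id = collapsed$site_id,
              animal_id = collapsed$animal_id,
              metabolite_id = collapsed$metabolite_id),
         FUN = mean)
}

# animals x metabolites matrix of resolved inflow for one organ
inflow_matrix <- function(arr, map, organ) {
  e <- map[map$organ == organ, , drop = FALSE]
  sites <- intersect(e$inflow_site, dimnames(arr)[[1]])
  if (length(sites) == 0L)
    return(matrix(NA_real_, dim(arr)[2], dim(arr)[3],
                  dimnames = dimnames(arr)[2:3]))
  e <- e[match(sites, e$inflow_site), , drop = FALSE]
  v <- arr[sites, , , drop = FALSE]
  w <- array(e$weight, dim = dim(v))
  if (e$renormalize[1]) {
    num <- apply(w * v, c(2, 3), sum, na.rm = TRUE)
    den <- apply(w * !is.na(v), c(2, 3), sum)
    res <- num / den
    res[den == 0] <- NA_real_
    res
  } else {
    if (abs(sum(e$weight) - 1) > 1e-9)
      stop("inflow weights for organ '", organ, "' do not sum to 1")
    apply(w * v, c(2, 3), sum)  # NA propagates: all sites required
  }
}

#' Fit organ-level metabolite flux classifications
#'
#' The central estimator. For every organ, metabolite and animal it forms the
#' per-animal log2(V/A) statistic (outflow over weighted inflow, see
#' [default_organ_map()]), then classifies each organ x metabolite x genotype
#' cell as `release`, `uptake` or `none` using a normality-gated one-sample
#' location test against 0 and a significance level `alpha`.
#' Benjamini-Hochberg q-values are computed within each organ x genotype
#' series.
#'
#' @param abundance abundance table. If it has a `replicate` column it is
#'   first collapsed with [collapse_replicates()]; internal-standard
#'   normalization is the caller's responsibility (see
#'   [normalize_internal_standard()]).
#' @param design an [study_design()].
#' @param map an [organ_map()]; defaults to [default_organ_map()].
#' @param alpha per-cell significance level for the release/uptake call.
#' @param normality_alpha,invert_gate Shapiro-Wilk gate parameters, see
#'   [normality_gate()].
#' @param outlier_k optional; when set, per-cell values beyond
#'   `outlier_k` sample SDs from the cell mean are removed before testing
#'   (see [remove_outliers()]).
#' @param min_n minimum usable animals per cell; smaller cells are reported
#'   with `call = "none"` and `p = NA`.
#' @param metabolites optional metabolite subset.
#' @return object of class `avflux`: list with `records` (one row per organ x
#'   metabolite x genotype: `n`, `mean_log2_va`, `test`, `p`, `q`, `call`),
#'   `samples` (per-animal log2(V/A) values), the organ map, design and
#'   settings.
#' @examples
#' truth <- synthetic_truth("demo")
#' cohort <- generate_cohort(truth, n_pairs = 4, seed = 1)
#' fit <- avflux(cohort$abundance, cohort$design)
#' summary(fit)
#' @export
avflux <- function(abundance, design, map = default_organ_map(),
                   alpha = 0.05, normality_alpha = 0.05, invert_gate = FALSE,
                   outlier_k = NULL, min_n = 3L, metabolites = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  abundance <- as.data.frame(abundance)
  if ("replicate" %in% names(abundance))
    abundance <- collapse_replicates(abundance)
  if (!is.null(metabolites))
    abundance <- abundance[abundance$metabolite_id %in% metabolites, ,
                           drop = FALSE]
  arr <- abundance_array(abundance)
  animals <- dimnames(arr)[[2]]
  mets <- dimnames(arr)[[3]]
  genotype <- design$animals$genotype[match(animals,
                                            design$animals$animal_id)]
  organs <- map_organs(map)

  samples <- vector("list", length(organs))
  for (i in seq_along(organs)) {
    o <- organs[i]
    inflow <- inflow_matrix(arr, map, o)
    out_site <- outflow_site_of(map, o)
    outflow <- if (out_site %in% dimnames(arr)[[1]])
      arr[out_site, , ] else inflow * NA_real_
    ratio <- suppressWarnings(log2(outflow / inflow))
    ratio[!is.finite(ratio) | is.na(outflow) | is.na(inflow) |
            outflow <= 0 | inflow <= 0] <- NA_real_
    samples[[i]] <- data.frame(
      organ = o,
      metabolite_id = rep(mets, each = length(animals)),
      animal_id = rep(animals, times = length(mets)),
      genotype = rep(genotype, times = length(mets)),
      log2_va = as.vector(ratio))
  }
  samples <- do.call(rbind, samples)
  samples <- samples[!is.na(samples$log2_va), , drop = FALSE]

  records <- classify_flux_table(samples, alpha = alpha,
                                 normality_alpha = normality_alpha,
                                 invert_gate = invert_gate,
                                 outlier_k = outlier_k, min_n = min_n)
  structure(list(records = records, samples = samples, alpha = alpha,
                 normality_alpha = normality_alpha,
                 invert_gate = invert_gate, outlier_k = outlier_k,
                 min_n = min_n, map = map, design = design),
            class = "avflux")
}

#' Classify flux from precomputed per-animal log2(V/A) values
#'
#' Entry point for externally supplied per-animal AV ratios -- e.g. plotted
#' per-figure values republished alongside a study -- bypassing the
#' abundance-table stage. Applies the same normality-gated one-sample test,
#' call rule and within-organ BH correction as [avflux()], so exchange
#' graphs and organ counts can be recomputed directly from such tables via
#' [exchange_graph()].
#'
#' @param samples long data.frame: `organ`, `metabolite_id`, `genotype`,
#'   `log2_va` (one row per animal).
#' @inheritParams avflux
#' @return flux records data.frame as in an [avflux()] fit.
#' @export
classify_flux_table <- function(samples, alpha, normality_alpha = 0.05,
                                invert_gate = FALSE, outlier_k = NULL,
                                min_n = 3L) {
  cells <- unique(samples[c("organ", "metabolite_id", "genotype")])
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- samples$organ == cells$organ[i] &
      samples$metabolite_id == cells$metabolite_id[i] &
      samples$genotype == cells$genotype[i]
    v <- samples$log2_va[sel]
    cl <- classify_flux(v, alpha = alpha, normality_alpha = normality_alpha,
                        invert_gate = invert_gate, outlier_k = outlier_k,
                        min_n = min_n)
    res[[i]] <- data.frame(cells[i, , drop = FALSE], cl,
                           stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, res)
  rownames(records) <- NULL
  records$q <- NA_real_
  for (o in unique(records$organ)) for (g in unique(records$genotype)) {
    idx <- records$organ == o & records$genotype == g
    records$q[idx] <- bh_fdr(records$p[idx])
  }
  records
}

#' Classify one flux cell
#'
#' Applies the optional outlier rule, the normality-gated one-sample test
#' against zero, and the release/uptake call to one vector of per-animal
#' log2(V/A) values.
#'
#' @param values per-animal log2(V/A) values (`NA`s are dropped).
#' @inheritParams avflux
#' @return one-row data.frame: `n`, `mean_log2_va`, `test`, `p`, `call`.
#' @export
classify_flux <- function(values, alpha = 0.05, normality_alpha = 0.05,
                          invert_gate = FALSE, outlier_k = NULL,
                          min_n = 3L) {
  v <- values[is.finite(values)]
  if (!is.null(outlier_k) && length(v) >= 3L)
    v <- remove_outliers(v, k = outlier_k)
  n <- length(v)
  if (n < min_n) {
    return(data.frame(n = n, mean_log2_va = if (n) mean(v) else NA_real_,
                      test = NA_character_, p = NA_real_, call = "none"))
  }
  tr <- one_sample_location_test(v, mu = 0, normality_alpha = normality_alpha,
                                 invert_gate = invert_gate)
  m <- mean(v)
  call <- if (!is.na(tr$p_value) && tr$p_value < alpha && m > 0) "release"
  else if (!is.na(tr$p_value) && tr$p_value < alpha && m < 0) "uptake"
  else "none"
  data.frame(n = n, mean_log2_va = m, test = tr$test_name, p = tr$p_value,
             call = call)
}

#' @export
print.avflux <- function(x, ...) {
  r <- x$records
  cat(sprintf("AV flux fit: %d organs, %d metabolites, genotypes: %s\n",
              length(unique(r$organ)), length(unique(r$metabolite_id)),
              paste(unique(r$genotype), collapse = ", ")))
  cat(sprintf("  alpha = %g; %d release, %d uptake, %d unclassified cells\n",
              x$alpha, sum(r$call == "release"), sum(r$call == "uptake"),
              sum(r$call == "none")))
  invisible(x)
}

#' Summarize an AV flux fit by organ
#'
#' Counts significant release and uptake metabolites per organ and genotype
#' (the organ-level trafficking summary).
#'
#' @param object an [avflux()] fit.
#' @param ... unused.
#' @return data.frame `organ`, `genotype`, `n_release`, `n_uptake`,
#'   `n_tested`, of class `summary.avflux`.
#' @export
summary.avflux <- function(object, ...) {
  r <- object$records
  cells <- unique(r[c("organ", "genotype")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    idx <- r$organ == cells$organ[i] & r$genotype == cells$genotype[i]
    data.frame(organ = cells$organ[i], genotype = cells$genotype[i],
               n_release = sum(r$call[idx] == "release"),
               n_uptake = sum(r$call[idx] == "uptake"),
               n_tested = sum(!is.na(r$p[idx])))
  }))
  rownames(out) <- NULL
  class(out) <- c("summary.avflux", "data.frame")
  out
}

#' @export
print.summary.avflux <- function(x, ...) {
  cat("Significant metabolite release/uptake per organ:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @describeIn avflux matrix of mean log2(V/A) per organ (rows) and
#'   metabolite (columns) for one genotype.
#' @param object,x an `avflux` fit.
#' @param genotype genotype whose coefficients to extract.
#' @param ... unused.
#' @export
coef.avflux <- function(object, genotype = "WT", ...) {
  r <- object$records[object$records$genotype == genotype, , drop = FALSE]
  organs <- unique(r$organ); mets <- unique(r$metabolite_id)
  m <- matrix(NA_real_, length(organs), length(mets),
              dimnames = list(organs, mets))
  m[cbind(match(r$organ, organs), match(r$metabolite_id, mets))] <-
    r$mean_log2_va
  m
}

#' @describeIn avflux per-animal deviations of log2(V/A) from the cell mean.
#' @export
residuals.avflux <- function(object, ...) {
  s <- object$samples
  key <- paste(s$organ, s$metabolite_id, s$genotype, sep = "\r")
  s$resid <- s$log2_va - stats::ave(s$log2_va, key)
  s[c("organ", "metabolite_id", "animal_id", "genotype", "resid")]
}

#' @describeIn avflux barplot of significant release/uptake counts per organ.
#' @export
plot.avflux <- function(x, ...) {
  s <- summary(x)
  genos <- unique(s$genotype)
  old <- graphics::par(mfrow = c(1, length(genos)), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(old))
  for (g in genos) {
    sg <- s[s$genotype == g, , drop = FALSE]
    m <- rbind(release = sg$n_release, uptake = -sg$n_uptake)
    colnames(m) <- sg$organ
    graphics::barplot(m, beside = TRUE, las = 2,
                      col = c("firebrick", "steelblue"),
                      main = paste0(g, " (alpha = ", x$alpha, ")"),
                      ylab = "metabolites released (+) / taken up (-)")
    graphics::abline(h = 0)
  }
  invisible(x)
}

#' Absolute arteriovenous concentration difference
#'
#' For metabolites with an absolute-concentration calibration, converts ion
#' counts to concentration units and returns outflow minus inflow (positive
#' = release). For organs like the lung whose uptake magnitudes are usually
#' quoted as positive numbers, set `as_uptake = TRUE` to get inflow minus
#' outflow instead.
#'
#' @inheritParams compute_log2_va
#' @param calibration named numeric vector: concentration units per ion
#'   count, names are metabolite ids.
#' @param as_uptake report inflow - outflow (positive = uptake) instead of
#'   the signed release convention.
#' @return concentration difference in calibrated units, `NA` when either
#'   side is unmeasured.
#' @export
flux_concentration_difference <- function(collapsed, map, organ, animal_id,
                                          metabolite_id, calibration,
                                          as_uptake = FALSE) {
  if (!(metabolite_id %in% names(calibration)))
    stop("metabolite '", metabolite_id, "' has no absolute calibration")
  f <- calibration[[metabolite_id]]
  inflow <- resolve_inflow_abundance(collapsed, map, organ, animal_id,
                                     metabolite_id)
  out_site <- outflow_site_of(map, organ)
  rows <- collapsed$animal_id == animal_id &
    collapsed$metabolite_id == metabolite_id & collapsed$site_id == out_site
  outflow <- if (any(rows)) collapsed$ion_count[rows][1] else NA_real_
  if (is.na(inflow) || is.na(outflow)) return(NA_real_)
  d <- f * (outflow - inflow)
  if (as_uptake) -d else d
}

#' Arterial metabolome genotype contrast
#'
#' Compares WT and CF littermates on the systemic arterial metabolome: per
#' metabolite, the per-pair log2(CF/WT) fold change at the arterial
#' reference, a normality-gated paired test, and Benjamini-Hochberg FDR
#' across metabolites (the volcano-plot analysis).
#'
#' @param abundance collapsed (or replicate-resolved) abundance table.
#' @param design an [study_design()] with littermate pairs.
#' @param arterial_sites systemic arterial site ids averaged into the
#'   reference value.
#' @param alpha significance level for the direction call.
#' @param normality_alpha,invert_gate gate parameters.
#' @param min_pairs minimum complete pairs per metabolite.
#' @return data.frame of class `av_contrast`: `metabolite_id`, `n_pairs`,
#'   `mean_log2fc` (CF/WT), `test`, `p`, `q`, `direction`
#'   (`"increased"`/`"decreased"`/`"none"`, CF relative to WT).
#' @export
arterial_contrast <- function(abundance, design,
                              arterial_sites = c("aorta", "femoral_artery"),
                              alpha = 0.05, normality_alpha = 0.05,
                              invert_gate = FALSE, min_pairs = 3L) {
  abundance <- as.data.frame(abundance)
  if ("replicate" %in% names(abundance))
    abundance <- collapse_replicates(abundance)
  a <- design$animals
  pairs <- unique(stats::na.omit(a$pair_id))
  if (length(pairs) == 0L) {
    warning("no littermate pairs in design; empty contrast")
    return(structure(data.frame(), class = c("av_contrast", "data.frame")))
  }
  art <- abundance[abundance$site_id %in% arterial_sites, , drop = FALSE]
  ref <- stats::aggregate(ion_count ~ animal_id + metabolite_id, data = art,
                          FUN = mean)
  mets <- unique(ref$metabolite_id)
  wt_id <- vapply(pairs, function(p)
    a$animal_id[!is.na(a$pair_id) & a$pair_id == p & a$genotype == "WT"][1],
    character(1))
  cf_id <- vapply(pairs, function(p)
    a$animal_id[!is.na(a$pair_id) & a$pair_id == p & a$genotype == "CF"][1],
    character(1))
  out <- vector("list", length(mets))
  for (i in seq_along(mets)) {
    rm_ <- ref[ref$metabolite_id == mets[i], , drop = FALSE]
    wt <- rm_$ion_count[match(wt_id, rm_$animal_id)]
    cf <- rm_$ion_count[match(cf_id, rm_$animal_id)]
    ok <- !is.na(wt) & !is.na(cf) & wt > 0 & cf > 0
    lfc <- log2(cf[ok] / wt[ok])
    if (sum(ok) < min_pairs) {
      out[[i]] <- data.frame(metabolite_id = mets[i], n_pairs = sum(ok),
                             mean_log2fc = if (any(ok)) mean(lfc) else NA_real_,
                             test = NA_character_, p = NA_real_)
      next
    }
    tr <- paired_two_group_test(log2(cf[ok]), log2(wt[ok]),
                                normality_alpha = normality_alpha,
                                invert_gate = invert_gate)
    out[[i]] <- data.frame(metabolite_id = mets[i], n_pairs = sum(ok),
                           mean_log2fc = mean(lfc), test = tr$test_name,
                           p = tr$p_value)
  }
  res <- do.call(rbind, out)
  res$q <- bh_fdr(res$p)
  res$direction <- ifelse(is.na(res$p) | res$p >= alpha, "none",
                          ifelse(res$mean_log2fc > 0, "increased",
                                 "decreased"))
  class(res) <- c("av_contrast", "data.frame")
  res
}
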