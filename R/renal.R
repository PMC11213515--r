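#' Creatinine-normalized urine/artery ratio
#'
#' The renal reabsorption index: a metabolite's urine abundance divided by
#' urine creatinine (correcting for urine concentration), then divided by
#' its arterial abundance. Low values mean efficient tubular reabsorption;
#' elevated values mean loss into urine. Both the ion-count unit and the
#' urine concentration factor cancel.
#'
#' @param urine,creatinine,arterial numeric vectors (recycled): urine
#'   metabolite abundance, urine creatinine abundance, arterial metabolite
#'   abundance.
#' @return `(urine / creatinine) / arterial`; `NA` where any input is
#'   missing or nonpositive.
#' @export
urine_artery_ratio <- function(urine, creatinine, arterial) {
  r <- (urine / creatinine) / arterial
  r[!is.finite(r) | urine <= 0 | creatinine <= 0 | arterial <= 0] <- NA_real_
  r
}

#' Per-animal reabsorption ratio table
#'
#' Extracts urine and arterial abundances from a collapsed abundance table
#' and computes the creatinine-normalized urine/artery ratio per animal and
#' metabolite.
#'
#' @param abundance collapsed abundance table including the urine site.
#' @param design an [study_design()].
#' @param urine_site site id of the urine sample.
#' @param arterial_sites systemic arterial site ids (averaged).
#' @param creatinine metabolite id used for urine normalization.
#' @param metabolites optional metabolite subset (creatinine itself is never
#'   reported as its own ratio).
#' @return data.frame: `animal_id`, `genotype`, `metabolite_id`, `ratio`.
#' @export
reabsorption_ratios <- function(abundance, design,
                                urine_site = "bladder_urine",
                                arterial_sites = c("aorta", "femoral_artery"),
                                creatinine = "creatinine",
                                metabolites = NULL) {
  abundance <- as.data.frame(abundance)
  if ("replicate" %in% names(abundance))
    abundance <- collapse_replicates(abundance)
  ur <- abundance[abundance$site_id == urine_site, , drop = FALSE]
  art <- abundance[abundance$site_id %in% arterial_sites, , drop = FALSE]
  art <- stats::aggregate(ion_count ~ animal_id + metabolite_id, data = art,
                          FUN = mean)
  crea <- ur[ur$metabolite_id == creatinine, , drop = FALSE]
  if (nrow(crea) == 0L) stop("urine creatinine ('", creatinine,
                             "') not found at site '", urine_site, "'")
  mets <- setdiff(unique(ur$metabolite_id), creatinine)
  if (!is.null(metabolites)) mets <- intersect(mets, metabolites)
  animals <- unique(ur$animal_id)
  genotype <- design$animals$genotype[match(animals,
                                            design$animals$animal_id)]
  crea_v <- crea$ion_count[match(animals, crea$animal_id)]
  out <- vector("list", length(mets))
  for (i in seq_along(mets)) {
    um <- ur[ur$metabolite_id == mets[i], , drop = FALSE]
    am <- art[art$metabolite_id == mets[i], , drop = FALSE]
    u <- um$ion_count[match(animals, um$animal_id)]
    a <- am$ion_count[match(animals, am$animal_id)]
    out[[i]] <- data.frame(animal_id = animals, genotype = genotype,
                           metabolite_id = mets[i],
                           ratio = urine_artery_ratio(u, crea_v, a))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genotype contrast of reabsorption ratios
#'
#' Per metabolite, compares WT and CF urine/artery ratios with a
#' normality-gated unpaired test on the log ratios (ratios are
#' multiplicative), plus Benjamini-Hochberg FDR across metabolites. The
#' direction is the sign of the CF - WT mean log ratio for significant
#' metabolites: `"CF_higher"` flags impaired CF reabsorption.
#'
#' @param ratios output of [reabsorption_ratios()].
#' @param alpha significance level for the direction call.
#' @param normality_alpha,invert_gate gate parameters.
#' @param min_n minimum animals per genotype group.
#' @return data.frame: `metabolite_id`, `n_wt`, `n_cf`, `geomean_wt`,
#'   `geomean_cf`, `test`, `p`, `q`, `direction`.
#' @export
reabsorption_contrast <- function(ratios, alpha = 0.05,
                                  normality_alpha = 0.05,
                                  invert_gate = FALSE, min_n = 3L) {
  mets <- unique(ratios$metabolite_id)
  out <- vector("list", length(mets))
  for (i in seq_along(mets)) {
    rm_ <- ratios[ratios$metabolite_id == mets[i], , drop = FALSE]
    wt <- rm_$ratio[rm_$genotype == "WT"]; wt <- wt[is.finite(wt) & wt > 0]
    cf <- rm_$ratio[rm_$genotype == "CF"]; cf <- cf[is.finite(cf) & cf > 0]
    if (length(wt) < min_n || length(cf) < min_n) {
      out[[i]] <- data.frame(metabolite_id = mets[i], n_wt = length(wt),
                             n_cf = length(cf),
                             geomean_wt = exp(mean(log(wt))),
                             geomean_cf = exp(mean(log(cf))),
                             test = NA_character_, p = NA_real_)
      next
    }
    tr <- two_group_test(log(cf), log(wt), normality_alpha = normality_alpha,
                         invert_gate = invert_gate)
    out[[i]] <- data.frame(metabolite_id = mets[i], n_wt = length(wt),
                           n_cf = length(cf),
                           geomean_wt = exp(mean(log(wt))),
                           geomean_cf = exp(mean(log(cf))),
                           test = tr$test_name, p = tr$p_value)
  }
  res <- do.call(rbind, out)
  res$q <- bh_fdr(res$p)
  d <- log(res$geomean_cf) - log(res$geomean_wt)
  res$direction <- ifelse(is.na(res$p) | res$p >= alpha, "none",
                          ifelse(d > 0, "CF_higher", "CF_lower"))
  rownames(res) <- NULL
  res
}

#' Stable-isotope tracer leakage index
#'
#' For an intravenously infused 13C-labeled amino acid at steady state, the
#' fraction appearing in urine: urine labeled counts over urine creatinine,
#' normalized to the arterial labeled counts. Zero urine label means
#' complete reabsorption of the filtered tracer.
#'
#' @param urine_labeled,urine_creatinine,arterial_labeled numeric vectors
#'   (recycled).
#' @return `(urine_labeled / urine_creatinine) / arterial_labeled`; `NA`
#'   where creatinine or the arterial label is nonpositive.
#' @export
tracer_leakage_index <- function(urine_labeled, urine_creatinine,
                                 arterial_labeled) {
  idx <- (urine_labeled / urine_creatinine) / arterial_labeled
  idx[urine_creatinine <= 0 | arterial_labeled <= 0 |
        !is.finite(urine_creatinine) | !is.finite(arterial_labeled)] <-
    NA_real_
  idx
}

#' Descriptive summary of tracer leakage
#'
#' Computes [tracer_leakage_index()] per animal and tracer and summarizes by
#' genotype with individual values and group means only. No p-values are
#' produced: tracer infusions are typically run on very few animals (n = 2
#' per genotype here), where hypothesis tests would be meaningless.
#'
#' @param tracer data.frame: `animal_id`, `tracer_id`, `compartment`
#'   (`"urine"` or `"arterial"`), `labeled_count`.
#' @param urine_creatinine data.frame `animal_id`, `ion_count` (urine
#'   creatinine per animal), or a named numeric vector.
#' @param design an [study_design()].
#' @return list with `indices` (animal-level data.frame: `tracer_id`,
#'   `animal_id`, `genotype`, `index`) and `means` (tracer x genotype group
#'   means and n).
#' @export
tracer_summary <- function(tracer, urine_creatinine, design) {
  tracer <- as.data.frame(tracer)
  if (is.data.frame(urine_creatinine)) {
    crea <- urine_creatinine$ion_count
    names(crea) <- urine_creatinine$animal_id
  } else crea <- urine_creatinine
  ur <- tracer[tracer$compartment == "urine", , drop = FALSE]
  art <- tracer[tracer$compartment == "arterial", , drop = FALSE]
  key <- function(d) paste(d$animal_id, d$tracer_id, sep = "\r")
  idx_rows <- unique(rbind(ur[c("animal_id", "tracer_id")],
                           art[c("animal_id", "tracer_id")]))
  u <- ur$labeled_count[match(key(idx_rows), key(ur))]
  a <- art$labeled_count[match(key(idx_rows), key(art))]
  cr <- crea[idx_rows$animal_id]
  res <- data.frame(
    tracer_id = idx_rows$tracer_id, animal_id = idx_rows$animal_id,
    genotype = design$animals$genotype[match(idx_rows$animal_id,
                                             design$animals$animal_id)],
    index = tracer_leakage_index(u, cr, a))
  rownames(res) <- NULL
  means <- stats::aggregate(index ~ tracer_id + genotype, data = res,
                            FUN = mean)
  means$n <- stats::aggregate(index ~ tracer_id + genotype, data = res,
                              FUN = length)$index
  list(indices = res, means = means)
}
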