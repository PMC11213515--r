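#' Ground truth for a synthetic AV metabolomics cohort
#'
#' Declares everything a virtual cohort is generated from: the metabolite
#' panel with genotype-specific arterial set-points, per-organ true log2
#' fluxes, homeostatic coupling slopes, renal reabsorption efficiencies,
#' tracer leakage fractions and the noise model. The built-in scenarios are:
#'
#' * `"cf_piglet"` -- a littermate-paired WT/CF cohort shaped like a newborn
#'   CF pig study: 20 amino acids, 10 long-chain fatty acids, glucose,
#'   lactate, 3-hydroxybutyrate, creatinine and 50 unnamed filler
#'   metabolites (5 of them with deliberately poor technical CV so the QC
#'   filter has work to do). Programmed effects: CF arterial tyrosine
#'   divided by 3 and glutamate doubled; broad liver amino-acid release in
#'   WT that largely collapses in CF; lung LCFA uptake attenuated in CF
#'   except arachidonic acid (C20:4), whose uptake is amplified about
#'   3-fold; 12 kidney homeostats (10 amino acids, glucose,
#'   3-hydroxybutyrate) in WT only; and CF amino-acid / lactate
#'   reabsorption efficiency cut in half, with 5-fold higher tracer
#'   leakage.
#' * `"recovery"` -- a compact panel (18 metabolites) with strong programmed
#'   fluxes (|log2 flux| >= 1) and no homeostatic coupling; meant for
#'   round-trip flux/edge recovery benchmarks.
#' * `"null"` -- the 28-metabolite calibrated panel with all fluxes,
#'   couplings and genotype differences switched off; everything observed
#'   downstream is noise.
#' * `"demo"` -- a tiny fast panel for examples.
#'
#' @param scenario one of `"cf_piglet"`, `"recovery"`, `"null"`, `"demo"`.
#' @param measurement_cv technical (per-injection) coefficient of variation
#'   as a fraction (default 0.05).
#' @param biological_cv animal-to-animal CV of arterial set-points (0.20).
#' @param litter_cv CV of the litter-shared multiplicative random effect
#'   (0.10); litters are what littermate pairing absorbs.
#' @param urine_concentration multiplicative urine concentration factor
#'   (cancels out of all creatinine-normalized indices).
#' @param qc_injections pooled-QC injections to emit (default 10).
#' @return object of class `synthetic_truth`; see Details for fields.
#' @export
synthetic_truth <- function(scenario = c("cf_piglet", "recovery", "null",
                                         "demo"),
                            measurement_cv = 0.05, biological_cv = 0.20,
                            litter_cv = 0.10, urine_concentration = 20,
                            qc_injections = 10L) {
  scenario <- match.arg(scenario)
  aas <- c("alanine", "arginine", "asparagine", "aspartate", "cysteine",
           "glutamate", "glutamine", "glycine", "histidine", "isoleucine",
           "leucine", "lysine", "methionine", "phenylalanine", "proline",
           "serine", "threonine", "tryptophan", "tyrosine", "valine")
  aa_set <- c(400, 150, 50, 20, 30, 100, 500, 300, 80, 100,
              150, 200, 40, 80, 200, 150, 150, 60, 90, 250)
  lcfas <- c("C14:0", "C16:0", "C18:0", "C18:1", "C18:2", "C18:3",
             "C20:3", "C20:4", "C20:5", "C22:6")
  lcfa_set <- c(15, 120, 80, 100, 60, 20, 5, 5, 2, 10)
  others <- c("glucose", "lactate", "3-hydroxybutyrate", "creatinine")
  other_set <- c(5000, 3000, 150, 80)
  calibrated <- c(aas, "glucose", "lactate", "3-hydroxybutyrate",
                  "C16:0", "C18:1", "C18:2", "C20:4", "C22:6")

  fx <- function(organ, mets, genotype, flux)
    data.frame(organ = organ, metabolite_id = mets, genotype = genotype,
               log2_flux = flux)
  cp <- function(organ, mets, genotype, slope)
    data.frame(organ = organ, metabolite_id = mets, genotype = genotype,
               slope = slope)
  eff <- function(mets, wt, cf)
    data.frame(metabolite_id = mets, efficiency_wt = wt, efficiency_cf = cf)

  if (scenario == "cf_piglet") {
    fillers <- sprintf("filler_%02d", 1:50)
    filler_set <- round(exp(seq(log(10), log(1000), length.out = 50)), 1)
    mets <- data.frame(
      metabolite_id = c(aas, lcfas, others, fillers),
      class = c(rep("amino_acid", 20), rep("lcfa", 10),
                "sugar", "organic_acid", "ketone", "waste",
                rep("filler", 50)),
      setpoint_wt = c(aa_set, lcfa_set, other_set, filler_set))
    mets$setpoint_cf <- mets$setpoint_wt
    # CF arterial metabolome: mild global amino-acid decrease, tyrosine / 3,
    # glutamate x 2, most (not all) LCFAs doubled
    idx_aa <- mets$class == "amino_acid"
    mets$setpoint_cf[idx_aa] <- mets$setpoint_wt[idx_aa] * 0.85
    mets$setpoint_cf[mets$metabolite_id == "tyrosine"] <- 90 / 3
    mets$setpoint_cf[mets$metabolite_id == "glutamate"] <- 100 * 2
    up_fa <- setdiff(lcfas, c("C20:4", "C22:6"))
    mets$setpoint_cf[mets$metabolite_id %in% up_fa] <-
      mets$setpoint_wt[mets$metabolite_id %in% up_fa] * 2
    mets$measurement_cv <- measurement_cv
    mets$measurement_cv[mets$metabolite_id %in% sprintf("filler_%02d", 46:50)] <- 1.2

    liver_rel_wt <- c(setdiff(aas, c("cysteine", "glutamine", "isoleucine",
                                     "leucine", "valine")))  # 15 AAs
    liver_rel_cf <- c("alanine", "glycine", "serine", "proline", "threonine")
    leg_upt_wt <- c("glutamate", "leucine", "isoleucine", "valine",
                    "phenylalanine", "methionine", "lysine", "threonine",
                    "histidine", "arginine")
    other_fa <- setdiff(lcfas, c("C20:4", "C22:6"))
    intest_rel <- c("alanine", "glycine", "proline", "serine", "glutamine",
                    "lysine", "leucine", "valine")
    flux <- rbind(
      # WT
      fx("lung", other_fa, "WT", -1.0), fx("lung", "C22:6", "WT", -0.8),
      fx("lung", "C20:4", "WT", -0.45),
      fx("liver", liver_rel_wt, "WT", 1.0),
      fx("liver", "glucose", "WT", 0.8),
      fx("liver", sprintf("filler_%02d", 1:10), "WT", 1.0),
      fx("leg", leg_upt_wt, "WT", -1.0),
      fx("leg", c("glutamine", "lactate"), "WT", c(0.8, 1.0)),
      fx("head", "glucose", "WT", -0.5),
      fx("head", sprintf("filler_%02d", 1:5), "WT", -1.0),
      fx("heart", c("lactate", "3-hydroxybutyrate"), "WT", c(-1.0, -0.8)),
      fx("heart", sprintf("filler_%02d", 6:8), "WT", -1.0),
      fx("spleen", sprintf("filler_%02d", 11:13), "WT", 1.0),
      fx("kidney", c("glucose", "glutamine"), "WT", c(0.5, -0.5)),
      fx("intestine", intest_rel, "WT", 0.8),
      fx("intestine", "glucose", "WT", 0.5),
      # CF
      fx("lung", other_fa, "CF", -0.2), fx("lung", "C22:6", "CF", -0.3),
      fx("lung", "C20:4", "CF", -1.1),
      fx("liver", liver_rel_cf, "CF", 1.0),
      fx("liver", "glucose", "CF", 0.8),
      fx("leg", c("glutamate", "leucine", "valine"), "CF", -1.0),
      fx("leg", c("glutamine", "lactate"), "CF", c(0.3, 1.0)),
      fx("head", "glucose", "CF", -0.5),
      fx("head", sprintf("filler_%02d", 1:5), "CF", -1.0),
      fx("heart", c("lactate", "3-hydroxybutyrate"), "CF", c(-1.0, -0.8)),
      fx("heart", sprintf("filler_%02d", 6:8), "CF", -1.0),
      fx("spleen", sprintf("filler_%02d", 11:13), "CF", 1.0),
      fx("kidney", "glutamine", "CF", -0.5),
      fx("intestine", intest_rel, "CF", 0.8),
      fx("intestine", "glucose", "CF", 0.5))
    homeostats <- c("alanine", "glycine", "serine", "proline", "threonine",
                    "valine", "leucine", "isoleucine", "lysine", "histidine",
                    "glucose", "3-hydroxybutyrate")
    coupling <- cp("kidney", homeostats, "WT", 1.2)
    reab <- rbind(
      eff(aas, 0.95, 0.475),
      eff(lcfas, 0.98, 0.98),
      eff("glucose", 0.995, 0.995),
      eff("lactate", 0.90, 0.45),
      eff("3-hydroxybutyrate", 0.90, 0.90),
      eff("creatinine", 0, 0),
      eff(fillers, 0.3, 0.3))
    tracer <- data.frame(
      tracer_id = c("13C-glutamate", "13C-proline", "13C-arginine",
                    "13C-tyrosine"),
      leakage_wt = 0.01, leakage_cf = 0.05)
  } else if (scenario == "recovery") {
    # dense known source/sink structure: every organ x metabolite cell
    # carries a programmed flux with |log2 flux| >= 1, alternating sign, so
    # each metabolite has both source and sink organs and no ambiguous
    # (null) cells dilute recovery metrics
    panel <- c(aas[1:10], "glucose", "lactate", lcfas[1:4], "creatinine")
    mets <- data.frame(
      metabolite_id = panel, class = "panel",
      setpoint_wt = c(aa_set[1:10], 5000, 3000, lcfa_set[1:4], 80))
    mets$setpoint_cf <- mets$setpoint_wt
    mets$measurement_cv <- measurement_cv
    organs8 <- c("lung", "head", "heart", "spleen", "kidney", "liver",
                 "intestine", "leg")
    grid <- expand.grid(mi = seq_along(panel), oi = seq_along(organs8))
    sign_ <- ifelse((grid$mi + grid$oi) %% 2L == 0L, 1, -1)
    mag <- 1 + 0.25 * ((grid$mi + grid$oi) %% 4L)
    flux <- rbind(
      fx(organs8[grid$oi], panel[grid$mi], "WT", sign_ * mag),
      fx(organs8[grid$oi], panel[grid$mi], "CF", sign_ * mag))
    coupling <- cp(character(), character(), character(), numeric())
    reab <- eff(panel, 0.9, 0.9)
    tracer <- data.frame(tracer_id = "13C-glutamate",
                         leakage_wt = 0.01, leakage_cf = 0.01)
  } else if (scenario == "null") {
    panel <- c(calibrated, "creatinine")
    mets <- data.frame(
      metabolite_id = panel, class = "panel",
      setpoint_wt = c(aa_set, 5000, 3000, 150, 120, 100, 60, 5, 10, 80))
    mets$setpoint_cf <- mets$setpoint_wt
    mets$measurement_cv <- measurement_cv
    flux <- fx(character(), character(), character(), numeric())
    coupling <- cp(character(), character(), character(), numeric())
    reab <- eff(panel, 0.5, 0.5)
    tracer <- data.frame(tracer_id = "13C-glutamate",
                         leakage_wt = 0.01, leakage_cf = 0.01)
  } else { # demo
    panel <- c(aas[1:5], "glucose", "creatinine")
    mets <- data.frame(metabolite_id = panel, class = "panel",
                       setpoint_wt = c(aa_set[1:5], 5000, 80))
    mets$setpoint_cf <- mets$setpoint_wt
    mets$measurement_cv <- measurement_cv
    flux <- rbind(fx("liver", aas[1:3], "WT", 1),
                  fx("leg", aas[1:3], "WT", -1),
                  fx("liver", aas[1:3], "CF", 1),
                  fx("leg", aas[1:2], "CF", -1))
    coupling <- cp(character(), character(), character(), numeric())
    reab <- eff(panel, 0.9, c(0.6, 0.6, 0.9, 0.9, 0.9, 0.9, 0))
    reab$efficiency_wt[panel == "creatinine"] <- 0
    tracer <- data.frame(tracer_id = "13C-glutamate",
                         leakage_wt = 0.01, leakage_cf = 0.05)
  }
  calibration <- calibrated[calibrated %in% mets$metabolite_id]
  truth <- structure(list(
    scenario = scenario, metabolites = mets, flux = flux,
    coupling = coupling, reabsorption = reab, tracer = tracer,
    calibrated = calibration,
    measurement_cv = measurement_cv, biological_cv = biological_cv,
    litter_cv = litter_cv, urine_concentration = urine_concentration,
    qc_injections = as.integer(qc_injections),
    internal_standard = "15N-valine"), class = "synthetic_truth")
  truth$uid <- truth_uid(truth)
  truth
}

# order-sensitive checksum so shuffled/edited truth is detectable
truth_uid <- function(truth) {
  num <- c(truth$flux$log2_flux, truth$coupling$slope,
           truth$reabsorption$efficiency_wt, truth$reabsorption$efficiency_cf,
           truth$tracer$leakage_wt, truth$tracer$leakage_cf,
           truth$metabolites$setpoint_wt, truth$metabolites$setpoint_cf,
           truth$measurement_cv, truth$biological_cv, truth$litter_cv)
  chk <- sum(num * seq_along(num)) %% 1e9
  sprintf("%s-%.6g", truth$scenario, chk)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth '%s': %d metabolites, %d flux cells, %d homeostats,\n",
    x$scenario, nrow(x$metabolites), nrow(x$flux), nrow(x$coupling)))
  cat(sprintf(
    "  measurement CV %.0f%%, biological CV %.0f%%, litter CV %.0f%%\n",
    100 * x$measurement_cv, 100 * x$biological_cv, 100 * x$litter_cv))
  invisible(x)
}

validate_truth <- function(truth) {
  r <- truth$reabsorption
  ok <- all(r$efficiency_wt >= 0 & r$efficiency_wt <= 1 &
              r$efficiency_cf >= 0 & r$efficiency_cf <= 1) &&
    all(truth$tracer$leakage_wt >= 0 & truth$tracer$leakage_wt <= 1 &
          truth$tracer$leakage_cf >= 0 & truth$tracer$leakage_cf <= 1) &&
    all(truth$metabolites$setpoint_wt > 0 &
          truth$metabolites$setpoint_cf > 0) &&
    truth$measurement_cv >= 0 && truth$biological_cv >= 0 &&
    truth$litter_cv >= 0
  if (!ok) stop("synthetic_truth invariants violated; generation refused")
  invisible(TRUE)
}

# base-flux / slope lookup matrices [metabolite x organ] for one genotype
truth_matrix <- function(df, value, mets, organs, genotype) {
  m <- matrix(0, length(mets), length(organs),
              dimnames = list(mets, organs))
  d <- df[df$genotype == genotype, , drop = FALSE]
  if (nrow(d))
    m[cbind(match(d$metabolite_id, mets), match(d$organ, organs))] <-
      d[[value]]
  m
}

#' Generate a littermate-paired synthetic cohort
#'
#' Draws a virtual WT/CF cohort from a [synthetic_truth()]. Arterial
#' concentrations are lognormal around the genotype set-point with a
#' litter-shared multiplicative random effect; each organ's outflow is its
#' resolved inflow times `2^(true flux - slope * log2(arterial /
#' set-point))`; urine is arterial times `(1 - reabsorption efficiency)`
#' times the urine concentration factor; every emitted count (including the
#' spiked internal standard and pooled-QC injections) carries independent
#' multiplicative lognormal measurement noise. The plumbing mirrors
#' [default_organ_map()]. Given the same truth and seed the output is
#' reproduced exactly.
#'
#' @param truth a [synthetic_truth()].
#' @param n_pairs littermate pairs (>= 2); one WT and one CF per pair.
#' @param replicates LC-MS injection replicates per biological sample.
#' @param seed integer random seed (mandatory).
#' @return list of class `av_cohort`: `abundance` (raw long table,
#'   replicate-resolved, internal standard included), `qc` (pooled-QC
#'   injections), `design` ([study_design()]), `map`, `tracer` (labeled
#'   counts per tracer/animal/compartment), `calibration` (named vector,
#'   concentration units per internal-standard-normalized count),
#'   `realized_flux` (the per-animal true log2 flux actually applied --
#'   ground truth for round-trip tests), `truth`, `seed`.
#' @export
generate_cohort <- function(truth, n_pairs = 8L, replicates = 3L, seed) {
  stopifnot(inherits(truth, "synthetic_truth"), n_pairs >= 2L,
            replicates >= 1L)
  validate_truth(truth)
  if (missing(seed)) stop("a seed is mandatory for cohort generation")
  set.seed(as.integer(seed))

  n <- as.integer(n_pairs)
  animals <- data.frame(
    animal_id = c(sprintf("WT%02d", 1:n), sprintf("CF%02d", 1:n)),
    genotype = rep(c("WT", "CF"), each = n),
    litter_id = rep(sprintf("litter%02d", 1:n), 2),
    pair_id = rep(sprintf("pair%02d", 1:n), 2),
    sex = rep(rep(c("M", "F"), length.out = n), 2))
  design <- study_design(animals, default_sites())
  map <- default_organ_map()
  organs <- map_organs(map)

  mets <- truth$metabolites$metabolite_id
  M <- length(mets); N <- nrow(animals)
  sdlog <- function(cv) sqrt(log1p(cv^2))
  bio_sd <- sdlog(truth$biological_cv)
  lit_sd <- sdlog(truth$litter_cv)
  meas_sd <- sdlog(truth$metabolites$measurement_cv)

  S <- matrix(0, M, N, dimnames = list(mets, animals$animal_id))
  S[, animals$genotype == "WT"] <- truth$metabolites$setpoint_wt
  S[, animals$genotype == "CF"] <- truth$metabolites$setpoint_cf
  litter_z <- stats::rnorm(n, 0, lit_sd)[match(animals$pair_id,
                                               sprintf("pair%02d", 1:n))]
  A <- S * exp(matrix(rep(litter_z, each = M), M, N) +
                 matrix(stats::rnorm(M * N, 0, bio_sd), M, N))
  dev <- log2(A / S)  # deviation from set-point, the homeostat input

  F0 <- list(WT = truth_matrix(truth$flux, "log2_flux", mets, organs, "WT"),
             CF = truth_matrix(truth$flux, "log2_flux", mets, organs, "CF"))
  SL <- list(WT = truth_matrix(truth$coupling, "slope", mets, organs, "WT"),
             CF = truth_matrix(truth$coupling, "slope", mets, organs, "CF"))
  geno <- animals$genotype
  realized <- function(organ) {
    f <- matrix(0, M, N, dimnames = dimnames(S))
    for (g in c("WT", "CF")) {
      idx <- geno == g
      f[, idx] <- F0[[g]][, organ] - SL[[g]][, organ] * dev[, idx]
    }
    f
  }
  FL <- lapply(organs, realized)
  names(FL) <- organs

  er <- truth$reabsorption
  eff <- matrix(0.5, M, N, dimnames = dimnames(S))
  i <- match(er$metabolite_id, mets)
  eff[i[!is.na(i)], geno == "WT"] <- er$efficiency_wt[!is.na(i)]
  eff[i[!is.na(i)], geno == "CF"] <- er$efficiency_cf[!is.na(i)]

  portal <- A * 2^FL$intestine
  site_conc <- list(
    aorta = A, femoral_artery = A, hepatic_artery = A,
    right_ventricle = A * 2^(-FL$lung),
    portal_vein = portal,
    hepatic_vein = (0.22 * A + 0.78 * portal) * 2^FL$liver,
    jugular_vein = A * 2^FL$head,
    coronary_sinus = A * 2^FL$heart,
    splenic_vein = A * 2^FL$spleen,
    renal_vein = A * 2^FL$kidney,
    femoral_vein = A * 2^FL$leg,
    bladder_urine = A * (1 - eff) * truth$urine_concentration)

  count_scale <- 100      # raw ion counts per concentration unit
  is_level <- 1000        # spiked internal standard, constant per sample
  sites <- names(site_conc)
  mets_all <- c(mets, truth$internal_standard)
  raw <- array(NA_real_, c(M + 1L, N, length(sites)),
               dimnames = list(mets_all, animals$animal_id, sites))
  for (s in seq_along(sites)) {
    raw[1:M, , s] <- site_conc[[s]] * count_scale
    raw[M + 1L, , s] <- is_level
  }
  meas_sd_all <- c(meas_sd, sdlog(truth$measurement_cv))

  blocks <- vector("list", replicates)
  base <- expand.grid(metabolite_id = mets_all,
                      animal_id = animals$animal_id,
                      site_id = sites, stringsAsFactors = FALSE)
  for (r in seq_len(replicates)) {
    noise <- exp(stats::rnorm(length(raw), 0, meas_sd_all))
    blocks[[r]] <- data.frame(base,
                              replicate = r,
                              ion_count = as.vector(raw) * noise)
  }
  abundance <- do.call(rbind, blocks)
  abundance <- abundance[c("animal_id", "site_id", "metabolite_id",
                           "replicate", "ion_count")]

  pooled <- apply(raw[, , sites != "bladder_urine", drop = FALSE],
                  1, mean)
  qc_n <- truth$qc_injections
  qc <- data.frame(
    metabolite_id = rep(mets_all, each = qc_n),
    injection = rep(seq_len(qc_n), length(mets_all)),
    ion_count = rep(pooled, each = qc_n) *
      exp(stats::rnorm(qc_n * length(mets_all), 0,
                       rep(meas_sd_all, each = qc_n))))

  tr <- truth$tracer
  n_tr_pairs <- min(2L, n)
  tr_animals <- animals$animal_id[animals$pair_id %in%
                                    sprintf("pair%02d", seq_len(n_tr_pairs))]
  tracer <- NULL
  if (nrow(tr)) {
    grid <- expand.grid(tracer_id = tr$tracer_id, animal_id = tr_animals,
                        stringsAsFactors = FALSE)
    g <- geno[match(grid$animal_id, animals$animal_id)]
    leak <- ifelse(g == "CF",
                   tr$leakage_cf[match(grid$tracer_id, tr$tracer_id)],
                   tr$leakage_wt[match(grid$tracer_id, tr$tracer_id)])
    art_true <- 100 * count_scale *
      exp(stats::rnorm(nrow(grid), 0, bio_sd))
    ur_true <- art_true * leak * truth$urine_concentration
    tracer <- rbind(
      data.frame(grid, compartment = "arterial",
                 labeled_count = art_true *
                   exp(stats::rnorm(nrow(grid), 0,
                                    sdlog(truth$measurement_cv)))),
      data.frame(grid, compartment = "urine",
                 labeled_count = ur_true *
                   exp(stats::rnorm(nrow(grid), 0,
                                    sdlog(truth$measurement_cv)))))
    rownames(tracer) <- NULL
  }

  realized_flux <- do.call(rbind, lapply(organs, function(o) {
    data.frame(organ = o,
               metabolite_id = rep(mets, N),
               animal_id = rep(animals$animal_id, each = M),
               log2_flux = as.vector(FL[[o]]))
  }))

  cal <- stats::setNames(
    rep(1 / count_scale * is_level, length(truth$calibrated)),
    truth$calibrated)

  structure(list(abundance = abundance, qc = qc, design = design, map = map,
                 tracer = tracer, calibration = cal,
                 realized_flux = realized_flux, truth = truth,
                 seed = as.integer(seed), n_pairs = n,
                 replicates = as.integer(replicates)),
            class = "av_cohort")
}

#' @export
print.av_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic AV cohort ('%s', seed %d): %d pairs, %d metabolites, %d rows\n",
    x$truth$scenario, x$seed, x$n_pairs,
    nrow(x$truth$metabolites), nrow(x$abundance)))
  invisible(x)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Convenience wrapper chaining QC filtering, internal-standard
#' normalization, replicate collapsing, the [avflux()] fit, the arterial
#' genotype contrast, the exchange graph, the homeostasis screen and the
#' renal analyses, exactly as [run_pipeline()] does for on-disk inputs.
#'
#' @param cohort an [generate_cohort()] result.
#' @param alpha flux/contrast significance level.
#' @param exchange_alpha edge significance level (defaults to `alpha`).
#' @param qc_threshold pooled-QC CV exclusion threshold (percent).
#' @param normality_alpha,invert_gate gate parameters.
#' @param outlier_k optional +/- k SD outlier removal before flux testing.
#' @return list with `qc`, `collapsed`, `fit`, `contrast`, `graph`,
#'   `screen`, `reabsorption`, `reabsorption_contrast`, `tracer` and the
#'   cohort's truth uid (consumed by [evaluate_recovery()]).
#' @export
analyze_cohort <- function(cohort, alpha = 0.05, exchange_alpha = alpha,
                           qc_threshold = 50, normality_alpha = 0.05,
                           invert_gate = FALSE, outlier_k = NULL) {
  stopifnot(inherits(cohort, "av_cohort"))
  std <- cohort$truth$internal_standard
  qc_norm <- normalize_qc(cohort$qc, std)
  qc <- qc_cv_filter(qc_norm, threshold = qc_threshold)
  tab <- normalize_internal_standard(cohort$abundance, std)
  keep <- c(qc$kept, qc$unassessable)
  tab <- tab[tab$metabolite_id %in% keep, , drop = FALSE]
  collapsed <- collapse_replicates(tab)
  fit <- avflux(collapsed, cohort$design, cohort$map, alpha = alpha,
                normality_alpha = normality_alpha,
                invert_gate = invert_gate, outlier_k = outlier_k,
                metabolites = setdiff(keep, std))
  contrast <- arterial_contrast(collapsed, cohort$design, alpha = alpha,
                                normality_alpha = normality_alpha,
                                invert_gate = invert_gate)
  graph <- exchange_graph(fit, alpha = exchange_alpha)
  screen <- homeostasis_screen(fit, collapsed,
                               metabolites = intersect(
                                 names(cohort$calibration), keep),
                               alpha = 0.05)
  ratios <- reabsorption_ratios(collapsed, cohort$design)
  reab <- reabsorption_contrast(ratios, alpha = alpha,
                                normality_alpha = normality_alpha,
                                invert_gate = invert_gate)
  tracer <- if (!is.null(cohort$tracer)) {
    crea <- collapsed[collapsed$site_id == "bladder_urine" &
                        collapsed$metabolite_id == "creatinine", ,
                      drop = FALSE]
    # tracer counts are raw; renormalize creatinine back to the raw scale
    # is unnecessary because the index is scale invariant per animal
    tracer_summary(cohort$tracer,
                   stats::setNames(crea$ion_count, crea$animal_id),
                   cohort$design)
  }
  list(qc = qc, collapsed = collapsed, fit = fit, contrast = contrast,
       graph = graph, screen = screen, reabsorption = ratios,
       reabsorption_contrast = reab, tracer = tracer,
       truth_uid = cohort$truth$uid)
}

# divide each QC injection by the same-injection internal standard
normalize_qc <- function(qc, standard) {
  std <- qc[qc$metabolite_id == standard, , drop = FALSE]
  denom <- std$ion_count[match(qc$injection, std$injection)]
  out <- qc
  out$ion_count <- qc$ion_count / denom
  out[!is.na(out$ion_count), , drop = FALSE]
}

# truth-implied exchange edges (base fluxes only)
truth_edges <- function(truth) {
  f <- truth$flux
  out <- vector("list", 0L)
  for (g in unique(f$genotype)) {
    fg <- f[f$genotype == g & f$log2_flux != 0, , drop = FALSE]
    for (m in unique(fg$metabolite_id)) {
      fm <- fg[fg$metabolite_id == m, , drop = FALSE]
      src <- fm$organ[fm$log2_flux > 0]
      snk <- fm$organ[fm$log2_flux < 0]
      if (length(src) && length(snk))
        out[[length(out) + 1L]] <-
          expand.grid(genotype = g, metabolite_id = m, source_organ = src,
                      sink_organ = snk, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(genotype = character(), metabolite_id = character(),
               source_organ = character(), sink_organ = character())
}

#' Score pipeline outputs against the generating truth
#'
#' Compares what the pipeline recovered with what the generator programmed.
#' Flux metrics are computed over truth cells with a nonzero base flux
#' (sign accuracy) and over fully null cells -- zero flux and zero
#' homeostatic slope -- for the false-positive rate; homeostatically coupled
#' zero-flux cells are excluded from both, since their per-animal flux is
#' genuinely nonzero by construction. Edge recovery is the Jaccard index
#' between detected exchange edges and truth-implied ones.
#'
#' @param results an [analyze_cohort()] bundle.
#' @param truth the [synthetic_truth()] the cohort was generated from; a
#'   truth that does not match the results' cohort is refused.
#' @return list of metrics: `flux_sign_accuracy`, `flux_fpr`,
#'   `edge_jaccard`, `homeostat_detection`, `homeostat_fpr`,
#'   `reabsorption_direction_accuracy`, plus the underlying counts.
#' @export
evaluate_recovery <- function(results, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!identical(results$truth_uid, truth_uid(truth)))
    stop("results were not produced from this truth; refusing to score")
  rec <- results$fit$records
  key <- function(o, m, g) paste(o, m, g, sep = "\r")
  f <- truth$flux[truth$flux$log2_flux != 0, , drop = FALSE]
  fk <- key(f$organ, f$metabolite_id, f$genotype)
  rk <- key(rec$organ, rec$metabolite_id, rec$genotype)
  idx <- match(fk, rk)
  hit <- !is.na(idx)
  want <- ifelse(f$log2_flux > 0, "release", "uptake")
  sign_acc <- mean(rec$call[idx[hit]] == want[hit])

  ck <- key(truth$coupling$organ, truth$coupling$metabolite_id,
            truth$coupling$genotype)
  null_cells <- !(rk %in% fk) & !(rk %in% ck)
  fpr <- mean(rec$call[null_cells] != "none")

  te <- truth_edges(truth)
  ek <- function(d) paste(d$genotype, d$metabolite_id, d$source_organ,
                          d$sink_organ, sep = "\r")
  tset <- unique(ek(te)); dset <- unique(ek(results$graph$edges))
  jac <- if (length(tset) + length(dset) == 0) 1 else
    length(intersect(tset, dset)) / length(union(tset, dset))

  hdet <- hfpr <- NA_real_
  if (!is.null(results$screen)) {
    sr <- results$screen$records
    sk <- key(sr$organ, sr$metabolite_id, sr$genotype)
    cin <- match(ck, sk)
    if (nrow(truth$coupling))
      hdet <- mean(sr$direction[cin[!is.na(cin)]] == "inverse")
    hnull <- !(sk %in% ck) & !(sk %in% fk)
    hfpr <- mean(sr$direction[hnull] != "none")
  }

  er <- truth$reabsorption
  diff_mets <- er$metabolite_id[er$efficiency_wt != er$efficiency_cf]
  rc <- results$reabsorption_contrast
  racc <- if (length(diff_mets) && !is.null(rc)) {
    i <- match(diff_mets, rc$metabolite_id)
    want_dir <- ifelse(
      (1 - er$efficiency_cf[match(diff_mets, er$metabolite_id)]) >
        (1 - er$efficiency_wt[match(diff_mets, er$metabolite_id)]),
      "CF_higher", "CF_lower")
    mean(rc$direction[i[!is.na(i)]] == want_dir[!is.na(i)])
  } else NA_real_

  list(flux_sign_accuracy = sign_acc, flux_fpr = fpr, edge_jaccard = jac,
       homeostat_detection = hdet, homeostat_fpr = hfpr,
       reabsorption_direction_accuracy = racc,
       n_flux_cells = sum(hit), n_null_cells = sum(null_cells),
       n_true_edges = length(tset), n_detected_edges = length(dset))
}
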