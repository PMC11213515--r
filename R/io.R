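#' Read a long-format abundance table
#'
#' Reads a TSV with columns `animal_id`, `site_id`, `metabolite_id`,
#' `replicate`, `ion_count` and validates it: malformed or negative rows are
#' a hard error listing the offending row numbers, and (when a design is
#' supplied) so are references to undeclared animals or sites.
#'
#' @param path TSV file path.
#' @param design optional [study_design()] for referential validation.
#' @return validated data.frame.
#' @export
read_abundance_table <- function(path, design = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "site_id", "metabolite_id", "replicate",
            "ion_count")
  if (!all(need %in% names(tab)))
    stop("abundance table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(tab$ion_count) | tab$ion_count < 0)
  if (length(bad))
    stop("invalid ion counts (negative or non-numeric) at row(s): ",
         paste(utils::head(bad, 20), collapse = ", "))
  if (!is.null(design)) {
    ua <- setdiff(unique(tab$animal_id), design$animals$animal_id)
    us <- setdiff(unique(tab$site_id), design$sites$site_id)
    if (length(ua)) stop("unknown animal id(s): ", paste(ua, collapse = ", "))
    if (length(us)) stop("unknown site id(s): ", paste(us, collapse = ", "))
  }
  tab
}

#' Read design tables
#'
#' @param animals_path TSV with columns `animal_id`, `genotype`,
#'   `litter_id`, `pair_id`, `sex` (empty `pair_id` = unpaired).
#' @param sites_path TSV with columns `site_id`, `kind`, `label`.
#' @return an [study_design()].
#' @export
read_design <- function(animals_path, sites_path) {
  animals <- utils::read.delim(animals_path, stringsAsFactors = FALSE,
                               na.strings = c("NA", ""))
  sites <- utils::read.delim(sites_path, stringsAsFactors = FALSE)
  study_design(animals, sites)
}

#' Read an organ plumbing map
#'
#' One row per organ inflow component: `organ`, `inflow_site`, `weight`,
#' `outflow_site`, `renormalize` (TRUE/FALSE).
#'
#' @param path TSV file path.
#' @return an [organ_map()].
#' @export
read_organ_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  m$renormalize <- as.logical(m$renormalize)
  organ_map(m)
}

#' Write a table as TSV
#'
#' Tab-separated, no quoting, missing values as empty fields.
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' @param abundance,animals,sites paths to the input TSVs.
#' @param organ_map path to an organ map TSV, or `NULL` for
#'   [default_organ_map()].
#' @param qc path to a pooled-QC TSV (`metabolite_id`, `injection`,
#'   `ion_count`), or `NULL` to skip CV filtering.
#' @param tracer path to a tracer TSV (`animal_id`, `tracer_id`,
#'   `compartment`, `labeled_count`), or `NULL`.
#' @param out_dir output directory (created if missing).
#' @param alpha,exchange_alpha,homeostasis_alpha significance levels.
#' @param normality_alpha,invert_gate Shapiro-Wilk gate settings.
#' @param qc_threshold pooled-QC CV exclusion threshold (percent).
#' @param outlier_k optional +/- k SD outlier rule for flux testing.
#' @param calibration named numeric vector of absolute-concentration
#'   factors; its names define the homeostasis screen panel.
#' @param internal_standard metabolite id of the internal standard, or
#'   `NULL` if the table is already normalized.
#' @param urine_site,creatinine urine site id and creatinine metabolite id.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(abundance, animals, sites, organ_map = NULL,
                       qc = NULL, tracer = NULL, out_dir = "avflux_out",
                       alpha = 0.05, exchange_alpha = alpha,
                       homeostasis_alpha = 0.05, normality_alpha = 0.05,
                       invert_gate = FALSE, qc_threshold = 50,
                       outlier_k = NULL, calibration = NULL,
                       internal_standard = "15N-valine",
                       urine_site = "bladder_urine",
                       creatinine = "creatinine", seed = 1L) {
  for (a in c(alpha, exchange_alpha, homeostasis_alpha, normality_alpha))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      stop("significance levels must lie strictly between 0 and 1")
  if (qc_threshold <= 0) stop("qc_threshold must be positive")
  for (p in c(abundance, animals, sites, organ_map, qc, tracer))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(abundance = abundance, animals = animals, sites = sites,
                 organ_map = organ_map, qc = qc, tracer = tracer,
                 out_dir = out_dir, alpha = alpha,
                 exchange_alpha = exchange_alpha,
                 homeostasis_alpha = homeostasis_alpha,
                 normality_alpha = normality_alpha,
                 invert_gate = invert_gate, qc_threshold = qc_threshold,
                 outlier_k = outlier_k, calibration = calibration,
                 internal_standard = internal_standard,
                 urine_site = urine_site, creatinine = creatinine,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the end-to-end AV metabolomics pipeline
#'
#' Stages, in order: QC CV filter, internal-standard normalization and
#' replicate collapsing, organ flux classification, arterial genotype
#' contrast, exchange graph, homeostasis screen, renal reabsorption (and
#' tracer summary when a tracer table is configured). All result tables are
#' written to `config$out_dir` together with a JSON run manifest recording
#' the configuration, stage row counts and package version. The pipeline is
#' deterministic: identical config and inputs reproduce identical outputs.
#' A stage failure retains the outputs written so far; the manifest records
#' the failure point.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of in-memory results per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "avflux",
                   version = as.character(utils::packageVersion("avflux")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "calibration")],
                   stages = list())
  results <- list()
  failed <- NULL

  stages <- list(
    qc = function() {
      design <- read_design(config$animals, config$sites)
      map <- if (is.null(config$organ_map)) default_organ_map() else
        read_organ_map(config$organ_map)
      v <- validate_design(design, map)
      if (nrow(v)) stop("design validation failed: ",
                        paste(v$problem, collapse = "; "))
      tab <- read_abundance_table(config$abundance, design)
      results$design <<- design; results$map <<- map
      if (!is.null(config$qc)) {
        qc_tab <- utils::read.delim(config$qc, stringsAsFactors = FALSE)
        if (!is.null(config$internal_standard))
          qc_tab <- normalize_qc(qc_tab, config$internal_standard)
        results$qc <<- qc_cv_filter(qc_tab, threshold = config$qc_threshold)
        write_tsv(results$qc$report,
                  file.path(config$out_dir, "qc_report.tsv"))
        keep <- c(results$qc$kept, results$qc$unassessable)
        tab <- tab[tab$metabolite_id %in%
                     c(keep, config$internal_standard), , drop = FALSE]
      }
      if (!is.null(config$internal_standard))
        tab <- normalize_internal_standard(tab, config$internal_standard)
      results$collapsed <<- collapse_replicates(tab)
      nrow(results$collapsed)
    },
    flux = function() {
      mets <- setdiff(unique(results$collapsed$metabolite_id),
                      config$internal_standard)
      results$fit <<- avflux(results$collapsed, results$design, results$map,
                             alpha = config$alpha,
                             normality_alpha = config$normality_alpha,
                             invert_gate = config$invert_gate,
                             outlier_k = config$outlier_k,
                             metabolites = mets)
      write_tsv(results$fit$records, file.path(config$out_dir, "flux.tsv"))
      nrow(results$fit$records)
    },
    contrast = function() {
      arterial <- results$design$sites$site_id[
        results$design$sites$kind == "arterial"]
      results$contrast <<- arterial_contrast(
        results$collapsed, results$design, arterial_sites = arterial,
        alpha = config$alpha, normality_alpha = config$normality_alpha,
        invert_gate = config$invert_gate)
      write_tsv(results$contrast, file.path(config$out_dir, "contrast.tsv"))
      nrow(results$contrast)
    },
    exchange = function() {
      results$graph <<- exchange_graph(results$fit,
                                       alpha = config$exchange_alpha)
      write_tsv(results$graph$edges, file.path(config$out_dir, "edges.tsv"))
      for (g in unique(results$graph$edges$genotype)) {
        m <- as.matrix(results$graph, genotype = g)
        utils::write.csv(m, file.path(config$out_dir,
                                      paste0("chord_", g, ".csv")))
      }
      nrow(results$graph$edges)
    },
    homeostasis = function() {
      panel <- names(config$calibration)
      results$screen <<- homeostasis_screen(
        results$fit, results$collapsed, metabolites = panel,
        alpha = config$homeostasis_alpha)
      write_tsv(results$screen$records,
                file.path(config$out_dir, "screen.tsv"))
      nrow(results$screen$records)
    },
    renal = function() {
      ratios <- reabsorption_ratios(results$collapsed, results$design,
                                    urine_site = config$urine_site,
                                    creatinine = config$creatinine)
      results$reabsorption <<- ratios
      results$reabsorption_contrast <<- reabsorption_contrast(
        ratios, alpha = config$alpha,
        normality_alpha = config$normality_alpha,
        invert_gate = config$invert_gate)
      write_tsv(ratios, file.path(config$out_dir, "reabsorption.tsv"))
      write_tsv(results$reabsorption_contrast,
                file.path(config$out_dir, "reabsorption_contrast.tsv"))
      if (!is.null(config$tracer)) {
        tr <- utils::read.delim(config$tracer, stringsAsFactors = FALSE)
        crea <- results$collapsed[
          results$collapsed$site_id == config$urine_site &
            results$collapsed$metabolite_id == config$creatinine, ,
          drop = FALSE]
        results$tracer <<- tracer_summary(
          tr, stats::setNames(crea$ion_count, crea$animal_id),
          results$design)
        write_tsv(results$tracer$indices,
                  file.path(config$out_dir, "tracer.tsv"))
      }
      nrow(results$reabsorption_contrast)
    }
  )

  for (nm in names(stages)) {
    res <- tryCatch(stages[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[nm]] <- list(status = "failed",
                                    error = conditionMessage(res))
      failed <- nm
      break
    }
    manifest$stages[[nm]] <- list(status = "complete", rows = res)
  }
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       null = "null")
  if (!is.null(failed))
    stop("pipeline failed at stage '", failed, "'; partial outputs in ",
         config$out_dir)
  invisible(results)
}

#' Write a synthetic cohort to disk
#'
#' Emits the abundance, QC, design, organ map and tracer tables of a
#' [generate_cohort()] result in the TSV dialects [run_pipeline()] reads, so
#' a synthetic cohort can exercise the on-disk pipeline end to end.
#'
#' @param cohort an `av_cohort`.
#' @param dir output directory (created if missing).
#' @return named character vector of the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "av_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             qc = file.path(dir, "qc.tsv"),
             animals = file.path(dir, "animals.tsv"),
             sites = file.path(dir, "sites.tsv"),
             organ_map = file.path(dir, "organ_map.tsv"),
             tracer = file.path(dir, "tracer.tsv"))
  write_tsv(cohort$abundance, paths["abundance"])
  write_tsv(cohort$qc, paths["qc"])
  write_tsv(cohort$design$animals, paths["animals"])
  write_tsv(cohort$design$sites, paths["sites"])
  write_tsv(as.data.frame(cohort$map), paths["organ_map"])
  if (!is.null(cohort$tracer)) write_tsv(cohort$tracer, paths["tracer"])
  else paths <- paths[names(paths) != "tracer"]
  paths
}
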