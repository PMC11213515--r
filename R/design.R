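#' Construct a study design
#'
#' Bundles the animal table and sampling-site table describing an
#' arteriovenous metabolomics cohort. Animals are genotyped (`WT`/`CF`) and
#' may be littermate-paired: a shared `pair_id` links exactly one WT and one
#' CF sibling, which is what powers the paired genotype contrasts.
#'
#' @param animals data.frame with columns `animal_id`, `genotype` (`"WT"` or
#'   `"CF"`), `litter_id`, `pair_id` (NA when unpaired), `sex` (`"M"`/`"F"`).
#' @param sites data.frame with columns `site_id`, `kind` (`"arterial"`,
#'   `"venous"` or `"urine"`) and free-text `label`.
#' @return an object of class `av_design` (list with `animals`, `sites`).
#' @seealso [validate_design()], [default_sites()]
#' @export
study_design <- function(animals, sites) {
  animals <- as.data.frame(animals)
  sites <- as.data.frame(sites)
  need_a <- c("animal_id", "genotype", "litter_id", "pair_id", "sex")
  need_s <- c("site_id", "kind", "label")
  stopifnot(all(need_a %in% names(animals)), all(need_s %in% names(sites)))
  structure(list(animals = animals, sites = sites), class = "av_design")
}

#' @export
print.av_design <- function(x, ...) {
  tab <- table(x$animals$genotype)
  cat(sprintf("AV study design: %d animals (%s), %d sampling sites\n",
              nrow(x$animals),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$sites)))
  n_pairs <- length(unique(stats::na.omit(x$animals$pair_id)))
  cat(sprintf("  littermate pairs: %d\n", n_pairs))
  invisible(x)
}

#' Default blood and urine sampling sites
#'
#' The sampling scheme of a whole-body AV study in a large animal: systemic
#' arterial references (aorta, femoral artery), the right ventricle (mixed
#' venous blood entering the lung), organ-draining veins, the dual liver
#' inflow (hepatic artery and portal vein), and bladder urine.
#'
#' @return data.frame with columns `site_id`, `kind`, `label`.
#' @export
default_sites <- function() {
  data.frame(
    site_id = c("aorta", "femoral_artery", "hepatic_artery", "right_ventricle",
                "portal_vein", "hepatic_vein", "jugular_vein", "coronary_sinus",
                "splenic_vein", "renal_vein", "femoral_vein", "bladder_urine"),
    kind = c("arterial", "arterial", "arterial", "venous",
             "venous", "venous", "venous", "venous",
             "venous", "venous", "venous", "urine"),
    label = c("aorta", "femoral artery", "hepatic artery", "right ventricle",
              "portal vein", "hepatic vein", "jugular vein", "coronary sinus",
              "splenic vein", "renal vein", "femoral vein", "bladder urine"),
    stringsAsFactors = FALSE
  )
}

#' Construct an organ plumbing map
#'
#' Describes, for each organ, which sampling sites carry its inflow (with
#' mixture weights) and which site drains it. The flux statistic for an organ
#' is log2(outflow / weighted-inflow), so the map is the single place where
#' anatomy enters the analysis.
#'
#' @param entries data.frame with one row per organ inflow component:
#'   columns `organ`, `inflow_site`, `weight`, `outflow_site`, and logical
#'   `renormalize` (if `TRUE`, missing inflow sites are tolerated by
#'   renormalizing the weights over the measured ones -- appropriate for
#'   redundant arterial references, not for true anatomical mixtures).
#' @return data.frame of class `organ_map`.
#' @export
organ_map <- function(entries) {
  entries <- as.data.frame(entries)
  need <- c("organ", "inflow_site", "weight", "outflow_site", "renormalize")
  stopifnot(all(need %in% names(entries)))
  class(entries) <- c("organ_map", "data.frame")
  entries
}

#' Default organ plumbing map
#'
#' Eight organs / body parts. The liver inflow is the anatomical mixture of
#' hepatic artery (22%) and portal vein (78%). The lung is fed by mixed
#' venous blood from the right ventricle and drains into the systemic
#' arterial circulation, so its inflow site is the right ventricle and its
#' outflow the aorta; the same log2(outflow/inflow) statistic then covers
#' every organ. All other organs use the mean of the two systemic arterial
#' sites as inflow reference (renormalizable: if only one was sampled it is
#' used alone), and their draining vein as outflow.
#'
#' @return an [organ_map()] data.frame.
#' @export
default_organ_map <- function() {
  arterial_ref <- function(organ, outflow) {
    data.frame(organ = organ,
               inflow_site = c("aorta", "femoral_artery"),
               weight = c(0.5, 0.5),
               outflow_site = outflow,
               renormalize = TRUE)
  }
  entries <- rbind(
    data.frame(organ = "lung", inflow_site = "right_ventricle", weight = 1,
               outflow_site = "aorta", renormalize = FALSE),
    arterial_ref("head", "jugular_vein"),
    arterial_ref("heart", "coronary_sinus"),
    arterial_ref("spleen", "splenic_vein"),
    arterial_ref("kidney", "renal_vein"),
    data.frame(organ = "liver",
               inflow_site = c("hepatic_artery", "portal_vein"),
               weight = c(0.22, 0.78),
               outflow_site = "hepatic_vein", renormalize = FALSE),
    arterial_ref("intestine", "portal_vein"),
    arterial_ref("leg", "femoral_vein")
  )
  organ_map(entries)
}

map_organs <- function(map) unique(map$organ)

#' Resolve the inflow abundance of an organ
#'
#' Computes the weighted-average inflow abundance Sum(w_i * abundance_i) for
#' one animal and metabolite from a replicate-collapsed abundance table.
#' Single-inflow organs return that site's abundance unchanged.
#'
#' @param collapsed replicate-collapsed abundance table (columns `animal_id`,
#'   `site_id`, `metabolite_id`, `ion_count`), see [collapse_replicates()].
#' @param map an [organ_map()].
#' @param organ organ name present in `map`.
#' @param animal_id,metabolite_id keys selecting the measurements.
#' @return the resolved inflow abundance, or `NA` when a required inflow site
#'   is unmeasured (for `renormalize = TRUE` organs the weights are instead
#'   renormalized over the measured sites, and `NA` is returned only when
#'   none is measured).
#' @export
resolve_inflow_abundance <- function(collapsed, map, organ, animal_id,
                                     metabolite_id) {
  e <- map[map$organ == organ, , drop = FALSE]
  if (nrow(e) == 0L) stop("unknown organ: ", organ)
  if (abs(sum(e$weight) - 1) > 1e-9)
    stop("inflow weights for organ '", organ, "' do not sum to 1")
  rows <- collapsed$animal_id == animal_id &
    collapsed$metabolite_id == metabolite_id
  vals <- collapsed$ion_count[rows][match(e$inflow_site,
                                          collapsed$site_id[rows])]
  ok <- !is.na(vals)
  if (!all(ok)) {
    if (!e$renormalize[1] || !any(ok)) return(NA_real_)
    w <- e$weight[ok] / sum(e$weight[ok])
    return(sum(w * vals[ok]))
  }
  sum(e$weight * vals)
}

outflow_site_of <- function(map, organ) {
  unique(map$outflow_site[map$organ == organ])
}

#' Validate a study design and organ map
#'
#' Reports every violation of the design invariants: unknown or missing
#' genotypes, littermate pairs that are not exactly one WT plus one CF,
#' duplicated site ids, invalid site kinds, organ inflow weights that do not
#' sum to one or fall outside \[0, 1\], outflow sites that coincide with an
#' inflow site, and map references to undeclared sites.
#'
#' @param design an [study_design()] object.
#' @param map an [organ_map()] (optional).
#' @return data.frame with columns `scope`, `id`, `problem`; zero rows iff
#'   the design is internally consistent.
#' @export
validate_design <- function(design, map = NULL) {
  a <- design$animals; s <- design$sites
  bad <- list()
  note <- function(scope, id, problem)
    bad[[length(bad) + 1L]] <<- data.frame(scope = scope, id = as.character(id),
                                           problem = problem)
  miss_g <- is.na(a$genotype) | !(a$genotype %in% c("WT", "CF"))
  for (id in a$animal_id[miss_g])
    note("animal", id, "genotype missing or not WT/CF")
  for (p in unique(stats::na.omit(a$pair_id))) {
    g <- a$genotype[!is.na(a$pair_id) & a$pair_id == p]
    if (!(length(g) == 2L && setequal(g, c("WT", "CF"))))
      note("pair", p, "littermate pair is not exactly one WT and one CF")
  }
  if (anyDuplicated(s$site_id))
    for (id in unique(s$site_id[duplicated(s$site_id)]))
      note("site", id, "duplicated site id")
  for (id in s$site_id[!(s$kind %in% c("arterial", "venous", "urine"))])
    note("site", id, "kind must be arterial, venous or urine")
  if (!is.null(map)) {
    for (o in map_organs(map)) {
      e <- map[map$organ == o, , drop = FALSE]
      if (abs(sum(e$weight) - 1) > 1e-9)
        note("organ", o, "inflow weights do not sum to 1")
      if (any(e$weight < 0 | e$weight > 1))
        note("organ", o, "inflow weight outside [0, 1]")
      if (any(e$outflow_site %in% e$inflow_site))
        note("organ", o, "outflow site equals an inflow site")
      missing_sites <- setdiff(c(e$inflow_site, e$outflow_site), s$site_id)
      for (m in missing_sites)
        note("organ", o, paste0("references undeclared site '", m, "'"))
    }
  }
  if (length(bad) == 0L)
    return(data.frame(scope = character(), id = character(),
                      problem = character()))
  do.call(rbind, bad)
}
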