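#' Concentration-flux correlation for one organ cell
#'
#' Tests whether an organ's net release/uptake of a metabolite tracks its
#' circulating concentration: Spearman correlation between the per-animal
#' inflow concentration \[X\] and the per-animal log2(V/A). A significant
#' negative rho (release falling as concentration rises) is the signature of
#' homeostatic set-point regulation.
#'
#' @param concentration per-animal inflow concentrations (for the liver this
#'   is the weighted portal/arterial mixture, i.e. the resolved inflow).
#' @param log2_va per-animal log2(V/A), aligned with `concentration`.
#' @param alpha significance level for the direction call.
#' @param min_n minimum animals with both quantities.
#' @return list: `n`, `rho`, `p_value`, `direction` (`"inverse"`, `"direct"`
#'   or `"none"`), `flagged` (insufficient n or zero rank variance).
#' @export
concentration_flux_correlation <- function(concentration, log2_va,
                                           alpha = 0.05, min_n = 4L) {
  stopifnot(length(concentration) == length(log2_va))
  keep <- is.finite(concentration) & is.finite(log2_va)
  if (sum(keep) < min_n)
    return(list(n = sum(keep), rho = NA_real_, p_value = NA_real_,
                direction = "none", flagged = TRUE))
  sc <- spearman_correlation(concentration[keep], log2_va[keep])
  direction <- if (sc$flagged || is.na(sc$p_value) || sc$p_value >= alpha)
    "none" else if (sc$rho < 0) "inverse" else "direct"
  list(n = sc$n, rho = sc$rho, p_value = sc$p_value, direction = direction,
       flagged = sc$flagged)
}

#' Homeostasis screen across metabolites and organs
#'
#' Runs [concentration_flux_correlation()] for every calibrated metabolite x
#' organ x genotype cell of an AV flux fit. Genotypes are screened
#' separately and never pooled. Per-cell p-values are reported uncorrected
#' (each cell is its own hypothesis, as in heatmap-with-stars displays);
#' Benjamini-Hochberg q-values across the screen are added for transparency
#' but do not enter the direction call.
#'
#' @param fit an [avflux()] fit (its `samples` supply per-animal log2(V/A)).
#' @param abundance the collapsed abundance table the fit was built from
#'   (used to recover per-animal inflow concentrations).
#' @param metabolites metabolite ids with absolute calibration (the screen
#'   panel); an empty vector yields an empty screen.
#' @param alpha per-cell significance level.
#' @param min_n minimum animals per cell.
#' @return object of class `homeostasis_screen`: list with `records` (organ,
#'   metabolite, genotype, n, rho, p, q, direction) and `summary` (per
#'   genotype: cells tested, significant, inverse, direct; per-organ inverse
#'   counts).
#' @export
homeostasis_screen <- function(fit, abundance, metabolites, alpha = 0.05,
                               min_n = 4L) {
  stopifnot(inherits(fit, "avflux"))
  if (length(metabolites) == 0L) {
    empty <- data.frame(organ = character(), metabolite_id = character(),
                        genotype = character(), n = integer(),
                        rho = numeric(), p = numeric(), q = numeric(),
                        direction = character())
    return(structure(list(records = empty, summary = empty, alpha = alpha),
                     class = "homeostasis_screen"))
  }
  abundance <- as.data.frame(abundance)
  if ("replicate" %in% names(abundance))
    abundance <- collapse_replicates(abundance)
  abundance <- abundance[abundance$metabolite_id %in% metabolites, ,
                         drop = FALSE]
  arr <- abundance_array(abundance)
  animals <- dimnames(arr)[[2]]
  map <- fit$map
  s <- fit$samples[fit$samples$metabolite_id %in% metabolites, , drop = FALSE]
  organs <- map_organs(map)
  res <- vector("list", 0L)
  for (o in organs) {
    inflow <- inflow_matrix(arr, map, o)
    so <- s[s$organ == o, , drop = FALSE]
    for (g in unique(so$genotype)) {
      sg <- so[so$genotype == g, , drop = FALSE]
      for (m in intersect(metabolites, dimnames(arr)[[3]])) {
        sm <- sg[sg$metabolite_id == m, , drop = FALSE]
        conc <- inflow[match(sm$animal_id, animals), m]
        cc <- concentration_flux_correlation(conc, sm$log2_va, alpha = alpha,
                                             min_n = min_n)
        res[[length(res) + 1L]] <- data.frame(
          organ = o, metabolite_id = m, genotype = g, n = cc$n,
          rho = cc$rho, p = cc$p_value, direction = cc$direction)
      }
    }
  }
  records <- do.call(rbind, res)
  rownames(records) <- NULL
  records$q <- NA_real_
  for (g in unique(records$genotype)) {
    idx <- records$genotype == g
    records$q[idx] <- bh_fdr(records$p[idx])
  }
  records <- records[c("organ", "metabolite_id", "genotype", "n", "rho",
                       "p", "q", "direction")]
  summ <- do.call(rbind, lapply(unique(records$genotype), function(g) {
    rg <- records[records$genotype == g, , drop = FALSE]
    per_organ <- vapply(organs, function(o)
      sum(rg$direction[rg$organ == o] == "inverse"), integer(1))
    data.frame(genotype = g, n_cells = nrow(rg),
               n_significant = sum(rg$direction != "none"),
               n_inverse = sum(rg$direction == "inverse"),
               n_direct = sum(rg$direction == "direct"),
               organ = organs, organ_inverse = per_organ)
  }))
  rownames(summ) <- NULL
  structure(list(records = records, summary = summ, alpha = alpha),
            class = "homeostasis_screen")
}

#' @export
print.homeostasis_screen <- function(x, ...) {
  r <- x$records
  cat(sprintf("Homeostasis screen (alpha = %g): %d cells\n", x$alpha, nrow(r)))
  for (g in unique(r$genotype))
    cat(sprintf("  %s: %d significant (%d inverse, %d direct)\n", g,
                sum(r$genotype == g & r$direction != "none"),
                sum(r$genotype == g & r$direction == "inverse"),
                sum(r$genotype == g & r$direction == "direct")))
  invisible(x)
}

#' Heatmap-ready correlation matrix
#'
#' @param x a [homeostasis_screen()].
#' @param genotype genotype to extract.
#' @param ... unused.
#' @return numeric organ x metabolite matrix of Spearman rho values.
#' @export
as.matrix.homeostasis_screen <- function(x, genotype = "WT", ...) {
  r <- x$records[x$records$genotype == genotype, , drop = FALSE]
  organs <- unique(r$organ); mets <- unique(r$metabolite_id)
  m <- matrix(NA_real_, length(organs), length(mets),
              dimnames = list(organs, mets))
  m[cbind(match(r$organ, organs), match(r$metabolite_id, mets))] <- r$rho
  m
}
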