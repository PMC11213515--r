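#' Normalize ion counts to an internal standard
#'
#' Divides every ion count by the count of the spiked internal standard
#' (e.g. 15N-valine) measured in the same sample, i.e. the same
#' (animal, site, replicate) triple. This cancels extraction-yield and
#' injection-volume variability. Samples in which the standard is missing or
#' nonpositive cannot be corrected and are dropped with a message.
#'
#' @param tab long abundance table: columns `animal_id`, `site_id`,
#'   `metabolite_id`, `replicate`, `ion_count`.
#' @param standard metabolite id of the internal standard.
#' @return the table with `ion_count` replaced by the normalized value; the
#'   standard's own rows become exactly 1.
#' @export
normalize_internal_standard <- function(tab, standard = "15N-valine") {
  tab <- as.data.frame(tab)
  key <- paste(tab$animal_id, tab$site_id, tab$replicate, sep = "\r")
  is_std <- tab$metabolite_id == standard
  if (!any(is_std)) stop("internal standard '", standard, "' not in table")
  std <- tab$ion_count[is_std]
  names(std) <- key[is_std]
  denom <- std[key]
  bad <- is.na(denom) | denom <= 0
  if (any(bad)) {
    dropped <- unique(key[bad])
    message(sprintf(
      "normalize_internal_standard: dropping %d sample(s) with missing/zero standard",
      length(dropped)))
    tab <- tab[!bad, , drop = FALSE]
    denom <- denom[!bad]
  }
  tab$ion_count <- tab$ion_count / unname(denom)
  tab
}

#' Collapse injection replicates to their median
#'
#' Each biological sample is injected several times; the per-sample value
#' used for all ratio statistics is the median over injections (midpoint
#' convention for even counts).
#'
#' @param tab long abundance table with a `replicate` column.
#' @return table with one row per animal x site x metabolite and the
#'   `replicate` column removed.
#' @export
collapse_replicates <- function(tab) {
  tab <- as.data.frame(tab)
  agg <- stats::aggregate(
    ion_count ~ animal_id + site_id + metabolite_id, data = tab,
    FUN = stats::median)
  agg[order(agg$animal_id, agg$site_id, agg$metabolite_id), , drop = FALSE]
}

#' Pooled-QC coefficient-of-variation filter
#'
#' Computes, per metabolite, the CV (100 x sample SD / mean) of repeated
#' pooled-QC injections and partitions the metabolites into kept (CV <=
#' threshold), dropped (CV strictly greater than threshold, or undefined
#' because the mean is zero) and un-assessable (fewer than 2 injections;
#' kept, with a warning).
#'
#' @param qc data.frame with columns `metabolite_id`, `injection`,
#'   `ion_count` (pooled-QC injections).
#' @param threshold CV threshold in percent (default 50; exclusion uses a
#'   strict `>`).
#' @return list with `kept`, `dropped`, `unassessable` (character vectors of
#'   metabolite ids) and `report` (data.frame `metabolite_id`, `n`, `cv`,
#'   `decision`).
#' @export
qc_cv_filter <- function(qc, threshold = 50) {
  stopifnot(threshold > 0)
  qc <- as.data.frame(qc)
  ids <- unique(qc$metabolite_id)
  n <- cv <- numeric(length(ids))
  decision <- character(length(ids))
  for (i in seq_along(ids)) {
    v <- qc$ion_count[qc$metabolite_id == ids[i]]
    n[i] <- length(v)
    if (n[i] < 2L) {
      cv[i] <- NA_real_; decision[i] <- "unassessable"
    } else if (mean(v) == 0) {
      cv[i] <- NA_real_; decision[i] <- "dropped"
    } else {
      cv[i] <- 100 * stats::sd(v) / mean(v)
      decision[i] <- if (cv[i] > threshold) "dropped" else "kept"
    }
  }
  if (any(decision == "unassessable"))
    warning(sum(decision == "unassessable"),
            " metabolite(s) have < 2 QC injections and cannot be assessed")
  report <- data.frame(metabolite_id = ids, n = n, cv = cv,
                       decision = decision)
  list(kept = ids[decision == "kept"],
       dropped = ids[decision == "dropped"],
       unassessable = ids[decision == "unassessable"],
       report = report)
}
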