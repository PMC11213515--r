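#' Build the interorgan source-to-sink exchange graph
#'
#' For every metabolite and genotype, emits one directed edge from each organ
#' with significant release (mean log2(V/A) > 0, p < alpha) to each organ
#' with significant uptake (mean log2(V/A) < 0, p < alpha). Edge gating uses
#' the raw per-cell p-values (the matching rule quotes P thresholds);
#' q-values remain available in the flux records.
#'
#' @param fit an [avflux()] fit, or its `records` data.frame.
#' @param alpha edge significance level (default 0.05; e.g. 0.1 for the
#'   relaxed fatty-acid trafficking variant).
#' @param genotype optional genotype subset; default: all genotypes present.
#' @return object of class `exchange_graph`: list with `edges` (one row per
#'   metabolite x source x sink x genotype, carrying both cells' means and
#'   p-values), `organs`, `alpha`.
#' @export
exchange_graph <- function(fit, alpha = 0.05, genotype = NULL) {
  records <- if (inherits(fit, "avflux")) fit$records else as.data.frame(fit)
  organs <- unique(records$organ)
  if (!is.null(genotype))
    records <- records[records$genotype %in% genotype, , drop = FALSE]
  r <- records[!is.na(records$p) & records$p < alpha, , drop = FALSE]
  edges <- vector("list", 0L)
  for (g in unique(r$genotype)) {
    rg <- r[r$genotype == g, , drop = FALSE]
    for (m in unique(rg$metabolite_id)) {
      rm_ <- rg[rg$metabolite_id == m, , drop = FALSE]
      src <- rm_[rm_$mean_log2_va > 0, , drop = FALSE]
      snk <- rm_[rm_$mean_log2_va < 0, , drop = FALSE]
      if (nrow(src) == 0L || nrow(snk) == 0L) next
      grid <- expand.grid(si = seq_len(nrow(src)), ki = seq_len(nrow(snk)))
      edges[[length(edges) + 1L]] <- data.frame(
        metabolite_id = m,
        source_organ = src$organ[grid$si],
        sink_organ = snk$organ[grid$ki],
        genotype = g, alpha = alpha,
        source_mean = src$mean_log2_va[grid$si],
        source_p = src$p[grid$si],
        sink_mean = snk$mean_log2_va[grid$ki],
        sink_p = snk$p[grid$ki])
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(metabolite_id = character(), source_organ = character(),
               sink_organ = character(), genotype = character(),
               alpha = numeric(), source_mean = numeric(),
               source_p = numeric(), sink_mean = numeric(),
               sink_p = numeric())
  rownames(edges) <- NULL
  structure(list(edges = edges, organs = organs, alpha = alpha),
            class = "exchange_graph")
}

#' @export
print.exchange_graph <- function(x, ...) {
  e <- x$edges
  cat(sprintf("Interorgan exchange graph (alpha = %g): %d edges\n",
              x$alpha, nrow(e)))
  for (g in unique(e$genotype))
    cat(sprintf("  %s: %d edges, %d metabolites exchanged\n", g,
                sum(e$genotype == g),
                length(unique(e$metabolite_id[e$genotype == g]))))
  invisible(x)
}

#' Exchange counts for one organ
#'
#' @param graph an [exchange_graph()].
#' @param organ organ name.
#' @param genotype optional genotype filter.
#' @return named numeric: `outgoing` (edges with this organ as source),
#'   `incoming` (as sink), `total`.
#' @export
organ_exchange_counts <- function(graph, organ, genotype = NULL) {
  e <- graph$edges
  if (!is.null(genotype)) e <- e[e$genotype == genotype, , drop = FALSE]
  if (!(organ %in% graph$organs))
    warning("organ '", organ, "' not present in the underlying flux fit")
  out <- sum(e$source_organ == organ)
  inc <- sum(e$sink_organ == organ)
  c(outgoing = out, incoming = inc, total = out + inc)
}

#' Chord-diagram count matrix
#'
#' Square organ x organ matrix of directed edge counts (rows = source,
#' columns = sink), the numeric backbone of a chord diagram.
#'
#' @param x an [exchange_graph()].
#' @param genotype optional genotype filter.
#' @param ... unused.
#' @return integer matrix with organ dimnames; its total equals the number
#'   of edges counted.
#' @export
as.matrix.exchange_graph <- function(x, genotype = NULL, ...) {
  e <- x$edges
  if (!is.null(genotype)) e <- e[e$genotype == genotype, , drop = FALSE]
  organs <- x$organs
  m <- matrix(0L, length(organs), length(organs),
              dimnames = list(source = organs, sink = organs))
  if (nrow(e))
    for (i in seq_len(nrow(e)))
      m[e$source_organ[i], e$sink_organ[i]] <-
        m[e$source_organ[i], e$sink_organ[i]] + 1L
  m
}

#' @describeIn as.matrix.exchange_graph heatmap of the source x sink count
#'   matrix (one panel per genotype).
#' @export
plot.exchange_graph <- function(x, genotype = NULL, ...) {
  genos <- if (is.null(genotype)) unique(x$edges$genotype) else genotype
  if (length(genos) == 0L) genos <- NA
  old <- graphics::par(mfrow = c(1, max(1L, length(genos))),
                       mar = c(6, 6, 3, 1))
  on.exit(graphics::par(old))
  for (g in genos) {
    m <- as.matrix(x, genotype = if (is.na(g)) NULL else g)
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                    axes = FALSE, xlab = "sink", ylab = "",
                    main = if (is.na(g)) "exchange" else g,
                    col = grDevices::hcl.colors(25, "Blues 3", rev = TRUE))
    graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2)
    graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2)
  }
  invisible(x)
}
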