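# From a recruitment matrix to a presence verdict. A genuinely resident
# genome recruits high-identity reads across its full length; a genome that
# is absent but shares universally conserved loci (rRNA operons) with a
# resident recruits only at those loci; a chimeric reference scaffold whose
# end is host sequence recruits only at that end. The verdict formalizes the
# visual reading of a recruitment plot into three stored metrics.

#' Breadth, concentration and edge metrics of high-identity recruitment
#'
#' Computed from the sub-matrix at identity >= `hi_identity`:
#' * `breadth_hi` — fraction of position bins with at least one read;
#' * `concentration` — fraction of high-identity reads falling in the most
#'   populated 5% of position bins (at least one bin), near 1 when
#'   recruitment collapses onto a single conserved locus;
#' * `edge_fraction` — fraction of high-identity reads in the first and last
#'   `edge_window` of the sequential axis (every bin overlapping either
#'   window counts as edge), near 1
#'   for a chimeric scaffold end;
#' * `n_hi_reads` — the high-identity read count.
#'
#' @param m A `recruitment_matrix` whose position bins cover the reference.
#' @param hi_identity High-identity cutoff in percent (default 90).
#' @param edge_window Fraction of the axis counted as each edge (default 0.1).
#' @param top_bin_frac Fraction of bins treated as the concentrated core
#'   (default 0.05).
#' @return Tibble with one row: sample_id, reference_id, breadth_hi,
#'   concentration, edge_fraction, n_hi_reads.
#' @export
presence_metrics <- function(m, hi_identity = 90, edge_window = 0.1,
                             top_bin_frac = 0.05) {
  stopifnot(inherits(m, "recruitment_matrix"))
  if (hi_identity < m$id_floor) {
    abort("`hi_identity` below the matrix identity floor; rebuild the matrix")
  }
  lower_edges <- m$id_floor + (seq_len(ncol(m$counts)) - 1L) * m$id_bin_size
  hi <- m$counts[, lower_edges >= hi_identity, drop = FALSE]
  per_bin <- rowSums(hi)
  n_bins <- length(per_bin)
  if (n_bins == 1L) {
    warn("reference shorter than one position bin; breadth is 0 or 1")
  }
  n_hi <- sum(per_bin)
  breadth <- mean(per_bin > 0)
  k <- max(1L, as.integer(ceiling(top_bin_frac * n_bins)))
  concentration <- if (n_hi == 0L) 0 else
    sum(sort(per_bin, decreasing = TRUE)[seq_len(k)]) / n_hi
  bin_start <- (seq_len(n_bins) - 1) * m$pos_bin_size
  bin_end <- pmin(bin_start + m$pos_bin_size, m$layout$total_length)
  w <- edge_window * m$layout$total_length
  is_edge <- bin_start < w | bin_end > m$layout$total_length - w
  edge_fraction <- if (n_hi == 0L) 0 else sum(per_bin[is_edge]) / n_hi
  tibble(
    sample_id = m$sample_id, reference_id = m$reference_id,
    breadth_hi = breadth, concentration = concentration,
    edge_fraction = edge_fraction, n_hi_reads = as.integer(n_hi)
  )
}

#' Thresholds for presence calling
#'
#' Defaults: a reference is `present` when high-identity reads cover at least
#' 80% of its position bins; an `edge_artifact` when at least 90% of them sit
#' in the terminal windows while breadth stays under 20%; a
#' `conserved_locus_artifact` when breadth is at most 10% with at least 80%
#' of reads concentrated in the top bins; anything else (including fewer
#' than `min_reads` high-identity reads) is `absent`. `min_reads` scales
#' with sample depth — 50 reads per 1e5 sequenced — so shallow test runs
#' behave like full-depth runs.
#'
#' @param min_reads Minimum high-identity reads for any non-absent verdict,
#'   at a depth of `depth_reference` reads.
#' @param sample_depth Optional total reads in the sample; when given,
#'   `min_reads` is rescaled by `sample_depth / depth_reference`.
#' @param depth_reference Depth at which `min_reads` is quoted (1e5).
#' @param present_breadth_min,edge_fraction_min,edge_breadth_max,
#'   locus_breadth_max,locus_concentration_min Rule thresholds (fractions).
#' @return A validated `presence_thresholds` list.
#' @export
presence_thresholds <- function(min_reads = 50, sample_depth = NULL,
                                depth_reference = 1e5,
                                present_breadth_min = 0.8,
                                edge_fraction_min = 0.9,
                                edge_breadth_max = 0.2,
                                locus_breadth_max = 0.1,
                                locus_concentration_min = 0.8) {
  if (!is.null(sample_depth)) {
    min_reads <- min_reads * sample_depth / depth_reference
  }
  th <- list(min_reads = min_reads,
             present_breadth_min = present_breadth_min,
             edge_fraction_min = edge_fraction_min,
             edge_breadth_max = edge_breadth_max,
             locus_breadth_max = locus_breadth_max,
             locus_concentration_min = locus_concentration_min)
  for (nm in names(th)) assert_scalar_number(th[[nm]], nm, lower = 0)
  if (th$present_breadth_min <= th$locus_breadth_max ||
      th$present_breadth_min <= th$edge_breadth_max) {
    abort("contradictory thresholds: presence floor must exceed artifact breadth ceilings")
  }
  structure(th, class = "presence_thresholds")
}

#' Call presence of a reference in a sample
#'
#' A pure function of the stored metrics, applied in fixed order: (1) too few
#' high-identity reads -> absent; (2) edge-concentrated with low breadth ->
#' edge_artifact; (3) broad high-identity recruitment -> present; (4) very
#' low breadth with high concentration -> conserved_locus_artifact; (5)
#' otherwise absent, with the metrics retained for inspection.
#'
#' @param metrics Tibble from [presence_metrics()] (one or more rows).
#' @param thresholds A [presence_thresholds()] object.
#' @return `metrics` with a `verdict` column (factor: present, absent,
#'   conserved_locus_artifact, edge_artifact) prepended after the labels.
#' @export
call_presence <- function(metrics, thresholds = presence_thresholds()) {
  stopifnot(inherits(thresholds, "presence_thresholds"))
  need <- c("breadth_hi", "concentration", "edge_fraction", "n_hi_reads")
  if (!all(need %in% names(metrics))) {
    abort("`metrics` must carry breadth_hi, concentration, edge_fraction, n_hi_reads")
  }
  if (any(!is.finite(as.matrix(metrics[, need])))) abort("non-finite metrics")
  v <- with(thresholds, dplyr::case_when(
    metrics$n_hi_reads < min_reads ~ "absent",
    metrics$edge_fraction >= edge_fraction_min &
      metrics$breadth_hi < edge_breadth_max ~ "edge_artifact",
    metrics$breadth_hi >= present_breadth_min ~ "present",
    metrics$breadth_hi <= locus_breadth_max &
      metrics$concentration >= locus_concentration_min ~
      "conserved_locus_artifact",
    TRUE ~ "absent"
  ))
  metrics$verdict <- factor(v, levels = c("present", "absent",
                                          "conserved_locus_artifact",
                                          "edge_artifact"))
  front <- intersect(c("sample_id", "reference_id", "verdict"), names(metrics))
  metrics[, c(front, setdiff(names(metrics), front))]
}
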