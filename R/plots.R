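# ggplot2 views of the analysis: the fragment recruitment heat map,
# rarefaction curves, stacked abundance bars and the verdict summary.

#' Render a fragment recruitment plot
#'
#' Heat map of log10(count + 1) over the (position x identity) grid:
#' x = sequential genome position (labelled in megabases, 1-based), y =
#' percent identity, with scaffold boundaries drawn as vertical lines. A
#' resident genome shows a horizontal band near 100(1 - divergence)%
#' identity across the full axis; artifacts show isolated columns.
#'
#' @param m A `recruitment_matrix`.
#' @param path Optional output path (PNG/SVG/PDF by extension); when NULL
#'   the ggplot object is returned without writing.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly when written.
#' @export
render_recruitment_plot <- function(m, path = NULL, width = 8, height = 4) {
  stopifnot(inherits(m, "recruitment_matrix"))
  g <- recruitment_long(m)
  p <- ggplot2::ggplot(g, ggplot2::aes(
    x = (.data$pos_mid + 1) / 1e6, y = .data$id_mid,
    fill = .data$log_count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10(reads + 1)") +
    ggplot2::labs(
      x = "Genome position (Mb)", y = "Identity (%)",
      title = sprintf("%s vs %s", m$sample_id, m$reference_id)) +
    ggplot2::theme_minimal()
  bounds <- m$layout$offsets[-1L]
  if (length(bounds) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = (bounds + 1) / 1e6,
                                 linewidth = 0.2, colour = "grey30")
  }
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(p)
}

recruitment_long <- function(m) {
  tm <- transform_matrix(m)
  g <- expand.grid(pos_bin = seq_len(nrow(tm)), id_bin = seq_len(ncol(tm)))
  g$pos_mid <- (g$pos_bin - 0.5) * m$pos_bin_size
  g$id_mid <- m$id_floor + (g$id_bin - 0.5) * m$id_bin_size
  g$count <- as.vector(m$counts)
  g$log_count <- as.vector(tm)
  as_tibble(g)
}

#' Plot rarefaction curves
#'
#' @param curves Tibble from [rarefaction_curve()] (rows from several samples
#'   may be bound together).
#' @param path Optional output path.
#' @return ggplot object.
#' @export
plot_rarefaction <- function(curves, path = NULL) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$depth, y = .data$expected_taxa, colour = .data$sample_id)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Subsampling depth (rRNA hits)",
                  y = "Expected distinct taxa", colour = "Sample") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Stacked relative-abundance bars for taxonomic profiles
#'
#' @param profiles List of [taxon_profile()] objects.
#' @param path Optional output path.
#' @return ggplot object.
#' @export
plot_taxon_bars <- function(profiles, path = NULL) {
  d <- bind_rows(lapply(profiles, function(p) {
    ra <- relative_abundance(p)
    tibble(sample_id = p$sample_id, taxon = names(ra), fraction = ra)
  }))
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$sample_id, y = .data$fraction, fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Sample x reference verdict heat map
#'
#' @param calls Tibble from [call_presence()] over several samples and
#'   references.
#' @param path Optional output path.
#' @return ggplot object.
#' @export
plot_verdicts <- function(calls, path = NULL) {
  p <- ggplot2::ggplot(calls, ggplot2::aes(
    x = .data$reference_id, y = .data$sample_id, fill = .data$verdict)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      present = "#1b7837", absent = "grey85",
      conserved_locus_artifact = "#f1a340", edge_artifact = "#998ec3"),
      drop = FALSE) +
    ggplot2::labs(x = "Candidate reference", y = "Sample", fill = "Verdict") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
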