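# The recruitment core: lay fragmented references out on one sequential
# axis, bin identity-scored alignments in position x identity space, and
# summarise per-scaffold read densities.

#' Lay out reference scaffolds on one sequential axis
#'
#' Fragmented genomes are concatenated (conceptually) into one sequential
#' coordinate axis for binning and plotting; `offsets` give each scaffold's
#' start on that axis.
#'
#' @param scaffolds Named integer vector of scaffold lengths (ordered), or a
#'   data frame with columns `label` and `length`.
#' @return A `reference_layout`: list(labels, lengths, offsets, total_length).
#' @examples
#' lay <- build_layout(c(A = 1000L, B = 500L))
#' global_position(lay, "B", 10L)  # 1010
#' @export
build_layout <- function(scaffolds) {
  if (is.data.frame(scaffolds)) {
    scaffolds <- setNames(scaffolds$length, scaffolds$label)
  }
  if (length(scaffolds) == 0L) abort("empty scaffold list")
  if (is.null(names(scaffolds)) || any(!nzchar(names(scaffolds)))) {
    abort("scaffolds must be named")
  }
  if (anyDuplicated(names(scaffolds))) abort("duplicate scaffold labels")
  if (any(scaffolds <= 0)) abort("scaffold lengths must be positive")
  lengths <- as.integer(scaffolds)
  offsets <- cumsum(c(0L, lengths[-length(lengths)]))
  structure(
    list(labels = names(scaffolds), lengths = lengths,
         offsets = setNames(as.integer(offsets), names(scaffolds)),
         total_length = sum(as.numeric(lengths))),
    class = "reference_layout"
  )
}

#' Scaffold-local to sequential-axis coordinates
#'
#' @param layout A [build_layout()] object.
#' @param scaffold Scaffold label(s).
#' @param pos 0-based scaffold-local position(s).
#' @return 0-based position(s) on the sequential axis.
#' @export
global_position <- function(layout, scaffold, pos) {
  stopifnot(inherits(layout, "reference_layout"))
  if (!all(scaffold %in% layout$labels)) {
    abort(sprintf("scaffold '%s' absent from layout",
                  setdiff(scaffold, layout$labels)[1L]))
  }
  unname(layout$offsets[scaffold]) + as.integer(pos)
}

#' Sequential-axis to scaffold-local coordinates
#'
#' @param layout A [build_layout()] object.
#' @param gpos 0-based position(s) on the sequential axis.
#' @return Tibble with columns `scaffold` and `pos` (0-based local).
#' @export
local_position <- function(layout, gpos) {
  stopifnot(inherits(layout, "reference_layout"))
  if (any(gpos < 0 | gpos >= layout$total_length)) {
    abort("position outside the sequential axis")
  }
  idx <- findInterval(gpos, layout$offsets)
  tibble(scaffold = layout$labels[idx],
         pos = as.integer(gpos - layout$offsets[idx]))
}

#' Bin alignments in position x identity space
#'
#' Each primary record increments one cell of a (position bin x identity bin)
#' grid: position bins of `pos_bin` bases along the sequential axis (a
#' record's position is its leftmost aligned base), identity bins of
#' `id_bin` percent from `id_floor` up to 100. Identity intervals are
#' half-open \[x, x + id_bin) except the top bin, which is closed at 100 so
#' perfect matches are representable. Records below `id_floor` are not
#' binned but tallied in `n_unbinned`, so that binned counts plus
#' `n_unbinned` always equals the number of input records.
#'
#' @param records Tibble from [alignment_records()]/[read_sam()]; primary
#'   records only.
#' @param layout A [build_layout()] covering every scaffold referenced.
#' @param pos_bin Position bin size in bases (default 50,000).
#' @param id_bin Identity bin width in percent (default 1).
#' @param id_floor Lowest identity retained in the grid (default 70).
#' @param sample_id,reference_id Labels carried on the matrix.
#' @return A `recruitment_matrix` object.
#' @export
bin_alignments <- function(records, layout, pos_bin = 50000L, id_bin = 1,
                           id_floor = 70, sample_id = "sample",
                           reference_id = "reference") {
  stopifnot(inherits(layout, "reference_layout"))
  assert_scalar_number(pos_bin, "pos_bin", lower = 1)
  assert_scalar_number(id_bin, "id_bin", lower = 1e-6, upper = 100)
  assert_scalar_number(id_floor, "id_floor", lower = 0, upper = 100 - id_bin)
  if (any(!records$is_primary)) {
    abort("non-primary records present; drop them before binning")
  }
  miss <- setdiff(unique(records$ref_id), layout$labels)
  if (length(miss) > 0L) {
    abort(sprintf("record references scaffold '%s' absent from layout", miss[1L]))
  }
  n_pos <- as.integer(ceiling(layout$total_length / pos_bin))
  n_id <- as.integer(ceiling((100 - id_floor) / id_bin))
  identity <- compute_identity(records)
  g <- global_position(layout, records$ref_id, records$pos)
  keep <- identity >= id_floor
  pb <- pmin(as.integer(g[keep] %/% pos_bin) + 1L, n_pos)
  ib <- pmin(as.integer(floor((identity[keep] - id_floor) / id_bin)) + 1L, n_id)
  counts <- matrix(0L, nrow = n_pos, ncol = n_id,
                   dimnames = list(
                     pos_start = format((seq_len(n_pos) - 1L) * pos_bin,
                                        scientific = FALSE, trim = TRUE),
                     id_lower = format(id_floor + (seq_len(n_id) - 1L) * id_bin,
                                       trim = TRUE)))
  if (length(pb) > 0L) {
    t <- table(factor(pb, levels = seq_len(n_pos)),
               factor(ib, levels = seq_len(n_id)))
    counts[] <- as.integer(t)
  }
  structure(
    list(counts = counts, pos_bin_size = as.integer(pos_bin),
         id_bin_size = id_bin, id_floor = id_floor, layout = layout,
         n_unbinned = sum(!keep), n_records = nrow(records),
         sample_id = sample_id, reference_id = reference_id),
    class = "recruitment_matrix"
  )
}

#' @export
print.recruitment_matrix <- function(x, ...) {
  cat(sprintf(
    "<recruitment_matrix> %s vs %s: %d x %d bins (%d b x %s%%), %d record(s), %d unbinned\n",
    x$sample_id, x$reference_id, nrow(x$counts), ncol(x$counts),
    x$pos_bin_size, format(x$id_bin_size), x$n_records, x$n_unbinned))
  invisible(x)
}

#' Log-transform a recruitment matrix
#'
#' Per-bin read counts span orders of magnitude between a dominant cyanobiont
#' and a 1% endophyte; plots therefore use log10(count + 1), which keeps
#' empty bins at zero and is monotone in the count.
#'
#' @param m A `recruitment_matrix`.
#' @return A numeric matrix of log10(count + 1) values.
#' @export
transform_matrix <- function(m) {
  stopifnot(inherits(m, "recruitment_matrix"))
  log10(m$counts + 1)
}

#' Per-scaffold read density at an identity cutoff
#'
#' Counts records at or above `min_identity` per scaffold and normalizes per
#' kilobase of scaffold length, the summary used to rank candidate scaffolds
#' across samples. Both the linear density and a log10 view are returned;
#' zero densities have no log and are reported as NA ("below scale").
#'
#' @param records Alignment records tibble (primary only).
#' @param scaffolds Named integer vector of scaffold lengths.
#' @param min_identity Identity cutoff in percent (default 97).
#' @param sample_id Label stamped on the rows.
#' @return Tibble: sample_id, scaffold, length, reads_at_or_above_cutoff,
#'   density (reads/kb), log_density.
#' @export
per_scaffold_summary <- function(records, scaffolds, min_identity = 97,
                                 sample_id = "sample") {
  if (is.null(names(scaffolds)) || any(scaffolds <= 0)) {
    abort("`scaffolds` must be a named vector of positive lengths")
  }
  identity <- compute_identity(records)
  qual <- records$ref_id[identity >= min_identity]
  counts <- table(factor(qual, levels = names(scaffolds)))
  density <- as.numeric(counts) / (as.numeric(scaffolds) / 1000)
  tibble(
    sample_id = sample_id,
    scaffold = names(scaffolds),
    length = as.integer(scaffolds),
    reads_at_or_above_cutoff = as.integer(counts),
    density = density,
    log_density = ifelse(density > 0, log10(density), NA_real_)
  )
}
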