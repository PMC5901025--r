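# Taxonomic-profile summaries: host-taxon masking, relative abundance,
# Shannon diversity, rarefaction and habitat overlap. Profiles arrive as
# count tables from external rRNA profilers; nothing here re-does taxonomic
# assignment.

#' Construct a taxonomic profile
#'
#' @param sample_id Sample label.
#' @param rank Taxonomic rank of the counts ("class", "order", ...).
#' @param counts Named non-negative integer vector, taxon -> count.
#' @param masked Character vector of taxa masked as host-derived; masked
#'   counts are retained for audit but excluded from every statistic.
#' @return A `taxon_profile` object.
#' @export
taxon_profile <- function(sample_id, rank, counts, masked = character(0)) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("`counts` must be fully named")
  }
  if (anyDuplicated(names(counts))) abort("duplicate taxon labels")
  if (any(counts < 0)) abort("negative counts")
  structure(
    list(sample_id = sample_id, rank = rank,
         counts = setNames(as.integer(counts), names(counts)),
         masked = unique(as.character(masked))),
    class = "taxon_profile"
  )
}

unmasked_counts <- function(p) {
  x <- p$counts[setdiff(names(p$counts), p$masked)]
  x[x > 0]
}

#' @export
print.taxon_profile <- function(x, ...) {
  um <- x$counts[setdiff(names(x$counts), x$masked)]
  cat(sprintf("<taxon_profile> %s (%s): %d taxa (%d masked), total %d\n",
              x$sample_id, x$rank, length(x$counts), length(x$masked),
              sum(um)))
  invisible(x)
}

#' Default host-derived taxon blocklist
#'
#' The labels removed before looking for low-abundance endophytes in a plant
#' holobiont: plastid, plant-nuclear, mitochondrial, cyanobacterial and
#' unclassified assignments. Plant mitochondrial rRNA absent from reference
#' databases is typically misassigned to Rickettsiales; extend the blocklist
#' with that label where it applies rather than special-casing it.
#'
#' @param keep_unclassified Retain "unclassified" assignments (default FALSE).
#' @return Character vector of taxon labels.
#' @export
default_host_blocklist <- function(keep_unclassified = FALSE) {
  b <- c("Chloroplast", "Viridiplantae", "Mitochondria", "Cyanobacteria")
  if (!keep_unclassified) b <- c(b, "unclassified")
  b
}

#' Mask host-derived taxa in a profile
#'
#' Blocked taxa are moved to the masked set; their counts stay stored for
#' audit. Blocking everything yields an empty profile with a warning.
#'
#' @param p A [taxon_profile()].
#' @param blocklist Taxon labels to mask (matched exactly).
#' @return The filtered `taxon_profile`.
#' @export
filter_host_taxa <- function(p, blocklist = default_host_blocklist()) {
  stopifnot(inherits(p, "taxon_profile"))
  p$masked <- union(p$masked, intersect(blocklist, names(p$counts)))
  if (sum(unmasked_counts(p)) == 0L) {
    warn(sprintf("profile '%s': all counts masked, total is 0", p$sample_id))
  }
  p
}

#' Relative abundance of unmasked taxa
#'
#' @param p A [taxon_profile()] with a positive unmasked total.
#' @return Named numeric vector of fractions summing to 1.
#' @export
relative_abundance <- function(p) {
  stopifnot(inherits(p, "taxon_profile"))
  x <- unmasked_counts(p)
  if (sum(x) == 0L) {
    abort("profile total is 0 after masking; handle the empty profile upstream")
  }
  x / sum(x)
}

#' Shannon diversity of a profile
#'
#' H = -sum f_i log f_i over unmasked taxa with positive counts; natural log
#' by default with a base switch for log2 users. A single-taxon profile has
#' H = 0.
#'
#' @param p A [taxon_profile()].
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon diversity (numeric scalar).
#' @export
shannon <- function(p, base = exp(1)) {
  stopifnot(inherits(p, "taxon_profile"))
  x <- unmasked_counts(p)
  if (sum(x) == 0L) abort("profile total is 0")
  as.numeric(vegan::diversity(x, index = "shannon", base = base))
}

#' Shannon diversity summarized over sample groups
#'
#' @param profiles List of [taxon_profile()] objects.
#' @param groups Optional character vector (one per profile) of group labels;
#'   defaults to one group.
#' @param base Logarithm base.
#' @return Tibble: group, n, mean_shannon, sd_shannon.
#' @export
shannon_summary <- function(profiles, groups = NULL, base = exp(1)) {
  h <- vapply(profiles, shannon, numeric(1), base = base)
  groups <- groups %||% rep("all", length(profiles))
  tibble(group = groups, shannon = h) |>
    group_by(.data$group) |>
    summarise(n = n(), mean_shannon = mean(.data$shannon),
              sd_shannon = stats::sd(.data$shannon), .groups = "drop")
}

#' Rarefaction curve of a profile
#'
#' Expected number of distinct taxa seen in a subsample of each depth.
#' Analytic mode uses the hypergeometric expectation
#' E\[S(n)\] = sum_i (1 - choose(N - N_i, n) / choose(N, n)) (via
#' [vegan::rarefy()]); Monte-Carlo mode subsamples without replacement and
#' averages. Curves are non-decreasing in depth and bounded by the observed
#' richness.
#'
#' @param p A [taxon_profile()].
#' @param depths Integer vector of subsampling depths (analytic mode requires
#'   depths <= total).
#' @param mode "analytic" or "montecarlo".
#' @param reps Monte-Carlo replicates (>= 1).
#' @param seed Seed for Monte-Carlo subsampling.
#' @return Tibble: sample_id, depth, expected_taxa.
#' @export
rarefaction_curve <- function(p, depths, mode = c("analytic", "montecarlo"),
                              reps = 100L, seed = NULL) {
  stopifnot(inherits(p, "taxon_profile"))
  mode <- match.arg(mode)
  x <- unmasked_counts(p)
  total <- sum(x)
  if (total == 0L) abort("profile total is 0")
  depths <- as.integer(depths)
  if (any(depths < 1L)) abort("depths must be >= 1")
  if (mode == "analytic") {
    if (any(depths > total)) {
      abort(sprintf("analytic rarefaction requires depths <= total (%d)", total))
    }
    es <- vapply(depths, function(n) {
      # vegan::rarefy warns when the community has no singletons; that advice
      # concerns richness extrapolation, not the expectation computed here
      withCallingHandlers(
        as.numeric(vegan::rarefy(x, sample = n)),
        warning = function(w) {
          if (grepl("smallest count", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    }, numeric(1))
  } else {
    if (reps < 1L) abort("reps must be >= 1")
    pool <- rep.int(seq_along(x), x)
    es <- with_seed_if(seed, vapply(depths, function(n) {
      n <- min(n, total)
      mean(vapply(seq_len(reps), function(r) {
        length(unique(pool[sample.int(total, n)]))
      }, numeric(1)))
    }, numeric(1)))
  }
  tibble(sample_id = p$sample_id, depth = depths, expected_taxa = es)
}

#' Taxon overlap between two habitats
#'
#' Shared unmasked taxa between two profiles at the same rank, with a
#' presence threshold.
#'
#' @param pA,pB [taxon_profile()] objects at the same rank.
#' @param min_count Minimum count for a taxon to count as present (default 1).
#' @return List: `n_shared` and `shared` (labels).
#' @export
habitat_overlap <- function(pA, pB, min_count = 1L) {
  stopifnot(inherits(pA, "taxon_profile"), inherits(pB, "taxon_profile"))
  if (!identical(pA$rank, pB$rank)) {
    abort(sprintf("rank mismatch: '%s' vs '%s'", pA$rank, pB$rank))
  }
  a <- unmasked_counts(pA)
  b <- unmasked_counts(pB)
  shared <- intersect(names(a)[a >= min_count], names(b)[b >= min_count])
  list(n_shared = length(shared), shared = shared)
}

#' Read taxonomic profiles from a count table
#'
#' Expects a TSV with columns `sample_id`, `rank`, `taxon`, `count`, one row
#' per sample x taxon, as produced by external rRNA profilers.
#'
#' @param path TSV path.
#' @param rank Keep only rows at this rank (default: all ranks, which must
#'   then be unique per sample).
#' @return Named list of [taxon_profile()] objects, one per sample.
#' @export
read_taxon_table <- function(path, rank = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "rank", "taxon", "count")
  if (!all(need %in% names(tab))) {
    abort(paste0("count table must have columns: ", paste(need, collapse = ", ")))
  }
  if (!is.null(rank)) tab <- tab[tab$rank == rank, ]
  out <- lapply(split(tab, tab$sample_id), function(d) {
    if (length(unique(d$rank)) != 1L) {
      abort(sprintf("sample '%s' mixes ranks; pass `rank=` to select one",
                    d$sample_id[1L]))
    }
    taxon_profile(d$sample_id[1L], d$rank[1L],
                  setNames(d$count, d$taxon))
  })
  out
}

#' Simulate an rRNA-profiler count table for a holobiont sample
#'
#' Multinomial draw of rRNA hits over taxa, emulating the output of an
#' external profiler on a community dominated by host-derived assignments
#' (plastid, nuclear, cyanobiont) with low-abundance endophyte taxa.
#'
#' @param abundances Named numeric vector of true taxon proportions
#'   (summing to 1).
#' @param n_hits Number of rRNA hits to draw.
#' @param sample_id,rank Labels.
#' @param seed Integer seed.
#' @return A [taxon_profile()].
#' @export
simulate_taxon_profile <- function(abundances, n_hits, sample_id = "S1",
                                   rank = "order", seed = NULL) {
  if (abs(sum(abundances) - 1) > 1e-9 || any(abundances < 0)) {
    abort("`abundances` must be non-negative and sum to 1")
  }
  counts <- with_seed_if(seed, {
    as.integer(stats::rmultinom(1L, size = n_hits, prob = abundances))
  })
  taxon_profile(sample_id, rank, setNames(counts, names(abundances)))
}
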