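# Screening a host genome assembly for bacterial scaffolds. rRNA gene
# detection is external (an rRNA-hit table is consumed, never computed);
# this module applies the length filter that separates scaffolds worth
# downstream annotation from short hit-bearing fragments, and offers an
# advisory tetranucleotide-composition score that never overrides the rRNA
# evidence.

#' Screen assembly scaffolds for bacterial candidates
#'
#' Every scaffold with at least one rRNA hit is listed; those of at least
#' `min_len` bases become candidates for downstream annotation, shorter ones
#' are kept with verdict `rejected(short)`. Hit taxonomy is carried through
#' verbatim. Scaffolds without hits do not appear.
#'
#' @param assembly Path to an assembly FASTA, or a named integer vector of
#'   scaffold lengths.
#' @param rrna_hits Data frame (or TSV path) with columns `scaffold`,
#'   `gene`, `start`, `end`, `taxon` (1-based inclusive coordinates, as
#'   emitted by rRNA predictors).
#' @param min_len Minimum candidate length in bases (default 100,000).
#' @return Tibble: scaffold, taxon, length, n_rrna_hits, passes_length,
#'   verdict — one row per hit-bearing scaffold, in assembly order.
#' @export
screen_scaffolds <- function(assembly, rrna_hits, min_len = 100000L) {
  if (is.character(assembly) && length(assembly) == 1L && file.exists(assembly)) {
    seqs <- Biostrings::readDNAStringSet(assembly)
    lens <- setNames(Biostrings::width(seqs), names(seqs))
  } else {
    lens <- assembly
  }
  if (is.null(names(lens))) abort("assembly scaffolds must be named")
  if (is.character(rrna_hits) && length(rrna_hits) == 1L) {
    rrna_hits <- readr::read_tsv(rrna_hits, show_col_types = FALSE)
  }
  need <- c("scaffold", "gene", "start", "end", "taxon")
  if (!all(need %in% names(rrna_hits))) {
    abort(paste0("rRNA hit table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  unknown <- setdiff(unique(rrna_hits$scaffold), names(lens))
  if (length(unknown) > 0L) {
    abort(sprintf("rRNA hit references unknown scaffold '%s'", unknown[1L]))
  }
  bad <- rrna_hits$start < 1 | rrna_hits$end < rrna_hits$start |
    rrna_hits$end > lens[rrna_hits$scaffold]
  if (any(bad)) {
    abort(sprintf("malformed hit coordinates on scaffold '%s'",
                  rrna_hits$scaffold[which(bad)[1L]]))
  }
  hit_scaffolds <- intersect(names(lens), unique(rrna_hits$scaffold))
  rows <- lapply(hit_scaffolds, function(s) {
    h <- rrna_hits[rrna_hits$scaffold == s, ]
    len <- as.integer(lens[[s]])
    tibble(
      scaffold = s,
      taxon = paste(unique(h$taxon), collapse = ";"),
      length = len,
      n_rrna_hits = nrow(h),
      passes_length = len >= min_len,
      verdict = if (len >= min_len) "candidate" else "rejected(short)"
    )
  })
  if (length(rows) == 0L) {
    return(tibble(scaffold = character(0), taxon = character(0),
                  length = integer(0), n_rrna_hits = integer(0),
                  passes_length = logical(0), verdict = character(0)))
  }
  bind_rows(rows)
}

tetranucleotide_profile <- function(seq) {
  f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), 4L)
  f / sum(f)
}

#' Tetranucleotide composition divergence of a scaffold
#'
#' Advisory triage score: the Euclidean distance between the scaffold's
#' tetranucleotide frequency vector and the host baseline (all host sequence
#' pooled), standardized against a null distribution of distances from
#' equal-sized windows subsampled from the host itself. Large positive
#' z-scores mark compositionally foreign sequence; the score never overrides
#' rRNA evidence.
#'
#' @param scaffold_seq Scaffold sequence (character; >= `min_len` bases for a
#'   stable 4-mer profile).
#' @param host_seqs Character vector of host baseline sequences.
#' @param n_subsamples Null windows drawn from the host (default 200).
#' @param window Null window size in bases (default: scaffold length, capped
#'   at the host length).
#' @param min_len Minimum sequence length (default 5000).
#' @param seed Seed for subsampling.
#' @return List: `distance` (raw Euclidean distance), `z` (standardized
#'   score), `null_mean`, `null_sd`. When the scaffold is too short, `z` is
#'   NA with a `reason`.
#' @export
composition_divergence <- function(scaffold_seq, host_seqs,
                                   n_subsamples = 200L, window = NULL,
                                   min_len = 5000L, seed = NULL) {
  if (nchar(scaffold_seq) < min_len) {
    return(list(distance = NA_real_, z = NA_real_,
                null_mean = NA_real_, null_sd = NA_real_,
                reason = sprintf("sequence shorter than %d b", min_len)))
  }
  host <- paste(host_seqs, collapse = "")
  if (nchar(host) < min_len) abort("host baseline too short")
  baseline <- tetranucleotide_profile(host)
  d_scaf <- sqrt(sum((tetranucleotide_profile(scaffold_seq) - baseline)^2))
  window <- as.integer(min(window %||% nchar(scaffold_seq),
                           nchar(host)))
  null <- with_seed_if(seed, {
    starts <- sample.int(nchar(host) - window + 1L, n_subsamples,
                         replace = TRUE)
    vapply(starts, function(s) {
      w <- substr(host, s, s + window - 1L)
      sqrt(sum((tetranucleotide_profile(w) - baseline)^2))
    }, numeric(1))
  })
  list(distance = d_scaf, z = (d_scaf - mean(null)) / stats::sd(null),
       null_mean = mean(null), null_sd = stats::sd(null))
}
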