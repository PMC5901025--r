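# Sequence primitives for the community simulator. Sequences are plain
# character strings over {A,C,G,T}; Biostrings handles file I/O, these
# helpers handle the simulation arithmetic on raw byte vectors, which is
# orders of magnitude faster than per-character R loops.

DNA_BASES_RAW <- charToRaw("ACGT")

#' Generate a random genome sequence
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content. This is the
#' background model for simulated host and endophyte genomes; real genomes
#' have k-mer structure that this deliberately ignores (see the methods
#' vignette).
#'
#' @param length Sequence length in bases (> 0).
#' @param gc Target GC fraction in \[0, 1\].
#' @param seed Optional integer seed for reproducibility.
#' @return A single character string of `length` bases.
#' @examples
#' nchar(random_genome(100, seed = 1))
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL) {
  assert_scalar_number(length, "length", lower = 1)
  assert_scalar_number(gc, "gc", lower = 0, upper = 1)
  with_seed_if(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    rawToChar(DNA_BASES_RAW[sample.int(4L, length, replace = TRUE, prob = p)])
  })
}

check_acgt <- function(seq) {
  bad <- gregexpr("[^ACGT]", seq)[[1L]]
  if (bad[1L] != -1L) {
    abort(sprintf("sequence contains non-ACGT character at position %d", bad[1L]))
  }
  invisible(seq)
}

# Substitute raw bytes at `idx` with a base drawn uniformly from the 3
# alternatives to the current base (rejection sampling; expected < 1.4 draws).
substitute_bases <- function(bytes, idx) {
  if (length(idx) == 0L) return(bytes)
  cur <- bytes[idx]
  new <- DNA_BASES_RAW[sample.int(4L, length(idx), replace = TRUE)]
  same <- new == cur
  while (any(same)) {
    new[same] <- DNA_BASES_RAW[sample.int(4L, sum(same), replace = TRUE)]
    same <- new == cur
  }
  bytes[idx] <- new
  bytes
}

#' Mutate a sequence by independent per-base substitution
#'
#' Each position is substituted independently with probability `divergence`,
#' the replacement drawn uniformly from the three alternative bases. This is
#' the generative model behind the identity bands seen in recruitment plots:
#' a resident genome at divergence d from its reference recruits reads in a
#' band centred near 100(1 - d) percent identity.
#'
#' @param seq Non-empty character string over {A,C,G,T}.
#' @param divergence Per-base substitution probability in \[0, 1).
#' @param seed Optional integer seed; the result is deterministic given it.
#' @return A character string of the same length.
#' @examples
#' mutate_sequence("ACGTACGT", 0)          # unchanged
#' mutate_sequence("ACGTACGT", 0.5, seed = 1)
#' @export
mutate_sequence <- function(seq, divergence, seed = NULL) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    abort("`seq` must be a single non-empty string")
  }
  assert_scalar_number(divergence, "divergence", lower = 0, upper = 1 - 1e-12)
  check_acgt(seq)
  if (divergence == 0) return(seq)
  with_seed_if(seed, {
    bytes <- charToRaw(seq)
    idx <- which(runif(length(bytes)) < divergence)
    rawToChar(substitute_bases(bytes, idx))
  })
}

#' Reverse-complement nucleotide sequences
#'
#' @param seqs Character vector of ACGT sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seqs) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", seqs))
}

# Per-read mismatch counts between two equal-length character vectors of
# equal-width strings, via one concatenated raw comparison.
count_mismatches_fixed_width <- function(a, b, width) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  diff <- charToRaw(paste(a, collapse = "")) != charToRaw(paste(b, collapse = ""))
  as.integer(colSums(matrix(diff, nrow = width)))
}
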