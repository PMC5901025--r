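# Shotgun read simulation over a community of resident genomes, with
# ground-truth alignments derived from the manifest's homology segments
# rather than from a read mapper. Reads are single-end by default: paired
# ends add nothing to the recruitment arithmetic, where every mate is
# counted independently anyway.

#' Describe a simulated sequencing experiment
#'
#' @param abundances Named numeric vector of relative genome abundances,
#'   summing to 1 (tolerance 1e-9). Names must cover every genome of the
#'   community handed to [simulate_reads()].
#' @param n_reads Number of reads to draw (> 0).
#' @param read_length Read length in bases (default 147, a typical desktop
#'   short-read sequencer average).
#' @param error_rate Per-base substitution error fraction in \[0, 0.05\].
#' @param indel_rate Optional per-base indel rate (default 0). Substitution
#'   -only simulation keeps the identity arithmetic exact; turning indels on
#'   exercises the CIGAR-handling path.
#' @param seed Integer seed.
#' @param replicate_id Sample label (supports triplicate naming such as
#'   "L1", "L2", "L3" and pooled variants).
#' @return A `community_truth` object.
#' @export
community_truth <- function(abundances, n_reads, read_length = 147L,
                            error_rate = 0.005, indel_rate = 0,
                            seed = 1L, replicate_id = "S1") {
  if (is.null(names(abundances)) || any(!nzchar(names(abundances)))) {
    abort("`abundances` must be a fully named numeric vector")
  }
  if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-9) {
    abort("`abundances` must be non-negative and sum to 1 (tolerance 1e-9)")
  }
  assert_scalar_number(n_reads, "n_reads", lower = 1)
  assert_scalar_number(read_length, "read_length", lower = 1)
  assert_scalar_number(error_rate, "error_rate", lower = 0, upper = 0.05)
  assert_scalar_number(indel_rate, "indel_rate", lower = 0, upper = 0.1)
  structure(
    list(abundances = abundances, n_reads = as.integer(n_reads),
         read_length = as.integer(read_length), error_rate = error_rate,
         indel_rate = indel_rate, seed = as.integer(seed),
         replicate_id = replicate_id),
    class = "community_truth"
  )
}

# Apply the indel model to one read: per template base, deletion with
# probability rate/2; after each surviving base, insertion of one random
# base with probability rate/2. Returns the new read string and CIGAR.
apply_indels_one <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  del <- runif(L) < rate / 2
  ins <- runif(L) < rate / 2
  # SAM forbids alignments that start or end in a deletion
  del[c(1L, L)] <- FALSE
  ops <- character(0)
  out <- character(0)
  for (i in seq_len(L)) {
    if (del[i]) {
      ops <- c(ops, "D")
    } else {
      ops <- c(ops, "M")
      out <- c(out, chars[i])
    }
    if (ins[i]) {
      ops <- c(ops, "I")
      out <- c(out, rawToChar(DNA_BASES_RAW[sample.int(4L, 1L)]))
    }
  }
  r <- rle(ops)
  list(seq = paste(out, collapse = ""),
       cigar = paste0(r$lengths, r$values, collapse = ""))
}

#' Simulate shotgun reads from a community
#'
#' Reads are drawn from resident genomes in proportion to their abundances,
#' with uniform start positions, random strand, substitution errors at
#' `error_rate` and (optionally) indels. Each read's ground-truth alignment
#' against the PIPELINE reference of its source genome is computed by direct
#' base comparison, so the recorded edit distance already reflects both the
#' genome's divergence from its reference and sequencing error.
#'
#' @param truth A [community_truth()] object.
#' @param genomes A `community_genomes` object from [simulate_genomes()].
#' @param truth_alignments Annotate every read with its ground-truth mapped
#'   state and edit distance immediately (default TRUE). With FALSE the
#'   annotation is deferred until [write_truth_sam()] needs it, which saves
#'   a pass over the reads when only per-candidate recruitment is wanted.
#' @return A `community_reads` object: list with `reads` (tibble: read_id,
#'   genome, start, t_len, strand, seq, cigar, and — once annotated —
#'   mapped, edit_distance), `truth`, and `genomes`.
#' @export
simulate_reads <- function(truth, genomes, truth_alignments = TRUE) {
  stopifnot(inherits(truth, "community_truth"),
            inherits(genomes, "community_genomes"))
  residents <- genomes$residents
  missing <- setdiff(names(residents), names(truth$abundances))
  if (length(missing) > 0L) {
    abort(paste0("abundances missing for genome(s): ",
                 paste(missing, collapse = ", ")))
  }
  L <- truth$read_length
  glens <- nchar(residents)
  if (L > min(glens)) {
    abort(sprintf("read_length (%d) exceeds shortest genome (%d b)",
                  L, min(glens)))
  }

  with_seed_if(truth$seed, {
    gnames <- names(residents)
    prob <- truth$abundances[gnames]
    src <- gnames[sample.int(length(gnames), truth$n_reads, replace = TRUE,
                             prob = prob)]
    start <- integer(truth$n_reads)
    seqs <- character(truth$n_reads)
    for (g in gnames) {
      idx <- which(src == g)
      if (length(idx) == 0L) next
      s <- sample.int(glens[[g]] - L + 1L, length(idx), replace = TRUE) - 1L
      start[idx] <- s
      seqs[idx] <- substring(residents[[g]], s + 1L, s + L)
    }
    # substitution sequencing errors, one vectorized pass over all bases
    if (truth$error_rate > 0) {
      bytes <- charToRaw(paste(seqs, collapse = ""))
      idx <- which(runif(length(bytes)) < truth$error_rate)
      big <- rawToChar(substitute_bases(bytes, idx))
      off <- (seq_along(seqs) - 1L) * L
      seqs <- substring(big, off + 1L, off + L)
    }
    cigar <- rep(paste0(L, "M"), truth$n_reads)
    t_len <- rep(L, truth$n_reads)
    if (truth$indel_rate > 0) {
      for (i in seq_len(truth$n_reads)) {
        r <- apply_indels_one(seqs[i], truth$indel_rate)
        seqs[i] <- r$seq
        cigar[i] <- r$cigar
      }
    }
    strand <- ifelse(runif(truth$n_reads) < 0.5, "+", "-")
    reads <- tibble(
      read_id = sprintf("%s_read%06d", truth$replicate_id,
                        seq_len(truth$n_reads)),
      genome = src, start = start, t_len = t_len, strand = strand,
      seq = seqs, cigar = cigar
    )
    sim <- structure(list(reads = reads, truth = truth, genomes = genomes),
                     class = "community_reads")
    if (truth_alignments) sim$reads <- annotate_truth_alignment(sim)
    sim
  })
}

# Mark each read mapped/unmapped against its own genome's reference (a read
# is mapped where a self segment of that reference covers its template span)
# and record the true edit distance by base comparison.
annotate_truth_alignment <- function(sim) {
  reads <- sim$reads
  segs <- sim$genomes$manifest$segments
  refs <- sim$genomes$references
  reads$mapped <- FALSE
  reads$edit_distance <- NA_integer_
  self <- segs[segs$kind %in% c("self", "self_head"), ]
  for (k in seq_len(nrow(self))) {
    s <- self[k, ]
    sel <- which(reads$genome == s$genome &
                   reads$start >= s$g_start &
                   reads$start + reads$t_len <= s$g_start + s$length)
    if (length(sel) == 0L) next
    pos <- s$ref_start + (reads$start[sel] - s$g_start)
    reads$mapped[sel] <- TRUE
    reads$edit_distance[sel] <- nm_against_reference(
      reads$seq[sel], reads$cigar[sel], refs[[s$ref_id]], pos)
  }
  reads
}

# Edit distance (mismatches + inserted + deleted bases) of each read against
# a window of `ref` starting at 0-based `pos`, honouring the CIGAR.
nm_against_reference <- function(seqs, cigars, ref, pos) {
  nm <- integer(length(seqs))
  plain <- !grepl("[ID]", cigars)
  if (any(plain)) {
    w <- nchar(seqs[plain])
    if (length(unique(w)) == 1L) {
      refwin <- substring(ref, pos[plain] + 1L, pos[plain] + w[1L])
      nm[plain] <- count_mismatches_fixed_width(seqs[plain], refwin, w[1L])
    } else {
      for (i in which(plain)) {
        refwin <- substr(ref, pos[i] + 1L, pos[i] + nchar(seqs[i]))
        nm[i] <- sum(charToRaw(seqs[i]) != charToRaw(refwin))
      }
    }
  }
  for (i in which(!plain)) {
    nm[i] <- nm_by_cigar(seqs[i], ref, pos[i], cigars[i])
  }
  nm
}

# CIGAR walk: count mismatches over M/=/X columns plus all I and D bases.
nm_by_cigar <- function(seq, ref, pos, cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  qi <- 0L
  ri <- pos
  nm <- 0L
  for (k in seq_along(ops)) {
    n <- lens[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      a <- charToRaw(substr(seq, qi + 1L, qi + n))
      b <- charToRaw(substr(ref, ri + 1L, ri + n))
      nm <- nm + sum(a != b)
      qi <- qi + n
      ri <- ri + n
    } else if (op == "I") {
      nm <- nm + n
      qi <- qi + n
    } else if (op == "D" || op == "N") {
      nm <- nm + n
      ri <- ri + n
    } else if (op == "S") {
      qi <- qi + n
    } # H, P consume nothing here
  }
  as.integer(nm)
}

#' Ground-truth recruitment of simulated reads onto one reference
#'
#' Emulates mapping the whole sample against a single candidate reference,
#' the way fragment recruitment is run in practice: each read aligns wherever
#' the manifest records homology between its source genome and the candidate
#' (the genome's own reference over its full length, a shared rRNA-like locus,
#' or the host-derived tail of a chimeric scaffold). Each read is reported at
#' most once (its lowest-edit-distance placement), emulating a
#' best-single-alignment mapper. Edit distances come from direct base
#' comparison against the candidate reference sequence.
#'
#' @param sim A `community_reads` object.
#' @param reference_id Name of the candidate reference scaffold.
#' @return Tibble of alignment records: read_id, ref_id, pos (0-based),
#'   cigar, seq, flag, edit_distance.
#' @export
recruitment_alignments <- function(sim, reference_id) {
  stopifnot(inherits(sim, "community_reads"))
  refs <- sim$genomes$references
  if (!reference_id %in% names(refs)) {
    abort(sprintf("unknown reference '%s'", reference_id))
  }
  segs <- sim$genomes$manifest$segments
  segs <- segs[segs$ref_id == reference_id, ]
  reads <- sim$reads
  hits <- list()
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, ]
    sel <- which(reads$genome == s$genome &
                   reads$start >= s$g_start &
                   reads$start + reads$t_len <= s$g_start + s$length)
    if (length(sel) == 0L) next
    pos <- s$ref_start + (reads$start[sel] - s$g_start)
    hits[[length(hits) + 1L]] <- tibble(
      read_id = reads$read_id[sel],
      ref_id = reference_id,
      pos = as.integer(pos),
      cigar = reads$cigar[sel],
      seq = reads$seq[sel],
      flag = ifelse(reads$strand[sel] == "+", 0L, 16L),
      edit_distance = nm_against_reference(
        reads$seq[sel], reads$cigar[sel], refs[[reference_id]], pos)
    )
  }
  if (length(hits) == 0L) {
    return(tibble(read_id = character(0), ref_id = character(0),
                  pos = integer(0), cigar = character(0), seq = character(0),
                  flag = integer(0), edit_distance = integer(0)))
  }
  out <- bind_rows(hits)
  # one placement per read: best (lowest) edit distance wins
  out <- out[order(out$read_id, out$edit_distance), ]
  out[!duplicated(out$read_id), ]
}

#' Write simulated reads as FASTQ
#'
#' Minus-strand reads are written reverse-complemented, as a sequencer would
#' deliver them. Qualities are constant 'I' (Q40); quality plays no role in
#' the recruitment arithmetic.
#'
#' @param sim A `community_reads` object.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  stopifnot(inherits(sim, "community_reads"))
  reads <- sim$reads
  seqs <- ifelse(reads$strand == "-", reverse_complement(reads$seq), reads$seq)
  lines <- character(4L * nrow(reads))
  lines[seq(1L, length(lines), 4L)] <- paste0("@", reads$read_id)
  lines[seq(2L, length(lines), 4L)] <- seqs
  lines[seq(3L, length(lines), 4L)] <- "+"
  lines[seq(4L, length(lines), 4L)] <- strrep("I", nchar(seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Write the ground-truth SAM for a simulated sample
#'
#' Every read is reported against its source genome's reference where the
#' manifest homology covers it; reads falling outside (e.g. in the resident
#' tail beyond a chimeric junction) are emitted as unmapped records. NM tags
#' carry the true edit distance.
#'
#' @param sim A `community_reads` object.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(sim, path) {
  stopifnot(inherits(sim, "community_reads"))
  if (is.null(sim$reads$mapped)) sim$reads <- annotate_truth_alignment(sim)
  reads <- sim$reads
  refs <- sim$genomes$references
  mapped <- reads[reads$mapped, ]
  recs <- tibble(
    read_id = mapped$read_id, ref_id = mapped$genome,
    pos = self_reference_pos(sim, mapped),
    cigar = mapped$cigar, seq = mapped$seq,
    flag = ifelse(mapped$strand == "+", 0L, 16L),
    edit_distance = mapped$edit_distance
  )
  un <- reads[!reads$mapped, ]
  write_sam(recs, nchar(refs), path, unmapped = un[, c("read_id", "seq")])
}

# 0-based position of each mapped read on its own reference via self segments.
self_reference_pos <- function(sim, mapped) {
  segs <- sim$genomes$manifest$segments
  self <- segs[segs$kind %in% c("self", "self_head"), ]
  pos <- integer(nrow(mapped))
  for (k in seq_len(nrow(self))) {
    s <- self[k, ]
    sel <- which(mapped$genome == s$genome &
                   mapped$start >= s$g_start &
                   mapped$start + mapped$t_len <= s$g_start + s$length)
    pos[sel] <- s$ref_start + (mapped$start[sel] - s$g_start)
  }
  pos
}
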