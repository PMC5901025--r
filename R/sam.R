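# Alignment record handling: SAM I/O through Rsamtools, and the identity
# score at the heart of fragment recruitment. The identity of a read is the
# fraction of alignment columns (matched/mismatched plus inserted plus
# deleted bases; clips excluded) at which read and reference agree —
# gap-compressed identity is deliberately NOT used.

#' Build alignment records from SAM-style fields
#'
#' Decomposes CIGAR strings and combines them with the edit distance (NM:
#' mismatches + inserted + deleted bases) to recover, per record, the number
#' of alignment columns and the number of matching columns:
#' `aligned_cols = M + I + D` and `matches = M - (NM - I - D)` where M counts
#' matched/mismatched columns. Soft/hard clips are excluded throughout.
#'
#' @param read_id,ref_id Character vectors.
#' @param pos Integer vector of 0-based leftmost reference positions.
#' @param cigar Character vector of CIGAR strings.
#' @param edit_distance Integer vector (NM tag values).
#' @param flag SAM flag (default 0); secondary (0x100) and supplementary
#'   (0x800) records are marked non-primary.
#' @param seq Optional read sequences, carried through for sequence-level
#'   cross-checks.
#' @return A tibble with one row per record: read_id, ref_id, pos, cigar,
#'   aligned_cols, matches, edit_distance, is_primary (+ seq if given).
#' @export
alignment_records <- function(read_id, ref_id, pos, cigar, edit_distance,
                              flag = 0L, seq = NULL) {
  n <- length(read_id)
  if (anyNA(edit_distance)) {
    bad <- read_id[which(is.na(edit_distance))[1L]]
    abort(sprintf("record '%s' lacks edit-distance (NM) information", bad))
  }
  if (any(pos < 0)) abort("negative reference position")
  ops <- GenomicAlignments::cigarOpTable(cigar)
  m_cols <- ops[, "M"] + ops[, "="] + ops[, "X"]
  ins <- ops[, "I"]
  del <- ops[, "D"] + ops[, "N"]
  aligned_cols <- m_cols + ins + del
  matches <- m_cols - (edit_distance - ins - del)
  bad <- which(matches < 0 | matches > m_cols | edit_distance > aligned_cols)
  if (length(bad) > 0L) {
    abort(sprintf(
      "record '%s': edit distance %d inconsistent with CIGAR '%s'",
      read_id[bad[1L]], edit_distance[bad[1L]], cigar[bad[1L]]))
  }
  out <- tibble(
    read_id = read_id, ref_id = as.character(ref_id),
    pos = as.integer(pos), cigar = cigar,
    aligned_cols = as.integer(aligned_cols),
    matches = as.integer(matches),
    edit_distance = as.integer(edit_distance),
    is_primary = bitwAnd(as.integer(flag), 0x900L) == 0L
  )
  if (!is.null(seq)) out$seq <- as.character(seq)
  out
}

#' Percent identity of alignment records
#'
#' identity = 100 * matches / aligned_cols, with indel bases counted in the
#' denominator and clips never counted. Secondary and supplementary records
#' are refused: with a best-single-alignment mapping every read contributes
#' exactly one record.
#'
#' @param records Tibble from [alignment_records()] or [read_sam()].
#' @return Numeric vector of percent identities in \[0, 100\].
#' @examples
#' r <- alignment_records("r1", "s1", 0L, "100M", 3L)
#' compute_identity(r)  # 97
#' @export
compute_identity <- function(records) {
  if (any(!records$is_primary)) {
    abort("secondary/supplementary records must be dropped before identity scoring")
  }
  if (any(records$aligned_cols == 0L)) {
    abort("fully clipped record (0 aligned columns); exclude it first")
  }
  100 * records$matches / records$aligned_cols
}

#' Brute-force percent identity from sequences
#'
#' Independent of the NM-based arithmetic in [compute_identity()]: walks the
#' CIGAR over the reference, compares read and reference base by base over
#' the matched/mismatched columns, and divides the match count by all aligned
#' columns (M + I + D). Used to cross-check the identity score.
#'
#' @param seq Read sequence (aligned orientation).
#' @param ref Full reference sequence the record aligns to.
#' @param pos 0-based leftmost reference position.
#' @param cigar CIGAR string.
#' @return Percent identity in \[0, 100\].
#' @export
identity_from_alignment <- function(seq, ref, pos, cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  qi <- 0L
  ri <- as.integer(pos)
  matches <- 0L
  cols <- 0L
  for (k in seq_along(ops)) {
    n <- lens[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      a <- charToRaw(substr(seq, qi + 1L, qi + n))
      b <- charToRaw(substr(ref, ri + 1L, ri + n))
      matches <- matches + sum(a == b)
      cols <- cols + n
      qi <- qi + n
      ri <- ri + n
    } else if (op == "I") {
      cols <- cols + n
      qi <- qi + n
    } else if (op %in% c("D", "N")) {
      cols <- cols + n
      ri <- ri + n
    } else if (op == "S") {
      qi <- qi + n
    }
  }
  100 * matches / cols
}

#' Write alignment records as SAM
#'
#' @param records Tibble with columns read_id, ref_id, pos (0-based), cigar,
#'   seq, flag, edit_distance.
#' @param ref_lengths Named integer vector of reference scaffold lengths
#'   (all become @SQ header lines).
#' @param path Output SAM path.
#' @param unmapped Optional tibble (read_id, seq) of unmapped reads to emit
#'   with flag 4.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref_lengths, path, unmapped = NULL) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths))
  )
  body <- character(0)
  if (nrow(records) > 0L) {
    body <- sprintf(
      "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
      records$read_id, records$flag, records$ref_id,
      internal_to_sam_pos(records$pos), records$cigar, records$seq,
      strrep("I", nchar(records$seq)), records$edit_distance)
  }
  tail <- character(0)
  if (!is.null(unmapped) && nrow(unmapped) > 0L) {
    tail <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                    unmapped$read_id, unmapped$seq,
                    strrep("I", nchar(unmapped$seq)))
  }
  writeLines(c(header, body, tail), path)
  invisible(path)
}

#' Read alignment records from a SAM/BAM file
#'
#' Parses via Rsamtools (SAM input is converted to BAM on the fly). Unmapped
#' reads are dropped with a counter; secondary and supplementary records are
#' dropped with counters, emulating a best-single-alignment mapping where
#' each read is taken once. A mapped record without an NM tag is a hard
#' error: the identity score cannot be computed without it. Positions are
#' converted to the package's 0-based convention.
#'
#' @param path SAM or BAM file path.
#' @return List: `records` (tibble as from [alignment_records()], with seq),
#'   `n_unmapped`, `n_secondary`, `n_supplementary`, `n_clipped_out`
#'   (records excluded for having zero aligned columns).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- x$flag
  unmapped <- bitwAnd(flag, 0x4L) != 0L
  secondary <- bitwAnd(flag, 0x100L) != 0L & !unmapped
  supplementary <- bitwAnd(flag, 0x800L) != 0L & !unmapped
  keep <- !unmapped & !secondary & !supplementary
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  if (anyNA(nm[keep])) {
    abort(sprintf("record '%s' lacks the required NM tag",
                  x$qname[keep][which(is.na(nm[keep]))[1L]]))
  }
  cig <- x$cigar[keep]
  ops <- GenomicAlignments::cigarOpTable(cig)
  cols <- rowSums(ops[, c("M", "=", "X", "I", "D", "N"), drop = FALSE])
  clipped_out <- cols == 0L
  if (any(clipped_out)) {
    inform(sprintf("%d fully clipped record(s) excluded", sum(clipped_out)))
  }
  sel <- which(keep)[!clipped_out]
  records <- alignment_records(
    read_id = x$qname[sel],
    ref_id = as.character(x$rname[sel]),
    pos = sam_to_internal_pos(x$pos[sel]),
    cigar = x$cigar[sel],
    edit_distance = nm[sel],
    flag = x$flag[sel],
    seq = as.character(x$seq[sel])
  )
  list(records = records,
       n_unmapped = sum(unmapped),
       n_secondary = sum(secondary),
       n_supplementary = sum(supplementary),
       n_clipped_out = sum(clipped_out))
}
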