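# TSV round-trip for recruitment matrices: a commented metadata header
# followed by a long-format table, so matrices survive a trip through the
# filesystem with everything needed to re-derive presence metrics.

#' Write a recruitment matrix as TSV
#'
#' @param m A `recruitment_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(inherits(m, "recruitment_matrix"))
  meta <- c(
    sprintf("# sample_id=%s", m$sample_id),
    sprintf("# reference_id=%s", m$reference_id),
    sprintf("# pos_bin_size=%d", m$pos_bin_size),
    sprintf("# id_bin_size=%s", format(m$id_bin_size)),
    sprintf("# id_floor=%s", format(m$id_floor)),
    sprintf("# n_unbinned=%d", m$n_unbinned),
    sprintf("# n_records=%d", m$n_records),
    sprintf("# scaffolds=%s",
            paste(sprintf("%s:%d", m$layout$labels, m$layout$lengths),
                  collapse = ","))
  )
  long <- tibble(
    pos_bin_start = rep(as.integer(rownames(m$counts) |> as.numeric()),
                        times = ncol(m$counts)),
    id_bin_lower = rep(as.numeric(colnames(m$counts)),
                       each = nrow(m$counts)),
    count = as.vector(m$counts)
  )
  writeLines(meta, path)
  readr::write_tsv(long, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a recruitment matrix from TSV
#'
#' @param path A TSV written by [write_matrix_tsv()].
#' @return A `recruitment_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", meta_lines), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                          character(1)),
                   vapply(kv, `[[`, character(1), 1L))
  sc <- strsplit(strsplit(meta[["scaffolds"]], ",", fixed = TRUE)[[1L]],
                 ":", fixed = TRUE)
  layout <- build_layout(setNames(
    as.integer(vapply(sc, `[[`, character(1), 2L)),
    vapply(sc, `[[`, character(1), 1L)))
  long <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  pos_bin <- as.integer(meta[["pos_bin_size"]])
  id_bin <- as.numeric(meta[["id_bin_size"]])
  id_floor <- as.numeric(meta[["id_floor"]])
  n_pos <- as.integer(ceiling(layout$total_length / pos_bin))
  n_id <- as.integer(ceiling((100 - id_floor) / id_bin))
  counts <- matrix(0L, n_pos, n_id,
                   dimnames = list(
                     pos_start = format((seq_len(n_pos) - 1L) * pos_bin,
                                        scientific = FALSE, trim = TRUE),
                     id_lower = format(id_floor + (seq_len(n_id) - 1L) * id_bin,
                                       trim = TRUE)))
  pi <- as.integer(long$pos_bin_start / pos_bin) + 1L
  ii <- as.integer(round((long$id_bin_lower - id_floor) / id_bin)) + 1L
  counts[cbind(pi, ii)] <- as.integer(long$count)
  structure(
    list(counts = counts, pos_bin_size = pos_bin, id_bin_size = id_bin,
         id_floor = id_floor, layout = layout,
         n_unbinned = as.integer(meta[["n_unbinned"]]),
         n_records = as.integer(meta[["n_records"]]),
         sample_id = meta[["sample_id"]],
         reference_id = meta[["reference_id"]]),
    class = "recruitment_matrix"
  )
}
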