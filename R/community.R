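# Simulated holobiont communities with known ground truth.
#
# A community is a set of genomes: a dominant host (plus plastid/cyanobiont
# background if desired) and low-abundance endophytes. For each genome the
# simulator emits two sequences: the REFERENCE handed to the recruitment
# pipeline and the RESIDENT genome actually present in the community, at a
# controlled per-base divergence from the reference. Two artifact mechanisms
# seen in real recruitment plots can be planted: a near-identical rRNA-like
# locus shared across genomes (conserved-locus artifact) and a chimeric
# reference scaffold whose terminal segment is host sequence (edge artifact).

#' Specify one genome of a simulated community
#'
#' @param name Unique genome label.
#' @param length Genome length in bases.
#' @param gc GC fraction in \[0, 1\].
#' @param divergence Expected per-base substitution fraction in \[0, 0.3\]
#'   between the resident genome and the reference given to the pipeline.
#' @param shared_locus Optional `list(length =, identity =, position = NULL)`
#'   describing an rRNA-like segment inserted near-identically into every
#'   genome that declares one: a single master locus sequence is generated
#'   per community and each copy is placed at `identity` (>= 0.97) to the
#'   master. `position` is the 0-based insertion start (default: centred).
#' @param chimera_with Optional `list(host =, junction =, host_start = 0)`
#'   marking the REFERENCE scaffold as a mis-assembly: sequence after
#'   `junction` (a fraction in (0, 1) of the scaffold) is copied verbatim
#'   from the named host genome starting at `host_start` (0-based).
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(name, length, gc = 0.5, divergence = 0,
                        shared_locus = NULL, chimera_with = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  assert_scalar_number(length, "length", lower = 1)
  assert_scalar_number(gc, "gc", lower = 0, upper = 1)
  assert_scalar_number(divergence, "divergence", lower = 0, upper = 0.3)
  if (!is.null(shared_locus)) {
    assert_scalar_number(shared_locus$length, "shared_locus$length",
                         lower = 1, upper = length - 1)
    assert_scalar_number(shared_locus$identity, "shared_locus$identity",
                         lower = 0.97, upper = 1)
    if (!is.null(shared_locus$position)) {
      assert_scalar_number(shared_locus$position, "shared_locus$position",
                           lower = 0, upper = length - shared_locus$length)
    }
  }
  if (!is.null(chimera_with)) {
    stopifnot(is.character(chimera_with$host), nzchar(chimera_with$host))
    j <- chimera_with$junction
    if (!is.numeric(j) || length(j) != 1L || j <= 0 || j >= 1) {
      abort("`chimera_with$junction` must be a fraction strictly inside (0, 1)")
    }
    chimera_with$host_start <- chimera_with$host_start %||% 0
  }
  structure(
    list(name = name, length = as.integer(length), gc = gc,
         divergence = divergence, shared_locus = shared_locus,
         chimera_with = chimera_with),
    class = "genome_spec"
  )
}

#' Simulate reference and resident genomes for a community
#'
#' For each [genome_spec()] a base sequence is drawn, shared loci are planted,
#' the resident genome is derived by substitution at the spec's divergence,
#' and the reference is the base sequence (with the host tail grafted on for
#' chimeric scaffolds). The manifest records every planted coordinate and the
#' homology segments that relate resident genomes to references; downstream
#' ground-truth alignments are computed from those segments.
#'
#' @param specs List of [genome_spec()] objects with unique names.
#' @param seed Integer seed; output is deterministic given it.
#' @return A `community_genomes` object: list with elements `references` and
#'   `residents` (named character vectors of sequences), `manifest` (list of
#'   tibbles `genomes` and `segments`), and `seed`.
#' @export
simulate_genomes <- function(specs, seed = 1L) {
  if (inherits(specs, "genome_spec")) specs <- list(specs)
  stopifnot(length(specs) > 0L,
            all(vapply(specs, inherits, logical(1), "genome_spec")))
  names <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names)) abort("duplicate genome names in `specs`")
  for (s in specs) {
    h <- s$chimera_with$host
    if (!is.null(h) && !(h %in% names)) {
      abort(sprintf("chimera host '%s' is not among the genome names", h))
    }
    if (!is.null(h) && h == s$name) abort("a genome cannot be its own chimera host")
  }

  with_seed_if(seed, {
    locus_specs <- Filter(function(s) !is.null(s$shared_locus), specs)
    master_locus <- NULL
    if (length(locus_specs) > 0L) {
      lens <- vapply(locus_specs, function(s) s$shared_locus$length, numeric(1))
      if (length(unique(lens)) != 1L) {
        abort("all `shared_locus` declarations must use the same length")
      }
      master_locus <- random_genome(lens[[1L]], gc = 0.5)
    }

    bases <- list()
    g_rows <- list()
    for (s in specs) {
      base <- random_genome(s$length, gc = s$gc)
      locus_start <- NA_integer_
      if (!is.null(s$shared_locus)) {
        llen <- as.integer(s$shared_locus$length)
        locus_start <- as.integer(
          s$shared_locus$position %||% ((s$length - llen) %/% 2L)
        )
        copy <- mutate_sequence(master_locus, 1 - s$shared_locus$identity)
        base <- paste0(
          substr(base, 1L, locus_start),
          copy,
          substr(base, locus_start + llen + 1L, s$length)
        )
      }
      bases[[s$name]] <- base
      g_rows[[s$name]] <- tibble(
        name = s$name, length = s$length, gc = s$gc,
        divergence = s$divergence,
        locus_start = locus_start,
        locus_length = if (is.null(s$shared_locus)) NA_integer_
                       else as.integer(s$shared_locus$length),
        locus_identity = if (is.null(s$shared_locus)) NA_real_
                         else s$shared_locus$identity,
        chimera_host = s$chimera_with$host %||% NA_character_,
        junction = if (is.null(s$chimera_with)) NA_real_ else s$chimera_with$junction,
        chimera_host_start = if (is.null(s$chimera_with)) NA_integer_
                             else as.integer(s$chimera_with$host_start)
      )
    }

    residents <- vapply(specs, function(s) {
      mutate_sequence(bases[[s$name]], s$divergence)
    }, character(1))
    names(residents) <- names

    references <- unlist(bases)[names]
    seg_rows <- list()
    for (s in specs) {
      L <- s$length
      if (is.null(s$chimera_with)) {
        seg_rows[[length(seg_rows) + 1L]] <- tibble(
          ref_id = s$name, ref_start = 0L, genome = s$name,
          g_start = 0L, length = L, kind = "self")
      } else {
        j <- as.integer(floor(s$chimera_with$junction * L))
        hs <- as.integer(s$chimera_with$host_start)
        host <- s$chimera_with$host
        host_len <- nchar(bases[[host]])
        tail_len <- L - j
        if (hs + tail_len > host_len) {
          abort(sprintf("chimera tail of '%s' overruns host '%s'", s$name, host))
        }
        references[[s$name]] <- paste0(
          substr(bases[[s$name]], 1L, j),
          substr(bases[[host]], hs + 1L, hs + tail_len)
        )
        seg_rows[[length(seg_rows) + 1L]] <- tibble(
          ref_id = s$name,
          ref_start = c(0L, j),
          genome = c(s$name, host),
          g_start = c(0L, hs),
          length = c(j, tail_len),
          kind = c("self_head", "chimera_tail"))
      }
    }
    # cross-genome homology from the shared locus: donor copies recruit onto
    # every other reference that carries the locus
    gtab <- bind_rows(g_rows)
    carriers <- gtab$name[!is.na(gtab$locus_start)]
    for (r in carriers) {
      for (g in setdiff(carriers, r)) {
        ri <- gtab[gtab$name == r, ]
        gi <- gtab[gtab$name == g, ]
        seg_rows[[length(seg_rows) + 1L]] <- tibble(
          ref_id = r, ref_start = ri$locus_start, genome = g,
          g_start = gi$locus_start, length = ri$locus_length,
          kind = "shared_locus")
      }
    }

    structure(
      list(references = references, residents = residents,
           manifest = list(genomes = gtab, segments = bind_rows(seg_rows)),
           seed = as.integer(seed)),
      class = "community_genomes"
    )
  })
}

#' @export
print.community_genomes <- function(x, ...) {
  cat("<community_genomes> ", length(x$references), " genome(s), seed ",
      x$seed, "\n", sep = "")
  print(x$manifest$genomes[, c("name", "length", "divergence",
                               "locus_start", "chimera_host")])
  invisible(x)
}

#' Write simulated genomes and manifest to disk
#'
#' Writes `references.fasta`, `residents.fasta` and `manifest.json` into
#' `dir`.
#'
#' @param genomes A `community_genomes` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genomes <- function(genomes, dir) {
  stopifnot(inherits(genomes, "community_genomes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genomes$references),
    file.path(dir, "references.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genomes$residents),
    file.path(dir, "residents.fasta"))
  jsonlite::write_json(
    list(seed = genomes$seed,
         genomes = genomes$manifest$genomes,
         segments = genomes$manifest$segments),
    file.path(dir, "manifest.json"),
    dataframe = "columns", na = "null", digits = NA, pretty = TRUE)
  invisible(dir)
}
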