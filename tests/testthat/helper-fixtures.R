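# Small fixtures built in code. Everything is seeded so the suite is
# deterministic.

# A two-genome community small enough for fast unit tests.
tiny_community <- function(seed = 1L, n_reads = 2000L, divergence = 0,
                           error_rate = 0, endo_abundance = 0.2,
                           indel_rate = 0) {
  specs <- list(
    genome_spec("hostA", 60000L, gc = 0.4),
    genome_spec("endoB", 30000L, gc = 0.55, divergence = divergence)
  )
  genomes <- simulate_genomes(specs, seed = seed)
  truth <- community_truth(
    c(hostA = 1 - endo_abundance, endoB = endo_abundance),
    n_reads = n_reads, error_rate = error_rate, indel_rate = indel_rate,
    seed = seed + 1L)
  list(genomes = genomes, sim = simulate_reads(truth, genomes))
}

# Alignment records of a sample recruited onto one reference, in memory.
recruit_records <- function(sim, ref) {
  aln <- recruitment_alignments(sim, ref)
  alignment_records(aln$read_id, aln$ref_id, aln$pos, aln$cigar,
                    aln$edit_distance, flag = aln$flag, seq = aln$seq)
}

# A hand-built alignment with 2 substitutions and a 2-base deletion:
# 98 read bases over 100 reference columns, NM = 4, identity 96.
deletion_fixture <- function() {
  ref <- strrep("ACGTTGCA", 25L)  # 200 b reference
  pos <- 20L                      # 0-based
  tmpl <- substr(ref, pos + 1L, pos + 100L)
  read <- paste0(substr(tmpl, 1, 49), substr(tmpl, 52, 100))
  sub_at <- function(s, i, b) {
    substr(s, i, i) <- b
    s
  }
  for (i in c(10L, 70L)) {
    orig <- substr(read, i, i)
    read <- sub_at(read, i, setdiff(c("A", "C", "G", "T"), orig)[1L])
  }
  list(ref = ref, read = read, pos = pos, cigar = "49M2D49M", nm = 4L)
}
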