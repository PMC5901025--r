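# Planted-truth presence scenarios. Each scenario builds a holobiont
# community — dominant host, plastid and cyanobiont background plus one
# candidate endophyte reference — in one of four configurations with a known
# correct verdict, at desk scale (1e5 reads by default against a ~1.7 Mb
# community). These are the study conditions under which the presence caller
# is validated.

#' Simulate a presence-calling scenario with known truth
#'
#' Community background: host (weight 0.75 of the non-endophyte mass, 800 kb),
#' plastid (0.10, 120 kb) and cyanobiont (0.15, 300 kb), plus a 500 kb
#' candidate endophyte reference handed to the pipeline. The four scenarios:
#'
#' * `present` — the endophyte is resident at `endo_abundance` and
#'   `divergence` from its reference; expected verdict `present`.
#' * `absent` — the endophyte is not in the community; expected `absent`.
#' * `shared_locus` — the endophyte is absent, but its reference and the
#'   resident cyanobiont share a 5 kb rRNA-like locus at 99% identity
#'   (placed on a position-bin boundary of the candidate); expected
#'   `conserved_locus_artifact`.
#' * `chimera` — the endophyte is absent and its reference scaffold is a
#'   mis-assembly whose final 10% is host sequence; expected `edge_artifact`.
#'
#' @param scenario One of "present", "absent", "shared_locus", "chimera".
#' @param seed Integer seed.
#' @param n_reads Reads in the sample (default 1e5).
#' @param endo_abundance Endophyte relative abundance in the `present`
#'   scenario (default 0.02).
#' @param divergence Endophyte divergence from its reference (default 0.02).
#' @param read_length,error_rate Passed to [community_truth()].
#' @return List: `sim` (a `community_reads`), `candidate` (the endophyte
#'   reference name), `expected` (the correct verdict), `scenario`.
#' @export
simulate_presence_scenario <- function(scenario = c("present", "absent",
                                                    "shared_locus", "chimera"),
                                       seed = 1L, n_reads = 1e5,
                                       endo_abundance = 0.02,
                                       divergence = 0.02,
                                       read_length = 147L,
                                       error_rate = 0.005) {
  scenario <- match.arg(scenario)
  candidate <- "endophyte"
  locus <- NULL
  cyano_locus <- NULL
  chim <- NULL
  if (scenario == "shared_locus") {
    # bin-aligned on the candidate so the locus occupies one position bin
    locus <- list(length = 5000, identity = 0.99, position = 100000)
    cyano_locus <- list(length = 5000, identity = 0.99)
  }
  if (scenario == "chimera") {
    chim <- list(host = "host", junction = 0.9, host_start = 0)
  }
  specs <- list(
    genome_spec("host", 8e5, gc = 0.40),
    genome_spec("plastid", 1.2e5, gc = 0.38),
    genome_spec("cyanobiont", 3e5, gc = 0.42, shared_locus = cyano_locus),
    genome_spec(candidate, 5e5, gc = 0.55, divergence = divergence,
                shared_locus = locus, chimera_with = chim)
  )
  a <- if (scenario == "present") endo_abundance else 0
  bg <- c(host = 0.75, plastid = 0.10, cyanobiont = 0.15) * (1 - a)
  abundances <- c(bg, setNames(a, candidate))
  genomes <- simulate_genomes(specs, seed = derive_seed(seed, 11L))
  truth <- community_truth(abundances, n_reads = n_reads,
                           read_length = read_length,
                           error_rate = error_rate,
                           seed = derive_seed(seed, 12L),
                           replicate_id = sprintf("scn_%s_%d", scenario, seed))
  expected <- switch(scenario,
                     present = "present",
                     absent = "absent",
                     shared_locus = "conserved_locus_artifact",
                     chimera = "edge_artifact")
  list(sim = simulate_reads(truth, genomes, truth_alignments = FALSE),
       candidate = candidate, expected = expected, scenario = scenario)
}

#' Recruit and call one presence scenario
#'
#' Convenience wrapper: recruits the sample onto the scenario's candidate
#' reference, bins, computes presence metrics and applies the decision rule
#' with `min_reads` scaled to the sample depth.
#'
#' @param scn A [simulate_presence_scenario()] result.
#' @param hi_identity High-identity cutoff (default 90).
#' @return The one-row calls tibble, with the expected verdict attached as
#'   column `expected`.
#' @export
call_scenario <- function(scn, hi_identity = 90) {
  sim <- scn$sim
  aln <- recruitment_alignments(sim, scn$candidate)
  records <- alignment_records(
    read_id = aln$read_id, ref_id = aln$ref_id, pos = aln$pos,
    cigar = aln$cigar, edit_distance = aln$edit_distance, flag = aln$flag)
  layout <- build_layout(setNames(
    nchar(sim$genomes$references[[scn$candidate]]), scn$candidate))
  m <- bin_alignments(records, layout,
                      sample_id = sim$truth$replicate_id,
                      reference_id = scn$candidate)
  th <- presence_thresholds(sample_depth = sim$truth$n_reads)
  out <- call_presence(presence_metrics(m, hi_identity = hi_identity), th)
  out$expected <- scn$expected
  out
}
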