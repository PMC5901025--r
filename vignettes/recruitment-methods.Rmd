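---
title: "Fragment recruitment and presence calling: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment recruitment and presence calling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endorecruit)
```

## The problem

Shotgun sequencing of a plant holobiont — say a floating fern together with
its leaf-pocket cyanobiont and whatever else lives inside it — yields a read
pool dominated by host nuclear, plastid and cyanobiont DNA, with candidate
endophyte genomes contributing a percent or two at most. Given a candidate
bacterial genome (often a scaffold recovered from the host's own genome
assembly), the question is whether that organism is genuinely resident in a
sample. Simple read counting cannot answer it: universally conserved genes
such as rRNA operons recruit high-identity reads from *any* related organism
in the sample, and chimeric assembly scaffolds recruit host reads along
their mis-joined segment. Both failure modes produce impressive read counts
from an organism that is not there.

Fragment recruitment answers the question spatially. Every read is aligned
to the candidate reference, scored by percent identity, and placed in a
(position × identity) grid. A resident genome produces a horizontal
high-identity band across the **full length** of the reference; the two
artifact classes produce sharply localized columns — at the conserved locus,
or at the chimeric end.

## The identity score

For one aligned read, let M be the matched/mismatched columns of the
alignment, I the inserted and D the deleted bases (soft/hard-clipped bases
excluded throughout), and NM the edit distance (mismatches + I + D). Then

$$\mathrm{identity} = 100 \times \frac{\mathrm{matches}}{M + I + D},
\qquad \mathrm{matches} = M - (NM - I - D).$$

The denominator deliberately includes indel bases ("common bases over the
whole alignment"), not the gap-compressed variant: a read with a 10-base
insertion is less similar to the reference than one without, and the score
should say so. `compute_identity()` implements the NM arithmetic;
`identity_from_alignment()` independently recomputes the same quantity by
walking the CIGAR and comparing bases, and the test suite requires exact
agreement between the two on indel-containing simulated alignments.

Only primary alignments are scored. With a best-single-alignment mapping
each read contributes exactly one record; secondary and supplementary
records are dropped with counters, and a mapped record without an NM tag is
a hard error rather than a silent skip.

## Binning and normalization

Records are binned at 50 kb × 1% identity by default, the identity axis
spanning a configurable floor (70%) to 100%. Identity intervals are
half-open [x, x+1) except the top bin [99, 100], which is closed so perfect
matches are representable. Records below the floor are tallied in
`n_unbinned`, preserving the invariant that binned counts plus unbinned
equal the input count exactly. Fragmented references are first laid out on
one sequential axis (`build_layout()`), with all internal coordinates
0-based half-open; SAM's 1-based positions are converted at the I/O
boundary and plots label 1-based megabases.

Per-bin counts span four orders of magnitude between cyanobiont and
endophyte, so displayed grids are log10(count + 1). For cross-sample
ranking of candidate scaffolds, `per_scaffold_summary()` instead counts
reads at ≥ 97% identity and normalizes per kilobase of scaffold — a
deliberately stricter cutoff than the presence rule below, because ranking
wants to separate near-identical residents from relatives, while presence
only asks whether *some* strain of the candidate is there.

## The presence decision rule

From the sub-matrix at identity ≥ 90% (the "high-identity" regime; a
resident strain diverged up to ~8% from its reference, plus ~0.5%
sequencing error, still clears it), three metrics are stored:

* **breadth_hi** — fraction of position bins holding ≥ 1 high-identity
  read. The signature of genuine residency is breadth near 1.
* **concentration** — fraction of high-identity reads in the most populated
  5% of position bins (at least one bin). Near 1 when recruitment collapses
  onto a single conserved locus.
* **edge_fraction** — fraction of high-identity reads in bins overlapping
  the first or last 10% of the axis. Near 1 for a chimeric scaffold end.

The rule, applied in fixed order: fewer than `min_reads` high-identity
reads → *absent*; edge_fraction ≥ 0.9 with breadth < 0.2 → *edge_artifact*;
breadth ≥ 0.8 → *present*; breadth ≤ 0.1 with concentration ≥ 0.8 →
*conserved_locus_artifact*; otherwise *absent*. The fallback is *absent*
rather than "ambiguous" — conservative, with the metrics retained so a
borderline case can be inspected. The numeric thresholds are this package's
own operationalization of what is, in practice, a visual judgement; they are
declared defaults, validated for internal consistency (the presence floor
must exceed the artifact ceilings) and configurable. `min_reads` is quoted
at a reference depth of 1e5 reads and rescaled by actual sample depth, so
shallow test runs behave like full-depth runs.

The rule is monotone in the right way: adding reads uniformly across the
genome can only increase breadth, so it can never demote *present* to
*absent* (property-tested). Verdicts are a pure function of the stored
metrics; re-calling from a saved calls table reproduces them.

## What the simulator emulates — and what it does not

`simulate_genomes()` / `simulate_reads()` generate communities with the
statistical structure the analysis assumes: a dominant host plus plastid
and cyanobiont background; endophytes at 1–5% abundance; residents at a
controlled per-base substitution divergence from the references handed to
the pipeline; an rRNA-like locus copied near-identically (≥ 97%) across
designated genomes; and chimeric references whose terminal segment is host
sequence. Reads are single-end, 147 b (a typical desktop short-read
average), uniform-start, strand-symmetric, with substitution errors at
0.5% by default and optional indels. Ground-truth alignments are derived
from the manifest's homology segments by direct base comparison — no read
mapper is run, so the recorded edit distances are exact, and
substitution-only defaults keep the identity oracle closed-form
(expected identity ≈ 100·(1−d)(1−e), with a +d·e/3 correction because an
error at a diverged site restores the reference base one time in three).

Real data differ in ways that matter for interpretation: genomes have
repeat and k-mer structure (our background is i.i.d., so cross-genome
spurious mapping is absent by construction); error rates are
quality-dependent; coverage is non-uniform (GC bias); and a real mapper's
sensitivity curve decides which diverged reads appear at all. Passing the
planted-truth tests therefore demonstrates that the *arithmetic and the
decision rule* behave as specified, not that any particular aligner +
sample combination will.

Two statistical subtleties surfaced while validating identity recovery and
are worth recording. First, the realized divergence of a finite genome is
itself binomial — for a 500 kb genome at d = 0.08 its standard deviation is
~0.04 identity points, shared across all reads — so comparisons of mean
recruited identity against 100·(1−d)(1−e) must include this component in
the standard error, not just read-sampling noise. Second, sequencing errors
partially mask divergence (the d·e/3 term above); at desk-scale read counts
this bias is comfortably inside 3 SE, which is why the closed form is still
the stated oracle.

## Diversity, rarefaction, screening

Taxonomic profiles from external rRNA profilers are consumed as count
tables. Host-derived assignments (plastid, plant-nuclear, mitochondrial,
cyanobacterial, unclassified) are masked — not deleted — before relative
abundance, so the audit trail survives; plant mitochondrial rRNA
misassigned to Rickettsiales by reference databases is handled by extending
the same blocklist, not special-cased. Shannon diversity uses natural log
(with a base switch) via vegan; analytic rarefaction is the hypergeometric
expectation (vegan's `rarefy`), cross-checked against this package's own
Monte-Carlo subsampler, which also covers depths beyond the analytic
precondition.

The assembly screen lists every scaffold with an rRNA hit and applies a
0.1 Mb length filter for candidacy; short hit-bearing scaffolds stay listed
as `rejected(short)` since they are still informative. The
tetranucleotide-composition z-score (scaffold distance to the pooled host
4-mer profile, standardized against host-window subsamples) is advisory
triage only — composition is noisy at these scales and never overrides
rRNA evidence.

## Numerical choices and problem sizes

Deterministic behaviour is a contract: all randomness flows from a single
seed through fixed per-stage derived seeds, TSV outputs are byte-identical
across reruns, and permuting input records leaves matrices unchanged. Tie
handling: identity exactly on a bin edge goes to the upper-edge-exclusive
convention; identity exactly at the 90% cutoff counts as high-identity;
ranking ties in the concentration metric resolve by taking the largest
bins, which can only overstate concentration for genuinely broad signals
(harmless, since the present rule fires first on breadth).

The shipped validation uses communities of ~1.7 Mb and 1e5 reads, 20
seeded replicates across four scenarios (present / absent /
absent-with-shared-locus / chimeric reference), with endophyte abundance
swept over 1–5% and divergence over 0–8%. These sizes were chosen as the
smallest at which every bin of a 500 kb candidate still receives tens of
reads from a 1% endophyte, so verdicts are limited by the decision rule
rather than by shot noise.

## A worked demo

```{r demo, eval = FALSE}
cfg <- system.file("extdata", "demo_community.yaml", package = "endorecruit")
report <- run_pipeline(cfg, "demo_out")
report$calls[, c("reference_id", "verdict", "breadth_hi",
                 "concentration", "edge_fraction")]
```

The demo community plants one resident endophyte, one absent genome sharing
a 5 kb rRNA-like locus with the resident cyanobiont, and one chimeric
reference; the three verdicts come out `present`,
`conserved_locus_artifact` and `edge_artifact` respectively.

## Known limitations

* The caller is rule-based, not probabilistic; it reports no uncertainty,
  and abundance estimation beyond read density is out of scope.
* Breadth thresholds assume the position grid is reasonably fine; for
  references shorter than ~5 position bins the breadth quantization is
  coarse and the caller warns in the single-bin case.
* Shared-locus and chimera geometry in the simulator is idealized (one
  locus, one junction); real assemblies can stack both artifacts on one
  scaffold.
* Paired-end information is ignored by design: each mate is an independent
  recruitment event.
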