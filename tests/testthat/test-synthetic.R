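test_that("mutate_sequence realizes the requested divergence", {
  # zero divergence is the identity
  expect_identical(mutate_sequence("ACGTACGT", 0, seed = 7), "ACGTACGT")

  # deterministic given seed
  s <- random_genome(5000, seed = 2)
  expect_identical(mutate_sequence(s, 0.1, seed = 3),
                   mutate_sequence(s, 0.1, seed = 3))

  # observed mismatch count within the binomial 99% CI at divergence 0.08
  s <- random_genome(10000, seed = 4)
  m <- mutate_sequence(s, 0.08, seed = 5)
  mm <- sum(charToRaw(s) != charToRaw(m))
  expect_gte(mm, qbinom(0.005, 10000, 0.08))
  expect_lte(mm, qbinom(0.995, 10000, 0.08))

  # per-site substitution frequency matches divergence (Monte-Carlo over seeds)
  n_seeds <- 3000L
  hits <- vapply(seq_len(n_seeds), function(k) {
    sum(charToRaw(mutate_sequence("ACGT", 0.6, seed = k)) != charToRaw("ACGT"))
  }, numeric(1))
  expect_gte(sum(hits), qbinom(0.0005, 4L * n_seeds, 0.6))
  expect_lte(sum(hits), qbinom(0.9995, 4L * n_seeds, 0.6))
})

test_that("mutate_sequence rejects bad input with the offending position", {
  expect_error(mutate_sequence("ACGNTT", 0.1), "position 4")
  expect_error(mutate_sequence("", 0.1), "non-empty")
  expect_error(mutate_sequence("ACGT", 1), "divergence")
})

test_that("simulate_genomes plants divergence, shared loci and chimeras", {
  # divergence 0: reference equals resident byte-for-byte
  g0 <- simulate_genomes(list(genome_spec("a", 10000L)), seed = 1)
  expect_identical(g0$references[["a"]], g0$residents[["a"]])

  # shared 5-kb locus at 0.99: locus copies nearly identical between the two
  # references, background at the ~25% identity expected by chance
  specs <- list(
    genome_spec("x", 40000L, shared_locus = list(length = 5000, identity = 0.99,
                                                 position = 10000)),
    genome_spec("y", 40000L, shared_locus = list(length = 5000, identity = 0.99,
                                                 position = 20000))
  )
  g <- simulate_genomes(specs, seed = 2)
  lx <- substr(g$references[["x"]], 10001, 15000)
  ly <- substr(g$references[["y"]], 20001, 25000)
  locus_id <- mean(charToRaw(lx) == charToRaw(ly))
  expect_gte(locus_id, 0.98)
  bx <- substr(g$references[["x"]], 25001, 35000)
  by <- substr(g$references[["y"]], 30001, 40000)
  expect_lt(abs(mean(charToRaw(bx) == charToRaw(by)) - 0.25), 0.03)

  # chimera at junction 0.9: the last 10% of the reference is host sequence
  specs <- list(
    genome_spec("host", 50000L),
    genome_spec("chim", 20000L,
                chimera_with = list(host = "host", junction = 0.9,
                                    host_start = 100))
  )
  g <- simulate_genomes(specs, seed = 3)
  tail_seq <- substr(g$references[["chim"]], 18001, 20000)
  expect_identical(tail_seq, substr(g$references[["host"]], 101, 2100))

  expect_error(simulate_genomes(list(genome_spec("a", 1000L),
                                     genome_spec("a", 1000L))),
               "duplicate")
  expect_error(
    simulate_genomes(list(genome_spec(
      "a", 1000L, chimera_with = list(host = "nope", junction = 0.5)))),
    "chimera host")
})

test_that("simulate_reads draws reads per abundance with true edit distances", {
  # single genome: every read references it
  g <- simulate_genomes(list(genome_spec("solo", 20000L)), seed = 1)
  tr <- community_truth(c(solo = 1), n_reads = 1000L, error_rate = 0, seed = 2)
  sim <- simulate_reads(tr, g)
  expect_true(all(sim$reads$genome == "solo"))
  expect_true(all(sim$reads$mapped))

  # error 0 and divergence 0: every truth record is a perfect match
  expect_true(all(sim$reads$edit_distance == 0L))

  # two genomes: endophyte read count within binomial 99% CI
  tc <- tiny_community(seed = 5, n_reads = 50000L, endo_abundance = 0.04)
  n_endo <- sum(tc$sim$reads$genome == "endoB")
  expect_gte(n_endo, qbinom(0.005, 50000L, 0.04))
  expect_lte(n_endo, qbinom(0.995, 50000L, 0.04))

  # reads longer than the shortest genome are rejected
  expect_error(
    simulate_reads(community_truth(c(solo = 1), 10L, read_length = 30000L), g),
    "shortest genome")
})

test_that("read counts per genome are multinomial in the abundances", {
  prob <- c(hostA = 0.8, endoB = 0.2)
  for (seed in 1:10) {
    tc <- tiny_community(seed = seed, n_reads = 10000L)
    obs <- table(factor(tc$sim$reads$genome, levels = names(prob)))
    p <- chisq.test(obs, p = prob)$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("truth-SAM identity tracks (1 - divergence)(1 - error)", {
  d <- 0.05
  e <- 0.01
  tc <- tiny_community(seed = 9, n_reads = 20000L, divergence = d,
                       error_rate = e)
  reads <- tc$sim$reads[tc$sim$reads$genome == "endoB", ]
  identity <- 1 - reads$edit_distance / reads$t_len
  expected <- (1 - d) * (1 - e)
  # SE includes the binomial realization of divergence on the 30-kb genome,
  # which is shared across reads, on top of read sampling
  se <- sqrt((sd(identity) / sqrt(nrow(reads)))^2 +
               (1 - e)^2 * d * (1 - d) / 30000)
  expect_lt(abs(mean(identity) - expected), 3 * se)
})

test_that("same seed gives byte-identical FASTQ and SAM outputs", {
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("a.fastq", "b.fastq", "a.sam", "b.sam"))
  for (i in 1:2) {
    tc <- tiny_community(seed = 11, n_reads = 500L, divergence = 0.02,
                         error_rate = 0.005)
    write_fastq(tc$sim, paths[i])
    write_truth_sam(tc$sim, paths[i + 2])
  }
  expect_identical(readLines(paths[1]), readLines(paths[2]))
  expect_identical(readLines(paths[3]), readLines(paths[4]))
})

test_that("genome and manifest output round-trips through the filesystem", {
  dir <- withr::local_tempdir()
  tc <- tiny_community(seed = 13, n_reads = 10L)
  write_genomes(tc$genomes, dir)
  refs <- Biostrings::readDNAStringSet(file.path(dir, "references.fasta"))
  expect_identical(as.character(refs[["hostA"]]),
                   tc$genomes$references[["hostA"]])
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_identical(sort(manifest$genomes$name), c("endoB", "hostA"))
})
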