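test_that("layout places scaffolds on one sequential axis", {
  expect_equal(build_layout(c(A = 1000L))$offsets, c(A = 0L))
  lay <- build_layout(c(A = 1000L, B = 500L))
  expect_equal(lay$total_length, 1500)
  expect_equal(global_position(lay, "B", 10L), 1010L)
  expect_error(build_layout(c(1000L)), "named")
  expect_error(build_layout(c(A = 1L, A = 2L)), "duplicate")
  expect_error(build_layout(setNames(integer(0), character(0))), "empty")
})

test_that("local/global coordinates round-trip", {
  lay <- build_layout(c(s1 = 40000L, s2 = 25000L, s3 = 10000L))
  withr::with_seed(31, {
    sc <- sample(lay$labels, 1000L, replace = TRUE)
    pos <- vapply(sc, function(s) {
      sample.int(lay$lengths[match(s, lay$labels)], 1L) - 1L
    }, integer(1))
    g <- global_position(lay, sc, pos)
    back <- local_position(lay, g)
    expect_identical(back$scaffold, unname(sc))
    expect_identical(back$pos, unname(pos))
  })
})

test_that("binning follows the stated interval conventions", {
  lay <- build_layout(c(A = 200000L))
  r <- alignment_records(c("a", "b", "c"), "A",
                         pos = c(120000L, 10L, 20L),
                         cigar = c("500M", "100M", "100M"),
                         edit_distance = c(8L, 2L, 0L))
  m <- bin_alignments(r, lay)
  expect_equal(dim(m$counts), c(4L, 30L))
  # 500M with NM 8 -> identity 98.4 at global 120000 -> pos bin 3, id bin [98,99)
  expect_equal(m$counts[3, "98"], 1L)
  # identity 98.0 sits on the half-open lower edge of the same id bin
  expect_equal(sum(m$counts[, "98"]), 2L)
  # identity 100 lands in the closed top bin [99,100]
  expect_equal(sum(m$counts[, "99"]), 1L)
})

test_that("matrix counts are conserved and order-invariant", {
  tc <- tiny_community(seed = 33, n_reads = 5000L, divergence = 0.02,
                       error_rate = 0.01)
  recs <- recruit_records(tc$sim, "hostA")
  lay <- build_layout(c(hostA = 60000L))
  m <- bin_alignments(recs, lay, pos_bin = 10000L)
  expect_equal(sum(m$counts) + m$n_unbinned, nrow(recs))

  shuffled <- recs[withr::with_seed(34, sample.int(nrow(recs))), ]
  m2 <- bin_alignments(shuffled, lay, pos_bin = 10000L)
  expect_identical(m$counts, m2$counts)

  # a record on a scaffold missing from the layout is a hard error
  bad <- recs
  bad$ref_id[1] <- "mystery"
  expect_error(bin_alignments(bad, lay, pos_bin = 10000L), "mystery")
})

test_that("log transform is the documented pointwise map", {
  lay <- build_layout(c(A = 100000L))
  r <- alignment_records(sprintf("r%d", 1:9), "A", rep(0L, 9), "100M",
                         rep(0L, 9))
  m <- bin_alignments(r, lay)
  tm <- transform_matrix(m)
  expect_equal(tm[1, "99"], 1)          # 9 reads -> log10(10) = 1
  expect_equal(sum(tm == 0), length(tm) - 1L)  # zeros stay zero
})

test_that("count-weighted identity recovers (1 - d)(1 - e)", {
  d <- 0.05
  e <- 0.01
  glen <- 30000L
  tc <- tiny_community(seed = 35, n_reads = 20000L, divergence = d,
                       error_rate = e, endo_abundance = 0.5)
  recs <- recruit_records(tc$sim, "endoB")
  q <- compute_identity(recs)
  # the SE of the mean has two parts: read sampling, and the binomial
  # realization of the genome's divergence (shared across reads)
  se_reads <- sd(q) / sqrt(length(q))
  se_genome <- 100 * (1 - e) * sqrt(d * (1 - d) / glen)
  se <- sqrt(se_reads^2 + se_genome^2)
  expect_lt(abs(mean(q) - 100 * (1 - d) * (1 - e)), 3 * se)
})

test_that("per-scaffold density is reads per kilobase above the cutoff", {
  # 1000 qualifying reads on a 1-Mb scaffold -> exactly 1.0 reads/kb
  r <- alignment_records(sprintf("r%d", 1:1000), "big", rep(0L, 1000),
                         "147M", rep(0L, 1000))
  s <- per_scaffold_summary(r, c(big = 1000000L))
  expect_identical(s$density, 1.0)
  expect_equal(s$log_density, 0)

  # reads below the cutoff do not count: all at 95%, cutoff 97 -> density 0
  r95 <- alignment_records(sprintf("r%d", 1:100), "big", rep(0L, 100),
                           "100M", rep(5L, 100))
  s95 <- per_scaffold_summary(r95, c(big = 1000000L))
  expect_identical(s95$reads_at_or_above_cutoff, 0L)
  expect_identical(s95$density, 0)
  expect_true(is.na(s95$log_density))

  expect_error(per_scaffold_summary(r, c(big = 0L)), "positive")
})

test_that("density per kb is invariant to scaffold length at fixed coverage", {
  density_at <- function(len, seed) {
    g <- simulate_genomes(list(genome_spec("s", len)), seed = seed)
    n <- as.integer(len / 100)  # fixed simulated read density
    tr <- community_truth(c(s = 1), n_reads = n, error_rate = 0, seed = seed)
    sim <- simulate_reads(tr, g)
    recs <- recruit_records(sim, "s")
    per_scaffold_summary(recs, setNames(len, "s"))$density
  }
  d1 <- density_at(200000L, seed = 41)
  d2 <- density_at(400000L, seed = 42)
  expect_lt(abs(d2 - d1) / d1, 0.02)
})

test_that("recruitment matrices survive a TSV round trip", {
  tc <- tiny_community(seed = 43, n_reads = 2000L, divergence = 0.03,
                       error_rate = 0.01)
  recs <- recruit_records(tc$sim, "endoB")
  lay <- build_layout(c(endoB = 30000L))
  m <- bin_alignments(recs, lay, pos_bin = 5000L, sample_id = "S9",
                      reference_id = "endoB")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  m2 <- read_matrix_tsv(path)
  expect_identical(m2$counts, m$counts)
  expect_identical(m2$n_unbinned, m$n_unbinned)
  expect_identical(m2$sample_id, "S9")
  expect_equal(m2$layout$total_length, m$layout$total_length)
})

test_that("recruitment plot renders a file for full and empty matrices", {
  tc <- tiny_community(seed = 45, n_reads = 1000L, divergence = 0.04,
                       error_rate = 0.01)
  recs <- recruit_records(tc$sim, "endoB")
  lay <- build_layout(c(endoB = 30000L))
  m <- bin_alignments(recs, lay, pos_bin = 5000L)
  path <- withr::local_tempfile(fileext = ".png")
  render_recruitment_plot(m, path)
  expect_gt(file.size(path), 0)

  # a present genome shows a modal identity band near 100(1 - d)
  col_sums <- colSums(m$counts)
  modal_lower <- as.numeric(names(which.max(col_sums)))
  expect_lt(abs(modal_lower - 95), 2)

  empty <- bin_alignments(recs[0, ], lay, pos_bin = 5000L)
  path2 <- withr::local_tempfile(fileext = ".png")
  render_recruitment_plot(empty, path2)
  expect_gt(file.size(path2), 0)
})
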