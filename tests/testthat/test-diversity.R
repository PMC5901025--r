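test_that("host-taxon masking removes blocked taxa but keeps the audit trail", {
  p <- taxon_profile("L1", "order",
                     c(Cyanobacteria = 70L, Rhizobiales = 2L,
                       Burkholderiales = 1L))
  # empty blocklist: unchanged
  expect_identical(filter_host_taxa(p, character(0))$masked, character(0))

  f <- filter_host_taxa(p, c("Cyanobacteria"))
  expect_setequal(f$masked, "Cyanobacteria")
  expect_identical(f$counts, p$counts)  # counts retained for audit
  expect_equal(sum(relative_abundance(f)), 1)
  expect_equal(unname(relative_abundance(f)[c("Rhizobiales",
                                              "Burkholderiales")]),
               c(2, 1) / 3)

  expect_warning(filter_host_taxa(p, names(p$counts)), "masked")
})

test_that("relative abundance reproduces the low-abundance endophyte pattern", {
  expect_equal(relative_abundance(taxon_profile("s", "order", c(A = 1L))),
               c(A = 1.0))
  expect_equal(relative_abundance(taxon_profile("s", "order",
                                                c(A = 2L, B = 2L))),
               c(A = 0.5, B = 0.5))
  # the 2%/1% Rhizobiales/Burkholderiales signature after masking
  p <- taxon_profile("L", "order",
                     c(Rhizobiales = 2L, Burkholderiales = 1L, other = 97L))
  ra <- relative_abundance(p)
  expect_equal(unname(ra["Rhizobiales"]), 0.02)
  expect_equal(unname(ra["Burkholderiales"]), 0.01)

  empty <- suppressWarnings(
    filter_host_taxa(taxon_profile("s", "order", c(A = 5L)), "A"))
  expect_error(relative_abundance(empty), "total is 0")
})

test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon(taxon_profile("s", "order", c(A = 50L))), 0)
  expect_equal(shannon(taxon_profile("s", "order",
                                     setNames(rep(10L, 4), letters[1:4]))),
               log(4), tolerance = 1e-12)
  p <- taxon_profile("s", "order", c(A = 50L, B = 25L, C = 25L))
  expect_equal(shannon(p), -(0.5 * log(0.5) + 0.5 * log(0.25)),
               tolerance = 1e-12)
  # base switch
  expect_equal(shannon(p, base = 2),
               -(0.5 * log2(0.5) + 0.5 * log2(0.25)), tolerance = 1e-12)
})

test_that("Shannon is maximal for the uniform profile at fixed richness", {
  withr::with_seed(51, {
    for (i in 1:20) {
      k <- sample(3:12, 1)
      counts <- setNames(sample(1:200, k, replace = TRUE), paste0("t", 1:k))
      h <- shannon(taxon_profile("s", "order", counts))
      expect_lte(h, log(k) + 1e-12)
    }
  })
})

test_that("replicate Shannon summaries report mean and SD per group", {
  profiles <- lapply(1:6, function(i) {
    simulate_taxon_profile(
      c(A = 0.5, B = 0.3, C = 0.2), n_hits = 2000L,
      sample_id = paste0("s", i), seed = 60 + i)
  })
  s <- shannon_summary(profiles, groups = rep(c("W", "P"), each = 3))
  expect_equal(nrow(s), 2L)
  expect_true(all(s$n == 3L))
  expect_true(all(s$sd_shannon >= 0))
})

test_that("rarefaction expectation matches its Monte-Carlo oracle", {
  p <- taxon_profile("s", "order", c(A = 50L, B = 30L, C = 20L))
  # exact endpoints
  expect_equal(rarefaction_curve(p, 100L)$expected_taxa, 3)
  single <- taxon_profile("s", "order", c(A = 40L))
  expect_true(all(rarefaction_curve(single, c(1L, 5L, 40L))$expected_taxa == 1))

  an <- rarefaction_curve(p, 10L)$expected_taxa
  reps <- 10000L
  mc_draws <- withr::with_seed(53, {
    pool <- rep.int(1:3, c(50L, 30L, 20L))
    vapply(seq_len(reps), function(r) {
      length(unique(pool[sample.int(100L, 10L)]))
    }, numeric(1))
  })
  se <- sd(mc_draws) / sqrt(reps)
  expect_lt(abs(an - mean(mc_draws)), 3 * se)
  # the package's own Monte-Carlo mode agrees too
  mc <- rarefaction_curve(p, 10L, mode = "montecarlo", reps = reps,
                          seed = 54)$expected_taxa
  expect_lt(abs(an - mc), 3 * se)

  # monotone, bounded by richness
  curve <- rarefaction_curve(p, c(1L, 5L, 20L, 60L, 100L))
  expect_true(all(diff(curve$expected_taxa) >= 0))
  expect_true(all(curve$expected_taxa <= 3))

  expect_error(rarefaction_curve(p, 101L), "depths <= total")
  expect_error(rarefaction_curve(p, 10L, mode = "montecarlo", reps = 0L),
               "reps")
})

test_that("habitat overlap counts shared unmasked taxa at one rank", {
  pA <- taxon_profile("plant", "order", c(Rhizobiales = 5L, Nostocales = 9L))
  pB <- taxon_profile("water", "order",
                      c(Burkholderiales = 7L, Rhodocyclales = 3L))
  expect_equal(habitat_overlap(pA, pB)$n_shared, 0L)
  expect_equal(habitat_overlap(pA, pA)$n_shared, 2L)
  expect_error(
    habitat_overlap(pA, taxon_profile("w", "class", c(x = 1L))), "rank")

  # simulated plant vs water communities from disjoint taxon pools
  plant <- simulate_taxon_profile(
    c(Rhizobiales = 0.6, Nostocales = 0.4), 5000L, "P", seed = 55)
  water <- simulate_taxon_profile(
    c(Burkholderiales = 0.5, Rhodocyclales = 0.3, Methylococcales = 0.2),
    5000L, "W", seed = 56)
  expect_equal(habitat_overlap(plant, water)$n_shared, 0L)
})

test_that("masking commutes with relative abundance", {
  p <- simulate_taxon_profile(
    c(Chloroplast = 0.5, Cyanobacteria = 0.3, Rhizobiales = 0.15,
      Burkholderiales = 0.05), 20000L, "L1", seed = 57)
  f <- filter_host_taxa(p)
  ra_masked <- relative_abundance(f)
  keep <- setdiff(names(p$counts), default_host_blocklist())
  manual <- p$counts[keep][p$counts[keep] > 0]
  expect_equal(ra_masked, manual / sum(manual))
  # and the remaining proportions track the planted truth
  expect_equal(unname(ra_masked["Rhizobiales"]), 0.75, tolerance = 0.05)
})

test_that("count tables round-trip as profiles", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(
    sample_id = rep(c("L1", "W1"), each = 2),
    rank = "order",
    taxon = c("Rhizobiales", "Cyanobacteria", "Burkholderiales",
              "Rhodocyclales"),
    count = c(2L, 70L, 7L, 3L))
  readr::write_tsv(tab, path)
  profiles <- read_taxon_table(path)
  expect_setequal(names(profiles), c("L1", "W1"))
  expect_equal(profiles$L1$counts[["Cyanobacteria"]], 70L)
  expect_error(read_taxon_table(withr::local_tempfile(lines = "x\ty")),
               "columns")
})
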