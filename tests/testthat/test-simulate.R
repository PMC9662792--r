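test_that("simulated references are valid and reproducible", {
  r1 <- simulate_reference(5, rng_seed = 1)
  r2 <- simulate_reference(5, rng_seed = 1)
  expect_identical(r1, r2)
  expect_false(identical(r1, simulate_reference(5, rng_seed = 2)))

  # closure under the loader's own validation (round-trip through disk)
  paths <- write_fixture_reference(r1)
  expect_identical(as.data.frame(read_trna_reference(paths$fasta, paths$annotation)),
                   as.data.frame(r1))

  one <- simulate_reference(1, rng_seed = 7)
  expect_true(one$anticodon_start >= 33 && one$anticodon_start <= 38)
  expect_true(endsWith(one$sequence, "CCA"))

  many <- simulate_reference(40, rng_seed = 3)
  expect_false(anyDuplicated(substr(many$sequence, 1, 40)) > 0)
  expect_error(simulate_reference(0), "integer")
})

test_that("the planted catalog meets every configured target exactly", {
  cfg <- small_config(seed = 5)
  ref <- small_reference(seed = 30)
  truth <- simulate_catalog(cfg, ref)

  expect_equal(nrow(truth), cfg$catalog_size)
  expect_false(anyDuplicated(truth$sequence) > 0)
  expect_equal(length(unique(truth$seed)), cfg$n_seed_groups)
  expect_equal(sum(truth$group == "normal_only"), 8)
  expect_equal(sum(truth$group == "iugr_only"), 5)
  expect_equal(sum(truth$log2fc == -3), 3)
  expect_equal(sum(truth$log2fc == 3), 2)
  expect_equal(sum(truth$log2fc == 0), 55)
  expect_true(all(truth$group[truth$log2fc != 0] == "shared"))

  vis <- truth$group != "iugr_only"
  b <- truth$baseline[vis] / sum(truth$baseline[vis])
  shares <- tapply(b, truth$type[vis], sum)
  for (ty in names(cfg$type_mixture)) {
    expect_equal(unname(shares[[ty]]), unname(cfg$type_mixture[[ty]]),
                 tolerance = 1e-6)
  }
  expect_equal(sum(b[truth$length[vis] %in% 31:32]), cfg$length_mass_31_32,
               tolerance = 1e-9)
  sorted <- sort(b, decreasing = TRUE)
  for (k in names(cfg$top_shares)) {
    expect_equal(sum(sorted[seq_len(as.integer(k))]),
                 unname(cfg$top_shares[[k]]), tolerance = 1e-9)
  }

  # truth-consistency: the classifier reproduces every planted label
  relab <- classify_fragment(truth[c("parent_id", "region", "start", "end")],
                             ref)
  expect_equal(relab$type, truth$type)

  # every planted fragment really is a substring of its parent at [start, end]
  for (k in seq_len(nrow(truth))) {
    p <- ref[ref$id == truth$parent_id[k], ]
    src <- if (truth$region[k] == "trailer") p$trailer else p$sequence
    expect_equal(substr(src, truth$start[k], truth$end[k]), truth$sequence[k])
  }
})

test_that("degenerate and single-type configurations behave as documented", {
  ref <- small_reference(seed = 12)
  cfg <- sim_config(n_trnas = 30, catalog_size = 20,
                    type_mixture = c("tRF-5c" = 1.0),
                    length_mass_31_32 = NA, top_shares = NULL,
                    n_seed_groups = NA,
                    group_specific = c(normal = 0L, iugr = 0L),
                    de_spikes = list(n_down = 0L, n_up = 0L, log2fc = 3),
                    depth = 1000, rng_seed = 4)
  truth <- simulate_catalog(cfg, ref)
  expect_true(all(truth$type == "tRF-5c"))
  expect_true(all(truth$start == 1))
  parents <- ref[match(truth$parent_id, ref$id), ]
  expect_true(all(truth$end < parents$anticodon_start - 3))

  expect_error(sim_config(type_mixture = c("tRF-5c" = 0.9)), "sum to 1")
  expect_error(sim_config(catalog_size = 50,
                          group_specific = c(normal = 40L, iugr = 20L)),
               "group-specific")
})

test_that("read simulation is seeded, group-aware and mass-conserving", {
  cfg <- small_config(seed = 6)
  ref <- small_reference(seed = 30)
  truth <- simulate_catalog(cfg, ref)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_reads(truth, d1, cfg)
  s2 <- simulate_reads(truth, d2, cfg)
  expect_identical(readLines(s1$fastq[1]), readLines(s2$fastq[1]))
  expect_equal(s1$group, rep(c("normal", "iugr"), each = 3))

  # group-specific fragments never emit reads in the other group
  iugr_only <- truth$sequence[truth$group == "iugr_only"]
  normal_reads <- collapse_reads(s1$fastq[1])
  expect_equal(length(intersect(normal_reads$sequence, iugr_only)), 0)
  expect_equal(sum(normal_reads$count), cfg$depth)
})

test_that("a single-fragment catalog yields a single-sequence library", {
  ref <- small_reference(seed = 12)
  cfg <- sim_config(n_trnas = 30, catalog_size = 12,
                    type_mixture = c("tRF-5c" = 1.0), length_mass_31_32 = NA,
                    top_shares = NULL, n_seed_groups = NA,
                    group_specific = c(normal = 0L, iugr = 0L),
                    de_spikes = list(n_down = 0L, n_up = 0L, log2fc = 3),
                    depth = 500, sigma = 0, rng_seed = 8)
  truth <- simulate_catalog(cfg, ref)
  # concentrate all abundance on one fragment: degenerate multinomial
  truth$baseline <- c(1, rep(0, nrow(truth) - 1))
  d <- withr::local_tempdir()
  sheet <- simulate_reads(truth, d, cfg)
  reads <- collapse_reads(sheet$fastq[1])
  expect_equal(reads$sequence, truth$sequence[1])
  expect_equal(reads$count, 500L)
})

test_that("simulated UTRs contain exactly the planted seed sites", {
  cfg <- small_config(seed = 13)
  ref <- small_reference(seed = 30)
  truth <- simulate_catalog(cfg, ref)
  idx <- which(!duplicated(truth$seed))[1:5]   # distinct seeds
  ts_seqs <- setNames(truth$sequence[idx], paste0("ts", 1:5))
  planted <- c(ts1 = "IGF1", ts3 = "GENEB")

  sim <- simulate_utrs(ts_seqs, n_genes = 8, planted = planted, rng_seed = 3)
  expect_equal(length(sim$utrs), 8)
  expect_equal(nrow(sim$truth), 2)

  seeds <- extract_seed(ts_seqs)
  for (g in names(sim$utrs)) {
    for (ts in names(ts_seqs)) {
      hits <- scan_utr(seeds[[ts]], sim$utrs[[g]])
      planted_here <- !is.na(planted[ts]) && identical(unname(planted[ts]), g)
      expect_equal(length(hits), as.integer(planted_here))
    }
  }

  sim2 <- simulate_utrs(ts_seqs, n_genes = 8, planted = planted, rng_seed = 3)
  expect_identical(sim, sim2)
  expect_error(simulate_utrs(ts_seqs, 8, c(missing = "X"), 1), "appear")
})

test_that("abundance-weighted type shares of reads converge to the mixture", {
  cfg <- small_config(seed = 21, sigma = 0, depth = 2e5)
  ref <- small_reference(seed = 30)
  truth <- simulate_catalog(cfg, ref)
  d <- withr::local_tempdir()
  sheet <- simulate_reads(truth, d, cfg)
  reads <- collapse_reads(sheet$fastq[1])  # one normal sample
  by_type <- tapply(reads$count,
                    truth$type[match(reads$sequence, truth$sequence)], sum)
  shares <- by_type / sum(by_type)
  for (ty in names(cfg$type_mixture)) {
    # within one percentage point of the configured mixture
    expect_lt(abs(shares[[ty]] - cfg$type_mixture[[ty]]), 0.01)
  }
})
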