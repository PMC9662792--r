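toy_counts <- function() {
  tibble::tibble(tsrna_id = c("a", "b", "c"),
                 n1 = c(80L, 10L, 10L), n2 = c(90L, 5L, 5L),
                 i1 = c(40L, 50L, 10L), i2 = c(50L, 40L, 10L))
}
toy_samples <- tibble::tibble(sample_id = c("n1", "n2", "i1", "i2"),
                              group = c("normal", "normal", "iugr", "iugr"))

test_that("CPM columns sum to one million", {
  cpm <- cpm_normalize(toy_counts())
  expect_equal(unname(colSums(as.matrix(cpm[-1]))), rep(1e6, 4))
  expect_equal(cpm$n1, c(8e5, 1e5, 1e5))

  one <- tibble::tibble(tsrna_id = "a", s = 7L)
  expect_equal(cpm_normalize(one)$s, 1e6)

  zero <- tibble::tibble(tsrna_id = c("a", "b"), s1 = c(1L, 1L), s2 = c(0L, 0L))
  expect_error(cpm_normalize(zero), "s2")
})

test_that("expressed sets partition the detected catalog", {
  counts <- tibble::tibble(tsrna_id = c("shared", "n_only", "i_only"),
                           n1 = c(3L, 2L, 0L), n2 = c(1L, 0L, 0L),
                           i1 = c(2L, 0L, 1L), i2 = c(0L, 0L, 0L))
  es <- expressed_sets(counts, toy_samples)
  expect_equal(es$normal_only, "n_only")
  expect_equal(es$iugr_only, "i_only")
  expect_equal(es$shared, "shared")
  venn <- setNames(es$venn$n, es$venn$set)
  expect_equal(unname(venn["normal_only"] + venn["iugr_only"] + venn["shared"]),
               unname(venn["detected_total"]))
})

test_that("top_share is the top-k fraction of group-mean CPM", {
  counts <- tibble::tibble(tsrna_id = c("a", "b"),
                           n1 = c(9L, 1L), n2 = c(9L, 1L),
                           i1 = c(5L, 5L), i2 = c(5L, 5L))
  expect_equal(top_share(counts, toy_samples, k = 1, group = "normal"), 0.9)
  expect_equal(top_share(counts, toy_samples, k = 2, group = "normal"), 1.0)
  # monotone in k
  s1 <- top_share(toy_counts(), toy_samples, 1, "iugr")
  s2 <- top_share(toy_counts(), toy_samples, 2, "iugr")
  expect_gte(s2, s1)
  expect_error(top_share(counts, toy_samples, 1, "nope"), "no samples")
  expect_error(top_share(counts, toy_samples, 5, "normal"), "catalog")
})

test_that("benjamini_hochberg matches the hand-computed step-up", {
  # p * m / j = (.03, .03, .03); step-up minimisation leaves them equal
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(rep(0.5, 4)), rep(0.5, 4))

  set.seed(1)
  for (i in 1:10) {
    p <- runif(50)
    got <- benjamini_hochberg(p)
    expect_equal(got, p.adjust(p, method = "BH"))  # independent route
    expect_true(all(got >= p))
    expect_false(is.unsorted(got[order(p)]))       # monotone in sorted p
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("differential expression is null on duplicated groups and
           antisymmetric under label swap", {
  counts <- tibble::tibble(tsrna_id = letters[1:4],
                           n1 = c(10L, 20L, 5L, 1L), n2 = c(12L, 18L, 6L, 2L),
                           i1 = c(10L, 20L, 5L, 1L), i2 = c(12L, 18L, 6L, 2L))
  de <- differential_expression(counts, toy_samples, case = "iugr",
                                control = "normal")
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$status == "ns"))

  counts2 <- toy_counts()
  de_f <- differential_expression(counts2, toy_samples, case = "iugr",
                                  control = "normal")
  de_r <- differential_expression(counts2, toy_samples, case = "normal",
                                  control = "iugr")
  ord <- match(de_f$tsrna_id, de_r$tsrna_id)
  expect_equal(de_f$log2fc, -de_r$log2fc[ord])
  expect_equal(de_f$fdr, de_r$fdr[ord])
})

test_that("a 16-fold spike with replicate-level wobble is recovered and
           matches the per-row t.test / p.adjust oracle", {
  # a spiked row, two flat rows, and a ballast row keeping the library
  # sizes equal so CPM does not redistribute the spike compositionally
  counts <- tibble::tibble(
    tsrna_id = c("spike", "flat1", "flat2", "noisy", "ballast"),
    n1 = c(1600L, 500L, 300L, 40L, 7560L),
    n2 = c(1500L, 520L, 310L, 60L, 7610L),
    n3 = c(1650L, 480L, 290L, 50L, 7530L),
    i1 = c(100L, 510L, 300L, 45L, 9045L),
    i2 = c(95L, 505L, 305L, 55L, 9040L),
    i3 = c(105L, 495L, 295L, 48L, 9057L))
  stopifnot(all(colSums(counts[-1]) == 10000L))
  samples <- tibble::tibble(sample_id = c("n1", "n2", "n3", "i1", "i2", "i3"),
                            group = rep(c("normal", "iugr"), each = 3))
  de <- differential_expression(counts, samples, case = "iugr",
                                control = "normal")

  # independent oracle: per-row stats::t.test on log2(CPM + 1) + p.adjust
  cpm <- as.matrix(cpm_normalize(counts)[-1])
  rownames(cpm) <- counts$tsrna_id
  lg <- log2(cpm + 1)
  p_oracle <- vapply(counts$tsrna_id, function(id) {
    stats::t.test(lg[id, 4:6], lg[id, 1:3])$p.value
  }, numeric(1))
  fdr_oracle <- p.adjust(p_oracle, method = "BH")
  ord <- match(names(p_oracle), de$tsrna_id)
  expect_equal(de$p_value[ord], unname(p_oracle), tolerance = 1e-12)
  expect_equal(de$fdr[ord], unname(fdr_oracle), tolerance = 1e-12)

  expect_equal(de$status[de$tsrna_id == "spike"], "down")
  expect_lte(abs(de$log2fc[de$tsrna_id == "spike"] + 4), 0.2)  # ~16-fold
  expect_true(all(de$status[de$tsrna_id != "spike"] == "ns"))

  expect_error(differential_expression(counts, samples[-c(1, 2), ]),
               "two samples")
})

test_that("spiked fold changes are recovered across seeds with BH-level
           error control", {
  hits <- 0L; false_calls <- 0L; trues <- 0L
  for (seed in 1:5) {
    cfg <- small_config(seed = 400 + seed, depth = 1e5)
    ref <- small_reference(seed = 30)
    truth <- simulate_catalog(cfg, ref)
    d <- withr::local_tempdir()
    sheet <- simulate_reads(truth, d, cfg)
    ts <- build_matrix(sheet, ref)
    de <- differential_expression(ts$counts, ts$samples, case = "iugr",
                                  control = "normal")
    called <- de$tsrna_id[de$status != "ns"]
    seqs <- ts$records$sequence[match(called, ts$records$tsrna_id)]
    spiked <- truth$sequence[truth$log2fc != 0]
    trues <- trues + length(spiked)
    hits <- hits + length(intersect(seqs, spiked))
    false_calls <- false_calls +
      sum(!(seqs %in% c(spiked, truth$sequence[truth$group != "shared"])))
  }
  expect_equal(hits, trues)        # every spike recovered
  expect_lte(false_calls, 2)       # at most the BH-nominal leakage
})
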