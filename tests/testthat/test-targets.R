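test_that("seed extraction and grouping partition the catalog", {
  expect_equal(extract_seed("GCATTGGTACGTACGT"), "CATTGGT")
  expect_equal(extract_seed("AAAAAAAA"), "AAAAAAA")
  expect_error(extract_seed("AAAAAAA"), "seed")

  records <- tibble::tibble(
    tsrna_id = paste0("t", 1:6),
    sequence = c("GCATTGGTAAAA", "TCATTGGTCCCC", "ACATTGGTGGGG",
                 "GCATTGGTTTTT", "GAAACCCTTTTG", "GTTTCCCAAAAG"),
    total_count = c(10, 5, 3, 2, 100, 1))
  groups <- group_by_seed(records)
  expect_equal(sum(groups$n_members), nrow(records))
  expect_equal(nrow(groups), 3)
  expect_equal(groups$n_members[groups$seed == "CATTGGT"], 4)
  # sorted by summed member abundance
  expect_equal(groups$seed[1], "AAACCCT")
})

test_that("position frequency matrices column-normalise over both windows", {
  pfm <- position_frequency_matrix("GCATTGGTAAAA", window = "seed")
  expect_equal(pfm$freq["C", 1], 1)
  expect_equal(unname(colSums(pfm$freq)), rep(1, 7))

  pfm2 <- position_frequency_matrix(c("AA", "AC"), window = "three_prime", k = 2)
  expect_equal(pfm2$freq["A", 2], 0.5)
  expect_equal(pfm2$freq["C", 2], 0.5)
  expect_equal(unname(colSums(pfm2$freq)), rep(1, 2))

  td <- generics::tidy(pfm2)
  expect_equal(sum(td$count), 4)
  expect_error(position_frequency_matrix(character(0)), "no sequences")
})

test_that("scan_utr finds every overlapping reverse-complement site", {
  # revcomp(CATTGGT) = ACCAATG, present once at position 3
  expect_equal(scan_utr("CATTGGT", "TTACCAATGTT"), 3L)
  expect_equal(scan_utr("CATTGGT", "GGGGGGGGGG"), integer(0))
  expect_equal(scan_utr("CATTGGT", "ACCAATGACCAATG"), c(1L, 8L))
  # overlapping self-similar sites are all reported
  expect_equal(scan_utr("TTTTTTT", "AAAAAAAAA"), 1:3)
})

test_that("single-stack and pairless duplexes score from the table", {
  par <- energy_parameters()
  # ts "GC" against utr "GC": pairs (1,2)=G:C and (2,1)=C:G, one GC/CG stack
  dup <- hybrid_mfe("GC", "GC", par)
  expect_equal(dup$mfe, par$init + par$stack["GC", "CG"], ignore_attr = TRUE)
  expect_equal(nrow(dup$pairs), 2)
  expect_equal(score_duplex(dup$pairs, "GC", "GC", par), dup$mfe)

  none <- hybrid_mfe("AAAA", "AAAA", par)
  expect_equal(none$mfe, 0)
  expect_equal(nrow(none$pairs), 0)

  expect_error(hybrid_mfe(strrep("A", 61), "ACGT"), "60")
})

test_that("the duplex DP equals brute-force enumeration on random 8-mers", {
  par <- energy_parameters(max_loop = 4)  # bounded loops keep the oracle small
  set.seed(20240901)
  for (trial in 1:40) {
    ts <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    ut <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    dup <- hybrid_mfe(ts, ut, par)
    expect_equal(dup$mfe, oracle_mfe(ts, ut, par), tolerance = 1e-9)
    if (nrow(dup$pairs) > 0) {
      expect_equal(score_duplex(dup$pairs, ts, ut, par), dup$mfe,
                   tolerance = 1e-9)
    }
  }
})

test_that("planted targets are recovered and background genes stay clean", {
  cfg <- small_config(seed = 33)
  ref <- small_reference(seed = 30)
  truth <- simulate_catalog(cfg, ref)
  idx <- which(!duplicated(truth$seed))[1:4]   # distinct seeds
  records <- tibble::tibble(tsrna_id = paste0("ts", 1:4),
                            sequence = truth$sequence[idx])
  planted <- c(ts1 = "IGF1", ts2 = "GENEB")
  sim <- simulate_utrs(setNames(records$sequence, records$tsrna_id),
                       n_genes = 10, planted = planted, rng_seed = 17)

  hits <- predict_targets(records, sim$utrs)
  expect_setequal(paste(hits$tsrna_id, hits$gene_id),
                  c("ts1 IGF1", "ts2 GENEB"))
  expect_true(all(hits$mfe <= -15))
  # the reported site is the planted seed match
  m <- merge(hits, sim$truth, by = "gene_id")
  expect_equal(m$utr_position, m$seed_position)

  # relaxing the cutoff can only grow the hit set
  all_hits <- predict_targets(records, sim$utrs, mfe_cutoff = 0)
  expect_true(all(paste(hits$tsrna_id, hits$gene_id) %in%
                  paste(all_hits$tsrna_id, all_hits$gene_id)))
  # seed gate: no reported gene lacks a seed match
  seeds <- extract_seed(records$sequence)
  for (k in seq_len(nrow(all_hits))) {
    i <- match(all_hits$tsrna_id[k], records$tsrna_id)
    expect_gt(length(scan_utr(seeds[i], sim$utrs[[all_hits$gene_id[k]]])), 0)
  }
})

test_that("pearson_correlation matches the closed form and flags bad input", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  res <- pearson_correlation(x, y)
  r_hand <- 9 / sqrt(84)          # sum(dx*dy) / sqrt(sum(dx^2) * sum(dy^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(1 / (1 - r_hand^2))   # df = n - 2 = 1
  expect_equal(res$p_value, 2 * pt(abs(t_hand), 1, lower.tail = FALSE),
               tolerance = 1e-12)

  perfect <- pearson_correlation(1:6, -(1:6))
  expect_equal(perfect$estimate, -1)
  expect_error(pearson_correlation(1:2, 2:3), "3 paired")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
})

test_that("hypergeometric enrichment equals the combinatorial tail sum", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = universe[1:5], other = universe[6:17])
  target <- c(universe[1:4], "g18")  # overlap 4 with 'hit'
  res <- hypergeometric_enrichment(target, sets, universe)

  # P(X >= 4) = [C(5,4) C(15,1) + C(5,5) C(15,0)] / C(20,5) = 76 / 15504
  expect_equal(res$p_value[res$set == "hit"], 76 / 15504, tolerance = 1e-12)
  expect_equal(res$overlap[res$set == "hit"], 4)
  expect_equal(res$fdr, benjamini_hochberg(res$p_value), tolerance = 1e-12)

  # an overlap that cannot be beaten has p = 1 only when nothing rarer exists
  res0 <- hypergeometric_enrichment(character(0), sets, universe)
  expect_true(all(res0$p_value == 1))

  full <- hypergeometric_enrichment(universe[1:5],
                                    list(s = universe[1:5]), universe[1:5])
  expect_equal(full$p_value, 1)  # drawing everything: overlap is certain

  expect_error(hypergeometric_enrichment("x", sets, universe), "outside")
  expect_error(hypergeometric_enrichment("g1", sets, character(0)), "empty")
})

test_that("GMT round-trip feeds enrichment", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tna\tg1\tg2\tg3", "setB\tna\tg4\tg5"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  res <- hypergeometric_enrichment(c("g1", "g2"), gmt, paste0("g", 1:10))
  expect_equal(res$overlap[res$set == "setA"], 2)
})
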