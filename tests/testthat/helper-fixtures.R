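# Fixtures and independent oracles shared across the suite.

# A deterministic 76-nt mature tRNA with anticodon GCC at 35-37 and a CCA
# tail; built by hand so coordinates are known exactly.
fixture_trna <- function() {
  set.seed(7601)
  s <- strsplit(paste(sample(c("A", "C", "G", "T"), 76, replace = TRUE),
                      collapse = ""), "")[[1]]
  s[35:37] <- c("G", "C", "C")
  s[74:76] <- c("C", "C", "A")
  # keep the anticodon occurrence unique so locate_anticodon is unambiguous
  seq <- paste(s, collapse = "")
  while (length(gregexpr("GCC", seq, fixed = TRUE)[[1]]) > 1) {
    hits <- gregexpr("GCC", seq, fixed = TRUE)[[1]]
    extra <- setdiff(hits, 35)[1]
    substr(seq, extra, extra) <- "A"
  }
  tibble::tibble(id = "tRNA-Gly-GCC-1-1", amino_acid = "Gly",
                 anticodon = "GCC", sequence = seq, length = 76L,
                 anticodon_start = 35L, anticodon_end = 37L,
                 origin = "cytoplasmic", trailer = "TGTTTCGAGTCATGCATGAC")
}

write_fixture_reference <- function(ref, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "ref.fa"); ann <- file.path(dir, "ref.tsv")
  write_trna_reference(ref, fa, ann)
  list(fasta = fa, annotation = ann)
}

write_fixture_fastq <- function(reads, path) {
  n <- length(reads)
  rec <- character(4 * n)
  rec[seq(1, length.out = n, by = 4)] <- sprintf("@read_%d", seq_len(n))
  rec[seq(2, length.out = n, by = 4)] <- reads
  rec[seq(3, length.out = n, by = 4)] <- "+"
  rec[seq(4, length.out = n, by = 4)] <- strrep("I", nchar(reads))
  writeLines(rec, path)
  path
}

# small but fully featured simulation settings used by the unit tests
small_config <- function(seed = 5, depth = 5e4, ...) {
  sim_config(n_trnas = 30L, catalog_size = 60L,
             length_mass_31_32 = 0.60,
             top_shares = c("2" = 0.5, "4" = 0.6, "10" = 0.7),
             n_seed_groups = 30L,
             group_specific = c(normal = 8L, iugr = 5L),
             de_spikes = list(n_down = 3L, n_up = 2L, log2fc = 3),
             depth = depth, rng_seed = seed, ...)
}

small_reference <- function(seed = 30) simulate_reference(30, rng_seed = seed)

# ---- brute-force placement oracle ----------------------------------------
# slides the query over every reference sequence (and trailer), counting
# mismatches position by position; the real implementation must agree
oracle_place <- function(sequence, reference, max_mismatch = 0) {
  q <- strsplit(sequence, "")[[1]]
  rows <- list()
  for (i in seq_len(nrow(reference))) {
    for (region in c("mature", "trailer")) {
      subj <- if (region == "mature") reference$sequence[i] else reference$trailer[i]
      if (is.na(subj) || !nzchar(subj)) next
      s <- strsplit(subj, "")[[1]]
      if (length(s) < length(q)) next
      for (start in seq_len(length(s) - length(q) + 1)) {
        mm <- sum(s[start:(start + length(q) - 1)] != q)
        if (mm <= max_mismatch) {
          rows[[length(rows) + 1]] <- data.frame(
            parent_id = reference$id[i], region = region, start = start,
            end = start + length(q) - 1, mismatches = mm)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[out$mismatches == min(out$mismatches), ]
  out[order(out$mismatches, out$start, out$parent_id), ]
}

# ---- brute-force duplex oracle -------------------------------------------
# exhaustive enumeration of antiparallel pair chains under the same model
# (complementary pairs, per-strand loop gaps <= max_loop), written before
# and independently of the dynamic programme
oracle_mfe <- function(ts_seq, ut_seq, params = energy_parameters()) {
  ts <- strsplit(ts_seq, "")[[1]]
  ut <- strsplit(ut_seq, "")[[1]]
  comp <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  pair_lab <- function(a, b) c(AT = "AU", TA = "UA", CG = "CG", GC = "GC",
                               GT = "GU", TG = "UG")[[paste0(a, b)]]
  best <- Inf
  g <- params$max_loop
  extend <- function(i, j, e) {
    best <<- min(best, e)
    for (i2 in (i + 1):min(length(ts), i + g + 1)) {
      if (i2 > length(ts)) break
      for (j2 in max(1, j - g - 1):(j - 1)) {
        if (j < 2) break
        if (!comp(ts[i2], ut[j2])) next
        gap1 <- i2 - i - 1; gap2 <- j - j2 - 1
        step <- if (gap1 == 0 && gap2 == 0) {
          params$stack[pair_lab(ts[i], ut[j]), pair_lab(ts[i2], ut[j2])]
        } else {
          params$loop_open + params$loop_per_nt * (gap1 + gap2)
        }
        extend(i2, j2, e + step)
      }
    }
  }
  for (i in seq_along(ts)) {
    for (j in seq_along(ut)) {
      if (comp(ts[i], ut[j])) extend(i, j, params$init)
    }
  }
  if (!is.finite(best) || best >= 0) 0 else best
}
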