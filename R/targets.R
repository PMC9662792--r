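#' Extract the seed sequence of a small RNA
#'
#' The seed is positions 2-8 (1-based, inclusive) at the 5' end of the
#' molecule; its reverse complement in a 3' UTR nucleates target
#' recognition.
#'
#' @param sequence Character vector of sequences, each of length >= 8.
#' @return Character vector of 7-mers.
#' @export
extract_seed <- function(sequence) {
  short <- nchar(sequence) < 8
  if (any(short)) {
    abort(sprintf("%d sequence(s) shorter than 8 nt have no seed", sum(short)))
  }
  substr(sequence, 2L, 8L)
}

#' Group tsRNAs by seed sequence
#'
#' One group per distinct positions-2-8 7-mer; groups partition the catalog
#' and are sorted by summed member abundance (falling back to member count
#' when no `total_count` column is present).
#'
#' @param records A records tibble with columns `tsrna_id`, `sequence`
#'   (and optionally `seed`, `total_count`).
#' @return A tibble with columns `seed`, `n_members`, `total_count`,
#'   `members` (list-column of tsrna_ids).
#' @export
group_by_seed <- function(records) {
  seed <- records[["seed"]] %||% extract_seed(records$sequence)
  weight <- records[["total_count"]] %||% rep(1, nrow(records))
  tibble(seed = seed, tsrna_id = records$tsrna_id, weight = weight) |>
    group_by(.data$seed) |>
    summarise(n_members = n(), total_count = sum(.data$weight),
              members = list(.data$tsrna_id), .groups = "drop") |>
    arrange(desc(.data$total_count))
}

#' Position frequency matrix over a sequence window
#'
#' Counts bases per position over either the seed window (positions 2-8)
#' or the last `k` characters (3' end), and column-normalises to
#' frequencies — the numbers behind a sequence logo.
#'
#' @param sequences Character vector of sequences covering the window.
#' @param window `"seed"` or `"three_prime"`.
#' @param k 3'-window width (default 7; ignored for `window = "seed"`).
#' @return An object of class `tsrna_pfm`: list with `counts` and `freq`
#'   (4 x width matrices over `A/C/G/T`), `window`, `width`.
#' @export
position_frequency_matrix <- function(sequences,
                                      window = c("seed", "three_prime"),
                                      k = 7L) {
  window <- match.arg(window)
  if (length(sequences) == 0) abort("no sequences: cannot build a PFM")
  sub <- if (window == "seed") {
    if (any(nchar(sequences) < 8)) abort("sequence(s) shorter than the seed window")
    substr(sequences, 2L, 8L)
  } else {
    if (any(nchar(sequences) < k)) abort(sprintf("sequence(s) shorter than %d nt", k))
    substr(sequences, nchar(sequences) - k + 1L, nchar(sequences))
  }
  width <- unique(nchar(sub))
  chars <- do.call(rbind, strsplit(sub, ""))
  counts <- vapply(seq_len(width), function(p) {
    tab <- table(factor(chars[, p], levels = DNA_BASES))
    as.integer(tab)
  }, integer(4))
  dimnames(counts) <- list(DNA_BASES, seq_len(width))
  freq <- sweep(counts, 2, colSums(counts), "/")
  structure(list(counts = counts, freq = freq, window = window,
                 width = width, n = length(sequences)),
            class = "tsrna_pfm")
}

#' @export
#' @method tidy tsrna_pfm
tidy.tsrna_pfm <- function(x, ...) {
  tibble(position = rep(seq_len(x$width), each = 4L),
         base = rep(DNA_BASES, x$width),
         count = as.integer(x$counts),
         freq = as.numeric(x$freq))
}

#' @export
print.tsrna_pfm <- function(x, ...) {
  cat(sprintf("<tsrna_pfm> %s window, %d positions, %d sequences\n",
              x$window, x$width, x$n))
  print(round(x$freq, 3))
  invisible(x)
}

#' Scan a 3' UTR for seed matches
#'
#' Reports every 1-based start position at which the UTR contains the
#' reverse complement of the seed; overlapping occurrences are all
#' reported.
#'
#' @param seed A 7-mer over `A/C/G/T`.
#' @param utr A UTR sequence over `A/C/G/T`.
#' @return Integer vector of match start positions (possibly empty).
#' @export
scan_utr <- function(seed, utr) {
  stopifnot(length(seed) == 1, length(utr) == 1)
  site <- revcomp(normalize_dna(seed, "seed"))
  utr <- normalize_dna(utr, "utr")
  w <- nchar(site)
  if (nchar(utr) < w) return(integer(0))
  starts <- seq_len(nchar(utr) - w + 1L)
  starts[substring(utr, starts, starts + w - 1L) == site]
}

#' Predict 3' UTR targets by seed match plus hybridisation energy
#'
#' For every (tsRNA, UTR) pair with at least one seed reverse-complement
#' match, each site is scored by [hybrid_mfe()] on a window of UTR context
#' around the site; hits at or below the energy cutoff are reported sorted
#' by energy.
#'
#' @param records A records tibble with `tsrna_id`, `sequence` (and
#'   optionally `seed`).
#' @param utrs Either a path to a UTR FASTA file or a named character
#'   vector of UTR sequences.
#' @param params An [energy_parameters()] object.
#' @param mfe_cutoff Report hits with `mfe <= mfe_cutoff` (kcal/mol,
#'   default -15).
#' @param context Nucleotides of UTR context on each side of the seed site
#'   (default 15).
#' @return A tibble with columns `tsrna_id`, `gene_id`, `utr_position`,
#'   `match_type`, `mfe`, `duplex`, sorted by `mfe` ascending.
#' @export
predict_targets <- function(records, utrs, params = energy_parameters(),
                            mfe_cutoff = -15, context = 15L) {
  utr_seqs <- read_utrs(utrs)
  seeds <- records[["seed"]] %||% extract_seed(records$sequence)
  hits <- purrr::map(seq_len(nrow(records)), function(i) {
    purrr::map(names(utr_seqs), function(g) {
      utr <- utr_seqs[[g]]
      pos <- scan_utr(seeds[i], utr)
      if (length(pos) == 0) return(NULL)
      purrr::map(pos, function(p) {
        win_start <- max(1L, p - context)
        win_end <- min(nchar(utr), p + 6L + context)
        window <- substr(utr, win_start, win_end)
        dup <- hybrid_mfe(records$sequence[i], window, params)
        tibble(tsrna_id = records$tsrna_id[i], gene_id = g,
               utr_position = p, match_type = "seed7", mfe = dup$mfe,
               duplex = list(dup))
      }) |> bind_rows()
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(hits) == 0) {
    return(tibble(tsrna_id = character(), gene_id = character(),
                  utr_position = integer(), match_type = character(),
                  mfe = numeric(), duplex = list()))
  }
  hits |> filter(.data$mfe <= mfe_cutoff, .data$mfe <= 0) |>
    arrange(.data$mfe)
}

read_utrs <- function(utrs) {
  if (is.character(utrs) && length(utrs) == 1 && file.exists(utrs)) {
    set <- Biostrings::readDNAStringSet(utrs, format = "fasta")
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(set))
    return(out)
  }
  if (is.null(names(utrs)) || any(!nzchar(names(utrs)))) {
    abort("UTRs must be a FASTA path or a named character vector")
  }
  utrs
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation between two numeric vectors (for example a
#' tsRNA's expression and a body-weight phenotype across animals) with a
#' two-sided p-value from the t transform on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, non-constant.
#' @return A one-row tibble with `estimate`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("constant input: Pearson correlation is undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one named gene set per line).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a target gene set
#' and each supplied gene set, within a gene universe, with
#' Benjamini-Hochberg FDR across sets.
#'
#' @param target_genes Character vector of gene ids (must lie within
#'   `universe`).
#' @param gene_sets A named list of character vectors, or a GMT file path.
#' @param universe Character vector of all considered gene ids.
#' @return A tibble with `set`, `set_size`, `overlap`, `p_value`, `fdr`,
#'   `genes` (list-column of overlapping ids), sorted by p-value.
#' @export
hypergeometric_enrichment <- function(target_genes, gene_sets, universe) {
  if (length(universe) == 0) abort("empty gene universe")
  universe <- unique(universe)
  target_genes <- unique(target_genes)
  outside <- setdiff(target_genes, universe)
  if (length(outside)) {
    abort(sprintf("target gene(s) outside the universe: %s",
                  paste(utils::head(outside, 5), collapse = ", ")))
  }
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  res <- purrr::imap(gene_sets, function(genes, set_name) {
    genes <- intersect(unique(genes), universe)
    ov <- intersect(target_genes, genes)
    p <- stats::phyper(length(ov) - 1, length(genes),
                       length(universe) - length(genes),
                       length(target_genes), lower.tail = FALSE)
    tibble(set = set_name, set_size = length(genes), overlap = length(ov),
           p_value = p, genes = list(ov))
  }) |> bind_rows()
  res$fdr <- benjamini_hochberg(res$p_value)
  res |> relocate("set", "set_size", "overlap", "p_value", "fdr", "genes") |>
    arrange(.data$p_value)
}
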