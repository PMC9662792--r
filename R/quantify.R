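#' Collapse a FASTQ file to distinct sequences
#'
#' Reads an adapter-trimmed FASTQ, keeps reads within the analysis length
#' window (14-40 nt by default) and tallies each distinct sequence.
#'
#' @param fastq Path to a FASTQ file.
#' @param length_window Integer vector `c(min, max)` in nt.
#' @return A tibble with columns `sequence`, `count`, sorted by decreasing
#'   count. Attribute `excluded` holds the number of out-of-window reads.
#' @export
collapse_reads <- function(fastq, length_window = c(14L, 40L)) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq"),
    error = function(e) abort(sprintf("malformed FASTQ '%s': %s", fastq,
                                      conditionMessage(e)))
  )
  w <- Biostrings::width(reads)
  keep <- w >= length_window[1] & w <= length_window[2]
  excluded <- sum(!keep)
  if (excluded > 0) {
    inform(sprintf("%s: %d read(s) outside the %d-%d nt window excluded",
                   basename(fastq), excluded, length_window[1], length_window[2]))
  }
  if (!any(keep)) {
    out <- tibble(sequence = character(), count = integer())
  } else {
    tab <- table(as.character(reads[keep]))
    out <- tibble(sequence = names(tab), count = as.integer(tab)) |>
      arrange(desc(.data$count), .data$sequence)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Place a fragment sequence on the mature tRNA reference
#'
#' Searches every reference tRNA (and its pre-tRNA trailer, when present)
#' for the fragment, reporting all placements at the minimal mismatch level
#' found. If nothing places and `allow_cca_trim` is `TRUE`, the search is
#' retried with 1-3 trailing characters removed when they are consistent
#' with a non-templated 3' `CCA` addition (trailing `A`, `CA` or `CCA`).
#'
#' @param sequence A single fragment sequence over `A/C/G/T`.
#' @param reference A tRNA reference tibble.
#' @param max_mismatch 0 (default) or 1 allowed mismatches.
#' @param allow_cca_trim Retry with trailing CCA characters trimmed.
#' @return A tibble of placements with columns `sequence`, `parent_id`,
#'   `region` (`"mature"`/`"trailer"`), `start`, `end`, `cca_trimmed`,
#'   `mismatches`. Zero rows if the fragment is unplaced.
#' @export
place_fragment <- function(sequence, reference, max_mismatch = 0L,
                           allow_cca_trim = TRUE) {
  stopifnot(length(sequence) == 1, max_mismatch %in% c(0L, 1L))
  subjects <- reference_subjects(reference)
  hit <- search_subjects(sequence, subjects, max_mismatch)
  cca_trimmed <- 0L
  if (nrow(hit) == 0 && isTRUE(allow_cca_trim)) {
    for (k in 1:3) {
      if (nchar(sequence) - k < 1) break
      tail_k <- substr(sequence, nchar(sequence) - k + 1L, nchar(sequence))
      if (tail_k != substr("CCA", 4L - k, 3L)) next
      trimmed <- substr(sequence, 1L, nchar(sequence) - k)
      hit <- search_subjects(trimmed, subjects, max_mismatch)
      if (nrow(hit) > 0) { cca_trimmed <- k; break }
    }
  }
  if (nrow(hit) == 0) {
    return(tibble(sequence = character(), parent_id = character(),
                  region = character(), start = integer(), end = integer(),
                  cca_trimmed = integer(), mismatches = integer()))
  }
  tibble(sequence = sequence, parent_id = hit$parent_id, region = hit$region,
         start = hit$start, end = hit$end, cca_trimmed = cca_trimmed,
         mismatches = hit$mismatches) |>
    arrange(.data$mismatches, .data$start, .data$parent_id)
}

# precompute the DNAStringSet searched by place_fragment
reference_subjects <- function(reference) {
  cached <- attr(reference, "subjects")
  if (!is.null(cached)) return(cached)
  mature <- tibble(parent_id = reference$id, region = "mature",
                   seq = reference$sequence)
  has_trailer <- nzchar(reference[["trailer"]] %||% character(0)) &
    !is.na(reference$trailer)
  trailer <- tibble(parent_id = reference$id[has_trailer], region = "trailer",
                    seq = reference$trailer[has_trailer])
  tab <- bind_rows(mature, trailer)
  list(meta = tab[c("parent_id", "region")],
       set = Biostrings::DNAStringSet(tab$seq))
}

search_subjects <- function(sequence, subjects, max_mismatch) {
  out <- vector("list", 0)
  for (mm in 0:max_mismatch) {
    pat <- Biostrings::DNAString(sequence)
    hits <- Biostrings::vmatchPattern(pat, subjects$set, max.mismatch = mm)
    n_per <- lengths(hits)
    if (sum(n_per) == 0) next
    starts <- unlist(Biostrings::startIndex(hits)[n_per > 0])
    parent <- rep(subjects$meta$parent_id[n_per > 0], n_per[n_per > 0])
    region <- rep(subjects$meta$region[n_per > 0], n_per[n_per > 0])
    res <- tibble(parent_id = parent, region = region,
                  start = as.integer(starts),
                  end = as.integer(starts) + nchar(sequence) - 1L,
                  mismatches = mm)
    # at mm = 1 vmatchPattern also reports the exact hits; keep minimal level
    return(res)
  }
  tibble(parent_id = character(), region = character(), start = integer(),
         end = integer(), mismatches = integer())
}

#' Build the tsRNA x sample count matrix
#'
#' Collapses every sample's FASTQ, places each distinct sequence on the
#' reference, classifies it, assigns stable tsRNA names and returns the
#' count matrix plus the per-tsRNA records.
#'
#' A tsRNA is a distinct placed read sequence. Its primary placement (lowest
#' mismatch count, then 5'-most start, then lexicographically smallest
#' parent id) determines its name and type. Names follow the field's
#' `tRF-<AA>-<anticodon>-<serial>` / `tiRNA-<AA>-<anticodon>-<serial>`
#' convention with serials assigned per isoacceptor in decreasing order of
#' total count (ties broken by sequence).
#'
#' @param samples A sample sheet tibble with columns `sample_id`, `group`,
#'   `fastq`.
#' @param reference A tRNA reference tibble.
#' @param max_mismatch,allow_cca_trim Passed to [place_fragment()].
#' @param length_window Passed to [collapse_reads()].
#' @param rules Passed to [classify_fragment()].
#' @return A list of class `tsrna_set` with elements `counts` (wide tibble,
#'   `tsrna_id` + one column per sample), `records` (tsrna_id, sequence,
#'   type, seed, primary placement columns, total_count, n_placements),
#'   `placements` (all placements of all catalog sequences), `samples`,
#'   `unaligned` (sequence + per-sample counts of unplaced reads) and `log`
#'   (per-sample totals).
#' @export
build_matrix <- function(samples, reference, max_mismatch = 0L,
                         allow_cca_trim = TRUE, length_window = c(14L, 40L),
                         rules = classification_rules()) {
  required <- c("sample_id", "group", "fastq")
  if (!all(required %in% names(samples))) {
    abort("sample sheet must have columns sample_id, group, fastq")
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in sample sheet")

  per_sample <- purrr::map(seq_len(nrow(samples)), function(i) {
    collapse_reads(samples$fastq[i], length_window)
  })
  names(per_sample) <- samples$sample_id

  all_seqs <- sort(unique(unlist(purrr::map(per_sample, "sequence"))))
  subjects <- reference_subjects(reference)
  reference_cached <- reference
  attr(reference_cached, "subjects") <- subjects
  placements <- purrr::map(all_seqs, place_fragment, reference = reference_cached,
                           max_mismatch = max_mismatch,
                           allow_cca_trim = allow_cca_trim) |>
    bind_rows()

  placed_seqs <- unique(placements$sequence)
  unplaced_seqs <- setdiff(all_seqs, placed_seqs)

  # sequence x sample count matrix
  count_of <- function(tab, seqs) {
    out <- tab$count[match(seqs, tab$sequence)]
    dplyr::coalesce(out, 0L)
  }
  counts_wide <- tibble(sequence = placed_seqs)
  for (sid in samples$sample_id) {
    counts_wide[[sid]] <- count_of(per_sample[[sid]], placed_seqs)
  }
  total <- rowSums(as.matrix(counts_wide[samples$sample_id]))

  # primary placement per sequence
  primary <- placements |>
    group_by(.data$sequence) |>
    arrange(.data$mismatches, .data$start, .data$parent_id, .by_group = TRUE) |>
    summarise(parent_id = dplyr::first(.data$parent_id),
              region = dplyr::first(.data$region),
              start = dplyr::first(.data$start),
              end = dplyr::first(.data$end),
              cca_trimmed = dplyr::first(.data$cca_trimmed),
              mismatches = dplyr::first(.data$mismatches),
              n_placements = n(), .groups = "drop")
  primary <- classify_fragment(primary, reference, rules)

  records <- primary |>
    left_join(tibble(sequence = placed_seqs, total_count = total),
              by = "sequence") |>
    left_join(reference |> select("id", "amino_acid", "anticodon"),
              by = c(parent_id = "id")) |>
    mutate(seed = substr(.data$sequence, 2L, 8L))

  # serials per isoacceptor, by decreasing total count then sequence
  prefix <- ifelse(records$type %in% c("tiRNA-5", "tiRNA-3"), "tiRNA", "tRF")
  family <- paste(prefix, records$amino_acid, records$anticodon, sep = "-")
  ord <- order(family, -records$total_count, records$sequence)
  serial <- integer(nrow(records))
  serial[ord] <- stats::ave(seq_along(ord), family[ord], FUN = seq_along)
  records$tsrna_id <- sprintf("%s-%03d", family, serial)

  records <- records |>
    relocate("tsrna_id", "sequence", "type", "seed", "parent_id", "region",
             "start", "end", "cca_trimmed", "mismatches", "n_placements",
             "total_count") |>
    arrange(desc(.data$total_count), .data$tsrna_id)

  counts <- counts_wide |>
    left_join(records |> select("tsrna_id", "sequence"), by = "sequence") |>
    select("tsrna_id", dplyr::all_of(samples$sample_id)) |>
    arrange(match(.data$tsrna_id, records$tsrna_id))

  unaligned <- tibble(sequence = unplaced_seqs)
  for (sid in samples$sample_id) {
    unaligned[[sid]] <- count_of(per_sample[[sid]], unplaced_seqs)
  }

  log <- tibble(
    sample_id = samples$sample_id,
    in_window_reads = unname(vapply(per_sample, function(x) sum(x$count), numeric(1))),
    excluded_reads = unname(vapply(per_sample, function(x) attr(x, "excluded"), numeric(1))),
    placed_reads = unname(colSums(as.matrix(counts[samples$sample_id]))),
    unplaced_reads = if (nrow(unaligned)) {
      unname(colSums(as.matrix(unaligned[samples$sample_id])))
    } else 0
  )

  structure(list(counts = counts, records = records, placements = placements,
                 samples = samples |> as_tibble(), unaligned = unaligned,
                 log = log),
            class = "tsrna_set")
}

#' @export
print.tsrna_set <- function(x, ...) {
  cat(sprintf("<tsrna_set> %d tsRNAs x %d samples (%s placed reads)\n",
              nrow(x$counts), nrow(x$samples),
              format(sum(x$log$placed_reads), big.mark = ",")))
  print(utils::head(x$records, 5))
  invisible(x)
}
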