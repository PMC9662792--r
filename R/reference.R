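#' Read a mature tRNA reference
#'
#' Loads mature (intron-free, CCA-terminated) tRNA sequences from FASTA,
#' attaches anticodon coordinates and origin from an optional annotation
#' table, and validates every record. The resulting table is the coordinate
#' frame for all downstream fragment placement and classification.
#'
#' GtRNAdb-style headers (`tRNA-Gly-GCC-1-1`) are parsed for the amino acid
#' and anticodon when no annotation row is available; anticodon coordinates
#' are then located with [locate_anticodon()]. An annotation row always wins
#' over header parsing.
#'
#' @param fasta_path Path to a FASTA file of mature tRNA sequences
#'   (`A/C/G/T/U`; `U` is normalised to `T`).
#' @param annotation_path Optional path to a tab-separated annotation table
#'   with header row and columns `id`, `amino_acid`, `anticodon`,
#'   `anticodon_start`, `anticodon_end`, `origin`, `trailer` (empty allowed).
#' @param genomically_encoded_cca If `TRUE` (default) sequences must already
#'   end in `CCA`; if `FALSE`, `CCA` is appended to every sequence (see
#'   [append_cca()]).
#'
#' @return A tibble with one row per tRNA and columns `id`, `amino_acid`,
#'   `anticodon`, `sequence`, `length`, `anticodon_start`, `anticodon_end`,
#'   `origin`, `trailer`. Coordinates are 1-based inclusive.
#' @export
read_trna_reference <- function(fasta_path, annotation_path = NULL,
                                genomically_encoded_cca = TRUE) {
  # read as raw strings first: U (RNA alphabet) is legal input and is
  # normalised to T below, which DNAStringSet would refuse or drop
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", fasta_path,
                                      conditionMessage(e)))
  )
  if (length(seqs) == 0) {
    warn(sprintf("empty FASTA '%s': returning an empty reference", fasta_path))
    return(empty_reference())
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate tRNA ids in '%s': %s", fasta_path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sequence <- normalize_dna(unname(as.character(seqs)), "reference sequence")
  sequence <- append_cca(sequence, genomically_encoded_cca)

  hdr <- parse_gtrnadb_id(ids)
  ref <- tibble(id = ids, amino_acid = hdr$amino_acid,
                anticodon = hdr$anticodon, sequence = sequence)

  if (!is.null(annotation_path)) {
    ann <- read_trna_annotation(annotation_path)
    ref <- ref |>
      left_join(ann, by = "id", suffix = c(".hdr", "")) |>
      mutate(
        amino_acid = dplyr::coalesce(.data$amino_acid, .data$amino_acid.hdr),
        anticodon  = dplyr::coalesce(.data$anticodon, .data$anticodon.hdr)
      ) |>
      select(-"amino_acid.hdr", -"anticodon.hdr")
  } else {
    ref$anticodon_start <- NA_integer_
    ref$anticodon_end <- NA_integer_
    ref$origin <- NA_character_
    ref$trailer <- NA_character_
  }

  ref <- ref |>
    mutate(
      amino_acid = dplyr::coalesce(.data$amino_acid, "Und"),
      origin = dplyr::coalesce(.data$origin, "cytoplasmic"),
      trailer = dplyr::coalesce(.data$trailer, ""),
      length = nchar(.data$sequence)
    )
  if (any(is.na(ref$anticodon))) {
    abort(sprintf(
      "no anticodon for id(s) %s: supply an annotation table or GtRNAdb-style headers",
      paste(ref$id[is.na(ref$anticodon)], collapse = ", ")))
  }
  ref$anticodon <- normalize_dna(ref$anticodon, "anticodon")

  # locate the anticodon where the annotation did not provide coordinates
  missing_pos <- is.na(ref$anticodon_start)
  if (any(missing_pos)) {
    located <- mapply(function(s, ac) locate_anticodon(s, ac)[1],
                      ref$sequence[missing_pos], ref$anticodon[missing_pos])
    ref$anticodon_start[missing_pos] <- as.integer(located)
    ref$anticodon_end[missing_pos] <- as.integer(located) + 2L
  }

  validate_reference(ref)
  ref |> relocate("id", "amino_acid", "anticodon", "sequence", "length",
                  "anticodon_start", "anticodon_end", "origin", "trailer")
}

#' Write a tRNA reference back to FASTA plus annotation table
#'
#' Inverse of [read_trna_reference()]; a written reference reloads to an
#' identical table (round-trip).
#'
#' @param reference A reference tibble from [read_trna_reference()] or
#'   [simulate_reference()].
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, `reference`.
#' @export
write_trna_reference <- function(reference, fasta_path, annotation_path) {
  validate_reference(reference)
  seqs <- Biostrings::DNAStringSet(setNames(reference$sequence, reference$id))
  Biostrings::writeXStringSet(seqs, fasta_path, format = "fasta")
  readr::write_tsv(
    reference |> select("id", "amino_acid", "anticodon", "anticodon_start",
                        "anticodon_end", "origin", "trailer"),
    annotation_path)
  invisible(reference)
}

#' Append or verify the 3' CCA tail
#'
#' Mature tRNAs end in a (frequently non-templated) `CCA`. With
#' `genomically_encoded_cca = FALSE` the tail is appended; with `TRUE` the
#' sequence is returned unchanged and must already end in `CCA`.
#'
#' @param sequence Character vector of sequences over `A/C/G/T`.
#' @param genomically_encoded_cca Logical flag (see above).
#' @return Character vector of CCA-terminated sequences.
#' @export
append_cca <- function(sequence, genomically_encoded_cca = FALSE) {
  if (any(!nzchar(sequence))) abort("sequence must be non-empty")
  if (isTRUE(genomically_encoded_cca)) {
    bad <- !endsWith(sequence, "CCA")
    if (any(bad)) {
      abort(sprintf(
        "genomically_encoded_cca = TRUE but %d sequence(s) do not end in CCA",
        sum(bad)))
    }
    sequence
  } else {
    paste0(sequence, "CCA")
  }
}

#' Locate an anticodon within a mature tRNA sequence
#'
#' Fallback used when no annotation table provides coordinates: among all
#' occurrences of the anticodon 3-mer the one whose start is nearest to the
#' canonical anticodon neighbourhood `round(L/2) - 4` is chosen, ties broken
#' toward the 5'-most occurrence.
#'
#' @param sequence A single sequence over `A/C/G/T`.
#' @param anticodon A 3-mer over `A/C/G/T`.
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
locate_anticodon <- function(sequence, anticodon) {
  stopifnot(length(sequence) == 1, length(anticodon) == 1)
  if (nchar(anticodon) != 3) abort("anticodon must be a 3-mer")
  hits <- gregexpr(anticodon, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    abort(sprintf(
      "anticodon %s not found in sequence; supply anticodon coordinates in the annotation table",
      anticodon))
  }
  target <- round(nchar(sequence) / 2) - 4
  start <- hits[order(abs(hits - target), hits)][1]
  c(start = as.integer(start), end = as.integer(start) + 2L)
}

empty_reference <- function() {
  tibble(id = character(), amino_acid = character(), anticodon = character(),
         sequence = character(), length = integer(),
         anticodon_start = integer(), anticodon_end = integer(),
         origin = character(), trailer = character())
}

parse_gtrnadb_id <- function(ids) {
  m <- regmatches(ids, regexec("^tRNA-([A-Za-z]{3}[0-9]?)-([ACGTUacgtu]{3})", ids))
  amino_acid <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_,
                       character(1))
  anticodon <- vapply(m, function(x) if (length(x) == 3) toupper(chartr("Uu", "Tt", x[3])) else NA_character_,
                      character(1))
  list(amino_acid = amino_acid, anticodon = anticodon)
}

read_trna_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), amino_acid = readr::col_character(),
    anticodon = readr::col_character(),
    anticodon_start = readr::col_integer(),
    anticodon_end = readr::col_integer(),
    origin = readr::col_character(), trailer = readr::col_character()))
  required <- c("id", "amino_acid", "anticodon", "anticodon_start",
                "anticodon_end", "origin", "trailer")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    abort(sprintf("annotation table '%s' lacks column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  ann$trailer <- dplyr::coalesce(ann$trailer, "")
  ann
}

validate_reference <- function(ref) {
  required <- c("id", "amino_acid", "anticodon", "sequence", "length",
                "anticodon_start", "anticodon_end", "origin", "trailer")
  missing <- setdiff(required, names(ref))
  if (length(missing)) {
    abort(sprintf("reference lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(ref) == 0) return(invisible(ref))
  if (anyDuplicated(ref$id)) abort("duplicate tRNA ids in reference")
  if (any(!endsWith(ref$sequence, "CCA"))) {
    abort(sprintf("sequence(s) not CCA-terminated: %s",
                  paste(ref$id[!endsWith(ref$sequence, "CCA")], collapse = ", ")))
  }
  if (any(ref$length != nchar(ref$sequence))) abort("length column out of step with sequence")
  if (any(ref$anticodon_end != ref$anticodon_start + 2L)) {
    abort("anticodon_end must equal anticodon_start + 2")
  }
  bad_range <- ref$anticodon_start < 1 | ref$anticodon_end > ref$length
  if (any(bad_range)) {
    abort(sprintf("anticodon coordinates outside sequence for: %s",
                  paste(ref$id[bad_range], collapse = ", ")))
  }
  observed <- substr(ref$sequence, ref$anticodon_start, ref$anticodon_end)
  bad <- observed != ref$anticodon
  if (any(bad)) {
    abort(sprintf("anticodon mismatch between annotation and sequence for: %s",
                  paste(ref$id[bad], collapse = ", ")))
  }
  invisible(ref)
}
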