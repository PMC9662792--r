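#' Classification rules for tsRNA types
#'
#' Fragments are typed from their cleavage positions on the parent mature
#' tRNA: 5'-anchored fragments ending before the anticodon loop are tRF-5
#' (subtyped by length), fragments ending inside the loop are tRNA halves
#' (tiRNA-5), and symmetrically for the 3' end (tRF-3, tiRNA-3); pre-tRNA
#' trailer fragments are tRF-1 and internal anticodon-spanning fragments are
#' tRF-2.
#'
#' @param loop_halfwidth Nucleotides on each side of the anticodon that
#'   define the anticodon loop (default 3, i.e. a 9-nt window including the
#'   anticodon).
#' @param trf5_bins Upper length bounds for tRF-5a and tRF-5b
#'   (`c(5a = 16, 5b = 24)`): tRF-5a is `<= 16` nt, tRF-5b 17-24 nt,
#'   tRF-5c `>= 25` nt.
#' @param trf3_bins Upper length bound for tRF-3a (`c(3a = 19)`): tRF-3a is
#'   `<= 19` nt, tRF-3b `>= 20` nt.
#' @return A list of class `tsrna_rules`.
#' @export
classification_rules <- function(loop_halfwidth = 3L,
                                 trf5_bins = c("5a" = 16L, "5b" = 24L),
                                 trf3_bins = c("3a" = 19L)) {
  stopifnot(loop_halfwidth >= 0, trf5_bins[1] < trf5_bins[2])
  structure(list(loop_halfwidth = as.integer(loop_halfwidth),
                 trf5_bins = setNames(as.integer(trf5_bins), names(trf5_bins)),
                 trf3_bins = setNames(as.integer(trf3_bins), names(trf3_bins))),
            class = "tsrna_rules")
}

TSRNA_TYPES <- c("tRF-5a", "tRF-5b", "tRF-5c", "tRF-3a", "tRF-3b", "tRF-1",
                 "tRF-2", "tiRNA-5", "tiRNA-3", "unclassified")

#' Classify placed fragments by cleavage position
#'
#' Applies the ordered rule table to each placement. Rules are evaluated in
#' order and the first match wins:
#' 1. trailer placements are `tRF-1`;
#' 2. `start == 1` with `end` inside the anticodon loop is `tiRNA-5`;
#' 3. `start == 1` with `end` before the loop is `tRF-5a/5b/5c` by length;
#' 4. `end == L` with `start` inside the loop is `tiRNA-3`;
#' 5. `end == L` with `start` after the loop is `tRF-3a/3b` by length;
#' 6. internal placements overlapping the anticodon are `tRF-2`;
#' 7. anything else is `unclassified`.
#'
#' @param placements A tibble with columns `parent_id`, `start`, `end` and
#'   optionally `region` (`"mature"` or `"trailer"`; missing means mature).
#'   Coordinates are 1-based inclusive on the mature tRNA.
#' @param reference A tRNA reference tibble (see [read_trna_reference()]).
#' @param rules A [classification_rules()] object.
#' @return `placements` with a `type` column added.
#' @export
classify_fragment <- function(placements, reference,
                              rules = classification_rules()) {
  stopifnot(inherits(rules, "tsrna_rules"))
  if (!all(c("parent_id", "start", "end") %in% names(placements))) {
    abort("placements must have columns parent_id, start, end")
  }
  region <- placements[["region"]] %||% rep("mature", nrow(placements))
  idx <- match(placements$parent_id, reference$id)
  if (anyNA(idx)) {
    abort(sprintf("unknown parent_id(s): %s",
                  paste(unique(placements$parent_id[is.na(idx)]), collapse = ", ")))
  }
  L <- reference$length[idx]
  ac_start <- reference$anticodon_start[idx]
  ac_end <- reference$anticodon_end[idx]
  s <- placements$start
  e <- placements$end
  mature <- region != "trailer"
  if (any(mature & (s < 1 | e > L | s > e))) {
    abort("placement outside [1, L] of the mature tRNA")
  }

  hw <- rules$loop_halfwidth
  loop_lo <- ac_start - hw
  loop_hi <- ac_end + hw
  len <- e - s + 1L

  type <- rep("unclassified", nrow(placements))
  trf5 <- ifelse(len <= rules$trf5_bins[["5a"]], "tRF-5a",
                 ifelse(len <= rules$trf5_bins[["5b"]], "tRF-5b", "tRF-5c"))
  trf3 <- ifelse(len <= rules$trf3_bins[["3a"]], "tRF-3a", "tRF-3b")

  r1 <- !mature
  r2 <- mature & s == 1L & e >= loop_lo & e <= loop_hi
  r3 <- mature & !r2 & s == 1L & e < loop_lo
  r4 <- mature & !r2 & !r3 & e == L & s >= loop_lo & s <= loop_hi
  r5 <- mature & !r2 & !r3 & !r4 & e == L & s > loop_hi
  r6 <- mature & !r2 & !r3 & !r4 & !r5 & s > 1L & e < L &
    s <= ac_end & e >= ac_start
  type[r6] <- "tRF-2"
  type[r5] <- trf3[r5]
  type[r4] <- "tiRNA-3"
  type[r3] <- trf5[r3]
  type[r2] <- "tiRNA-5"
  type[r1] <- "tRF-1"

  placements$type <- type
  placements
}

#' Type composition of a tsRNA catalog
#'
#' Fraction of the catalog in each tsRNA type, either by distinct species
#' or weighted by summed counts across samples.
#'
#' @param records A records tibble with columns `tsrna_id` and `type` (e.g.
#'   from [build_matrix()]).
#' @param counts A wide counts tibble (`tsrna_id` plus one column per
#'   sample); required for `weighting = "abundance"`.
#' @param weighting `"abundance"` (default) or `"species"`.
#' @return A tibble with columns `type`, `weight`, `fraction`; fractions
#'   sum to 1.
#' @export
type_composition <- function(records, counts = NULL,
                             weighting = c("abundance", "species")) {
  weighting <- match.arg(weighting)
  if (nrow(records) == 0) abort("empty catalog: nothing to summarise")
  w <- composition_weights(records, counts, weighting)
  tibble(type = records$type, weight = w) |>
    group_by(.data$type) |>
    summarise(weight = sum(.data$weight), .groups = "drop") |>
    mutate(fraction = .data$weight / sum(.data$weight)) |>
    arrange(desc(.data$fraction))
}

#' Fragment length distribution of a tsRNA catalog
#'
#' As [type_composition()], keyed by fragment length (nt) within the
#' analysis window.
#'
#' @inheritParams type_composition
#' @param records A records tibble with columns `tsrna_id` and `sequence`.
#' @return A tibble with columns `length`, `weight`, `fraction`.
#' @export
length_distribution <- function(records, counts = NULL,
                                weighting = c("abundance", "species")) {
  weighting <- match.arg(weighting)
  if (nrow(records) == 0) abort("empty catalog: nothing to summarise")
  w <- composition_weights(records, counts, weighting)
  tibble(length = nchar(records$sequence), weight = w) |>
    group_by(.data$length) |>
    summarise(weight = sum(.data$weight), .groups = "drop") |>
    mutate(fraction = .data$weight / sum(.data$weight)) |>
    arrange(.data$length)
}

composition_weights <- function(records, counts, weighting) {
  if (weighting == "species") return(rep(1, nrow(records)))
  if (is.null(counts)) abort("abundance weighting needs the counts table")
  m <- counts_matrix(counts)
  total <- rowSums(m)[match(records$tsrna_id, rownames(m))]
  if (anyNA(total)) abort("records and counts tables disagree on tsrna_id")
  if (sum(total) == 0) abort("all counts are zero")
  total
}

# wide counts tibble (tsrna_id + sample columns) -> named numeric matrix
counts_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  if (!"tsrna_id" %in% names(counts)) abort("counts must have a tsrna_id column")
  m <- as.matrix(counts[setdiff(names(counts), "tsrna_id")])
  rownames(m) <- counts$tsrna_id
  storage.mode(m) <- "double"
  m
}
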