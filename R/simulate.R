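#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults are
#' the measured composition of tsRNA expression in porcine skeletal muscle:
#' a 586-fragment catalog dominated by tRF-5c (92% of abundance), ~80% of
#' abundance at 31-32 nt, a heavy-tailed abundance law anchored so the two,
#' four and ten most expressed fragments carry 76%, 81.42% and 89.16% of
#' normal-group expression, 221 distinct seed 7-mers, 103 normal-only and
#' 38 IUGR-only fragments, and 19 down- / 9 up-spiked fold changes of
#' 2^3 = 8 between two 3-replicate groups.
#'
#' @param n_trnas Number of reference tRNAs to simulate against.
#' @param catalog_size Number of distinct planted fragments.
#' @param type_mixture Named abundance fractions per tsRNA type (sums to 1).
#' @param length_mass_31_32 Fraction of abundance at 31-32 nt (`NA` to
#'   leave lengths uncontrolled). Only tRF-5c fragments are planted at
#'   31-32 nt so this mass can be set exactly; requires
#'   `type_mixture["tRF-5c"] >= length_mass_31_32`.
#' @param top_shares Named numeric vector of top-k abundance shares of the
#'   normal group (names are k values), e.g. `c("2" = 0.76, "4" = 0.8142,
#'   "10" = 0.8916)`; `NULL` for an unanchored Zipf law.
#' @param zipf_exponent Within-block abundance decay exponent.
#' @param n_seed_groups Number of distinct seed 7-mers to plant (`NA` to
#'   leave uncontrolled).
#' @param group_specific Named counts `c(normal = ..., iugr = ...)` of
#'   group-specific fragments.
#' @param de_spikes List with `n_down`, `n_up`, `log2fc` (spiked effects,
#'   applied on the IUGR side).
#' @param replicates_per_group Samples per group.
#' @param depth Reads per sample.
#' @param sigma Per-replicate lognormal abundance jitter (sd of log).
#' @param error_rate Per-read probability of one random substitution
#'   (default 0: clean reads).
#' @param rng_seed Master seed; every random step derives from it.
#' @return A list of class `tsrna_sim_config`.
#' @export
sim_config <- function(n_trnas = 160L,
                       catalog_size = 586L,
                       type_mixture = c("tRF-5c" = 0.92, "tRF-5a" = 0.005,
                                        "tRF-5b" = 0.01, "tRF-3a" = 0.01,
                                        "tRF-3b" = 0.025, "tiRNA-5" = 0.01,
                                        "tiRNA-3" = 0.02),
                       length_mass_31_32 = 0.80,
                       top_shares = c("2" = 0.76, "4" = 0.8142,
                                      "10" = 0.8916),
                       zipf_exponent = 0.7,
                       n_seed_groups = 221L,
                       group_specific = c(normal = 103L, iugr = 38L),
                       de_spikes = list(n_down = 19L, n_up = 9L, log2fc = 3),
                       replicates_per_group = 3L,
                       depth = 2e6,
                       sigma = 0.1,
                       error_rate = 0,
                       rng_seed = 1L) {
  if (abs(sum(type_mixture) - 1) > 1e-9) abort("type_mixture must sum to 1")
  if (any(type_mixture < 0) || any(type_mixture > 1)) {
    abort("type_mixture fractions must lie in [0, 1]")
  }
  unknown <- setdiff(names(type_mixture), setdiff(TSRNA_TYPES, "unclassified"))
  if (length(unknown)) {
    abort(sprintf("unknown type(s) in type_mixture: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!is.na(length_mass_31_32)) {
    if ((type_mixture["tRF-5c"] %||% 0) < length_mass_31_32) {
      abort("length_mass_31_32 exceeds the tRF-5c mixture share")
    }
  }
  if (!is.null(top_shares)) {
    ks <- as.integer(names(top_shares))
    if (anyNA(ks) || is.unsorted(ks, strictly = TRUE) ||
        is.unsorted(top_shares, strictly = TRUE)) {
      abort("top_shares must have increasing integer names and increasing values")
    }
  }
  if (catalog_size < sum(group_specific)) {
    abort("catalog_size must cover the group-specific subsets")
  }
  if (depth <= 0) abort("depth must be positive")
  structure(list(n_trnas = check_scalar_count(n_trnas, "n_trnas"),
                 catalog_size = check_scalar_count(catalog_size, "catalog_size"),
                 type_mixture = type_mixture,
                 length_mass_31_32 = length_mass_31_32,
                 top_shares = top_shares,
                 zipf_exponent = zipf_exponent,
                 n_seed_groups = if (is.na(n_seed_groups)) NA_integer_ else
                   check_scalar_count(n_seed_groups, "n_seed_groups"),
                 group_specific = group_specific,
                 de_spikes = de_spikes,
                 replicates_per_group = check_scalar_count(replicates_per_group,
                                                           "replicates_per_group"),
                 depth = depth, sigma = sigma, error_rate = error_rate,
                 rng_seed = check_scalar_count(rng_seed, "rng_seed", min = 0)),
            class = "tsrna_sim_config")
}

#' Simulate a mature tRNA reference
#'
#' Random CCA-terminated mature tRNAs of 70-90 nt with the anticodon at a
#' canonical position (start in 33-38), GtRNAdb-style ids
#' `tRNA-<AA>-<anticodon>-<k>-1`, a 20-nt 3' trailer, pairwise-distinct
#' 40-nt 5' prefixes and pairwise-distinct positions 2-8 (so fragment to
#' parent assignment and seed accounting are unambiguous).
#'
#' @param n_trnas Number of tRNAs (>= 1).
#' @param rng_seed Integer seed; fixed seed gives identical output.
#' @param length_range Mature length range in nt.
#' @param trailer_length 3' pre-tRNA trailer length in nt.
#' @return A reference tibble (same schema as [read_trna_reference()]).
#' @export
simulate_reference <- function(n_trnas, rng_seed = 1L,
                               length_range = c(70L, 90L),
                               trailer_length = 20L) {
  n_trnas <- check_scalar_count(n_trnas, "n_trnas")
  set.seed(rng_seed)
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  aa3 <- Biostrings::AMINO_ACID_CODE[Biostrings::GENETIC_CODE[codons]]
  anticodons <- revcomp(codons)

  rows <- vector("list", n_trnas)
  seen_prefix <- character(0); seen_seed <- character(0)
  for (k in seq_len(n_trnas)) {
    repeat {
      ci <- sample(length(codons), 1)
      L <- sample(length_range[1]:length_range[2], 1)
      ac_start <- sample(33:38, 1)
      s <- strsplit(random_dna(L), "")[[1]]
      s[ac_start:(ac_start + 2L)] <- strsplit(anticodons[ci], "")[[1]]
      s[(L - 2L):L] <- c("C", "C", "A")
      seq <- paste(s, collapse = "")
      prefix <- substr(seq, 1, 40)
      seed7 <- substr(seq, 2, 8)
      if (!(prefix %in% seen_prefix) && !(seed7 %in% seen_seed)) break
    }
    seen_prefix <- c(seen_prefix, prefix); seen_seed <- c(seen_seed, seed7)
    rows[[k]] <- tibble(
      id = sprintf("tRNA-%s-%s-%d-1", aa3[ci], anticodons[ci], k),
      amino_acid = unname(aa3[ci]), anticodon = anticodons[ci],
      sequence = seq, length = nchar(seq),
      anticodon_start = as.integer(ac_start),
      anticodon_end = as.integer(ac_start) + 2L,
      origin = "cytoplasmic", trailer = random_dna(trailer_length))
  }
  ref <- bind_rows(rows)
  validate_reference(ref)
  ref
}

# ---- catalog construction -------------------------------------------------

#' Simulate a planted fragment catalog
#'
#' Builds `catalog_size` distinct fragment sequences placed on the
#' reference so that, by construction and exactly: abundance-weighted type
#' shares match `type_mixture`; the abundance mass at 31-32 nt matches
#' `length_mass_31_32`; the top-k shares match `top_shares`; group-specific
#' subsets have the configured sizes; spiked fragments carry the configured
#' log2 fold changes; and the number of distinct seed 7-mers equals
#' `n_seed_groups`. All shares are anchored on the normal-group baseline
#' (the composition a normal sample draws from).
#'
#' @param config A [sim_config()] object.
#' @param reference A reference tibble (e.g. from [simulate_reference()]).
#' @return A tibble of class `tsrna_truth`: one row per planted fragment
#'   with `sequence`, `parent_id`, `region`, `start`, `end`, `length`,
#'   `type`, `seed`, `block`, `baseline` (normal-group fraction),
#'   `group` (`shared`/`normal_only`/`iugr_only`), `log2fc`. The config is
#'   attached as attribute `config`.
#' @export
simulate_catalog <- function(config, reference) {
  stopifnot(inherits(config, "tsrna_sim_config"))
  if (nrow(reference) == 0) abort("empty reference")
  set.seed(derive_seeds(config$rng_seed, 4)[1])

  species <- allocate_species(config)
  frags <- plant_fragments(config, reference, species)
  frags <- assign_groups(config, frags)
  frags <- assign_abundance(config, frags)
  frags <- assign_spikes(config, frags)

  # truth-consistency: the classifier reproduces every planted label
  check <- classify_fragment(frags[c("parent_id", "region", "start", "end")],
                             reference, classification_rules())
  if (!identical(check$type, frags$type)) {
    abort("internal error: planted types disagree with classify_fragment")
  }
  verify_catalog(config, frags)
  frags <- frags |> arrange(desc(.data$baseline))
  structure(frags, class = c("tsrna_truth", class(frags)), config = config)
}

# species counts per type: non-tRF-5c types get ~3x their abundance share
# of the catalog (they are many-species / low-abundance), tRF-5c the rest
allocate_species <- function(config) {
  mix <- config$type_mixture[config$type_mixture > 0]
  if (!"tRF-5c" %in% names(mix)) {
    n <- round(config$catalog_size * mix / sum(mix))
    n[1] <- config$catalog_size - sum(n[-1])
    return(n)
  }
  other <- mix[setdiff(names(mix), "tRF-5c")]
  n_other <- if (length(other)) {
    n <- round(config$catalog_size * other * 3)
    n[n < 2] <- 2L
    n
  } else {
    integer(0)
  }
  n5c <- config$catalog_size - sum(n_other)
  if (n5c < 12) abort("catalog_size too small for the requested type mixture")
  c("tRF-5c" = n5c, n_other)
}

FIVE_ANCHORED <- c("tRF-5a", "tRF-5b", "tRF-5c", "tiRNA-5")

# candidate fragment lengths per type for one parent; only tRF-5c may take
# lengths 31-32 (so the 31-32 abundance mass can be set exactly)
slot_lengths <- function(type, L, ac_start, ac_end) {
  lens <- switch(type,
    "tRF-5a" = 14:16,
    "tRF-5b" = 17:24,
    "tRF-5c" = 25:min(34L, ac_start - 4L),
    "tiRNA-5" = (ac_start - 3L):min(40L, ac_end + 3L),
    "tRF-3a" = 14:19,
    "tRF-3b" = 20:min(40L, L - ac_end - 3L),
    "tiRNA-3" = max(14L, L - ac_end - 2L):min(40L, L - ac_start + 4L),
    "tRF-2" = 14:30,
    "tRF-1" = 14:20)
  if (length(lens) == 0 || lens[1] > lens[length(lens)]) return(integer(0))
  if (type != "tRF-5c") lens <- setdiff(lens, 31:32)
  lens
}

# one concrete placement of `type` with length `len` on parent row `p`
make_placement <- function(type, len, p) {
  L <- p$length
  if (type %in% FIVE_ANCHORED) {
    start <- 1L; end <- len; region <- "mature"
  } else if (type %in% c("tRF-3a", "tRF-3b", "tiRNA-3")) {
    start <- L - len + 1L; end <- L; region <- "mature"
  } else if (type == "tRF-2") {
    lo <- max(2L, p$anticodon_start - len + 1L)
    hi <- min(p$anticodon_end, L - len)
    if (lo > hi) return(NULL)
    start <- sample_one(lo:hi); end <- start + len - 1L
    region <- "mature"
  } else if (type == "tRF-1") {
    Ltr <- nchar(p$trailer)
    if (Ltr < len) return(NULL)
    start <- sample_one(seq_len(Ltr - len + 1L)); end <- start + len - 1L
    region <- "trailer"
  } else {
    abort(sprintf("cannot plant type %s", type))
  }
  src <- if (region == "trailer") p$trailer else p$sequence
  tibble(parent_id = p$id, region = region, start = start, end = end,
         length = len, type = type,
         sequence = substr(src, start, end))
}

plant_fragments <- function(config, reference, species) {
  five <- intersect(names(species), FIVE_ANCHORED)
  non5 <- setdiff(names(species), FIVE_ANCHORED)
  n_five <- sum(species[five]); n_non5 <- sum(species[non5])

  control_seeds <- !is.na(config$n_seed_groups)
  if (control_seeds) {
    n_parents <- config$n_seed_groups - n_non5
    if (n_parents < 1) {
      abort("n_seed_groups too small: every non-5'-anchored fragment carries its own seed")
    }
    if (n_five > 0 && n_parents > min(nrow(reference), n_five)) {
      abort("n_seed_groups too large for this reference / catalog")
    }
    if (n_five == 0 && n_parents != 0) {
      abort("n_seed_groups incompatible with a catalog lacking 5'-anchored types")
    }
  } else {
    n_parents <- min(nrow(reference), max(1L, n_five))
  }

  parents <- reference[sample.int(nrow(reference)), ]
  used_seeds <- character(0)
  used_seqs <- character(0)
  out <- vector("list", 0)

  # ---- 5'-anchored fragments: seed == parent positions 2-8 ----------------
  if (n_five > 0) {
    parents5 <- utils::head(parents, n_parents)
    # the abundance-anchor parent hosts the top-4 fragments (needs deep
    # 5' arm so 30-33 nt tRF-5c fragments all exist)
    ord <- order(-parents5$anticodon_start)
    parents5 <- parents5[ord, ]
    budget <- species[five]
    taken <- list()  # per parent: lengths already used
    add_frag <- function(p, len) {
      fr <- make_placement(classify_len5(len, p), len, p)
      out[[length(out) + 1L]] <<- fr
      used_seqs <<- c(used_seqs, fr$sequence)
      taken[[p$id]] <<- c(taken[[p$id]], len)
    }
    classify_len5 <- function(len, p) {
      lo <- p$anticodon_start - 3L; hi <- p$anticodon_end + 3L
      if (len >= lo && len <= hi) "tiRNA-5"
      else if (len <= 16L) "tRF-5a" else if (len <= 24L) "tRF-5b" else "tRF-5c"
    }
    top_lens <- integer(0)
    if (!is.null(config$top_shares) && budget["tRF-5c"] >= 10) {
      p1 <- parents5[1, ]
      lens1 <- slot_lengths("tRF-5c", p1$length, p1$anticodon_start,
                            p1$anticodon_end)
      top_lens <- utils::head(c(intersect(c(31L, 32L, 30L, 33L), lens1),
                                setdiff(rev(lens1), c(31L, 32L, 30L, 33L))), 4)
      if (length(top_lens) < 4) abort("anchor parent cannot host the top-4 fragments")
      for (len in top_lens) add_frag(p1, len)
      budget["tRF-5c"] <- budget["tRF-5c"] - 4L
      # ranks 5-10: rank 5 at 31/32 nt, ranks 6-10 elsewhere
      pool31 <- which(vapply(seq_len(nrow(parents5))[-1], function(i) {
        any(c(31L, 32L) %in% slot_lengths("tRF-5c", parents5$length[i],
                                          parents5$anticodon_start[i],
                                          parents5$anticodon_end[i]))
      }, logical(1))) + 1L
      if (length(pool31) == 0) abort("no parent can host a 31-32 nt tRF-5c")
      p5 <- parents5[pool31[1], ]
      l5 <- intersect(c(31L, 32L), slot_lengths("tRF-5c", p5$length,
                                                p5$anticodon_start,
                                                p5$anticodon_end))[1]
      add_frag(p5, l5)
      budget["tRF-5c"] <- budget["tRF-5c"] - 1L
      others <- setdiff(2:min(7L, nrow(parents5)), pool31[1])
      for (i in utils::head(others, 5)) {
        p <- parents5[i, ]
        lens <- setdiff(slot_lengths("tRF-5c", p$length, p$anticodon_start,
                                     p$anticodon_end), c(31:32, taken[[p$id]]))
        if (length(lens) == 0) abort("cannot place a top-10 tRF-5c fragment")
        add_frag(p, lens[1])
        budget["tRF-5c"] <- budget["tRF-5c"] - 1L
      }
      if (length(out) < 10) abort("reference too small to anchor the top-10 fragments")
    }
    n_top <- length(out)

    # every parent must host at least one fragment (it contributes a seed)
    for (i in seq_len(nrow(parents5))) {
      p <- parents5[i, ]
      if (!is.null(taken[[p$id]])) next
      placed <- FALSE
      for (ty in names(sort(budget, decreasing = TRUE))) {
        if (budget[ty] <= 0) next
        lens <- setdiff(slot_lengths(ty, p$length, p$anticodon_start,
                                     p$anticodon_end), taken[[p$id]])
        if (ty == "tRF-5c") lens <- setdiff(lens, 31:32)
        if (length(lens) == 0) next
        add_frag(p, sample_one(lens)); budget[ty] <- budget[ty] - 1L
        placed <- TRUE; break
      }
      if (!placed) abort("a selected parent cannot host any budgeted fragment type")
    }

    # the 31-32 nt tRF-5c tail block, then everything else round-robin
    n_b3 <- 0L
    if (!is.na(config$length_mass_31_32) && budget["tRF-5c"] > 0) {
      n_b3 <- min(budget["tRF-5c"],
                  max(1L, round(0.25 * budget["tRF-5c"])))
      if (!is.null(config$top_shares) && n_top > 0) {
        # keep every tail fragment below the smallest top-rank abundance:
        # spread the 31-32 nt tail mass over enough fragments
        shares <- top_share_values(config$top_shares)
        top_lens <- vapply(out[seq_len(n_top)], function(f) f$length, integer(1))
        b3_mass <- config$length_mass_31_32 - sum(shares[top_lens %in% 31:32])
        if (b3_mass > 0) {
          n_b3 <- min(budget["tRF-5c"],
                      max(n_b3, ceiling(2 * b3_mass / min(shares))))
        }
      }
      pool <- list()
      for (i in seq_len(nrow(parents5))) {
        p <- parents5[i, ]
        lens <- setdiff(intersect(c(31L, 32L),
                                  slot_lengths("tRF-5c", p$length,
                                               p$anticodon_start,
                                               p$anticodon_end)),
                        taken[[p$id]])
        for (len in lens) pool[[length(pool) + 1L]] <- list(i = i, len = len)
      }
      if (length(pool) < n_b3) n_b3 <- length(pool)
      if (n_b3 == 0L) abort("no capacity for 31-32 nt tRF-5c fragments")
      pick <- sample(length(pool), n_b3)
      for (k in pick) add_frag(parents5[pool[[k]]$i, ], pool[[k]]$len)
      budget["tRF-5c"] <- budget["tRF-5c"] - n_b3
    }
    guard <- 0L
    while (sum(budget) > 0) {
      guard <- guard + 1L
      if (guard > 50L * n_five) abort("cannot place all 5'-anchored fragments: increase n_trnas")
      i <- sample(nrow(parents5), 1); p <- parents5[i, ]
      ty <- sample(names(budget)[budget > 0], 1)
      lens <- setdiff(slot_lengths(ty, p$length, p$anticodon_start,
                                   p$anticodon_end), taken[[p$id]])
      if (ty == "tRF-5c" && !is.na(config$length_mass_31_32)) {
        lens <- setdiff(lens, 31:32)
      }
      if (length(lens) == 0) next
      add_frag(p, sample_one(lens)); budget[ty] <- budget[ty] - 1L
    }
    used_seeds <- c(used_seeds, substr(parents5$sequence, 2, 8))
  }

  # ---- non-5'-anchored fragments: one fresh seed each ---------------------
  for (ty in non5) {
    eligible <- reference[vapply(seq_len(nrow(reference)), function(i) {
      length(slot_lengths(ty, reference$length[i], reference$anticodon_start[i],
                          reference$anticodon_end[i])) > 0
    }, logical(1)), ]
    if (nrow(eligible) == 0) abort(sprintf("no reference tRNA can host type %s", ty))
    for (k in seq_len(species[[ty]])) {
      placed <- FALSE
      for (attempt in 1:200) {
        p <- eligible[sample(nrow(eligible), 1), ]
        lens <- slot_lengths(ty, p$length, p$anticodon_start, p$anticodon_end)
        fr <- make_placement(ty, sample_one(lens), p)
        if (is.null(fr)) next
        sd7 <- substr(fr$sequence, 2, 8)
        if (fr$sequence %in% used_seqs) next
        if (control_seeds && sd7 %in% used_seeds) next
        out[[length(out) + 1L]] <- fr
        used_seqs <- c(used_seqs, fr$sequence)
        used_seeds <- c(used_seeds, sd7)
        placed <- TRUE; break
      }
      if (!placed) {
        abort(sprintf("could not place a distinct %s fragment after 200 attempts", ty))
      }
    }
  }

  frags <- bind_rows(out)
  if (anyDuplicated(frags$sequence)) abort("internal error: duplicate planted sequences")
  frags$seed <- substr(frags$sequence, 2, 8)
  if (control_seeds && length(unique(frags$seed)) != config$n_seed_groups) {
    abort("internal error: seed-group count off target")
  }
  has_top <- !is.null(config$top_shares) &&
    "tRF-5c" %in% names(species) && species[["tRF-5c"]] >= 10
  n_top <- if (has_top) as.integer(max(as.integer(names(config$top_shares)))) else 0L
  frags$block <- dplyr::case_when(
    seq_len(nrow(frags)) <= n_top ~ "top",
    frags$type == "tRF-5c" & frags$length %in% 31:32 ~ "b31_32",
    frags$type == "tRF-5c" ~ "b5c_other",
    TRUE ~ paste0("b_", frags$type))
  frags
}

assign_groups <- function(config, frags) {
  frags$group <- "shared"
  gs <- config$group_specific
  n_spec <- sum(gs)
  if (n_spec == 0) return(frags)
  pool <- which(frags$block != "top")
  if (length(pool) < n_spec) abort("not enough non-top fragments for group-specific subsets")
  # stratified by block so group-specific removal barely moves type shares
  by_block <- split(pool, frags$block[pool])
  alloc <- largest_remainder(n_spec, lengths(by_block))
  chosen <- unlist(purrr::map2(by_block, alloc, function(idx, k) {
    if (k == 0) integer(0) else sample_n_of(idx, k)
  }), use.names = FALSE)
  chosen <- sample(chosen)  # interleave blocks before splitting normal/iugr
  frags$group[chosen[seq_len(gs[["normal"]])]] <- "normal_only"
  if (gs[["iugr"]] > 0) {
    frags$group[chosen[gs[["normal"]] + seq_len(gs[["iugr"]])]] <- "iugr_only"
  }
  frags
}

largest_remainder <- function(total, sizes) {
  quota <- total * sizes / sum(sizes)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    up <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[up] <- base[up] + 1
  }
  # never allocate more than a stratum holds
  over <- base > sizes
  while (any(over)) {
    excess <- sum(base[over] - sizes[over]); base[over] <- sizes[over]
    room <- which(base < sizes)
    base[room[seq_len(min(excess, length(room)))]] <-
      base[room[seq_len(min(excess, length(room)))]] + 1
    over <- base > sizes
  }
  base
}

assign_abundance <- function(config, frags) {
  vis <- frags$group != "iugr_only"   # the normal-group baseline
  baseline <- numeric(nrow(frags))
  zipf <- function(n) if (n == 0) numeric(0) else
    (seq_len(n)^(-config$zipf_exponent)) / sum(seq_len(n)^(-config$zipf_exponent))

  top_idx <- which(frags$block == "top")
  top_mass <- 0; top_31_32 <- 0
  if (length(top_idx)) {
    shares <- top_share_values(config$top_shares)
    if (length(shares) != length(top_idx)) {
      abort("internal error: top block size disagrees with top_shares")
    }
    baseline[top_idx] <- shares
    top_mass <- sum(shares)
    top_31_32 <- sum(shares[frags$length[top_idx] %in% 31:32])
  }

  mix <- config$type_mixture
  blocks <- setdiff(unique(frags$block[vis]), "top")
  mass <- numeric(length(blocks)); names(mass) <- blocks
  if ("b31_32" %in% blocks) {
    m <- config$length_mass_31_32
    if (is.na(m)) m <- top_31_32 + 0.05  # uncontrolled: nominal tail
    mass["b31_32"] <- m - top_31_32
  }
  if ("b5c_other" %in% blocks) {
    b31 <- if ("b31_32" %in% blocks) mass[["b31_32"]] else 0
    mass["b5c_other"] <- mix[["tRF-5c"]] - top_mass - b31
  }
  for (b in grep("^b_", blocks, value = TRUE)) {
    mass[b] <- mix[[sub("^b_", "", b)]]
  }
  if (any(mass < 0)) {
    abort("infeasible abundance targets: top shares / length mass / mixture conflict")
  }
  total_check <- top_mass + sum(mass)
  if (abs(total_check - 1) > 1e-9) {
    abort(sprintf("abundance masses sum to %.6f, not 1: check the configuration",
                  total_check))
  }
  min_top <- if (length(top_idx)) min(baseline[top_idx]) else Inf
  for (b in blocks) {
    idx <- which(vis & frags$block == b)
    if (length(idx) == 0) {
      if (mass[b] > 1e-12) abort(sprintf("block %s has mass but no fragments", b))
      next
    }
    w <- zipf(length(idx))[sample(length(idx))]
    # the planted top ranks must stay the top ranks: flatten a tail block
    # whose head would outrank them, and fail loudly if even a uniform
    # spread cannot fit under the smallest top share
    if (mass[b] * max(w) >= min_top * 0.999) {
      w <- rep(1 / length(idx), length(idx))
    }
    if (mass[b] * max(w) >= min_top * 0.999) {
      abort(sprintf(
        "top_shares incompatible with tail block %s (%.4f mass over %d fragments)",
        b, mass[b], length(idx)))
    }
    baseline[idx] <- mass[b] * w
  }

  # IUGR-only fragments: typical tail abundance of their block (only the
  # IUGR side ever sees it)
  for (b in blocks) {
    idx <- which(!vis & frags$block == b)
    if (length(idx) == 0) next
    donors <- baseline[vis & frags$block == b]
    baseline[idx] <- if (length(donors)) stats::median(donors) else 1e-5
  }
  frags$baseline <- baseline
  frags
}

# split anchored cumulative top-k shares into per-rank values: within each
# anchored segment, linearly decreasing weights
top_share_values <- function(top_shares) {
  ks <- as.integer(names(top_shares))
  out <- numeric(max(ks))
  prev_k <- 0; prev_s <- 0
  for (i in seq_along(ks)) {
    n <- ks[i] - prev_k
    seg <- top_shares[i] - prev_s
    w <- rev(seq_len(n)) + n  # gentle within-segment decrease
    out[(prev_k + 1):ks[i]] <- seg * w / sum(w)
    prev_k <- ks[i]; prev_s <- top_shares[i]
  }
  out
}

assign_spikes <- function(config, frags) {
  frags$log2fc <- 0
  sp <- config$de_spikes
  n_sp <- sp$n_down + sp$n_up
  if (n_sp == 0) return(frags)
  eligible <- which(frags$group == "shared" & frags$block != "top")
  if (length(eligible) < n_sp) abort("not enough shared tail fragments to spike")
  eligible <- eligible[order(-frags$baseline[eligible])]
  chosen <- eligible[seq_len(n_sp)]
  frags$log2fc[chosen[seq_len(sp$n_down)]] <- -abs(sp$log2fc)
  if (sp$n_up > 0) {
    frags$log2fc[chosen[sp$n_down + seq_len(sp$n_up)]] <- abs(sp$log2fc)
  }
  frags
}

# exactness checks on the constructed catalog (normal-group baseline)
verify_catalog <- function(config, frags) {
  if (nrow(frags) != config$catalog_size) {
    abort("internal error: catalog size off target")
  }
  vis <- frags$group != "iugr_only"
  b <- frags$baseline[vis] / sum(frags$baseline[vis])
  shares <- tapply(b, frags$type[vis], sum)
  for (ty in names(config$type_mixture)) {
    got <- shares[[ty]] %||% 0
    if (abs(got - config$type_mixture[[ty]]) > 1e-6) {
      abort(sprintf("internal error: %s abundance share %.6f != %.6f",
                    ty, got, config$type_mixture[[ty]]))
    }
  }
  if (!is.na(config$length_mass_31_32)) {
    got <- sum(b[frags$length[vis] %in% 31:32])
    if (abs(got - config$length_mass_31_32) > 1e-9) {
      abort("internal error: 31-32 nt abundance mass off target")
    }
  }
  if (!is.null(config$top_shares)) {
    sorted <- sort(b, decreasing = TRUE)
    for (k in names(config$top_shares)) {
      got <- sum(sorted[seq_len(as.integer(k))])
      if (abs(got - config$top_shares[[k]]) > 1e-9) {
        abort(sprintf("internal error: top-%s share %.6f != %.6f",
                      k, got, config$top_shares[[k]]))
      }
    }
  }
  invisible(frags)
}

# ---- read simulation ------------------------------------------------------

#' Simulate two-condition small-RNA FASTQ read sets
#'
#' Per sample, read counts are a multinomial draw of size `depth` over the
#' planted fragments visible to that sample's group, with per-replicate
#' lognormal abundance jitter and the spiked fold changes applied on the
#' IUGR side. Reads are exact fragment sequences unless `error_rate > 0`.
#' Output is deterministic for a fixed config seed.
#'
#' @param truth A catalog from [simulate_catalog()].
#' @param out_dir Directory for the FASTQ files and `sample_sheet.tsv`.
#' @param config A [sim_config()]; defaults to the one attached to `truth`.
#' @return The sample sheet tibble (`sample_id`, `group`, `fastq`).
#' @export
simulate_reads <- function(truth, out_dir, config = NULL) {
  config <- config %||% attr(truth, "config")
  stopifnot(inherits(config, "tsrna_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_rep <- config$replicates_per_group
  sheet <- tibble(
    sample_id = c(paste0("normal_", seq_len(n_rep)),
                  paste0("iugr_", seq_len(n_rep))),
    group = rep(c("normal", "iugr"), each = n_rep))
  sheet$fastq <- file.path(out_dir, paste0(sheet$sample_id, ".fastq"))
  seeds <- derive_seeds(config$rng_seed + 1L, nrow(sheet))

  for (i in seq_len(nrow(sheet))) {
    set.seed(seeds[i])
    g <- sheet$group[i]
    visible <- truth$group == "shared" | truth$group == paste0(g, "_only")
    w <- truth$baseline[visible]
    if (g == "iugr") w <- w * 2^truth$log2fc[visible]
    w <- w * exp(rnorm(length(w), 0, config$sigma))
    counts <- as.integer(rmultinom(1, config$depth, w / sum(w)))
    reads <- rep(truth$sequence[visible], counts)
    if (config$error_rate > 0 && length(reads)) {
      hit <- which(stats::runif(length(reads)) < config$error_rate)
      for (r in hit) {
        pos <- sample(nchar(reads[r]), 1)
        substr(reads[r], pos, pos) <- sample(DNA_BASES, 1)
      }
    }
    write_fastq(reads, sheet$sample_id[i], sheet$fastq[i])
  }
  readr::write_tsv(sheet, file.path(out_dir, "sample_sheet.tsv"))
  sheet
}

write_fastq <- function(reads, sample_id, path) {
  n <- length(reads)
  if (n == 0) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  rec <- character(4L * n)
  rec[seq(1, 4 * n, by = 4)] <- sprintf("@%s_%d", sample_id, seq_len(n))
  rec[seq(2, 4 * n, by = 4)] <- reads
  rec[seq(3, 4 * n, by = 4)] <- "+"
  rec[seq(4, 4 * n, by = 4)] <- strrep("I", nchar(reads))
  readr::write_lines(rec, path)
  invisible(path)
}

# ---- UTR simulation -------------------------------------------------------

#' Simulate 3' UTRs with planted tsRNA target sites
#'
#' Each planted gene's UTR contains the reverse complement of the first
#' `site_extend` nucleotides of its tsRNA (an extended complementary site
#' containing exactly one reverse-complement occurrence of the seed,
#' positions 2-8); background UTRs contain no reverse complement of any
#' listed tsRNA's seed (rejection-sampled).
#'
#' @param tsrna_seqs Named character vector of tsRNA sequences.
#' @param n_genes Total number of UTRs (planted plus background).
#' @param planted Named character vector mapping tsRNA name -> gene id.
#' @param rng_seed Integer seed.
#' @param utr_length UTR length in nt.
#' @param site_extend Length of the planted complementary site (>= 8 so it
#'   covers the seed).
#' @param fasta_path Optional path; when given the UTRs are also written as
#'   FASTA.
#' @param max_attempts Rejection-sampling bound per UTR.
#' @return A list with `utrs` (named character vector) and `truth` (tibble
#'   `gene_id`, `tsrna`, `seed_position`, `site`).
#' @export
simulate_utrs <- function(tsrna_seqs, n_genes, planted, rng_seed = 1L,
                          utr_length = 400L, site_extend = 16L,
                          fasta_path = NULL, max_attempts = 200L) {
  if (is.null(names(tsrna_seqs))) abort("tsrna_seqs must be named")
  if (!all(names(planted) %in% names(tsrna_seqs))) {
    abort("planted tsRNAs must appear in tsrna_seqs")
  }
  if (site_extend < 8) abort("site_extend must be >= 8 to cover the seed")
  if (n_genes < length(planted)) abort("n_genes smaller than the planted map")
  set.seed(rng_seed)
  seeds <- extract_seed(tsrna_seqs)
  forbidden <- unique(revcomp(seeds))

  clean_utr <- function(len) {
    for (attempt in seq_len(max_attempts)) {
      u <- random_dna(len)
      if (!any(vapply(forbidden, function(f) grepl(f, u, fixed = TRUE),
                      logical(1)))) {
        return(u)
      }
    }
    abort("rejection sampling failed: try a longer UTR or fewer seeds")
  }

  gene_ids <- unique(c(unname(planted),
                       sprintf("gene%03d", seq_len(n_genes))))[seq_len(n_genes)]
  utrs <- character(length(gene_ids)); names(utrs) <- gene_ids
  truth <- vector("list", 0)
  for (g in gene_ids) {
    ts_name <- names(planted)[match(g, planted)]
    if (is.na(ts_name)) { utrs[g] <- clean_utr(utr_length); next }
    site <- revcomp(substr(tsrna_seqs[[ts_name]], 1L, site_extend))
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      u <- clean_utr(utr_length)
      at <- sample(utr_length - site_extend + 1L, 1)
      substr(u, at, at + site_extend - 1L) <- site
      hits <- scan_utr(seeds[[ts_name]], u)
      # tsRNAs sharing the planted seed match the planted site by design;
      # only genuinely different seeds must stay absent
      other_seeds <- setdiff(unique(seeds), seeds[[ts_name]])
      clash <- any(vapply(other_seeds,
                          function(s) length(scan_utr(s, u)) > 0, logical(1)))
      if (length(hits) == 1 && !clash) {
        utrs[g] <- u
        truth[[length(truth) + 1L]] <-
          tibble(gene_id = g, tsrna = ts_name, seed_position = hits, site = site)
        ok <- TRUE; break
      }
    }
    if (!ok) abort("rejection sampling failed while planting a site")
  }
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(utrs), fasta_path)
  }
  list(utrs = utrs, truth = bind_rows(truth))
}
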