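#' Nearest-neighbour duplex energy parameters
#'
#' A reduced nearest-neighbour parameterisation for intermolecular RNA-RNA
#' duplexes: Watson-Crick stack free energies (kcal/mol at 37 C) with a
#' uniform value for wobble-containing stacks, an affine penalty for bulges
#' and internal loops, and a duplex initiation term. Parameters are data:
#' pass a modified object to swap the model.
#'
#' Pairs are labelled by the small-RNA base followed by the target base in
#' RNA letters (`"AU"`, `"UA"`, `"CG"`, `"GC"`, `"GU"`, `"UG"`). The stack
#' matrix entry `stack[p1, p2]` is the energy of helix step `p1` (pair at
#' positions `i, j`) followed by `p2` (pair at `i+1, j-1`).
#'
#' @param init Duplex initiation penalty (kcal/mol, > 0). The reduced
#'   model uses a small nominal term rather than the full Turner
#'   initiation/symmetry corrections, so that short perfect helices keep a
#'   negative reported energy, as hybridisation tools conventionally do.
#' @param loop_open Penalty for opening a bulge or internal loop (> 0).
#' @param loop_per_nt Penalty per unpaired nucleotide in a loop (> 0).
#' @param max_loop Maximum unpaired nucleotides per strand in one loop.
#' @return A list of class `tsrna_energy`.
#' @export
energy_parameters <- function(init = 0.5, loop_open = 2.0,
                              loop_per_nt = 0.5, max_loop = 10L) {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(c(
    # p2:   AU     UA     CG     GC     GU     UG
    -0.93, -1.10, -2.24, -2.08, -1.20, -1.20,  # p1 = AU
    -1.33, -0.93, -2.35, -2.11, -1.20, -1.20,  # p1 = UA
    -2.11, -2.08, -3.26, -2.36, -1.20, -1.20,  # p1 = CG
    -2.35, -2.24, -3.42, -3.26, -1.20, -1.20,  # p1 = GC
    -1.20, -1.20, -1.20, -1.20, -0.50, -0.50,  # p1 = GU
    -1.20, -1.20, -1.20, -1.20, -0.50, -0.50), # p1 = UG
    nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  stopifnot(all(stack < 0), init > 0, loop_open > 0, loop_per_nt > 0,
            max_loop >= 1)
  structure(list(pairs = pairs, stack = stack, init = init,
                 loop_open = loop_open, loop_per_nt = loop_per_nt,
                 max_loop = as.integer(max_loop)),
            class = "tsrna_energy")
}

# pair index (into params$pairs) of small-RNA base a against target base b,
# DNA alphabet in, RNA pairing rules (A-U, G-C, G-U); 0 when unpairable
pair_index <- function(a, b) {
  key <- paste0(a, b)
  idx <- c(AT = 1L, TA = 2L, CG = 3L, GC = 4L, GT = 5L, TG = 6L)[key]
  ifelse(is.na(idx), 0L, idx)
}

#' Minimum free energy of an intermolecular duplex
#'
#' Computes the minimum free energy over all antiparallel intermolecular
#' duplexes of a small RNA against a target window, allowing Watson-Crick
#' and G-U pairs, bulges and internal loops with affine size penalties, no
#' intramolecular pairs and no pseudoknots. The duplex initiation penalty
#' is applied once. Dynamic programming over prefix pairs; loop sizes are
#' bounded by `params$max_loop` per strand.
#'
#' @param tsrna_seq Small-RNA sequence (5'->3', `A/C/G/T`, length <= 60).
#' @param utr_window Target subsequence (5'->3', length <= 60).
#' @param params An [energy_parameters()] object.
#' @return A list of class `tsrna_duplex` with `mfe` (kcal/mol, 0 when no
#'   duplex reaches a negative energy), `pairs` (tibble of `ts_pos`,
#'   `utr_pos`), and `duplex` (text rendering). Re-scoring `pairs` with
#'   [score_duplex()] reproduces `mfe`.
#' @export
hybrid_mfe <- function(tsrna_seq, utr_window, params = energy_parameters()) {
  stopifnot(inherits(params, "tsrna_energy"))
  if (nchar(tsrna_seq) > 60 || nchar(utr_window) > 60) {
    abort("sequences longer than 60 nt: re-window around the seed site")
  }
  ts <- strsplit(normalize_dna(tsrna_seq, "tsrna_seq"), "")[[1]]
  ut <- strsplit(normalize_dna(utr_window, "utr_window"), "")[[1]]
  n <- length(ts); m <- length(ut)
  pidx <- outer(ts, ut, pair_index)          # n x m pair-type indices
  g <- params$max_loop

  h <- matrix(Inf, n, m)                     # best energy ending at pair (i, j)
  from_i <- matrix(0L, n, m); from_j <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    for (j in rev(seq_len(m))) {
      if (pidx[i, j] == 0L) next
      best <- params$init; bi <- 0L; bj <- 0L
      i0 <- max(1L, i - g - 1L); j1 <- min(m, j + g + 1L)
      if (i > 1L && j < m) {
        ii <- i0:(i - 1L); jj <- (j + 1L):j1
        sub <- h[ii, jj, drop = FALSE]
        gap1 <- i - ii - 1L; gap2 <- jj - j - 1L
        pen <- outer(gap1, gap2, function(a, b)
          params$loop_open + params$loop_per_nt * (a + b))
        # the adjacent predecessor is a helix stack, not a loop
        if (pidx[i - 1L, j + 1L] != 0L) {
          pen[length(ii), 1L] <- params$stack[pidx[i - 1L, j + 1L], pidx[i, j]]
        }
        cand <- sub + pen
        k <- which.min(cand)
        if (length(k) && cand[k] < best) {
          best <- cand[k]
          bi <- ii[(k - 1L) %% length(ii) + 1L]
          bj <- jj[(k - 1L) %/% length(ii) + 1L]
        }
      }
      h[i, j] <- best; from_i[i, j] <- bi; from_j[i, j] <- bj
    }
  }

  if (!any(is.finite(h)) || min(h) >= 0) {
    return(structure(list(mfe = 0, pairs = tibble(ts_pos = integer(),
                                                  utr_pos = integer()),
                          duplex = ""),
                     class = "tsrna_duplex"))
  }
  end <- arrayInd(which.min(h), dim(h))
  i <- end[1]; j <- end[2]
  ts_pos <- integer(0); utr_pos <- integer(0)
  while (i != 0L) {
    ts_pos <- c(i, ts_pos); utr_pos <- c(j, utr_pos)
    ii <- from_i[i, j]; j <- from_j[i, j]; i <- ii
  }
  pairs <- tibble(ts_pos = ts_pos, utr_pos = utr_pos)
  structure(list(mfe = min(h), pairs = pairs,
                 duplex = render_duplex(ts, ut, pairs)),
            class = "tsrna_duplex")
}

#' Re-score a duplex traceback under an energy parameter set
#'
#' Evaluates the energy of an explicit list of pairs exactly as the dynamic
#' programme does: initiation once, stack terms for adjacent pairs, affine
#' loop penalties otherwise.
#'
#' @param pairs A tibble with `ts_pos` (increasing) and `utr_pos`
#'   (decreasing) columns.
#' @param tsrna_seq,utr_window The two sequences.
#' @param params An [energy_parameters()] object.
#' @return The duplex energy in kcal/mol (`0` for an empty pair list).
#' @export
score_duplex <- function(pairs, tsrna_seq, utr_window,
                         params = energy_parameters()) {
  if (nrow(pairs) == 0) return(0)
  ts <- strsplit(normalize_dna(tsrna_seq, "tsrna_seq"), "")[[1]]
  ut <- strsplit(normalize_dna(utr_window, "utr_window"), "")[[1]]
  idx <- pair_index(ts[pairs$ts_pos], ut[pairs$utr_pos])
  if (any(idx == 0L)) abort("pair list contains an unpairable base pair")
  e <- params$init
  if (nrow(pairs) > 1) {
    for (t in seq_len(nrow(pairs) - 1)) {
      g1 <- pairs$ts_pos[t + 1] - pairs$ts_pos[t] - 1L
      g2 <- pairs$utr_pos[t] - pairs$utr_pos[t + 1] - 1L
      if (g1 < 0 || g2 < 0) abort("pairs must advance along both strands")
      e <- e + if (g1 == 0 && g2 == 0) {
        params$stack[idx[t], idx[t + 1]]
      } else {
        params$loop_open + params$loop_per_nt * (g1 + g2)
      }
    }
  }
  e
}

render_duplex <- function(ts, ut, pairs) {
  marks_ts <- rep(" ", length(ts)); marks_ts[pairs$ts_pos] <- "|"
  lab <- sprintf("tsRNA 5'-%s-3'", paste(ts, collapse = ""))
  bonds <- sprintf("         %s", paste(marks_ts, collapse = ""))
  aligned_ut <- rep(".", length(ts))
  aligned_ut[pairs$ts_pos] <- ut[pairs$utr_pos]
  target <- sprintf("target 3'-%s-5' (paired positions shown)",
                    paste(aligned_ut, collapse = ""))
  paste(lab, bonds, target, sep = "\n")
}

#' @export
print.tsrna_duplex <- function(x, ...) {
  cat(sprintf("<tsrna_duplex> mfe = %.2f kcal/mol, %d pairs\n%s\n",
              x$mfe, nrow(x$pairs), x$duplex))
  invisible(x)
}
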