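#' Counts-per-million normalisation
#'
#' `CPM[i, j] = counts[i, j] / colsum(j) * 1e6`; every column of the result
#' sums to one million.
#'
#' @param counts Wide counts tibble (`tsrna_id` + one column per sample).
#' @return A tibble of the same shape holding CPM values.
#' @export
cpm_normalize <- function(counts) {
  m <- counts_matrix(counts)
  depth <- colSums(m)
  if (any(depth <= 0)) {
    abort(sprintf("zero-depth sample(s): %s",
                  paste(colnames(m)[depth <= 0], collapse = ", ")))
  }
  cpm <- sweep(m, 2, depth, "/") * 1e6
  bind_cols(tibble(tsrna_id = counts$tsrna_id), as_tibble(cpm))
}

#' Group-wise expressed sets (Venn partition)
#'
#' A tsRNA is expressed in a group when its total count across that group's
#' samples reaches `min_group_count`. With two groups the detected catalog
#' partitions into group-specific and shared sets.
#'
#' @param counts Wide counts tibble.
#' @param samples Sample sheet with `sample_id`, `group`.
#' @param min_group_count Detection threshold (default 1 read).
#' @return A list with the per-group id sets (named `<group>_only`),
#'   `shared`, and a `venn` tibble of counts.
#' @export
expressed_sets <- function(counts, samples, min_group_count = 1L) {
  m <- counts_matrix(counts)
  groups <- split(samples$sample_id, samples$group)
  if (length(groups) < 2) abort("need at least two groups")
  detected <- vapply(groups, function(sids) {
    rowSums(m[, sids, drop = FALSE]) >= min_group_count
  }, logical(nrow(m)))
  anywhere <- rowSums(detected) > 0
  only <- lapply(seq_along(groups), function(g) {
    rownames(m)[detected[, g] & rowSums(detected[, -g, drop = FALSE]) == 0]
  })
  names(only) <- paste0(names(groups), "_only")
  shared <- rownames(m)[rowSums(detected) == length(groups)]
  venn <- tibble(set = c(names(only), "shared", "detected_total"),
                 n = c(lengths(only), length(shared), sum(anywhere)))
  c(only, list(shared = shared, venn = venn))
}

#' Share of expression carried by the top-k tsRNAs
#'
#' Sum of the `k` largest group-mean CPM values over the total group-mean
#' CPM for one group.
#'
#' @param counts Wide counts tibble.
#' @param samples Sample sheet with `sample_id`, `group`.
#' @param k Number of top tsRNAs.
#' @param group Group label to evaluate.
#' @return A single fraction in `[0, 1]`.
#' @export
top_share <- function(counts, samples, k = 10L, group) {
  sids <- samples$sample_id[samples$group == group]
  if (length(sids) == 0) abort(sprintf("no samples in group '%s'", group))
  cpm <- counts_matrix(cpm_normalize(counts))
  mean_cpm <- rowMeans(cpm[, sids, drop = FALSE])
  if (k > length(mean_cpm)) abort("k exceeds the catalog size")
  sum(sort(mean_cpm, decreasing = TRUE)[seq_len(k)]) / sum(mean_cpm)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `fdr_i = min over j with p_(j) >= p_(i) of p_(j) * m / j`, clipped at 1,
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(p_values[ord] * m / seq(m, 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Differential expression between two groups
#'
#' Per tsRNA: Welch two-sample t-test on `log2(CPM + pseudocount)` between
#' the two groups, two-sided p, Benjamini-Hochberg FDR across all tested
#' tsRNAs. `log2FC` is the log2 ratio of group-mean CPM (`case` over
#' `control`, pseudocount applied); a tsRNA is `up` when `fdr < alpha` and
#' `log2FC >= log2(fc)`, `down` when `fdr < alpha` and
#' `log2FC <= -log2(fc)`, otherwise `ns`. Rows with zero counts in every
#' sample are excluded from testing.
#'
#' @param counts Wide counts tibble.
#' @param samples Sample sheet with `sample_id`, `group` (exactly two
#'   groups, each with at least two samples).
#' @param case,control Group labels defining the fold-change direction;
#'   default: alphabetically later group over earlier (`log2FC > 0` means
#'   higher in `case`).
#' @param pseudocount Added to CPM before logging (default 1).
#' @param fc Fold-change threshold (default 2; boundary inclusive).
#' @param alpha FDR threshold (default 0.05).
#' @return A tibble of class `tsrna_de` with columns `tsrna_id`,
#'   `mean_cpm_<control>`, `mean_cpm_<case>`, `log2fc`, `p_value`, `fdr`,
#'   `status`.
#' @export
differential_expression <- function(counts, samples, case = NULL,
                                    control = NULL, pseudocount = 1,
                                    fc = 2, alpha = 0.05) {
  groups <- unique(samples$group)
  if (length(groups) != 2) abort("differential expression needs exactly two groups")
  case <- case %||% sort(groups)[2]
  control <- control %||% setdiff(groups, case)
  stopifnot(case %in% groups, control %in% groups, case != control)
  sids_case <- samples$sample_id[samples$group == case]
  sids_ctrl <- samples$sample_id[samples$group == control]
  if (length(sids_case) < 2 || length(sids_ctrl) < 2) {
    abort("each group needs at least two samples")
  }

  cpm <- counts_matrix(cpm_normalize(counts))
  tested <- rowSums(counts_matrix(counts)) > 0
  cpm <- cpm[tested, , drop = FALSE]

  x <- log2(cpm[, sids_case, drop = FALSE] + pseudocount)
  y <- log2(cpm[, sids_ctrl, drop = FALSE] + pseudocount)
  welch <- welch_t_rows(x, y)

  mean_case <- rowMeans(cpm[, sids_case, drop = FALSE])
  mean_ctrl <- rowMeans(cpm[, sids_ctrl, drop = FALSE])
  log2fc <- log2(mean_case + pseudocount) - log2(mean_ctrl + pseudocount)
  fdr <- benjamini_hochberg(welch$p)
  lfc_cut <- log2(fc)
  status <- ifelse(fdr < alpha & log2fc >= lfc_cut, "up",
                   ifelse(fdr < alpha & log2fc <= -lfc_cut, "down", "ns"))

  out <- tibble(tsrna_id = rownames(cpm),
                "mean_cpm_{control}" := unname(mean_ctrl),
                "mean_cpm_{case}" := unname(mean_case),
                log2fc = unname(log2fc), p_value = unname(welch$p),
                fdr = unname(fdr), status = unname(status)) |>
    arrange(.data$fdr, .data$p_value)
  structure(out, class = c("tsrna_de", class(out)),
            case = case, control = control, fc = fc, alpha = alpha,
            pseudocount = pseudocount)
}

# vectorised Welch t-test over matrix rows; degenerate rows (both groups
# zero-variance) get p = 1 when the means agree and p = 0 otherwise
welch_t_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  tstat[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 0, Inf)
  list(t = tstat, df = df, p = p)
}

#' @importFrom rlang :=
NULL

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
#' @method tidy tsrna_de
tidy.tsrna_de <- function(x, ...) {
  as_tibble(x)
}

#' @export
#' @method glance tsrna_de
glance.tsrna_de <- function(x, ...) {
  tibble(n_tested = nrow(x),
         n_de = sum(x$status != "ns"),
         n_up = sum(x$status == "up"),
         n_down = sum(x$status == "down"),
         case = attr(x, "case"), control = attr(x, "control"),
         fc = attr(x, "fc"), alpha = attr(x, "alpha"))
}
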