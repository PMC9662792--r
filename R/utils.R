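#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols desc across n pull relocate distinct rename
#' @importFrom stats rmultinom rnorm setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

# vectorised reverse complement over the DNA alphabet
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# U -> T, uppercase; reject anything outside the nucleotide alphabet
normalize_dna <- function(x, what = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGTU characters (first offender: %s)",
                  what, x[which(bad)[1]]))
  }
  x
}

random_dna <- function(n_chars) {
  paste(sample(DNA_BASES, n_chars, replace = TRUE), collapse = "")
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  as.integer(x)
}

# integer sub-seeds derived from one master seed, kept below 2^31
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# sample() guards: never trigger the 1:n expansion on length-1 input
sample_one <- function(x) x[sample.int(length(x), 1L)]
sample_n_of <- function(x, n) x[sample.int(length(x), n)]
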