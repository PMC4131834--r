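#' Reverse-complement sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Assembly N50
#'
#' Minimum length L such that sequences of length >= L contain at least half
#' of the total assembly length.
#'
#' @param lengths integer vector of sequence lengths.
#' @return N50 in bp (0 for an empty set).
#' @export
n50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (!length(lengths) || sum(lengths) == 0) return(0)
  cum <- cumsum(lengths)
  lengths[which(cum >= sum(lengths) / 2)[1]]
}

#' Assembly summary statistics
#'
#' @param lengths integer vector of contig lengths.
#' @return one-row data.frame: n, n50, max_len, mean_len, total_len.
#' @export
assembly_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  data.frame(
    n = length(lengths),
    n50 = n50(lengths),
    max_len = if (length(lengths)) max(lengths) else 0,
    mean_len = if (length(lengths)) round(sum(lengths) / length(lengths)) else 0,
    total_len = sum(lengths)
  )
}

# random DNA string of length n (uses the current RNG state)
random_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# substitute a base with a different one, uniformly
other_base <- function(base) {
  bases <- c("A", "C", "G", "T")
  vapply(base, function(b) sample(setdiff(bases, b), 1L), character(1),
         USE.NAMES = FALSE)
}

# total length of the union of half-open intervals
interval_union_len <- function(starts, ends) {
  if (!length(starts)) return(0)
  if (requireNamespace("IRanges", quietly = TRUE)) {
    r <- IRanges::reduce(IRanges::IRanges(start = starts + 1, end = ends))
    return(sum(IRanges::width(r)))
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > ce) { tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i] }
    else ce <- max(ce, ends[i])
  }
  tot + (ce - cs)
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stop(sprintf("%s must be a scalar in [%s, %s]", name, lo, hi), call. = FALSE)
  invisible(x)
}

# empty data.frame with given column names/prototypes
empty_df <- function(proto) proto[0, , drop = FALSE]
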