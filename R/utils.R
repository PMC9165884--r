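#' @importFrom stats runif rnorm setNames
#' @importFrom utils head tail write.table read.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-stage child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483629
}

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that preserves `N`
#' and accepts plain character input.
#'
#' @param x single character string of DNA.
#' @return reverse-complemented character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 0-based half-open interval helpers ---------------------------------------

check_interval <- function(start, end) {
  if (!(start < end)) stop("invalid interval: start must be < end (0-based half-open)")
  invisible(TRUE)
}

check_strand <- function(strand) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  invisible(TRUE)
}

# Extract [start, end) (0-based) from a DNAStringSet genome, N-padding beyond
# the chromosome ends.
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  chrom_len <- length(genome[[chrom]])
  left_pad <- max(0L, -start)
  right_pad <- max(0L, end - chrom_len)
  s <- max(0L, start)
  e <- min(chrom_len, end)
  core <- if (s < e) as.character(Biostrings::subseq(genome[[chrom]], s + 1L, e)) else ""
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}
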