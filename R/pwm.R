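# Generic sliding-window splice-site scorer: any window-based site scorer
# (here a log-odds PWM built from collapsed annotations; externally computed
# score tables can be dropped in through the same interface) applied at every
# placement covering a variant, reporting the maximum absolute ref-vs-alt
# score difference. This mirrors the classic fixed-width site scorers (9-base
# donor / 23-base acceptor windows) but detects cryptic sites anywhere.

#' Construct a sliding-window site scorer
#'
#' @param site_class `"acceptor"` or `"donor"`.
#' @param width window width in bases.
#' @param offset_of_site 1-based index of the splice-site base within the
#'   window.
#' @param score function mapping a window-length DNA string to a numeric
#'   score.
#' @param meta optional list stored alongside (e.g. the PWM).
#' @return object of class `site_scorer`.
#' @export
site_scorer <- function(site_class = c("acceptor", "donor"), width,
                        offset_of_site, score, meta = NULL) {
  site_class <- match.arg(site_class)
  width <- as.integer(width)
  offset_of_site <- as.integer(offset_of_site)
  stopifnot(width > 0L, offset_of_site >= 1L, offset_of_site <= width,
            is.function(score))
  structure(list(site_class = site_class, width = width,
                 offset_of_site = offset_of_site, score = score, meta = meta),
            class = "site_scorer")
}

#' Build a log-odds PWM scorer from collapsed splice sites
#'
#' Collects the `width`-base windows around every annotated site of
#' `site_class` (in transcription orientation), builds a position frequency
#' matrix with a pseudocount, and scores windows additively by
#' `log2(p_position / p_background)`. Background base frequencies are taken
#' from the genome unless supplied.
#'
#' @param genes `collapsed_annotation`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param site_class `"acceptor"` or `"donor"`.
#' @param width window width (conventionally 23 for acceptors, 9 for donors).
#' @param offset_of_site 1-based index of the site base within the window.
#' @param pseudocount added to every cell of the frequency matrix (> 0).
#' @param background optional length-4 base probabilities (A,C,G,T).
#' @return a `site_scorer` whose `meta$pwm` is the 4 x width log-odds matrix.
#' @export
build_pwm_scorer <- function(genes, genome, site_class = c("acceptor", "donor"),
                             width = NULL, offset_of_site = NULL,
                             pseudocount = 0.1, background = NULL) {
  site_class <- match.arg(site_class)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (is.null(width)) width <- if (site_class == "acceptor") 23L else 9L
  if (is.null(offset_of_site)) {
    offset_of_site <- if (site_class == "acceptor") 21L else 3L
  }
  windows <- character(0)
  for (g in genes) {
    sites <- if (site_class == "acceptor") g$acceptors else g$donors
    for (s in sites) {
      if (g$strand == "+") {
        w <- genome_subseq(genome, g$chrom, s - (offset_of_site - 1L),
                           s + (width - offset_of_site) + 1L)
      } else {
        w <- revcomp(genome_subseq(genome, g$chrom,
                                   s - (width - offset_of_site),
                                   s + offset_of_site))
      }
      windows <- c(windows, w)
    }
  }
  if (length(windows) == 0L) stop("no sites of class ", site_class)
  counts <- matrix(pseudocount, nrow = 4L, ncol = width,
                   dimnames = list(DNA_ORDER, NULL))
  for (w in windows) {
    chars <- strsplit(w, "", fixed = TRUE)[[1L]]
    idx <- match(chars, DNA_ORDER)
    ok <- !is.na(idx)
    counts[cbind(idx[ok], which(ok))] <- counts[cbind(idx[ok], which(ok))] + 1
  }
  probs <- sweep(counts, 2L, colSums(counts), `/`)
  if (is.null(background)) {
    freq <- Biostrings::alphabetFrequency(genome, baseOnly = TRUE)
    tot <- colSums(freq[, DNA_ORDER, drop = FALSE])
    background <- tot / sum(tot)
  }
  pwm <- log2(sweep(probs, 1L, background, `/`))
  score_fun <- function(window) {
    chars <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
    if (length(chars) != width) stop("window of width ", length(chars),
                                     " given to scorer of width ", width)
    idx <- match(chars, DNA_ORDER)
    ok <- !is.na(idx)
    sum(pwm[cbind(idx[ok], which(ok))])   # N contributes 0
  }
  site_scorer(site_class, width, offset_of_site, score_fun,
              meta = list(pwm = pwm, background = background,
                          n_sites = length(windows)))
}

#' Write / read a PWM as TSV
#'
#' @param scorer a `site_scorer` from [build_pwm_scorer()].
#' @param path TSV path (4 rows A,C,G,T; one column per window position).
#' @export
write_pwm <- function(scorer, path) {
  stopifnot(!is.null(scorer$meta$pwm))
  df <- as.data.frame(scorer$meta$pwm)
  names(df) <- paste0("p", seq_len(ncol(df)))
  df <- cbind(base = DNA_ORDER,
              site_class = scorer$site_class,
              offset_of_site = scorer$offset_of_site, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  pwm <- as.matrix(df[, grep("^p[0-9]+$", names(df)), drop = FALSE])
  rownames(pwm) <- df$base
  width <- ncol(pwm)
  offset <- df$offset_of_site[1L]
  score_fun <- function(window) {
    chars <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
    if (length(chars) != width) stop("window width mismatch")
    idx <- match(chars, DNA_ORDER)
    ok <- !is.na(idx)
    sum(pwm[cbind(idx[ok], which(ok))])
  }
  site_scorer(df$site_class[1L], width, offset, score_fun,
              meta = list(pwm = pwm))
}

#' Maximum sliding-window score change of a variant
#'
#' Slides the scorer window over every placement touching the edited region
#' (for an SNV: exactly `width` placements) on both the reference and the
#' alternative sequence, pairing placements by their left coordinate
#' relative to the variant, and returns the maximum absolute score
#' difference. When the gene strand is unknown both strands are evaluated
#' and the larger delta returned.
#'
#' @inheritParams normalize_variant
#' @param scorer a `site_scorer`.
#' @param strand `"+"`, `"-"`, or `"both"` (default).
#' @return list with `delta` (max |ref - alt|), `offset` (left offset,
#'   relative to the variant position, of the maximising placement) and
#'   `strand` of that placement.
#' @export
sliding_delta <- function(genome, chrom, pos, ref, alt, scorer,
                          strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  w <- scorer$width
  pos0 <- pos - 1L
  lr <- nchar(ref); la <- nchar(alt)
  flank <- w - 1L
  left <- genome_subseq(genome, chrom, pos0 - flank, pos0)
  right <- genome_subseq(genome, chrom, pos0 + lr, pos0 + lr + flank)
  ref_seq <- paste0(left, toupper(ref), right)
  alt_seq <- paste0(left, toupper(alt), right)
  offsets <- seq.int(-(w - 1L), max(lr, la) - 1L)  # union of placements touching either allele
  best <- list(delta = 0, offset = offsets[1L], strand = "+")
  strands <- if (strand == "both") c("+", "-") else strand
  for (st in strands) {
    for (k in offsets) {
      # window left coordinate pos0 + k; each sequence has `flank` bases
      # before its allele block, so the window starts at string index
      # flank + k + 1; minus-strand placements score the reverse complement
      i <- flank + k + 1L
      if (i < 1L || i + w - 1L > nchar(ref_seq) || i + w - 1L > nchar(alt_seq)) next
      wr <- substr(ref_seq, i, i + w - 1L)
      wa <- substr(alt_seq, i, i + w - 1L)
      if (st == "-") {
        wr <- revcomp(wr)
        wa <- revcomp(wa)
      }
      dlt <- abs(scorer$score(wr) - scorer$score(wa))
      if (dlt > best$delta) best <- list(delta = dlt, offset = k, strand = st)
    }
  }
  best
}
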