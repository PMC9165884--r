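#' Encoder configuration
#'
#' Geometry of training windows: each window predicts `predict_len` bases
#' given `context_len` bases of flanking context split evenly between the two
#' sides (so window inputs are `predict_len + context_len` bases). The
#' defaults (5,000 predicted given 10,000 of context, i.e. 15,000-base
#' windows) are the full-scale setting; desk-scale work uses smaller values.
#'
#' @param predict_len bases predicted per window.
#' @param context_len total flanking context; must be even.
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(predict_len = 5000L, context_len = 10000L) {
  predict_len <- as.integer(predict_len)
  context_len <- as.integer(context_len)
  stopifnot(predict_len > 0L, context_len > 0L, context_len %% 2L == 0L)
  structure(list(predict_len = predict_len, context_len = context_len),
            class = "encoder_config")
}

DNA_ORDER <- c("A", "C", "G", "T")
LABEL_ORDER <- c("neither", "acceptor", "donor")

#' One-hot encode a DNA string
#'
#' Rows in order A, C, G, T; any other letter (`N`; lowercase is uppercased
#' first) becomes an all-zero row.
#'
#' @param seq single character string.
#' @return numeric matrix `nchar(seq)` x 4.
#' @export
one_hot <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_ORDER)
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, DNA_ORDER))
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Decode a one-hot DNA matrix back to a string
#'
#' All-zero rows decode to `N`.
#' @param m matrix from [one_hot()].
#' @return character string.
#' @export
decode_one_hot <- function(m) {
  hit <- max.col(m, ties.method = "first")
  chars <- DNA_ORDER[hit]
  chars[rowSums(m) == 0] <- "N"
  paste(chars, collapse = "")
}

#' One-hot encode per-position splice labels
#'
#' Classes in fixed order neither, acceptor, donor; every row sums to one.
#'
#' @param classes character vector over `"neither"`, `"acceptor"`, `"donor"`.
#' @return numeric matrix `length(classes)` x 3.
#' @export
one_hot_labels <- function(classes) {
  idx <- match(classes, LABEL_ORDER)
  if (anyNA(idx)) stop("unknown label class: ", classes[is.na(idx)][1L])
  m <- matrix(0, nrow = length(classes), ncol = 3L,
              dimnames = list(NULL, LABEL_ORDER))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Extract the (flanked) sequence of a collapsed gene
#'
#' Returns the genomic sequence of the gene span enlarged by `flank` bases on
#' both sides, clipped at chromosome ends with `N` padding so the result
#' always has length `span + 2*flank`. Minus-strand genes are
#' reverse-complemented so the sequence (and the accompanying coordinate map)
#' runs in transcription direction.
#'
#' @param genome a named [Biostrings::DNAStringSet] keyed by chromosome.
#' @param gene a `collapsed_gene`.
#' @param flank bases added on each side (default 5,000).
#' @return list with `sequence` (character), `coords` (integer vector of
#'   0-based genomic positions, one per sequence base; `NA` for pad), and
#'   `offset0` (index, 1-based, of the first span base in `sequence`).
#' @export
extract_gene_sequence <- function(genome, gene, flank = 5000L) {
  flank <- as.integer(flank)
  start <- gene$span[1] - flank
  end <- gene$span[2] + flank
  seq <- genome_subseq(genome, gene$chrom, start, end)
  coords <- seq.int(start, end - 1L)
  chrom_len <- length(genome[[gene$chrom]])
  coords[coords < 0L | coords >= chrom_len] <- NA_integer_
  if (gene$strand == "-") {
    seq <- revcomp(seq)
    coords <- rev(coords)
  }
  list(sequence = seq, coords = coords, offset0 = flank + 1L)
}

#' Per-position label track of a collapsed gene
#'
#' One class per span position, in transcription orientation (matching
#' [extract_gene_sequence()] without the flanks): `acceptor` at acceptor
#' positions, `donor` at donor positions, `neither` elsewhere. A position
#' recorded as both acceptor and donor across isoforms is labelled
#' `acceptor` (deterministic priority, warned about), since one-hot labels
#' admit a single class.
#'
#' @param gene a `collapsed_gene`.
#' @return character vector of length `span_end - span_start` over the label
#'   classes.
#' @export
label_track <- function(gene) {
  len <- gene$span[2] - gene$span[1]
  labels <- rep("neither", len)
  acc_idx <- gene$acceptors - gene$span[1] + 1L
  don_idx <- gene$donors - gene$span[1] + 1L
  if (any(acc_idx < 1L | acc_idx > len) || any(don_idx < 1L | don_idx > len)) {
    stop("gene ", gene$gene_id, ": splice site outside span")
  }
  both <- intersect(acc_idx, don_idx)
  if (length(both) > 0L) {
    warning("gene ", gene$gene_id, ": ", length(both),
            " position(s) annotated as both acceptor and donor; labelled acceptor")
  }
  labels[don_idx] <- "donor"
  labels[acc_idx] <- "acceptor"
  if (gene$strand == "-") labels <- rev(labels)
  labels
}

#' Slice a gene into fixed-size encoded windows
#'
#' Windows tile the gene span: window `i` predicts span bases
#' `[i*predict_len, (i+1)*predict_len)` (transcription orientation) given
#' `context_len/2` bases of flanking sequence on each side drawn from the
#' neighbouring span or the flank. Sequence beyond the available bases is
#' `N` (all-zero rows); label rows beyond the span are class `neither`.
#'
#' @param seq flanked gene sequence from [extract_gene_sequence()]; its flank
#'   must be at least `cfg$context_len / 2`.
#' @param labels label track from [label_track()].
#' @param cfg an [encoder_config()].
#' @param flank the flank width `seq` was extracted with.
#' @param gene_id id stored on each window.
#' @return list of `encoded_window` objects: lists with `gene_id`,
#'   `window_index`, `sequence` ((predict_len+context_len) x 4 one-hot),
#'   `labels` (predict_len x 3 one-hot), and `n_real` (unpadded label rows).
#' @export
slice_windows <- function(seq, labels, cfg, flank = 5000L, gene_id = NA_character_) {
  stopifnot(inherits(cfg, "encoder_config"))
  half <- cfg$context_len %/% 2L
  if (flank < half) stop("flank (", flank, ") smaller than context/2 (", half, ")")
  span_len <- length(labels)
  stopifnot(nchar(seq) == span_len + 2L * flank)
  n_win <- max(1L, as.integer(ceiling(span_len / cfg$predict_len)))
  lapply(seq_len(n_win), function(i) {
    p0 <- (i - 1L) * cfg$predict_len          # 0-based span offset of first predicted base
    # input covers span offsets [p0 - half, p0 + predict_len + half)
    s0 <- p0 - half + flank                    # 0-based offset into `seq`
    want <- cfg$predict_len + cfg$context_len
    avail_end <- min(s0 + want, nchar(seq))
    sub <- substr(seq, s0 + 1L, avail_end)
    if (nchar(sub) < want) sub <- paste0(sub, strrep("N", want - nchar(sub)))
    lab_idx <- (p0 + 1L):(p0 + cfg$predict_len)
    lab <- rep("neither", cfg$predict_len)
    real <- lab_idx <= span_len
    lab[real] <- labels[lab_idx[real]]
    structure(
      list(
        gene_id = gene_id,
        window_index = i,
        sequence = one_hot(sub),
        labels = one_hot_labels(lab),
        n_real = sum(real)
      ),
      class = "encoded_window"
    )
  })
}

#' Encode a set of collapsed genes into training windows
#'
#' @param genes `collapsed_annotation` or list of `collapsed_gene`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param cfg an [encoder_config()].
#' @return list (one element per gene) of lists of `encoded_window`.
#' @export
encode_genes <- function(genes, genome, cfg = encoder_config()) {
  flank <- cfg$context_len %/% 2L
  out <- lapply(genes, function(g) {
    ext <- extract_gene_sequence(genome, g, flank = flank)
    slice_windows(ext$sequence, label_track(g), cfg, flank = flank,
                  gene_id = g$gene_id)
  })
  names(out) <- vapply(genes, `[[`, character(1), "gene_id")
  out
}

#' Aggregate encoded genes into training chunks
#'
#' Splits a gene list into consecutive chunks of `chunk_size`, merging the
#' last two chunks when the remainder is non-zero so no chunk is smaller than
#' `chunk_size` (unless fewer than `chunk_size` genes exist in total, which
#' yields a single short chunk).
#'
#' @param genes a list (any element type; typically encoded genes).
#' @param chunk_size target genes per chunk (default 100).
#' @return list of chunks (each a list of elements of `genes`).
#' @export
chunk_genes <- function(genes, chunk_size = 100L) {
  n <- length(genes)
  if (n == 0L) return(list())
  if (n < chunk_size) return(list(genes))
  n_chunks <- n %/% chunk_size
  sizes <- rep(chunk_size, n_chunks)
  rem <- n - n_chunks * chunk_size
  if (rem > 0L) sizes[n_chunks] <- sizes[n_chunks] + rem
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(sizes), function(i) genes[starts[i]:ends[i]])
}
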