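# VCF delta-score annotation: predict acceptor/donor probability tracks on
# reference and alternative sequence around a variant, align the alternative
# track back onto reference coordinates (zero-fill for deletions, max-collapse
# for insertions), and report the four per-class delta scores and positions.

#' Normalise a variant to its minimal left-aligned representation
#'
#' Trims the shared suffix then the shared prefix of ref/alt (always keeping
#' at least one base of each), and left-aligns pure indels through repeat
#' tracts against the genome.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param chrom,pos,ref,alt VCF-style variant (`pos` 1-based; `ref`/`alt`
#'   uppercase ACGT).
#' @return list with normalised `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(genome, chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt)) stop("empty allele")
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
    stop("non-ACGT allele: ", ref, ">", alt)
  }
  # trim shared suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim shared prefix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  # left-align pure indels (anchor base + inserted/deleted tail): whenever
  # both alleles end in the same base the representation can be re-anchored
  # one base to the left (drop the shared tail, prepend the preceding base);
  # iterating walks indels to the left end of a repeat tract
  is_indel <- (nchar(ref) == 1L && nchar(alt) > 1L && substr(alt, 1L, 1L) == ref) ||
    (nchar(alt) == 1L && nchar(ref) > 1L && substr(ref, 1L, 1L) == alt)
  if (is_indel) {
    while (pos > 1L &&
           substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
      prev <- genome_subseq(genome, chrom, pos - 2L, pos - 1L)
      ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
    }
  }
  list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

#' Build reference and alternative prediction windows around a variant
#'
#' The reference window covers the variant's ref allele plus
#' `max_distance + context` bases on each side (`N`-padded beyond chromosome
#' ends); the alternative window is the same sequence with the ref allele
#' replaced by the alt allele. For minus-strand genes both windows are
#' reverse-complemented so prediction runs in transcription direction;
#' coordinate mapping back to the genome is handled downstream.
#'
#' @inheritParams normalize_variant
#' @param gene `collapsed_gene` supplying the strand.
#' @param max_distance maximum distance from the variant scored (default
#'   5,000).
#' @param context per-side flanking context for the predictor (default
#'   5,000, i.e. half the full-scale 10,000-nt context).
#' @param check_ref verify the ref allele against the genome (default TRUE).
#' @return list with `ref_seq`, `alt_seq`, `origin` (0-based genomic
#'   position of the first ref-track base), and `strand`.
#' @export
build_ref_alt_windows <- function(genome, chrom, pos, ref, alt, gene,
                                  max_distance = 5000L, context = 5000L,
                                  check_ref = TRUE) {
  pos0 <- pos - 1L
  lr <- nchar(ref)
  flank <- max_distance + context
  left <- genome_subseq(genome, chrom, pos0 - flank, pos0)
  ref_obs <- genome_subseq(genome, chrom, pos0, pos0 + lr)
  right <- genome_subseq(genome, chrom, pos0 + lr, pos0 + lr + flank)
  if (check_ref && !identical(ref_obs, toupper(ref))) {
    stop("ref allele mismatch at ", chrom, ":", pos, " (VCF '", ref,
         "' vs genome '", ref_obs, "')")
  }
  ref_seq <- paste0(left, ref_obs, right)
  alt_seq <- paste0(left, toupper(alt), right)
  if (gene$strand == "-") {
    ref_seq <- revcomp(ref_seq)
    alt_seq <- revcomp(alt_seq)
  }
  list(ref_seq = ref_seq, alt_seq = alt_seq,
       origin = pos0 - max_distance, strand = gene$strand)
}

#' Align an alternative-allele track onto reference coordinates
#'
#' Both tracks are per-position probabilities whose central allele block
#' starts after `max_distance` flank positions. Net deletions are compensated
#' by inserting zeros at the deleted reference positions (immediately after
#' the retained allele prefix); net insertions by collapsing the
#' alternative-allele block onto the final reference-allele base with the
#' elementwise maximum (block-plus-anchor rule). Multi-nucleotide
#' substitutions reduce to the same rules through their net length
#' difference.
#'
#' @param ref_track numeric vector of length `2*max_distance + nchar(ref)`.
#' @param alt_track numeric vector of length `2*max_distance + nchar(alt)`.
#' @param ref,alt allele strings.
#' @param max_distance flank length on each side of the allele block.
#' @return numeric vector with `length(ref_track)`.
#' @export
align_alt_track <- function(ref_track, alt_track, ref, alt, max_distance) {
  lr <- nchar(ref); la <- nchar(alt)
  D <- as.integer(max_distance)
  if (length(ref_track) != 2L * D + lr || length(alt_track) != 2L * D + la) {
    stop("track lengths inconsistent with alleles: ref ", length(ref_track),
         " vs ", 2L * D + lr, ", alt ", length(alt_track), " vs ", 2L * D + la)
  }
  d <- la - lr
  if (d == 0L) return(alt_track)
  left <- alt_track[seq_len(D)]
  right <- alt_track[(D + la + 1L):(2L * D + la)]
  if (d < 0L) {
    block <- c(alt_track[(D + 1L):(D + la)], rep(0, -d))
  } else {
    keep <- if (lr > 1L) alt_track[(D + 1L):(D + lr - 1L)] else numeric(0)
    block <- c(keep, max(alt_track[(D + lr):(D + la)]))
  }
  c(left, block, right)
}

#' Per-class delta scores and positions
#'
#' Over positions within `max_distance` of the variant, the acceptor/donor
#' gain scores are the maximum positive increase of the alternative over the
#' reference track (0-clipped), and the loss scores the maximum positive
#' decrease. Each delta position (DP) is the signed genomic offset from the
#' variant position of the corresponding maximum; ties go to the smallest
#' absolute offset, then negative before positive.
#'
#' @param ref_tracks,alt_tracks lists with `acceptor` and `donor` vectors on
#'   reference coordinates (alt already aligned), length
#'   `2*max_distance + nchar(ref)`.
#' @param ref ref allele string.
#' @param max_distance scoring radius.
#' @return list of class `delta_annotation` with `DS_AG`, `DS_AL`, `DS_DG`,
#'   `DS_DL`, `DP_AG`, `DP_AL`, `DP_DG`, `DP_DL`.
#' @export
delta_scores <- function(ref_tracks, alt_tracks, ref, max_distance) {
  D <- as.integer(max_distance)
  lr <- nchar(ref)
  offsets <- seq.int(-D, D + lr - 1L)   # genomic offset of each track index
  keep <- abs(offsets) <= D
  offsets <- offsets[keep]
  pick <- function(diff) {
    diff <- pmax(diff[keep], 0)
    m <- max(diff)
    at <- which(diff == m)
    at <- at[order(abs(offsets[at]), offsets[at] >= 0)][1L]
    list(ds = m, dp = offsets[at])
  }
  ag <- pick(alt_tracks$acceptor - ref_tracks$acceptor)
  al <- pick(ref_tracks$acceptor - alt_tracks$acceptor)
  dg <- pick(alt_tracks$donor - ref_tracks$donor)
  dl <- pick(ref_tracks$donor - alt_tracks$donor)
  structure(
    list(DS_AG = ag$ds, DS_AL = al$ds, DS_DG = dg$ds, DS_DL = dl$ds,
         DP_AG = ag$dp, DP_AL = al$dp, DP_DG = dg$dp, DP_DL = dl$dp),
    class = "delta_annotation"
  )
}

#' @export
print.delta_annotation <- function(x, ...) {
  cat(sprintf("<delta_annotation> AG %.2f@%d AL %.2f@%d DG %.2f@%d DL %.2f@%d\n",
              x$DS_AG, x$DP_AG, x$DS_AL, x$DP_AL, x$DS_DG, x$DP_DG,
              x$DS_DL, x$DP_DL))
  invisible(x)
}

# Predict acceptor/donor tracks for `seq` (a window whose first
# context/2 and last context/2 bases are context only), mapped back to
# genomic ascending orientation for minus-strand genes.
predict_variant_tracks <- function(predictor, seq, strand) {
  tr <- predict_window(predictor, seq)
  if (strand == "-") {
    tr <- list(acceptor = rev(tr$acceptor), donor = rev(tr$donor))
  }
  tr
}

# Annotate one variant against one gene; returns a delta_annotation or NULL.
delta_for_variant <- function(genome, predictor, chrom, pos, ref, alt, gene,
                              max_distance = 5000L) {
  context <- predictor$context_len %/% 2L
  win <- build_ref_alt_windows(genome, chrom, pos, ref, alt, gene,
                               max_distance = max_distance, context = context)
  ref_tr <- predict_variant_tracks(predictor, win$ref_seq, win$strand)
  alt_tr <- predict_variant_tracks(predictor, win$alt_seq, win$strand)
  alt_aligned <- list(
    acceptor = align_alt_track(ref_tr$acceptor, alt_tr$acceptor, ref, alt, max_distance),
    donor = align_alt_track(ref_tr$donor, alt_tr$donor, ref, alt, max_distance)
  )
  delta_scores(ref_tr, alt_aligned, ref, max_distance)
}

DELTA_INFO_KEY <- "SDELTA"

#' Annotate a VCF with splice delta scores
#'
#' For every variant x overlapping-gene pair (a gene overlaps when the
#' variant lies within its span enlarged by `max_distance`), adds one entry
#' `ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL` (scores to
#' two decimals) to the `SDELTA` INFO field of the output VCF. Multi-allelic
#' records yield one entry per alt allele. Records with symbolic alleles,
#' missing contigs, or no overlapping gene receive no entry and are counted
#' against coverage.
#'
#' @param vcf_in input VCF path (4.x, plain text).
#' @param genome named [Biostrings::DNAStringSet].
#' @param annotation `collapsed_annotation` (or path to its TSV).
#' @param predictor a `splice_predictor`.
#' @param vcf_out output VCF path.
#' @param max_distance scoring radius around each variant (default 5,000).
#' @return invisibly, a list with `n_variants`, `n_annotated`, `coverage`
#'   and `skipped` (data frame of record index + reason).
#' @export
annotate_vcf <- function(vcf_in, genome, annotation, predictor, vcf_out,
                         max_distance = 5000L) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  vcf <- vcfR::read.vcfR(vcf_in, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  gene_chrom <- vapply(annotation, `[[`, character(1), "chrom")
  gene_start <- vapply(annotation, function(g) g$span[1], integer(1))
  gene_end <- vapply(annotation, function(g) g$span[2], integer(1))

  info_out <- character(n)
  skipped <- list()
  n_annotated <- 0L
  for (i in seq_len(n)) {
    chrom <- unname(fix[i, "CHROM"])
    pos <- unname(as.integer(fix[i, "POS"]))
    ref <- unname(fix[i, "REF"])
    alts <- unname(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]])
    entries <- character(0)
    if (!chrom %in% names(genome)) {
      skipped[[length(skipped) + 1L]] <- data.frame(record = i, reason = "missing contig")
    } else {
      pos0 <- pos - 1L
      hit <- which(gene_chrom == chrom &
                     gene_start - max_distance <= pos0 &
                     pos0 < gene_end + max_distance)
      if (length(hit) == 0L) {
        skipped[[length(skipped) + 1L]] <- data.frame(record = i, reason = "no overlapping gene")
      } else {
        for (alt in alts) {
          if (grepl("[^ACGTacgt]", alt) || grepl("[^ACGTacgt]", ref)) {
            warning("record ", i, ": symbolic or non-ACGT allele skipped (", ref, ">", alt, ")")
            next
          }
          nv <- normalize_variant(genome, chrom, pos, ref, alt)
          shift <- nv$pos - pos   # report DP relative to the record position
          for (gi in hit) {
            gene <- annotation[[gi]]
            ds <- delta_for_variant(genome, predictor, nv$chrom, nv$pos,
                                    nv$ref, nv$alt, gene, max_distance)
            for (f in c("DP_AG", "DP_AL", "DP_DG", "DP_DL")) ds[[f]] <- ds[[f]] + shift
            entries <- c(entries, sprintf(
              "%s|%s|%.2f|%.2f|%.2f|%.2f|%d|%d|%d|%d",
              alt, gene$gene_name, ds$DS_AG, ds$DS_AL, ds$DS_DG, ds$DS_DL,
              ds$DP_AG, ds$DP_AL, ds$DP_DG, ds$DP_DL))
          }
        }
        if (length(entries) == 0L) {
          skipped[[length(skipped) + 1L]] <- data.frame(record = i, reason = "no scorable allele")
        }
      }
    }
    if (length(entries) > 0L) n_annotated <- n_annotated + 1L
    info_out[i] <- if (length(entries) > 0L) {
      paste0(DELTA_INFO_KEY, "=", paste(entries, collapse = ","))
    } else ""
  }

  # output: original header plus our INFO definition, then the body
  header <- vcf@meta
  info_line <- paste0(
    '##INFO=<ID=', DELTA_INFO_KEY, ',Number=.,Type=String,Description=',
    '"Splice delta scores: ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL">')
  chrom_line <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  body <- vapply(seq_len(n), function(i) {
    old_info <- fix[i, "INFO"]
    has_old <- !is.na(old_info) && nzchar(old_info) && old_info != "."
    info <- if (nzchar(info_out[i])) {
      if (has_old) paste(old_info, info_out[i], sep = ";") else info_out[i]
    } else if (has_old) old_info else "."
    paste(fix[i, "CHROM"], fix[i, "POS"],
          ifelse(is.na(fix[i, "ID"]), ".", fix[i, "ID"]),
          fix[i, "REF"], fix[i, "ALT"],
          ifelse(is.na(fix[i, "QUAL"]), ".", fix[i, "QUAL"]),
          ifelse(is.na(fix[i, "FILTER"]), ".", fix[i, "FILTER"]),
          info, sep = "\t")
  }, character(1))
  writeLines(c(header, info_line, chrom_line, body), vcf_out)

  skipped <- if (length(skipped) > 0L) do.call(rbind, skipped) else
    data.frame(record = integer(0), reason = character(0))
  invisible(list(n_variants = n, n_annotated = n_annotated,
                 coverage = if (n > 0L) n_annotated / n else NA_real_,
                 skipped = skipped))
}

#' Read delta-score annotations back from an annotated VCF
#'
#' Parses the `SDELTA` INFO entries written by [annotate_vcf()] into one row
#' per variant x gene.
#'
#' @param path annotated VCF path.
#' @return data frame with `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene_name`, the four `DS_*` and four `DP_*` columns, and `max_ds`.
#' @export
read_delta_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    info <- fix[i, "INFO"]
    if (is.na(info)) next
    m <- regmatches(info, regexpr(paste0(DELTA_INFO_KEY, "=[^;]*"), info))
    if (length(m) == 0L) next
    entries <- strsplit(sub(paste0(DELTA_INFO_KEY, "="), "", m), ",", fixed = TRUE)[[1L]]
    for (e in entries) {
      f <- strsplit(e, "|", fixed = TRUE)[[1L]]
      if (length(f) != 10L) stop("malformed ", DELTA_INFO_KEY, " entry: ", e)
      ds <- as.numeric(f[3:6])
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = variant_id(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                                fix[i, "REF"], f[1L]),
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = f[1L], gene_name = f[2L],
        DS_AG = ds[1L], DS_AL = ds[2L], DS_DG = ds[3L], DS_DL = ds[4L],
        DP_AG = as.integer(f[7L]), DP_AL = as.integer(f[8L]),
        DP_DG = as.integer(f[9L]), DP_DL = as.integer(f[10L]),
        max_ds = max(ds), stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(variant_id = character(0)))
  }
  do.call(rbind, rows)
}

#' Per-variant maximum delta scores from an annotated VCF
#'
#' The binary-task score of a variant: the maximum of the four delta scores
#' over all its gene entries.
#'
#' @param annotations data frame from [read_delta_vcf()] (or a VCF path).
#' @return named numeric vector keyed by `variant_id`.
#' @export
variant_scores <- function(annotations) {
  if (is.character(annotations)) annotations <- read_delta_vcf(annotations)
  if (nrow(annotations) == 0L) return(setNames(numeric(0), character(0)))
  tapply_res <- tapply(annotations$max_ds, annotations$variant_id, max)
  setNames(as.numeric(tapply_res), names(tapply_res))
}
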