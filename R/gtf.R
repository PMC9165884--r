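#' Parse a GENCODE-dialect GTF into transcript models
#'
#' Reads `transcript` and `exon` features and assembles one transcript model
#' per transcript, with exon coordinates converted from GTF 1-based inclusive
#' to the package-internal 0-based half-open convention.
#'
#' @param path path to a GTF file whose features carry `gene_id`,
#'   `transcript_id` and (for transcripts) `level` attributes.
#' @return a list of transcript models; each is a list with elements
#'   `transcript_id`, `gene_id`, `gene_name`, `level` (integer or `NA`),
#'   `chrom`, `strand` and `exons` (two-column matrix of 0-based half-open
#'   `start`/`end`, sorted by start).
#' @export
parse_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ", conditionMessage(e))
  )
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_exon <- type == "exon"
  if (!any(is_exon)) stop("GTF contains no exon features: ", path)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id[is_exon])) {
    bad <- which(is_exon & (if (is.null(mc$transcript_id)) TRUE else is.na(mc$transcript_id)))
    stop("exon feature(s) without transcript_id attribute (feature ",
         paste(head(bad, 3L), collapse = ", "), ")")
  }
  if (is.null(mc$gene_id) || anyNA(mc$gene_id[is_exon])) {
    stop("exon feature(s) without gene_id attribute")
  }

  tx_rows <- which(type == "transcript")
  tx_meta <- new.env(parent = emptyenv())
  for (i in tx_rows) {
    tid <- mc$transcript_id[i]
    if (is.na(tid)) stop("transcript feature without transcript_id attribute (feature ", i, ")")
    lvl <- if (!is.null(mc$level)) suppressWarnings(as.integer(mc$level[i])) else NA_integer_
    assign(tid, lvl, envir = tx_meta)
  }

  exon_idx <- which(is_exon)
  tids <- mc$transcript_id[exon_idx]
  if (length(tx_rows) > 0L) {
    orphan <- setdiff(unique(tids), ls(tx_meta))
    if (length(orphan) > 0L) {
      stop("exon(s) reference transcript_id with no transcript feature: ",
           paste(head(orphan, 3L), collapse = ", "))
    }
  }

  split_idx <- split(exon_idx, tids)
  # preserve file order of first appearance
  first_seen <- vapply(split_idx, min, integer(1))
  split_idx <- split_idx[order(first_seen)]

  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(BiocGenerics::strand(gr))

  lapply(names(split_idx), function(tid) {
    idx <- split_idx[[tid]]
    chrom <- unique(chroms[idx])
    strand <- unique(strands[idx])
    if (length(chrom) != 1L || length(strand) != 1L) {
      stop("transcript ", tid, " has exons on multiple chromosomes or strands")
    }
    check_strand(strand)
    ex <- cbind(start = starts[idx] - 1L, end = ends[idx])
    ex <- ex[order(ex[, "start"]), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex[-1L, "start"] < ex[-nrow(ex), "end"])) {
      stop("transcript ", tid, " has overlapping exons")
    }
    gname <- if (!is.null(mc$gene_name)) mc$gene_name[idx[1L]] else NA_character_
    lvl <- if (exists(tid, envir = tx_meta)) get(tid, envir = tx_meta) else {
      if (!is.null(mc$level)) suppressWarnings(as.integer(mc$level[idx[1L]])) else NA_integer_
    }
    list(
      transcript_id = tid,
      gene_id = mc$gene_id[idx[1L]],
      gene_name = if (is.na(gname)) mc$gene_id[idx[1L]] else gname,
      level = lvl,
      chrom = chrom,
      strand = strand,
      exons = ex
    )
  })
}

#' Filter transcripts by annotation level
#'
#' Retains transcripts whose GENCODE annotation level is at most `max_level`;
#' with the default `max_level = 2` this excludes level-3 (automated)
#' annotations so that only manually annotated transcripts remain.
#'
#' @param transcripts list of transcript models from [parse_gtf()].
#' @param max_level highest level to keep (default 2).
#' @param missing_level what to do with transcripts lacking a level attribute:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return filtered list of transcript models.
#' @export
filter_level <- function(transcripts, max_level = 2L,
                         missing_level = c("drop", "error")) {
  missing_level <- match.arg(missing_level)
  levels <- vapply(transcripts, function(t) as.integer(t$level %||% NA_integer_), integer(1))
  if (anyNA(levels)) {
    if (missing_level == "error") stop("transcript(s) without level attribute")
    warning(sum(is.na(levels)), " transcript(s) without level attribute dropped")
  }
  transcripts[!is.na(levels) & levels <= max_level]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Internal splice-site boundaries of one transcript
#'
#' Returns the internal exon boundaries of a transcript, i.e. the splice
#' sites, excluding the transcript's outermost start/end coordinates (so a
#' single-exon transcript yields no sites). The acceptor is the genomic
#' position of the first exonic base at a 3' splice site and the donor the
#' genomic position of the last exonic base at a 5' splice site; on the minus
#' strand the genomic roles swap accordingly.
#'
#' @param transcript a transcript model.
#' @return list with sorted integer vectors `acceptors` and `donors`
#'   (0-based genomic positions).
#' @export
internal_boundaries <- function(transcript) {
  ex <- transcript$exons
  n <- nrow(ex)
  if (n < 2L) return(list(acceptors = integer(0), donors = integer(0)))
  left <- ex[-1L, "start"]       # starts of all but the first (genomic) exon
  right <- ex[-n, "end"] - 1L    # last base of all but the last (genomic) exon
  if (transcript$strand == "+") {
    list(acceptors = sort(unique(as.integer(left))),
         donors = sort(unique(as.integer(right))))
  } else {
    list(acceptors = sort(unique(as.integer(right))),
         donors = sort(unique(as.integer(left))))
  }
}

#' Collapse the transcripts of one gene into a single pseudo-isoform
#'
#' Aggregates the internal splice sites of all supplied transcripts (assumed
#' to belong to one gene) into one collapsed representation: the union of
#' acceptor positions, the union of donor positions, and the overall span.
#' Genes whose retained transcripts contribute no internal splice site (e.g.
#' only single-exon transcripts) collapse to `NULL`.
#'
#' @param transcripts list of transcript models sharing `gene_id`, `chrom`
#'   and `strand`.
#' @return a `collapsed_gene` (list with `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `span` = c(start, end) 0-based half-open, `acceptors`,
#'   `donors`), or `NULL`.
#' @export
collapse_gene <- function(transcripts) {
  if (length(transcripts) == 0L) return(NULL)
  gid <- unique(vapply(transcripts, `[[`, character(1), "gene_id"))
  chrom <- unique(vapply(transcripts, `[[`, character(1), "chrom"))
  strand <- unique(vapply(transcripts, `[[`, character(1), "strand"))
  if (length(gid) != 1L) stop("collapse_gene: transcripts from multiple genes")
  if (length(chrom) != 1L || length(strand) != 1L) {
    stop("gene ", gid, ": transcripts on mixed chromosomes or strands")
  }
  sites <- lapply(transcripts, internal_boundaries)
  acceptors <- sort(unique(unlist(lapply(sites, `[[`, "acceptors"))))
  donors <- sort(unique(unlist(lapply(sites, `[[`, "donors"))))
  if (length(acceptors) == 0L && length(donors) == 0L) return(NULL)
  span <- c(
    min(vapply(transcripts, function(t) min(t$exons[, "start"]), numeric(1))),
    max(vapply(transcripts, function(t) max(t$exons[, "end"]), numeric(1)))
  )
  structure(
    list(
      gene_id = gid,
      gene_name = transcripts[[1L]]$gene_name,
      chrom = chrom,
      strand = strand,
      span = as.integer(span),
      acceptors = as.integer(acceptors),
      donors = as.integer(donors)
    ),
    class = "collapsed_gene"
  )
}

#' @export
print.collapsed_gene <- function(x, ...) {
  cat(sprintf("<collapsed_gene> %s (%s) %s:%d-%d (%s)  %d acceptors, %d donors\n",
              x$gene_id, x$gene_name, x$chrom, x$span[1], x$span[2], x$strand,
              length(x$acceptors), length(x$donors)))
  invisible(x)
}

#' Build a collapsed splice-site annotation from a GTF
#'
#' Full annotation pipeline: parse, filter by annotation level, optionally
#' restrict to a chromosome list and exclude genes (e.g. paralog lists for
#' held-out evaluation), then collapse per gene. Genes left without internal
#' splice sites are dropped.
#'
#' @inheritParams parse_gtf
#' @inheritParams filter_level
#' @param chroms optional character vector of chromosomes to keep.
#' @param exclude_genes optional character vector of gene ids to drop.
#' @return list of `collapsed_gene` objects (class `collapsed_annotation`).
#' @export
build_collapsed_annotation <- function(path, max_level = 2L, chroms = NULL,
                                       exclude_genes = character(0),
                                       missing_level = c("drop", "error")) {
  tx <- parse_gtf(path)
  tx <- filter_level(tx, max_level = max_level, missing_level = missing_level)
  if (!is.null(chroms)) {
    tx <- Filter(function(t) t$chrom %in% chroms, tx)
  }
  if (length(exclude_genes) > 0L) {
    tx <- Filter(function(t) !(t$gene_id %in% exclude_genes), tx)
  }
  by_gene <- split(tx, vapply(tx, `[[`, character(1), "gene_id"))
  genes <- lapply(by_gene, collapse_gene)
  genes <- Filter(Negate(is.null), genes)
  genes <- genes[order(vapply(genes, function(g) g$span[1], integer(1)),
                       vapply(genes, `[[`, character(1), "gene_id"))]
  structure(unname(genes), class = "collapsed_annotation")
}

#' @export
print.collapsed_annotation <- function(x, ...) {
  cat(sprintf("<collapsed_annotation> %d genes, %d acceptors, %d donors\n",
              length(x),
              sum(vapply(x, function(g) length(g$acceptors), integer(1))),
              sum(vapply(x, function(g) length(g$donors), integer(1)))))
  invisible(x)
}

#' Write / read a collapsed annotation as TSV
#'
#' Eight tab-separated columns: `gene_id`, `gene_name`, `chrom`, `strand`,
#' `span_start`, `span_end` (0-based half-open) and comma-separated 0-based
#' `acceptors` and `donors`. The round trip is the identity.
#'
#' @param genes list of `collapsed_gene` objects.
#' @param path output/input TSV path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns a `collapsed_annotation`.
#' @export
write_annotation <- function(genes, path) {
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_id: ", ids[duplicated(ids)][1L])
  df <- data.frame(
    gene_id = ids,
    gene_name = vapply(genes, `[[`, character(1), "gene_name"),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    span_start = vapply(genes, function(g) g$span[1], integer(1)),
    span_end = vapply(genes, function(g) g$span[2], integer(1)),
    acceptors = vapply(genes, function(g) paste(g$acceptors, collapse = ","), character(1)),
    donors = vapply(genes, function(g) paste(g$donors, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  if (length(genes) == 0L) {
    df <- df[0L, , drop = FALSE]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character")
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in annotation: ", df$gene_id[duplicated(df$gene_id)][1L])
  }
  parse_sites <- function(s) {
    if (is.na(s) || !nzchar(s)) integer(0) else as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
  }
  genes <- lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(
        gene_id = df$gene_id[i],
        gene_name = df$gene_name[i],
        chrom = df$chrom[i],
        strand = df$strand[i],
        span = c(as.integer(df$span_start[i]), as.integer(df$span_end[i])),
        acceptors = parse_sites(df$acceptors[i]),
        donors = parse_sites(df$donors[i])
      ),
      class = "collapsed_gene"
    )
  })
  structure(genes, class = "collapsed_annotation")
}
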