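# Deterministic synthetic genome / annotation / variant generator with
# motif-defined splice sites, plus a rule-based oracle predictor, so the
# whole pipeline (collapse -> encode -> predict -> delta -> benchmark) can be
# validated end to end with provably correct answers and no external data.
#
# Every splice site carries an exact consensus motif (GT-anchored donor
# 9-mer, AG-anchored acceptor 23-mer); the generator guarantees no exact
# motif occurrence exists anywhere else (accidental occurrences are
# rewritten), so the oracle predictor — probability 1 exactly at motif-borne
# sites, 0 elsewhere — is correct by construction and reacts to variant
# edits. A noisy-motif mode (per-base corruption of the non-anchor motif
# positions) emulates the degeneracy of real splice signals and provides a
# learnable, non-trivial task for the desk-scale network; the oracle only
# applies at noise 0.

#' Specification of a synthetic splice fixture
#'
#' @param n_genes number of genes.
#' @param seed master seed; all stages derive substreams from it.
#' @param isoforms_range min/max isoforms per gene.
#' @param exon_range min/max exons of the master isoform.
#' @param exon_len,intron_len min/max exon and intron lengths (bases).
#' @param intergenic min/max gap between genes.
#' @param donor_motif fixed donor 9-mer (3 exonic + GT + 4 intronic);
#'   `donor_site_offset` is the 1-based index of the splice-site base (the
#'   last exonic base).
#' @param acceptor_motif fixed acceptor 23-mer (20 intronic ending in AG + 3
#'   exonic); `acceptor_site_offset` indexes the first exonic base.
#' @param fraction_level3 probability that a non-primary isoform is level 3
#'   (automated annotation).
#' @param p_alt_exon probability a gene carries an alternative cassette exon.
#' @param p_single_exon_isoform probability of an extra single-exon isoform.
#' @param p_single_exon_gene probability a gene consists of one exon only
#'   (such genes collapse to nothing).
#' @param cryptic_per_gene max number of near-miss (one-base-off) motif
#'   copies planted in introns; a single-nucleotide variant restoring one
#'   creates a cryptic splice site.
#' @param noise per-base corruption probability of non-anchor motif
#'   positions (0 = exact motifs, oracle-compatible).
#' @param chrom chromosome name.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 50L, seed = 1L,
                         isoforms_range = c(1L, 4L),
                         exon_range = c(3L, 6L),
                         exon_len = c(80L, 300L),
                         intron_len = c(150L, 600L),
                         intergenic = c(400L, 1000L),
                         donor_motif = "CAGGTAAGT",
                         donor_site_offset = 3L,
                         acceptor_motif = "TTCTTTCTTTTTTTTTTCAGGTT",
                         acceptor_site_offset = 21L,
                         fraction_level3 = 0.25,
                         p_alt_exon = 0.6,
                         p_single_exon_isoform = 0.15,
                         p_single_exon_gene = 0.06,
                         cryptic_per_gene = 2L,
                         noise = 0,
                         chrom = "chrS") {
  stopifnot(nchar(donor_motif) == 9L, nchar(acceptor_motif) == 23L,
            substr(donor_motif, donor_site_offset + 1L, donor_site_offset + 2L) == "GT",
            substr(acceptor_motif, acceptor_site_offset - 2L, acceptor_site_offset - 1L) == "AG",
            noise >= 0, noise < 1)
  structure(as.list(environment()), class = "fixture_spec")
}

# Genomic footprint [start, end) of the motif around a site, and the motif
# string as it appears on the forward genome strand.
motif_footprint <- function(spec, site, class, strand) {
  if (class == "donor") {
    w <- nchar(spec$donor_motif); o <- spec$donor_site_offset
    m <- spec$donor_motif
  } else {
    w <- nchar(spec$acceptor_motif); o <- spec$acceptor_site_offset
    m <- spec$acceptor_motif
  }
  if (strand == "+") {
    list(start = site - (o - 1L), end = site + (w - o) + 1L, seq = m)
  } else {
    list(start = site - (w - o), end = site + o, seq = revcomp(m))
  }
}

# Anchor (GT/AG) genomic positions of a site's motif; never corrupted and
# targeted by loss variants.
motif_anchor_positions <- function(spec, site, class, strand) {
  o <- if (class == "donor") spec$donor_site_offset else spec$acceptor_site_offset
  anchor_td <- if (class == "donor") c(o + 1L, o + 2L) else c(o - 2L, o - 1L)
  fp <- motif_footprint(spec, site, class, strand)
  if (strand == "+") fp$start + anchor_td - 1L
  else fp$end - anchor_td  # td index i maps to genomic fp$end - i
}

#' Fixture specification for network training
#'
#' The standard conditions for training the desk-scale network: motif-defined
#' splice sites with 5% per-base corruption of the non-anchor motif positions
#' (the invariant GT/AG dinucleotides are never corrupted), and no planted
#' near-miss decoy motifs. The corruption level is calibrated so that an
#' ideal (generative-model) detector still separates sites from background
#' almost perfectly (pooled PR-AUC about 0.99): residual error of a trained
#' model is then attributable to training, not to task ambiguity. Near-miss
#' decoys are confined to the exact-motif fixtures used for variant-effect
#' experiments: under corruption they are indistinguishable from corrupted
#' true sites, which makes site recognition information-theoretically capped
#' well below what real splice annotation supports.
#'
#' @param n_genes number of genes (default 100).
#' @param seed master seed.
#' @param noise per-base corruption probability (default 0.05).
#' @return a [fixture_spec()].
#' @export
noisy_training_spec <- function(n_genes = 100L, seed = 1L, noise = 0.05) {
  fixture_spec(n_genes = n_genes, seed = seed, noise = noise,
               cryptic_per_gene = 0L)
}

#' Generate a synthetic genome with planted splice-site annotation
#'
#' Lays out `n_genes` multi-isoform genes on both strands along one
#' chromosome, plants the exact (or noise-corrupted) splice motifs at every
#' planned site, plants near-miss cryptic motifs in introns, rewrites any
#' accidental exact motif occurrence elsewhere, and derives the ground-truth
#' collapsed annotation (union of internal splice sites of the isoforms at
#' annotation level <= `max_level`) directly from the planting plan.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory; writes `genome.fa`,
#'   `annotation.gtf` and `truth_annotation.tsv`.
#' @param max_level level filter applied when deriving the truth collapsed
#'   annotation (matching the default of [build_collapsed_annotation()]).
#' @return list of class `splice_fixture`: `spec`, `genome`
#'   ([Biostrings::DNAStringSet]), `transcripts` (GTF-shaped plan),
#'   `truth` (`collapsed_annotation`), `sites` (data frame of planted real
#'   sites), `cryptic` (data frame of near-miss sites), `protected`
#'   (footprint intervals), and file paths when `dir` was given.
#' @export
generate_genome_and_annotation <- function(spec, dir = NULL, max_level = 2L) {
  plan <- with_seed(derive_seed(spec$seed, 1L), plan_genes(spec))
  chars <- with_seed(derive_seed(spec$seed, 2L),
                     sample(DNA_ORDER, plan$chrom_length, replace = TRUE))
  # plant real motifs (possibly noise-corrupted), then near-misses
  chars <- with_seed(derive_seed(spec$seed, 3L), {
    for (i in seq_len(nrow(plan$sites))) {
      s <- plan$sites[i, ]
      fp <- motif_footprint(spec, s$site, s$class, s$strand)
      m <- strsplit(fp$seq, "", fixed = TRUE)[[1L]]
      if (spec$noise > 0) {
        anchors <- motif_anchor_positions(spec, s$site, s$class, s$strand)
        gpos <- fp$start:(fp$end - 1L)
        for (j in seq_along(m)) {
          if (!(gpos[j] %in% anchors) && runif(1) < spec$noise) {
            m[j] <- sample(setdiff(DNA_ORDER, m[j]), 1L)
          }
        }
      }
      chars[(fp$start + 1L):fp$end] <- m
    }
    for (i in seq_len(nrow(plan$cryptic))) {
      cr <- plan$cryptic[i, ]
      fp <- motif_footprint(spec, cr$site, cr$class, cr$strand)
      m <- strsplit(fp$seq, "", fixed = TRUE)[[1L]]
      # corrupt exactly one non-anchor position; record the restoring edit
      anchors <- motif_anchor_positions(spec, cr$site, cr$class, cr$strand)
      gpos <- fp$start:(fp$end - 1L)
      cand <- which(!(gpos %in% anchors))
      j <- sample(cand, 1L)
      orig <- m[j]
      m[j] <- sample(setdiff(DNA_ORDER, orig), 1L)
      chars[(fp$start + 1L):fp$end] <- m
      plan$cryptic$fix_pos[i] <- gpos[j]
      plan$cryptic$fix_base[i] <- orig
      plan$cryptic$broken_base[i] <- m[j]
    }
    chars
  })
  # rewrite accidental exact motif occurrences outside the plan
  chars <- with_seed(derive_seed(spec$seed, 4L),
                     scrub_collisions(chars, spec, plan))

  genome <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), spec$chrom))
  truth <- plan_truth(plan, spec, max_level = max_level)
  fx <- structure(
    list(spec = spec, genome = genome, transcripts = plan$transcripts,
         truth = truth, sites = plan$sites, cryptic = plan$cryptic,
         protected = plan$protected, chrom_length = plan$chrom_length),
    class = "splice_fixture"
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fx$genome_path <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fx$genome_path)
    fx$gtf_path <- file.path(dir, "annotation.gtf")
    write_fixture_gtf(fx, fx$gtf_path)
    fx$truth_path <- file.path(dir, "truth_annotation.tsv")
    write_annotation(truth, fx$truth_path)
  }
  fx
}

#' @export
print.splice_fixture <- function(x, ...) {
  cat(sprintf("<splice_fixture> %d genes on %s (%d bp), %d planted sites, %d cryptic sites, noise %.2f\n",
              length(unique(x$transcripts$gene_id)), x$spec$chrom,
              x$chrom_length, nrow(x$sites), nrow(x$cryptic), x$spec$noise))
  invisible(x)
}

# -- planning ---------------------------------------------------------------

plan_genes <- function(spec) {
  rint <- function(lim) sample(lim[1]:lim[2], 1L)
  transcripts <- list()   # rows: gene, transcript, level, strand, exon start/end
  sites <- list()
  cryptic <- list()
  cursor <- rint(spec$intergenic)
  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("G%04d", g)
    gname <- sprintf("SYN%04d", g)
    strand <- sample(c("+", "-"), 1L)
    single_gene <- runif(1) < spec$p_single_exon_gene
    if (single_gene) {
      len <- rint(spec$exon_len)
      exons <- matrix(c(cursor, cursor + len), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
      transcripts[[length(transcripts) + 1L]] <- data.frame(
        gene_id = gid, gene_name = gname, transcript_id = paste0(gid, ".T1"),
        level = sample(1:2, 1L), strand = strand,
        exon_start = exons[, 1L], exon_end = exons[, 2L])
      cursor <- cursor + len + rint(spec$intergenic)
      next
    }
    n_ex <- rint(spec$exon_range)
    ex_len <- vapply(seq_len(n_ex), function(i) rint(spec$exon_len), integer(1))
    in_len <- vapply(seq_len(n_ex - 1L), function(i) rint(spec$intron_len), integer(1))
    starts <- cursor + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    master <- cbind(start = starts, end = ends)

    # place a cassette exon in an intron with room; returns c(start, end) or
    # NULL (`used` marks introns already taken)
    place_cassette <- function(used) {
      alt_len <- sample(50:90, 1L)
      room <- in_len - (alt_len + 100L)   # motif footprints + margins
      ok <- setdiff(which(room > 0L), used)
      if (length(ok) == 0L) return(NULL)
      k <- if (length(ok) == 1L) ok else sample(ok, 1L)
      lo <- ends[k] + 50L
      hi <- starts[k + 1L] - 50L - alt_len
      a0 <- sample(lo:hi, 1L)
      c(start = a0, end = a0 + alt_len, intron = k)
    }

    n_iso <- rint(spec$isoforms_range)

    # motif-borne alternative cassette exon: planted and always used by a
    # retained (level <= 2) isoform, so planted motifs and labels agree
    alt_exon <- NULL
    if (runif(1) < spec$p_alt_exon && n_ex >= 2L && n_iso >= 2L) {
      alt_exon <- place_cassette(integer(0))
    }
    # level-3-only cassette exon: annotated but with no motif planted (an
    # automated-annotation artifact); exercises the level filter
    l3_exon <- NULL
    if (runif(1) < 0.35 && n_ex >= 2L) {
      l3_exon <- place_cassette(if (is.null(alt_exon)) integer(0) else alt_exon["intron"])
    }

    with_cassette <- function(cassette) {
      ex <- rbind(master, cassette[c("start", "end")])
      ex[order(ex[, "start"]), , drop = FALSE]
    }
    iso_exons <- list(master)
    iso_levels <- sample(1:2, 1L)
    if (!is.null(alt_exon)) {
      iso_exons[[2L]] <- with_cassette(alt_exon)
      iso_levels <- c(iso_levels, sample(1:2, 1L))
    }
    while (length(iso_exons) < n_iso) {
      choices <- c("dup", if (n_ex >= 3L) "skip", if (!is.null(alt_exon)) "alt")
      type <- sample(choices, 1L)
      ex <- master
      if (type == "skip") {
        drop <- sample(2:(n_ex - 1L), 1L)
        ex <- master[-drop, , drop = FALSE]
      } else if (type == "alt") {
        ex <- with_cassette(alt_exon)
      }
      iso_exons[[length(iso_exons) + 1L]] <- ex
      iso_levels <- c(iso_levels,
                      if (runif(1) < spec$fraction_level3) 3L else sample(1:2, 1L))
    }
    if (!is.null(l3_exon)) {
      iso_exons[[length(iso_exons) + 1L]] <- with_cassette(l3_exon)
      iso_levels <- c(iso_levels, 3L)
    }
    if (runif(1) < spec$p_single_exon_isoform) {
      iso_exons[[length(iso_exons) + 1L]] <- master[1L, , drop = FALSE]
      iso_levels <- c(iso_levels, sample(1:3, 1L))
    }

    for (j in seq_along(iso_exons)) {
      ex <- iso_exons[[j]]
      transcripts[[length(transcripts) + 1L]] <- data.frame(
        gene_id = gid, gene_name = gname,
        transcript_id = sprintf("%s.T%d", gid, j),
        level = iso_levels[j], strand = strand,
        exon_start = ex[, "start"], exon_end = ex[, "end"])
    }

    # planted sites = internal boundaries of the union exon set (master +
    # alt); acceptors at exon starts / donors at exon ends on '+', swapped
    # on '-'
    all_ex <- if (is.null(alt_exon)) master else with_cassette(alt_exon)
    left <- all_ex[-1L, "start"]
    right <- all_ex[-nrow(all_ex), "end"] - 1L
    acc <- if (strand == "+") left else right
    don <- if (strand == "+") right else left
    for (s in acc) {
      sites[[length(sites) + 1L]] <- data.frame(
        gene_id = gid, class = "acceptor", site = as.integer(s), strand = strand)
    }
    for (s in don) {
      sites[[length(sites) + 1L]] <- data.frame(
        gene_id = gid, class = "donor", site = as.integer(s), strand = strand)
    }

    # cryptic near-miss sites in introns clear of other footprints
    n_cr <- sample(0:spec$cryptic_per_gene, 1L)
    if (n_cr > 0L && n_ex >= 2L) {
      taken <- c(if (!is.null(alt_exon)) alt_exon[["intron"]],
                 if (!is.null(l3_exon)) l3_exon[["intron"]])
      free_iv <- list()
      for (k in setdiff(seq_len(n_ex - 1L), taken)) {
        lo <- ends[k] + 40L
        hi <- starts[k + 1L] - 40L
        if (hi - lo > 60L) free_iv[[length(free_iv) + 1L]] <- c(lo, hi)
      }
      if (length(free_iv) > 0L) {
        for (cc in seq_len(n_cr)) {
          iv <- free_iv[[sample(seq_along(free_iv), 1L)]]
          cls <- sample(c("acceptor", "donor"), 1L)
          site <- sample((iv[1] + 25L):(iv[2] - 25L), 1L)
          near <- vapply(c(sites, cryptic), function(x) abs(x$site - site) < 40L, logical(1))
          if (any(near)) next
          cryptic[[length(cryptic) + 1L]] <- data.frame(
            gene_id = gid, class = cls, site = as.integer(site), strand = strand,
            fix_pos = NA_integer_, fix_base = NA_character_,
            broken_base = NA_character_)
        }
      }
    }
    cursor <- max(ends) + rint(spec$intergenic)
  }
  transcripts <- do.call(rbind, transcripts)
  sites <- if (length(sites) > 0L) do.call(rbind, sites) else
    data.frame(gene_id = character(0), class = character(0),
               site = integer(0), strand = character(0))
  cryptic <- if (length(cryptic) > 0L) do.call(rbind, cryptic) else
    data.frame(gene_id = character(0), class = character(0), site = integer(0),
               strand = character(0), fix_pos = integer(0),
               fix_base = character(0), broken_base = character(0))
  chrom_length <- cursor + 200L
  spec_obj <- spec
  protected <- rbind(
    do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
      fp <- motif_footprint(spec_obj, sites$site[i], sites$class[i], sites$strand[i])
      data.frame(start = fp$start, end = fp$end)
    })),
    do.call(rbind, lapply(seq_len(nrow(cryptic)), function(i) {
      fp <- motif_footprint(spec_obj, cryptic$site[i], cryptic$class[i], cryptic$strand[i])
      data.frame(start = fp$start, end = fp$end)
    }))
  )
  if (is.null(protected)) protected <- data.frame(start = integer(0), end = integer(0))
  list(transcripts = transcripts, sites = sites, cryptic = cryptic,
       protected = protected, chrom_length = chrom_length)
}

# Remove accidental exact motif occurrences: any match of either motif (or
# its reverse complement) whose footprint is not a planned one gets one
# non-protected base rewritten. Iterates until clean.
scrub_collisions <- function(chars, spec, plan) {
  seq_str <- function() paste(chars, collapse = "")
  planned <- paste(plan$protected$start, plan$protected$end)
  prot_mask <- rep(FALSE, length(chars))
  for (i in seq_len(nrow(plan$protected))) {
    prot_mask[(plan$protected$start[i] + 1L):plan$protected$end[i]] <- TRUE
  }
  patterns <- unique(c(spec$donor_motif, spec$acceptor_motif,
                       revcomp(spec$donor_motif), revcomp(spec$acceptor_motif)))
  for (round in 1:100) {
    s <- seq_str()
    bad <- list()
    for (p in patterns) {
      hits <- gregexpr(p, s, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      for (h in hits) {
        fp_start <- h - 1L
        fp_end <- fp_start + nchar(p)
        if (!(paste(fp_start, fp_end) %in% planned)) {
          bad[[length(bad) + 1L]] <- c(fp_start, fp_end)
        }
      }
    }
    if (length(bad) == 0L) return(chars)
    for (b in bad) {
      idx <- (b[1] + 1L):b[2]
      free <- idx[!prot_mask[idx]]
      if (length(free) == 0L) stop("cannot scrub motif collision at ", b[1])
      j <- free[(length(free) + 1L) %/% 2L]
      chars[j] <- sample(setdiff(DNA_ORDER, chars[j]), 1L)
    }
  }
  stop("motif collision scrubbing did not converge")
}

# Ground-truth collapsed annotation straight from the planting plan: union
# of internal boundaries of the isoforms at level <= max_level.
plan_truth <- function(plan, spec, max_level = 2L) {
  tx <- plan$transcripts
  genes <- list()
  for (gid in unique(tx$gene_id)) {
    gt <- tx[tx$gene_id == gid & tx$level <= max_level, , drop = FALSE]
    if (nrow(gt) == 0L) next
    acc <- integer(0); don <- integer(0)
    for (tid in unique(gt$transcript_id)) {
      ex <- gt[gt$transcript_id == tid, , drop = FALSE]
      ex <- ex[order(ex$exon_start), , drop = FALSE]
      n <- nrow(ex)
      if (n < 2L) next
      left <- ex$exon_start[-1L]
      right <- ex$exon_end[-n] - 1L
      if (ex$strand[1L] == "+") {
        acc <- c(acc, left); don <- c(don, right)
      } else {
        acc <- c(acc, right); don <- c(don, left)
      }
    }
    if (length(acc) == 0L && length(don) == 0L) next
    genes[[length(genes) + 1L]] <- structure(
      list(gene_id = gid, gene_name = gt$gene_name[1L], chrom = spec$chrom,
           strand = gt$strand[1L],
           span = c(min(gt$exon_start), max(gt$exon_end)),
           acceptors = sort(unique(acc)), donors = sort(unique(don))),
      class = "collapsed_gene")
  }
  structure(genes, class = "collapsed_annotation")
}

# GENCODE-dialect GTF writer for the fixture plan (1-based inclusive).
write_fixture_gtf <- function(fx, path) {
  tx <- fx$transcripts
  lines <- c("##description: synthetic splice fixture",
             sprintf("##seed: %d", fx$spec$seed))
  for (gid in unique(tx$gene_id)) {
    gt <- tx[tx$gene_id == gid, , drop = FALSE]
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";', gid, gt$gene_name[1L])
    lines <- c(lines, paste(fx$spec$chrom, "SYNTHETIC", "gene",
                            min(gt$exon_start) + 1L, max(gt$exon_end), ".",
                            gt$strand[1L], ".", attr_g, sep = "\t"))
    for (tid in unique(gt$transcript_id)) {
      ex <- gt[gt$transcript_id == tid, , drop = FALSE]
      ex <- ex[order(ex$exon_start), , drop = FALSE]
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; level %d;',
                        gid, tid, ex$gene_name[1L], ex$level[1L])
      lines <- c(lines, paste(fx$spec$chrom, "SYNTHETIC", "transcript",
                              min(ex$exon_start) + 1L, max(ex$exon_end), ".",
                              ex$strand[1L], ".", attr_t, sep = "\t"))
      for (i in seq_len(nrow(ex))) {
        lines <- c(lines, paste(fx$spec$chrom, "SYNTHETIC", "exon",
                                ex$exon_start[i] + 1L, ex$exon_end[i], ".",
                                ex$strand[1L], ".",
                                paste0(attr_t, sprintf(' exon_number %d;', i)),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# -- oracle predictor -------------------------------------------------------

#' Rule-based oracle splice predictor for fixture genomes
#'
#' Satisfies the predictor contract: scans the input sequence and outputs
#' probability 1 exactly where the surrounding window equals the planted
#' motif (0 elsewhere). Because it is sequence-driven, variant edits change
#' its output: destroying a motif removes the site, creating one (e.g.
#' restoring a near-miss) adds a site. Correct by construction on
#' collision-free fixtures generated at noise 0.
#'
#' @param spec the [fixture_spec()] whose motifs define the rule.
#' @param context_len declared context of the predictor (must leave room for
#'   the motif overhangs; default 80).
#' @return object of classes `oracle_predictor`, `splice_predictor`.
#' @export
oracle_predictor <- function(spec, context_len = 80L) {
  over_left <- max(spec$acceptor_site_offset, spec$donor_site_offset) - 1L
  over_right <- max(nchar(spec$acceptor_motif) - spec$acceptor_site_offset,
                    nchar(spec$donor_motif) - spec$donor_site_offset)
  if (context_len %/% 2L < max(over_left, over_right)) {
    stop("context_len too small for motif widths")
  }
  structure(list(spec = spec, context_len = as.integer(context_len)),
            class = c("oracle_predictor", "splice_predictor"))
}

#' @export
predict_window.oracle_predictor <- function(predictor, x) {
  x <- check_window_input(predictor, x)
  s <- decode_one_hot(x)
  spec <- predictor$spec
  half <- predictor$context_len %/% 2L
  L <- nrow(x) - predictor$context_len
  centers <- (half + 1L):(half + L)
  match_at <- function(motif, offset) {
    starts <- centers - (offset - 1L)
    ends <- starts + nchar(motif) - 1L
    ok <- starts >= 1L & ends <= nchar(s)
    out <- rep(0, L)
    out[ok] <- as.numeric(substring(s, starts[ok], ends[ok]) == motif)
    out
  }
  list(
    acceptor = match_at(spec$acceptor_motif, spec$acceptor_site_offset),
    donor = match_at(spec$donor_motif, spec$donor_site_offset)
  )
}

#' @export
print.oracle_predictor <- function(x, ...) {
  cat(sprintf("<oracle_predictor> motif rule, context %d nt\n", x$context_len))
  invisible(x)
}

# -- variants ---------------------------------------------------------------

#' Generate validation variants with known splice effects
#'
#' Affecting variants either destroy a planted splice site (SNV at an
#' anchor base, small deletion/insertion/multi-nucleotide substitution
#' disrupting the motif; effect class `acceptor_loss`/`donor_loss` at the
#' planted site) or restore a planted near-miss motif (SNV; effect class
#' `*_gain` at the cryptic site). Neutral variants fall at least 30 bases
#' from every planted footprint and are verified not to create any exact
#' motif. Deterministic given the fixture seed.
#'
#' @param fx a `splice_fixture` (generated at noise 0 for oracle use).
#' @param n_affecting,n_neutral variant counts.
#' @param indel_fraction fraction of variants that are not SNVs (split
#'   between deletions, insertions and multi-nucleotide substitutions with
#'   deletions most common, mirroring curated clinical sets).
#' @param dir optional output directory; writes `variants.vcf` and
#'   `truth_variants.csv`.
#' @return list with `truth` (data frame in [load_truth_csv()] layout),
#'   and file paths when `dir` was given.
#' @export
generate_variants <- function(fx, n_affecting = 100L, n_neutral = 100L,
                              indel_fraction = 0.2, dir = NULL) {
  spec <- fx$spec
  chars <- strsplit(as.character(fx$genome[[1L]]), "", fixed = TRUE)[[1L]]
  prot <- fx$protected
  min_dist <- 30L

  # gap between the edited interval [lo, hi) and the nearest footprint
  # (0 when they overlap)
  dist_to_protected <- function(lo, hi) {
    if (nrow(prot) == 0L) return(Inf)
    min(pmax(pmax(prot$start - hi, lo - prot$end), 0L))
  }

  # does the alt sequence around an edit contain any exact motif occurrence?
  creates_motif <- function(pos0, ref, alt) {
    w <- 30L
    lo <- max(0L, pos0 - w)
    hi <- min(length(chars), pos0 + nchar(ref) + w)
    local_ref <- paste(chars[(lo + 1L):hi], collapse = "")
    rel <- pos0 - lo
    local_alt <- paste0(substr(local_ref, 1L, rel), alt,
                        substr(local_ref, rel + nchar(ref) + 1L, nchar(local_ref)))
    pats <- unique(c(spec$donor_motif, spec$acceptor_motif,
                     revcomp(spec$donor_motif), revcomp(spec$acceptor_motif)))
    any(vapply(pats, function(p) grepl(p, local_alt, fixed = TRUE), logical(1)))
  }

  ref_at <- function(pos0, len) paste(chars[(pos0 + 1L):(pos0 + len)], collapse = "")
  rand_base_not <- function(b) sample(setdiff(DNA_ORDER, b), 1L)

  res <- with_seed(derive_seed(spec$seed, 5L), {
    rows <- list()
    used <- character(0)
    add_row <- function(pos0, ref, alt, affecting, effects) {
      vid <- variant_id(spec$chrom, pos0 + 1L, ref, alt)
      if (vid %in% used) return(FALSE)
      used <<- c(used, vid)
      rows[[length(rows) + 1L]] <<- list(
        chrom = spec$chrom, pos = pos0 + 1L, ref = ref, alt = alt,
        affects_splicing = affecting, source = "synthetic", effects = effects)
      TRUE
    }
    vclasses <- function() {
      if (runif(1) >= indel_fraction) return("snv")
      sample(c("del", "ins", "mnv"), 1L, prob = c(0.55, 0.3, 0.15))
    }

    n_gain_target <- min(ceiling(n_affecting / 3), nrow(fx$cryptic))
    free_cryptic <- seq_len(nrow(fx$cryptic))
    made <- 0L
    guard <- 0L
    while (made < n_affecting && guard < n_affecting * 200L) {
      guard <- guard + 1L
      want_gain <- made < n_gain_target && length(free_cryptic) > 0L
      if (want_gain) {
        ci <- if (length(free_cryptic) == 1L) free_cryptic else sample(free_cryptic, 1L)
        free_cryptic <- setdiff(free_cryptic, ci)
        cr <- fx$cryptic[ci, ]
        pos0 <- cr$fix_pos
        ref <- ref_at(pos0, 1L)
        alt <- cr$fix_base
        if (ref == alt) next   # should not happen; guard anyway
        eff <- list(list(class = paste0(cr$class, "_gain"), pos = cr$site + 1L))
        if (add_row(pos0, ref, alt, TRUE, eff)) made <- made + 1L
        next
      }
      s <- fx$sites[sample.int(nrow(fx$sites), 1L), ]
      anchors <- motif_anchor_positions(spec, s$site, s$class, s$strand)
      fp <- motif_footprint(spec, s$site, s$class, s$strand)
      cls <- vclasses()
      eff <- list(list(class = paste0(s$class, "_loss"), pos = s$site + 1L))
      if (cls == "snv") {
        pos0 <- sample(anchors, 1L)
        ref <- ref_at(pos0, 1L)
        alt <- rand_base_not(ref)
        if (creates_motif(pos0, ref, alt)) next
        if (add_row(pos0, ref, alt, TRUE, eff)) made <- made + 1L
      } else if (cls == "del") {
        del_len <- sample(2:5, 1L)
        del_start <- sample(seq.int(min(anchors) - del_len + 1L, max(anchors)), 1L)
        pos0 <- del_start - 1L
        if (pos0 < 0L) next
        ref <- ref_at(pos0, del_len + 1L)
        alt <- ref_at(pos0, 1L)
        if (creates_motif(pos0, ref, alt)) next
        if (add_row(pos0, ref, alt, TRUE, eff)) made <- made + 1L
      } else if (cls == "ins") {
        pos0 <- min(anchors)          # insert between the two anchor bases
        ref <- ref_at(pos0, 1L)
        ins <- paste(sample(DNA_ORDER, sample(1:3, 1L), replace = TRUE), collapse = "")
        alt <- paste0(ref, ins)
        if (creates_motif(pos0, ref, alt)) next
        if (add_row(pos0, ref, alt, TRUE, eff)) made <- made + 1L
      } else {
        pos0 <- min(anchors)
        ref <- ref_at(pos0, 2L)       # the GT / AG dinucleotide
        repeat {
          alt <- paste(sample(DNA_ORDER, 2L, replace = TRUE), collapse = "")
          if (alt != ref) break
        }
        if (creates_motif(pos0, ref, alt)) next
        if (add_row(pos0, ref, alt, TRUE, eff)) made <- made + 1L
      }
    }
    if (made < n_affecting) stop("could not place requested affecting variants")

    spans <- do.call(rbind, lapply(fx$truth, function(g) {
      data.frame(start = g$span[1], end = g$span[2])
    }))
    made <- 0L; guard <- 0L
    while (made < n_neutral && guard < n_neutral * 200L) {
      guard <- guard + 1L
      sp <- spans[sample.int(nrow(spans), 1L), ]
      pos0 <- sample(sp$start:(sp$end - 6L), 1L)
      cls <- vclasses()
      len_ref <- switch(cls, snv = 1L, del = sample(3:6, 1L), ins = 1L, mnv = 2L)
      if (dist_to_protected(pos0, pos0 + len_ref) < min_dist) next
      ref <- ref_at(pos0, len_ref)
      alt <- switch(cls,
        snv = rand_base_not(ref),
        del = substr(ref, 1L, 1L),
        ins = paste0(ref, paste(sample(DNA_ORDER, sample(1:3, 1L), replace = TRUE), collapse = "")),
        mnv = {
          repeat {
            a <- paste(sample(DNA_ORDER, 2L, replace = TRUE), collapse = "")
            if (a != ref && substr(a, 1L, 1L) != substr(ref, 1L, 1L)) break
          }
          a
        })
      if (creates_motif(pos0, ref, alt)) next
      if (add_row(pos0, ref, alt, FALSE, list())) made <- made + 1L
    }
    if (made < n_neutral) stop("could not place requested neutral variants")
    rows
  })

  ord <- order(vapply(res, `[[`, numeric(1), "pos"))
  res <- res[ord]
  truth <- data.frame(
    chrom = vapply(res, `[[`, character(1), "chrom"),
    pos = vapply(res, `[[`, numeric(1), "pos"),
    ref = vapply(res, `[[`, character(1), "ref"),
    alt = vapply(res, `[[`, character(1), "alt"),
    affects_splicing = vapply(res, `[[`, logical(1), "affects_splicing"),
    source = "synthetic",
    stringsAsFactors = FALSE
  )
  truth$effects <- lapply(res, `[[`, "effects")
  truth$variant_id <- variant_id(truth$chrom, truth$pos, truth$ref, truth$alt)

  out <- list(truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$vcf_path <- file.path(dir, "variants.vcf")
    write_fixture_vcf(truth, spec, fx$chrom_length, out$vcf_path)
    out$truth_path <- file.path(dir, "truth_variants.csv")
    write_truth_csv(truth, out$truth_path)
  }
  out
}

write_fixture_vcf <- function(truth, spec, chrom_length, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", spec$chrom, chrom_length),
    sprintf("##source=splicedelta synthetic fixture (seed %d)", spec$seed),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  truth$chrom, truth$pos, truth$ref, truth$alt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: genome + annotation + variants, written to `dir`.
#'
#' @inheritParams generate_genome_and_annotation
#' @inheritParams generate_variants
#' @return list combining the fixture and the variant set.
#' @export
simulate_dataset <- function(spec, n_affecting = 100L, n_neutral = 100L,
                             indel_fraction = 0.2, dir = NULL) {
  fx <- generate_genome_and_annotation(spec, dir = dir)
  vars <- generate_variants(fx, n_affecting = n_affecting,
                            n_neutral = n_neutral,
                            indel_fraction = indel_fraction, dir = dir)
  c(list(fixture = fx), vars)
}
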