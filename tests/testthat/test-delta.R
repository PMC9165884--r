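test_that("variant normalization trims to minimal representation and left-aligns", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGGACCCCTAGGG"))
  # SNV unchanged
  nv <- normalize_variant(genome, "chr1", 5, "C", "T")
  expect_equal(nv[c("pos", "ref", "alt")], list(pos = 5L, ref = "C", alt = "T"))
  # shared suffix then prefix trimming
  nv <- normalize_variant(genome, "chr1", 4, "ACC", "AC")
  expect_equal(nv[c("pos", "ref", "alt")], list(pos = 4L, ref = "AC", alt = "A"))
  # deletion inside the C-run left-aligns to the run start
  nv <- normalize_variant(genome, "chr1", 7, "CC", "C")
  expect_equal(nv$pos, 4L)
  expect_equal(nv$ref, "AC")
  expect_equal(nv$alt, "A")
  # insertion of C in the run left-aligns likewise
  nv <- normalize_variant(genome, "chr1", 8, "C", "CC")
  expect_equal(nv$pos, 4L)
  expect_equal(nv$alt, "AC")
  expect_error(normalize_variant(genome, "chr1", 1, "G", "<DEL>"), "non-ACGT")
})

test_that("ref/alt windows differ only at the allele and honour strand", {
  set.seed(61)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  gene_p <- structure(list(gene_id = "G", gene_name = "G", chrom = "chr1",
                           strand = "+", span = c(50L, 250L),
                           acceptors = 100L, donors = 150L),
                      class = "collapsed_gene")
  pos <- 150L
  ref <- substr(seq, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  win <- build_ref_alt_windows(genome, "chr1", pos, ref, alt, gene_p,
                               max_distance = 20, context = 10)
  expect_equal(nchar(win$ref_seq), 2 * 30 + 1)
  diffs <- which(strsplit(win$ref_seq, "")[[1]] != strsplit(win$alt_seq, "")[[1]])
  expect_equal(diffs, 31L)   # exactly the centre base
  # 2-base deletion: alt window shorter by 2
  win_d <- build_ref_alt_windows(genome, "chr1", pos, substr(seq, pos, pos + 2),
                                 substr(seq, pos, pos), gene_p,
                                 max_distance = 20, context = 10)
  expect_equal(nchar(win_d$ref_seq) - nchar(win_d$alt_seq), 2L)
  # minus strand: the windows are reverse-complemented
  gene_m <- gene_p; gene_m$strand <- "-"
  win_m <- build_ref_alt_windows(genome, "chr1", pos, ref, alt, gene_m,
                                 max_distance = 20, context = 10)
  expect_equal(win_m$ref_seq, revcomp(win$ref_seq))
  expect_equal(win_m$alt_seq, revcomp(win$alt_seq))
  # C>T on the minus strand enters the prediction input as G>A
  mid <- 31L
  expect_equal(substr(win_m$alt_seq, mid, mid), revcomp(alt))
  # reference allele mismatches are refused
  expect_error(build_ref_alt_windows(genome, "chr1", pos, alt, ref, gene_p,
                                     max_distance = 20, context = 10),
               "ref allele mismatch")
})

test_that("windows at chromosome edges are N-padded to full width", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGT"))
  gene <- structure(list(gene_id = "G", gene_name = "G", chrom = "chr1",
                         strand = "+", span = c(0L, 12L),
                         acceptors = 5L, donors = 6L),
                    class = "collapsed_gene")
  win <- build_ref_alt_windows(genome, "chr1", 2, "C", "A", gene,
                               max_distance = 5, context = 5)
  expect_equal(nchar(win$ref_seq), 21L)
  expect_equal(substr(win$ref_seq, 1, 9), "NNNNNNNNN")
})

test_that("align_alt_track inserts zeros for deletions and max-collapses insertions", {
  D <- 3
  # SNV: identity
  r <- runif(2 * D + 1); a <- runif(2 * D + 1)
  expect_identical(align_alt_track(r, a, "C", "T", D), a)
  # deletion of 3 (ref CAAA > alt C): zeros at the three deleted positions
  ref_track <- runif(2 * D + 4)
  alt_track <- c(0.1, 0.2, 0.3, 0.9, 0.4, 0.5, 0.6)
  out <- align_alt_track(ref_track, alt_track, "CAAA", "C", D)
  expect_length(out, 2 * D + 4)
  expect_equal(out, c(0.1, 0.2, 0.3, 0.9, 0, 0, 0, 0.4, 0.5, 0.6))
  # insertion of 2 (C > CTT): anchor takes the max of anchor + inserted block
  alt_ins <- c(0.1, 0.2, 0.3, 0.1, 0.2, 0.7, 0.4, 0.5, 0.6)
  out_i <- align_alt_track(runif(2 * D + 1), alt_ins, "C", "CTT", D)
  expect_length(out_i, 2 * D + 1)
  expect_equal(out_i, c(0.1, 0.2, 0.3, 0.7, 0.4, 0.5, 0.6))
  # inconsistent lengths are refused
  expect_error(align_alt_track(runif(5), runif(9), "C", "CTT", D), "inconsistent")
})

test_that("alignment closure: aligned alt tracks always match the ref length", {
  set.seed(62)
  for (i in 1:500) {
    D <- sample(5:30, 1)
    lr <- sample(1:20, 1)
    la <- sample(1:20, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), lr, replace = TRUE), collapse = "")
    alt <- paste(sample(c("A", "C", "G", "T"), la, replace = TRUE), collapse = "")
    out <- align_alt_track(runif(2 * D + lr), runif(2 * D + la), ref, alt, D)
    expect_length(out, 2 * D + lr)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("delta scores and positions match an exhaustive scan", {
  D <- 12
  # identical tracks: all deltas zero
  tr <- list(acceptor = runif(2 * D + 1), donor = runif(2 * D + 1))
  ds0 <- delta_scores(tr, tr, "A", D)
  expect_equal(unlist(ds0[1:4]), c(DS_AG = 0, DS_AL = 0, DS_DG = 0, DS_DL = 0))
  # hand case: acceptor probability drops 0.9 -> 0.1 at offset -12
  ref_t <- list(acceptor = rep(0, 2 * D + 1), donor = rep(0, 2 * D + 1))
  alt_t <- ref_t
  ref_t$acceptor[1] <- 0.9   # offset -12
  alt_t$acceptor[1] <- 0.1
  ds <- delta_scores(ref_t, alt_t, "A", D)
  expect_equal(ds$DS_AL, 0.8)
  expect_equal(ds$DP_AL, -12L)
  # random tracks against the brute-force oracle
  set.seed(63)
  for (i in 1:200) {
    lr <- sample(1:4, 1)
    mk <- function() list(acceptor = round(runif(2 * D + lr), 2),
                          donor = round(runif(2 * D + lr), 2))
    a <- mk(); b <- mk()
    got <- delta_scores(a, b, strrep("A", lr), D)
    want <- brute_delta(a, b, strrep("A", lr), D)
    expect_equal(got[names(want)], want)
  }
})

test_that("annotation covers fixture variants fully and deterministically", {
  fx <- cached_fixture(6, 88)
  vars <- generate_variants(fx, n_affecting = 10, n_neutral = 10, dir = tempfile())
  orc <- oracle_predictor(fx$spec)
  out1 <- tempfile(fileext = ".vcf"); out2 <- tempfile(fileext = ".vcf")
  res <- annotate_vcf(vars$vcf_path, fx$genome, fx$truth, orc, out1,
                      max_distance = 5000)
  expect_equal(res$n_variants, 20L)
  expect_equal(res$coverage, 1)
  annotate_vcf(vars$vcf_path, fx$genome, fx$truth, orc, out2,
               max_distance = 5000)
  expect_identical(readLines(out1), readLines(out2))
  anns <- read_delta_vcf(out1)
  expect_true(all(c("DS_AG", "DP_DL", "gene_name") %in% names(anns)))
  expect_true(all(anns$max_ds >= 0 & anns$max_ds <= 1))
  # the added INFO header line declares the field
  expect_true(any(grepl("##INFO=<ID=SDELTA", readLines(out1), fixed = TRUE)))
})

test_that("variants outside all genes and symbolic alleles are skipped", {
  fx <- cached_fixture(6, 88)
  far_pos <- fx$chrom_length - 2L
  vcf <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", fx$spec$chrom),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", fx$spec$chrom, far_pos,
            splicedelta:::genome_subseq(fx$genome, fx$spec$chrom,
                                        far_pos - 1L, far_pos), "A"),
    sprintf("%s\t%d\t.\tN\t<DEL>\t.\t.\t.", fx$spec$chrom,
            fx$truth[[1]]$span[1] + 10L)
  ), ".vcf")
  out <- tempfile(fileext = ".vcf")
  expect_warning(
    res <- annotate_vcf(vcf, fx$genome, fx$truth, oracle_predictor(fx$spec),
                        out, max_distance = 200),
    "symbolic")
  expect_equal(res$n_annotated, 0L)
  expect_equal(res$coverage, 0)
  expect_equal(sort(unique(res$skipped$reason)),
               c("no overlapping gene", "no scorable allele"))
})

test_that("delta annotation is invariant under reverse-complementing the genome", {
  fx <- cached_fixture(6, 93)
  is_plus <- vapply(fx$truth, function(g) g$strand == "+", logical(1))
  g <- fx$truth[[which(is_plus)[1]]]
  L <- fx$chrom_length
  site <- g$donors[1]
  pos0 <- site + 1L          # the G of the donor GT on the plus strand
  ref <- splicedelta:::genome_subseq(fx$genome, g$chrom, pos0, pos0 + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  orc <- oracle_predictor(fx$spec)
  ds_fw <- splicedelta:::delta_for_variant(fx$genome, orc, g$chrom, pos0 + 1L,
                                           ref, alt, g, max_distance = 100)
  # mirrored representation: reverse-complemented genome, strand flipped
  genome_rc <- Biostrings::DNAStringSet(
    setNames(revcomp(as.character(fx$genome[[1]])), g$chrom))
  g_rc <- g
  g_rc$strand <- "-"
  g_rc$span <- c(L - g$span[2], L - g$span[1])
  g_rc$acceptors <- sort(L - 1L - g$acceptors)
  g_rc$donors <- sort(L - 1L - g$donors)
  pos_rc0 <- L - 1L - pos0
  ds_rc <- splicedelta:::delta_for_variant(genome_rc, orc, g$chrom, pos_rc0 + 1L,
                                           revcomp(ref), revcomp(alt), g_rc,
                                           max_distance = 100)
  for (f in c("DS_AG", "DS_AL", "DS_DG", "DS_DL")) {
    expect_equal(ds_rc[[f]], ds_fw[[f]])
  }
  expect_equal(ds_fw$DS_DL, 1)
  for (f in c("DP_DL")) expect_equal(ds_rc[[f]], -ds_fw[[f]])
})
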