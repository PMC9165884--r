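# Shared helpers: hand-built transcripts, independent brute-force oracles,
# and a memoised fixture cache so expensive generation runs once per session.

make_tx <- function(gene_id, exons, strand = "+", level = 1L,
                    transcript_id = paste0(gene_id, ".T1"), chrom = "chr1",
                    gene_name = gene_id) {
  ex <- matrix(as.integer(unlist(exons)), ncol = 2L, byrow = TRUE,
               dimnames = list(NULL, c("start", "end")))
  ex <- ex[order(ex[, "start"]), , drop = FALSE]
  list(transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
       level = level, chrom = chrom, strand = strand, exons = ex)
}

# Independent collapse oracle: enumerate every exon of every transcript and
# union the non-terminal boundaries directly.
brute_collapse <- function(transcripts) {
  acc <- c(); don <- c()
  for (t in transcripts) {
    ex <- t$exons
    n <- nrow(ex)
    if (n < 2L) next
    for (i in seq_len(n)) {
      if (i > 1L) {  # left boundary of a non-first exon
        p <- ex[i, "start"]
        if (t$strand == "+") acc <- c(acc, p) else don <- c(don, p)
      }
      if (i < n) {   # right boundary of a non-last exon
        p <- ex[i, "end"] - 1L
        if (t$strand == "+") don <- c(don, p) else acc <- c(acc, p)
      }
    }
  }
  list(acceptors = sort(unique(as.integer(acc))),
       donors = sort(unique(as.integer(don))))
}

random_transcript_set <- function(gene_id = "G") {
  strand <- sample(c("+", "-"), 1L)
  n_tx <- sample(1:4, 1L)
  lapply(seq_len(n_tx), function(j) {
    n_ex <- sample(1:5, 1L)
    starts <- sort(sample(0:500, n_ex)) * 10L
    lens <- sample(3:9, n_ex, replace = TRUE)
    make_tx(gene_id, Map(c, starts, starts + lens), strand = strand,
            transcript_id = sprintf("%s.T%d", gene_id, j))
  })
}

# Exhaustive accuracy search over every cut (independent of binary_eval).
brute_best_accuracy <- function(scores, labels) {
  s <- scores
  s[is.na(s)] <- -Inf
  cand <- sort(unique(c(s[is.finite(s)], min(s[is.finite(s)], 0) - 1,
                        max(s[is.finite(s)], 0) + 1)))
  best <- 0
  for (t in cand) best <- max(best, mean((s >= t) == labels))
  best
}

# Step-interpolated PR curve computed point by point.
brute_pr_auc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- as.logical(labels[ord])
  thresholds <- unique(s)
  area <- 0; prev_recall <- 0
  n_pos <- sum(l)
  for (t in thresholds) {
    sel <- s >= t
    tp <- sum(l & sel); fp <- sum(!l & sel)
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

brute_roc_auc <- function(scores, labels) {
  l <- as.logical(labels)
  pos <- scores[l]; neg <- scores[!l]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Exhaustive-scan delta oracle: independent max/argmax over the window with
# the documented tie rules.
brute_delta <- function(ref_tracks, alt_tracks, ref, max_distance) {
  D <- max_distance; lr <- nchar(ref)
  offsets <- seq.int(-D, D + lr - 1L)
  pick <- function(diff) {
    best_ds <- 0; best_dp <- NA
    for (i in seq_along(offsets)) {
      if (abs(offsets[i]) > D) next
      v <- max(diff[i], 0)
      better <- is.na(best_dp) || v > best_ds ||
        (v == best_ds && (abs(offsets[i]) < abs(best_dp) ||
                          (abs(offsets[i]) == abs(best_dp) && offsets[i] < best_dp)))
      if (better) { best_ds <- v; best_dp <- offsets[i] }
    }
    list(ds = best_ds, dp = best_dp)
  }
  ag <- pick(alt_tracks$acceptor - ref_tracks$acceptor)
  al <- pick(ref_tracks$acceptor - alt_tracks$acceptor)
  dg <- pick(alt_tracks$donor - ref_tracks$donor)
  dl <- pick(ref_tracks$donor - alt_tracks$donor)
  list(DS_AG = ag$ds, DS_AL = al$ds, DS_DG = dg$ds, DS_DL = dl$ds,
       DP_AG = ag$dp, DP_AL = al$dp, DP_DG = dg$dp, DP_DL = dl$dp)
}

# Memoised fixtures (shared across test files within a session).
.fx_cache <- new.env(parent = emptyenv())
cached_fixture <- function(n_genes, seed, noise = 0, cryptic = 2L) {
  key <- paste(n_genes, seed, noise, cryptic, sep = "_")
  if (!exists(key, envir = .fx_cache)) {
    spec <- fixture_spec(n_genes = n_genes, seed = seed, noise = noise,
                         cryptic_per_gene = cryptic)
    assign(key, generate_genome_and_annotation(spec), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
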