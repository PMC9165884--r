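truth_df <- function(labels, ids = sprintf("v%02d", seq_along(labels))) {
  data.frame(variant_id = ids, affects_splicing = labels,
             stringsAsFactors = FALSE)
}

test_that("PR and ROC areas match independent step/rank oracles", {
  set.seed(501)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    scores <- round(runif(n), 2)   # ties likely
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(pr_auc(scores, labels), brute_pr_auc(scores, labels),
                 tolerance = 1e-9)
    expect_equal(roc_auc(scores, labels), brute_roc_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("ROC-AUC agrees with pROC on a tied, imperfect score set", {
  set.seed(502)
  scores <- round(runif(60), 1)
  labels <- runif(60) < plogis(3 * scores - 1.5)
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(roc_auc(scores, labels), want, tolerance = 1e-9)
})

test_that("binary_eval handles perfect, degenerate, and invalid inputs", {
  tr <- truth_df(c(TRUE, TRUE, FALSE, FALSE))
  perfect <- setNames(c(0.9, 0.8, 0.2, 0.1), tr$variant_id)
  be <- binary_eval(perfect, tr)
  expect_equal(be$auc_pr, 1)
  expect_equal(be$auc_roc, 1)
  expect_equal(be$accuracy_at_optimal, 1)
  expect_equal(be$coverage, 1)
  # all-equal scores: optimum is the majority class
  tr2 <- truth_df(c(TRUE, FALSE, FALSE))
  be2 <- binary_eval(setNames(rep(0.5, 3), tr2$variant_id), tr2)
  expect_equal(be2$accuracy_at_optimal, 2 / 3)
  expect_error(binary_eval(perfect, truth_df(logical(0))), "empty")
  expect_error(binary_eval(perfect[1:2], truth_df(c(TRUE, TRUE))), "single class")
})

test_that("the optimal threshold equals exhaustive enumeration over all cuts", {
  # fixed 12-pair hand case
  scores <- setNames(c(0.05, 0.1, 0.2, 0.2, 0.35, 0.4, 0.5, 0.55, 0.7, 0.8, 0.9, 0.95),
                     sprintf("v%02d", 1:12))
  labels <- c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  tr <- truth_df(labels)
  be <- binary_eval(scores, tr)
  expect_equal(be$accuracy_at_optimal, brute_best_accuracy(scores, labels))
  expect_equal(mean((scores >= be$optimal_threshold) == labels),
               be$accuracy_at_optimal)
  # property: optimal accuracy is never beaten by any user threshold
  set.seed(503)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    s <- setNames(round(runif(n), 2), sprintf("v%02d", 1:n))
    l <- runif(n) < 0.5
    if (!any(l) || all(l)) next
    be <- binary_eval(s, truth_df(l))
    expect_equal(be$accuracy_at_optimal, brute_best_accuracy(s, l))
    for (t in runif(5, -0.2, 1.2)) {
      expect_gte(be$accuracy_at_optimal, mean((s >= t) == l))
    }
  }
})

test_that("missing predictions count against coverage but score as non-affecting", {
  tr <- truth_df(c(TRUE, TRUE, FALSE, FALSE, TRUE))
  scores <- setNames(c(0.9, NA, 0.1, 0, NA), tr$variant_id)
  be <- binary_eval(scores, tr)
  expect_equal(be$coverage, 0.6)
  # at the optimum (between 0.1 and 0.9) the two missing positives are wrong
  expect_equal(be$accuracy_at_optimal, 3 / 5)
  # a legitimate score of 0 still ranks above a missing prediction: a
  # 0-scoring positive separates perfectly from a missing negative, which a
  # fill-with-zero scheme could not do
  tr2 <- truth_df(c(TRUE, FALSE))
  be2 <- binary_eval(setNames(c(0, NA), tr2$variant_id), tr2)
  expect_equal(be2$auc_roc, 1)
})

test_that("exact_eval requires position-exact delta positions per class", {
  ann <- data.frame(
    variant_id = c("v1", "v2", "v3"), pos = c(100L, 200L, 300L),
    DS_AG = c(0.9, 0, 0), DS_AL = c(0, 0.8, 0),
    DS_DG = 0, DS_DL = c(0, 0, 0.7),
    DP_AG = c(-10L, 0L, 0L), DP_AL = c(0L, 5L, 0L),
    DP_DG = 0L, DP_DL = c(0L, 0L, 4L),
    stringsAsFactors = FALSE
  )
  tr <- data.frame(
    variant_id = c("v1", "v2", "v3"),
    affects_splicing = TRUE, stringsAsFactors = FALSE
  )
  tr$effects <- list(
    list(list(class = "acceptor_gain", pos = 90)),
    list(list(class = "acceptor_loss", pos = 206)),   # off by one
    list(list(class = "donor_loss", pos = 304),
         list(class = "donor_loss", pos = 305))       # either position counts
  )
  ee <- exact_eval(ann, tr)
  expect_equal(unname(ee$accuracy["acceptor_gain"]), 1)
  expect_equal(unname(ee$accuracy["acceptor_loss"]), 0)
  expect_equal(unname(ee$accuracy["donor_loss"]), 1)
  expect_true(is.na(ee$accuracy["donor_gain"]))
  # a one-base tolerance rescues the off-by-one variant
  ee1 <- exact_eval(ann, tr, tolerance = 1)
  expect_equal(unname(ee1$accuracy["acceptor_loss"]), 1)
})

test_that("shuffled delta positions score near chance on the exact task", {
  fx <- cached_fixture(8, 42)
  vars <- generate_variants(fx, n_affecting = 20, n_neutral = 5, dir = tempfile())
  out <- tempfile(fileext = ".vcf")
  annotate_vcf(vars$vcf_path, fx$genome, fx$truth, oracle_predictor(fx$spec),
               out, max_distance = 5000)
  anns <- read_delta_vcf(out)
  truth <- load_truth_csv(vars$truth_path)
  baseline <- exact_eval(anns, truth)
  set.seed(504)
  shuffled <- anns
  for (f in c("DP_AG", "DP_AL", "DP_DG", "DP_DL")) {
    shuffled[[f]] <- shuffled[[f]] + sample(c(-50:-20, 20:50), nrow(shuffled),
                                            replace = TRUE)
  }
  ee <- exact_eval(shuffled, truth)
  ok <- !is.na(baseline$accuracy)
  expect_true(all(baseline$accuracy[ok] == 1))
  expect_true(all(ee$accuracy[ok] < 0.2))
})

test_that("predictive-error comparison counts changes and improvements", {
  tr <- truth_df(c(TRUE, TRUE, FALSE, FALSE))
  a <- setNames(c(0.1, 0.9, 0.8, 0.1), tr$variant_id)   # wrong, right, wrong, right
  expect_equal(compare_predictive_error(a, a, tr)$fraction_changed, 0)
  b <- setNames(c(0.9, 0.95, 0.1, 0.05), tr$variant_id) # all right, all changed
  cmp <- compare_predictive_error(a, b, tr)
  expect_equal(cmp$fraction_changed, 1)
  expect_equal(cmp$fraction_improved, 1)
  # random paired scores against a direct count
  set.seed(505)
  for (i in 1:20) {
    n <- 30
    l <- runif(n) < 0.5
    trr <- truth_df(l)
    sa <- setNames(round(runif(n), 2), trr$variant_id)
    sb <- setNames(round(runif(n), 2), trr$variant_id)
    got <- compare_predictive_error(sa, sb, trr)
    ea <- abs(sa - as.numeric(l)); eb <- abs(sb - as.numeric(l))
    expect_equal(got$fraction_changed, mean(ea != eb))
    if (any(ea != eb)) {
      expect_equal(got$fraction_improved, sum(eb < ea) / sum(ea != eb))
    }
  }
})

test_that("truth CSVs round-trip and enforce their invariants", {
  tr <- data.frame(
    chrom = "chrS", pos = c(100L, 250L, 400L), ref = c("A", "CT", "G"),
    alt = c("T", "C", "GAA"), affects_splicing = c(TRUE, TRUE, FALSE),
    source = "synthetic", stringsAsFactors = FALSE
  )
  tr$effects <- list(
    list(list(class = "donor_loss", pos = 102)),
    list(list(class = "acceptor_loss", pos = 240),
         list(class = "acceptor_gain", pos = 260)),
    list()
  )
  path <- tempfile(fileext = ".csv")
  write_truth_csv(tr, path)
  back <- load_truth_csv(path)
  expect_equal(back$pos, tr$pos)
  expect_equal(back$affects_splicing, tr$affects_splicing)
  expect_equal(length(back$effects[[2]]), 2L)
  expect_equal(back$effects[[2]][[2]]$class, "acceptor_gain")
  expect_equal(back$effects[[2]][[2]]$pos, 260)
  # malformed class
  bad <- readLines(path)
  bad <- sub("donor_loss", "donor_banana", bad)
  expect_error(load_truth_csv(write_lines_tmp(bad, ".csv")), "unknown effect class")
  # duplicate variants
  dup <- readLines(path)
  expect_error(load_truth_csv(write_lines_tmp(c(dup, dup[2]), ".csv")), "duplicate")
  # effects imply affecting
  contradictory <- sub("100,A,T,true", "100,A,T,false", readLines(path))
  expect_error(load_truth_csv(write_lines_tmp(contradictory, ".csv")),
               "marked non-affecting")
  # a hand-written three-row file parses to three records
  hand <- write_lines_tmp(c(
    "chrom,pos,ref,alt,affects_splicing,source,effect_class,effect_pos",
    "chr1,10,A,T,true,paper,donor_loss,12",
    "chr1,20,C,CAT,false,paper,,",
    "chr2,10,G,A,true,paper,acceptor_gain;donor_gain,8;30"
  ), ".csv")
  h <- load_truth_csv(hand)
  expect_equal(nrow(h), 3L)
  expect_equal(vapply(h$effects, length, integer(1)), c(1L, 0L, 2L))
})
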