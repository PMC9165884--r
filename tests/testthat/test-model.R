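random_onehot <- function(L, alphabet = c("A", "C", "G", "T")) {
  one_hot(paste(sample(alphabet, L, replace = TRUE), collapse = ""))
}

test_that("the learning rate is halved at 60/70/80/90% of training", {
  expect_equal(lr_schedule(59, 100), 0.001)
  expect_equal(lr_schedule(60, 100), 0.0005)
  expect_equal(lr_schedule(95, 100), 0.001 / 16)
  # boundaries scale with the total step count
  expect_equal(lr_schedule(53, 90), 0.001)
  expect_equal(lr_schedule(54, 90), 0.0005)
})

test_that("the desk-scale network is compact, softmax-valid, and reproducible", {
  m <- splice_cnn(context_len = 80, seed = 9)
  expect_lt(n_params(m), 1e6)
  x <- random_onehot(280)
  probs <- splicedelta:::cnn_forward(m, x)
  expect_equal(nrow(probs), 200L)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-5))
  expect_true(all(probs >= 0 & probs <= 1))
  m2 <- splice_cnn(context_len = 80, seed = 9)
  expect_identical(m$params, m2$params)
  expect_error(splice_cnn(context_len = 100, kernel = 11,
                          dilations = c(1, 1, 1, 1)),
               "receptive-field context of this stack is 80")
})

test_that("the predictor contract validates input and handles unknown bases", {
  m <- splice_cnn(context_len = 80, seed = 1)
  expect_error(predict_window(m, random_onehot(80)), "must exceed")
  expect_error(predict_window(m, matrix(0, 100, 3)), "one-hot")
  tr <- predict_window(m, strrep("N", 130))
  expect_length(tr$acceptor, 50L)
  expect_true(all(tr$acceptor >= 0 & tr$acceptor <= 1))
  expect_true(all(tr$donor >= 0 & tr$donor <= 1))
  # batch prediction preserves order
  set.seed(5)
  wins <- replicate(3, random_onehot(130), simplify = FALSE)
  batch <- predict_windows(m, wins)
  for (i in 1:3) expect_identical(batch[[i]], predict_window(m, wins[[i]]))
})

test_that("backpropagated gradients match finite differences", {
  set.seed(77)
  m <- splice_cnn(context_len = 16, channels = 5, kernel = 3,
                  dilations = c(1, 3), seed = 3)
  x <- random_onehot(46)
  y <- one_hot_labels(sample(c("neither", "acceptor", "donor"), 30, replace = TRUE))
  loss <- function(model) {
    p <- splicedelta:::cnn_forward(model, x)
    -mean(rowSums(y * log(p + 1e-12)))
  }
  fwd <- splicedelta:::cnn_forward(m, x, keep_cache = TRUE)
  g <- splicedelta:::cnn_backward(m, fwd, y)
  eps <- 1e-6
  numeric_grad <- function(mutate) {
    mp <- mutate(m, eps); lm_ <- mutate(m, -eps)
    (loss(mp) - loss(lm_)) / (2 * eps)
  }
  probes <- list(
    list(get = function() g$W_in[2, 3],
         mut = function(m, d) { m$params$W_in[2, 3] <- m$params$W_in[2, 3] + d; m }),
    list(get = function() g$b_in[1],
         mut = function(m, d) { m$params$b_in[1] <- m$params$b_in[1] + d; m }),
    list(get = function() g$blocks[[1]]$g1[2],
         mut = function(m, d) { m$params$blocks[[1]]$g1[2] <- m$params$blocks[[1]]$g1[2] + d; m }),
    list(get = function() g$blocks[[2]]$be2[4],
         mut = function(m, d) { m$params$blocks[[2]]$be2[4] <- m$params$blocks[[2]]$be2[4] + d; m }),
    list(get = function() g$blocks[[2]]$W1[2, 4, 1],
         mut = function(m, d) { m$params$blocks[[2]]$W1[2, 4, 1] <- m$params$blocks[[2]]$W1[2, 4, 1] + d; m }),
    list(get = function() g$blocks[[1]]$W2[3, 1, 5],
         mut = function(m, d) { m$params$blocks[[1]]$W2[3, 1, 5] <- m$params$blocks[[1]]$W2[3, 1, 5] + d; m }),
    list(get = function() g$W_out[4, 2],
         mut = function(m, d) { m$params$W_out[4, 2] <- m$params$W_out[4, 2] + d; m })
  )
  for (p in probes) {
    expect_equal(unname(p$get()), numeric_grad(p$mut), tolerance = 1e-5)
  }
})

test_that("ensembles average member tracks elementwise", {
  m <- splice_cnn(context_len = 80, seed = 4)
  x <- random_onehot(180)
  same <- splice_ensemble(list(m, m, m))
  expect_equal(predict_window(same, x), predict_window(m, x))
  # members outputting 0 and 1 average to 0.5
  const_pred <- function(v) {
    structure(list(context_len = 80L, value = v),
              class = c("const_pred", "splice_predictor"))
  }
  registerS3method("predict_window", "const_pred",
                   function(predictor, x) {
                     L <- nrow(x) - predictor$context_len
                     list(acceptor = rep(predictor$value, L),
                          donor = rep(predictor$value, L))
                   },
                   envir = asNamespace("splicedelta"))
  ens <- splice_ensemble(list(const_pred(0), const_pred(1)))
  tr <- predict_window(ens, x)
  expect_true(all(tr$acceptor == 0.5))
  # convexity: ensemble of valid predictors stays within [0, 1]
  mix <- predict_window(splice_ensemble(list(m, splice_cnn(80, seed = 8))), x)
  expect_true(all(mix$acceptor >= 0 & mix$acceptor <= 1))
  expect_error(splice_ensemble(list(m, splice_cnn(40, kernel = 11,
                                                  dilations = c(1, 1)))),
               "disagree")
})

make_toy_chunks <- function(n_genes, n_chunks, seed) {
  spec <- fixture_spec(n_genes = n_genes, seed = seed,
                       exon_range = c(2L, 3L), exon_len = c(60L, 120L),
                       intron_len = c(150L, 250L), isoforms_range = c(1L, 1L),
                       p_alt_exon = 0, p_single_exon_gene = 0,
                       p_single_exon_isoform = 0, cryptic_per_gene = 0L)
  fx <- generate_genome_and_annotation(spec)
  enc <- encode_genes(fx$truth, fx$genome, encoder_config(1000L, 80L))
  chunk_genes(enc, max(1L, length(enc) %/% n_chunks))
}

test_that("training is reproducible and follows the configured schedule", {
  chunks <- make_toy_chunks(8, 4, 91)
  cfg <- train_config(n_models = 1, seed = 23)
  e1 <- train_splice_models(chunks, cfg, channels = 6)
  e2 <- train_splice_models(chunks, cfg, channels = 6)
  expect_identical(e1$models[[1]]$params, e2$models[[1]]$params)
  expect_identical(e1$history[[1]]$validation, e2$history[[1]]$validation)
  h <- e1$history[[1]]
  n_train <- length(h$train_chunks)
  expect_equal(n_train, max(1, floor(0.9 * length(chunks))))
  expect_equal(h$total_steps, 10 * n_train)
  expect_equal(h$lr_trace,
               lr_schedule(seq_len(h$total_steps), h$total_steps))
  # degenerate configurations
  expect_error(train_splice_models(list(), cfg), "no training chunks")
  expect_error(train_splice_models(list(list()), cfg), "empty chunk")
  expect_warning(
    train_splice_models(chunks[1], train_config(n_models = 1, seed = 2),
                        channels = 4),
    "fewer than 2 chunks")
})

test_that("the desk model overfits a tiny exact-motif dataset", {
  chunks <- make_toy_chunks(10, 10, 92)
  cfg <- train_config(n_models = 1, seed = 31)
  ens <- train_splice_models(chunks, cfg, context_len = 80, channels = 12)
  train_genes <- unlist(chunks[ens$history[[1]]$train_chunks], recursive = FALSE)
  auc <- splicedelta:::validation_pr_auc(ens$models[[1]], train_genes)
  expect_gte(auc, 0.95)
})

test_that("validation scoring and the benchmark share one PR-AUC implementation", {
  fx <- cached_fixture(6, 71)
  enc <- encode_genes(fx$truth, fx$genome, encoder_config(800L, 80L))
  orc <- oracle_predictor(fx$spec)
  internal <- splicedelta:::validation_pr_auc(orc, enc)
  scores <- c(); labels <- c()
  for (gene in enc) for (w in gene) {
    tr <- predict_window(orc, w$sequence)
    keep <- seq_len(w$n_real)
    scores <- c(scores, tr$acceptor[keep], tr$donor[keep])
    labels <- c(labels, w$labels[keep, 2] > 0, w$labels[keep, 3] > 0)
  }
  expect_identical(internal, pr_auc(scores, labels))
})

test_that("checkpoints round-trip through save and load", {
  dir <- tempfile()
  m <- splice_cnn(context_len = 80, seed = 12)
  ens <- splice_ensemble(list(m, splice_cnn(80, seed = 13)))
  save_predictor(ens, dir)
  back <- load_predictor(dir)
  x <- random_onehot(140)
  expect_equal(predict_window(back, x), predict_window(ens, x))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$context_len, 80L)
  expect_equal(unlist(manifest$class_order), c("neither", "acceptor", "donor"))
})
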