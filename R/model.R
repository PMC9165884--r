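# Per-nucleotide splice predictor: a residual dilated 1-D convolutional
# network over one-hot DNA, softmax over {neither, acceptor, donor} per
# position. The network is fully convolutional: any input of length
# L + context_len yields per-position probabilities for the central L bases.
# Forward/backward passes are written as shifted matrix products so the whole
# model runs on BLAS without compiled code.

#' Build a reference splice prediction network
#'
#' Constructs a residual dilated-convolution network: a 1x1 input projection
#' to `channels`, `n_blocks` pre-activation residual blocks (two
#' `kernel`-wide dilated convolutions each), and a 1x1 output projection to
#' three classes with per-position softmax. The receptive-field context is
#' fully determined by the stack: `2 * sum(2 * (kernel - 1)/2 * dilations)`
#' = `2 * (kernel - 1) * sum(dilations)`, and must equal `context_len`.
#' Defaults give an 80-nt context desk-scale model; the same code scales to
#' larger contexts via wider kernels/dilations.
#'
#' @param context_len declared total context (even).
#' @param channels feature channels per layer.
#' @param kernel odd convolution width.
#' @param dilations integer vector, one dilation per residual block.
#' @param seed integer seed for weight initialisation (reproducible
#'   bit-for-bit).
#' @return object of class `splice_cnn` (also `splice_predictor`).
#' @export
splice_cnn <- function(context_len = 80L, channels = 12L, kernel = 11L,
                       dilations = c(1L, 1L, 1L, 1L), seed = 1L) {
  context_len <- as.integer(context_len)
  stopifnot(kernel %% 2L == 1L, context_len %% 2L == 0L, channels >= 4L)
  rf <- 2L * (kernel - 1L) * sum(dilations)
  if (rf != context_len) {
    stop("context_len ", context_len, " incompatible with dilation stack: ",
         "receptive-field context of this stack is ", rf)
  }
  params <- with_seed(seed, {
    he <- function(k, cin, cout) {
      array(rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))), dim = c(k, cin, cout))
    }
    p <- list(W_in = matrix(rnorm(4 * channels, sd = sqrt(2 / 4)), 4, channels),
              b_in = numeric(channels),
              blocks = lapply(dilations, function(d) {
                list(g1 = rep(1, channels), be1 = numeric(channels),
                     W1 = he(kernel, channels, channels), b1 = numeric(channels),
                     g2 = rep(1, channels), be2 = numeric(channels),
                     W2 = he(kernel, channels, channels), b2 = numeric(channels),
                     dilation = as.integer(d))
              }),
              W_out = matrix(rnorm(channels * 3, sd = sqrt(1 / channels)), channels, 3),
              # output bias starts at the approximate class-prior logits
              # (splice sites are ~1 in 400 bases), so early optimizer steps
              # are not spent learning the background rate
              b_out = c(6, 0, 0))
    p
  })
  structure(
    list(context_len = context_len, channels = channels, kernel = kernel,
         dilations = as.integer(dilations), seed = as.integer(seed),
         params = params),
    class = c("splice_cnn", "splice_predictor")
  )
}

#' Number of trainable parameters
#' @param model a `splice_cnn`.
#' @return integer count.
#' @export
n_params <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), identity, numeric(1)))
}

# -- convolution primitives -------------------------------------------------

# Dilated 1-D convolution on BLAS: one wide matrix product against the
# stacked kernel (all taps side by side), then k shifted block additions.
# out[i,] = sum_j x[i + o_j,] %*% W[j,,] with o_j the tap offsets; rows
# beyond the sequence act as zeros.

conv1d_fwd <- function(x, W, b, dilation) {
  k <- dim(W)[1L]; cout <- dim(W)[3L]
  mid <- (k + 1L) %/% 2L
  L <- nrow(x)
  # (Cin x k*Cout), tap blocks side by side
  Wall <- matrix(aperm(W, c(2L, 3L, 1L)), ncol = k * cout)
  XW <- x %*% Wall
  out <- matrix(b, L, cout, byrow = TRUE)
  for (j in seq_len(k)) {
    o <- (j - mid) * dilation
    cols <- ((j - 1L) * cout + 1L):(j * cout)
    if (o == 0L) {
      out <- out + XW[, cols, drop = FALSE]
    } else if (o > 0L && o < L) {
      out[1:(L - o), ] <- out[1:(L - o), ] + XW[(1 + o):L, cols, drop = FALSE]
    } else if (o < 0L && -o < L) {
      out[(1 - o):L, ] <- out[(1 - o):L, ] + XW[1:(L + o), cols, drop = FALSE]
    }
  }
  out
}

conv1d_bwd <- function(x, W, dilation, g) {
  k <- dim(W)[1L]; cin <- dim(W)[2L]; cout <- dim(W)[3L]
  mid <- (k + 1L) %/% 2L
  L <- nrow(x)
  # dx[i+o_j,] += g[i,] %*% t(W[j,,])  -- one wide product, k shifted adds
  WTall <- matrix(aperm(W, c(3L, 2L, 1L)), ncol = k * cin)
  GW <- g %*% WTall
  dx <- matrix(0, L, cin)
  dW <- array(0, dim = dim(W))
  for (j in seq_len(k)) {
    o <- (j - mid) * dilation
    cols <- ((j - 1L) * cin + 1L):(j * cin)
    if (o == 0L) {
      dx <- dx + GW[, cols, drop = FALSE]
      dW[j, , ] <- crossprod(x, g)
    } else if (o > 0L && o < L) {
      dx[(1 + o):L, ] <- dx[(1 + o):L, ] + GW[1:(L - o), cols, drop = FALSE]
      dW[j, , ] <- crossprod(x[(1 + o):L, , drop = FALSE], g[1:(L - o), , drop = FALSE])
    } else if (o < 0L && -o < L) {
      dx[1:(L + o), ] <- dx[1:(L + o), ] + GW[(1 - o):L, cols, drop = FALSE]
      dW[j, , ] <- crossprod(x[1:(L + o), , drop = FALSE], g[(1 - o):L, , drop = FALSE])
    }
  }
  list(dx = dx, dW = dW, db = colSums(g))
}

# Per-channel normalization over the positions of one window (deterministic
# at inference; statistics are part of the forward pass, not trained state).
norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  list(out = sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`),
       xhat = xhat, istd = istd)
}

norm_bwd <- function(cache, gamma, dy) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  t1 <- sweep(dy, 2L, dbeta / n)
  t2 <- sweep(cache$xhat, 2L, dgamma / n, `*`)
  dx <- sweep(t1 - t2, 2L, gamma * cache$istd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

cnn_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  h <- x %*% p$W_in + matrix(p$b_in, nrow(x), model$channels, byrow = TRUE)
  cache <- if (keep_cache) list(x = x, blocks = vector("list", length(p$blocks)))
  for (i in seq_along(p$blocks)) {
    bl <- p$blocks[[i]]
    n1 <- norm_fwd(h, bl$g1, bl$be1)
    a1 <- pmax(n1$out, 0)
    c1 <- conv1d_fwd(a1, bl$W1, bl$b1, bl$dilation)
    n2 <- norm_fwd(c1, bl$g2, bl$be2)
    a2 <- pmax(n2$out, 0)
    c2 <- conv1d_fwd(a2, bl$W2, bl$b2, bl$dilation)
    if (keep_cache) {
      cache$blocks[[i]] <- list(n1 = n1, a1 = a1, n2 = n2, a2 = a2)
    }
    h <- h + c2
  }
  z <- h %*% p$W_out + matrix(p$b_out, nrow(x), 3L, byrow = TRUE)
  half <- model$context_len %/% 2L
  rows <- (half + 1L):(nrow(x) - half)
  zc <- z[rows, , drop = FALSE]
  zc <- zc - apply(zc, 1L, max)
  e <- exp(zc)
  probs <- e / rowSums(e)
  if (keep_cache) {
    cache$h_top <- h
    cache$rows <- rows
    list(probs = probs, cache = cache)
  } else {
    probs
  }
}

# Gradient of mean categorical cross-entropy wrt all parameters for one
# window. Returns grads in the same nested shape as model$params.
cnn_backward <- function(model, fwd, y) {
  p <- model$params
  cache <- fwd$cache
  n <- nrow(y)
  dz_c <- (fwd$probs - y) / n
  L <- nrow(cache$h_top)
  dz <- matrix(0, L, 3L)
  dz[cache$rows, ] <- dz_c
  g <- list(W_in = NULL, b_in = NULL, blocks = vector("list", length(p$blocks)),
            W_out = crossprod(cache$h_top, dz), b_out = colSums(dz))
  dh <- dz %*% t(p$W_out)
  for (i in rev(seq_along(p$blocks))) {
    bl <- p$blocks[[i]]
    cb <- cache$blocks[[i]]
    dc2 <- dh
    b2 <- conv1d_bwd(cb$a2, bl$W2, bl$dilation, dc2)
    da2 <- b2$dx * (cb$a2 > 0)
    nb2 <- norm_bwd(cb$n2, bl$g2, da2)
    dc1 <- nb2$dx
    b1 <- conv1d_bwd(cb$a1, bl$W1, bl$dilation, dc1)
    da1 <- b1$dx * (cb$a1 > 0)
    nb1 <- norm_bwd(cb$n1, bl$g1, da1)
    g$blocks[[i]] <- list(g1 = nb1$dgamma, be1 = nb1$dbeta,
                          W1 = b1$dW, b1 = b1$db,
                          g2 = nb2$dgamma, be2 = nb2$dbeta,
                          W2 = b2$dW, b2 = b2$db)
    dh <- dh + nb1$dx
  }
  g$W_in <- crossprod(cache$x, dh)
  g$b_in <- colSums(dh)
  g
}

add_grads <- function(a, b, scale = 1) {
  if (is.null(a)) return(rapply(b, function(v) v * scale, how = "replace"))
  out <- a
  out$W_in <- a$W_in + b$W_in * scale
  out$b_in <- a$b_in + b$b_in * scale
  out$W_out <- a$W_out + b$W_out * scale
  out$b_out <- a$b_out + b$b_out * scale
  for (i in seq_along(a$blocks)) {
    for (nm in names(a$blocks[[i]])) {
      out$blocks[[i]][[nm]] <- a$blocks[[i]][[nm]] + b$blocks[[i]][[nm]] * scale
    }
  }
  out
}

# -- predictor contract -----------------------------------------------------

#' Predict splice tracks for one encoded window
#'
#' The predictor contract: given a one-hot sequence matrix of
#' `L + context_len(predictor)` rows, return acceptor/donor probability
#' tracks of length `L` (the central bases). All predictor classes
#' (`splice_cnn`, `splice_ensemble`, the fixture oracle) implement it.
#'
#' @param predictor a `splice_predictor`.
#' @param x one-hot matrix ((L + context) x 4) or character DNA string.
#' @return list with numeric `acceptor` and `donor` of length L.
#' @export
predict_window <- function(predictor, x) UseMethod("predict_window")

check_window_input <- function(predictor, x) {
  if (is.character(x)) x <- one_hot(x)
  if (!is.matrix(x) || ncol(x) != 4L) stop("input must be an L x 4 one-hot matrix")
  if (nrow(x) <= predictor$context_len) {
    stop("input length ", nrow(x), " must exceed predictor context ",
         predictor$context_len)
  }
  x
}

#' @export
predict_window.splice_cnn <- function(predictor, x) {
  x <- check_window_input(predictor, x)
  probs <- cnn_forward(predictor, x)
  list(acceptor = probs[, 2L], donor = probs[, 3L])
}

#' @export
print.splice_cnn <- function(x, ...) {
  cat(sprintf(
    "<splice_cnn> context %d nt, %d channels, kernel %d, %d residual blocks, %s parameters\n",
    x$context_len, x$channels, x$kernel, length(x$dilations),
    format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Ensemble of splice predictors
#'
#' Prediction is the elementwise arithmetic mean of the member probability
#' tracks (the usual convention for this model family).
#'
#' @param models list of `splice_predictor` objects sharing `context_len`.
#' @param history optional training history (kept by [train_splice_models()]).
#' @return object of class `splice_ensemble`.
#' @export
splice_ensemble <- function(models, history = NULL) {
  stopifnot(length(models) >= 1L)
  ctx <- unique(vapply(models, `[[`, integer(1), "context_len"))
  if (length(ctx) != 1L) stop("ensemble members disagree on context_len")
  structure(list(models = models, context_len = ctx, history = history),
            class = c("splice_ensemble", "splice_predictor"))
}

#' @export
predict_window.splice_ensemble <- function(predictor, x) {
  x <- check_window_input(predictor, x)
  tracks <- lapply(predictor$models, predict_window, x = x)
  list(
    acceptor = Reduce(`+`, lapply(tracks, `[[`, "acceptor")) / length(tracks),
    donor = Reduce(`+`, lapply(tracks, `[[`, "donor")) / length(tracks)
  )
}

#' @export
print.splice_ensemble <- function(x, ...) {
  cat(sprintf("<splice_ensemble> %d members, context %d nt\n",
              length(x$models), x$context_len))
  invisible(x)
}

#' Predict splice tracks for a batch of windows
#'
#' @param predictor a `splice_predictor`.
#' @param windows list of one-hot matrices (or `encoded_window` objects).
#' @return list of track lists, order-preserving.
#' @export
predict_windows <- function(predictor, windows) {
  lapply(windows, function(w) {
    if (inherits(w, "encoded_window")) w <- w$sequence
    predict_window(predictor, w)
  })
}

# -- training ---------------------------------------------------------------

#' Training configuration
#'
#' The training schedule: each model sees an independent random 90% of the
#' gene chunks as its training set (remainder = validation); it is trained
#' for `total_steps_factor` times the number of training chunks, each step
#' visiting one randomly chosen chunk and taking one Adam step per gene
#' (all windows of the gene as one batch, mean cross-entropy). The learning
#' rate starts at `initial_lr` and is halved when training passes 60%, 70%,
#' 80% and 90% of the total chunk-visit steps.
#'
#' @param n_models ensemble size (default 5).
#' @param chunk_fraction_train fraction of chunks used for training (0.90).
#' @param total_steps_factor chunk visits per training chunk (10).
#' @param initial_lr initial Adam learning rate (0.001).
#' @param lr_halving_points sorted fractions of total steps at which the
#'   learning rate halves.
#' @param seed master seed; model `m` trains under a seed derived from it.
#' @return list of class `train_config`.
#' @export
train_config <- function(n_models = 5L, chunk_fraction_train = 0.9,
                         total_steps_factor = 10L, initial_lr = 0.001,
                         lr_halving_points = c(0.6, 0.7, 0.8, 0.9),
                         seed = 1L) {
  stopifnot(chunk_fraction_train > 0, chunk_fraction_train < 1,
            !is.unsorted(lr_halving_points))
  structure(list(n_models = as.integer(n_models),
                 chunk_fraction_train = chunk_fraction_train,
                 total_steps_factor = as.integer(total_steps_factor),
                 initial_lr = initial_lr,
                 lr_halving_points = lr_halving_points,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given training step
#'
#' The rate is `initial_lr` halved once for every schedule boundary already
#' reached: with 100 total steps and the default boundaries the rate is
#' 0.001 through step 59 and 0.0005 from step 60 (the first step at or past
#' the 60% boundary), halving again at 70, 80 and 90.
#'
#' @param step 1-based step index.
#' @param total_steps total training steps.
#' @param initial_lr,halving_points see [train_config()].
#' @return numeric learning rate.
#' @export
lr_schedule <- function(step, total_steps, initial_lr = 0.001,
                        halving_points = c(0.6, 0.7, 0.8, 0.9)) {
  n_halved <- vapply(step, function(s) sum(s >= halving_points * total_steps),
                     numeric(1))
  initial_lr * 0.5^n_halved
}

adam_init <- function(params) {
  zero <- function(v) rapply(list(v), function(x) x * 0, how = "replace")[[1L]]
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd_leaf <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      # iterate the gradient's entries: params may carry extra non-trainable
      # fields (e.g. a block's dilation) that gradients do not
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (nm in keys) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      upd_leaf(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# Mean gradient over all windows of one gene.
gene_gradient <- function(model, windows) {
  g <- NULL
  for (w in windows) {
    fwd <- cnn_forward(model, w$sequence, keep_cache = TRUE)
    gw <- cnn_backward(model, fwd, w$labels)
    g <- add_grads(g, gw, scale = 1)
  }
  rapply(g, function(v) v / length(windows), how = "replace")
}

# Pooled splice-site PR-AUC of a predictor over encoded genes: acceptor and
# donor probabilities at every (unpadded) predicted position, scored against
# the one-hot labels.
validation_pr_auc <- function(model, encoded_genes) {
  scores <- list(); labels <- list(); k <- 0L
  for (gene in encoded_genes) {
    for (w in gene) {
      probs <- predict_window(model, w$sequence)
      keep <- seq_len(w$n_real)
      k <- k + 1L
      scores[[k]] <- c(probs$acceptor[keep], probs$donor[keep])
      labels[[k]] <- c(w$labels[keep, 2L], w$labels[keep, 3L])
    }
  }
  pr_auc(unlist(scores), unlist(labels) > 0.5)
}

#' Train an ensemble of splice prediction networks
#'
#' Implements the chunked training schedule described in [train_config()].
#' With fewer than two chunks the single chunk is used for both training and
#' validation, with a warning.
#'
#' @param chunks list of chunks from [chunk_genes()]; each chunk is a list of
#'   encoded genes (lists of `encoded_window`).
#' @param cfg a [train_config()].
#' @param context_len,channels,kernel,dilations architecture, passed to
#'   [splice_cnn()].
#' @param eval_every record validation PR-AUC every this many steps (also at
#'   the final step); 0 records only the final value.
#' @return a `splice_ensemble` whose `history` holds, per model, the
#'   training-chunk indices, the learning-rate trace and the validation
#'   PR-AUC records.
#' @export
train_splice_models <- function(chunks, cfg = train_config(),
                                context_len = 80L, channels = 12L,
                                kernel = 11L, dilations = c(1L, 1L, 1L, 1L),
                                eval_every = 0L) {
  if (length(chunks) == 0L) stop("no training chunks")
  if (any(vapply(chunks, length, integer(1)) == 0L)) stop("empty chunk")
  models <- vector("list", cfg$n_models)
  history <- vector("list", cfg$n_models)
  for (m in seq_len(cfg$n_models)) {
    seed_m <- derive_seed(cfg$seed, m)
    model <- splice_cnn(context_len, channels, kernel, dilations, seed = seed_m)
    res <- with_seed(seed_m, {
      n_chunks <- length(chunks)
      if (n_chunks < 2L) {
        warning("fewer than 2 chunks: training on all chunks, validation = training data")
        train_ids <- seq_len(n_chunks)
        val_ids <- seq_len(n_chunks)
      } else {
        n_train <- max(1L, floor(cfg$chunk_fraction_train * n_chunks))
        train_ids <- sort(sample.int(n_chunks, n_train))
        val_ids <- setdiff(seq_len(n_chunks), train_ids)
      }
      total_steps <- cfg$total_steps_factor * length(train_ids)
      state <- adam_init(model$params)
      lr_trace <- numeric(total_steps)
      evals <- list()
      for (step in seq_len(total_steps)) {
        lr <- lr_schedule(step, total_steps, cfg$initial_lr, cfg$lr_halving_points)
        lr_trace[step] <- lr
        chunk <- chunks[[sample(train_ids, 1L)]]
        for (gene in chunk) {
          grads <- gene_gradient(model, gene)
          upd <- adam_step(model$params, grads, state, lr)
          model$params <- upd$params
          state <- upd$state
        }
        if (eval_every > 0L && (step %% eval_every == 0L) && step < total_steps) {
          evals[[length(evals) + 1L]] <- list(
            step = step,
            val_pr_auc = validation_pr_auc(model, unlist(chunks[val_ids], recursive = FALSE))
          )
        }
      }
      val_genes <- unlist(chunks[val_ids], recursive = FALSE)
      evals[[length(evals) + 1L]] <- list(
        step = total_steps,
        val_pr_auc = validation_pr_auc(model, val_genes)
      )
      list(model = model,
           history = list(seed = seed_m, train_chunks = train_ids,
                          val_chunks = val_ids, total_steps = total_steps,
                          lr_trace = lr_trace,
                          validation = do.call(rbind, lapply(evals, as.data.frame))))
    })
    models[[m]] <- res$model
    history[[m]] <- res$history
  }
  splice_ensemble(models, history = history)
}

# -- checkpointing ----------------------------------------------------------

#' Save / load a trained predictor
#'
#' Writes each member's weights as an RDS file next to a JSON manifest
#' recording the architecture, class order and seeds.
#'
#' @param predictor a `splice_cnn` or `splice_ensemble`.
#' @param dir checkpoint directory (created if needed).
#' @return `save_predictor` returns `dir` invisibly; `load_predictor`
#'   returns the predictor.
#' @export
save_predictor <- function(predictor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- if (inherits(predictor, "splice_ensemble")) predictor$models else list(predictor)
  manifest <- list(
    n_models = length(models),
    context_len = models[[1L]]$context_len,
    channels = models[[1L]]$channels,
    kernel = models[[1L]]$kernel,
    dilations = models[[1L]]$dilations,
    class_order = LABEL_ORDER,
    seeds = vapply(models, `[[`, integer(1), "seed")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (i in seq_along(models)) {
    saveRDS(models[[i]], file.path(dir, sprintf("model_%d.rds", i)))
  }
  invisible(dir)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  models <- lapply(seq_len(manifest$n_models), function(i) {
    readRDS(file.path(dir, sprintf("model_%d.rds", i)))
  })
  if (length(models) == 1L) models[[1L]] else splice_ensemble(models)
}
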