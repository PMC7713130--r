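#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` over a batch of predicted
#' probabilities. Always non-negative; zero only in the perfect-prediction
#' limit.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels binary labels of the same length.
#' @return scalar loss.
#' @export
bce_loss <- function(probs, labels) {
  if (length(probs) != length(labels)) stop("length mismatch")
  stopifnot(all(probs > 0 & probs < 1), all(labels %in% c(0, 1)))
  -mean(labels * log(probs) + (1 - labels) * log(1 - probs))
}

# numerically stable BCE straight from decoder logits
bce_from_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Training configuration
#'
#' Defaults follow the model's published recipe: Adam at learning rate 5e-4,
#' mini-batch size 256, 15 epochs, dropout 0.1, hidden sizes 64 and 16,
#' summation gate.
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size (the last batch may be smaller).
#' @param epochs number of training epochs.
#' @param dropout dropout rate in `[0, 1)`.
#' @param d1,d2 hidden sizes of the two layers.
#' @param decoder_hidden decoder hidden-layer width; 0 for the plain affine
#'   decoder (see [init_params()]).
#' @param gate aggregation gate name.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @param patience optional early-stopping patience (epochs without
#'   validation improvement); `NULL` disables early stopping.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 256L,
                         epochs = 15L, dropout = 0.1, d1 = 64L, d2 = 16L,
                         decoder_hidden = 64L, gate = "sum", seed = 1L,
                         patience = NULL) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0,
            dropout >= 0, dropout < 1, d1 >= 1, d2 >= 1, decoder_hidden >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 d1 = as.integer(d1), d2 = as.integer(d2),
                 decoder_hidden = as.integer(decoder_hidden), gate = gate,
                 seed = as.integer(seed), patience = patience),
            class = "train_config")
}

# scatter-add pair-level gradients into node rows
scatter_rows <- function(idx, G, n) {
  as.matrix(Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                                 dims = c(n, length(idx))) %*% G)
}

# analytic gradients of mean BCE w.r.t. every parameter, for one batch.
# fw is the cache from model_forward(training = TRUE); pairs in given order.
model_backward <- function(params, fw, Fo, Fs, pairs, labels, gate) {
  variant <- attr(params, "variant")
  E <- fw$E
  n <- nrow(E)
  m <- nrow(pairs)
  d <- ncol(E)
  z <- decode_logits(E, pairs, params, cache = TRUE)
  dc <- attr(z, "cache")
  dz <- (plogis(as.numeric(z)) - labels) / m
  if (!is.null(params$W_d1)) {
    g <- list(w_d = drop(crossprod(dc$h, dz)), b = sum(dz))
    dh <- outer(dz, params$w_d) * (dc$pre > 0)
    g$W_d1 <- crossprod(dc$U, dh)
    g$b_d1 <- colSums(dh)
    dU <- dh %*% t(params$W_d1)
  } else {
    g <- list(w_d = drop(crossprod(dc$U, dz)), b = sum(dz))
    dU <- outer(dz, params$w_d)
  }
  dE <- scatter_rows(pairs[, 1L], dU[, seq_len(d), drop = FALSE], n) +
        scatter_rows(pairs[, 2L], dU[, d + seq_len(d), drop = FALSE], n)

  mul <- function(M, mask) if (is.null(mask)) M else M * mask
  if (variant == "skipgnn") {
    c1 <- fw$l1$cache
    g$W_o1 <- crossprod(fw$FH1d, dE)
    g$W_s1 <- crossprod(fw$FsS1d, dE)
    dH1 <- mul(as.matrix(Fo %*% dE %*% t(params$W_o1)), fw$mH1)
    dS1 <- mul(as.matrix(Fs %*% dE %*% t(params$W_s1)), fw$mS1)
    dA2 <- dS1 * (c1$A2 > 0)
    gb2 <- agg_backward(gate, dA2, c1$R, c1$T2)
    g$W_s <- crossprod(c1$FsS, gb2$dA)
    g$W_sp <- crossprod(c1$FH1, gb2$dB)
    dH1 <- dH1 + as.matrix(Fo %*% gb2$dB %*% t(params$W_sp))
    dA1 <- dH1 * (c1$A1 > 0)
    gb1 <- agg_backward(gate, dA1, c1$P, c1$Q)
    g$W_o <- crossprod(c1$FH, gb1$dA)
    g$W_op <- crossprod(c1$FsS, gb1$dB)
  } else if (variant == "gcn_only") {
    g$W_o1 <- crossprod(fw$FH1d, dE)
    dH1 <- mul(as.matrix(Fo %*% dE %*% t(params$W_o1)), fw$mH1)
    dA1 <- dH1 * (fw$A1 > 0)
    g$W_o <- crossprod(fw$FX, dA1)
  } else { # no_fusion
    d2 <- ncol(fw$FH1d %*% params$W_o1)
    dEo <- dE[, seq_len(d2), drop = FALSE]
    dEs <- dE[, d2 + seq_len(d2), drop = FALSE]
    g$W_o1 <- crossprod(fw$FH1d, dEo)
    g$W_s1 <- crossprod(fw$FsS1d, dEs)
    dH1 <- mul(as.matrix(Fo %*% dEo %*% t(params$W_o1)), fw$mH1)
    dS1 <- mul(as.matrix(Fs %*% dEs %*% t(params$W_s1)), fw$mS1)
    g$W_o <- crossprod(fw$FX, dH1 * (fw$A1o > 0))
    g$W_s <- crossprod(fw$FsX, dS1 * (fw$A1s > 0))
  }
  lapply(g, function(x) if (is.matrix(x)) x else x)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# loss over a sample set with dropout off, canonical pair order
eval_loss <- function(params, X, Fo, Fs, set, gate) {
  fw <- model_forward(params, X, Fo, Fs, gate = gate, training = FALSE)
  z <- decode_logits(fw$E, set$pairs, params)
  bce_from_logits(z, set$labels)
}

#' Train a model with mini-batch Adam and validation-based selection
#'
#' Shuffled mini-batches of labeled pairs are scored by a full-graph forward
#' pass (embeddings are recomputed for all nodes each step; mini-batching
#' applies to the pairs only) and optimized by Adam on the mean binary
#' cross-entropy. After each epoch the validation loss is computed with
#' dropout off; the returned parameters are those of the epoch with the
#' lowest validation loss (ties broken towards the earlier epoch). Fully
#' reproducible for a fixed `config$seed`.
#'
#' @param variant model variant, see [skipgnn_forward()].
#' @param Fo,Fs propagation operators built from training edges only.
#' @param X input feature matrix.
#' @param samples list with `edge_sample_set`s `train` and `valid` (e.g. from
#'   [link_prediction_splits()]).
#' @param config a [train_config()].
#' @return a `skipgnn_fit`: `best_params`, `history` (per-epoch train and
#'   validation loss), `selected_epoch`, plus the variant/gate used.
#' @export
train_skipgnn <- function(variant = c("skipgnn", "gcn_only", "no_fusion"),
                          Fo, Fs, X, samples, config = train_config()) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "train_config"))
  tr <- samples$train
  va <- samples$valid
  if (!nrow(tr$pairs)) stop("training split is empty")
  withr::with_seed(config$seed, {
    params <- init_params(variant, d_in = ncol(X), d1 = config$d1,
                          d2 = config$d2,
                          decoder_hidden = config$decoder_hidden %||% 64L,
                          seed = NULL)
    state <- adam_init(params)
    best <- params
    best_val <- Inf
    best_epoch <- 0L
    hist <- data.frame(epoch = integer(0), train_loss = double(0),
                       val_loss = double(0))
    n <- nrow(tr$pairs)
    since_best <- 0L
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        bi <- perm[start:min(start + config$batch_size - 1L, n)]
        fw <- model_forward(params, X, Fo, Fs, gate = config$gate,
                            dropout = config$dropout, training = TRUE)
        bp <- tr$pairs[bi, , drop = FALSE]
        z <- decode_logits(fw$E, bp, params)
        loss <- bce_from_logits(z, tr$labels[bi])
        if (!is.finite(loss)) stop("training diverged at epoch ", ep)
        grads <- model_backward(params, fw, Fo, Fs, bp, tr$labels[bi],
                                config$gate)
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      vl <- eval_loss(params, X, Fo, Fs, va, config$gate)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_loss = vl))
      if (vl < best_val) {
        best_val <- vl
        best <- params
        best_epoch <- ep
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (!is.null(config$patience) && since_best >= config$patience) break
      }
    }
    structure(list(best_params = best, history = hist,
                   selected_epoch = best_epoch, variant = variant,
                   gate = config$gate, config = config),
              class = "skipgnn_fit")
  })
}

#' @export
print.skipgnn_fit <- function(x, ...) {
  cat("skipgnn_fit:", x$variant, "variant,", nrow(x$history),
      "epochs trained, selected epoch", x$selected_epoch, "\n")
  if (nrow(x$history)) {
    cat(sprintf("validation loss at selection: %.4f\n",
                x$history$val_loss[x$selected_epoch]))
  }
  invisible(x)
}

#' Predict interaction probabilities with a trained model
#'
#' Inference-mode forward pass (dropout off, symmetrized pair scoring by
#' default); deterministic.
#'
#' @param object a `skipgnn_fit` from [train_skipgnn()].
#' @param Fo,Fs,X the propagation operators and features used in training.
#' @param pairs `m x 2` integer matrix of node pairs to score.
#' @param symmetrize average over both pair orders (default `TRUE`).
#' @param ... unused.
#' @return numeric vector of probabilities, one per pair.
#' @export
predict.skipgnn_fit <- function(object, Fo, Fs, X, pairs,
                                symmetrize = TRUE, ...) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) return(numeric(0))
  if (max(pairs) > nrow(X) || min(pairs) < 1L) {
    stop("unknown node index in pairs")
  }
  skipgnn_forward(object$variant, object$best_params, X, Fo, Fs, pairs,
                  gate = object$gate, training = FALSE,
                  symmetrize = symmetrize)
}
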