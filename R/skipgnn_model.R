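#' Aggregation gate
#'
#' Elementwise operator combining the original-graph and skip-graph streams:
#' `sum` (A + B, the default and best-performing gate), `weighted_l1`
#' (|A - B|) and `hadamard` (A * B). All three are symmetric in their
#' arguments.
#'
#' @param gate gate name.
#' @param A,B matrices of identical shape.
#' @return matrix of the same shape.
#' @export
agg <- function(gate = c("sum", "weighted_l1", "hadamard"), A, B) {
  gate <- match.arg(gate)
  if (!identical(dim(A), dim(B))) stop("agg: shape mismatch")
  switch(gate, sum = A + B, weighted_l1 = abs(A - B), hadamard = A * B)
}

# gradients of agg w.r.t. both arguments given upstream gradient dC
agg_backward <- function(gate, dC, A, B) {
  switch(gate,
    sum = list(dA = dC, dB = dC),
    weighted_l1 = {
      s <- sign(A - B)
      list(dA = dC * s, dB = -dC * s)
    },
    hadamard = list(dA = dC * B, dB = dC * A))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize model parameters
#'
#' Glorot-uniform weight matrices and a zero decoder bias for the requested
#' variant. The full model carries four fusion matrices in the first layer
#' (`W_o`, `W_op`, `W_s`, `W_sp`) and two output matrices (`W_o1`, `W_s1`);
#' `gcn_only` keeps only the original-graph path; `no_fusion` keeps two
#' independent stacks whose final embeddings are concatenated, doubling the
#' decoder input width.
#'
#' @param variant `"skipgnn"`, `"gcn_only"` or `"no_fusion"`.
#' @param d_in input feature dimension.
#' @param d1 first hidden size (default 64).
#' @param d2 final embedding size (default 16).
#' @param decoder_hidden width of the decoder's ReLU hidden layer (default
#'   64). `0` gives the plain affine decoder
#'   `logistic(w_d . concat(E_i, E_j) + b)`; note the affine form scores a
#'   pair additively in the two embeddings, so it cannot express pair
#'   interactions and is kept only as the minimal decoder.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return a `skipgnn_params` list of weight matrices plus decoder weights
#'   `w_d`, `b` (and `W_d1`, `b_d1` when `decoder_hidden > 0`) and a `dims`
#'   attribute.
#' @export
init_params <- function(variant = c("skipgnn", "gcn_only", "no_fusion"),
                        d_in, d1 = 64L, d2 = 16L, decoder_hidden = 64L,
                        seed = NULL) {
  variant <- match.arg(variant)
  dec_in <- if (variant == "no_fusion") 4L * d2 else 2L * d2
  draw <- function() {
    ps <- switch(variant,
      skipgnn = list(
        W_o = glorot(d_in, d1), W_op = glorot(d_in, d1),
        W_s = glorot(d_in, d1), W_sp = glorot(d1, d1),
        W_o1 = glorot(d1, d2), W_s1 = glorot(d1, d2)),
      gcn_only = list(
        W_o = glorot(d_in, d1), W_o1 = glorot(d1, d2)),
      no_fusion = list(
        W_o = glorot(d_in, d1), W_s = glorot(d_in, d1),
        W_o1 = glorot(d1, d2), W_s1 = glorot(d1, d2)))
    if (decoder_hidden > 0L) {
      ps$W_d1 <- glorot(dec_in, decoder_hidden)
      ps$b_d1 <- numeric(decoder_hidden)
      ps$w_d <- drop(glorot(decoder_hidden, 1L))
    } else {
      ps$w_d <- drop(glorot(dec_in, 1L))
    }
    ps$b <- 0
    structure(ps, class = "skipgnn_params",
              variant = variant,
              dims = c(d_in = d_in, d1 = d1, d2 = d2,
                       decoder_hidden = decoder_hidden))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# inverted dropout: NULL mask means identity (inference)
make_dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

apply_mask <- function(X, mask) if (is.null(mask)) X else X * mask

#' One iterative-fusion layer
#'
#' The propagation rule fusing the two streams: first the original-graph
#' embedding is updated from its own stream and the skip stream,
#' `H1 = relu(AGG(F H W_o, F_s S W_op))`; then the skip-graph embedding is
#' updated using the *freshly updated* `H1`,
#' `S1 = relu(AGG(F_s S W_s, F H1 W_sp))`. Dropout is applied to the layer
#' inputs `H` and `S` during training only.
#'
#' @param H,S current-layer node embeddings for the original and skip graph.
#' @param Fo,Fs renormalized propagation operators (see [renormalize()]).
#' @param W_o,W_op,W_s,W_sp layer weight matrices.
#' @param gate aggregation gate, see [agg()].
#' @param dropout dropout rate in `[0, 1)`.
#' @param training logical; dropout is active only when `TRUE`.
#' @return list with updated `H`, `S` and a `cache` for backpropagation.
#' @export
fusion_layer <- function(H, S, Fo, Fs, W_o, W_op, W_s, W_sp,
                         gate = "sum", dropout = 0, training = FALSE) {
  mH <- if (training) make_dropout_mask(nrow(H), ncol(H), dropout) else NULL
  mS <- if (training) make_dropout_mask(nrow(S), ncol(S), dropout) else NULL
  Hd <- apply_mask(H, mH)
  Sd <- apply_mask(S, mS)
  FH <- as.matrix(Fo %*% Hd)
  FsS <- as.matrix(Fs %*% Sd)
  P <- FH %*% W_o
  Q <- FsS %*% W_op
  A1 <- agg(gate, P, Q)
  H1 <- relu(A1)
  FH1 <- as.matrix(Fo %*% H1)
  R <- FsS %*% W_s
  T2 <- FH1 %*% W_sp
  A2 <- agg(gate, R, T2)
  S1 <- relu(A2)
  if (!all(is.finite(H1)) || !all(is.finite(S1))) {
    stop("fusion_layer: non-finite embeddings (divergence)")
  }
  list(H = H1, S = S1,
       cache = list(mH = mH, mS = mS, FH = FH, FsS = FsS, FH1 = FH1,
                    P = P, Q = Q, R = R, T2 = T2, A1 = A1, A2 = A2,
                    H1 = H1, gate = gate))
}

#' Final node embedding
#'
#' Output layer `E = F H1 W_o1 + F_s S1 W_s1`: a summation gate with no
#' activation, since the embedding feeds straight into the decoder.
#'
#' @param H1,S1 embeddings produced by [fusion_layer()].
#' @param Fo,Fs propagation operators.
#' @param W_o1,W_s1 output weight matrices.
#' @return `N x d2` numeric matrix.
#' @export
final_embedding <- function(H1, S1, Fo, Fs, W_o1, W_s1) {
  as.matrix(Fo %*% H1 %*% W_o1) + as.matrix(Fs %*% S1 %*% W_s1)
}

#' Decode one node pair into an interaction probability
#'
#' `p_ij = logistic(w_d . concat(E_i, E_j) + b)`. Concatenation is the
#' combination function, so the raw score is order-dependent; see
#' [skipgnn_forward()] for the symmetrized inference-time score.
#'
#' @param Ei,Ej embedding rows of the two nodes.
#' @param w_d decoder weight vector of length `2 * length(Ei)`.
#' @param b decoder bias scalar.
#' @return probability in (0, 1).
#' @export
decode_pair <- function(Ei, Ej, w_d, b) {
  stopifnot(length(w_d) == length(Ei) + length(Ej))
  plogis(sum(w_d * c(Ei, Ej)) + b)
}

# vectorized decoder logits for a pair matrix; with a hidden layer when the
# parameter set carries one. Returns the logits, with the decoder cache
# attached for backprop when cache = TRUE.
decode_logits <- function(E, pairs, params, cache = FALSE) {
  U <- cbind(E[pairs[, 1L], , drop = FALSE],
             E[pairs[, 2L], , drop = FALSE])
  if (!is.null(params$W_d1)) {
    pre <- sweep(U %*% params$W_d1, 2L, params$b_d1, "+")
    h <- relu(pre)
    z <- drop(h %*% params$w_d) + params$b
    if (cache) attr(z, "cache") <- list(U = U, pre = pre, h = h)
    z
  } else {
    z <- drop(U %*% params$w_d) + params$b
    if (cache) attr(z, "cache") <- list(U = U)
    z
  }
}

# full forward pass; returns E plus caches needed for gradients
model_forward <- function(params, X, Fo, Fs, gate = "sum", dropout = 0,
                          training = FALSE) {
  variant <- attr(params, "variant")
  if (variant == "skipgnn") {
    l1 <- fusion_layer(X, X, Fo, Fs, params$W_o, params$W_op, params$W_s,
                       params$W_sp, gate = gate, dropout = dropout,
                       training = training)
    mH1 <- if (training) {
      make_dropout_mask(nrow(l1$H), ncol(l1$H), dropout)
    } else NULL
    mS1 <- if (training) {
      make_dropout_mask(nrow(l1$S), ncol(l1$S), dropout)
    } else NULL
    H1d <- apply_mask(l1$H, mH1)
    S1d <- apply_mask(l1$S, mS1)
    FH1d <- as.matrix(Fo %*% H1d)
    FsS1d <- as.matrix(Fs %*% S1d)
    E <- FH1d %*% params$W_o1 + FsS1d %*% params$W_s1
    list(E = E, l1 = l1, mH1 = mH1, mS1 = mS1, FH1d = FH1d, FsS1d = FsS1d)
  } else if (variant == "gcn_only") {
    mX <- if (training) make_dropout_mask(nrow(X), ncol(X), dropout) else NULL
    Xd <- apply_mask(X, mX)
    FX <- as.matrix(Fo %*% Xd)
    A1 <- FX %*% params$W_o
    H1 <- relu(A1)
    mH1 <- if (training) make_dropout_mask(nrow(H1), ncol(H1), dropout) else NULL
    H1d <- apply_mask(H1, mH1)
    FH1d <- as.matrix(Fo %*% H1d)
    E <- FH1d %*% params$W_o1
    list(E = E, mX = mX, FX = FX, A1 = A1, H1 = H1, mH1 = mH1, FH1d = FH1d)
  } else { # no_fusion: two independent GCN stacks, concatenated outputs
    mX <- if (training) make_dropout_mask(nrow(X), ncol(X), dropout) else NULL
    Xd <- apply_mask(X, mX)
    FX <- as.matrix(Fo %*% Xd)
    FsX <- as.matrix(Fs %*% Xd)
    A1o <- FX %*% params$W_o
    H1 <- relu(A1o)
    A1s <- FsX %*% params$W_s
    S1 <- relu(A1s)
    mH1 <- if (training) make_dropout_mask(nrow(H1), ncol(H1), dropout) else NULL
    mS1 <- if (training) make_dropout_mask(nrow(S1), ncol(S1), dropout) else NULL
    H1d <- apply_mask(H1, mH1)
    S1d <- apply_mask(S1, mS1)
    FH1d <- as.matrix(Fo %*% H1d)
    FsS1d <- as.matrix(Fs %*% S1d)
    Eo <- FH1d %*% params$W_o1
    Es <- FsS1d %*% params$W_s1
    list(E = cbind(Eo, Es), mX = mX, FX = FX, FsX = FsX, A1o = A1o,
         A1s = A1s, H1 = H1, S1 = S1, mH1 = mH1, mS1 = mS1,
         FH1d = FH1d, FsS1d = FsS1d)
  }
}

#' Model forward pass: probabilities for a list of node pairs
#'
#' Runs the requested variant end to end — fusion layer(s), final embedding,
#' decoder — and returns one interaction probability per pair. At inference
#' (`training = FALSE`) dropout is off and, by default, the score is
#' symmetrized as `(p_ij + p_ji) / 2` since undirected pairs have no natural
#' order; during training pairs are scored in the given (canonical) order.
#'
#' @param variant `"skipgnn"` (full model), `"gcn_only"` (skip graph
#'   removed; a plain two-layer GCN) or `"no_fusion"` (two independent
#'   stacks, concatenated).
#' @param params a `skipgnn_params` object matching the variant.
#' @param X input feature matrix (`N x d_in`).
#' @param Fo,Fs propagation operators of the original and skip graph.
#' @param pairs `m x 2` integer matrix of node pairs.
#' @param gate aggregation gate.
#' @param dropout dropout rate used when `training = TRUE`.
#' @param training logical.
#' @param seed optional seed for the dropout draw.
#' @param symmetrize average the two pair orders at inference.
#' @return numeric vector of probabilities in (0, 1), one per pair.
#' @export
skipgnn_forward <- function(variant = c("skipgnn", "gcn_only", "no_fusion"),
                            params, X, Fo, Fs, pairs, gate = "sum",
                            dropout = 0, training = FALSE, seed = NULL,
                            symmetrize = !training) {
  variant <- match.arg(variant)
  if (!identical(attr(params, "variant"), variant)) {
    stop("params were initialized for variant '", attr(params, "variant"),
         "', not '", variant, "'")
  }
  if (nrow(X) != nrow(Fo)) stop("X row count must equal node count")
  pairs <- as.matrix(pairs)
  if (length(pairs) && max(pairs) > nrow(X)) stop("unknown node index in pairs")
  run <- function() {
    fw <- model_forward(params, X, Fo, Fs, gate = gate, dropout = dropout,
                        training = training)
    if (!nrow(pairs)) return(numeric(0))
    p <- plogis(decode_logits(fw$E, pairs, params))
    if (symmetrize) {
      p <- (p + plogis(decode_logits(fw$E, pairs[, 2:1, drop = FALSE],
                                     params))) / 2
    }
    p
  }
  if (training && !is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Final embeddings of a trained or given parameter set
#'
#' Inference-mode pass returning the final node embedding matrix `E` (used
#' e.g. for silhouette diagnostics by node type).
#'
#' @inheritParams skipgnn_forward
#' @return `N x d2` (or `N x 2 d2` for `no_fusion`) matrix.
#' @export
skipgnn_embed <- function(params, X, Fo, Fs, gate = "sum") {
  model_forward(params, X, Fo, Fs, gate = gate, dropout = 0,
                training = FALSE)$E
}
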