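#' @useDynLib skipgnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# CSR slots of a symmetric sparse adjacency (0-based, sorted per node)
adjacency_csr <- function(A) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  list(indptr = A@p, indices = A@i, n = nrow(A))
}

#' Generate second-order biased random walks
#'
#' node2vec-style walk corpus: `walks_per_node` walks of length `walk_length`
#' from every non-isolated node. The second-order transition gives
#' unnormalized weight `1/p` to returning to the previous node, 1 to a
#' neighbor of the previous node and `1/q` to all other neighbors; with
#' `p = q = 1` walks are uniform first-order random walks.
#'
#' @param A symmetric binary adjacency matrix of the training graph.
#' @param p return parameter. @param q in-out parameter.
#' @param walk_length nodes per walk (>= 1).
#' @param walks_per_node walks started from each non-isolated node.
#' @param seed integer seed; walks are deterministic given the seed.
#' @return a `walk_corpus`: list of integer node-index sequences plus the
#'   walk parameters and node count.
#' @export
generate_walks <- function(A, p = 1, q = 1, walk_length = 80L,
                           walks_per_node = 10L, seed = 1L) {
  stopifnot(walk_length >= 1L, walks_per_node >= 1L, p > 0, q > 0)
  csr <- adjacency_csr(A)
  walks <- cpp_generate_walks(csr$indptr, csr$indices, p, q,
                              as.integer(walk_length),
                              as.integer(walks_per_node), as.integer(seed))
  structure(list(walks = walks, n_nodes = csr$n, walk_length = walk_length,
                 walks_per_node = walks_per_node, p = p, q = q),
            class = "walk_corpus")
}

#' Train skip-gram node embeddings on a walk corpus
#'
#' Standard skip-gram with negative sampling (dynamic window, unigram^0.75
#' negative distribution, linearly decaying learning rate), run
#' single-threaded so results are bit-reproducible for a fixed seed. Nodes
#' absent from every walk (isolated nodes) receive a seeded Gaussian row
#' scaled by `1/sqrt(dim)` so the matrix is total over nodes.
#'
#' @param corpus a `walk_corpus` from [generate_walks()].
#' @param dim embedding dimension.
#' @param window maximum context window (actual window drawn uniformly from
#'   1..window per position).
#' @param epochs passes over the corpus; `epochs = 0` returns the seeded
#'   uniform initialization unchanged.
#' @param negative negative samples per context pair.
#' @param alpha initial learning rate.
#' @param seed integer seed.
#' @return `N x dim` numeric matrix of node embeddings.
#' @export
train_skipgram <- function(corpus, dim = 128L, window = 10L, epochs = 5L,
                           negative = 5L, alpha = 0.025, seed = 1L) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (dim <= 0) stop("dim must be positive")
  if (!length(corpus$walks)) stop("corpus is empty")
  tokens <- unlist(corpus$walks, use.names = FALSE)
  lens <- lengths(corpus$walks)
  X <- cpp_train_skipgram(tokens, lens, corpus$n_nodes, as.integer(dim),
                          as.integer(window), as.integer(epochs),
                          as.integer(negative), alpha, as.integer(seed))
  seen <- tabulate(tokens, nbins = corpus$n_nodes) > 0
  if (any(!seen)) {
    X[!seen, ] <- withr::with_seed(derive_seed(seed, 97), {
      matrix(stats::rnorm(sum(!seen) * dim), ncol = dim) / sqrt(dim)
    })
  }
  X
}

#' Input node features for the model
#'
#' Dispatches between the initializers for `H^(0) = S^(0) = X`:
#' * `node2vec` — [generate_walks()] + [train_skipgram()] on the training
#'   adjacency (the default; walk parameters via `...`),
#' * `random` — seeded standard-normal matrix scaled by `1/sqrt(dim)`,
#' * `spectral` — the `dim` leading eigenvectors of the renormalized
#'   operator of `A` (dense eigendecomposition; intended for small graphs).
#'
#' @param A symmetric binary training adjacency.
#' @param method initializer name.
#' @param dim embedding dimension.
#' @param seed integer seed.
#' @param ... passed on to [generate_walks()] / [train_skipgram()].
#' @return `N x dim` numeric matrix, finite everywhere.
#' @export
init_features <- function(A, method = c("node2vec", "random", "spectral"),
                          dim = 128L, seed = 1L, ...) {
  method <- match.arg(method)
  if (dim < 1) stop("dim must be >= 1")
  n <- nrow(A)
  X <- switch(method,
    random = withr::with_seed(seed, {
      matrix(stats::rnorm(n * dim), ncol = dim) / sqrt(dim)
    }),
    spectral = {
      Fop <- renormalize(A)
      eg <- eigen(as.matrix(Fop), symmetric = TRUE)
      k <- min(dim, n)
      V <- eg$vectors[, seq_len(k), drop = FALSE]
      # fix sign so the largest-magnitude entry of each column is positive
      for (c in seq_len(k)) {
        piv <- which.max(abs(V[, c]))
        if (V[piv, c] < 0) V[, c] <- -V[, c]
      }
      if (k < dim) V <- cbind(V, matrix(0, n, dim - k))
      V
    },
    node2vec = {
      dots <- list(...)
      walk_args <- dots[names(dots) %in% c("p", "q", "walk_length",
                                           "walks_per_node")]
      sg_args <- dots[names(dots) %in% c("window", "epochs", "negative",
                                         "alpha")]
      corpus <- do.call(generate_walks,
                        c(list(A = A, seed = seed), walk_args))
      if (!length(corpus$walks)) {
        return(withr::with_seed(seed, {
          matrix(stats::rnorm(n * dim), ncol = dim) / sqrt(dim)
        }))
      }
      do.call(train_skipgram,
              c(list(corpus = corpus, dim = dim, seed = seed), sg_args))
    })
  if (!all(is.finite(X))) stop("non-finite entries in feature matrix")
  X
}
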