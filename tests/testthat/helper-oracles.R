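# independent oracles used across the suite; deliberately naive and
# structurally unrelated to the package implementation

# triple-nested-loop enumeration of 2-paths
oracle_skip_adjacency <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (k in seq_len(n)) {
      if (A[i, k] == 1 && A[k, j] == 1) {
        S[i, j] <- 1
        break
      }
    }
  }
  S
}

# literal dense transcription of the layer updates and output layer
oracle_fusion <- function(X, Fo, Fs, params, gate = "sum") {
  Fo <- as.matrix(Fo)
  Fs <- as.matrix(Fs)
  gfun <- switch(gate, sum = `+`, weighted_l1 = function(a, b) abs(a - b),
                 hadamard = `*`)
  act <- function(m) pmax(m, 0)
  H1 <- act(gfun(Fo %*% X %*% params$W_o, Fs %*% X %*% params$W_op))
  S1 <- act(gfun(Fs %*% X %*% params$W_s, Fo %*% H1 %*% params$W_sp))
  E <- Fo %*% H1 %*% params$W_o1 + Fs %*% S1 %*% params$W_s1
  list(H1 = H1, S1 = S1, E = E)
}

# enumerate every threshold by hand for average precision
oracle_pr_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(thr))
  P <- sum(labels == 1)
  for (k in seq_along(thr)) {
    sel <- scores >= thr[k]
    prec[k] <- sum(labels[sel] == 1) / sum(sel)
    rec[k] <- sum(labels[sel] == 1) / P
  }
  sum(prec * diff(c(0, rec)))
}

# all positive/negative comparisons, ties worth 1/2
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Erdos-Renyi graph as an edge matrix, independent of the package generators
random_er_edges <- function(n, p, seed) {
  withr::with_seed(seed, {
    idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    hit <- stats::runif(nrow(idx)) < p
    idx[hit, , drop = FALSE]
  })
}

random_er_network <- function(n, p, seed) {
  interaction_network(random_er_edges(n, p, seed),
                      node_ids = paste0("v", seq_len(n)))
}

# small bipartite benchmark shrunk for fast method-level tests
small_benchmark <- function(seed) {
  generate_bipartite_cluster(n_left = 80L, n_right = 40L, k = 4L,
                             p_in = 0.4, p_out = 0.02, seed = seed)
}

# textbook silhouette on a tiny instance, straight a/b arithmetic
oracle_silhouette <- function(E, types) {
  D <- as.matrix(stats::dist(E))
  s <- numeric(nrow(E))
  for (i in seq_len(nrow(E))) {
    own <- setdiff(which(types == types[i]), i)
    a <- mean(D[i, own])
    others <- setdiff(unique(types), types[i])
    b <- min(sapply(others, function(t) mean(D[i, types == t])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
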