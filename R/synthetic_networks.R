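#' Bipartite clustered interaction network generator
#'
#' Emulates heterogeneous interaction networks (drug-target, gene-disease):
#' two node types where only cross-type edges exist, and entities of the same
#' type share interaction partners when they belong to the same latent
#' cluster. Each node is assigned uniformly to one of `k` clusters; a
#' cross-type pair is linked independently with probability `p_in` when the
#' two nodes share a cluster and `p_out` otherwise. Because all direct edges
#' are between types, same-type similarity is visible only through the skip
#' graph — the regime the skip-similarity principle targets.
#'
#' @param n_left,n_right node counts of the two types.
#' @param k number of latent clusters.
#' @param p_in within-cluster cross-type edge probability.
#' @param p_out between-cluster cross-type edge probability, `< p_in`.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return an [interaction_network] with `node_types` `"left"`/`"right"` and
#'   cluster assignments in `metadata$cluster`.
#' @export
generate_bipartite_cluster <- function(n_left = 300L, n_right = 150L,
                                       k = 10L, p_in = 0.3, p_out = 0.01,
                                       seed = 0L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1, k >= 1,
            k <= min(n_left, n_right))
  withr::with_seed(seed, {
    cl_left <- sample.int(k, n_left, replace = TRUE)
    cl_right <- sample.int(k, n_right, replace = TRUE)
    g <- expand.grid(i = seq_len(n_left), j = seq_len(n_right))
    prob <- ifelse(cl_left[g$i] == cl_right[g$j], p_in, p_out)
    hit <- stats::rbinom(nrow(g), 1L, prob) == 1L
    edges <- cbind(g$i[hit], n_left + g$j[hit])
  })
  ids <- c(paste0("L", seq_len(n_left)), paste0("R", seq_len(n_right)))
  interaction_network(
    edges, node_ids = ids,
    node_types = rep(c("left", "right"), c(n_left, n_right)),
    metadata = list(cluster = c(cl_left, cl_right),
                    config = list(n_left = n_left, n_right = n_right, k = k,
                                  p_in = p_in, p_out = p_out, seed = seed))
  )
}

#' Stochastic block model generator
#'
#' Standard undirected SBM emulating homogeneous interaction networks
#' (drug-drug, protein-protein): `n` nodes in `k` uniformly assigned blocks,
#' within-block pairs linked with probability `p_in` and between-block pairs
#' with `p_out`. No self-loops.
#'
#' @param n node count.
#' @param k block count.
#' @param p_in,p_out within-/between-block edge probabilities.
#' @param seed integer seed.
#' @return an [interaction_network] with block labels in `metadata$block`.
#' @export
generate_sbm <- function(n = 200L, k = 4L, p_in = 0.2, p_out = 0.01,
                         seed = 0L) {
  stopifnot(p_out >= 0, p_out <= p_in, p_in <= 1, k >= 1, n >= 2)
  withr::with_seed(seed, {
    block <- sample.int(k, n, replace = TRUE)
    idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    prob <- ifelse(block[idx[, 1L]] == block[idx[, 2L]], p_in, p_out)
    hit <- stats::rbinom(nrow(idx), 1L, prob) == 1L
    edges <- idx[hit, , drop = FALSE]
  })
  interaction_network(
    edges, node_ids = paste0("n", seq_len(n)),
    metadata = list(block = block,
                    config = list(n = n, k = k, p_in = p_in, p_out = p_out,
                                  seed = seed))
  )
}

#' Canonical tiny fixture graphs
#'
#' Small named graphs with hand-checkable skip graphs, used throughout the
#' unit tests: `path3` (a-b-c), `cycle4`, `triangle`, `star4` (one hub, three
#' leaves) and `two_cliques` (two disjoint K5s).
#'
#' @param name fixture name.
#' @return an [interaction_network].
#' @export
fixture_network <- function(name = c("path3", "cycle4", "triangle", "star4",
                                     "two_cliques")) {
  name <- match.arg(name)
  edges <- switch(name,
    path3 = rbind(c(1, 2), c(2, 3)),
    cycle4 = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
    triangle = rbind(c(1, 2), c(2, 3), c(1, 3)),
    star4 = rbind(c(1, 2), c(1, 3), c(1, 4)),
    two_cliques = {
      k5 <- t(utils::combn(5, 2))
      rbind(k5, k5 + 5L)
    })
  n <- max(edges)
  meta <- if (name == "two_cliques") {
    list(block = rep(1:2, each = 5L))
  } else list()
  interaction_network(edges, node_ids = letters[seq_len(n)], metadata = meta)
}
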