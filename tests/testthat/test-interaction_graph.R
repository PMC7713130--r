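test_that("edge lists are deduplicated, self-loops dropped, ids by first appearance", {
  f <- withr::local_tempfile(lines = c("a b", "b a", "a b"))
  net <- load_edge_list(f)
  expect_equal(net$N, 2L)
  expect_equal(net$M, 1L)
  expect_equal(net$node_ids, c("a", "b"))

  f2 <- withr::local_tempfile(lines = c("a a", "a b"))
  expect_warning(net2 <- load_edge_list(f2), "self-loop")
  expect_equal(net2$N, 2L)
  expect_equal(net2$M, 1L)

  expect_error(load_edge_list(withr::local_tempfile(lines = "# only comment")),
               "empty")
  expect_error(load_edge_list(withr::local_tempfile(lines = c("a b", "c"))),
               "line 2")
})

test_that("typed three-column files keep node types", {
  set.seed(3)
  # 10 typed nodes, 12 unique cross-type pairs; oracle: build the set by hand
  drugs <- paste0("d", 1:5)
  prots <- paste0("p", 1:5)
  pairs <- unique(cbind(sample(drugs, 30, TRUE), sample(prots, 30, TRUE)))[1:12, ]
  lines <- paste(pairs[, 1], pairs[, 2], "drug:protein")
  f <- withr::local_tempfile(lines = lines)
  net <- load_edge_list(f, format = "typed_three_column")
  expect_equal(net$N, length(unique(c(pairs))))
  expect_equal(net$M, nrow(unique(pairs)))
  expect_setequal(unique(net$node_types), c("drug", "protein"))
  expect_true(all(net$node_types[match(pairs[, 1], net$node_ids)] == "drug"))
})

test_that("average degree matches published interaction-network statistics", {
  expect_equal(round(average_degree(7343, 15139), 2), 4.12)   # drug-target
  expect_equal(round(average_degree(1514, 48514), 2), 64.09)  # drug-drug
  expect_equal(average_degree(fixture_network("triangle")), 2.0)
})

test_that("adjacency is symmetric, binary, zero-diagonal and counts edges", {
  A <- build_adjacency(fixture_network("path3"))
  expect_equal(as.matrix(A),
               matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3), ignore_attr = TRUE)
  empty <- interaction_network(matrix(integer(0), ncol = 2), c("a", "b"))
  expect_equal(sum(build_adjacency(empty)), 0)
  net <- random_er_network(20, 0.2, seed = 11)
  A <- build_adjacency(net)
  expect_equal(as.matrix(A), t(as.matrix(A)))
  expect_equal(sum(A), 2 * net$M)
})

test_that("skip graph equals hand-derivable two-hop structure on fixtures", {
  skip_of <- function(name) {
    as.matrix(build_skip_adjacency(build_adjacency(fixture_network(name))))
  }
  s <- skip_of("path3")                        # a-b-c: only (a,c)
  expect_equal(sum(s), 2)
  expect_equal(s[1, 3], 1)
  s <- skip_of("cycle4")                       # diagonals only
  expect_equal(sum(s), 4)
  expect_equal(s[1, 3] + s[2, 4], 2)
  s <- skip_of("triangle")                     # its own adjacency
  expect_equal(s, as.matrix(build_adjacency(fixture_network("triangle"))),
               ignore_attr = TRUE)
  s <- skip_of("star4")                        # leaves form a triangle
  expect_equal(sum(s[1, ]), 0)
  expect_equal(sum(s[-1, -1]), 6)
})

test_that("skip graph matches brute-force 2-path enumeration on random graphs", {
  for (i in 1:25) {
    n <- sample(5:50, 1)
    p <- sample(seq(0.05, 0.5, by = 0.05), 1)
    A <- build_adjacency(random_er_network(n, p, seed = i))
    expect_equal(as.matrix(build_skip_adjacency(A)), oracle_skip_adjacency(A),
                 ignore_attr = TRUE)
  }
})

test_that("bipartite skip graphs contain only within-type edges", {
  for (s in 1:5) {
    net <- generate_bipartite_cluster(40, 20, k = 3, p_in = 0.4,
                                      p_out = 0.05, seed = s)
    As <- build_skip_adjacency(build_adjacency(net))
    ij <- Matrix::which(As != 0, arr.ind = TRUE)
    expect_true(all(net$node_types[ij[, 1]] == net$node_types[ij[, 2]]))
  }
})

test_that("renormalized operator has the closed forms and bounded spectrum", {
  one_edge <- interaction_network(rbind(c(1, 2)), c("a", "b"))
  Fo <- renormalize(build_adjacency(one_edge))
  expect_equal(as.matrix(Fo), matrix(0.5, 2, 2), ignore_attr = TRUE)

  empty <- interaction_network(matrix(integer(0), ncol = 2), c("a", "b", "c"))
  expect_equal(as.matrix(renormalize(build_adjacency(empty))), diag(3),
               ignore_attr = TRUE)

  A <- build_adjacency(random_er_network(30, 0.15, seed = 2))
  Fo <- renormalize(A)
  ev <- eigen(as.matrix(Fo), symmetric = TRUE, only.values = TRUE)$values
  expect_lte(max(abs(ev)), 1 + 1e-9)
  # nonnegative entries; sqrt of the renormalized degree is the unit
  # eigenvector (F v = v with v = sqrt(deg + 1)); permutation consistency
  expect_true(all(Fo@x >= 0))
  v <- sqrt(Matrix::rowSums(A) + 1)
  expect_equal(as.numeric(Fo %*% v), v, tolerance = 1e-12)
  perm <- withr::with_seed(5, sample.int(30))
  P <- diag(30)[, perm]
  Ap <- as.matrix(A)[perm, perm]
  expect_equal(as.matrix(renormalize(Matrix::Matrix(Ap, sparse = TRUE))),
               t(P) %*% as.matrix(renormalize(A)) %*% P,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("edge splitting uses floor-then-remainder rounding and is seeded", {
  big <- random_er_network(40, 0.35, seed = 7)      # ~270 edges
  net100 <- big
  net100$edges <- big$edges[1:100, ]
  net100$M <- 100L
  sp <- split_edges(net100, seed = 4)
  expect_equal(vapply(sp, nrow, 1L), c(train = 70L, valid = 10L, test = 20L))

  net101 <- big
  net101$edges <- big$edges[1:101, ]
  net101$M <- 101L
  sp <- split_edges(net101, seed = 4)
  expect_equal(vapply(sp, nrow, 1L), c(train = 70L, valid = 10L, test = 21L))

  expect_identical(split_edges(net100, seed = 9), split_edges(net100, seed = 9))
  small <- random_er_network(5, 0.5, seed = 1)
  small$edges <- small$edges[1:4, , drop = FALSE]
  small$M <- 4L
  expect_error(split_edges(small), "at least 10")
})

test_that("negative sampling avoids positives, honors exclusions and types", {
  k4 <- interaction_network(t(utils::combn(4, 2)), letters[1:4])
  expect_error(sample_negatives(k4, 1), "complement exhausted")

  p3 <- fixture_network("path3")
  neg <- sample_negatives(p3, 1, seed = 1)
  expect_equal(as.vector(neg), c(1L, 3L))   # the single non-edge

  bip <- generate_bipartite_cluster(5, 5, k = 1, p_in = 0.45, p_out = 0,
                                    seed = 3)
  n <- 10L
  neg <- sample_negatives(bip, n, seed = 2)
  expect_equal(nrow(neg), n)
  expect_true(all(bip$node_types[neg[, 1]] != bip$node_types[neg[, 2]]))
  pos_keys <- paste(bip$edges[, 1], bip$edges[, 2])
  expect_false(any(paste(neg[, 1], neg[, 2]) %in% pos_keys))
  # exclusions respected and draws deterministic
  neg2 <- sample_negatives(bip, 5, seed = 9, exclude = neg)
  expect_false(any(paste(neg2[, 1], neg2[, 2]) %in% paste(neg[, 1], neg[, 2])))
  expect_identical(sample_negatives(bip, n, seed = 2), neg)
})

test_that("edge masking partitions edges and keeps the node set", {
  net <- random_er_network(40, 0.35, seed = 6)
  mk <- mask_edges(net, 1.0, seed = 1)
  expect_equal(nrow(mk$held_out), 0L)

  netm <- net
  netm$edges <- net$edges[1:100, ]
  netm$M <- 100L
  mk <- mask_edges(netm, 0.1, seed = 1)
  expect_equal(mk$network$M, 10L)
  expect_equal(nrow(mk$held_out), 90L)
  expect_equal(mk$network$N, netm$N)

  for (s in 1:10) {
    net <- random_er_network(sample(10:30, 1), 0.3, seed = 100 + s)
    if (net$M < 2) next
    mk <- mask_edges(net, 0.5, seed = s)
    together <- rbind(mk$network$edges, mk$held_out)
    expect_setequal(paste(together[, 1], together[, 2]),
                    paste(net$edges[, 1], net$edges[, 2]))
  }
})

test_that("link-prediction splits are balanced, disjoint and leak-free", {
  net <- small_benchmark(seed = 1)
  sp <- link_prediction_splits(net, seed = 3)
  for (s in sp[c("train", "valid", "test")]) {
    expect_equal(sum(s$labels == 1), sum(s$labels == 0))
  }
  keys <- function(m) paste(m[, 1], m[, 2])
  negs <- lapply(sp[c("train", "valid", "test")],
                 function(s) keys(s$pairs[s$labels == 0, ]))
  expect_equal(anyDuplicated(unlist(negs)), 0L)
  expect_false(any(unlist(negs) %in% keys(net$edges)))
  pos <- lapply(sp[c("train", "valid", "test")],
                function(s) keys(s$pairs[s$labels == 1, ]))
  expect_equal(anyDuplicated(unlist(pos)), 0L)
})
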