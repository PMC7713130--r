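# shared small instance for model tests
model_instance <- function(n = 12, d_in = 6, seed = 1) {
  net <- random_er_network(n, 0.3, seed = seed)
  A <- build_adjacency(net)
  As <- build_skip_adjacency(A)
  list(net = net, A = A,
       Fo = renormalize(A), Fs = renormalize(As, "skip"),
       X = withr::with_seed(seed, matrix(rnorm(n * d_in), n, d_in)))
}

test_that("aggregation gates have their algebraic identities", {
  A <- matrix(rnorm(12), 3)
  expect_equal(agg("sum", A, -A), matrix(0, 3, 4))
  expect_equal(agg("weighted_l1", A, A), matrix(0, 3, 4))
  expect_equal(agg("hadamard", A, matrix(1, 3, 4)), A)
  # symmetry of all gates
  B <- matrix(rnorm(12), 3)
  for (g in c("sum", "weighted_l1", "hadamard")) {
    expect_equal(agg(g, A, B), agg(g, B, A))
  }
  expect_error(agg("sum", A, matrix(0, 2, 2)), "shape")
})

test_that("fusion layer reduces to a plain GCN layer when skip weights vanish", {
  inst <- model_instance()
  p <- init_params("skipgnn", 6, d1 = 5, d2 = 3, seed = 2)
  p$W_op[] <- 0
  p$W_sp[] <- 0
  out <- fusion_layer(inst$X, inst$X, inst$Fo, inst$Fs, p$W_o, p$W_op,
                      p$W_s, p$W_sp)
  gcn <- pmax(as.matrix(inst$Fo %*% inst$X %*% p$W_o), 0)
  expect_equal(out$H, gcn, tolerance = 1e-12)

  zero <- init_params("skipgnn", 6, d1 = 5, d2 = 3, seed = 2)
  for (nm in c("W_o", "W_op", "W_s", "W_sp")) zero[[nm]][] <- 0
  out0 <- fusion_layer(inst$X, inst$X, inst$Fo, inst$Fs, zero$W_o, zero$W_op,
                       zero$W_s, zero$W_sp)
  expect_equal(out0$H, matrix(0, 12, 5), ignore_attr = TRUE)
  expect_equal(out0$S, matrix(0, 12, 5), ignore_attr = TRUE)
})

test_that("fusion layer and final embedding match a literal re-implementation", {
  for (gate in c("sum", "weighted_l1", "hadamard")) {
    inst <- model_instance(seed = 3)
    p <- init_params("skipgnn", 6, d1 = 5, d2 = 3, seed = 4)
    out <- fusion_layer(inst$X, inst$X, inst$Fo, inst$Fs, p$W_o, p$W_op,
                        p$W_s, p$W_sp, gate = gate)
    E <- final_embedding(out$H, out$S, inst$Fo, inst$Fs, p$W_o1, p$W_s1)
    orc <- oracle_fusion(inst$X, inst$Fo, inst$Fs, p, gate = gate)
    expect_equal(out$H, orc$H1, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(out$S, orc$S1, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(E, orc$E, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("final embedding obeys its closed forms", {
  inst <- model_instance(seed = 5)
  p <- init_params("skipgnn", 6, d1 = 5, d2 = 3, seed = 5)
  H1 <- matrix(abs(rnorm(12 * 5)), 12)
  S1 <- matrix(abs(rnorm(12 * 5)), 12)
  z <- p$W_s1
  z[] <- 0
  expect_equal(final_embedding(H1, S1, inst$Fo, inst$Fs, p$W_o1, z),
               as.matrix(inst$Fo %*% H1 %*% p$W_o1), ignore_attr = TRUE)
  # empty graph: both operators are the identity
  I3 <- renormalize(build_adjacency(
    interaction_network(matrix(integer(0), ncol = 2), letters[1:12])))
  W <- diag(5)[, 1:3]
  expect_equal(final_embedding(H1, S1, I3, I3, W, W),
               (H1 + S1) %*% W, ignore_attr = TRUE)
})

test_that("decoder is a logistic affine map of the concatenated embeddings", {
  expect_equal(decode_pair(c(1, 2), c(3, 4), rep(0, 4), 0), 0.5)
  expect_gt(decode_pair(c(1, 2), c(3, 4), rep(0, 4), 30), 1 - 1e-12)
  Ei <- c(0.2, -0.1)
  Ej <- c(0.3, 0.5)
  w <- c(1, -2, 0.5, 0.25)
  b <- -0.3
  expect_equal(decode_pair(Ei, Ej, w, b),
               1 / (1 + exp(-(sum(w * c(Ei, Ej)) + b))), tolerance = 1e-12)
})

test_that("forward returns valid probabilities and honors variants", {
  inst <- model_instance(seed = 6)
  pairs <- rbind(c(1, 2), c(3, 7), c(4, 11))
  for (v in c("skipgnn", "gcn_only", "no_fusion")) {
    p <- init_params(v, 6, d1 = 5, d2 = 3, seed = 7)
    prob <- skipgnn_forward(v, p, inst$X, inst$Fo, inst$Fs, pairs)
    expect_length(prob, 3L)
    expect_true(all(prob > 0 & prob < 1))
    expect_identical(prob,
                     skipgnn_forward(v, p, inst$X, inst$Fo, inst$Fs, pairs))
  }
  p <- init_params("skipgnn", 6, seed = 1)
  expect_error(skipgnn_forward("gcn_only", p, inst$X, inst$Fo, inst$Fs,
                               pairs), "variant")
})

test_that("zeroing skip-side weights makes skipgnn equal the plain GCN variant", {
  inst <- model_instance(seed = 8)
  pg <- init_params("gcn_only", 6, d1 = 5, d2 = 3, decoder_hidden = 4,
                    seed = 9)
  ps <- init_params("skipgnn", 6, d1 = 5, d2 = 3, decoder_hidden = 4,
                    seed = 10)
  ps$W_o <- pg$W_o
  ps$W_o1 <- pg$W_o1
  ps$W_d1 <- pg$W_d1
  ps$b_d1 <- pg$b_d1
  ps$w_d <- pg$w_d
  ps$b <- pg$b
  for (nm in c("W_op", "W_sp", "W_s1")) ps[[nm]][] <- 0
  pairs <- rbind(c(1, 5), c(2, 9), c(3, 12), c(6, 7))
  expect_equal(
    skipgnn_forward("skipgnn", ps, inst$X, inst$Fo, inst$Fs, pairs),
    skipgnn_forward("gcn_only", pg, inst$X, inst$Fo, inst$Fs, pairs),
    tolerance = 1e-10)
})

test_that("forward is permutation equivariant", {
  inst <- model_instance(seed = 11)
  p <- init_params("skipgnn", 6, d1 = 5, d2 = 3, seed = 12)
  pairs <- rbind(c(1, 4), c(2, 10), c(5, 9))
  prob <- skipgnn_forward("skipgnn", p, inst$X, inst$Fo, inst$Fs, pairs)
  perm <- withr::with_seed(13, sample.int(12))
  inv <- order(perm)
  Ap <- as.matrix(inst$A)[perm, perm]
  Fop <- renormalize(Matrix::Matrix(Ap, sparse = TRUE))
  Fsp <- renormalize(build_skip_adjacency(Matrix::Matrix(Ap, sparse = TRUE)),
                     "skip")
  # node i of the original sits at position inv[i] of the permuted graph
  prob_p <- skipgnn_forward("skipgnn", p, inst$X[perm, ], Fop, Fsp,
                            cbind(inv[pairs[, 1]], inv[pairs[, 2]]))
  expect_equal(prob, prob_p, tolerance = 1e-10)
})

test_that("outputs stay finite for bounded weights and inputs", {
  inst <- model_instance(seed = 14)
  p <- init_params("skipgnn", 6, d1 = 5, d2 = 3, seed = 15)
  for (nm in setdiff(names(p), "b")) p[[nm]][] <- 10 * sign(p[[nm]][])
  prob <- skipgnn_forward("skipgnn", p, pmin(pmax(inst$X, -1), 1), inst$Fo,
                          inst$Fs, rbind(c(1, 2)))
  expect_true(is.finite(prob))
})
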