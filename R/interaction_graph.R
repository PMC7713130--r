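#' Construct an interaction network
#'
#' An `interaction_network` is an undirected, simple graph over biomedical
#' entities (drugs, proteins, genes, diseases, ...). Edges are stored as an
#' `M x 2` integer matrix of 1-based node indices with `i < j` per row; node
#' identity is kept in `node_ids`, and heterogeneous networks carry a
#' categorical `node_types` vector (e.g. `"drug"` / `"protein"`).
#'
#' Self-loops are dropped (with a warning) and duplicate undirected edges are
#' collapsed, so the invariants `M = nrow(edges)` and unordered-uniqueness
#' always hold on the returned object.
#'
#' @param edges integer matrix (or two-column data frame) of node indices.
#' @param node_ids character vector of unique external node identifiers;
#'   position defines the internal integer id.
#' @param node_types optional character vector parallel to `node_ids`.
#' @param metadata optional list of generator metadata (cluster labels etc.).
#' @return an object of class `interaction_network` with fields `node_ids`,
#'   `node_types`, `edges`, `N`, `M`, `metadata`.
#' @export
interaction_network <- function(edges, node_ids, node_types = NULL,
                                metadata = list()) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  N <- length(node_ids)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- canonicalize_pairs(edges)
  if (nrow(edges)) {
    if (min(edges) < 1L || max(edges) > N) {
      stop("edge endpoint out of range [1, ", N, "]")
    }
    loops <- edges[, 1L] == edges[, 2L]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      edges <- edges[!loops, , drop = FALSE]
    }
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  if (!is.null(node_types)) {
    node_types <- as.character(node_types)
    stopifnot(length(node_types) == N)
  }
  structure(
    list(node_ids = node_ids, node_types = node_types, edges = edges,
         N = N, M = nrow(edges), metadata = metadata),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", x$N, "nodes,", x$M, "undirected edges\n")
  if (!is.null(x$node_types)) {
    cat("node types:",
        paste(sprintf("%s (%d)", names(table(x$node_types)),
                      table(x$node_types)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an interaction network from a plain-text edge list
#'
#' One interaction per line: two whitespace- or tab-separated node
#' identifiers, optionally followed by a third field `type1:type2` giving the
#' node types of the two endpoints (`typed_three_column` format). Lines
#' starting with `#` and blank lines are ignored. Node ids are assigned by
#' first appearance; duplicate undirected edges are collapsed and self-loops
#' dropped with a warning.
#'
#' @param path path to the edge-list file.
#' @param format `"two_column"` or `"typed_three_column"`.
#' @return an [interaction_network].
#' @export
load_edge_list <- function(path, format = c("two_column",
                                            "typed_three_column")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("empty edge list: ", path)
  want <- if (format == "two_column") 2L else 3L
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf != want)) {
    bad <- idx[which(nf != want)[1L]]
    stop("malformed line ", bad, ": expected ", want, " fields, got ",
         nf[which(nf != want)[1L]])
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  ids <- unique(as.vector(rbind(from, to)))   # first-appearance order
  ei <- match(from, ids)
  ej <- match(to, ids)
  node_types <- NULL
  if (format == "typed_three_column") {
    tt <- strsplit(vapply(toks, `[[`, "", 3L), ":", fixed = TRUE)
    if (any(lengths(tt) != 2L)) {
      bad <- idx[which(lengths(tt) != 2L)[1L]]
      stop("malformed line ", bad, ": type field must be 'type1:type2'")
    }
    t1 <- vapply(tt, `[[`, "", 1L)
    t2 <- vapply(tt, `[[`, "", 2L)
    node_types <- rep(NA_character_, length(ids))
    for (k in seq_along(ei)) {
      for (pair in list(c(ei[k], k, 1L), c(ej[k], k, 2L))) {
        node <- pair[1L]
        ty <- if (pair[3L] == 1L) t1[pair[2L]] else t2[pair[2L]]
        if (is.na(node_types[node])) {
          node_types[node] <- ty
        } else if (node_types[node] != ty) {
          stop("conflicting type for node '", ids[node], "' at line ",
               idx[pair[2L]])
        }
      }
    }
  }
  interaction_network(cbind(ei, ej), node_ids = ids, node_types = node_types)
}

#' Average node degree 2M/N of a network
#' @param net an [interaction_network], or a node count when `m` is given.
#' @param m optional edge count; when supplied, `net` is taken as the node
#'   count so published dataset statistics can be checked directly.
#' @return `2 * M / N`.
#' @export
average_degree <- function(net, m = NULL) {
  if (!is.null(m)) {
    n <- net
  } else {
    stopifnot(inherits(net, "interaction_network"))
    n <- net$N
    m <- net$M
  }
  if (n <= 0) stop("N must be positive")
  2 * m / n
}

#' Binary adjacency matrix of a network
#'
#' @param net an [interaction_network].
#' @return a symmetric, zero-diagonal sparse `dgCMatrix` with a 1 for every
#'   undirected edge.
#' @export
build_adjacency <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (net$M == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = double(0),
                                dims = c(net$N, net$N)))
  }
  A <- Matrix::sparseMatrix(
    i = c(net$edges[, 1L], net$edges[, 2L]),
    j = c(net$edges[, 2L], net$edges[, 1L]),
    x = 1, dims = c(net$N, net$N)
  )
  methods::as(A, "generalMatrix")
}

#' Skip-graph adjacency: connect all pairs joined by a two-hop path
#'
#' The skip graph G_s has an edge (i, j), i != j, whenever some node k is
#' adjacent to both i and j in the input graph; its adjacency is
#' `sign(A %*% A)` with the diagonal zeroed. In a bipartite network every
#' two-hop path returns to the starting side, so the skip graph links only
#' same-type nodes — the "skip similarity" structure the model exploits.
#'
#' @param A symmetric binary zero-diagonal adjacency matrix (sparse or dense).
#' @return sparse binary symmetric zero-diagonal adjacency of the skip graph.
#' @export
build_skip_adjacency <- function(A) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  As <- A %*% A
  As <- methods::as(methods::as(As, "generalMatrix"), "CsparseMatrix")
  Matrix::diag(As) <- 0
  As <- Matrix::drop0(As)
  As@x[] <- 1
  As
}

#' Renormalized propagation operator
#'
#' Computes `F = D~^{-1/2} (A + I) D~^{-1/2}` with `D~` the degree matrix of
#' `A + I` (the renormalization trick). Rows of isolated nodes reduce to a
#' lone diagonal 1, so node order and count are preserved. All eigenvalues of
#' the operator lie in `[-1, 1]`.
#'
#' @param A symmetric binary zero-diagonal adjacency matrix.
#' @param source label recorded on the result, `"original"` or `"skip"`.
#' @return sparse symmetric matrix with attribute `source`.
#' @export
renormalize <- function(A, source = c("original", "skip")) {
  source <- match.arg(source)
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  n <- nrow(A)
  At <- A + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(At))
  Fop <- Matrix::Diagonal(n, dinv) %*% At %*% Matrix::Diagonal(n, dinv)
  Fop <- methods::as(methods::as(Fop, "generalMatrix"), "CsparseMatrix")
  attr(Fop, "source") <- source
  Fop
}

#' Random 7:1:2 split of the positive edges
#'
#' Partitions the network's edges into train/validation/test positive sets.
#' Counts are `floor(r_train * M)` and `floor(r_valid * M)` with the
#' remainder going to test. Deterministic for a fixed seed.
#'
#' @param net an [interaction_network].
#' @param ratios length-3 numeric summing to 1.
#' @param seed integer seed.
#' @return list with integer matrices `train`, `valid`, `test` (rows `i < j`).
#' @export
split_edges <- function(net, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(inherits(net, "interaction_network"), length(ratios) == 3L)
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  M <- net$M
  if (M < 10L) stop("need at least 10 edges to split, have ", M)
  n_tr <- floor(ratios[1L] * M)
  n_va <- floor(ratios[2L] * M)
  n_te <- M - n_tr - n_va
  if (min(n_tr, n_va, n_te) < 1L) {
    stop("split ratios leave an empty partition (M = ", M, ")")
  }
  perm <- withr::with_seed(seed, sample.int(M))
  list(
    train = net$edges[perm[seq_len(n_tr)], , drop = FALSE],
    valid = net$edges[perm[n_tr + seq_len(n_va)], , drop = FALSE],
    test = net$edges[perm[n_tr + n_va + seq_len(n_te)], , drop = FALSE]
  )
}

# enumerate the candidate pair domain: all cross-type pairs when type_aware,
# otherwise all unordered pairs; returns m x 2 matrix with i < j
enumerate_pair_domain <- function(net, type_aware) {
  if (type_aware) {
    tys <- unique(net$node_types)
    a <- which(net$node_types == tys[1L])
    b <- which(net$node_types == tys[2L])
    g <- expand.grid(i = a, j = b)
    canonicalize_pairs(cbind(g$i, g$j))
  } else {
    idx <- which(upper.tri(matrix(FALSE, net$N, net$N)), arr.ind = TRUE)
    cbind(idx[, "row"], idx[, "col"])
  }
}

# number of pairs in the candidate domain
domain_size <- function(net, type_aware) {
  if (type_aware) {
    tab <- table(net$node_types)
    as.double(tab[1L]) * as.double(tab[2L])
  } else {
    net$N * (net$N - 1) / 2
  }
}

#' Sample negative (non-interacting) node pairs
#'
#' Draws `n` unordered pairs from the complement of the full positive edge
#' set, excluding `exclude` (e.g. negatives already assigned to another
#' split), without duplicates. With `type_aware = TRUE` (the default whenever
#' node types are present and all positive edges are cross-type) candidate
#' pairs follow the type pattern of the positives, e.g. drug-protein only.
#'
#' @param net an [interaction_network]; its full edge set defines positives.
#' @param n number of pairs to draw.
#' @param seed integer seed.
#' @param type_aware logical or `NULL` (auto-detect).
#' @param exclude optional matrix of pairs to avoid.
#' @return `n x 2` integer matrix of pairs with `i < j`.
#' @export
sample_negatives <- function(net, n, seed = 1L, type_aware = NULL,
                             exclude = NULL) {
  stopifnot(inherits(net, "interaction_network"), is_count(n))
  if (is.null(type_aware)) {
    type_aware <- !is.null(net$node_types) &&
      length(unique(net$node_types)) == 2L &&
      net$M > 0L &&
      all(net$node_types[net$edges[, 1L]] != net$node_types[net$edges[, 2L]])
  }
  if (type_aware && (is.null(net$node_types) ||
                     length(unique(net$node_types)) != 2L)) {
    stop("type_aware sampling needs exactly two node types")
  }
  pos_keys <- pair_key(net$edges[, 1L], net$edges[, 2L])
  ex_keys <- character(0)
  if (!is.null(exclude) && length(exclude)) {
    exclude <- canonicalize_pairs(exclude)
    ex_keys <- pair_key(exclude[, 1L], exclude[, 2L])
  }
  forbidden <- unique(c(pos_keys, ex_keys))
  total <- domain_size(net, type_aware)

  if (total <= 2e5) {
    dom <- enumerate_pair_domain(net, type_aware)
    keys <- pair_key(dom[, 1L], dom[, 2L])
    ok <- !(keys %in% forbidden)
    avail <- sum(ok)
    if (avail < n) {
      stop("complement exhausted: requested ", n, " negative pairs, only ",
           avail, " available")
    }
    cand <- which(ok)
    pick <- withr::with_seed(seed, cand[sample.int(length(cand), n)])
    return(dom[pick, , drop = FALSE])
  }

  # large domain: count exactly, sample by rejection
  in_domain <- function(keys) {
    if (!type_aware) return(rep(TRUE, length(keys)))
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    i <- as.integer(parts[, 1L]); j <- as.integer(parts[, 2L])
    net$node_types[i] != net$node_types[j]
  }
  avail <- total - sum(in_domain(forbidden))
  if (avail < n) {
    stop("complement exhausted: requested ", n, " negative pairs, only ",
         avail, " available")
  }
  withr::with_seed(seed, {
    got <- character(0)
    out <- matrix(integer(0), ncol = 2L)
    tries <- 0L
    if (type_aware) {
      tys <- unique(net$node_types)
      a <- which(net$node_types == tys[1L])
      b <- which(net$node_types == tys[2L])
    }
    while (nrow(out) < n) {
      tries <- tries + 1L
      if (tries > 1000L) stop("negative sampling failed to converge")
      m <- 2L * (n - nrow(out)) + 16L
      cand <- if (type_aware) {
        cbind(sample(a, m, replace = TRUE), sample(b, m, replace = TRUE))
      } else {
        cbind(sample.int(net$N, m, replace = TRUE),
              sample.int(net$N, m, replace = TRUE))
      }
      cand <- cand[cand[, 1L] != cand[, 2L], , drop = FALSE]
      cand <- canonicalize_pairs(cand)
      keys <- pair_key(cand[, 1L], cand[, 2L])
      keep <- !(keys %in% forbidden) & !(keys %in% got) & !duplicated(keys)
      cand <- cand[keep, , drop = FALSE]
      keys <- keys[keep]
      take <- seq_len(min(nrow(cand), n - nrow(out)))
      out <- rbind(out, cand[take, , drop = FALSE])
      got <- c(got, keys[take])
    }
    out
  })
}

#' Mask edges to emulate an incomplete interaction network
#'
#' Keeps a random `round(keep_fraction * M)` subset of the edges as the
#' observed (training) network and returns the rest as held-out pairs. The
#' node set is unchanged, so nodes isolated by masking stay in place.
#'
#' @param net an [interaction_network].
#' @param keep_fraction fraction of edges to keep, in (0, 1].
#' @param seed integer seed.
#' @return list with `network` (the masked [interaction_network]) and
#'   `held_out` (matrix of removed edges).
#' @export
mask_edges <- function(net, keep_fraction, seed = 1L) {
  stopifnot(inherits(net, "interaction_network"),
            keep_fraction > 0, keep_fraction <= 1)
  n_keep <- round(keep_fraction * net$M)
  if (n_keep < 1L) stop("keep_fraction * M must be >= 1")
  perm <- withr::with_seed(seed, sample.int(net$M))
  kept <- net$edges[perm[seq_len(n_keep)], , drop = FALSE]
  held <- net$edges[perm[-seq_len(n_keep)], , drop = FALSE]
  masked <- net
  masked$edges <- kept[order(kept[, 1L], kept[, 2L]), , drop = FALSE]
  masked$M <- nrow(kept)
  list(network = masked, held_out = held)
}

#' Labeled pair set for one split
#'
#' @param split `"train"`, `"valid"` or `"test"`.
#' @param pairs `m x 2` integer matrix of node pairs.
#' @param labels binary vector, one per pair.
#' @return an `edge_sample_set` (list with `split`, `pairs`, `labels`).
#' @export
edge_sample_set <- function(split = c("train", "valid", "test"), pairs,
                            labels) {
  split <- match.arg(split)
  pairs <- canonicalize_pairs(pairs)
  labels <- as.integer(labels)
  stopifnot(nrow(pairs) == length(labels), all(labels %in% c(0L, 1L)))
  structure(list(split = split, pairs = pairs, labels = labels),
            class = "edge_sample_set")
}

#' Build balanced train/valid/test samples for link prediction
#'
#' Splits the positive edges 7:1:2, then samples an equal number of negatives
#' per split from the complement of the *full* positive edge set, disjoint
#' across splits (negatives are fixed once, not resampled per epoch). The
#' training positives define the propagation graph; validation/test positives
#' never enter it.
#'
#' @param net an [interaction_network].
#' @param seed integer seed.
#' @param ratios split ratios, default `c(0.7, 0.1, 0.2)`.
#' @param type_aware passed to [sample_negatives()].
#' @return list with `edge_sample_set`s `train`, `valid`, `test` and the
#'   matrix `train_edges` of positive training edges.
#' @export
link_prediction_splits <- function(net, seed = 1L,
                                   ratios = c(0.7, 0.1, 0.2),
                                   type_aware = NULL) {
  pos <- split_edges(net, ratios, seed = seed)
  neg_tr <- sample_negatives(net, nrow(pos$train), seed = derive_seed(seed, 1),
                             type_aware = type_aware)
  neg_va <- sample_negatives(net, nrow(pos$valid), seed = derive_seed(seed, 2),
                             type_aware = type_aware, exclude = neg_tr)
  neg_te <- sample_negatives(net, nrow(pos$test), seed = derive_seed(seed, 3),
                             type_aware = type_aware,
                             exclude = rbind(neg_tr, neg_va))
  mk <- function(split, p, n) {
    edge_sample_set(split, rbind(p, n),
                    c(rep(1L, nrow(p)), rep(0L, nrow(n))))
  }
  list(train = mk("train", pos$train, neg_tr),
       valid = mk("valid", pos$valid, neg_va),
       test = mk("test", pos$test, neg_te),
       train_edges = pos$train)
}
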