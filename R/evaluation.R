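#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated sum `sum(Prec(k) * dRec(k))` over the score-sorted
#' operating points. Tied scores are grouped into a single operating point.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels; both classes must be present.
#' @return scalar in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("pr_auc needs both a positive and a negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tabulate(grp)
  tp <- cumsum(tp_g)
  fp <- cumsum(n_g - tp_g)
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  sum(prec * diff(c(0, rec)))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`, which equals the probability that a random positive
#' outranks a random negative, ties counted 1/2.
#'
#' @inheritParams pr_auc
#' @return scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc needs both a positive and a negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean silhouette coefficient of embeddings grouped by node type
#'
#' For each node, `a` is its mean Euclidean distance to same-type nodes and
#' `b` its mean distance to the nearest other type; the silhouette is
#' `mean((b - a) / pmax(a, b))`. Positive values mean types form separated
#' groups in embedding space; values near 0 mean no separation. The caller
#' chooses the coordinate space (raw final embeddings by default, or 2-D
#' reduced coordinates).
#'
#' @param E numeric matrix of coordinates, one row per node.
#' @param types categorical labels, one per row; at least 2 types, each with
#'   at least 2 members.
#' @return scalar mean silhouette in `[-1, 1]`.
#' @export
silhouette_by_type <- function(E, types) {
  E <- as.matrix(E)
  types <- as.character(types)
  stopifnot(nrow(E) == length(types))
  tab <- table(types)
  if (length(tab) < 2L) stop("need at least 2 node types")
  if (any(tab < 2L)) {
    stop("every type needs at least 2 members (",
         paste(names(tab)[tab < 2L], collapse = ", "), " has 1)")
  }
  D <- as.matrix(stats::dist(E))
  n <- nrow(E)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- types == types[i]
    a <- sum(D[i, same]) / (sum(same) - 1)   # exclude self (distance 0)
    b <- min(vapply(setdiff(names(tab), types[i]),
                    function(t) mean(D[i, types == t]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# prepare everything one run needs: split, negatives, operators, features
prepare_run <- function(net, seed, config, init_method, init_dim, ...) {
  splits <- link_prediction_splits(net, seed = seed)
  tr_net <- net
  tr_net$edges <- splits$train_edges
  tr_net$M <- nrow(splits$train_edges)
  A <- build_adjacency(tr_net)
  As <- build_skip_adjacency(A)
  list(splits = splits,
       Fo = renormalize(A, "original"),
       Fs = renormalize(As, "skip"),
       X = init_features(A, method = init_method, dim = init_dim,
                         seed = derive_seed(seed, 11), ...))
}

#' Run the full link-prediction experiment for one or more model variants
#'
#' For each of `n_runs` seeds: split the edges 7:1:2, sample balanced
#' negatives, build the propagation operators and the skip graph from the
#' training edges only, initialize node features, train each variant on the
#' identical inputs (runs are paired across variants), and evaluate on the
#' test split.
#'
#' @param net an [interaction_network].
#' @param variants character vector of model variants to run.
#' @param config a [train_config()]; its seed is the base seed.
#' @param n_runs number of independent runs (fresh splits), default 5.
#' @param init_method,init_dim feature initializer, see [init_features()].
#' @param compute_silhouette also report the node-type silhouette of the
#'   final embeddings (needs `net$node_types`).
#' @param ... extra arguments to [init_features()].
#' @return data frame with one row per (variant, run): `pr_auc`, `roc_auc`,
#'   `silhouette` (NA unless requested), `selected_epoch`, `seed`.
#' @export
run_experiment <- function(net, variants = "skipgnn",
                           config = train_config(), n_runs = 5L,
                           init_method = "node2vec", init_dim = 128L,
                           compute_silhouette = FALSE, ...) {
  stopifnot(inherits(net, "interaction_network"), n_runs >= 1L)
  out <- list()
  for (r in seq_len(n_runs)) {
    seed_r <- derive_seed(config$seed, r)
    prep <- prepare_run(net, seed_r, config, init_method, init_dim, ...)
    for (v in variants) {
      cfg <- config
      cfg$seed <- seed_r
      fit <- train_skipgnn(v, prep$Fo, prep$Fs, prep$X, prep$splits, cfg)
      p <- predict(fit, prep$Fo, prep$Fs, prep$X, prep$splits$test$pairs)
      sil <- NA_real_
      if (compute_silhouette && !is.null(net$node_types)) {
        E <- skipgnn_embed(fit$best_params, prep$X, prep$Fo, prep$Fs,
                           gate = cfg$gate)
        sil <- silhouette_by_type(E, net$node_types)
      }
      out[[length(out) + 1L]] <- data.frame(
        variant = v, run = r, seed = seed_r,
        pr_auc = pr_auc(p, prep$splits$test$labels),
        roc_auc = roc_auc(p, prep$splits$test$labels),
        silhouette = sil, selected_epoch = fit$selected_epoch)
    }
  }
  do.call(rbind, out)
}

#' Robustness to network incompleteness
#'
#' Trains on 10-70% of the edges and tests on the rest: per fraction and run,
#' [mask_edges()] keeps that fraction for training, 10% of the held-out edges
#' become the validation set (used for model selection) and the remaining
#' 90% the test set, each balanced with fresh negatives. Reports the mean
#' test PR-AUC per fraction with a 95% t-interval over runs.
#'
#' @param net an [interaction_network].
#' @param variant model variant.
#' @param fractions training-edge fractions, each in (0, 1).
#' @param config a [train_config()].
#' @param n_runs runs per fraction.
#' @inheritParams run_experiment
#' @return data frame with one row per fraction: `fraction`, `mean_pr_auc`,
#'   `sd_pr_auc`, `ci_lo`, `ci_hi`, `n_runs`.
#' @export
robustness_curve <- function(net, variant = "skipgnn",
                             fractions = c(0.1, 0.3, 0.5, 0.7),
                             config = train_config(), n_runs = 5L,
                             init_method = "node2vec", init_dim = 128L,
                             ...) {
  if (any(fractions >= 1 | fractions <= 0)) {
    stop("fractions must lie strictly inside (0, 1)")
  }
  rows <- list()
  for (f in fractions) {
    vals <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      seed_r <- derive_seed(config$seed, r)
      mk <- mask_edges(net, f, seed = seed_r)
      held <- mk$held_out
      nh <- nrow(held)
      perm <- withr::with_seed(derive_seed(seed_r, 5), sample.int(nh))
      n_va <- max(1L, floor(0.1 * nh))
      va_pos <- held[perm[seq_len(n_va)], , drop = FALSE]
      te_pos <- held[perm[-seq_len(n_va)], , drop = FALSE]
      tr_pos <- mk$network$edges
      neg_tr <- sample_negatives(net, nrow(tr_pos),
                                 seed = derive_seed(seed_r, 1))
      neg_va <- sample_negatives(net, nrow(va_pos),
                                 seed = derive_seed(seed_r, 2),
                                 exclude = neg_tr)
      neg_te <- sample_negatives(net, nrow(te_pos),
                                 seed = derive_seed(seed_r, 3),
                                 exclude = rbind(neg_tr, neg_va))
      mk_set <- function(split, p, n) {
        edge_sample_set(split, rbind(p, n),
                        c(rep(1L, nrow(p)), rep(0L, nrow(n))))
      }
      samples <- list(train = mk_set("train", tr_pos, neg_tr),
                      valid = mk_set("valid", va_pos, neg_va),
                      test = mk_set("test", te_pos, neg_te))
      A <- build_adjacency(mk$network)
      As <- build_skip_adjacency(A)
      Fo <- renormalize(A, "original")
      Fs <- renormalize(As, "skip")
      X <- init_features(A, method = init_method, dim = init_dim,
                         seed = derive_seed(seed_r, 11), ...)
      cfg <- config
      cfg$seed <- seed_r
      fit <- train_skipgnn(variant, Fo, Fs, X, samples, cfg)
      p <- predict(fit, Fo, Fs, X, samples$test$pairs)
      vals[r] <- pr_auc(p, samples$test$labels)
    }
    mu <- mean(vals)
    sdv <- stats::sd(vals)
    half <- if (n_runs > 1L) {
      stats::qt(0.975, n_runs - 1L) * sdv / sqrt(n_runs)
    } else 0
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, mean_pr_auc = mu, sd_pr_auc = sdv,
      ci_lo = mu - half, ci_hi = mu + half, n_runs = n_runs)
  }
  do.call(rbind, rows)
}

# Exact Wilcoxon signed-rank p-value via the exact null distribution of the
# positive-rank sum W, valid with tied |d| (average ranks are half-integers,
# so doubled ranks make the DP integral). Zero differences must already be
# dropped. For n > 25 callers should use the normal approximation instead.
exact_signed_rank_p <- function(d, alternative = "two.sided") {
  n <- length(d)
  r2 <- 2 * rank(abs(d))             # doubled average ranks: integers
  W2 <- sum(r2[d > 0])
  tot <- sum(r2)
  # counts of sign patterns attaining each doubled rank-sum
  ways <- numeric(tot + 1)
  ways[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), ways[seq_len(tot + 1 - r)])
    ways <- ways + shifted
  }
  probs <- ways / 2^n
  sums <- 0:tot
  p_ge <- sum(probs[sums >= W2])
  p_le <- sum(probs[sums <= W2])
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Compare methods over paired runs
#'
#' Summarizes per-method performance (mean and sd over runs), ranks methods
#' by mean PR-AUC within each dataset, averages ranks across datasets, and
#' tests each method against a reference with the Wilcoxon signed-rank test
#' over the paired per-run metric values (exact null distribution for up to
#' 25 pairs, normal approximation above; zero differences dropped).
#'
#' @param reports data frame with columns `method`, `run`, `pr_auc`,
#'   `roc_auc` and optionally `dataset`; runs must be paired (same run ids
#'   present for every method within a dataset).
#' @param reference method name to test the others against; defaults to the
#'   first method.
#' @param metric which metric(s) feed the signed-rank test: `"both"` pools
#'   PR-AUC and ROC-AUC samples, or a single metric.
#' @param alternative test sidedness, default two-sided.
#' @return list with `summary` (mean/sd per method and dataset), `ranks`
#'   (average rank per method) and `wilcoxon` (p-value per non-reference
#'   method).
#' @export
compare_methods <- function(reports, reference = NULL,
                            metric = c("both", "pr_auc", "roc_auc"),
                            alternative = c("two.sided", "greater", "less")) {
  metric <- match.arg(metric)
  alternative <- match.arg(alternative)
  stopifnot(all(c("method", "run", "pr_auc", "roc_auc") %in% names(reports)))
  if (!"dataset" %in% names(reports)) reports$dataset <- "dataset"
  methods_ <- unique(reports$method)
  if (length(methods_) < 2L) stop("need at least 2 methods to compare")
  reference <- reference %||% methods_[1L]
  key <- function(df) paste(df$dataset, df$run)
  ref_rows <- reports[reports$method == reference, ]
  for (m in methods_) {
    rows <- reports[reports$method == m, ]
    if (!setequal(key(rows), key(ref_rows)) ||
        nrow(rows) != nrow(ref_rows)) {
      stop("runs are not paired across methods (method '", m, "')")
    }
  }
  summary_df <- do.call(rbind, lapply(split(
    reports, reports[c("method", "dataset")], drop = TRUE),
    function(df) data.frame(
      method = df$method[1L], dataset = df$dataset[1L], n = nrow(df),
      mean_pr_auc = mean(df$pr_auc), sd_pr_auc = stats::sd(df$pr_auc),
      mean_roc_auc = mean(df$roc_auc), sd_roc_auc = stats::sd(df$roc_auc))))
  rownames(summary_df) <- NULL
  # rank methods by mean PR-AUC within each dataset (1 = best)
  rank_df <- do.call(rbind, lapply(split(summary_df, summary_df$dataset),
    function(df) data.frame(method = df$method, dataset = df$dataset[1L],
                            rank = rank(-df$mean_pr_auc))))
  avg_rank <- stats::aggregate(rank ~ method, rank_df, mean)
  names(avg_rank)[2L] <- "average_rank"
  pick <- function(df) switch(metric,
    both = c(df$pr_auc, df$roc_auc), pr_auc = df$pr_auc,
    roc_auc = df$roc_auc)
  ord <- function(df) df[order(df$dataset, df$run), ]
  ref_v <- pick(ord(ref_rows))
  wil <- lapply(setdiff(methods_, reference), function(m) {
    x <- pick(ord(reports[reports$method == m, ]))
    d <- x - ref_v
    d <- d[d != 0]
    p <- if (!length(d)) {
      1
    } else if (length(d) <= 25L) {
      exact_signed_rank_p(d, alternative)
    } else {
      stats::wilcox.test(d, exact = FALSE, correct = FALSE,
                         alternative = alternative)$p.value
    }
    data.frame(method = m, reference = reference, n_pairs = length(d),
               p_value = p)
  })
  list(summary = summary_df, ranks = avg_rank,
       wilcoxon = do.call(rbind, wil))
}
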