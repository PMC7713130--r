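# skipgnn

Link prediction on molecular interaction networks — drug–target, drug–drug,
protein–protein, gene–disease — with a graph neural network built around
**skip similarity**: in biological networks, the entities that are alike are
often the ones that *share* interaction partners (two drugs binding the same
protein), not the ones that interact directly. A plain GCN only propagates
messages along edges and so only encodes direct similarity; this package
derives the **skip graph**

```
A_s = sign(A %*% t(A)),  diagonal zeroed
```

— connecting every pair of nodes joined by a 2-path — and trains two fused
propagation streams, one on the interaction network and one on its skip
graph:

```
H(l+1) = relu(AGG(F  H(l) W_o,  F_s S(l)   W_o'))
S(l+1) = relu(AGG(F_s S(l) W_s,  F  H(l+1) W_s'))     # uses the fresh H(l+1)
E      = F H(1) W_o1 + F_s S(1) W_s1
p_ij   = decoder(concat(E_i, E_j))                     # logistic output
```

where `F = D~^(-1/2) (A + I) D~^(-1/2)` is the renormalized propagation
operator (and `F_s` its skip-graph analogue), AGG is a summation gate by
default, and the decoder is a small neural network ending in a logistic
link. Training is mini-batch Adam on binary cross-entropy over positive
edges and an equal number of sampled non-edges, with validation-loss model
selection. The package also ships node2vec feature initialisation (C++
walks + skip-gram), leakage-safe 7:1:2 edge splitting, PR-AUC / ROC-AUC
evaluation, silhouette embedding diagnostics, an incompleteness-robustness
experiment, paired Wilcoxon method comparison, synthetic network generators,
and a command-line interface. Intended users: computational biologists and
network scientists who want a fully inspectable, CPU-scale implementation
of skip-graph message passing.

## Worked example

Train on a synthetic drug–target-like network (two node types, latent
clusters, cross-type edges only) and evaluate on held-out interactions:

```r
library(skipgnn)

net <- generate_bipartite_cluster(n_left = 300, n_right = 150, k = 10,
                                  p_in = 0.3, p_out = 0.01, seed = 0)
net
#> interaction_network: 450 nodes, 1775 undirected edges
#> node types: left (300), right (150)

sp  <- link_prediction_splits(net, seed = 0)          # 7:1:2 + negatives
trn <- interaction_network(sp$train_edges, net$node_ids, net$node_types)
A   <- build_adjacency(trn)                           # training edges only
Fo  <- renormalize(A)
Fs  <- renormalize(build_skip_adjacency(A), "skip")
X   <- init_features(A, "node2vec", dim = 128, seed = 0)

fit <- train_skipgnn("skipgnn", Fo, Fs, X, sp, train_config(seed = 0))
p   <- predict(fit, Fo, Fs, X, sp$test$pairs)
pr_auc(p, sp$test$labels)
#> [1] 0.7641126
roc_auc(p, sp$test$labels)
#> [1] 0.7513414
```

A PR-AUC of ~0.76 on balanced test pairs means held-out interactions are
ranked well above sampled non-interactions (0.5 is chance; the generator's
information-theoretic ceiling is ~0.85, see the vignette). The embeddings
also separate the two node types — the signature of skip similarity, which
a plain GCN (`"gcn_only"` variant) cannot pick up:

```r
E <- skipgnn_embed(fit$best_params, X, Fo, Fs)
silhouette_by_type(E, net$node_types)
#> [1] 0.04612382
```

The same pipeline runs from the shell via the installed script:

```sh
Rscript inst/cli/skipgnn train --synthetic bipartite --seed 0 --out results/
Rscript inst/cli/skipgnn predict --model results/model.rds --pairs cand.txt \
    --out scored.tsv --top 10
Rscript inst/cli/skipgnn robustness --synthetic bipartite --seed 0 --out results/
```

Real networks load from plain-text edge lists (`load_edge_list()`, two
whitespace-separated id columns, optional third column `type1:type2`,
`#` comments).

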