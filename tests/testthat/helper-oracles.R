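# Independent oracles used across the suite. Each deliberately reimplements
# the checked quantity through a different route than the package code.

# multiset aggregators for the injectivity checks
agg_sum <- function(xs) if (length(xs)) sum(xs) else 0
agg_mean <- function(xs) if (length(xs)) mean(xs) else 0
agg_max <- function(xs) if (length(xs)) max(xs) else 0

# confusion-matrix metrics via base::table cross-tabulation (the package
# counts with explicit comparisons instead)
oracle_metrics <- function(y_true, y_pred, n_classes) {
  lv <- seq_len(n_classes) - 1L
  cm <- table(
    factor(y_true, levels = lv),
    factor(y_pred, levels = lv)
  )
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- sum(cm) - tp - fp - fn
  div0 <- function(a, b) ifelse(b == 0, 0, a / b)
  p <- mean(div0(tp, tp + fp))
  r <- mean(div0(tp, tp + fn))
  list(
    accuracy = mean((tp + tn) / sum(cm)),
    precision = p,
    recall = r,
    f1 = if (p + r == 0) 0 else 2 * p * r / (p + r)
  )
}

# plain-R reimplementation of one attention encoder block (no autodiff)
oracle_attention <- function(X, ap) {
  heads <- lapply(ap$heads, function(hp) {
    Q <- X %*% hp$Wq
    K <- X %*% hp$Wk
    V <- X %*% hp$Wv
    S <- Q %*% t(K) / sqrt(ncol(hp$Wq))
    A <- t(apply(S, 1L, function(z) {
      e <- exp(z - max(z))
      e / sum(e)
    }))
    if (nrow(S) == 1L) A <- matrix(A, 1L) # apply() drops to a vector
    A %*% V
  })
  att <- do.call(cbind, heads) %*% ap$Wo
  ln <- function(x, g, b, eps = 1e-5) {
    t(apply(x, 1L, function(row) {
      mu <- mean(row)
      v <- mean((row - mu)^2)
      ((row - mu) / sqrt(v + eps)) * drop(g) + drop(b)
    }))
  }
  h1 <- ln(X + att, ap$ln1_g, ap$ln1_b)
  ffn <- pmax(sweep(h1 %*% ap$ffn_W1, 2L, drop(ap$ffn_b1), "+"), 0) %*%
    ap$ffn_W2
  ffn <- sweep(ffn, 2L, drop(ap$ffn_b2), "+")
  ln(h1 + ffn, ap$ln2_g, ap$ln2_b)
}

# small worlds and configs for fast pipeline tests
tiny_world <- function(seed = 0L, task = "binary") {
  generate_toy_world(toy_world_spec(
    n_drugs = 16L, n_clusters = 2L, n_triples = 270L, n_pairs = 60L,
    task = task, seed = seed
  ))
}

tiny_config <- function(task = "binary", epochs = 3L, seed = 1L, ...) {
  ddi_config(
    task = task, epochs = epochs, dense_hidden = 64L,
    kg = kg_config(epochs = 5L, negatives_per_positive = 8L, seed = seed),
    seed = seed, ...
  )
}

# build a molecular_graph by hand (for analytic GIN cases)
manual_graph <- function(n, edges, node_features,
                         edge_features = NULL) {
  e <- if (length(edges)) {
    do.call(rbind, edges)
  } else {
    matrix(integer(0), 0L, 2L)
  }
  colnames(e) <- c("from", "to")
  structure(
    list(
      drug_id = "manual", atom_count = n,
      elements = rep("C", n),
      degrees = tabulate(e[, "to"], nbins = n),
      edges = e,
      bond_orders = rep(1L, nrow(e)),
      node_features = node_features,
      edge_features = edge_features,
      scheme = "manual"
    ),
    class = "molecular_graph"
  )
}
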