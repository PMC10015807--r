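#' Graph isomorphism network (GIN) encoder for molecular graphs
#'
#' The structure view of each drug is computed by a GIN: at every layer each
#' atom's state is updated as
#' \deqn{h_v^{(k)} = MLP^{(k)}\big((1+\epsilon^{(k)}) h_v^{(k-1)} +
#'   \sum_{u \in N(v)} (h_u^{(k-1)} + e_{u\to v})\big),}
#' where the sum runs over in-neighbours along directed edges and
#' \eqn{e_{u\to v}} is the edge feature projected to the node dimension
#' (the source-plus-edge message convention). Sum aggregation, unlike mean or
#' max, is injective on feature multisets, which is what lets the encoder
#' tell apart neighbourhoods such as \{x\} vs \{x, x\}.
#'
#' The whole-graph embedding is the concat-over-depth readout
#' \deqn{h_G = \mathrm{concat}_k \sum_{v} h_v^{(k)}, \quad k = 0, \dots, K,}
#' followed by a linear projection to the shared 100-dimensional space in
#' which the two views are fused.
#'
#' The encoder is used with fixed random weights: drawn once from a
#' seed-determined fan-in-scaled Gaussian and then frozen, so the structure
#' view is a deterministic function of the molecular graph.
#'
#' @param f_node,f_edge Node and edge feature dimensions of the featurization
#'   scheme (see [feature_dims()]).
#' @param hidden Hidden width of each GIN layer MLP.
#' @param n_layers Number of message-passing layers (the readout then
#'   concatenates `n_layers + 1` per-depth sums).
#' @param out_dim Dimension of the projected graph embedding (the shared
#'   fusion dimension).
#' @param seed Integer seed for the weight draw.
#' @return A `gin_params` list with one `epsilon`, edge projection and
#'   two-layer MLP per layer, plus the readout projection matrix.
#' @examples
#' p <- init_gin_params(seed = 1)
#' g <- featurize(parse_smiles("c1ccccc1", "benzene"))
#' length(encode_drug(g, p))  # 100
#' @export
init_gin_params <- function(f_node = feature_dims()[["node"]],
                            f_edge = feature_dims()[["edge"]],
                            hidden = 32L, n_layers = 5L, out_dim = 100L,
                            seed = 1L) {
  withr::with_seed(seed, {
    d_in <- f_node
    layers <- vector("list", n_layers)
    for (k in seq_len(n_layers)) {
      layers[[k]] <- list(
        epsilon = 0,
        edge_proj = init_mat(f_edge, d_in),
        mlp = list(
          W1 = init_mat(d_in, hidden), b1 = matrix(0, 1L, hidden),
          W2 = init_mat(hidden, hidden), b2 = matrix(0, 1L, hidden)
        )
      )
      d_in <- hidden
    }
    readout_len <- f_node + n_layers * hidden
    structure(
      list(
        f_node = f_node, f_edge = f_edge, hidden = hidden,
        n_layers = n_layers, out_dim = out_dim,
        layers = layers,
        proj = init_mat(readout_len, out_dim)
      ),
      class = "gin_params"
    )
  })
}

apply_mlp <- function(x, mlp) {
  h <- pmax(sweep(x %*% mlp$W1, 2L, drop(mlp$b1), "+"), 0)
  sweep(h %*% mlp$W2, 2L, drop(mlp$b2), "+")
}

#' Run one GIN message-passing layer
#'
#' @param node_feats Matrix `atom_count` x d of current node states.
#' @param graph A featurized `molecular_graph` (its directed edges and edge
#'   features drive the aggregation).
#' @param params A single layer's parameters: `epsilon` (scalar), `edge_proj`
#'   (edge-dim x d matrix, or `NULL` to drop edge features), and `mlp`
#'   (either a `W1/b1/W2/b2` list or a function, e.g. `identity`, which is
#'   handy for analytic checks).
#' @return Updated node-state matrix.
#' @export
gin_layer <- function(node_feats, graph, params) {
  stopifnot(
    inherits(graph, "molecular_graph"),
    nrow(node_feats) == graph$atom_count
  )
  agg <- matrix(0, graph$atom_count, ncol(node_feats))
  if (nrow(graph$edges) > 0L) {
    msg <- node_feats[graph$edges[, "from"], , drop = FALSE]
    if (!is.null(params$edge_proj)) {
      ef <- graph$edge_features
      if (is.null(ef)) stop("graph has no edge features; run featurize()")
      stopifnot(ncol(ef) == nrow(params$edge_proj))
      msg <- msg + ef %*% params$edge_proj
    }
    acc <- rowsum(msg, group = graph$edges[, "to"])
    agg[as.integer(rownames(acc)), ] <- acc
  }
  pre <- (1 + params$epsilon) * node_feats + agg
  if (is.function(params$mlp)) params$mlp(pre) else apply_mlp(pre, params$mlp)
}

#' Concat-over-depth sum readout
#'
#' Sums node states within each depth and concatenates across depths; exact
#' permutation invariance under any node relabelling follows from the sums.
#'
#' @param per_layer_feats List of `K + 1` node-state matrices (input features
#'   first, then one per layer).
#' @return Numeric vector of length `sum of per-depth widths`.
#' @export
gin_readout <- function(per_layer_feats) {
  stopifnot(is.list(per_layer_feats), length(per_layer_feats) >= 1L)
  unlist(lapply(per_layer_feats, colSums), use.names = FALSE)
}

#' Encode one drug's molecular graph into the shared 100-dim space
#'
#' @param graph A featurized `molecular_graph`.
#' @param params A `gin_params` object.
#' @return Numeric vector of length `params$out_dim`.
#' @rdname init_gin_params
#' @export
encode_drug <- function(graph, params) {
  stopifnot(inherits(params, "gin_params"))
  if (is.null(graph$node_features)) {
    stop("graph is not featurized; run featurize() first", call. = FALSE)
  }
  h <- graph$node_features
  states <- vector("list", params$n_layers + 1L)
  states[[1L]] <- h
  for (k in seq_len(params$n_layers)) {
    h <- gin_layer(h, graph, params$layers[[k]])
    states[[k + 1L]] <- h
  }
  drop(gin_readout(states) %*% params$proj)
}

#' Encode a list of drugs into an n x 100 structure-view matrix
#'
#' @param graphs Named list of featurized `molecular_graph` objects (as from
#'   [parse_drug_table()]).
#' @param params A `gin_params` object.
#' @return Matrix with one row per drug (rownames = drug ids).
#' @export
encode_drugs <- function(graphs, params) {
  out <- t(vapply(
    graphs, encode_drug,
    numeric(params$out_dim),
    params = params
  ))
  rownames(out) <- names(graphs)
  out
}
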