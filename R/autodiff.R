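# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Every tensor is an environment holding a numeric matrix, an
# accumulated gradient, and vector-Jacobian-product closures back to its
# parents. Only the operations the fusion and classifier networks need are
# implemented; gradients are verified against central finite differences in
# the test suite.
#
# Nodes created from parameters (or downstream of one) carry `track = TRUE`;
# constants short-circuit so backward() never walks into them.

ad_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

ad_node <- function(value, parents = list(), track = FALSE) {
  stopifnot(is.numeric(value))
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  e <- new.env(parent = emptyenv())
  e$id <- ad_counter()
  e$value <- value
  e$grad <- NULL
  e$parents <- if (track) parents else list()
  e$track <- track
  class(e) <- "ad_node"
  e
}

#' @noRd
ad_param <- function(value) ad_node(value, track = TRUE)

#' @noRd
ad_const <- function(value) ad_node(value, track = FALSE)

ad_value <- function(x) x$value

# parent edge: node plus the vjp mapping the child's gradient to the parent's
ad_edge <- function(node, vjp) list(node = node, vjp = vjp)

ad_tracked <- function(...) {
  any(vapply(list(...), function(n) isTRUE(n$track), logical(1)))
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

# Reverse pass from a scalar node: collect the reachable tracked subgraph,
# process in decreasing creation order (a valid reverse topological order
# because parents are always created before children).
ad_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) {
      if (isTRUE(p$node$track)) stack[[length(stack) + 1L]] <- p$node
    }
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  loss$grad <- matrix(1, 1L, 1L)
  for (n in nodes[ord]) {
    g <- n$grad
    if (is.null(g)) next
    for (p in n$parents) {
      if (isTRUE(p$node$track)) ad_accum(p$node, p$vjp(g))
    }
  }
  invisible(loss)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- primitive operations ----------------------------------------------

ad_matmul <- function(a, b) {
  av <- a$value
  bv <- b$value
  ad_node(av %*% bv,
    parents = list(
      ad_edge(a, function(g) g %*% t(bv)),
      ad_edge(b, function(g) t(av) %*% g)
    ),
    track = ad_tracked(a, b)
  )
}

ad_add <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ad_node(a$value + b$value,
    parents = list(ad_edge(a, identity), ad_edge(b, identity)),
    track = ad_tracked(a, b)
  )
}

ad_sub <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ad_node(a$value - b$value,
    parents = list(ad_edge(a, identity), ad_edge(b, function(g) -g)),
    track = ad_tracked(a, b)
  )
}

# add a 1 x m bias row to every row of a
ad_add_bias <- function(a, bias) {
  stopifnot(nrow(bias$value) == 1L, ncol(a$value) == ncol(bias$value))
  ad_node(sweep(a$value, 2L, drop(bias$value), "+"),
    parents = list(
      ad_edge(a, identity),
      ad_edge(bias, function(g) matrix(colSums(g), 1L))
    ),
    track = ad_tracked(a, bias)
  )
}

ad_mul <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  av <- a$value
  bv <- b$value
  ad_node(av * bv,
    parents = list(
      ad_edge(a, function(g) g * bv),
      ad_edge(b, function(g) g * av)
    ),
    track = ad_tracked(a, b)
  )
}

ad_scale <- function(a, s) {
  ad_node(a$value * s,
    parents = list(ad_edge(a, function(g) g * s)),
    track = a$track
  )
}

ad_relu <- function(a) {
  mask <- a$value > 0
  ad_node(a$value * mask,
    parents = list(ad_edge(a, function(g) g * mask)),
    track = a$track
  )
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(s,
    parents = list(ad_edge(a, function(g) g * s * (1 - s))),
    track = a$track
  )
}

# numerically stable log(1 + exp(x))
softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

ad_softplus <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(softplus(a$value),
    parents = list(ad_edge(a, function(g) g * s)),
    track = a$track
  )
}

ad_log <- function(a, floor = 1e-12) {
  v <- pmax(a$value, floor)
  ad_node(log(v),
    parents = list(ad_edge(a, function(g) g / v)),
    track = a$track
  )
}

# row-wise softmax; vjp uses the standard (g - rowSums(g*s)) * s identity
ad_softmax_rows <- function(a) {
  z <- a$value - apply(a$value, 1L, max)
  ez <- exp(z)
  s <- ez / rowSums(ez)
  ad_node(s,
    parents = list(ad_edge(a, function(g) (g - rowSums(g * s)) * s)),
    track = a$track
  )
}

# row-wise log-softmax (stable); vjp: g - rowSums(g) * softmax
ad_log_softmax_rows <- function(a) {
  mx <- apply(a$value, 1L, max)
  z <- a$value - mx
  lse <- log(rowSums(exp(z)))
  s <- exp(z - lse)
  ad_node(z - lse,
    parents = list(ad_edge(a, function(g) g - rowSums(g) * s)),
    track = a$track
  )
}

ad_concat_cols <- function(nodes) {
  vals <- lapply(nodes, ad_value)
  widths <- vapply(vals, ncol, integer(1))
  stops <- cumsum(widths)
  starts <- stops - widths + 1L
  parents <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    local({
      a <- starts[[i]]
      b <- stops[[i]]
      parents[[i]] <<- ad_edge(nodes[[i]], function(g) g[, a:b, drop = FALSE])
    })
  }
  ad_node(do.call(cbind, vals),
    parents = parents,
    track = do.call(ad_tracked, nodes)
  )
}

ad_slice_cols <- function(a, idx) {
  nc <- ncol(a$value)
  ad_node(a$value[, idx, drop = FALSE],
    parents = list(ad_edge(a, function(g) {
      out <- matrix(0, nrow(g), nc)
      out[, idx] <- g
      out
    })),
    track = a$track
  )
}

# row gather with duplicate-aware scatter-add on the way back
ad_gather_rows <- function(a, idx) {
  nr <- nrow(a$value)
  ad_node(a$value[idx, , drop = FALSE],
    parents = list(ad_edge(a, function(g) {
      acc <- rowsum(g, group = idx)
      out <- matrix(0, nr, ncol(g))
      out[as.integer(rownames(acc)), ] <- acc
      out
    })),
    track = a$track
  )
}

ad_sum <- function(a) {
  d <- dim(a$value)
  ad_node(matrix(sum(a$value), 1L, 1L),
    parents = list(ad_edge(a, function(g) matrix(g[1L], d[1L], d[2L]))),
    track = a$track
  )
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$value))

# row-wise layer normalization with learnable 1 x m scale/shift
ad_layernorm_rows <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  m <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- drop(gamma$value)
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, drop(beta$value), "+")
  ad_node(y,
    parents = list(
      ad_edge(a, function(g) {
        dxhat <- sweep(g, 2L, gv, "*")
        (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
      }),
      ad_edge(gamma, function(g) matrix(colSums(g * xhat), 1L)),
      ad_edge(beta, function(g) matrix(colSums(g), 1L))
    ),
    track = ad_tracked(a, gamma, beta)
  )
}

# 1-D cross-correlation expressed through a tap-index matrix. `x` holds one
# flattened signal per row (channel-major blocks for multi-channel input);
# `idx` is n_out x n_taps, row p giving the flat input indices feeding output
# position p; `w` is n_taps x n_channels_out, `bias` 1 x n_channels_out.
# Output is n x (n_out * n_channels_out), channel-major.
ad_conv1d <- function(x, w, bias, idx) {
  xv <- x$value
  wv <- w$value
  n_out <- nrow(idx)
  n_tap <- ncol(idx)
  n_ch <- ncol(wv)
  stopifnot(nrow(wv) == n_tap, ncol(bias$value) == n_ch)
  taps <- lapply(seq_len(n_tap), function(t) xv[, idx[, t], drop = FALSE])
  out <- matrix(0, nrow(xv), n_out * n_ch)
  for (ch in seq_len(n_ch)) {
    acc <- matrix(bias$value[1L, ch], nrow(xv), n_out)
    for (t in seq_len(n_tap)) acc <- acc + taps[[t]] * wv[t, ch]
    out[, (ch - 1L) * n_out + seq_len(n_out)] <- acc
  }
  ad_node(out,
    parents = list(
      ad_edge(x, function(g) {
        dx <- matrix(0, nrow(g), ncol(xv))
        for (ch in seq_len(n_ch)) {
          gch <- g[, (ch - 1L) * n_out + seq_len(n_out), drop = FALSE]
          for (t in seq_len(n_tap)) {
            cols <- idx[, t]
            dx[, cols] <- dx[, cols] + gch * wv[t, ch]
          }
        }
        dx
      }),
      ad_edge(w, function(g) {
        dw <- matrix(0, n_tap, n_ch)
        for (ch in seq_len(n_ch)) {
          gch <- g[, (ch - 1L) * n_out + seq_len(n_out), drop = FALSE]
          for (t in seq_len(n_tap)) dw[t, ch] <- sum(taps[[t]] * gch)
        }
        dw
      }),
      ad_edge(bias, function(g) {
        matrix(vapply(seq_len(n_ch), function(ch) {
          sum(g[, (ch - 1L) * n_out + seq_len(n_out)])
        }, numeric(1)), 1L)
      })
    ),
    track = ad_tracked(x, w, bias)
  )
}

## ---- Adam optimizer -----------------------------------------------------

adam_init <- function(params) {
  list(
    t = 0L,
    m = lapply(params, function(p) p$value * 0),
    v = lapply(params, function(p) p$value * 0)
  )
}

adam_step <- function(state, params, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    p$value <- p$value -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  ad_zero_grads(params)
  state
}

# fan-in scaled Gaussian initialization used throughout the model
init_mat <- function(nr, nc, sd = 1 / sqrt(nr)) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}
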