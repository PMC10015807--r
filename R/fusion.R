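# Multi-level latent fusion of the two drug views.
#
# Each drug carries a 100-dim structure vector (GIN view, h_G) and a 100-dim
# KG vector (RotatE view, e_h). Five 20-dim latent features are formed:
#   LF1  row-stack of the two views (a 2 x 100 image per drug) -> 2-D conv
#        (kernel 2 x 10) -> 1-D conv (kernel 5) -> adaptive mean-pool to 20
#   LF2  column-stack (1 x 200 signal per drug) -> same conv stack with a
#        1 x 10 first kernel
#   LF3  elementwise add of the views -> autoencoder middle layer (width 20)
#   LF4  elementwise product             -> its own autoencoder, same shape
#   LF5  LF1 + LF2 + LF3 + LF4
# X = [LF1 || LF2 || LF3 || LF4 || LF5] (n x 100) is refined by one
# multi-head self-attention encoder block (drugs are the attention tokens),
# giving X_att of the same shape.
#
# Forward passes are written once against the autodiff tensors; the exported
# functions wrap plain matrices in constant nodes and return plain matrices.

LATENT_DIM <- 20L

#' Initialize multi-head attention parameters
#'
#' Per-head query/key/value projections at width `d_in / n_heads` (25 with 4
#' heads, 50 with 2), an output projection, two layer norms, and a
#' position-wise feed-forward net, i.e. one standard encoder block.
#'
#' @param d_in Token width (the fused latent width, 100).
#' @param n_heads Number of attention heads; must divide `d_in`. Defaults
#'   follow the task: 2 for binary, 4 for multi-class.
#' @param ffn_hidden Feed-forward hidden width.
#' @param seed Seed for the weight draw.
#' @return An `attention_params` list with element `d_k` (= `d_v` =
#'   `d_in / n_heads`).
#' @export
init_attention_params <- function(d_in = 100L, n_heads = 4L,
                                  ffn_hidden = 2L * d_in, seed = 1L) {
  if (d_in %% n_heads != 0L) {
    stop("d_in (", d_in, ") is not divisible by n_heads (", n_heads, ")",
      call. = FALSE
    )
  }
  d_k <- d_in %/% n_heads
  withr::with_seed(seed, {
    structure(
      list(
        d_in = as.integer(d_in), n_heads = as.integer(n_heads),
        d_k = as.integer(d_k),
        heads = lapply(seq_len(n_heads), function(i) {
          list(
            Wq = init_mat(d_in, d_k),
            Wk = init_mat(d_in, d_k),
            Wv = init_mat(d_in, d_k)
          )
        }),
        Wo = init_mat(d_in, d_in),
        ln1_g = matrix(1, 1L, d_in), ln1_b = matrix(0, 1L, d_in),
        ffn_W1 = init_mat(d_in, ffn_hidden),
        ffn_b1 = matrix(0, 1L, ffn_hidden),
        ffn_W2 = init_mat(ffn_hidden, d_in),
        ffn_b2 = matrix(0, 1L, d_in),
        ln2_g = matrix(1, 1L, d_in), ln2_b = matrix(0, 1L, d_in)
      ),
      class = "attention_params"
    )
  })
}

#' Initialize the full fusion block
#'
#' Draws the two convolutional branches (kernel sizes 10 then 5, 1 -> 8 -> 1
#' channels, stride 1, no padding), the two autoencoders (100 -> 60 -> 20 ->
#' 60 -> 100) and the attention encoder.
#'
#' @param d_in Shared view dimension (100).
#' @param n_heads Attention heads (2 binary / 4 multi-class).
#' @param conv_channels Channels of the first convolution stage.
#' @param ae_hidden Outer hidden width of the autoencoders.
#' @param seed Seed for all weight draws.
#' @return A `fusion_params` list (`conv_row`, `conv_col`, `ae_add`,
#'   `ae_prod`, `attn`).
#' @export
init_fusion_params <- function(d_in = 100L, n_heads = 4L,
                               conv_channels = 8L, ae_hidden = 60L,
                               seed = 1L) {
  withr::with_seed(seed, {
    mk_conv <- function(k1_taps) {
      list(
        W1 = init_mat(k1_taps, conv_channels),
        b1 = matrix(0, 1L, conv_channels),
        W2 = init_mat(5L * conv_channels, 1L),
        b2 = matrix(0, 1L, 1L)
      )
    }
    mk_ae <- function() {
      list(
        W1 = init_mat(d_in, ae_hidden), b1 = matrix(0, 1L, ae_hidden),
        W2 = init_mat(ae_hidden, LATENT_DIM), b2 = matrix(0, 1L, LATENT_DIM),
        W3 = init_mat(LATENT_DIM, ae_hidden), b3 = matrix(0, 1L, ae_hidden),
        W4 = init_mat(ae_hidden, d_in), b4 = matrix(0, 1L, d_in)
      )
    }
    structure(
      list(
        d_in = as.integer(d_in),
        conv_channels = as.integer(conv_channels),
        conv_row = mk_conv(2L * 10L),
        conv_col = mk_conv(10L),
        ae_add = mk_ae(),
        ae_prod = mk_ae(),
        attn = init_attention_params(
          d_in = 5L * LATENT_DIM, n_heads = n_heads,
          seed = sample.int(.Machine$integer.max, 1L)
        )
      ),
      class = "fusion_params"
    )
  })
}

## ---- conv plumbing ------------------------------------------------------

# tap-index matrix for the 2 x 10 kernel over a per-drug 2 x d image stored
# as [view1 (1..d), view2 (d+1..2d)]
conv_idx_row_stack <- function(d = 100L, k = 10L) {
  pos <- seq_len(d - k + 1L)
  idx <- matrix(0L, length(pos), 2L * k)
  for (o in seq_len(k)) {
    idx[, o] <- pos + o - 1L # top row taps
    idx[, k + o] <- d + pos + o - 1L # bottom row taps
  }
  idx
}

# 1 x k kernel over a length-L signal
conv_idx_flat <- function(L, k) {
  pos <- seq_len(L - k + 1L)
  idx <- matrix(0L, length(pos), k)
  for (o in seq_len(k)) idx[, o] <- pos + o - 1L
  idx
}

# k-tap kernel across ch channel-major blocks of length L each
conv_idx_channels <- function(L, k, ch) {
  pos <- seq_len(L - k + 1L)
  idx <- matrix(0L, length(pos), k * ch)
  for (c in seq_len(ch)) {
    for (o in seq_len(k)) {
      idx[, (c - 1L) * k + o] <- (c - 1L) * L + pos + o - 1L
    }
  }
  idx
}

# adaptive mean-pool matrix, bin i averaging input positions
# floor((i-1)L/out)+1 .. ceil(iL/out)
pool_matrix <- function(L, out = LATENT_DIM) {
  P <- matrix(0, L, out)
  for (i in seq_len(out)) {
    a <- floor((i - 1L) * L / out) + 1L
    b <- ceiling(i * L / out)
    P[a:b, i] <- 1 / (b - a + 1L)
  }
  P
}

# AD forward of one concatenate-level branch; hG/eh are n x d nodes
concat_level_forward <- function(hG, eh, mode, cp, d_in, channels) {
  x <- ad_concat_cols(list(hG, eh))
  if (mode == "row_stack") {
    idx1 <- conv_idx_row_stack(d_in, 10L)
  } else {
    idx1 <- conv_idx_flat(2L * d_in, 10L)
  }
  m1 <- nrow(idx1)
  h <- ad_relu(ad_conv1d(x, cp$W1, cp$b1, idx1)) # n x (m1 * channels)
  idx2 <- conv_idx_channels(m1, 5L, channels)
  h <- ad_relu(ad_conv1d(h, cp$W2, cp$b2, idx2)) # n x (m1 - 4)
  ad_matmul(h, ad_const(pool_matrix(m1 - 4L)))
}

# AD forward of one scalar-level branch; returns latent + reconstruction
scalar_level_forward <- function(hG, eh, mode, ae) {
  fused <- if (mode == "add") ad_add(hG, eh) else ad_mul(hG, eh)
  enc <- ad_relu(ad_add_bias(ad_matmul(fused, ae$W1), ae$b1))
  z <- ad_add_bias(ad_matmul(enc, ae$W2), ae$b2)
  dec <- ad_relu(ad_add_bias(ad_matmul(z, ae$W3), ae$b3))
  recon <- ad_add_bias(ad_matmul(dec, ae$W4), ae$b4)
  list(latent = z, recon = recon, fused = fused)
}

attention_forward <- function(X, ap) {
  n <- nrow(ad_value(X))
  heads <- lapply(ap$heads, function(hp) {
    Q <- ad_matmul(X, hp$Wq)
    K <- ad_matmul(X, hp$Wk)
    V <- ad_matmul(X, hp$Wv)
    A <- ad_softmax_rows(ad_scale(
      ad_matmul(Q, ad_transpose(K)),
      1 / sqrt(ad_value(hp$Wq) |> ncol())
    ))
    ad_matmul(A, V)
  })
  att <- ad_matmul(ad_concat_cols(heads), ap$Wo)
  h1 <- ad_layernorm_rows(ad_add(X, att), ap$ln1_g, ap$ln1_b)
  ffn <- ad_add_bias(
    ad_matmul(
      ad_relu(ad_add_bias(ad_matmul(h1, ap$ffn_W1), ap$ffn_b1)),
      ap$ffn_W2
    ),
    ap$ffn_b2
  )
  ad_layernorm_rows(ad_add(h1, ffn), ap$ln2_g, ap$ln2_b)
}

# transpose helper (constant-Jacobian)
ad_transpose <- function(a) {
  ad_node(t(a$value),
    parents = list(ad_edge(a, function(g) t(g))),
    track = a$track
  )
}

# wrap every leaf matrix of a (nested) parameter list in an ad_param node
params_to_nodes <- function(p) {
  rapply(p,
    function(x) if (is.matrix(x)) ad_param(x) else x,
    how = "replace"
  )
}

# pull trained values back out of the node tree
nodes_to_params <- function(p) {
  rapply(p,
    function(x) if (inherits(x, "ad_node")) ad_value(x) else x,
    classes = c("ad_node", "ANY"), how = "replace"
  )
}

# flat list of every ad_node leaf (for the optimizer)
collect_param_nodes <- function(p) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "ad_node")) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      lapply(x, walk)
    }
  }
  walk(p)
  out
}

## ---- exported plain-matrix surface --------------------------------------

check_view_matrices <- function(hG_mat, eh_mat, d_in) {
  stopifnot(is.matrix(hG_mat), is.matrix(eh_mat))
  if (ncol(hG_mat) != d_in || ncol(eh_mat) != d_in) {
    stop("view matrices must have ", d_in, " columns", call. = FALSE)
  }
  if (nrow(hG_mat) != nrow(eh_mat)) {
    stop("view matrices must have the same number of rows", call. = FALSE)
  }
}

#' Concatenate-level fusion branch (LF1 / LF2)
#'
#' Stacks the structure and KG views of each drug into a small image
#' (`row_stack`: 2 x 100; `col_stack`: 1 x 200), applies a 2-D convolution
#' (kernel 2 x 10 or 1 x 10), a 1-D convolution (kernel 5) and adaptive
#' average pooling to 20, yielding one 20-dim latent per drug. The branches
#' act per drug: no information crosses drug rows.
#'
#' @param hG_mat,eh_mat n x 100 view matrices (structure and KG views).
#' @param mode `"row_stack"` (emits LF1) or `"col_stack"` (LF2).
#' @param params A `fusion_params` object.
#' @return n x 20 matrix with attribute `branch_tag` `"LF1"` or `"LF2"`.
#' @export
concat_level <- function(hG_mat, eh_mat, mode = c("row_stack", "col_stack"),
                         params = init_fusion_params()) {
  mode <- match.arg(mode)
  check_view_matrices(hG_mat, eh_mat, params$d_in)
  cp <- if (mode == "row_stack") params$conv_row else params$conv_col
  out <- ad_value(concat_level_forward(
    ad_const(hG_mat), ad_const(eh_mat), mode,
    params_to_nodes(cp), params$d_in, params$conv_channels
  ))
  structure(out, branch_tag = if (mode == "row_stack") "LF1" else "LF2")
}

#' Scalar-level fusion branch (LF3 / LF4)
#'
#' Fuses the views elementwise (`add` or `product`) and compresses the fused
#' 100-dim vector through an autoencoder (100 -> 60 -> 20 -> 60 -> 100); the
#' middle-layer activation is the latent feature.
#'
#' @param hG_mat,eh_mat n x 100 view matrices.
#' @param mode `"add"` (emits LF3) or `"product"` (LF4).
#' @param params A `fusion_params` object.
#' @return n x 20 matrix with attribute `branch_tag` `"LF3"` or `"LF4"`.
#' @export
scalar_level <- function(hG_mat, eh_mat, mode = c("add", "product"),
                         params = init_fusion_params()) {
  mode <- match.arg(mode)
  check_view_matrices(hG_mat, eh_mat, params$d_in)
  ae <- if (mode == "add") params$ae_add else params$ae_prod
  fw <- scalar_level_forward(
    ad_const(hG_mat), ad_const(eh_mat), mode, params_to_nodes(ae)
  )
  structure(
    ad_value(fw$latent),
    branch_tag = if (mode == "add") "LF3" else "LF4"
  )
}

#' Autoencoder reconstruction error
#'
#' Mean squared error between a fused view matrix and its reconstruction
#' through one of the scalar-level autoencoders. During joint training this
#' term (weighted by `lambda_ae`) keeps the 20-dim latents faithful to the
#' fused inputs.
#'
#' @param fused n x 100 matrix (elementwise add or product of the views).
#' @param ae One autoencoder parameter list (`params$ae_add` or
#'   `params$ae_prod` of a `fusion_params`).
#' @return Non-negative scalar.
#' @export
ae_reconstruction_loss <- function(fused, ae) {
  nodes <- params_to_nodes(ae)
  enc <- ad_relu(ad_add_bias(ad_matmul(ad_const(fused), nodes$W1), nodes$b1))
  z <- ad_add_bias(ad_matmul(enc, nodes$W2), nodes$b2)
  dec <- ad_relu(ad_add_bias(ad_matmul(z, nodes$W3), nodes$b3))
  recon <- ad_value(ad_add_bias(ad_matmul(dec, nodes$W4), nodes$b4))
  mean((recon - fused)^2)
}

#' Combine the four branch latents into the fused matrix X
#'
#' Forms the fifth latent as the elementwise sum `LF5 = LF1 + LF2 + LF3 +
#' LF4` and concatenates all five in fixed order into an n x 100 matrix.
#'
#' @param lf1,lf2,lf3,lf4 n x 20 latent matrices.
#' @return n x 100 matrix `[LF1 || LF2 || LF3 || LF4 || LF5]`.
#' @export
fuse_latents <- function(lf1, lf2, lf3, lf4) {
  lfs <- list(lf1, lf2, lf3, lf4)
  for (m in lfs) {
    stopifnot(is.matrix(m), ncol(m) == LATENT_DIM, nrow(m) == nrow(lf1))
  }
  lf5 <- lf1 + lf2 + lf3 + lf4
  cbind(lf1, lf2, lf3, lf4, lf5)
}

#' Multi-head self-attention over the fused drug matrix
#'
#' Rows of `X` (drugs) are the attention tokens. Per head,
#' `softmax(Q K' / sqrt(d_k)) V` with `Q/K/V = X W`; heads are concatenated,
#' projected, and passed through residual + layer-norm, a position-wise
#' feed-forward net, and a second residual + layer-norm. Output shape equals
#' input shape. Because tokens are the drugs in the matrix, the output for a
#' drug depends on which drugs it is processed with; at inference the
#' package always attends over the full training drug matrix.
#'
#' @param X n x 100 fused latent matrix (from [fuse_latents()]).
#' @param params An `attention_params` object (or a `fusion_params`, whose
#'   `$attn` is used).
#' @return n x 100 refined matrix.
#' @export
multi_head_attention <- function(X, params = init_attention_params()) {
  if (inherits(params, "fusion_params")) params <- params$attn
  stopifnot(is.matrix(X), ncol(X) == params$d_in, nrow(X) >= 1L)
  ad_value(attention_forward(ad_const(X), params_to_nodes(params)))
}

# full fusion forward on the AD graph; branch flags support the ablation
# variants (a disabled branch contributes an all-zero latent)
fusion_forward <- function(hG, eh, nodes, d_in, channels,
                           branches = c(
                             lf1 = TRUE, lf2 = TRUE,
                             lf3 = TRUE, lf4 = TRUE
                           ),
                           use_attention = TRUE) {
  n <- nrow(ad_value(hG))
  zero <- function() ad_const(matrix(0, n, LATENT_DIM))
  lf1 <- if (branches[["lf1"]]) {
    concat_level_forward(hG, eh, "row_stack", nodes$conv_row, d_in, channels)
  } else {
    zero()
  }
  lf2 <- if (branches[["lf2"]]) {
    concat_level_forward(hG, eh, "col_stack", nodes$conv_col, d_in, channels)
  } else {
    zero()
  }
  sl3 <- if (branches[["lf3"]]) {
    scalar_level_forward(hG, eh, "add", nodes$ae_add)
  } else {
    NULL
  }
  sl4 <- if (branches[["lf4"]]) {
    scalar_level_forward(hG, eh, "product", nodes$ae_prod)
  } else {
    NULL
  }
  lf3 <- if (is.null(sl3)) zero() else sl3$latent
  lf4 <- if (is.null(sl4)) zero() else sl4$latent
  lf5 <- ad_add(ad_add(lf1, lf2), ad_add(lf3, lf4))
  X <- ad_concat_cols(list(lf1, lf2, lf3, lf4, lf5))
  X_att <- if (use_attention) attention_forward(X, nodes$attn) else X
  list(X = X, X_att = X_att, sl3 = sl3, sl4 = sl4)
}
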