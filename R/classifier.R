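#' Assemble the final drug representation matrix
#'
#' Concatenates, per drug, the attention-refined fused features, the raw
#' structure view and the raw KG view: `D = [X_att || h_G || e_h]`, one
#' 300-dim row per drug.
#'
#' @param x_att n x 100 attention output (see [multi_head_attention()]).
#' @param hG n x 100 structure-view matrix.
#' @param eh n x 100 KG-view matrix.
#' @return n x 300 matrix; rownames are taken from `hG`.
#' @export
assemble_drug_matrix <- function(x_att, hG, eh) {
  stopifnot(
    is.matrix(x_att), is.matrix(hG), is.matrix(eh),
    nrow(x_att) == nrow(hG), nrow(hG) == nrow(eh),
    ncol(x_att) == 100L, ncol(hG) == 100L, ncol(eh) == 100L
  )
  D <- cbind(x_att, hG, eh)
  rownames(D) <- rownames(hG)
  D
}

#' Initialize the pair-scoring head
#'
#' A dense net over the ordered concatenation of two drug rows:
#' `2 * 300` inputs -> `hidden` (2048) -> 1 output (binary) or `n_classes`
#' outputs (multi-class).
#'
#' @param task `"binary"` or `"multiclass"`.
#' @param n_classes Output classes for the multi-class task.
#' @param hidden Hidden width of the dense layer.
#' @param d_drug Width of one drug row in `D`.
#' @param seed Seed for the weight draw.
#' @return A `classifier_params` list.
#' @export
init_classifier_params <- function(task = c("binary", "multiclass"),
                                   n_classes = 2L, hidden = 2048L,
                                   d_drug = 300L, seed = 1L) {
  task <- match.arg(task)
  n_out <- if (task == "binary") 1L else as.integer(n_classes)
  withr::with_seed(seed, {
    structure(
      list(
        task = task, n_out = n_out, hidden = as.integer(hidden),
        d_drug = as.integer(d_drug),
        W1 = init_mat(2L * d_drug, hidden), b1 = matrix(0, 1L, hidden),
        W2 = init_mat(hidden, n_out), b2 = matrix(0, 1L, n_out)
      ),
      class = "classifier_params"
    )
  })
}

# AD forward: logits for pair index rows (m x 2 integer matrix into D's rows)
classifier_forward <- function(D, pair_idx, head) {
  di <- ad_gather_rows(D, pair_idx[, 1L])
  dj <- ad_gather_rows(D, pair_idx[, 2L])
  x <- ad_concat_cols(list(di, dj))
  h <- ad_relu(ad_add_bias(ad_matmul(x, head$W1), head$b1))
  ad_add_bias(ad_matmul(h, head$W2), head$b2)
}

#' Score one drug pair
#'
#' Runs the dense head on `[d_i || d_j]` and squashes with a sigmoid
#' (binary) or row softmax (multi-class). Concatenation is ordered, so
#' `predict_pair(D, i, j)` need not equal `predict_pair(D, j, i)`; the
#' trained model averages both orders (see [predict.ddi_fit()]).
#'
#' @param D Drug representation matrix from [assemble_drug_matrix()] (rows
#'   named by drug id).
#' @param i,j Drug ids (rownames of `D`) or row indices.
#' @param head_params A `classifier_params` object.
#' @return A list of class `pair_prediction`: `drug_i`, `drug_j`, `task`,
#'   and `output` (probability in (0,1) for binary; a probability vector
#'   summing to 1 for multi-class).
#' @export
predict_pair <- function(D, i, j, head_params) {
  ri <- if (is.character(i)) match(i, rownames(D)) else as.integer(i)
  rj <- if (is.character(j)) match(j, rownames(D)) else as.integer(j)
  if (is.na(ri) || is.na(rj) || ri < 1L || rj < 1L ||
    ri > nrow(D) || rj > nrow(D)) {
    stop("unknown drug id or row index", call. = FALSE)
  }
  head_nodes <- params_to_nodes(
    head_params[c("W1", "b1", "W2", "b2")]
  )
  z <- ad_value(classifier_forward(
    ad_const(D), cbind(ri, rj), head_nodes
  ))
  output <- if (head_params$task == "binary") {
    unname(stats::plogis(z[1L, 1L]))
  } else {
    unname(drop(softmax_row(z)))
  }
  structure(
    list(drug_i = i, drug_j = j, task = head_params$task, output = output),
    class = "pair_prediction"
  )
}

softmax_row <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Binary cross-entropy for one pair prediction
#'
#' Standard form: `-(y log p + (1 - y) log(1 - p))` on the predicted
#' probability, with probabilities floored at `1e-12` inside the logs.
#' Setting `double_sigmoid_fidelity = TRUE` re-applies a sigmoid to `p` and
#' to `1 - p` inside the logs; this variant cannot reach zero loss and is
#' kept only for fidelity against the printed form (see the methods
#' vignette).
#'
#' @param prediction Predicted interaction probability in (0, 1).
#' @param label 0 or 1.
#' @param double_sigmoid_fidelity Use the double-squashing variant.
#' @return Non-negative scalar (the fidelity variant has a positive floor).
#' @export
binary_loss <- function(prediction, label, double_sigmoid_fidelity = FALSE) {
  if (!label %in% c(0, 1)) stop("label must be 0 or 1", call. = FALSE)
  stopifnot(prediction > 0, prediction < 1)
  if (double_sigmoid_fidelity) {
    p1 <- stats::plogis(prediction)
    p0 <- stats::plogis(1 - prediction)
    -(label * log(pmax(p1, 1e-12)) + (1 - label) * log(pmax(p0, 1e-12)))
  } else {
    -(label * log(pmax(prediction, 1e-12)) +
      (1 - label) * log(pmax(1 - prediction, 1e-12)))
  }
}

#' Label-smoothing cross-entropy for one multi-class prediction
#'
#' \deqn{l_m = (1-\epsilon)\,ce(i) + \epsilon \sum_{j \ne i}
#'   \frac{ce(j)}{N_c - 1}, \qquad ce(c) = -\log p_c.}
#' At `epsilon = 0` this is the plain cross-entropy `-log p_i`.
#'
#' @param prob_vector Probability vector of length `n_classes`.
#' @param true_class Zero-based class label (matching the on-disk DDI label
#'   convention `0 .. n_classes - 1`).
#' @param epsilon Smoothing mass in `[0, 1)`; the experimental default is
#'   0.15.
#' @param n_classes Number of classes (defaults to the vector length).
#' @return Non-negative scalar.
#' @export
label_smoothing_loss <- function(prob_vector, true_class, epsilon = 0.15,
                                 n_classes = length(prob_vector)) {
  stopifnot(
    epsilon >= 0, epsilon < 1,
    length(prob_vector) == n_classes,
    true_class >= 0, true_class < n_classes
  )
  if (any(prob_vector < 1e-12)) {
    warning("probabilities below the 1e-12 floor were clamped",
      call. = FALSE
    )
  }
  ce <- -log(pmax(prob_vector, 1e-12))
  i <- true_class + 1L
  (1 - epsilon) * ce[i] + epsilon * sum(ce[-i]) / (n_classes - 1L)
}

# smoothed one-hot target matrix for the AD training path: (1 - eps) on the
# true class, eps / (Nc - 1) elsewhere, so that -sum(T * log p) per row
# reproduces label_smoothing_loss() exactly
smooth_targets <- function(labels0, n_classes, epsilon) {
  T_ <- matrix(epsilon / (n_classes - 1L), length(labels0), n_classes)
  T_[cbind(seq_along(labels0), labels0 + 1L)] <- 1 - epsilon
  T_
}
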