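#' Training configuration for the full DDI model
#'
#' Defaults follow the experimental setup of the underlying method: learning
#' rate 0.0015 with batch size 3072 and 2 attention heads for the binary
#' task; learning rate 0.001, batch size 1000 and 4 heads for multi-class;
#' 200 epochs, label-smoothing 0.15, dense hidden width 2048, 20% test
#' split, and 1:1 negative-pair sampling for the binary task.
#'
#' @param task `"binary"` or `"multiclass"`.
#' @param learning_rate Adam step size for the joint stage (task default if
#'   `NULL`).
#' @param batch_size Pairs per minibatch (task default if `NULL`; batches
#'   larger than the training set collapse to full-batch steps).
#' @param epochs Joint-stage epochs.
#' @param n_heads Attention heads (task default if `NULL`: 2 binary / 4
#'   multi-class).
#' @param n_classes Classes for the multi-class task.
#' @param test_fraction Held-out fraction of the labeled pairs.
#' @param negative_pair_ratio Negatives sampled per positive when a binary
#'   pair table contains positives only.
#' @param smooth_epsilon Label-smoothing mass for the multi-class loss.
#' @param dense_hidden Hidden width of the pair-scoring dense layer.
#' @param lambda_ae Weight of the autoencoder reconstruction terms added to
#'   the task loss.
#' @param gin_hidden,gin_layers Width and depth of the (frozen) GIN encoder.
#' @param branches Named logical vector enabling the fusion branches
#'   (`lf1`, `lf2`, `lf3`, `lf4`); a disabled branch contributes a zero
#'   latent (the ablation hooks).
#' @param use_attention Disable to pass X through unrefined (attention
#'   ablation).
#' @param views Named logical vector enabling the `structure` and `kg`
#'   views; a disabled view enters fusion as a zero matrix (single-view
#'   ablations).
#' @param kg A [kg_config()] for the embedding pretraining stage.
#' @param seed Master seed; all stages derive their randomness from it.
#' @return A `ddi_config` list.
#' @export
ddi_config <- function(task = c("binary", "multiclass"),
                       learning_rate = NULL, batch_size = NULL,
                       epochs = 200L, n_heads = NULL, n_classes = 4L,
                       test_fraction = 0.2, negative_pair_ratio = 1,
                       smooth_epsilon = 0.15, dense_hidden = 2048L,
                       lambda_ae = 0.1, gin_hidden = 32L, gin_layers = 5L,
                       branches = c(
                         lf1 = TRUE, lf2 = TRUE,
                         lf3 = TRUE, lf4 = TRUE
                       ),
                       use_attention = TRUE,
                       views = c(structure = TRUE, kg = TRUE),
                       kg = kg_config(), seed = 1L) {
  task <- match.arg(task)
  stopifnot(
    test_fraction > 0, test_fraction < 1,
    smooth_epsilon >= 0, smooth_epsilon < 1
  )
  if (is.null(learning_rate)) {
    learning_rate <- if (task == "binary") 0.0015 else 0.001
  }
  if (is.null(batch_size)) batch_size <- if (task == "binary") 3072L else 1000L
  if (is.null(n_heads)) n_heads <- if (task == "binary") 2L else 4L
  stopifnot(batch_size >= 1L, epochs >= 1L)
  structure(
    list(
      task = task, learning_rate = learning_rate,
      batch_size = as.integer(batch_size), epochs = as.integer(epochs),
      n_heads = as.integer(n_heads), n_classes = as.integer(n_classes),
      test_fraction = test_fraction,
      negative_pair_ratio = negative_pair_ratio,
      smooth_epsilon = smooth_epsilon,
      dense_hidden = as.integer(dense_hidden), lambda_ae = lambda_ae,
      gin_hidden = as.integer(gin_hidden),
      gin_layers = as.integer(gin_layers),
      branches = branches, use_attention = use_attention, views = views,
      kg = kg, seed = as.integer(seed)
    ),
    class = "ddi_config"
  )
}

#' Train the multi-view DDI model
#'
#' Runs the three-stage pipeline: (1) pretrain RotatE embeddings on the KG
#' triples; (2) encode every drug's molecular graph with the frozen-weight
#' GIN; (3) jointly train the fusion block (convolutional and autoencoder
#' branches plus multi-head attention) and the pair classifier on the
#' training pairs, with the autoencoder reconstruction error as an
#' auxiliary loss. Drugs lacking either view (unparsable SMILES or no KG
#' node) are dropped with a warning, as are pairs referencing them. Each
#' training pair is presented in both orders; inference averages the two
#' orders. The run is fully deterministic given `config$seed` (and
#' `config$kg$seed` for the pretraining stage).
#'
#' For a binary pair table containing positives only, pseudo-negatives are
#' drawn at `config$negative_pair_ratio` before splitting.
#'
#' @param pairs Labeled DDI pairs (tibble with `drug_i`, `drug_j`, `label`).
#' @param drugs Drug table (tibble with `drug_id`, `smiles`).
#' @param kg_triples KG triples (tibble with `head`, `relation`, `tail`).
#' @param config A [ddi_config()].
#' @return A `ddi_fit` object; see [predict.ddi_fit()], [tidy()] /
#'   [glance()], [autoplot.ddi_fit()]. The held-out metrics live in
#'   `fit$metrics`.
#' @export
ddi_train <- function(pairs, drugs, kg_triples, config = ddi_config()) {
  stopifnot(inherits(config, "ddi_config"))
  pairs <- tibble::as_tibble(pairs)
  drugs <- tibble::as_tibble(drugs)
  kg_triples <- tibble::as_tibble(kg_triples)
  if (nrow(pairs) == 0L) stop("empty DDI pair set", call. = FALSE)

  ## ---- resolve drugs in both views -------------------------------------
  graphs <- parse_drug_table(drugs, on_error = "skip")
  kg_entities <- unique(c(kg_triples$head, kg_triples$tail))
  ids <- names(graphs)
  in_kg <- ids %in% kg_entities
  if (config$views[["kg"]] && !all(in_kg)) {
    warning(
      sum(!in_kg), " drug(s) without a KG node dropped: ",
      paste(utils::head(ids[!in_kg], 5L), collapse = ", "),
      call. = FALSE
    )
    ids <- ids[in_kg]
  }
  graphs <- graphs[ids]
  keep <- pairs$drug_i %in% ids & pairs$drug_j %in% ids
  if (!all(keep)) {
    warning(sum(!keep), " pair(s) referencing dropped drugs removed",
      call. = FALSE
    )
    pairs <- pairs[keep, ]
  }
  if (nrow(pairs) == 0L) stop("no trainable pairs left", call. = FALSE)

  ## ---- stage 1: KG pretraining ------------------------------------------
  kg_table <- NULL
  if (config$views[["kg"]]) {
    kg_table <- train_kg_embeddings(kg_triples, config$kg)
    eh <- kg_view_matrix(kg_table, ids)
  } else {
    eh <- matrix(0, length(ids), 100L, dimnames = list(ids, NULL))
  }

  ## ---- stage 2: frozen-GIN structure encoding ---------------------------
  if (config$views[["structure"]]) {
    gin <- init_gin_params(
      hidden = config$gin_hidden, n_layers = config$gin_layers,
      seed = config$seed
    )
    hG <- encode_drugs(graphs, gin)
  } else {
    gin <- NULL
    hG <- matrix(0, length(ids), 100L, dimnames = list(ids, NULL))
  }

  # column standardization keeps the two views on comparable scales
  scale_hG <- standardize_cols(hG)
  scale_eh <- standardize_cols(eh)
  hG_s <- scale_hG$x
  eh_s <- scale_eh$x

  ## ---- split / negative sampling ---------------------------------------
  if (config$task == "binary" && all(pairs$label == 1L)) {
    negs <- sample_negative_pairs(
      pairs, ids, config$negative_pair_ratio,
      seed = config$seed
    )
    pairs <- dplyr::bind_rows(pairs, negs)
  }
  split <- split_pairs(pairs, config$test_fraction, seed = config$seed)

  ## ---- stage 3: joint fusion + classifier training ----------------------
  joint <- train_joint_stage(hG_s, eh_s, ids, split$train, config)

  ## ---- final representations and held-out metrics -----------------------
  fit <- structure(
    list(
      config = config, drug_ids = ids,
      kg_table = kg_table, gin = gin,
      hG = hG_s, eh = eh_s,
      scale_hG = scale_hG[c("center", "scale")],
      scale_eh = scale_eh[c("center", "scale")],
      fusion = joint$fusion, head = joint$head,
      X = joint$X, X_att = joint$X_att,
      D = assemble_drug_matrix(joint$X_att, hG_s, eh_s),
      history = joint$history,
      train_pairs = split$train, test_pairs = split$test
    ),
    class = "ddi_fit"
  )
  fit$metrics <- ddi_evaluate(fit, split$test)
  fit
}

standardize_cols <- function(x) {
  ctr <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv < 1e-9] <- 1
  list(
    x = scale(x, center = ctr, scale = sdv)[, , drop = FALSE],
    center = ctr, scale = sdv
  )
}

# joint optimization of fusion + classifier on the AD graph
train_joint_stage <- function(hG, eh, ids, train_pairs, config) {
  n_drugs <- length(ids)
  pair_i <- match(train_pairs$drug_i, ids)
  pair_j <- match(train_pairs$drug_j, ids)
  # symmetrization: each labeled pair in both orders
  pidx <- rbind(cbind(pair_i, pair_j), cbind(pair_j, pair_i))
  labels <- rep(train_pairs$label, 2L)
  m <- nrow(pidx)

  withr::with_seed(config$seed, {
    fusion_np <- init_fusion_params(
      n_heads = config$n_heads,
      seed = sample.int(.Machine$integer.max, 1L)
    )
    head_np <- init_classifier_params(
      task = config$task, n_classes = config$n_classes,
      hidden = config$dense_hidden,
      seed = sample.int(.Machine$integer.max, 1L)
    )
    fusion_nodes <- params_to_nodes(
      fusion_np[c("conv_row", "conv_col", "ae_add", "ae_prod", "attn")]
    )
    head_nodes <- params_to_nodes(head_np[c("W1", "b1", "W2", "b2")])
    param_nodes <- c(
      collect_param_nodes(fusion_nodes), collect_param_nodes(head_nodes)
    )
    opt <- adam_init(param_nodes)
    hG_c <- ad_const(hG)
    eh_c <- ad_const(eh)
    targets <- if (config$task == "multiclass") {
      smooth_targets(labels, config$n_classes, config$smooth_epsilon)
    } else {
      matrix(labels, ncol = 1L)
    }
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(m)
      epoch_loss <- 0
      for (s in seq(1L, m, by = config$batch_size)) {
        b <- perm[s:min(s + config$batch_size - 1L, m)]
        fw <- fusion_forward(
          hG_c, eh_c, fusion_nodes, 100L, fusion_np$conv_channels,
          branches = config$branches, use_attention = config$use_attention
        )
        D <- ad_concat_cols(list(fw$X_att, hG_c, eh_c))
        z <- classifier_forward(D, pidx[b, , drop = FALSE], head_nodes)
        task_loss <- if (config$task == "binary") {
          y <- ad_const(targets[b, , drop = FALSE])
          ad_scale(
            ad_sum(ad_sub(ad_softplus(z), ad_mul(y, z))),
            1 / length(b)
          )
        } else {
          lp <- ad_log_softmax_rows(z)
          ad_scale(
            ad_sum(ad_mul(ad_const(targets[b, , drop = FALSE]), lp)),
            -1 / length(b)
          )
        }
        loss <- task_loss
        for (sl in list(fw$sl3, fw$sl4)) {
          if (!is.null(sl)) {
            mse <- ad_scale(
              ad_sum({
                d <- ad_sub(sl$recon, sl$fused)
                ad_mul(d, d)
              }),
              1 / length(ad_value(sl$fused))
            )
            loss <- ad_add(loss, ad_scale(mse, config$lambda_ae))
          }
        }
        ad_backward(loss)
        epoch_loss <- epoch_loss + ad_value(task_loss)[1L] * length(b)
        opt <- adam_step(opt, param_nodes, config$learning_rate)
      }
      history[epoch] <- epoch_loss / m
    }
    # freeze final representations over the full drug matrix
    fusion_final <- nodes_to_params(fusion_nodes)
    fusion_np[names(fusion_final)] <- fusion_final
    head_final <- nodes_to_params(head_nodes)
    head_np[names(head_final)] <- head_final
    fw <- fusion_forward(
      hG_c, eh_c, fusion_nodes, 100L, fusion_np$conv_channels,
      branches = config$branches, use_attention = config$use_attention
    )
    list(
      fusion = fusion_np, head = head_np,
      X = ad_value(fw$X), X_att = ad_value(fw$X_att),
      history = tibble::tibble(
        epoch = seq_len(config$epochs), loss = history
      )
    )
  })
}

#' Predict interaction scores for drug pairs
#'
#' Scores each pair with the trained head over the frozen drug
#' representation matrix, averaging the two concatenation orders
#' `[d_i || d_j]` and `[d_j || d_i]`.
#'
#' @param object A `ddi_fit`.
#' @param pairs Tibble with columns `drug_i`, `drug_j`.
#' @param ... Unused.
#' @return The input as a tibble with `score` (binary: interaction
#'   probability) or `class` + `prob` (multi-class: argmax class and its
#'   probability) appended.
#' @export
predict.ddi_fit <- function(object, pairs, ...) {
  pairs <- tibble::as_tibble(pairs)
  i <- match(pairs$drug_i, object$drug_ids)
  j <- match(pairs$drug_j, object$drug_ids)
  if (anyNA(i) || anyNA(j)) {
    stop("pairs reference drugs unknown to the model", call. = FALSE)
  }
  head_nodes <- params_to_nodes(object$head[c("W1", "b1", "W2", "b2")])
  D <- ad_const(object$D)
  z_fwd <- ad_value(classifier_forward(D, cbind(i, j), head_nodes))
  z_rev <- ad_value(classifier_forward(D, cbind(j, i), head_nodes))
  if (object$config$task == "binary") {
    score <- unname((stats::plogis(z_fwd[, 1L]) + stats::plogis(z_rev[, 1L])) / 2)
    dplyr::mutate(pairs, score = score)
  } else {
    p <- unname((t(apply(z_fwd, 1L, softmax_row)) +
      t(apply(z_rev, 1L, softmax_row))) / 2)
    cls <- max.col(p) - 1L
    dplyr::mutate(
      pairs,
      class = cls,
      prob = p[cbind(seq_len(nrow(p)), cls + 1L)]
    )
  }
}

#' Evaluate a fitted model on labeled pairs
#'
#' @param fit A `ddi_fit`.
#' @param pairs Labeled pairs (`drug_i`, `drug_j`, `label`).
#' @param threshold Decision threshold for the binary task.
#' @return A [compute_metrics()] report.
#' @export
ddi_evaluate <- function(fit, pairs, threshold = 0.5) {
  pred <- predict(fit, pairs)
  y_pred <- if (fit$config$task == "binary") {
    as.integer(pred$score >= threshold)
  } else {
    pred$class
  }
  suppressWarnings(compute_metrics(
    pairs$label, y_pred,
    n_classes = if (fit$config$task == "binary") 2L else fit$config$n_classes
  ))
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat(sprintf(
    "<ddi_fit: %s task, %d drugs, %d train / %d test pairs, %d epochs>\n",
    x$config$task, length(x$drug_ids), nrow(x$train_pairs),
    nrow(x$test_pairs), x$config$epochs
  ))
  print(x$metrics)
  invisible(x)
}

#' Per-epoch training loss of a fitted model
#'
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss` (mean per-pair task loss).
#' @method tidy ddi_fit
#' @export
tidy.ddi_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @return One-row tibble: held-out metrics plus key configuration.
#' @method glance ddi_fit
#' @export
glance.ddi_fit <- function(x, ...) {
  dplyr::mutate(
    glance(x$metrics),
    task = x$config$task,
    n_drugs = length(x$drug_ids),
    epochs = x$config$epochs,
    final_loss = x$history$loss[nrow(x$history)]
  )
}

#' Plot the training loss curve
#'
#' @param object A `ddi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddi_fit
#' @export
autoplot.ddi_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$history,
    ggplot2::aes(x = .data$epoch, y = .data$loss)
  ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(
      x = "epoch", y = "mean task loss",
      title = "Joint fusion + classifier training loss"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-class precision and recall
#'
#' @param object A `ddi_metrics` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddi_metrics
#' @export
autoplot.ddi_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_class[, c("class", "precision", "recall")],
    c("precision", "recall"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = factor(.data$class), y = .data$value, fill = .data$metric
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "class", y = NULL, title = "Per-class metrics") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom stats predict
#' @importFrom rlang .data
NULL
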