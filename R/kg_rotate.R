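#' Configuration for RotatE knowledge-graph embedding training
#'
#' @param margin Fixed margin \eqn{\gamma_1} of the negative-sampling loss.
#' @param negatives_per_positive Corrupted triples drawn per positive.
#' @param learning_rate Adam step size.
#' @param epochs Passes over the triple set.
#' @param batch_size Positives per minibatch.
#' @param dim Flattened entity embedding length; entities live in complex
#'   space of dimension `dim / 2` so that `real || imag` has length `dim`.
#' @param seed Seed controlling initialization and negative sampling.
#' @param loss_convention `"rotate-standard"` uses the self-consistent
#'   distance form \eqn{-\log\sigma(\gamma_1 - s_{pos}) - \frac{1}{k}\sum
#'   \log\sigma(s_{neg} - \gamma_1)}; `"as-printed"` uses
#'   \eqn{-\sum\log\sigma(s_{pos} - s_{neg} - \gamma_1)}, which rewards
#'   *large* positive scores and is kept only for fidelity checks (see the
#'   methods vignette).
#' @return A `kg_config` list.
#' @export
kg_config <- function(margin = 12, negatives_per_positive = 128L,
                      learning_rate = 0.05, epochs = 200L,
                      batch_size = 512L, dim = 100L, seed = 1L,
                      loss_convention = c("rotate-standard", "as-printed")) {
  stopifnot(
    margin >= 0, negatives_per_positive >= 1L, dim %% 2L == 0L,
    learning_rate > 0, epochs >= 1L
  )
  structure(
    list(
      margin = margin,
      negatives_per_positive = as.integer(negatives_per_positive),
      learning_rate = learning_rate,
      epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      dim = as.integer(dim),
      seed = as.integer(seed),
      loss_convention = match.arg(loss_convention)
    ),
    class = "kg_config"
  )
}

#' RotatE triple score
#'
#' Entities are complex vectors and each relation a vector of unit-modulus
#' rotations \eqn{e^{i\theta}} (Euler form \eqn{\cos\theta + i \sin\theta}).
#' The score of a triple is the distance
#' \eqn{score(h, r, t) = \lVert e_h \circ e_r - e_t \rVert} (elementwise
#' complex product, Euclidean norm): 0 exactly when rotating the head by the
#' relation reproduces the tail, and larger the less plausible the triple.
#'
#' @param head_vec,tail_vec Complex vectors of equal length.
#' @param relation_phase Numeric phase vector (radians), same length.
#' @return Non-negative scalar distance.
#' @examples
#' h <- complex(real = rnorm(4), imaginary = rnorm(4))
#' th <- runif(4, -pi, pi)
#' rotate_score(h, th, h * complex(modulus = 1, argument = th))  # 0
#' @export
rotate_score <- function(head_vec, relation_phase, tail_vec) {
  stopifnot(
    length(head_vec) == length(relation_phase),
    length(head_vec) == length(tail_vec)
  )
  r <- complex(modulus = 1, argument = relation_phase)
  sqrt(sum(Mod(head_vec * r - tail_vec)^2))
}

#' Initialize a complex embedding table
#'
#' Entity coordinates start uniform on \[-0.5, 0.5\]; relation phases uniform
#' on \[-pi, pi\]. Relations are *stored* as phases, so their complex modulus
#' is exactly 1 by construction, at initialization and after every update.
#'
#' @param entities,relations Character vectors naming the vocabularies.
#' @param dim Flattened embedding length (complex dimension `dim / 2`).
#' @param seed Seed for the draw.
#' @return A `kg_embeddings` object with matrices `ent_re`, `ent_im`
#'   (`n_entities` x `dim/2`) and `rel_phase` (`n_relations` x `dim/2`).
#' @export
init_kg_table <- function(entities, relations, dim = 100L, seed = 1L) {
  stopifnot(dim %% 2L == 0L, !anyDuplicated(entities), !anyDuplicated(relations))
  d_c <- dim %/% 2L
  withr::with_seed(seed, {
    structure(
      list(
        entities = as.character(entities),
        relations = as.character(relations),
        d_c = d_c,
        ent_re = matrix(stats::runif(length(entities) * d_c, -0.5, 0.5),
          length(entities), d_c,
          dimnames = list(entities, NULL)
        ),
        ent_im = matrix(stats::runif(length(entities) * d_c, -0.5, 0.5),
          length(entities), d_c,
          dimnames = list(entities, NULL)
        ),
        rel_phase = matrix(stats::runif(length(relations) * d_c, -pi, pi),
          length(relations), d_c,
          dimnames = list(relations, NULL)
        ),
        loss_history = numeric(0)
      ),
      class = "kg_embeddings"
    )
  })
}

#' @export
print.kg_embeddings <- function(x, ...) {
  cat(sprintf(
    "<kg_embeddings: %d entities, %d relations, complex dim %d (%d epochs trained)>\n",
    length(x$entities), length(x$relations), x$d_c, length(x$loss_history)
  ))
  invisible(x)
}

#' Complex entity embedding lookup
#' @noRd
entity_complex <- function(table, entity_id) {
  i <- match(entity_id, table$entities)
  if (is.na(i)) stop("unknown entity: ", entity_id, call. = FALSE)
  complex(real = table$ent_re[i, ], imaginary = table$ent_im[i, ])
}

#' Flattened real entity vector for the fusion module
#'
#' Concatenates the real and imaginary entity coordinates into a single real
#' vector of the shared fusion length (`2 * d_c`, 100 by default).
#'
#' @param table A `kg_embeddings` object.
#' @param entity_id Entity name.
#' @return Numeric vector of length `2 * table$d_c`.
#' @export
entity_vector <- function(table, entity_id) {
  i <- match(entity_id, table$entities)
  if (is.na(i)) stop("unknown entity: ", entity_id, call. = FALSE)
  c(table$ent_re[i, ], table$ent_im[i, ])
}

#' Relation phase lookup
#' @param table A `kg_embeddings` object.
#' @param relation_id Relation name.
#' @return Numeric phase vector (radians) of length `table$d_c`.
#' @export
relation_phase <- function(table, relation_id) {
  i <- match(relation_id, table$relations)
  if (is.na(i)) stop("unknown relation: ", relation_id, call. = FALSE)
  table$rel_phase[i, ]
}

#' Score a table of triples under a trained embedding
#'
#' @param table A `kg_embeddings` object.
#' @param triples Data frame with character columns `head`, `relation`,
#'   `tail`.
#' @return The input as a tibble with a `score` column appended.
#' @export
score_triples <- function(table, triples) {
  idx <- triple_indices(table, triples)
  tibble::as_tibble(triples) |>
    dplyr::mutate(score = score_idx(table, idx$h, idx$r, idx$t))
}

triple_indices <- function(table, triples) {
  h <- match(triples$head, table$entities)
  r <- match(triples$relation, table$relations)
  t_ <- match(triples$tail, table$entities)
  if (anyNA(h) || anyNA(r) || anyNA(t_)) {
    stop("triples contain ids outside the embedding vocabularies",
      call. = FALSE
    )
  }
  list(h = h, r = r, t = t_)
}

# vectorized distance for index triples
score_idx <- function(table, h, r, t_) {
  ct <- cos(table$rel_phase[r, , drop = FALSE])
  st <- sin(table$rel_phase[r, , drop = FALSE])
  hre <- table$ent_re[h, , drop = FALSE]
  him <- table$ent_im[h, , drop = FALSE]
  mre <- hre * ct - him * st - table$ent_re[t_, , drop = FALSE]
  mim <- hre * st + him * ct - table$ent_im[t_, , drop = FALSE]
  unname(sqrt(rowSums(mre^2 + mim^2)))
}

#' Sample corrupted (negative) triples for one positive
#'
#' Each negative replaces the head or the tail (fair coin) with a uniformly
#' drawn entity and is rejected if it reproduces any known positive triple.
#'
#' @param triple A list or one-row data frame with `head`, `relation`,
#'   `tail`.
#' @param entities Character vector of candidate entities (the vocabulary).
#' @param k Number of negatives.
#' @param seed Integer seed; same seed, same output.
#' @param positive_keys Optional character set of `"h|r|t"` keys to filter
#'   against (defaults to the positive triple itself).
#' @return Tibble of `k` corrupted triples.
#' @export
sample_negatives <- function(triple, entities, k, seed = 1L,
                             positive_keys = NULL) {
  stopifnot(k >= 0L)
  if (length(entities) < 2L) {
    stop("need at least 2 entities to corrupt a triple", call. = FALSE)
  }
  if (is.null(positive_keys)) {
    positive_keys <- triple_key(triple$head, triple$relation, triple$tail)
  }
  if (k == 0L) {
    return(tibble::tibble(
      head = character(0), relation = character(0), tail = character(0)
    ))
  }
  withr::with_seed(seed, {
    heads <- character(0)
    tails <- character(0)
    guard <- 0L
    while (length(heads) < k && guard < 100L) {
      need <- k - length(heads)
      corrupt_head <- stats::runif(need) < 0.5
      repl <- sample(entities, need, replace = TRUE)
      h <- ifelse(corrupt_head, repl, triple$head)
      t_ <- ifelse(corrupt_head, triple$tail, repl)
      ok <- !(triple_key(h, triple$relation, t_) %in% positive_keys)
      heads <- c(heads, h[ok])
      tails <- c(tails, t_[ok])
      guard <- guard + 1L
    }
    if (length(heads) < k) {
      stop("could not find enough non-positive corruptions", call. = FALSE)
    }
    tibble::tibble(
      head = heads[seq_len(k)],
      relation = triple$relation,
      tail = tails[seq_len(k)]
    )
  })
}

triple_key <- function(h, r, t_) paste(h, r, t_, sep = "\r")

#' Negative-sampling loss for one positive triple
#'
#' Under `"rotate-standard"` the loss is
#' \eqn{-\log\sigma(\gamma_1 - s_{pos}) - \frac{1}{k}\sum_i
#' \log\sigma(s_{neg,i} - \gamma_1)}; under `"as-printed"` it is
#' \eqn{-\sum_i \log\sigma(s_{pos} - s_{neg,i} - \gamma_1)}.
#'
#' @param positive One triple (list/one-row data frame with `head`,
#'   `relation`, `tail`).
#' @param negatives Data frame of corrupted triples (nonempty).
#' @param table A `kg_embeddings` object.
#' @param config A `kg_config` (supplies the margin and the convention).
#' @return Finite scalar loss.
#' @export
kg_loss <- function(positive, negatives, table, config = kg_config()) {
  stopifnot(nrow(negatives) >= 1L)
  pos_idx <- triple_indices(table, tibble::as_tibble(positive))
  s_pos <- score_idx(table, pos_idx$h, pos_idx$r, pos_idx$t)
  neg_idx <- triple_indices(table, negatives)
  s_neg <- score_idx(table, neg_idx$h, neg_idx$r, neg_idx$t)
  kg_loss_from_scores(s_pos, s_neg, config)
}

kg_loss_from_scores <- function(s_pos, s_neg, config) {
  g <- config$margin
  if (config$loss_convention == "as-printed") {
    -sum(log_sigmoid(s_pos - s_neg - g))
  } else {
    -log_sigmoid(g - s_pos) - mean(log_sigmoid(s_neg - g))
  }
}

log_sigmoid <- function(x) -softplus(-x)

#' Train RotatE embeddings on a triple set
#'
#' Stochastic minibatch training with Adam on the entity coordinates and
#' relation phases. Relations are parameterized as phases throughout, so the
#' unit-modulus constraint is conserved exactly at every step. Negative
#' triples are resampled each epoch (filtered against the positive set) and
#' the per-epoch mean loss is recorded in `loss_history`. The full run is
#' deterministic given `config$seed`.
#'
#' @param triples Data frame with character columns `head`, `relation`,
#'   `tail` (one positive triple per row).
#' @param config A `kg_config`.
#' @param entities,relations Optional explicit vocabularies; by default they
#'   are collected (in order of first appearance) from the triples.
#' @return A trained `kg_embeddings` object.
#' @export
train_kg_embeddings <- function(triples, config = kg_config(),
                                entities = NULL, relations = NULL) {
  triples <- tibble::as_tibble(triples)
  if (nrow(triples) == 0L) stop("empty triple set", call. = FALSE)
  if (is.null(entities)) {
    entities <- unique(c(triples$head, triples$tail))
  }
  if (is.null(relations)) relations <- unique(triples$relation)
  table <- init_kg_table(entities, relations, config$dim, config$seed)
  idx <- triple_indices(table, triples)
  H <- idx$h
  R <- idx$r
  T_ <- idx$t
  n <- length(H)
  n_ent <- length(entities)
  pos_keys <- paste(H, R, T_)
  k <- config$negatives_per_positive
  params <- list(
    ent_re = table$ent_re, ent_im = table$ent_im, phase = table$rel_phase
  )
  opt <- list(
    t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        b <- perm[s:min(s + config$batch_size - 1L, n)]
        nb <- length(b)
        # corrupt head or tail uniformly; filter collisions with positives
        ch <- matrix(stats::runif(nb * k) < 0.5, nb, k)
        repl <- matrix(sample.int(n_ent, nb * k, replace = TRUE), nb, k)
        nh <- ifelse(ch, repl, H[b])
        nt <- ifelse(ch, T_[b], repl)
        bad <- matrix(paste(nh, R[b], nt) %in% pos_keys, nb, k)
        for (pass in 1:5) {
          if (!any(bad)) break
          m <- sum(bad)
          repl2 <- sample.int(n_ent, m, replace = TRUE)
          nh[bad] <- ifelse(ch[bad], repl2, H[b][row(bad)[bad]])
          nt[bad] <- ifelse(ch[bad], T_[b][row(bad)[bad]], repl2)
          bad <- matrix(paste(nh, R[b], nt) %in% pos_keys, nb, k)
        }
        step <- kg_sgd_step(params, H[b], R[b], T_[b], nh, nt, config)
        epoch_loss <- epoch_loss + step$loss * nb
        opt <- kg_adam(opt, params, step$grads, config$learning_rate)
        params <- opt$params
      }
      table$loss_history <- c(table$loss_history, epoch_loss / n)
    }
  })
  table$ent_re <- params$ent_re
  table$ent_im <- params$ent_im
  table$rel_phase <- params$phase
  dimnames(table$ent_re) <- list(entities, NULL)
  dimnames(table$ent_im) <- list(entities, NULL)
  dimnames(table$rel_phase) <- list(relations, NULL)
  table
}

# score + analytic gradient for a batch: positives (h, r, t vectors) and the
# nb x k corruption matrices. Returns mean per-positive loss and gradient
# matrices matching params.
kg_sgd_step <- function(params, h, r, t_, neg_h, neg_t, config) {
  k <- ncol(neg_h)
  nb <- length(h)
  g <- config$margin
  sp <- kg_dist(params, h, r, t_)
  rl <- rep(r, k)
  sn <- kg_dist(params, as.vector(neg_h), rl, as.vector(neg_t))
  if (config$loss_convention == "as-printed") {
    x <- rep(sp$d, k) - sn$d - g
    w <- 1 - stats::plogis(x)
    loss <- sum(softplus(-x)) / nb
    coef_pos <- -rowSums(matrix(w, nb, k)) / nb
    coef_neg <- w / nb
  } else {
    loss <- (sum(softplus(sp$d - g)) + sum(softplus(g - sn$d)) / k) / nb
    coef_pos <- (1 - stats::plogis(g - sp$d)) / nb
    coef_neg <- -(1 - stats::plogis(sn$d - g)) / (k * nb)
  }
  grads <- kg_zero_grads(params)
  grads <- kg_accum_grad(grads, params, sp, h, r, t_, coef_pos)
  grads <- kg_accum_grad(
    grads, params, sn, as.vector(neg_h), rl, as.vector(neg_t), coef_neg
  )
  list(loss = loss, grads = grads)
}

# distances plus the intermediates needed for the chain rule
kg_dist <- function(params, h, r, t_) {
  ct <- cos(params$phase[r, , drop = FALSE])
  st <- sin(params$phase[r, , drop = FALSE])
  hre <- params$ent_re[h, , drop = FALSE]
  him <- params$ent_im[h, , drop = FALSE]
  rot_re <- hre * ct - him * st
  rot_im <- hre * st + him * ct
  mre <- rot_re - params$ent_re[t_, , drop = FALSE]
  mim <- rot_im - params$ent_im[t_, , drop = FALSE]
  list(
    d = sqrt(rowSums(mre^2 + mim^2)),
    ct = ct, st = st, rot_re = rot_re, rot_im = rot_im, mre = mre, mim = mim
  )
}

kg_zero_grads <- function(params) lapply(params, function(p) p * 0)

# d(coef * d)/d(params): g_m = coef * m / d, chained through the rotation
kg_accum_grad <- function(grads, params, s, h, r, t_, coef) {
  d_safe <- pmax(s$d, 1e-12)
  gre <- (coef / d_safe) * s$mre
  gim <- (coef / d_safe) * s$mim
  dh_re <- gre * s$ct + gim * s$st
  dh_im <- -gre * s$st + gim * s$ct
  dth <- gre * (-s$rot_im) + gim * s$rot_re
  grads$ent_re <- scatter_add(grads$ent_re, h, dh_re)
  grads$ent_im <- scatter_add(grads$ent_im, h, dh_im)
  grads$ent_re <- scatter_add(grads$ent_re, t_, -gre)
  grads$ent_im <- scatter_add(grads$ent_im, t_, -gim)
  grads$phase <- scatter_add(grads$phase, r, dth)
  grads
}

scatter_add <- function(acc, idx, rows) {
  s <- rowsum(rows, group = idx)
  ii <- as.integer(rownames(s))
  acc[ii, ] <- acc[ii, , drop = FALSE] + s
  acc
}

kg_adam <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                    eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  opt$params <- params
  opt
}

#' KG-view matrix for a set of drugs
#'
#' Stacks [entity_vector()] rows for the given drugs.
#'
#' @param table A `kg_embeddings` object.
#' @param drug_ids Character vector of entity names.
#' @return Matrix `length(drug_ids)` x `2 * d_c` with rownames `drug_ids`.
#' @export
kg_view_matrix <- function(table, drug_ids) {
  out <- t(vapply(
    drug_ids, function(id) entity_vector(table, id),
    numeric(2L * table$d_c)
  ))
  rownames(out) <- drug_ids
  out
}
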