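#' Split labeled drug pairs into train and test sets
#'
#' Disjoint, exhaustive, seed-deterministic split; with `stratify = TRUE`
#' the split is drawn per label so class proportions carry over within
#' rounding. A label with fewer than 2 members makes stratification fall
#' back to a plain split with a warning.
#'
#' @param pairs Data frame of labeled pairs (columns `drug_i`, `drug_j`,
#'   `label`).
#' @param test_fraction Fraction held out, in (0, 1); the experimental
#'   default holds out 20%.
#' @param seed Integer seed.
#' @param stratify Stratify by `label`.
#' @return List with tibbles `train` and `test`.
#' @export
split_pairs <- function(pairs, test_fraction = 0.2, seed = 1L,
                        stratify = TRUE) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(nrow(pairs) >= 2L, test_fraction > 0, test_fraction < 1)
  if (stratify && min(table(pairs$label)) < 2L) {
    warning("a label has fewer than 2 members; splitting without strata",
      call. = FALSE
    )
    stratify <- FALSE
  }
  withr::with_seed(seed, {
    take <- function(n) {
      n_test <- max(1L, round(n * test_fraction))
      sample(rep(c(TRUE, FALSE), c(n_test, n - n_test)))
    }
    is_test <- if (stratify) {
      flags <- logical(nrow(pairs))
      for (lv in unique(pairs$label)) {
        rows <- which(pairs$label == lv)
        flags[rows] <- take(length(rows))
      }
      flags
    } else {
      take(nrow(pairs))
    }
    list(train = pairs[!is_test, ], test = pairs[is_test, ])
  })
}

#' Sample non-interacting drug pairs for the binary task
#'
#' Draws unordered drug pairs uniformly from the vocabulary, rejecting
#' anything present (in either order) in the positive set or already drawn,
#' and labels them 0. The binary DDI matrix records known interactions only,
#' so these are pseudo-negatives: a 0 does not certify the absence of an
#' interaction.
#'
#' @param positive_pairs Data frame with columns `drug_i`, `drug_j`.
#' @param drug_vocab Character vector of candidate drug ids.
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed.
#' @return Tibble of sampled pairs with `label = 0`.
#' @export
sample_negative_pairs <- function(positive_pairs, drug_vocab, ratio = 1,
                                  seed = 1L) {
  stopifnot(ratio > 0, length(drug_vocab) >= 2L)
  n_want <- ceiling(nrow(positive_pairs) * ratio)
  n_possible <- choose(length(drug_vocab), 2L)
  pos_keys <- unordered_key(positive_pairs$drug_i, positive_pairs$drug_j)
  if (n_want > n_possible - length(unique(pos_keys))) {
    stop("candidate pair space exhausted: cannot sample ", n_want,
      " negatives",
      call. = FALSE
    )
  }
  withr::with_seed(seed, {
    drawn <- character(0)
    di <- character(0)
    dj <- character(0)
    while (length(drawn) < n_want) {
      need <- n_want - length(drawn)
      a <- sample(drug_vocab, 2L * need + 10L, replace = TRUE)
      b <- sample(drug_vocab, 2L * need + 10L, replace = TRUE)
      ok <- a != b
      a <- a[ok]
      b <- b[ok]
      key <- unordered_key(a, b)
      keep <- !(key %in% pos_keys) & !(key %in% drawn) & !duplicated(key)
      a <- a[keep]
      b <- b[keep]
      key <- key[keep]
      take <- seq_len(min(need, length(key)))
      drawn <- c(drawn, key[take])
      di <- c(di, a[take])
      dj <- c(dj, b[take])
    }
    tibble::tibble(drug_i = di, drug_j = dj, label = 0L)
  })
}

unordered_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Classification metrics with per-class macro averaging
#'
#' Builds one-vs-rest confusion counts per class and reports
#' \deqn{Acc = \frac{1}{N_c}\sum_i \frac{TP_i + TN_i}{TP_i + FN_i + FP_i +
#'   TN_i}, \quad Precision = \frac{1}{N_c}\sum_i \frac{TP_i}{TP_i + FP_i},}
#' \deqn{Recall = \frac{1}{N_c}\sum_i \frac{TP_i}{TP_i + FN_i}, \quad
#'   F1 = \frac{2 \cdot Precision \cdot Recall}{Precision + Recall},}
#' i.e. the F1 is formed from the macro precision and recall (not averaged
#' per class). Undefined 0/0 ratios contribute 0 with a warning. The plain
#' sample accuracy `mean(y_true == y_pred)` is reported separately as
#' `accuracy_plain` (for two classes the per-class mean accuracy coincides
#' with it).
#'
#' @param y_true,y_pred Integer class labels, zero-based (`0 .. n_classes -
#'   1`), equal length.
#' @param n_classes Number of classes (default: largest label + 1).
#' @return A `ddi_metrics` object: list with `per_class` (tibble of TP, TN,
#'   FP, FN, precision, recall per class) and scalars `accuracy`,
#'   `precision`, `recall`, `f1`, `accuracy_plain`, `n`.
#' @examples
#' m <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' m$recall # 0.75
#' @export
compute_metrics <- function(y_true, y_pred,
                            n_classes = max(y_true, y_pred) + 1L) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  stopifnot(all(y_true >= 0L), all(y_pred >= 0L), all(y_true < n_classes),
    all(y_pred < n_classes))
  n <- length(y_true)
  classes <- seq_len(n_classes) - 1L
  tp <- fp <- fn <- tn <- integer(n_classes)
  for (k in seq_along(classes)) {
    c_ <- classes[k]
    tp[k] <- sum(y_true == c_ & y_pred == c_)
    fp[k] <- sum(y_true != c_ & y_pred == c_)
    fn[k] <- sum(y_true == c_ & y_pred != c_)
    tn[k] <- sum(y_true != c_ & y_pred != c_)
  }
  safe_ratio <- function(num, den, what) {
    out <- ifelse(den == 0L, 0, num / den)
    if (any(den == 0L)) {
      warning("undefined ", what, " (0/0) set to 0 for ",
        sum(den == 0L), " class(es)",
        call. = FALSE
      )
    }
    out
  }
  prec_k <- safe_ratio(tp, tp + fp, "precision")
  rec_k <- safe_ratio(tp, tp + fn, "recall")
  precision <- mean(prec_k)
  recall <- mean(rec_k)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(
      per_class = tibble::tibble(
        class = classes, tp = tp, tn = tn, fp = fp, fn = fn,
        precision = prec_k, recall = rec_k
      ),
      accuracy = mean((tp + tn) / n),
      precision = precision,
      recall = recall,
      f1 = f1,
      accuracy_plain = mean(y_true == y_pred),
      n = n,
      n_classes = as.integer(n_classes)
    ),
    class = "ddi_metrics"
  )
}

#' @export
print.ddi_metrics <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<ddi_metrics: n = %d, %d classes>\n",
      "  accuracy (per-class mean): %.4f   plain: %.4f\n",
      "  macro precision: %.4f   macro recall: %.4f   F1: %.4f\n"
    ),
    x$n, x$n_classes, x$accuracy, x$accuracy_plain,
    x$precision, x$recall, x$f1
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-class metric rows
#'
#' @param x A `ddi_metrics` object.
#' @param ... Unused.
#' @return Tibble with one row per class (counts, precision, recall).
#' @method tidy ddi_metrics
#' @export
tidy.ddi_metrics <- function(x, ...) x$per_class

#' One-row metric summary
#'
#' @param x A `ddi_metrics` object.
#' @param ... Unused.
#' @return One-row tibble with the macro metrics.
#' @method glance ddi_metrics
#' @export
glance.ddi_metrics <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    accuracy_plain = x$accuracy_plain,
    precision = x$precision,
    recall = x$recall,
    f1 = x$f1,
    n = x$n,
    n_classes = x$n_classes
  )
}
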