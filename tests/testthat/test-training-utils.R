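# Pair splitting, pseudo-negative sampling, and the macro-averaged metrics
# against an independent confusion-matrix oracle.

test_that("splits are disjoint, exhaustive and seed-deterministic", {
  pairs <- tibble::tibble(
    drug_i = paste0("A", 1:10), drug_j = paste0("B", 1:10),
    label = rep(c(0L, 1L), 5L)
  )
  sp <- split_pairs(pairs, 0.2, seed = 1L)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$test), 2L)
  joined <- dplyr::bind_rows(sp$train, sp$test)
  expect_setequal(
    paste(joined$drug_i, joined$drug_j),
    paste(pairs$drug_i, pairs$drug_j)
  )
  expect_identical(sp, split_pairs(pairs, 0.2, seed = 1L))
  expect_false(identical(sp$test, split_pairs(pairs, 0.2, seed = 2L)$test))
})

test_that("stratified splitting preserves class proportions", {
  withr::with_seed(2, {
    pairs <- tibble::tibble(
      drug_i = sprintf("X%03d", 1:200),
      drug_j = sprintf("Y%03d", 1:200),
      label = rep(0:4, each = 40L)
    )
  })
  sp <- split_pairs(pairs, 0.25, seed = 3L)
  expect_equal(as.vector(table(sp$test$label)), rep(10L, 5L))
  expect_equal(as.vector(table(sp$train$label)), rep(30L, 5L))
  # degenerate stratum falls back with a warning
  small <- pairs[c(1L, 41L, 81L, 121L, 161L, 2L), ]
  small$label[6L] <- 9L
  expect_warning(split_pairs(small, 0.3, seed = 1L), "fewer than 2")
})

test_that("negative pairs avoid positives, duplicates and are seeded", {
  vocab <- sprintf("D%02d", 1:15)
  pos <- tibble::tibble(
    drug_i = vocab[1:10], drug_j = vocab[6:15], label = 1L
  )
  negs <- sample_negative_pairs(pos, vocab, ratio = 1, seed = 4L)
  expect_equal(nrow(negs), 10L)
  expect_true(all(negs$label == 0L))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_false(any(key(negs$drug_i, negs$drug_j) %in%
    key(pos$drug_i, pos$drug_j)))
  expect_false(anyDuplicated(key(negs$drug_i, negs$drug_j)) > 0)
  expect_identical(negs, sample_negative_pairs(pos, vocab, 1, seed = 4L))
  # candidate space exhaustion
  expect_error(
    sample_negative_pairs(pos, c("a", "b"), ratio = 50),
    "exhausted"
  )
})

test_that("metrics match the hand-built confusion oracle", {
  # truth (1,1,0,0), prediction (1,0,0,0): macro recall 0.75,
  # macro precision 5/6, F1 = 2PR/(P+R)
  m <- compute_metrics(c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L))
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(
    m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
    tolerance = 1e-12
  )
  expect_equal(m$f1, 0.7894737, tolerance = 1e-6)
  # per-class counts: class 1 has TP 1, FN 1, FP 0, TN 2
  c1 <- m$per_class[m$per_class$class == 1L, ]
  expect_equal(c(c1$tp, c1$fn, c1$fp, c1$tn), c(1L, 1L, 0L, 2L))

  perfect <- compute_metrics(0:3, 0:3)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  # all-one-class predictions on balanced truth: macro recall 0.5
  all1 <- suppressWarnings(
    compute_metrics(rep(0:1, each = 10L), rep(1L, 20L))
  )
  expect_equal(all1$recall, 0.5)
  expect_warning(
    compute_metrics(rep(0:1, each = 10L), rep(1L, 20L)),
    "undefined precision"
  )
})

test_that("metrics agree with an independent implementation on random
           configurations", {
  withr::with_seed(7, {
    for (i in 1:200) {
      nc <- sample(2:8, 1L)
      n <- sample(10:60, 1L)
      y_true <- sample(0:(nc - 1L), n, replace = TRUE)
      y_pred <- sample(0:(nc - 1L), n, replace = TRUE)
      m <- suppressWarnings(compute_metrics(y_true, y_pred, nc))
      o <- oracle_metrics(y_true, y_pred, nc)
      expect_equal(m$accuracy, o$accuracy, tolerance = 1e-12)
      expect_equal(m$precision, o$precision, tolerance = 1e-12)
      expect_equal(m$recall, o$recall, tolerance = 1e-12)
      expect_equal(m$f1, o$f1, tolerance = 1e-12)
      # count conservation per class
      expect_true(all(
        m$per_class$tp + m$per_class$tn +
          m$per_class$fp + m$per_class$fn == n
      ))
    }
  })
})

test_that("metric accessors expose tidy and glance views", {
  m <- compute_metrics(c(0L, 1L, 1L, 0L), c(0L, 1L, 0L, 0L))
  td <- generics::tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2L)
  gl <- generics::glance(m)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("accuracy", "precision", "recall", "f1") %in% names(gl)))
  expect_error(compute_metrics(0:1, 0L), "equal length")
})
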