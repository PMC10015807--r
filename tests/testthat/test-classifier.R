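# Final representation assembly, pair scoring head, and the two loss
# functions with their scalar oracles.

test_that("drug matrix assembly is a width-300 ordered concatenation", {
  withr::with_seed(1, {
    xa <- matrix(rnorm(300), 3L)
    hg <- matrix(rnorm(300), 3L, dimnames = list(c("A", "B", "C"), NULL))
    eh <- matrix(rnorm(300), 3L)
  })
  D <- assemble_drug_matrix(xa, hg, eh)
  expect_equal(dim(D), c(3L, 300L))
  expect_equal(D[, 1:100], xa, ignore_attr = TRUE)
  expect_equal(D[, 101:200], hg, ignore_attr = TRUE)
  expect_equal(D[, 201:300], eh, ignore_attr = TRUE)
  expect_equal(rownames(D), c("A", "B", "C"))
  # single drug works
  expect_equal(
    dim(assemble_drug_matrix(xa[1L, , drop = FALSE],
      hg[1L, , drop = FALSE], eh[1L, , drop = FALSE])),
    c(1L, 300L)
  )
  expect_error(assemble_drug_matrix(xa[, 1:50], hg, eh))
})

test_that("pair predictions are proper probabilities", {
  withr::with_seed(2, D <- matrix(rnorm(4 * 300), 4L,
    dimnames = list(paste0("D", 1:4), NULL)
  ))
  hb <- init_classifier_params("binary", hidden = 32L, seed = 3L)
  pb <- predict_pair(D, "D1", "D2", hb)
  expect_s3_class(pb, "pair_prediction")
  expect_true(pb$output > 0 && pb$output < 1)

  hm <- init_classifier_params("multiclass", n_classes = 5L,
    hidden = 32L, seed = 3L)
  pm <- predict_pair(D, 1L, 4L, hm)
  expect_length(pm$output, 5L)
  expect_equal(sum(pm$output), 1, tolerance = 1e-12)
  expect_true(all(pm$output > 0))

  # zero weights and biases: sigmoid(0) = 0.5
  hz <- hb
  hz$W1 <- hz$W1 * 0
  hz$W2 <- hz$W2 * 0
  expect_equal(predict_pair(D, "D1", "D2", hz)$output, 0.5)

  expect_error(predict_pair(D, "D1", "nope", hb), "unknown drug")
})

test_that("binary cross-entropy matches its scalar oracle", {
  expect_equal(binary_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(binary_loss(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(binary_loss(0.9, 1), -log(0.9), tolerance = 1e-12)
  expect_error(binary_loss(0.5, 2), "label")
  withr::with_seed(4, {
    for (i in 1:200) {
      p <- runif(1, 0.01, 0.99)
      y <- rbinom(1, 1, 0.5)
      expect_gte(binary_loss(p, y), 0)
    }
  })
  # the double-squashing fidelity form cannot reach zero loss
  expect_gt(binary_loss(1 - 1e-9, 1, double_sigmoid_fidelity = TRUE), 0.3)
  expect_equal(
    binary_loss(0.9, 1, double_sigmoid_fidelity = TRUE),
    -log(plogis(0.9)),
    tolerance = 1e-12
  )
})

test_that("label smoothing reduces to plain CE at epsilon 0 and matches
           hand arithmetic", {
  p <- c(0.7, 0.2, 0.1)
  expect_equal(label_smoothing_loss(p, 0L, epsilon = 0), -log(0.7),
    tolerance = 1e-12
  )
  # hand case, epsilon = 0.15, true class 0 of 3
  expect_equal(
    label_smoothing_loss(p, 0L, epsilon = 0.15),
    0.85 * (-log(0.7)) + 0.15 * ((-log(0.2)) + (-log(0.1))) / 2,
    tolerance = 1e-12
  )
  # uniform distribution: loss = ln(Nc) for every epsilon
  for (eps in c(0, 0.1, 0.15, 0.5)) {
    expect_equal(
      label_smoothing_loss(rep(1 / 7, 7L), 3L, epsilon = eps),
      log(7),
      tolerance = 1e-12
    )
  }
})

test_that("smoothing-loss properties hold on random distributions", {
  withr::with_seed(5, {
    for (i in 1:1000) {
      nc <- sample(2:10, 1L)
      p <- runif(nc, 0.01, 1)
      p <- p / sum(p)
      cl <- sample(nc, 1L) - 1L
      eps <- runif(1, 0, 0.9)
      l <- label_smoothing_loss(p, cl, eps, nc)
      expect_gte(l, 0)
      expect_equal(
        label_smoothing_loss(p, cl, 0, nc), -log(p[cl + 1L]),
        tolerance = 1e-12
      )
      # convex combination form: (1-eps) ce(i) + eps mean of the others
      ce <- -log(p)
      expect_equal(
        l, (1 - eps) * ce[cl + 1L] + eps * mean(ce[-(cl + 1L)]),
        tolerance = 1e-10
      )
    }
  })
})

test_that("the smoothed target matrix reproduces the scalar loss exactly", {
  withr::with_seed(6, {
    p <- matrix(runif(12, 0.05, 1), 3L)
    p <- p / rowSums(p)
    labels <- c(0L, 3L, 1L)
    T_ <- mvddi:::smooth_targets(labels, 4L, 0.15)
    for (r in 1:3) {
      expect_equal(
        -sum(T_[r, ] * log(p[r, ])),
        label_smoothing_loss(p[r, ], labels[r], 0.15),
        tolerance = 1e-12
      )
    }
  })
})
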