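# Fusion block: branch output shapes, analytic identities, attention
# arithmetic against a plain-R oracle, and shape conservation end to end.

test_that("concatenate-level branches emit 20-dim latents per drug", {
  p <- init_fusion_params(seed = 1L)
  for (n in c(1L, 8L)) {
    withr::with_seed(n, {
      hG <- matrix(rnorm(n * 100), n)
      eh <- matrix(rnorm(n * 100), n)
    })
    lf1 <- concat_level(hG, eh, "row_stack", p)
    lf2 <- concat_level(hG, eh, "col_stack", p)
    expect_equal(dim(lf1), c(n, 20L))
    expect_equal(dim(lf2), c(n, 20L))
    expect_identical(attr(lf1, "branch_tag"), "LF1")
    expect_identical(attr(lf2, "branch_tag"), "LF2")
  }
  expect_error(
    concat_level(matrix(0, 2L, 50L), matrix(0, 2L, 50L), "row_stack", p),
    "100 columns"
  )
})

test_that("zeroed convolution weights produce an all-zero latent", {
  p <- init_fusion_params(seed = 2L)
  p$conv_row <- lapply(p$conv_row, function(m) m * 0)
  out <- concat_level(
    matrix(rnorm(300), 3L), matrix(rnorm(300), 3L), "row_stack", p
  )
  expect_equal(unclass(out), matrix(0, 3L, 20L), ignore_attr = TRUE)
})

test_that("a single drug is convolved independently of batch composition", {
  p <- init_fusion_params(seed = 3L)
  withr::with_seed(31, {
    hG <- matrix(rnorm(500), 5L)
    eh <- matrix(rnorm(500), 5L)
  })
  whole <- concat_level(hG, eh, "row_stack", p)
  solo <- concat_level(hG[3L, , drop = FALSE], eh[3L, , drop = FALSE],
    "row_stack", p)
  expect_equal(whole[3L, ], solo[1L, ])
})

test_that("scalar-level identities hold: zero addend and unit factor", {
  p <- init_fusion_params(seed = 4L)
  withr::with_seed(41, hG <- matrix(rnorm(400), 4L))
  zero <- matrix(0, 4L, 100L)
  ones <- matrix(1, 4L, 100L)
  lf3 <- scalar_level(hG, zero, "add", p)
  lf4 <- scalar_level(hG, ones, "product", p)
  expect_equal(dim(lf3), c(4L, 20L))
  # encoder(hG + 0) computed directly through the autoencoder weights
  enc <- function(x, ae) {
    h <- pmax(sweep(x %*% ae$W1, 2L, drop(ae$b1), "+"), 0)
    sweep(h %*% ae$W2, 2L, drop(ae$b2), "+")
  }
  expect_equal(unclass(lf3), enc(hG, p$ae_add), ignore_attr = TRUE)
  expect_equal(unclass(lf4), enc(hG, p$ae_prod), ignore_attr = TRUE)
  expect_identical(attr(lf3, "branch_tag"), "LF3")
  expect_identical(attr(lf4, "branch_tag"), "LF4")
})

test_that("reconstruction error matches hand arithmetic and is positive on
           untrained nets", {
  # tiny hand case: 1 x 2 input through explicit weights, plain arithmetic
  ae <- list(
    W1 = diag(2), b1 = matrix(0, 1L, 2L),
    W2 = matrix(c(1, 1), 2L, 1L), b2 = matrix(0, 1L, 1L),
    W3 = matrix(c(1, 0), 1L, 2L), b3 = matrix(0, 1L, 2L),
    W4 = diag(2), b4 = matrix(0, 1L, 2L)
  )
  x <- matrix(c(3, 4), 1L)
  # encoder: relu([3,4]) = [3,4]; z = 7; decoder: relu([7,0]) -> [7,0]
  # mse = ((7-3)^2 + (0-4)^2) / 2 = 16
  expect_equal(ae_reconstruction_loss(x, ae), 16)

  p <- init_fusion_params(seed = 5L)
  withr::with_seed(51, fused <- matrix(rnorm(200), 2L))
  loss <- ae_reconstruction_loss(fused, p$ae_add)
  expect_true(is.finite(loss) && loss > 0)
})

test_that("latent fusion stacks the five blocks in fixed order", {
  withr::with_seed(6, lfs <- lapply(1:4, function(i) matrix(rnorm(60), 3L)))
  X <- fuse_latents(lfs[[1]], lfs[[2]], lfs[[3]], lfs[[4]])
  expect_equal(dim(X), c(3L, 100L))
  for (i in 1:4) expect_equal(X[, (i - 1) * 20 + 1:20], lfs[[i]])
  expect_equal(X[, 81:100], Reduce(`+`, lfs))
  # all-equal inputs: LF5 = 4 L
  L <- lfs[[1]]
  expect_equal(fuse_latents(L, L, L, L)[, 81:100], 4 * L)
  expect_error(fuse_latents(L, L, L, L[, 1:10]), "ncol")
})

test_that("head width follows d_in / n_heads and indivisible widths fail", {
  expect_equal(init_attention_params(100L, 4L)$d_k, 25L)
  expect_equal(init_attention_params(100L, 2L)$d_k, 50L)
  expect_equal(ncol(init_attention_params(100L, 4L)$heads[[1L]]$Wq), 25L)
  expect_error(init_attention_params(100L, 3L), "not divisible")
})

test_that("attention output matches an independent plain-R oracle", {
  for (heads in c(1L, 2L, 4L)) {
    ap <- init_attention_params(100L, heads, seed = heads)
    withr::with_seed(heads, X <- matrix(rnorm(700), 7L))
    expect_equal(
      multi_head_attention(X, ap),
      oracle_attention(X, ap),
      tolerance = 1e-10
    )
  }
})

test_that("attention preserves shape for n in {1, 7, 64} and normalizes
           rows of the attention matrix", {
  ap <- init_attention_params(100L, 4L, seed = 9L)
  for (n in c(1L, 7L, 64L)) {
    withr::with_seed(n, X <- matrix(rnorm(n * 100), n))
    out <- multi_head_attention(X, ap)
    expect_equal(dim(out), c(n, 100L))
    expect_true(all(is.finite(out)))
  }
  # row-normalization of softmax(Q K' / sqrt(d_k))
  withr::with_seed(10, X <- matrix(rnorm(500), 5L))
  hp <- ap$heads[[1L]]
  S <- (X %*% hp$Wq) %*% t(X %*% hp$Wk) / sqrt(ap$d_k)
  A <- exp(S - apply(S, 1L, max))
  A <- A / rowSums(A)
  expect_equal(rowSums(A), rep(1, 5L), tolerance = 1e-12)
})

test_that("whole-module shapes are conserved (two views to X to X_att)", {
  p <- init_fusion_params(seed = 11L, n_heads = 2L)
  for (n in c(1L, 7L, 64L)) {
    withr::with_seed(n, {
      hG <- matrix(rnorm(n * 100), n)
      eh <- matrix(rnorm(n * 100), n)
    })
    lf1 <- concat_level(hG, eh, "row_stack", p)
    lf2 <- concat_level(hG, eh, "col_stack", p)
    lf3 <- scalar_level(hG, eh, "add", p)
    lf4 <- scalar_level(hG, eh, "product", p)
    X <- fuse_latents(lf1, lf2, lf3, lf4)
    X_att <- multi_head_attention(X, p)
    expect_equal(dim(X), c(n, 100L))
    expect_equal(dim(X_att), c(n, 100L))
  }
})
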