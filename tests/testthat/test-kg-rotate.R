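# RotatE score function, negative sampling, the two loss conventions, and
# seed-deterministic training with exact modulus conservation.

test_that("the score is zero exactly when the rotated head equals the tail", {
  withr::with_seed(21, {
    h <- complex(real = rnorm(50), imaginary = rnorm(50))
    th <- runif(50, -pi, pi)
    t_exact <- h * complex(modulus = 1, argument = th)
    expect_identical(rotate_score(h, th, t_exact), 0)
    # identity rotation, tail = head
    expect_identical(rotate_score(h, rep(0, 50), h), 0)
    # d_c = 1 hand case: |1 * i - 0| = 1
    expect_equal(
      rotate_score(1 + 0i, pi / 2, 0 + 0i), 1
    )
    # non-negativity with strict positivity off the minimum
    for (i in 1:20) {
      t_off <- t_exact + complex(real = rnorm(50, sd = 0.1))
      expect_gt(rotate_score(h, th, t_off), 0)
    }
  })
})

test_that("negative sampling corrupts one side, filters positives, and is
           reproducible", {
  ents <- paste0("e", 1:20)
  pos <- list(head = "e1", relation = "r", tail = "e2")
  expect_equal(nrow(sample_negatives(pos, ents, 0L)), 0L)
  negs <- sample_negatives(pos, ents, 25L, seed = 5L)
  expect_equal(nrow(negs), 25L)
  # never reproduces the positive; exactly one side changed
  expect_false(any(negs$head == "e1" & negs$tail == "e2"))
  expect_true(all(negs$head == "e1" | negs$tail == "e2"))
  expect_identical(negs, sample_negatives(pos, ents, 25L, seed = 5L))
  expect_false(identical(negs, sample_negatives(pos, ents, 25L, seed = 6L)))
  expect_error(sample_negatives(pos, "e1", 1L), "at least 2 entities")
})

# hand-built d_c = 1 table: entity values chosen so triple scores are exact
hand_table <- function() {
  tab <- init_kg_table(c("a", "b", "c"), "r", dim = 2L, seed = 1L)
  tab$ent_re[, 1L] <- c(0, 0, 5) # a = 0, b = 0, c = 5 (all real)
  tab$ent_im[, 1L] <- 0
  tab$rel_phase[, 1L] <- 0 # identity rotation
  tab
}

test_that("loss conventions reproduce scalar sigmoid oracles", {
  tab <- hand_table()
  pos <- tibble::tibble(head = "a", relation = "r", tail = "b") # score 0
  neg5 <- tibble::tibble(head = "c", relation = "r", tail = "a") # score 5
  neg0 <- tibble::tibble(head = "b", relation = "r", tail = "a") # score 0

  printed <- function(margin) {
    kg_config(
      margin = margin, loss_convention = "as-printed",
      negatives_per_positive = 1L
    )
  }
  # equal scores, margin 0: -ln sigma(0) = ln 2
  expect_equal(kg_loss(pos, neg0, tab, printed(0)), log(2), tolerance = 1e-12)
  # score(pos) = 0, score(neg) = 5, margin 1: -ln sigma(-6)
  expect_equal(
    kg_loss(pos, neg5, tab, printed(1)),
    -log(plogis(-6)),
    tolerance = 1e-12
  )
  # summed form: doubling identical negatives doubles the loss
  expect_equal(
    kg_loss(pos, dplyr::bind_rows(neg5, neg5), tab, printed(1)),
    2 * kg_loss(pos, neg5, tab, printed(1)),
    tolerance = 1e-12
  )
  # rotate-standard convention, scalar oracle:
  # -ln sigma(g - s_pos) - ln sigma(s_neg - g) at g = 1
  std <- kg_config(
    margin = 1, loss_convention = "rotate-standard",
    negatives_per_positive = 1L
  )
  expect_equal(
    kg_loss(pos, neg5, tab, std),
    -log(plogis(1 - 0)) - log(plogis(5 - 1)),
    tolerance = 1e-12
  )
  expect_error(kg_loss(pos, neg5[0, ], tab, std), "negatives")
})

test_that("flattened entity vectors are real||imag of length dim", {
  tab <- init_kg_table(paste0("e", 1:4), "r", dim = 100L, seed = 2L)
  v <- entity_vector(tab, "e2")
  expect_length(v, 100L)
  expect_equal(v[1:50], tab$ent_re[2L, ])
  expect_equal(v[51:100], tab$ent_im[2L, ])
  # round trip back to the complex form
  expect_equal(
    complex(real = v[1:50], imaginary = v[51:100]),
    mvddi:::entity_complex(tab, "e2")
  )
  tab$ent_re[3L, ] <- 0
  tab$ent_im[3L, ] <- 0
  expect_equal(entity_vector(tab, "e3"), rep(0, 100L))
  expect_error(entity_vector(tab, "nope"), "unknown entity")
})

test_that("training is seed-deterministic, loss trends down, and relation
           moduli stay exactly 1", {
  kg <- toy_pattern_kg("symmetric", n_entities = 20L, n_base = 40L, seed = 3L)
  cfg <- kg_config(
    margin = 6, negatives_per_positive = 8L, epochs = 40L,
    dim = 20L, seed = 9L
  )
  t1 <- train_kg_embeddings(kg$train, cfg, entities = kg$entities)
  t2 <- train_kg_embeddings(kg$train, cfg, entities = kg$entities)
  expect_identical(t1$ent_re, t2$ent_re)
  expect_identical(t1$rel_phase, t2$rel_phase)
  # moving average of the loss does not increase start to end
  h <- t1$loss_history
  expect_lt(mean(utils::tail(h, 5L)), mean(utils::head(h, 5L)))
  # phase parameterization conserves |e_r| = 1 exactly
  expect_identical(
    max(abs(Mod(complex(modulus = 1, argument = t1$rel_phase)) - 1)), 0
  )
  expect_error(train_kg_embeddings(kg$train[0, ], cfg), "empty")
})

test_that("trained embeddings rank true triples above random corruptions", {
  kg <- toy_pattern_kg("symmetric", n_entities = 25L, n_base = 50L, seed = 4L)
  cfg <- kg_config(
    margin = 6, negatives_per_positive = 16L, epochs = 80L,
    dim = 40L, seed = 2L
  )
  tab <- train_kg_embeddings(kg$train, cfg, entities = kg$entities)
  s_true <- score_triples(tab, kg$train)$score
  ctrl <- withr::with_seed(8, tibble::tibble(
    head = sample(kg$entities, 300L, replace = TRUE),
    relation = "r_sym",
    tail = sample(kg$entities, 300L, replace = TRUE)
  ))
  keys <- paste(kg$train$head, kg$train$tail)
  ctrl <- ctrl[ctrl$head != ctrl$tail &
    !(paste(ctrl$head, ctrl$tail) %in% keys), ]
  s_ctrl <- score_triples(tab, ctrl)$score
  expect_lt(mean(s_true), mean(s_ctrl))
})
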