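# Toy world generator: template validity, planted closures, label balance,
# determinism, and learnability of the planted rule by a model-free baseline.

test_that("every SMILES template in the pools parses", {
  pool <- mvddi:::smiles_pool()
  for (s in c(pool$plain, pool$aromatic)) {
    expect_no_error(parse_smiles(s))
  }
  expect_gt(length(pool$aromatic), 40L)
  expect_gt(length(pool$plain), 20L)
})

test_that("the default world has the documented shape and balance", {
  w <- generate_toy_world(toy_world_spec(seed = 0L))
  expect_equal(nrow(w$drugs), 60L)
  expect_equal(nrow(w$triples), 300L)
  expect_equal(nrow(w$pairs), 400L)
  expect_false(anyDuplicated(w$drugs$smiles) > 0)
  # planted positive rate near one half
  expect_gt(mean(w$pairs$label), 0.4)
  expect_lt(mean(w$pairs$label), 0.6)
  # labels follow the planted two-view rule exactly
  arom <- w$meta$aromatic
  clus <- w$meta$cluster
  expected <- as.integer(
    clus[w$pairs$drug_i] == clus[w$pairs$drug_j] &
      arom[w$pairs$drug_i] & arom[w$pairs$drug_j]
  )
  expect_equal(w$pairs$label, expected)
})

test_that("symmetric relations are emitted closed under mirroring", {
  w <- generate_toy_world(toy_world_spec(seed = 3L))
  sym <- w$triples[w$triples$relation == "interacts_sym", ]
  expect_gt(nrow(sym), 0L)
  expect_setequal(
    paste(sym$head, sym$tail),
    paste(sym$tail, sym$head)
  )
  # inverse pair: every activates has its activated_by mirror
  act <- w$triples[w$triples$relation == "activates", ]
  inv <- w$triples[w$triples$relation == "activated_by", ]
  expect_setequal(paste(act$head, act$tail), paste(inv$tail, inv$head))
  # composition: linked closes every precedes-then-follows path planted
  pre <- w$triples[w$triples$relation == "precedes", ]
  fol <- w$triples[w$triples$relation == "follows", ]
  lnk <- w$triples[w$triples$relation == "linked", ]
  expect_equal(nrow(lnk), nrow(pre))
  expect_equal(nrow(fol), nrow(pre))
})

test_that("same seed gives byte-identical files, different seed differs", {
  w1 <- generate_toy_world(toy_world_spec(seed = 5L))
  w2 <- generate_toy_world(toy_world_spec(seed = 5L))
  w3 <- generate_toy_world(toy_world_spec(seed = 6L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_toy_world(w1, d1)
  write_toy_world(w2, d2)
  for (f in c("drugs.tsv", "kg.tsv", "ddi.tsv")) {
    expect_identical(
      readBin(file.path(d1, f), "raw", 1e6),
      readBin(file.path(d2, f), "raw", 1e6)
    )
  }
  expect_false(identical(w1$drugs$smiles, w3$drugs$smiles))
})

test_that("oversized worlds and undersized triple budgets are rejected", {
  expect_error(
    generate_toy_world(toy_world_spec(n_drugs = 500L)),
    "template pool"
  )
  expect_error(
    generate_toy_world(toy_world_spec(n_triples = 100L)),
    "n_triples too small"
  )
})

test_that("the planted rule is learnable from the raw views by 1-NN", {
  w <- generate_toy_world(toy_world_spec(seed = 0L))
  graphs <- parse_drug_table(w$drugs)
  hG <- encode_drugs(graphs, init_gin_params(seed = 1L))
  tab <- train_kg_embeddings(
    w$triples,
    kg_config(epochs = 60L, negatives_per_positive = 32L, dim = 100L,
      seed = 1L)
  )
  eh <- kg_view_matrix(tab, w$drugs$drug_id)
  feats <- cbind(scale(hG), scale(eh))
  rownames(feats) <- w$drugs$drug_id
  x <- cbind(feats[w$pairs$drug_i, ], feats[w$pairs$drug_j, ])
  sp <- split_pairs(w$pairs, 0.2, seed = 2L)
  tr <- match(
    paste(sp$train$drug_i, sp$train$drug_j),
    paste(w$pairs$drug_i, w$pairs$drug_j)
  )
  te <- match(
    paste(sp$test$drug_i, sp$test$drug_j),
    paste(w$pairs$drug_i, w$pairs$drug_j)
  )
  d2 <- as.matrix(stats::dist(x))
  pred <- vapply(te, function(i) {
    sp$train$label[which.min(d2[i, tr])]
  }, integer(1))
  expect_gt(mean(pred == sp$test$label), 0.7)
})

test_that("multiclass labels refine the rule into four classes", {
  w <- generate_toy_world(toy_world_spec(task = "multiclass", seed = 1L))
  expect_setequal(unique(w$pairs$label), 0:3)
  arom <- w$meta$aromatic
  clus <- w$meta$cluster
  expected <- 2L * as.integer(clus[w$pairs$drug_i] == clus[w$pairs$drug_j]) +
    as.integer(arom[w$pairs$drug_i] & arom[w$pairs$drug_j])
  expect_equal(w$pairs$label, expected)
})
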