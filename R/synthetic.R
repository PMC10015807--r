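# Seed-deterministic toy data: SMILES drugs, a knowledge graph with planted
# relation patterns, and DDI labels from a planted two-view rule.

# programmatic SMILES template pools; every template is a valid, mutually
# non-isomorphic heavy-atom graph (parseability is asserted in the tests)
smiles_pool <- function() {
  chains <- vapply(1:8, function(k) strrep("C", k), character(1))
  plain <- c(
    chains,
    paste0(chains[2:8], "O"), # alcohols
    paste0(chains[2:7], "N"), # amines
    paste0(chains[1:6], "C(=O)O"), # acids
    "CC(C)C", "CC(C)CC", "CC(C)(C)C", "CCOCC", "COC", "CCOC",
    "C1CCCCC1", "C1CCCC1", "CC1CCCCC1", "OC1CCCCC1"
  )
  prefixes <- c(
    "", "C", "CC", "CCC", "CCCC", "CCCCC", "O", "OC", "OCC",
    "N", "NC", "NCC", "Cl", "F"
  )
  rings <- c("c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1")
  aromatic <- as.vector(outer(prefixes, rings, paste0))
  list(plain = unique(plain), aromatic = unique(aromatic))
}

#' Specify a synthetic drug world
#'
#' The toy world emulates the structure of the real inputs at desk scale: a
#' drug table with SMILES, a knowledge graph whose relations include planted
#' symmetric, inverse and compositional patterns, and labeled DDI pairs.
#' Labels follow a planted rule that needs *both* views: each drug carries a
#' structure flag (aromatic ring present, visible only in the SMILES) and a
#' KG cluster (the target entity it `binds`, visible only in the graph).
#' A pair interacts (binary label 1) exactly when the drugs share their KG
#' target *and* both carry the aromatic flag, so neither view alone
#' separates the classes. The multi-class label refines the same rule into
#' four classes: `2 * shared_target + both_aromatic`.
#'
#' @param n_drugs Number of drugs (limited by the SMILES template pools).
#' @param n_clusters Number of KG target entities drugs bind to.
#' @param aromatic_fraction Fraction of drugs drawn from the aromatic pool.
#' @param n_extra_entities Generic non-target entities padding the KG.
#' @param n_triples Total KG triples; planted-pattern triples are emitted
#'   first and generic `assoc` triples pad (or are trimmed) to this count.
#' @param n_pairs Labeled DDI pairs to emit.
#' @param task `"binary"` or `"multiclass"`.
#' @param seed Integer seed; the whole world is a pure function of the spec.
#' @return A `toy_world_spec` list.
#' @export
toy_world_spec <- function(n_drugs = 60L, n_clusters = 4L,
                           aromatic_fraction = 2 / 3,
                           n_extra_entities = 10L, n_triples = 300L,
                           n_pairs = 400L,
                           task = c("binary", "multiclass"), seed = 0L) {
  task <- match.arg(task)
  structure(
    list(
      n_drugs = as.integer(n_drugs), n_clusters = as.integer(n_clusters),
      aromatic_fraction = aromatic_fraction,
      n_extra_entities = as.integer(n_extra_entities),
      n_triples = as.integer(n_triples), n_pairs = as.integer(n_pairs),
      task = task, n_classes = if (task == "binary") 2L else 4L,
      seed = as.integer(seed)
    ),
    class = "toy_world_spec"
  )
}

#' Generate the synthetic world
#'
#' @param spec A [toy_world_spec()].
#' @return A `toy_world` list: `drugs` (tibble `drug_id`, `smiles`),
#'   `triples` (tibble `head`, `relation`, `tail`), `pairs` (tibble
#'   `drug_i`, `drug_j`, `label`), and `meta` (per-drug aromatic flags and
#'   cluster assignments plus the spec). Same spec, byte-identical output.
#' @examples
#' w <- generate_toy_world(toy_world_spec(n_drugs = 20, n_pairs = 60))
#' table(w$pairs$label)
#' @export
generate_toy_world <- function(spec = toy_world_spec()) {
  stopifnot(inherits(spec, "toy_world_spec"))
  pool <- smiles_pool()
  n_arom <- round(spec$n_drugs * spec$aromatic_fraction)
  n_plain <- spec$n_drugs - n_arom
  if (n_arom > length(pool$aromatic) || n_plain > length(pool$plain)) {
    stop("n_drugs exceeds the SMILES template pool capacity", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    drug_ids <- sprintf("D%03d", seq_len(spec$n_drugs))
    smiles <- c(
      sample(pool$aromatic, n_arom),
      sample(pool$plain, n_plain)
    )
    aromatic <- rep(c(TRUE, FALSE), c(n_arom, n_plain))
    ord <- sample.int(spec$n_drugs)
    smiles <- smiles[ord]
    aromatic <- aromatic[ord]
    cluster <- sample(rep_len(seq_len(spec$n_clusters), spec$n_drugs))
    targets <- sprintf("T%02d", seq_len(spec$n_clusters))
    extras <- sprintf("E%02d", seq_len(spec$n_extra_entities))

    triples <- toy_triples(spec, drug_ids, cluster, targets, extras)
    pairs <- toy_pairs(spec, drug_ids, aromatic, cluster)

    structure(
      list(
        drugs = tibble::tibble(drug_id = drug_ids, smiles = smiles),
        triples = triples,
        pairs = pairs,
        meta = list(
          aromatic = stats::setNames(aromatic, drug_ids),
          cluster = stats::setNames(cluster, drug_ids),
          spec = spec
        )
      ),
      class = "toy_world"
    )
  })
}

# KG assembly: per-drug binds edges, then symmetric / inverse / composition
# plantings over drugs, then generic assoc padding to the requested size
toy_triples <- function(spec, drug_ids, cluster, targets, extras) {
  n <- length(drug_ids)
  binds <- tibble::tibble(
    head = drug_ids, relation = "binds", tail = targets[cluster]
  )
  pick_pairs <- function(k) {
    a <- sample(drug_ids, 3L * k, replace = TRUE)
    b <- sample(drug_ids, 3L * k, replace = TRUE)
    ok <- a != b & !duplicated(unordered_key(a, b))
    cbind(a[ok], b[ok])[seq_len(k), , drop = FALSE]
  }
  sym <- pick_pairs(30L)
  sym_tr <- tibble::tibble(
    head = c(sym[, 1L], sym[, 2L]),
    relation = "interacts_sym",
    tail = c(sym[, 2L], sym[, 1L])
  )
  inv <- pick_pairs(25L)
  inv_tr <- tibble::tibble(
    head = c(inv[, 1L], inv[, 2L]),
    relation = rep(c("activates", "activated_by"), each = nrow(inv)),
    tail = c(inv[, 2L], inv[, 1L])
  )
  xyz <- cbind(
    sample(drug_ids, 30L, replace = TRUE),
    sample(drug_ids, 30L, replace = TRUE),
    sample(drug_ids, 30L, replace = TRUE)
  )
  xyz <- xyz[xyz[, 1L] != xyz[, 2L] & xyz[, 2L] != xyz[, 3L] &
    xyz[, 1L] != xyz[, 3L], , drop = FALSE]
  comp_tr <- tibble::tibble(
    head = c(xyz[, 1L], xyz[, 2L], xyz[, 1L]),
    relation = rep(c("precedes", "follows", "linked"), each = nrow(xyz)),
    tail = c(xyz[, 2L], xyz[, 3L], xyz[, 3L])
  )
  planted <- dplyr::bind_rows(binds, sym_tr, inv_tr, comp_tr)
  n_pad <- spec$n_triples - nrow(planted)
  if (n_pad < 0L) {
    # trim generic-capable rows only; pattern closures must stay intact
    stop("n_triples too small for the planted patterns (need >= ",
      nrow(planted), ")",
      call. = FALSE
    )
  }
  pad <- tibble::tibble(
    head = sample(drug_ids, n_pad, replace = TRUE),
    relation = "assoc",
    tail = sample(extras, n_pad, replace = TRUE)
  )
  dplyr::bind_rows(planted, pad)
}

# label rule and pair sampling; negatives are drawn across the rule's
# failure modes so that each single view is non-separating by construction
toy_pairs <- function(spec, drug_ids, aromatic, cluster) {
  idx <- utils::combn(length(drug_ids), 2L)
  i <- idx[1L, ]
  j <- idx[2L, ]
  shared <- cluster[i] == cluster[j]
  both_arom <- aromatic[i] & aromatic[j]
  if (spec$task == "binary") {
    label <- as.integer(shared & both_arom)
    pos <- which(label == 1L)
    neg <- which(label == 0L)
    n_pos <- min(length(pos), spec$n_pairs %/% 2L)
    n_neg <- spec$n_pairs - n_pos
    take <- c(
      sample(pos, n_pos),
      sample(neg, min(n_neg, length(neg)))
    )
  } else {
    label <- 2L * as.integer(shared) + as.integer(both_arom)
    per_class <- spec$n_pairs %/% spec$n_classes
    take <- unlist(lapply(0:(spec$n_classes - 1L), function(cl) {
      rows <- which(label == cl)
      sample(rows, min(per_class, length(rows)))
    }), use.names = FALSE)
  }
  take <- sample(take) # shuffle class blocks together
  tibble::tibble(
    drug_i = drug_ids[i[take]],
    drug_j = drug_ids[j[take]],
    label = label[take]
  )
}

#' Generate a toy knowledge graph with one planted relation pattern
#'
#' Builds a KG in which the named pattern holds by construction, withholding
#' a fraction of the *implied* triples from the training set: the mirror
#' `(t, r, h)` for a symmetric relation, `(t, r2, h)` for an inverse pair,
#' `(x, r3, z)` for a composition `r3 = r1 then r2`. A trained embedding
#' that models the pattern should score the held-out implied triples better
#' (lower) than corrupted controls.
#'
#' @param pattern `"symmetric"`, `"inverse"` or `"composition"`.
#' @param n_entities Entities in the KG.
#' @param n_base Base facts planted (pairs or triangles).
#' @param holdout_fraction Fraction of implied triples withheld.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `implied`, plus `entities` and the
#'   pattern's `relations`.
#' @export
toy_pattern_kg <- function(pattern = c("symmetric", "inverse", "composition"),
                           n_entities = 30L, n_base = 60L,
                           holdout_fraction = 0.2, seed = 1L) {
  pattern <- match.arg(pattern)
  entities <- sprintf("e%03d", seq_len(n_entities))
  withr::with_seed(seed, {
    if (pattern %in% c("symmetric", "inverse")) {
      all_pairs <- t(utils::combn(n_entities, 2L))
      base <- all_pairs[sample(nrow(all_pairs), n_base), , drop = FALSE]
      a <- entities[base[, 1L]]
      b <- entities[base[, 2L]]
      if (pattern == "symmetric") {
        fwd <- tibble::tibble(head = a, relation = "r_sym", tail = b)
        implied_all <- tibble::tibble(head = b, relation = "r_sym", tail = a)
        relations <- "r_sym"
      } else {
        fwd <- tibble::tibble(head = a, relation = "r_fwd", tail = b)
        implied_all <- tibble::tibble(head = b, relation = "r_inv", tail = a)
        relations <- c("r_fwd", "r_inv")
      }
      hold <- sample(n_base, ceiling(holdout_fraction * n_base))
      train <- dplyr::bind_rows(fwd, implied_all[-hold, ])
      implied <- implied_all[hold, ]
    } else {
      x <- sample(entities, n_base, replace = TRUE)
      y <- sample(entities, n_base, replace = TRUE)
      z <- sample(entities, n_base, replace = TRUE)
      ok <- x != y & y != z & x != z
      x <- x[ok]
      y <- y[ok]
      z <- z[ok]
      k <- length(x)
      legs <- dplyr::bind_rows(
        tibble::tibble(head = x, relation = "r_one", tail = y),
        tibble::tibble(head = y, relation = "r_two", tail = z)
      )
      implied_all <- tibble::tibble(head = x, relation = "r_comp", tail = z)
      hold <- sample(k, ceiling(holdout_fraction * k))
      train <- dplyr::bind_rows(legs, implied_all[-hold, ])
      implied <- implied_all[hold, ]
      relations <- c("r_one", "r_two", "r_comp")
    }
    list(
      train = train, implied = implied,
      entities = entities, relations = relations
    )
  })
}
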