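# Independent split-search oracle: grows a partition greedily, at each step
# enumerating every (block, feature) refinement and recomputing the total
# absolute loss of the whole partition from scratch; returns the best
# achievable total loss. Shares no code with fit_lad_tree.
oracle_greedy_loss <- function(x, r, n_leaves) {
  part_loss <- function(blocks) {
    sum(vapply(blocks, function(i) sum(abs(r[i] - stats::median(r[i]))), 0))
  }
  blocks <- list(seq_along(r))
  repeat {
    if (length(blocks) >= n_leaves) break
    best_loss <- part_loss(blocks)
    best_blocks <- NULL
    for (b in seq_along(blocks)) {
      for (j in seq_len(ncol(x))) {
        i <- blocks[[b]]
        left <- i[x[i, j] == 0]
        right <- i[x[i, j] == 1]
        if (length(left) == 0 || length(right) == 0) next
        cand <- c(blocks[-b], list(left, right))
        cl <- part_loss(cand)
        if (cl < best_loss - 1e-12) {
          best_loss <- cl
          best_blocks <- cand
        }
      }
    }
    if (is.null(best_blocks)) break
    blocks <- best_blocks
  }
  part_loss(blocks)
}

tree_training_loss <- function(tree, x, r) {
  sum(abs(r - predict_lad_tree(tree, x)))
}

test_that("a perfectly separating feature yields a single clean split", {
  x <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(NULL, "f1"))
  tree <- fit_lad_tree(x, targets = c(1, 1, 0, 0), n_leaves = 4)
  pred <- predict_lad_tree(tree, x)
  expect_equal(pred, c(1, 1, 0, 0))
  # no further split can reduce the (already zero) loss
  expect_equal(sum(tree$nodes$is_leaf), 2L)
})

test_that("constant targets give a single-leaf tree at their value", {
  x <- matrix(sample(0:1, 20, TRUE), 5, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  tree <- fit_lad_tree(x, targets = rep(0.7, 5), n_leaves = 4)
  expect_equal(nrow(tree$nodes), 1L)
  expect_equal(tree$nodes$value, 0.7)
})

test_that("all-constant features give a single leaf at the median residual", {
  x <- matrix(1L, 6, 3, dimnames = list(NULL, paste0("f", 1:3)))
  tree <- fit_lad_tree(x, targets = c(0, 0, 1, 1, 1, 1), n_leaves = 4)
  expect_equal(nrow(tree$nodes), 1L)
  expect_equal(tree$nodes$value, 1)
})

test_that("greedy tree loss matches the exhaustive split-search oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- 12
    p <- sample(3:8, 1)
    x <- matrix(sample(0:1, n * p, TRUE), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    fit0 <- runif(n, 0, 1)
    y <- sample(0:1, n, TRUE)
    tree <- fit_lad_tree(x, y, current_fit = fit0, n_leaves = 4)
    expect_equal(tree_training_loss(tree, x, y - fit0),
                 oracle_greedy_loss(x, y - fit0, 4),
                 tolerance = 1e-10)
  }
})

test_that("each split never increases the training loss", {
  set.seed(202)
  for (rep in 1:20) {
    x <- matrix(sample(0:1, 14 * 6, TRUE), 14, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- runif(14)
    tree <- fit_lad_tree(x, y, n_leaves = 4)
    trace <- attr(tree, "loss_trace")
    expect_true(all(diff(trace) <= 1e-12))
  }
})

test_that("sample_batch draws the right counts and respects probabilities", {
  w <- tibble::tibble(
    locus_id = rep(sprintf("l%02d", 1:10), each = 2),
    gene_id = sprintf("p%02d", 1:20),
    probability = rep(c(0.5, 0.5), 10)
  )
  pool <- sprintf("n%02d", 1:30)
  set.seed(1)
  b <- sample_batch(w, pool, locus_fraction = 0.7)
  expect_length(b$positives, 7)
  expect_length(b$negatives, 7)
  expect_length(intersect(b$positives, b$negatives), 0)
  expect_false(any(duplicated(b$negatives)))

  # degenerate probability concentrates all draws
  w1 <- tibble::tibble(locus_id = "l1", gene_id = c("A", "B"),
                       probability = c(1, 0))
  set.seed(2)
  for (i in 1:20) {
    expect_equal(sample_batch(w1, pool, 1)$positives, "A")
  }

  # overlapping pool is rejected
  expect_error(sample_batch(w, c(pool, "p01"), 0.7), "overlaps")
  # pool too small
  expect_error(sample_batch(w, pool[1:3], 0.7), "smaller")
})

test_that("empirical sampling frequency matches the locus probabilities", {
  w <- tibble::tibble(locus_id = "l1", gene_id = c("A", "B"),
                      probability = c(0.8, 0.2))
  set.seed(33)
  draws <- vapply(1:10000, function(i) {
    sample_batch(w, c("n1", "n2"), 1)$positives
  }, "")
  expect_gte(mean(draws == "A"), 0.78)
  expect_lte(mean(draws == "A"), 0.82)
})

test_that("degenerate boosting configurations reduce to the constant model", {
  sc <- small_scenario()
  wl <- weighted_from_scenario(sc)
  set.seed(3)
  m0 <- boost(wl$weighted, sc$trait$features, wl$pool, n_trees = 0)
  expect_length(m0$trees, 0)
  expect_equal(unname(predict(m0, sc$trait$features, type = "response")),
               rep(m0$f0, nrow(sc$trait$features)))

  set.seed(3)
  mshrink <- boost(wl$weighted, sc$trait$features, wl$pool, n_trees = 5,
                   config = training_config(shrinkage = 0))
  expect_equal(unname(predict(mshrink, sc$trait$features, type = "response")),
               rep(mshrink$f0, nrow(sc$trait$features)))
})

test_that("boosting separates planted causal genes from pool negatives", {
  sc <- small_scenario()
  wl <- weighted_from_scenario(sc)
  set.seed(4)
  m <- boost(wl$weighted, sc$trait$features, wl$pool, n_trees = 60)
  raw <- predict(m, sc$trait$features, type = "response", clamp = FALSE)
  causal <- sc$trait$truth$causal_genes
  expect_gt(median(raw[causal]), median(raw[wl$pool]))
})

test_that("the log-odds transform clamps and preserves order", {
  expect_equal(predict_log_odds(0.5), 0)
  expect_equal(predict_log_odds(1.2), log(0.999 / 0.001))
  expect_equal(predict_log_odds(1.2), 6.906755, tolerance = 1e-6)
  expect_equal(predict_log_odds(-5), -log(0.999 / 0.001))
  f <- sort(runif(50, -0.5, 1.5))
  lo <- predict_log_odds(f)
  expect_true(all(diff(lo) >= 0))
})

test_that("burn-in tally filter reproduces the worked example", {
  w <- tibble::tibble(
    locus_id = "l1", gene_id = c("A", "B", "C"),
    total = c(5L, 5L, 0L), increments = c(12L, 6L, 2L),
    probability = NA_real_
  )
  out <- locusboost:::burnin_filter(w, training_config())
  expect_equal(out$running_score, c(17L, 11L, 2L))
  # locus tally 30, cutoff 7.5: A and B pass, C drops
  expect_equal(out$kept, c(TRUE, TRUE, FALSE))
  expect_equal(out$probability, c(17 / 28, 11 / 28, 0))
})

test_that("burn-in keeps single-gene loci and never empties a locus", {
  w <- tibble::tibble(
    locus_id = c("l1", rep("l2", 4)),
    gene_id = c("S", "A", "B", "C", "D"),
    total = c(0L, rep(0L, 4)),
    increments = c(0L, rep(5L, 4)),  # four-way tie at exactly 25%
    probability = NA_real_
  )
  out <- locusboost:::burnin_filter(w, training_config())
  expect_true(out$kept[out$gene_id == "S"])
  # the tie would eliminate everyone; the deterministic top gene survives
  expect_equal(out$gene_id[out$locus_id == "l2" & out$kept], "A")
})

test_that("burn-in refinement retains planted causal genes", {
  sc <- small_scenario()
  wl <- weighted_from_scenario(sc)
  set.seed(5)
  ref <- burnin_refine(wl$weighted, sc$trait$features, wl$pool,
                       training_config())
  kept <- ref$gene_id[ref$kept]
  causal <- sc$trait$truth$causal_genes
  expect_gte(mean(causal %in% kept), 0.75)
  # refined probabilities still sum to one per locus
  sums <- tapply(ref$probability, ref$locus_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("cross-validation is reproducible and scores every gene", {
  sc <- small_scenario()
  wl <- weighted_from_scenario(sc)
  cfg <- fast_config()
  s1 <- cross_validate(wl$weighted, sc$trait$features, sc$genome$gene_id,
                       cfg, seed = 9)
  s2 <- cross_validate(wl$weighted, sc$trait$features, sc$genome$gene_id,
                       cfg, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), nrow(sc$genome))
  expect_true(all(is.finite(s1$log_odds)))
  expect_true(all(is.finite(s1$round_1)))

  s3 <- cross_validate(wl$weighted, sc$trait$features, sc$genome$gene_id,
                       cfg, seed = 10)
  expect_false(identical(s1$log_odds, s3$log_odds))
})

test_that("mendelian mode trains fixed positives without burn-in", {
  sc <- small_scenario()
  positives <- sc$trait$truth$causal_genes
  w <- mendelian_weights(positives)
  cfg <- fast_config("mendelian")
  s <- cross_validate(w, sc$trait$features, sc$genome$gene_id, cfg, seed = 21)
  expect_true(all(is.finite(s$log_odds)))
  # planted signal puts held-out positives above the background
  others <- setdiff(sc$genome$gene_id, positives)
  expect_gt(median(s$log_odds[s$gene_id %in% positives]),
            median(s$log_odds[s$gene_id %in% others]))
})

test_that("cross-validation refuses fewer units than folds", {
  sc <- small_scenario()
  wl <- weighted_from_scenario(sc)
  w2 <- wl$weighted[wl$weighted$locus_id %in% unique(wl$weighted$locus_id)[1:2], ]
  expect_error(cross_validate(w2, sc$trait$features, sc$genome$gene_id,
                              fast_config(), seed = 1), "fewer")
})

test_that("model JSON round-trips through the serializer", {
  sc <- small_scenario()
  wl <- weighted_from_scenario(sc)
  set.seed(6)
  m <- boost(wl$weighted, sc$trait$features, wl$pool, n_trees = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$f0, m$f0)
  expect_equal(m2$shrinkage, m$shrinkage)
  expect_equal(unname(predict(m2, sc$trait$features)),
               unname(predict(m, sc$trait$features)))
})

test_that("tidy and glance summarize a fitted ensemble", {
  sc <- small_scenario()
  wl <- weighted_from_scenario(sc)
  set.seed(7)
  m <- boost(wl$weighted, sc$trait$features, wl$pool, n_trees = 3)
  td <- tidy(m)
  expect_true(all(c("tree", "id", "is_leaf", "feature", "value") %in% names(td)))
  expect_equal(dplyr::n_distinct(td$tree), 3L)
  gl <- glance(m)
  expect_equal(gl$n_trees, 3L)
  expect_equal(gl$shrinkage, 0.1)
})
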