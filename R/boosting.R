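new_lad_tree <- function(nodes) {
  structure(list(nodes = nodes), class = "lad_tree")
}

new_lb_boost <- function(f0, shrinkage, trees) {
  structure(list(f0 = f0, shrinkage = shrinkage, trees = trees),
            class = "lb_boost")
}

#' Training configuration for the boosting engine
#'
#' Defaults mirror the published procedure: six rounds of eight-fold
#' cross-validation, 60 main trees of four terminal leaves, 70% of loci per
#' tree, a 20-tree burn-in whose tally filter keeps genes above 25% of the
#' locus total, and a log-odds clamp of 1e-3. The shrinkage weight applied
#' to each tree is not dictated by the procedure; the default is 0.1.
#'
#' @param mode `"gwa"` (per-locus positive sampling with burn-in) or
#'   `"mendelian"` (fixed positive gene list, no burn-in).
#' @param n_rounds,n_folds Cross-validation layout.
#' @param n_main_trees,n_burnin_trees Trees in the main and burn-in phases.
#' @param n_leaves Terminal leaves per tree.
#' @param locus_fraction Fraction of loci (or positive genes) sampled per
#'   tree.
#' @param shrinkage Weight added per tree.
#' @param burnin_keep_fraction Tally fraction a gene must exceed to survive
#'   burn-in.
#' @param burnin_tally_initial Whether the locus tally includes the initial
#'   prior scores (default) or increments only.
#' @param epsilon Clamp applied before the logit transform.
#' @return A list of class `lb_config`.
#' @export
training_config <- function(mode = c("gwa", "mendelian"), n_rounds = 6L,
                            n_folds = 8L, n_main_trees = 60L,
                            n_burnin_trees = 20L, n_leaves = 4L,
                            locus_fraction = 0.7, shrinkage = 0.1,
                            burnin_keep_fraction = 0.25,
                            burnin_tally_initial = TRUE, epsilon = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(locus_fraction > 0, locus_fraction <= 1, n_leaves >= 2,
            shrinkage >= 0, shrinkage <= 1, epsilon > 0, epsilon < 0.5)
  structure(list(
    mode = mode, n_rounds = n_rounds, n_folds = n_folds,
    n_main_trees = n_main_trees, n_burnin_trees = n_burnin_trees,
    n_leaves = n_leaves, locus_fraction = locus_fraction,
    shrinkage = shrinkage, burnin_keep_fraction = burnin_keep_fraction,
    burnin_tally_initial = burnin_tally_initial, epsilon = epsilon
  ), class = "lb_config")
}

#' Fit a least-absolute-deviation regression tree on binary features
#'
#' Best-first greedy growth: at each step the (leaf, feature) pair whose
#' split most reduces the total absolute deviation of the residuals
#' (`targets - current_fit`) from the per-side medians is expanded, until
#' `n_leaves` leaves are reached or no split reduces the loss. Leaf values
#' are medians of the residuals they contain. Ties in the split search
#' break to the earlier-created leaf, then the lower feature index.
#'
#' @param x 0/1 matrix, examples x features.
#' @param targets Numeric response (0/1 class labels during boosting).
#' @param current_fit Current ensemble prediction per example (default 0).
#' @param n_leaves Maximum terminal leaves, default 4.
#' @return A `lad_tree` object; its `loss_trace` attribute records the
#'   total absolute loss after each split.
#' @export
fit_lad_tree <- function(x, targets, current_fit = 0, n_leaves = 4L) {
  stopifnot(nrow(x) >= 1, length(targets) == nrow(x))
  r <- targets - current_fit
  # inline median on a sorted copy; hot path of the split search
  fast_median <- function(v) {
    n <- length(v)
    s <- sort.int(v, method = "quick")
    if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
  }
  leaf_loss <- function(v) sum(abs(v - fast_median(v)))

  nodes <- tibble(
    id = 1L, is_leaf = TRUE, feature = NA_character_,
    left = NA_integer_, right = NA_integer_, value = median(r)
  )
  leaf_members <- list(`1` = seq_len(nrow(x)))
  loss_trace <- leaf_loss(r)

  while (sum(nodes$is_leaf) < n_leaves) {
    best <- NULL
    for (leaf_id in sort(as.integer(names(leaf_members)))) {
      idx <- leaf_members[[as.character(leaf_id)]]
      if (length(idx) < 2) next
      base <- leaf_loss(r[idx])
      xi <- x[idx, , drop = FALSE]
      for (j in seq_len(ncol(x))) {
        on <- xi[, j] == 1
        right <- idx[on]
        left <- idx[!on]
        if (length(left) == 0 || length(right) == 0) next
        gain <- base - leaf_loss(r[left]) - leaf_loss(r[right])
        if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12)) {
          best <- list(gain = gain, leaf_id = leaf_id, j = j,
                       left = left, right = right)
        }
      }
    }
    if (is.null(best)) break
    nl <- nrow(nodes) + 1L
    nr <- nrow(nodes) + 2L
    nodes$is_leaf[nodes$id == best$leaf_id] <- FALSE
    nodes$feature[nodes$id == best$leaf_id] <- colnames(x)[best$j]
    nodes$left[nodes$id == best$leaf_id] <- nl
    nodes$right[nodes$id == best$leaf_id] <- nr
    nodes$value[nodes$id == best$leaf_id] <- NA_real_
    nodes <- dplyr::bind_rows(nodes, tibble(
      id = c(nl, nr), is_leaf = TRUE, feature = NA_character_,
      left = NA_integer_, right = NA_integer_,
      value = c(median(r[best$left]), median(r[best$right]))
    ))
    leaf_members[[as.character(best$leaf_id)]] <- NULL
    leaf_members[[as.character(nl)]] <- best$left
    leaf_members[[as.character(nr)]] <- best$right
    loss_trace <- c(loss_trace, sum(vapply(leaf_members, function(i) {
      leaf_loss(r[i])
    }, 0)))
  }
  tr <- new_lad_tree(nodes)
  attr(tr, "loss_trace") <- loss_trace
  tr
}

#' Predict with a single LAD tree
#' @param tree A `lad_tree`.
#' @param x 0/1 feature matrix; missing split features are imputed as 0.
#' @return Numeric vector of leaf values, one per row of `x`.
#' @export
predict_lad_tree <- function(tree, x) {
  nodes <- tree$nodes
  at <- rep(1L, nrow(x))
  repeat {
    row <- match(at, nodes$id)
    internal <- !nodes$is_leaf[row]
    if (!any(internal)) break
    idx <- which(internal)
    feat <- nodes$feature[row[idx]]
    col <- match(feat, colnames(x))
    fval <- matrix(0L, length(idx), 1)
    known <- !is.na(col)
    if (any(known)) {
      fval[known] <- x[cbind(idx[known], col[known])]
    }
    at[idx] <- ifelse(fval == 1, nodes$right[row[idx]], nodes$left[row[idx]])
  }
  nodes$value[match(at, nodes$id)]
}

#' Sample one stochastic training batch
#'
#' Chooses `ceiling(locus_fraction * L)` loci uniformly without
#' replacement; at each chosen locus one positive gene is drawn by the
#' locus's sampling probabilities; an equal number of negatives is drawn
#' uniformly without replacement from `negatives_pool`.
#'
#' @param weighted Weighted-locus tibble (`locus_id`, `gene_id`,
#'   `probability`).
#' @param negatives_pool Character vector of genes outside all loci.
#' @param locus_fraction Fraction of loci per batch, default 0.7.
#' @return A list with `positives` and `negatives` gene-id vectors.
#' @export
sample_batch <- function(weighted, negatives_pool, locus_fraction = 0.7) {
  locus_ids <- unique(weighted$locus_id)
  if (length(intersect(weighted$gene_id, negatives_pool)) > 0) {
    abort("negatives_pool overlaps locus member genes")
  }
  n_sel <- ceiling(locus_fraction * length(locus_ids))
  chosen <- sample(locus_ids, n_sel, replace = FALSE)
  gene <- weighted$gene_id
  prob <- weighted$probability
  spl <- split(seq_along(gene), weighted$locus_id)
  positives <- vapply(chosen, function(l) {
    i <- spl[[l]]
    if (sum(prob[i]) <= 0) abort(paste0("locus ", l, " has no probability mass"))
    if (length(i) == 1) gene[i] else sample(gene[i], 1, prob = prob[i])
  }, "")
  if (length(negatives_pool) < n_sel) {
    abort("negatives pool smaller than the number of sampled loci")
  }
  negatives <- sample(negatives_pool, n_sel, replace = FALSE)
  list(positives = unname(positives), negatives = negatives)
}

#' Grow a boosted LAD ensemble with per-locus positive sampling
#'
#' The initial constant `f0` is the median of a first batch's 0/1 targets.
#' Each tree is fit to the residuals of a fresh stochastic batch and added
#' with weight `shrinkage`. Consumes the ambient RNG stream; seed at a
#' higher level for reproducibility.
#'
#' @param weighted Weighted-locus tibble (`locus_id`, `gene_id`,
#'   `probability`).
#' @param features 0/1 matrix with gene ids as rownames covering all batch
#'   genes.
#' @param negatives_pool Character vector of negative-candidate genes.
#' @param n_trees Number of trees to add.
#' @param config `lb_config` from [training_config()].
#' @param initial_model Optional `lb_boost` to continue (trees appended;
#'   its `f0` is kept).
#' @return A `lb_boost` model; attribute `fitted` holds the current
#'   ensemble output for every row of `features`.
#' @export
boost <- function(weighted, features, negatives_pool, n_trees,
                  config = training_config(), initial_model = NULL) {
  stopifnot(is.matrix(features))
  if (is.null(initial_model)) {
    b0 <- sample_batch(weighted, negatives_pool, config$locus_fraction)
    f0 <- median(c(rep(1, length(b0$positives)), rep(0, length(b0$negatives))))
    trees <- list()
    fitted <- rep(f0, nrow(features))
  } else {
    f0 <- initial_model$f0
    trees <- initial_model$trees
    fitted <- attr(initial_model, "fitted")
    if (is.null(fitted)) {
      m <- new_lb_boost(f0, config$shrinkage, trees)
      fitted <- predict(m, features, type = "response", clamp = FALSE)
    }
  }
  names(fitted) <- rownames(features)
  if (n_trees > 0) {
    for (t in seq_len(n_trees)) {
      b <- sample_batch(weighted, negatives_pool, config$locus_fraction)
      ids <- c(b$positives, b$negatives)
      y <- c(rep(1, length(b$positives)), rep(0, length(b$negatives)))
      xb <- features[ids, , drop = FALSE]
      tree <- fit_lad_tree(xb, y, current_fit = fitted[ids],
                           n_leaves = config$n_leaves)
      trees <- c(trees, list(tree))
      fitted <- fitted + config$shrinkage * predict_lad_tree(tree, features)
    }
  }
  model <- new_lb_boost(f0, config$shrinkage, trees)
  attr(model, "fitted") <- fitted
  model
}

#' Predict from a boosted model
#'
#' @param object A `lb_boost`.
#' @param newdata 0/1 feature matrix (genes x features); split features
#'   absent from `newdata` are imputed as 0.
#' @param type `"log_odds"` (clamped logit of the ensemble output, the
#'   default) or `"response"` (the raw additive output).
#' @param epsilon Clamp for the logit transform, default 1e-3.
#' @param clamp Whether `"response"` output is clamped to `[0, 1]`
#'   (ignored for `"log_odds"`).
#' @param ... Unused.
#' @return Named numeric vector, one value per row of `newdata`.
#' @export
predict.lb_boost <- function(object, newdata, type = c("log_odds", "response"),
                             epsilon = 1e-3, clamp = TRUE, ...) {
  type <- match.arg(type)
  out <- rep(object$f0, nrow(newdata))
  for (tree in object$trees) {
    out <- out + object$shrinkage * predict_lad_tree(tree, newdata)
  }
  names(out) <- rownames(newdata)
  if (type == "response") {
    if (clamp) out <- pmin(pmax(out, 0), 1)
    return(out)
  }
  p <- pmin(pmax(out, epsilon), 1 - epsilon)
  log(p / (1 - p))
}

#' Clamped log-odds transform of an ensemble output
#' @param f Raw additive-model output (an estimated class probability).
#' @param epsilon Clamp, default 1e-3.
#' @return `log(p / (1 - p))` with `p = clamp(f, epsilon, 1 - epsilon)`.
#' @export
predict_log_odds <- function(f, epsilon = 1e-3) {
  p <- pmin(pmax(f, epsilon), 1 - epsilon)
  log(p / (1 - p))
}

#' Refine per-locus positive examples with a burn-in boosting phase
#'
#' Trees are grown one at a time exactly as in [boost()]; after each tree,
#' the gene with the highest current ensemble score at every locus (ties
#' to the lower gene id) gains one tally point. After `n_burnin_trees`
#' trees, each locus's tally total is computed (initial prior scores plus
#' increments by default) and only genes whose running score exceeds
#' `burnin_keep_fraction` of that total keep their (renormalized) sampling
#' probability; all others drop to 0. A locus that the filter would empty
#' retains its top-scoring gene; single-gene loci always survive. The
#' burn-in trees are discarded.
#'
#' @inheritParams boost
#' @param weighted Weighted-locus tibble with `locus_id`, `gene_id`,
#'   `total` (initial prior score) and `probability`.
#' @return The refined weighted tibble, with columns `increments`,
#'   `running_score`, `kept` added and `probability` updated.
#' @export
burnin_refine <- function(weighted, features, negatives_pool,
                          config = training_config()) {
  stopifnot(config$mode == "gwa")
  weighted <- dplyr::arrange(as_tibble(weighted), .data$locus_id, .data$gene_id)
  inc <- rep(0L, nrow(weighted))
  model <- NULL
  for (t in seq_len(config$n_burnin_trees)) {
    model <- boost(weighted, features, negatives_pool, n_trees = 1L,
                   config = config, initial_model = model)
    fitted <- attr(model, "fitted")
    for (l in unique(weighted$locus_id)) {
      rows <- which(weighted$locus_id == l)
      sc <- fitted[weighted$gene_id[rows]]
      top <- rows[order(-sc, weighted$gene_id[rows])[1]]
      inc[top] <- inc[top] + 1L
    }
  }
  weighted$increments <- inc
  burnin_filter(weighted, config)
}

# Apply the burn-in tally filter to a weighted tibble that already carries
# an `increments` column; see burnin_refine() for the rule.
burnin_filter <- function(weighted, config = training_config()) {
  weighted$running_score <- weighted$total + weighted$increments
  tally_base <- if (config$burnin_tally_initial) {
    weighted$running_score
  } else {
    weighted$increments
  }
  kept <- logical(nrow(weighted))
  for (l in unique(weighted$locus_id)) {
    rows <- which(weighted$locus_id == l)
    if (length(rows) == 1) {
      kept[rows] <- TRUE
      next
    }
    tally <- sum(tally_base[rows])
    pass <- tally_base[rows] > config$burnin_keep_fraction * tally
    if (!any(pass)) {
      pass <- seq_along(rows) == order(-tally_base[rows],
                                       weighted$gene_id[rows])[1]
    }
    kept[rows] <- pass
  }
  weighted$kept <- kept
  prob <- numeric(nrow(weighted))
  for (l in unique(weighted$locus_id)) {
    rows <- which(weighted$locus_id == l)
    krows <- rows[kept[rows]]
    prob[krows] <- to_probabilities(weighted$running_score[krows])
  }
  weighted$probability <- prob
  weighted
}

#' Cross-validated genome-wide gene scoring
#'
#' Runs `n_rounds` rounds of `n_folds`-fold cross-validation. In `"gwa"`
#' mode loci are partitioned into folds; each fold's model is trained on
#' the remaining loci (burn-in refinement followed by `n_main_trees` fresh
#' trees) and a locus gene's score comes from the fold holding out its
#' locus. In `"mendelian"` mode the positive genes themselves are
#' partitioned and no burn-in is run. Genes at no (held-out) locus receive
#' the mean over the round's fold models; the final score is the mean over
#' rounds.
#'
#' @param weighted Weighted-locus tibble (`locus_id`, `gene_id`, `total`,
#'   `probability`). In `"mendelian"` mode use [mendelian_weights()].
#' @param features 0/1 gene x feature matrix; universe genes missing from
#'   it are imputed as all-zero rows.
#' @param universe Character vector of all genes to score (default: the
#'   rownames of `features`).
#' @param config `lb_config` from [training_config()].
#' @param seed Integer seed making the whole procedure reproducible.
#' @return A tibble of class `lb_scores`: `gene_id`, `log_odds` (mean over
#'   rounds), one `round_<r>` column per round, and `is_locus_gene`.
#' @export
cross_validate <- function(weighted, features, universe = rownames(features),
                           config = training_config(), seed = NULL) {
  with_seed(seed, {
    features <- align_features(features, universe)
    locus_ids <- unique(weighted$locus_id)
    units <- if (config$mode == "gwa") locus_ids else unique(weighted$gene_id)
    if (length(units) < config$n_folds) {
      abort("fewer cross-validation units than folds")
    }
    locus_genes <- unique(weighted$gene_id)
    pool <- setdiff(universe, locus_genes)
    round_scores <- matrix(NA_real_, length(universe), config$n_rounds,
                           dimnames = list(universe, NULL))
    for (r in seq_len(config$n_rounds)) {
      fold_of <- setNames(
        sample(rep(seq_len(config$n_folds), length.out = length(units))),
        units
      )
      fold_preds <- matrix(NA_real_, length(universe), config$n_folds,
                           dimnames = list(universe, NULL))
      for (f in seq_len(config$n_folds)) {
        held_units <- units[fold_of[units] == f]
        if (config$mode == "gwa") {
          train_w <- weighted[!(weighted$locus_id %in% held_units), ]
        } else {
          train_w <- weighted[!(weighted$gene_id %in% held_units), ]
        }
        if (length(unique(train_w$locus_id)) == 0) {
          abort("cross-validation fold with zero training loci")
        }
        if (config$mode == "gwa" && config$n_burnin_trees > 0) {
          train_w <- burnin_refine(train_w, features, pool, config = config)
        }
        model <- boost(train_w, features, pool,
                       n_trees = config$n_main_trees, config = config)
        fold_preds[, f] <- predict_log_odds(attr(model, "fitted"),
                                            epsilon = config$epsilon)
      }
      sc <- rowMeans(fold_preds)
      if (config$mode == "gwa") {
        # Held-out scoring: a locus gene's value comes from the fold(s)
        # holding out its locus (mean when a gene sits at several loci).
        gl <- dplyr::distinct(weighted, .data$locus_id, .data$gene_id)
        gl$value <- fold_preds[cbind(match(gl$gene_id, universe),
                                     unname(fold_of[gl$locus_id]))]
        held <- dplyr::summarise(dplyr::group_by(gl, .data$gene_id),
                                 value = mean(.data$value), .groups = "drop")
        sc[match(held$gene_id, universe)] <- held$value
      } else {
        pos <- unique(weighted$gene_id)
        sc[match(pos, universe)] <- fold_preds[cbind(match(pos, universe),
                                                     unname(fold_of[pos]))]
      }
      round_scores[, r] <- sc
    }
    out <- tibble(
      gene_id = universe,
      log_odds = rowMeans(round_scores),
      is_locus_gene = universe %in% locus_genes
    )
    for (r in seq_len(config$n_rounds)) {
      out[[paste0("round_", r)]] <- round_scores[, r]
    }
    class(out) <- c("lb_scores", class(out))
    out
  })
}

#' Represent a Mendelian positive gene list as weighted loci
#'
#' Each positive gene becomes its own single-gene unit with sampling
#' probability 1, so the same boosting machinery applies without burn-in.
#'
#' @param positive_genes Character vector of established disease genes.
#' @return A weighted-locus tibble.
#' @export
mendelian_weights <- function(positive_genes) {
  positive_genes <- sort(unique(positive_genes))
  tibble(
    locus_id = paste0("gene_", positive_genes),
    gene_id = positive_genes,
    total = 1L,
    probability = 1
  )
}

align_features <- function(features, universe) {
  missing_genes <- setdiff(universe, rownames(features))
  if (length(missing_genes) > 0) {
    pad <- matrix(0L, length(missing_genes), ncol(features),
                  dimnames = list(missing_genes, colnames(features)))
    features <- rbind(features, pad)
  }
  features[universe, , drop = FALSE]
}

#' Write a gene score table as TSV
#' @param scores `lb_scores` tibble from [cross_validate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(as_tibble(scores), path)
  invisible(path)
}

#' @export
print.lb_boost <- function(x, ...) {
  cat("Boosted LAD-tree model:", length(x$trees), "trees, f0 =", x$f0,
      ", shrinkage =", x$shrinkage, "\n")
  invisible(x)
}

#' Tidy a boosted model
#'
#' One row per tree node: tree index, node id, split feature or leaf
#' value.
#' @param x A `lb_boost` model.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lb_boost
#' @export
tidy.lb_boost <- function(x, ...) {
  purrr::imap(x$trees, function(tr, i) {
    dplyr::mutate(tr$nodes, tree = i, .before = 1)
  }) |> dplyr::bind_rows()
}

#' One-row summary of a boosted model
#' @param x A `lb_boost` model.
#' @param ... Unused.
#' @return A one-row tibble with `n_trees`, `f0`, `shrinkage`,
#'   `n_features_used`.
#' @method glance lb_boost
#' @export
glance.lb_boost <- function(x, ...) {
  nd <- tidy(x)
  tibble(
    n_trees = length(x$trees),
    f0 = x$f0,
    shrinkage = x$shrinkage,
    n_features_used = dplyr::n_distinct(nd$feature[!is.na(nd$feature)])
  )
}
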