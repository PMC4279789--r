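#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation with midrank tie handling:
#' the probability that a random positive outranks a random negative,
#' counting ties as one half.
#'
#' @param scores Named numeric vector (gene -> score), or a data frame with
#'   `gene_id` and `log_odds`.
#' @param labels Character vector of positive gene ids, or a logical vector
#'   aligned with `scores`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  s <- score_vector(scores)
  y <- label_vector(s, labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("need at least one positive and one negative")
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    return(setNames(scores$log_odds, scores$gene_id))
  }
  scores
}

label_vector <- function(s, labels) {
  if (is.logical(labels)) {
    stopifnot(length(labels) == length(s))
    return(labels)
  }
  if (is.null(names(s))) abort("scores must be named when labels are gene ids")
  names(s) %in% labels
}

#' Precision at a fixed recall, with binomial significance
#'
#' The score threshold is the smallest top-k capturing at least
#' `recall_level` of the positives (descending score, ties by name for
#' determinism). Precision is the fraction of the top-k that are positive;
#' significance is the upper binomial tail `P(X >= observed)` with
#' `X ~ Binomial(k, prevalence)`.
#'
#' @inheritParams auroc
#' @param recall_level Target recall in `(0, 1]`, default 0.2.
#' @return A one-row tibble: `recall_level`, `k`, `n_hits`, `precision`,
#'   `binom_p`.
#' @export
precision_at_recall <- function(scores, labels, recall_level = 0.2) {
  stopifnot(recall_level > 0, recall_level <= 1)
  s <- score_vector(scores)
  y <- label_vector(s, labels)
  n_pos <- sum(y)
  if (n_pos == 0) abort("no positive labels")
  ord <- order(-s, names(s) %||% seq_along(s))
  cum_pos <- cumsum(y[ord])
  k <- which(cum_pos >= recall_level * n_pos)[1]
  n_hits <- cum_pos[k]
  prevalence <- n_pos / length(s)
  tibble(
    recall_level = recall_level,
    k = as.integer(k),
    n_hits = as.integer(n_hits),
    precision = n_hits / k,
    binom_p = pbinom(n_hits - 1, k, prevalence, lower.tail = FALSE)
  )
}

#' Within-locus rank permutation test for likely-positive prioritization
#'
#' The statistic counts loci at which a likely-positive gene sits within
#' the locus-size-dependent top window: the top three for loci of four or
#' more genes, the top two for three-gene loci, and the top one for
#' two-gene loci. The null permutes ranks independently and uniformly
#' within each locus. Only loci with at least one likely positive and at
#' least two genes can contribute. The empirical p-value uses the +1
#' correction: `(1 + #null >= observed) / (n_perm + 1)`.
#'
#' @param ranked Tibble with `locus_id`, `gene_id`, `rank` (1 = best) and
#'   logical `likely_positive`.
#' @param n_perm Number of permutations, default 10,000.
#' @param seed Optional integer seed.
#' @return A list of class `lb_permutation`: `observed`, `null` (integer
#'   vector), `empirical_p`, `n_perm`, `n_loci`.
#' @export
topk_permutation_test <- function(ranked, n_perm = 10000L, seed = NULL) {
  with_seed(seed, {
    ranked <- as_tibble(ranked)
    info <- dplyr::summarise(
      dplyr::group_by(ranked, .data$locus_id),
      n = dplyr::n(),
      n_lp = sum(.data$likely_positive),
      hit = any(.data$likely_positive & .data$rank <= top_window(dplyr::n())),
      .groups = "drop"
    )
    info <- dplyr::filter(info, .data$n >= 2, .data$n_lp >= 1)
    if (nrow(info) == 0) abort("no contributing loci (need >= 2 genes and a likely positive)")
    observed <- sum(info$hit)
    # Under a uniform within-locus rank permutation, the number of likely
    # positives landing in the top-w window of a locus with n genes and m
    # likely positives is Hypergeometric(m, n - m, w); a locus hits when
    # that count is >= 1, and loci permute independently.
    w <- top_window(info$n)
    null <- integer(n_perm)
    for (l in seq_len(nrow(info))) {
      x <- stats::rhyper(n_perm, info$n_lp[l], info$n[l] - info$n_lp[l], w[l])
      null <- null + as.integer(x >= 1)
    }
    structure(list(
      observed = observed,
      null = null,
      empirical_p = (1 + sum(null >= observed)) / (n_perm + 1),
      n_perm = n_perm,
      n_loci = nrow(info)
    ), class = "lb_permutation")
  })
}

top_window <- function(n) {
  ifelse(n >= 4, 3L, ifelse(n == 3, 2L, 1L))
}

#' @export
print.lb_permutation <- function(x, ...) {
  cat("Within-locus rank permutation test:", x$observed, "of", x$n_loci,
      "loci hit; p =", signif(x$empirical_p, 3),
      paste0("(", x$n_perm, " permutations)\n"))
  invisible(x)
}

#' Empirical null for the top score at a locus
#'
#' For each locus of `n` genes, draws `n` scores from the genome-wide
#' score pool `n_iter` times (without replacement within an iteration, as
#' a locus's genes are distinct; set `replace = TRUE` for the
#' with-replacement variant) and records each iteration's maximum. The
#' per-locus p-value is the fraction of iterations whose maximum is at
#' least the observed top score (optionally with the +1 correction).
#'
#' @param locus_gene_counts Integer vector of locus sizes `n`.
#' @param global_scores Numeric pool of genome-wide scores.
#' @param observed_top Numeric vector of observed per-locus top scores
#'   (same length as `locus_gene_counts`).
#' @param n_iter Iterations, default 10,000.
#' @param replace Sample with replacement within an iteration (default
#'   `FALSE`).
#' @param plus_one Use the `(1 + hits) / (n_iter + 1)` correction instead
#'   of the raw fraction (default `FALSE`, matching the fraction form).
#' @param seed Optional integer seed.
#' @return A tibble with `n_genes`, `observed_top`, `empirical_p`.
#' @export
top_score_null <- function(locus_gene_counts, global_scores, observed_top,
                           n_iter = 10000L, replace = FALSE,
                           plus_one = FALSE, seed = NULL) {
  stopifnot(length(locus_gene_counts) == length(observed_top),
            length(global_scores) > 0)
  if (!replace && max(locus_gene_counts) > length(global_scores)) {
    abort("locus size exceeds the score pool (without replacement)")
  }
  with_seed(seed, {
    p <- purrr::map2_dbl(locus_gene_counts, observed_top, function(n, obs) {
      tops <- vapply(seq_len(n_iter), function(i) {
        max(sample(global_scores, n, replace = replace))
      }, 0)
      hits <- sum(tops >= obs)
      if (plus_one) (1 + hits) / (n_iter + 1) else hits / n_iter
    })
    tibble(n_genes = locus_gene_counts, observed_top = observed_top,
           empirical_p = p)
  })
}

#' Fisher enrichment of one gene set in another
#'
#' Builds the 2x2 table `a = n_overlap`, `b = n_set_b - a`,
#' `c = n_set_a - a`, `d = n_universe - a - b - c`, reports the sample
#' odds ratio `ad / bc` (0.5 continuity correction on zero cells) and the
#' one-sided hypergeometric over-representation p-value (two-sided on
#' request via [stats::fisher.test()]'s convention of summing all tables
#' at most as probable).
#'
#' @param n_overlap,n_set_a,n_set_b,n_universe The four counts.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A one-row tibble with `odds_ratio` and `p`.
#' @export
fisher_enrichment <- function(n_overlap, n_set_a, n_set_b, n_universe,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_overlap > min(n_set_a, n_set_b)) abort("overlap exceeds a set size")
  a <- n_overlap
  b <- n_set_b - a
  c <- n_set_a - a
  d <- n_universe - a - b - c
  if (d < 0) abort("inconsistent counts: universe smaller than the union")
  or <- sample_odds_ratio(a, b, c, d)
  p <- if (alternative == "greater") {
    phyper(a - 1, n_set_b, n_universe - n_set_b, n_set_a, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, c, b, d), 2), alternative = "two.sided")$p.value
  }
  tibble(odds_ratio = or, p = p)
}

#' Rank locus genes by model score
#'
#' Joins cross-validated scores onto weighted loci and ranks genes within
#' each locus (1 = highest score; ties by gene id for determinism),
#' producing the input for [topk_permutation_test()].
#'
#' @param weighted Weighted-locus tibble ([weigh_loci()]).
#' @param scores `lb_scores` tibble ([cross_validate()]) or named vector.
#' @return Tibble with `locus_id`, `gene_id`, `log_odds`, `rank`,
#'   `likely_positive`.
#' @export
rank_locus_genes <- function(weighted, scores) {
  s <- score_vector(scores)
  out <- dplyr::distinct(as_tibble(weighted), .data$locus_id, .data$gene_id,
                         .data$likely_positive)
  out$log_odds <- unname(s[out$gene_id])
  if (anyNA(out$log_odds)) abort("some locus genes have no score")
  out <- dplyr::group_by(out, .data$locus_id)
  out <- dplyr::mutate(out, rank = order(order(-.data$log_odds, .data$gene_id)))
  dplyr::ungroup(out)
}

#' Summary evaluation report
#'
#' AUROC of the scores against the likely-positive labels, precision at a
#' fixed recall with its binomial p, and the within-locus permutation test.
#'
#' @param scores `lb_scores` tibble or named score vector.
#' @param weighted Weighted-locus tibble carrying `likely_positive` flags.
#' @param labels Positive gene ids to evaluate against; defaults to the
#'   likely positives of `weighted` (pass the established gene list in
#'   Mendelian mode).
#' @param recall_level Recall level for the precision statistic,
#'   default 0.2.
#' @param n_perm Permutations for the rank test, default 10,000.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `auroc`, `recall_level`, `precision`,
#'   `binom_p`, `n_predictions_at_threshold`, `perm_observed`, `perm_p`.
#' @export
evaluate_scores <- function(scores, weighted, labels = NULL,
                            recall_level = 0.2, n_perm = 10000L,
                            seed = NULL) {
  s <- score_vector(scores)
  lp <- labels %||% flag_likely_positives(weighted)
  roc <- auroc(s, lp)
  pr <- precision_at_recall(s, lp, recall_level = recall_level)
  ranked <- rank_locus_genes(weighted, s)
  perm <- tryCatch(
    topk_permutation_test(ranked, n_perm = n_perm, seed = seed),
    error = function(e) NULL
  )
  tibble(
    auroc = roc,
    recall_level = pr$recall_level,
    precision = pr$precision,
    binom_p = pr$binom_p,
    n_predictions_at_threshold = pr$k,
    perm_observed = if (is.null(perm)) NA_integer_ else perm$observed,
    perm_p = if (is.null(perm)) NA_real_ else perm$empirical_p
  )
}
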