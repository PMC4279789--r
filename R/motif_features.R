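BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' Applies a pseudocount to every cell and renormalizes columns, so no
#' frequency is exactly zero.
#'
#' @param freqs 4 x L matrix of per-position base frequencies (rows A, C,
#'   G, T; columns sum to 1).
#' @param motif_id Motif identifier.
#' @param background Background base frequencies (named or in A,C,G,T
#'   order), default uniform.
#' @param pseudocount Added to each cell before renormalization,
#'   default 0.01.
#' @return A list of class `lb_pwm` with elements `motif_id`, `f`
#'   (pseudocounted frequencies), `p` (background), `length`.
#' @export
pwm <- function(freqs, motif_id = "motif", background = rep(0.25, 4),
                pseudocount = 0.01) {
  stopifnot(nrow(freqs) == 4, ncol(freqs) >= 1, pseudocount >= 0)
  if (is.null(rownames(freqs))) rownames(freqs) <- BASES
  freqs <- freqs[BASES, , drop = FALSE]
  if (any(abs(colSums(freqs) - 1) > 1e-6)) {
    abort(paste0("motif ", motif_id, ": columns must sum to 1"))
  }
  f <- sweep(freqs + pseudocount, 2, colSums(freqs + pseudocount), "/")
  background <- if (is.null(names(background))) {
    setNames(as.numeric(background), BASES)
  } else {
    background[BASES]
  }
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  if (any(background <= 0)) abort("background frequencies must be positive")
  structure(list(motif_id = motif_id, f = f, p = background,
                 length = ncol(freqs)), class = "lb_pwm")
}

#' Per-position information-content weights
#'
#' `w_j = 2 + sum_b f_bj log2 f_bj`, the information content of column j
#' for a 4-letter alphabet, in `[0, 2]`: 0 for a uniform column, 2 for a
#' degenerate one (at pseudocount 0). A `literal` variant
#' (`2 - sum_b log2 f_bj`) reproducing an alternative printed form is
#' available behind the flag.
#'
#' @param pwm A `lb_pwm` object.
#' @param literal Use the literal alternative form (default `FALSE`).
#' @return Numeric vector of length `pwm$length`.
#' @export
position_weights <- function(pwm, literal = FALSE) {
  stopifnot(inherits(pwm, "lb_pwm"))
  if (literal) {
    return(2 - colSums(log2(pwm$f)))
  }
  fl <- pwm$f * log2(pwm$f)
  fl[pwm$f == 0] <- 0  # x log2 x -> 0 as x -> 0
  2 + colSums(fl)
}

#' Entropy-weighted motif match score of one window
#'
#' `MMS = sum_j w_j log2(f_{b(j),j} / p_{b(j)}) / sum_j w_j`, where `b(j)`
#' is the window base at motif position `j`. Higher scores are better
#' matches; set `paper_sign = TRUE` for the negated convention.
#'
#' @param pwm A `lb_pwm`.
#' @param window Character scalar of length `pwm$length` over A/C/G/T.
#' @param paper_sign Emit the negated score (default `FALSE`).
#' @param literal_weights Passed to [position_weights()].
#' @return The match score (numeric scalar).
#' @export
mms <- function(pwm, window, paper_sign = FALSE, literal_weights = FALSE) {
  b <- strsplit(toupper(window), "")[[1]]
  if (length(b) != pwm$length) abort("window length must equal motif length")
  if (!all(b %in% BASES)) abort("window must be over A/C/G/T")
  w <- position_weights(pwm, literal = literal_weights)
  sw <- sum(w)
  if (sw <= 0) abort(paste0("motif ", pwm$motif_id,
                            " is uninformative (all positions uniform)"))
  idx <- cbind(match(b, BASES), seq_along(b))
  term <- w * log2(pwm$f[idx] / pwm$p[b])
  term[w == 0] <- 0  # zero-information positions contribute nothing
  s <- sum(term) / sw
  if (paper_sign) -s else s
}

# Vectorized MMS over all windows of a sequence (one strand).
mms_profile <- function(pwm, seq_chars, paper_sign = FALSE,
                        literal_weights = FALSE) {
  L <- pwm$length
  n <- length(seq_chars) - L + 1
  if (n < 1) return(numeric(0))
  w <- position_weights(pwm, literal = literal_weights)
  sw <- sum(w)
  if (sw <= 0) abort(paste0("motif ", pwm$motif_id,
                            " is uninformative (all positions uniform)"))
  base_idx <- match(seq_chars, BASES)
  lr <- log2(pwm$f / matrix(pwm$p, 4, L))
  contrib <- sweep(lr, 2, w, "*")
  contrib[, w == 0] <- 0  # zero-information positions contribute nothing
  out <- numeric(n)
  ok <- !logical(n)
  for (j in seq_len(L)) {
    bj <- base_idx[seq_len(n) + j - 1]
    bad <- is.na(bj)
    ok <- ok & !bad
    bj[bad] <- 1L
    out <- out + contrib[cbind(bj, j)]
  }
  out <- out / sw
  out[!ok] <- NA_real_  # windows containing non-ACGT bases score NA
  if (paper_sign) -out else out
}

revcomp_chars <- function(seq_chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(ifelse(seq_chars %in% BASES, comp[seq_chars], seq_chars)))
}

#' Scan a sequence for motif matches on both strands
#'
#' Slides the motif over the forward sequence and its reverse complement
#' and emits every window whose match score reaches `threshold`.
#' Overlapping hits are all retained. Hit positions are 0-based starts on
#' the forward strand.
#'
#' @param pwm A `lb_pwm`.
#' @param sequence Character scalar (A/C/G/T; windows containing other
#'   letters are skipped), or a named vector of sequences.
#' @param threshold Minimum match score for a hit.
#' @param seq_id Sequence name used in the output (default `"seq"`; for a
#'   named vector the names are used).
#' @param ... Passed to the scorer ([mms()] conventions).
#' @return A tibble of hits: `seq_id`, `motif_id`, `pos`, `width`,
#'   `strand`, `mms`, sorted by position.
#' @export
empty_hits <- function() {
  tibble(seq_id = character(), motif_id = character(), pos = integer(),
         width = integer(), strand = character(), mms = numeric())
}

scan_pwm <- function(pwm, sequence, threshold, seq_id = "seq", ...) {
  if (length(sequence) == 0) return(empty_hits())
  if (length(sequence) > 1 || !is.null(names(sequence))) {
    ids <- names(sequence) %||% paste0("seq", seq_along(sequence))
    out <- purrr::map2(unname(sequence), ids, function(s, id) {
      scan_pwm(pwm, s, threshold, seq_id = id, ...)
    })
    return(dplyr::bind_rows(out))
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- pwm$length
  hit_rows <- function(profile, strand, starts) {
    keep <- which(!is.na(profile) & profile >= threshold)
    tibble(
      seq_id = seq_id, motif_id = pwm$motif_id,
      pos = starts[keep], width = L, strand = strand,
      mms = profile[keep]
    )
  }
  fwd <- mms_profile(pwm, chars, ...)
  n <- length(chars)
  rev_profile <- mms_profile(pwm, revcomp_chars(chars), ...)
  # window i (0-based) of the reverse complement starts at n - i - L
  # on the forward strand
  out <- dplyr::bind_rows(
    hit_rows(fwd, "+", seq_len(length(fwd)) - 1L),
    hit_rows(rev_profile, "-", n - (seq_len(length(rev_profile)) - 1L) - L)
  )
  dplyr::arrange(out, .data$pos, .data$strand)
}

#' Fit a Gaussian mixture to motif scores and derive a match threshold
#'
#' One-dimensional `k`-component Gaussian mixture fit by EM (k-means++
#' initialization, best log-likelihood of `n_restarts` restarts,
#' convergence tolerance 1e-8, at most 500 iterations). Components are
#' reported by ascending mean; the three components of the default `k = 3`
#' are read as low-, intermediate- and high-confidence binding, and the
#' threshold is the minimum score among points MAP-assigned to the
#' highest-mean component.
#'
#' @param scores Numeric vector of empirical match scores.
#' @param k Number of components, default 3.
#' @param n_restarts EM restarts, default 20.
#' @param tol Relative log-likelihood convergence tolerance, default 1e-8.
#' @param max_iter Maximum EM iterations per restart, default 500.
#' @param seed Optional integer seed.
#' @return A list of class `lb_mixture`: `means`, `sds`, `weights` (each
#'   ordered by ascending mean), `threshold`, `log_lik`, `converged`,
#'   `loglik_trace` (of the winning restart).
#' @export
fit_threshold <- function(scores, k = 3L, n_restarts = 20L, tol = 1e-8,
                          max_iter = 500L, seed = NULL) {
  scores <- as.numeric(scores)
  if (length(unique(scores)) < 3 * k) {
    abort(paste0("need at least ", 3 * k, " distinct score values"))
  }
  scores <- sort(scores)  # fit is independent of input order by design
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- em_gmm1d(scores, k, tol = tol, max_iter = max_iter)
      if (is.null(best) || fit$log_lik > best$log_lik) best <- fit
    }
    ord <- order(best$means)
    means <- best$means[ord]
    sds <- best$sds[ord]
    weights <- best$weights[ord]
    # MAP assignment; the high-confidence component is the last (highest
    # mean) after ordering
    resp <- gmm_responsibilities(scores, means, sds, weights)
    map <- max.col(resp, ties.method = "last")
    high <- which(map == k)
    threshold <- if (length(high) > 0) min(scores[high]) else max(scores)
    if (!best$converged) {
      warn("EM did not converge in max_iter iterations; best likelihood returned")
    }
    structure(list(
      means = means, sds = sds, weights = weights, threshold = threshold,
      log_lik = best$log_lik, converged = best$converged,
      loglik_trace = best$trace
    ), class = "lb_mixture")
  })
}

# k-means++ style seeding: first center uniform, later centers drawn with
# probability proportional to squared distance from the nearest center.
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(x, function(v) min((v - centers[1:(j - 1)])^2), 0)
      if (sum(d2) == 0) {
        centers[j] <- x[sample.int(length(x), 1)]
      } else {
        centers[j] <- x[sample.int(length(x), 1, prob = d2)]
      }
    }
  }
  centers
}

gmm_responsibilities <- function(x, means, sds, weights) {
  dens <- vapply(seq_along(means), function(j) {
    weights[j] * dnorm(x, means[j], sds[j])
  }, numeric(length(x)))
  dens <- pmax(dens, .Machine$double.xmin)
  dens / rowSums(dens)
}

em_gmm1d <- function(x, k, tol = 1e-8, max_iter = 500L) {
  n <- length(x)
  means <- kmeanspp_centers(x, k)
  sds <- rep(max(sd(x) / k, 1e-3), k)
  weights <- rep(1 / k, k)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      weights[j] * dnorm(x, means[j], sds[j])
    }, numeric(n))
    rowsum_dens <- pmax(rowSums(dens), .Machine$double.xmin)
    ll <- sum(log(rowsum_dens))
    trace <- c(trace, ll)
    resp <- dens / rowsum_dens
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    weights <- nk / n
    means <- colSums(resp * x) / nk
    sds <- sqrt(colSums(resp * (outer(x, means, "-"))^2) / nk)
    sds <- pmax(sds, 1e-6)  # variance floor against degenerate spikes
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(means = means, sds = sds, weights = weights, log_lik = ll_old,
       converged = converged, trace = trace)
}

#' @export
print.lb_mixture <- function(x, ...) {
  cat("Gaussian mixture threshold:", signif(x$threshold, 5), "\n")
  cat("  means:", paste(signif(x$means, 4), collapse = ", "), "\n")
  cat("  sds:", paste(signif(x$sds, 4), collapse = ", "), "\n")
  cat("  weights:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Map motif hits to nearby genes and count them
#'
#' A hit counts for every gene whose body `[tx_start, tx_end)` expanded by
#' `window_bp` on each side contains the hit's start coordinate; the hit's
#' `seq_id` must match the gene's chromosome. Counts accumulate over hits.
#'
#' @param hits Hits tibble ([scan_pwm()]).
#' @param genes Gene annotation tibble.
#' @param window_bp Window in bp (10,000 for experimental binding sites,
#'   25,000 for conserved sites).
#' @return A tibble with `gene_id`, `count` covering every annotated gene
#'   (zeros included).
#' @export
hits_to_gene_counts <- function(hits, genes, window_bp = 10000L) {
  stopifnot(window_bp >= 0)
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      n <- sum(hits$seq_id == g$chrom &
                 hits$pos >= g$tx_start - window_bp &
                 hits$pos < g$tx_end + window_bp)
      counts[i] <- n
    }
  }
  tibble(gene_id = genes$gene_id, count = unname(counts))
}

#' Discretize per-gene hit counts into nested binary features
#'
#' Indicators for at least 1, more than 1, more than 2 and more than 3
#' copies, so a gene with five copies scores 1,1,1,1 and one with two
#' copies 1,1,0,0.
#'
#' @param counts Tibble with `gene_id`, `count` (or a named vector).
#' @param prefix Feature id prefix, default `"tfbs"`.
#' @return A tibble with `gene_id` and the four 0/1 columns
#'   `<prefix>_ge1` ... `<prefix>_ge4`.
#' @export
count_threshold_features <- function(counts, prefix = "tfbs") {
  if (!is.data.frame(counts)) {
    counts <- tibble(gene_id = names(counts), count = unname(counts))
  }
  stopifnot(all(counts$count >= 0))
  out <- tibble(gene_id = counts$gene_id)
  for (t in 1:4) {
    out[[paste0(prefix, "_ge", t)]] <- as.integer(counts$count >= t)
  }
  out
}

#' Percentile-threshold binary features
#'
#' For each sample (column) and percentile, a gene scores 1 iff its value
#' strictly exceeds the linear-interpolation quantile cutoff of that
#' sample. A constant sample yields an all-zero column (with a warning).
#'
#' @param values Matrix or data frame of gene x sample values with gene
#'   ids as rownames (or a `gene_id` column).
#' @param percentiles Percentile cutoffs, default `c(75, 90, 99)`.
#' @return A tibble with `gene_id` and one 0/1 column
#'   `<sample>_p<percentile>` per (sample, percentile) pair.
#' @export
percentile_features <- function(values, percentiles = c(75, 90, 99)) {
  if (is.data.frame(values)) {
    if ("gene_id" %in% names(values)) {
      ids <- values$gene_id
      values <- as.matrix(values[setdiff(names(values), "gene_id")])
      rownames(values) <- ids
    } else {
      values <- as.matrix(values)
    }
  }
  if (is.null(rownames(values))) abort("values need gene ids as rownames")
  out <- tibble(gene_id = rownames(values))
  for (s in colnames(values)) {
    v <- values[, s]
    if (length(unique(v)) < 2) {
      warn(paste0("sample ", s, " is constant; its columns are all zero"))
    }
    for (p in percentiles) {
      cutoff <- quantile(v, p / 100, type = 7, names = FALSE)
      out[[paste0(s, "_p", p)]] <- as.integer(v > cutoff)
    }
  }
  out
}

#' Convert discretized feature tibbles to triplets
#'
#' Helper to append feature columns (from [count_threshold_features()] or
#' [percentile_features()]) to the sparse triplet representation consumed
#' by [feature_matrix_from_triplets()].
#'
#' @param feature_tbl Tibble with `gene_id` and 0/1 feature columns.
#' @return Triplet tibble (`gene_id`, `feature_id`, `value`), nonzero
#'   entries only.
#' @export
features_to_triplets <- function(feature_tbl) {
  tidyr::pivot_longer(feature_tbl, -"gene_id", names_to = "feature_id",
                      values_to = "value") |>
    dplyr::filter(.data$value != 0) |>
    dplyr::arrange(.data$gene_id, .data$feature_id)
}
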