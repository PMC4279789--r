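mat4 <- function(...) {
  m <- cbind(...)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# direct entropy recomputation, independent of position_weights()
entropy_weight <- function(col) {
  nz <- col[col > 0]
  2 - sum(-nz * log2(nz))
}

test_that("position weights span the information-content range", {
  uniform <- mat4(rep(0.25, 4))
  degenerate <- mat4(c(1, 0, 0, 0))
  p0 <- pwm(cbind(uniform, degenerate), pseudocount = 0)
  w <- position_weights(p0)
  expect_equal(w[1], 0)
  expect_equal(w[2], 2)

  set.seed(31)
  for (rep in 1:10) {
    cols <- replicate(4, {
      x <- runif(4)
      x / sum(x)
    })
    p <- pwm(mat4(cols), pseudocount = 0)
    expect_equal(position_weights(p),
                 apply(p$f, 2, entropy_weight), tolerance = 1e-12)
    expect_true(all(position_weights(p) >= 0 & position_weights(p) <= 2))
  }
})

test_that("match score follows the weighted log-ratio definition", {
  # degenerate A column plus an uninformative column: only the first
  # position scores, so MMS = log2(1 / 0.25) = 2
  p <- pwm(mat4(c(1, 0, 0, 0), rep(0.25, 4)), pseudocount = 0)
  expect_equal(mms(p, "AA"), 2)

  # frequencies equal to background everywhere score zero
  bg <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  pbg <- pwm(mat4(c(0.4, 0.1, 0.1, 0.4), c(0.4, 0.1, 0.1, 0.4)),
             background = bg, pseudocount = 0)
  expect_equal(mms(pbg, "AT"), 0, tolerance = 1e-12)

  # the published-sign flag negates
  expect_equal(mms(p, "AA", paper_sign = TRUE), -2)

  # a motif that is uniform everywhere is uninformative
  puni <- pwm(mat4(rep(0.25, 4), rep(0.25, 4)), pseudocount = 0)
  expect_error(mms(puni, "AA"), "uninformative")
})

test_that("match score is invariant under simultaneous base relabeling", {
  set.seed(32)
  f <- replicate(3, { x <- runif(4); x / sum(x) })
  bg <- c(0.3, 0.2, 0.3, 0.2)
  perm <- c(3, 1, 4, 2)  # relabel A<->G, C<->A etc.
  p1 <- pwm(mat4(f), background = setNames(bg, c("A", "C", "G", "T")))
  p2 <- pwm(mat4(f[perm, ]), background = setNames(bg[perm], c("A", "C", "G", "T")))
  win1 <- "ACG"
  relabel <- setNames(c("A", "C", "G", "T")[order(perm)], c("A", "C", "G", "T"))
  win2 <- paste(relabel[strsplit(win1, "")[[1]]], collapse = "")
  expect_equal(mms(p1, win1), mms(p2, win2), tolerance = 1e-12)
})

test_that("3-mer score distribution matches brute force over all 64 windows", {
  set.seed(33)
  f <- replicate(3, { x <- runif(4); x / sum(x) })
  p <- pwm(mat4(f), motif_id = "m3")
  bases <- c("A", "C", "G", "T")
  wins <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  direct <- vapply(wins, function(wd) {
    b <- strsplit(wd, "")[[1]]
    w <- apply(p$f, 2, entropy_weight)
    sum(w * vapply(1:3, function(j) log2(p$f[b[j], j] / 0.25), 0)) / sum(w)
  }, 0)
  via_pkg <- vapply(wins, function(wd) mms(p, wd), 0)
  expect_equal(via_pkg, direct, tolerance = 1e-12)
})

test_that("scanning equals exhaustive window evaluation on both strands", {
  set.seed(34)
  f <- replicate(3, { x <- runif(4); x / sum(x) })
  p <- pwm(mat4(f), motif_id = "m3")
  seqc <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  thr <- 0.3
  hits <- scan_pwm(p, seqc, threshold = thr)

  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  expected <- list()
  for (i in 0:(nchar(seqc) - 3)) {
    wd <- substr(seqc, i + 1, i + 3)
    s_f <- mms(p, wd)
    if (s_f >= thr) expected[[length(expected) + 1]] <- c(i, 1, s_f)
    s_r <- mms(p, revcomp(wd))
    if (s_r >= thr) expected[[length(expected) + 1]] <- c(i, -1, s_r)
  }
  exp_df <- do.call(rbind, expected)
  expect_equal(nrow(hits), nrow(exp_df))
  got <- hits[order(hits$pos, hits$strand), ]
  exp_ord <- exp_df[order(exp_df[, 1], exp_df[, 2]), , drop = FALSE]
  expect_equal(got$pos, as.integer(exp_ord[, 1]))
  expect_equal(got$mms, unname(exp_ord[, 3]), tolerance = 1e-12)
})

test_that("a threshold above the maximum attainable score yields no hits", {
  p <- pwm(mat4(c(1, 0, 0, 0), c(0, 1, 0, 0)), motif_id = "ac")
  hits <- scan_pwm(p, "ACACAC", threshold = 10)
  expect_equal(nrow(hits), 0L)
})

test_that("palindromic motifs hit both strands symmetrically", {
  # ACGT's reverse complement is ACGT
  p <- pwm(mat4(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1)),
           motif_id = "pal")
  seqc <- "GGACGTGG"
  hits <- scan_pwm(p, seqc, threshold = 1)
  expect_equal(sum(hits$strand == "+"), sum(hits$strand == "-"))
  expect_setequal(hits$pos[hits$strand == "+"], hits$pos[hits$strand == "-"])
})

test_that("mixture fit recovers well-separated components and the threshold", {
  set.seed(35)
  scores <- c(rnorm(1000, 0), rnorm(1000, 5), rnorm(1000, 10))
  fit <- fit_threshold(scores, seed = 36)
  expect_equal(fit$means, c(0, 5, 10), tolerance = 0.3)
  expect_gt(fit$threshold, 5)
  expect_lt(fit$threshold, 10)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("mixture fit is order invariant and needs enough distinct values", {
  set.seed(37)
  scores <- c(rnorm(300, 0), rnorm(300, 4), rnorm(300, 8))
  f1 <- fit_threshold(scores, seed = 38)
  f2 <- fit_threshold(sample(scores), seed = 38)
  expect_equal(f1$means, f2$means, tolerance = 1e-6)
  expect_equal(f1$threshold, f2$threshold)

  expect_error(fit_threshold(rep(1:8, 10)), "distinct")
})

test_that("mixture fit agrees with an established mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(39)
  scores <- c(rnorm(800, 0), rnorm(800, 5, 1.2), rnorm(800, 11))
  fit <- fit_threshold(scores, seed = 40)
  ref <- mclust::Mclust(scores, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(fit$means, sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.2)
})

test_that("hits map to genes within the window by start coordinate", {
  genes <- tiny_genes(3)  # bodies [100k,110k), [200k,210k), [300k,310k)
  hits <- tibble::tibble(
    seq_id = "chr1", motif_id = "m",
    pos = c(95000L, 205000L, 205100L, 205200L, 270000L),
    width = 8L, strand = "+", mms = 1
  )
  counts <- hits_to_gene_counts(hits, genes, window_bp = 10000L)
  expect_equal(counts$count[counts$gene_id == "g01"], 1L)  # 5 kb upstream
  expect_equal(counts$count[counts$gene_id == "g02"], 3L)  # three in-body hits
  expect_equal(counts$count[counts$gene_id == "g03"], 0L)  # 30 kb away
  counts25 <- hits_to_gene_counts(hits, genes, window_bp = 25000L)
  expect_equal(counts25$count[counts25$gene_id == "g03"], 0L)
})

test_that("count discretizer emits the four nested copy-number columns", {
  counts <- tibble::tibble(gene_id = c("a", "b", "c"), count = c(5L, 2L, 0L))
  ft <- count_threshold_features(counts, prefix = "m")
  expect_equal(unlist(ft[ft$gene_id == "a", -1]), c(m_ge1 = 1L, m_ge2 = 1L,
                                                    m_ge3 = 1L, m_ge4 = 1L))
  expect_equal(unname(unlist(ft[ft$gene_id == "b", -1])), c(1L, 1L, 0L, 0L))
  expect_equal(unname(unlist(ft[ft$gene_id == "c", -1])), c(0L, 0L, 0L, 0L))
  # nesting invariant on random counts
  set.seed(41)
  rand <- tibble::tibble(gene_id = paste0("g", 1:50),
                         count = rpois(50, 2))
  fr <- count_threshold_features(rand)
  m <- as.matrix(fr[-1])
  expect_true(all(m[, 4] <= m[, 3]))
  expect_true(all(m[, 3] <= m[, 2]))
  expect_true(all(m[, 2] <= m[, 1]))
})

test_that("percentile features use strict exceedance of interpolated quantiles", {
  set.seed(42)
  v <- matrix(rnorm(200), 100, 2,
              dimnames = list(paste0("g", 1:100), c("s1", "s2")))
  ft <- percentile_features(v)
  for (s in c("s1", "s2")) {
    for (p in c(75, 90, 99)) {
      cutoff <- quantile(v[, s], p / 100, type = 7, names = FALSE)
      expect_equal(ft[[paste0(s, "_p", p)]], as.integer(v[, s] > cutoff))
    }
  }
  # higher percentiles are nested within lower ones
  expect_true(all(ft$s1_p99 <= ft$s1_p90))
  expect_true(all(ft$s1_p90 <= ft$s1_p75))

  const <- matrix(1, 10, 1, dimnames = list(paste0("g", 1:10), "flat"))
  expect_warning(fc <- percentile_features(const), "constant")
  expect_true(all(fc$flat_p75 == 0))
})
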