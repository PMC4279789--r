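#' Over-representation test of gene-set terms among locus genes
#'
#' One-sided hypergeometric enrichment of each term of a collection in the
#' pooled locus gene list, Benjamini-Hochberg adjusted across the terms of
#' the collection. The log-odds score is the natural log of the sample odds
#' ratio of the 2x2 table (a 0.5 continuity correction is applied to zero
#' cells). Terms passing both `adj_p < adj_p_max` and `log_odds > lod_min`
#' are returned, sorted by adjusted p.
#'
#' @param locus_genes Character vector of genes at trait loci (the query).
#' @param collection Named list of gene sets (term_id -> gene ids), e.g.
#'   from [read_gmt()].
#' @param universe Character vector of all annotated genes.
#' @param adj_p_max Adjusted-p threshold, default 0.05.
#' @param lod_min Log-odds threshold, default 1.
#' @return A tibble with `term_id`, `n_overlap`, `n_term`, `p`, `adj_p`,
#'   `log_odds` and a `member_genes` list column (the term's genes among
#'   `locus_genes`).
#' @export
term_enrichment <- function(locus_genes, collection, universe,
                            adj_p_max = 0.05, lod_min = 1) {
  locus_genes <- unique(locus_genes)
  if (!all(locus_genes %in% universe)) {
    abort("locus_genes must be a subset of the universe")
  }
  if (length(locus_genes) == 0) {
    return(tibble(term_id = character(), n_overlap = integer(),
                  n_term = integer(), p = numeric(), adj_p = numeric(),
                  log_odds = numeric(), member_genes = list()))
  }
  N <- length(universe)
  n_q <- length(locus_genes)
  rows <- purrr::imap(collection, function(set, id) {
    set <- intersect(unique(set), universe)
    if (length(set) == 0) return(NULL)
    ov <- intersect(set, locus_genes)
    a <- length(ov)
    # P(X >= a), X ~ Hypergeom(white = |set|, black = N - |set|, drawn = n_q)
    p <- phyper(a - 1, length(set), N - length(set), n_q, lower.tail = FALSE)
    tibble(
      term_id = id,
      n_overlap = a,
      n_term = length(set),
      p = p,
      log_odds = log(sample_odds_ratio(a, length(set) - a,
                                       n_q - a, N - length(set) - n_q + a)),
      member_genes = list(sort(ov))
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(tibble(term_id = character(), n_overlap = integer(),
                  n_term = integer(), p = numeric(), adj_p = numeric(),
                  log_odds = numeric(), member_genes = list()))
  }
  out$adj_p <- p.adjust(out$p, method = "BH")
  out <- dplyr::filter(out, .data$adj_p < adj_p_max, .data$log_odds > lod_min)
  out <- dplyr::arrange(out, .data$adj_p, .data$term_id)
  dplyr::select(out, "term_id", "n_overlap", "n_term", "p", "adj_p",
                "log_odds", "member_genes")
}

# Sample odds ratio ad/bc with a 0.5 continuity correction when any cell
# is zero.
sample_odds_ratio <- function(a, b, c, d) {
  if (min(a, b, c, d) < 0) abort("negative 2x2 cell")
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Score the genes of mapped loci by prior evidence
#'
#' Each gene at a multi-gene locus collects 5 points for a TSS within
#' `proximity_bp` of the tag SNP and 5 points per membership in each of the
#' OMIM-like, enriched-GO and enriched-mouse-phenotype evidence sets
#' (maximum 20). The sole gene of a single-gene locus is overridden to a
#' total of 1 with all components 0. Scores are converted to per-locus
#' sampling probabilities (total probability 1 per locus; an all-zero locus
#' becomes uniform so it can still contribute a positive example), and
#' genes with `total >= lp_threshold` are flagged likely positives.
#'
#' @param loci Loci tibble from [map_loci()].
#' @param genes Gene annotation tibble (TSS lookup for proximity).
#' @param omim_genes Character vector: genes implicated by the OMIM-like
#'   source for this trait.
#' @param go_genes,mpd_genes Character vectors: genes of enriched GO-like /
#'   mouse-phenotype-like terms (e.g. pooled `member_genes` from
#'   [term_enrichment()]).
#' @param proximity_bp Proximity window in bp, default 50,000.
#' @param weight Points per evidence source, default 5.
#' @param lp_threshold Likely-positive threshold on the total, default 10.
#' @return A tibble with one row per (locus, gene): `locus_id`, `gene_id`,
#'   `proximity_pts`, `omim_pts`, `go_pts`, `mpd_pts`, `total`,
#'   `probability`, `likely_positive`. Empty loci contribute no rows.
#' @export
weigh_loci <- function(loci, genes, omim_genes = character(),
                       go_genes = character(), mpd_genes = character(),
                       proximity_bp = 50000L, weight = 5L,
                       lp_threshold = 10L) {
  tss <- setNames(genes$tss, genes$gene_id)
  rows <- purrr::pmap(
    list(loci$locus_id, loci$tag_pos, loci$member_genes),
    function(locus_id, tag_pos, members) {
      if (length(members) == 0) return(NULL)
      unknown <- setdiff(members, names(tss))
      if (length(unknown) > 0) {
        abort(paste0("locus ", locus_id, " members missing from annotation: ",
                     paste(unknown, collapse = ", ")))
      }
      prox <- unname(abs(tss[members] - tag_pos) <= proximity_bp)
      sc <- tibble(
        locus_id = locus_id,
        gene_id = members,
        proximity_pts = ifelse(prox, weight, 0L),
        omim_pts = ifelse(members %in% omim_genes, weight, 0L),
        go_pts = ifelse(members %in% go_genes, weight, 0L),
        mpd_pts = ifelse(members %in% mpd_genes, weight, 0L)
      )
      sc$total <- sc$proximity_pts + sc$omim_pts + sc$go_pts + sc$mpd_pts
      if (length(members) == 1) {
        sc$proximity_pts <- 0L; sc$omim_pts <- 0L
        sc$go_pts <- 0L; sc$mpd_pts <- 0L
        sc$total <- 1L
      }
      sc
    }
  )
  out <- dplyr::bind_rows(purrr::compact(rows))
  out <- dplyr::group_by(out, .data$locus_id)
  out <- dplyr::mutate(out, probability = to_probabilities(.data$total))
  out <- dplyr::ungroup(out)
  out$likely_positive <- out$total >= lp_threshold
  out
}

#' Convert per-locus scores to sampling probabilities
#'
#' Proportional normalization to a total of 1; an all-zero score vector
#' becomes uniform.
#'
#' @param scores Numeric vector of non-negative scores at one locus.
#' @return Numeric probability vector of the same length, summing to 1.
#' @export
to_probabilities <- function(scores) {
  stopifnot(length(scores) >= 1, all(scores >= 0))
  s <- sum(scores)
  if (s == 0) return(rep(1 / length(scores), length(scores)))
  scores / s
}

#' Likely-positive genes across loci
#'
#' Genes whose prior-evidence total reaches the threshold at any locus
#' (the flag is the max over loci for genes at several loci).
#'
#' @param weighted Weighted-locus tibble from [weigh_loci()].
#' @param threshold Score threshold, default 10.
#' @return Sorted character vector of gene ids.
#' @export
flag_likely_positives <- function(weighted, threshold = 10L) {
  sort(unique(weighted$gene_id[weighted$total >= threshold]))
}

#' Write weighted loci as TSV
#' @param weighted Tibble from [weigh_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weighted_loci <- function(weighted, path) {
  readr::write_tsv(weighted, path)
  invisible(path)
}
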