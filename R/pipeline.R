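#' Map tag SNPs to loci from files
#'
#' Reads the annotation, tag SNPs, LD table and hotspot BED, builds one
#' locus per tag and writes both a BED6+ file and a TSV summary.
#'
#' @param genes_file,tags_file,ld_file,hotspots_file Input paths (see the
#'   corresponding readers).
#' @param out_prefix Output prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @param r2_min,flank_bp,fallback_bp Mapping parameters.
#' @return The loci tibble, invisibly.
#' @export
run_map_loci <- function(genes_file, tags_file, ld_file, hotspots_file,
                         out_prefix, r2_min = 0.5, flank_bp = 250000L,
                         fallback_bp = 50000L) {
  genes <- read_gene_annotation(genes_file)
  tags <- read_tag_snps(tags_file)
  ld <- read_ld_pairs(ld_file)
  hotspots <- read_hotspots(hotspots_file)
  loci <- map_loci(tags, ld, hotspots, genes, r2_min = r2_min,
                   flank_bp = flank_bp, fallback_bp = fallback_bp)
  write_loci_bed(loci, paste0(out_prefix, ".bed"))
  flat <- dplyr::mutate(loci, member_genes = vapply(.data$member_genes,
                                                    paste, "", collapse = ","))
  readr::write_tsv(flat, paste0(out_prefix, ".tsv"))
  inform(paste0("mapped ", nrow(loci), " loci (", sum(loci$empty),
                " empty) covering ", sum(loci$n_genes), " gene assignments"))
  invisible(loci)
}

#' Score all genes for a trait end-to-end from files
#'
#' Full pipeline: locus mapping, evidence weighting (with internal term
#' enrichment for the GO-like and mouse-phenotype-like collections),
#' cross-validated boosting, and an evaluation report. Writes
#' `<prefix>_scores.tsv` and `<prefix>_report.json`.
#'
#' @inheritParams run_map_loci
#' @param omim_file,go_file,mpd_file Evidence GMT paths (the OMIM-like GMT
#'   may hold one or more sets; their union is used directly).
#' @param features_file Feature matrix path (triplet TSV by default).
#' @param features_format Passed to [read_feature_matrix()].
#' @param mode `"gwa"` or `"mendelian"`; mendelian mode reads the positive
#'   gene list from the OMIM-like GMT and skips mapping, weighting and
#'   burn-in.
#' @param seed Integer seed.
#' @param config Optional `lb_config`; by default built from `mode`.
#' @return A list with `scores`, `weighted`, `report`, invisibly.
#' @export
run_prioritize <- function(genes_file, tags_file = NULL, ld_file = NULL,
                           hotspots_file = NULL, omim_file, go_file = NULL,
                           mpd_file = NULL, features_file,
                           features_format = "triplet", out_prefix,
                           mode = c("gwa", "mendelian"), seed = 1L,
                           config = NULL) {
  mode <- match.arg(mode)
  config <- config %||% training_config(mode = mode)
  genes <- read_gene_annotation(genes_file)
  universe <- genes$gene_id
  features <- read_feature_matrix(features_file, format = features_format)
  omim_sets <- read_gmt(omim_file)
  omim_genes <- sort(unique(unlist(omim_sets)))

  if (mode == "gwa") {
    tags <- read_tag_snps(tags_file)
    ld <- read_ld_pairs(ld_file)
    hotspots <- read_hotspots(hotspots_file)
    loci <- map_loci(tags, ld, hotspots, genes)
    locus_genes <- unique(unlist(loci$member_genes))
    enriched_members <- function(path) {
      if (is.null(path)) return(character(0))
      enr <- term_enrichment(locus_genes, read_gmt(path), universe)
      sort(unique(unlist(enr$member_genes)))
    }
    weighted <- weigh_loci(loci, genes, omim_genes = omim_genes,
                           go_genes = enriched_members(go_file),
                           mpd_genes = enriched_members(mpd_file))
  } else {
    inform("mendelian mode: fixed positive gene list, no burn-in phase")
    weighted <- mendelian_weights(intersect(omim_genes, universe))
    weighted$likely_positive <- TRUE
  }
  scores <- cross_validate(weighted, features, universe = universe,
                           config = config, seed = seed)
  labels <- if (mode == "mendelian") unique(weighted$gene_id) else NULL
  report <- evaluate_scores(scores, weighted, labels = labels,
                            seed = seed + 1L)
  write_scores(scores, paste0(out_prefix, "_scores.tsv"))
  jsonlite::write_json(as.list(report), paste0(out_prefix, "_report.json"),
                       auto_unbox = TRUE, digits = NA)
  inform(paste0("scored ", nrow(scores), " genes; AUROC vs likely positives ",
                signif(report$auroc, 3), " (seed ", seed, ", shrinkage ",
                config$shrinkage, ")"))
  invisible(list(scores = scores, weighted = weighted, report = report))
}

#' Scan sequences for motif hits and emit binary features, from files
#'
#' For each motif: scores every window of every sequence on both strands,
#' fits the three-component Gaussian-mixture threshold to the empirical
#' score distribution, keeps hits at or above the threshold, maps hits to
#' genes within `window_bp`, and discretizes the counts into the four
#' nested copy-number features. Writes `<prefix>_hits.bed` and
#' `<prefix>_features.tsv` (sparse triplets).
#'
#' @param fasta_file FASTA of sequences (names must match annotation
#'   chromosomes for gene mapping).
#' @param pwm_file JASPAR-style PFM or MEME minimal file.
#' @param genes_file Gene annotation TSV.
#' @param out_prefix Output prefix.
#' @param window_bp Hit-to-gene window, default 10,000.
#' @param threshold Optional fixed score threshold; when `NULL` (default)
#'   it is fitted per motif by [fit_threshold()], with the mixture
#'   parameters reported.
#' @param seed Integer seed for the mixture fit.
#' @return A list with `hits` and `features` tibbles, invisibly.
#' @export
run_motif_features <- function(fasta_file, pwm_file, genes_file, out_prefix,
                               window_bp = 10000L, threshold = NULL,
                               seed = 1L) {
  seqs <- read_fasta_seqs(fasta_file)
  pwms <- read_pwms(pwm_file)
  genes <- read_gene_annotation(genes_file)
  if (length(seqs) == 0) {
    warn("empty FASTA: no sequences to scan")
  }
  all_hits <- list(); all_feats <- list()
  for (id in names(pwms)) {
    p <- pwm(pwms[[id]], motif_id = id)
    thr <- threshold
    if (is.null(thr)) {
      pool <- unlist(lapply(seqs, function(s) {
        prof <- mms_profile(p, strsplit(s, "")[[1]])
        prof[!is.na(prof)]
      }))
      if (length(unique(pool)) < 9) {
        warn(paste0("motif ", id, ": too few distinct scores to fit a ",
                    "mixture; skipping"))
        next
      }
      mix <- fit_threshold(pool, seed = seed)
      thr <- mix$threshold
      inform(paste0("motif ", id, ": threshold ", signif(thr, 4),
                    " from mixture means ",
                    paste(signif(mix$means, 4), collapse = "/")))
    }
    hits <- scan_pwm(p, seqs, threshold = thr)
    all_hits[[id]] <- hits
    counts <- hits_to_gene_counts(hits, genes, window_bp = window_bp)
    all_feats[[id]] <- count_threshold_features(counts, prefix = id)
  }
  hits <- dplyr::bind_rows(c(list(empty_hits()), all_hits))
  feats <- if (length(all_feats) > 0) {
    purrr::reduce(all_feats, dplyr::left_join, by = "gene_id")
  } else {
    tibble(gene_id = genes$gene_id)
  }
  write_hits_bed(hits, paste0(out_prefix, "_hits.bed"))
  trip <- if (ncol(feats) > 1) features_to_triplets(feats) else {
    tibble(gene_id = character(), feature_id = character(), value = integer())
  }
  readr::write_tsv(trip, paste0(out_prefix, "_features.tsv"))
  invisible(list(hits = hits, features = feats))
}

#' Generate and write the synthetic benchmark, from parameters
#'
#' @param dir Output directory.
#' @param ... Passed to [sim_config()].
#' @return The paths written, invisibly.
#' @export
run_simulate <- function(dir, ...) {
  config <- sim_config(...)
  genome <- make_genome(config)
  trait <- make_trait(genome, config)
  write_trait_files(trait, genome, dir)
}
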