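#' Configuration for the synthetic benchmark generator
#'
#' The defaults define the benchmark scenario used throughout the test
#' suite: one chromosome of 2,000 genes at ~80 kb spacing, 15 well-
#' separated loci of roughly 4-10 genes, 200 binary features of which 10
#' are planted (carried by causal genes at rate `q_causal = 0.8` and by
#' all other genes at `q_background = 0.05`), and prior-evidence
#' annotations covering half of the causal genes per source.
#'
#' @param n_chroms Number of chromosomes.
#' @param n_genes Total genes.
#' @param gene_spacing_bp Mean TSS-to-TSS spacing (jittered uniformly by
#'   +/-50%).
#' @param n_loci Number of trait loci.
#' @param genes_per_locus Intended (min, max) genes per locus; attained
#'   through the interplay of spacing, hotspot placement and the 250 kb
#'   flank rather than enforced exactly.
#' @param n_features,n_planted Feature counts.
#' @param q_causal,q_background Bernoulli rates for planted features on
#'   causal versus all other genes.
#' @param evidence_coverage Fraction of causal genes annotated by each
#'   evidence source.
#' @param seed Integer seed.
#' @return A list of class `lb_simconfig`.
#' @export
sim_config <- function(n_chroms = 1L, n_genes = 2000L,
                       gene_spacing_bp = 80000L, n_loci = 15L,
                       genes_per_locus = c(4L, 10L), n_features = 200L,
                       n_planted = 10L, q_causal = 0.8, q_background = 0.05,
                       evidence_coverage = 0.5, seed = 20141203L) {
  stopifnot(n_planted <= n_features, q_causal >= 0, q_causal <= 1,
            q_background >= 0, q_background <= 1,
            evidence_coverage >= 0, evidence_coverage <= 1,
            n_loci * max(genes_per_locus) <= n_genes)
  structure(list(
    n_chroms = n_chroms, n_genes = n_genes,
    gene_spacing_bp = gene_spacing_bp, n_loci = n_loci,
    genes_per_locus = genes_per_locus, n_features = n_features,
    n_planted = n_planted, q_causal = q_causal,
    q_background = q_background, evidence_coverage = evidence_coverage,
    seed = seed
  ), class = "lb_simconfig")
}

#' Generate a synthetic gene annotation
#'
#' Genes are laid head-to-tail along each chromosome with uniformly
#' jittered spacing; gene bodies (2-20 kb) never overlap because the
#' minimum spacing exceeds twice the maximum body length. Strands are
#' random and the TSS respects them.
#'
#' @param config `lb_simconfig` from [sim_config()].
#' @param seed Integer seed (default: the config's seed).
#' @return A gene annotation tibble (see [read_gene_annotation()]).
#' @export
make_genome <- function(config = sim_config(), seed = config$seed) {
  with_seed(seed, {
    per_chrom <- diff(round(seq(0, config$n_genes,
                                length.out = config$n_chroms + 1)))
    rows <- purrr::imap(per_chrom, function(ng, ci) {
      spacing <- round(config$gene_spacing_bp *
                         runif(ng, 0.5, 1.5))
      tss <- cumsum(spacing)
      len <- round(runif(ng, 2000, 20000))
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      tibble(
        chrom = paste0("chr", ci),
        tss = as.integer(tss),
        tx_start = as.integer(ifelse(strand == "+", tss, tss - len + 1)),
        tx_end = as.integer(ifelse(strand == "+", tss + len, tss + 1)),
        strand = strand
      )
    })
    genes <- dplyr::bind_rows(rows)
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    validate_gene_annotation(
      dplyr::select(genes, "gene_id", "chrom", "tx_start", "tx_end",
                    "strand", "tss")
    )
  })
}

#' Generate a synthetic trait with planted causal structure
#'
#' Picks `n_loci` well-separated causal genes; places a tag SNP within
#' 30 kb of each causal TSS (so the causal gene always earns the proximity
#' points); generates in-block LD partners (r-squared uniform on
#' `[0.55, 1]`) and decoy partners (`[0, 0.45]`), flanking recombination
#' hotspots 5-20 kb outside the block, and evidence gene sets covering
#' `evidence_coverage` of the causal genes per source; and draws the
#' binary feature matrix with the planted-feature Bernoulli rates. The
#' intended locus membership recorded in the truth is computed from the
#' same inclusion rules the mapper implements (TSS in the hotspot+flank
#' interval, or tag SNP inside the gene body), coded independently here.
#'
#' @param genome Gene annotation tibble from [make_genome()].
#' @param config `lb_simconfig`.
#' @param seed Integer seed (default: the config's seed plus one, so the
#'   genome and trait draws differ).
#' @return A list of class `lb_trait`: `tags`, `ld`, `hotspots`,
#'   `omim_genes`, `go_sets`, `mpd_sets`, `features` (0/1 matrix),
#'   `truth` (list with `loci` tibble, `causal_genes`,
#'   `planted_features`, `q_causal`, `q_background`, `seed`), `config`.
#' @export
make_trait <- function(genome, config = sim_config(),
                       seed = config$seed + 1L) {
  with_seed(seed, {
    flank <- 250000L
    min_sep <- 1500000L
    causal <- pick_separated_genes(genome, config$n_loci, min_sep)
    if (length(causal) < config$n_loci) {
      abort("infeasible packing: cannot place that many separated loci")
    }
    tag_list <- list(); ld_list <- list(); hs_list <- list()
    truth_rows <- list()
    for (i in seq_along(causal)) {
      g <- genome[genome$gene_id == causal[i], ]
      rsid <- sprintf("rs%05d", i)
      tag_pos <- max(0L, g$tss + as.integer(round(runif(1, -30000, 30000))))
      n_in <- sample(2:4, 1)
      in_off <- as.integer(round(runif(n_in, -40000, 40000)))
      n_out <- sample(1:3, 1)
      out_off <- as.integer(round(runif(n_out, 60000, 200000))) *
        sample(c(-1L, 1L), n_out, replace = TRUE)
      ld_list[[i]] <- tibble(
        rsid_a = rsid,
        rsid_b = sprintf("%s_p%02d", rsid, seq_len(n_in + n_out)),
        pos_b = pmax(0L, tag_pos + c(in_off, out_off)),
        r2 = c(runif(n_in, 0.55, 1), runif(n_out, 0, 0.45)),
        chrom_b = g$chrom
      )
      block_lo <- min(tag_pos, tag_pos + in_off)
      block_hi <- max(tag_pos, tag_pos + in_off) + 1L
      hot_lo <- max(0L, block_lo - as.integer(round(runif(1, 5000, 20000))))
      hot_hi <- block_hi + as.integer(round(runif(1, 5000, 20000)))
      hs_list[[i]] <- tibble(chrom = g$chrom, pos = c(hot_lo, hot_hi))
      iv_lo <- max(0L, hot_lo - flank)
      iv_hi <- hot_hi + flank
      on_chrom <- genome[genome$chrom == g$chrom, ]
      member <- (on_chrom$tss >= iv_lo & on_chrom$tss < iv_hi) |
        (on_chrom$tx_start <= tag_pos & tag_pos < on_chrom$tx_end)
      members <- on_chrom$gene_id[member]
      members <- members[order(on_chrom$tss[member], members)]
      tag_list[[i]] <- tibble(rsid = rsid, chrom = g$chrom, pos = tag_pos,
                              trait = "synthetic_trait")
      truth_rows[[i]] <- tibble(
        tag_rsid = rsid, causal_gene = causal[i],
        member_genes = list(members), n_genes = length(members)
      )
    }
    tags <- dplyr::bind_rows(tag_list)
    truth_loci <- dplyr::bind_rows(truth_rows)

    feature_ids <- sprintf("feat_%03d", seq_len(config$n_features))
    planted <- sort(sample(feature_ids, config$n_planted))
    m <- matrix(
      rbinom(nrow(genome) * config$n_features, 1, config$q_background),
      nrow(genome), config$n_features,
      dimnames = list(genome$gene_id, feature_ids)
    )
    m[causal, planted] <- rbinom(length(causal) * length(planted), 1,
                                 config$q_causal)
    storage.mode(m) <- "integer"

    locus_genes <- unique(unlist(truth_loci$member_genes))
    decoy_pool <- setdiff(genome$gene_id, locus_genes)
    n_cov <- round(config$evidence_coverage * length(causal))
    evidence_set <- function() {
      sort(c(sample(causal, n_cov), sample(decoy_pool, 40)))
    }
    omim_genes <- evidence_set()
    make_collection <- function(prefix) {
      sets <- list(evidence_set())
      names(sets) <- paste0(prefix, "_term_1")
      for (d in 2:4) {
        sets[[paste0(prefix, "_term_", d)]] <- sort(sample(decoy_pool, 30))
      }
      sets
    }
    go_sets <- make_collection("go")
    mpd_sets <- make_collection("mpd")

    structure(list(
      tags = tags,
      ld = dplyr::bind_rows(ld_list),
      hotspots = dplyr::arrange(dplyr::bind_rows(hs_list), .data$chrom,
                                .data$pos),
      omim_genes = omim_genes,
      go_sets = go_sets,
      mpd_sets = mpd_sets,
      features = m,
      truth = list(
        loci = truth_loci,
        causal_genes = causal,
        planted_features = planted,
        q_causal = config$q_causal,
        q_background = config$q_background,
        seed = seed
      ),
      config = config
    ), class = "lb_trait")
  })
}

# Greedily pick n genes pairwise separated by >= min_sep bp (same
# chromosome); genes on different chromosomes never conflict.
pick_separated_genes <- function(genome, n, min_sep) {
  avail <- genome
  chosen <- character(0)
  while (length(chosen) < n && nrow(avail) > 0) {
    i <- sample.int(nrow(avail), 1)
    g <- avail[i, ]
    chosen <- c(chosen, g$gene_id)
    keep <- avail$chrom != g$chrom | abs(avail$tss - g$tss) >= min_sep
    avail <- avail[keep, ]
  }
  sort(chosen)
}

#' Write all files of a synthetic trait to a directory
#'
#' Emits the exact dialects the readers consume: gene annotation TSV, tag
#' SNP TSV, PLINK-style LD table, hotspot BED3, evidence GMTs, sparse
#' feature triplets and a truth JSON.
#'
#' @param trait `lb_trait` from [make_trait()].
#' @param genome The gene annotation tibble it was generated from.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_trait_files <- function(trait, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, "genes.tsv"),
    tags = file.path(dir, "tags.tsv"),
    ld = file.path(dir, "ld.tsv"),
    hotspots = file.path(dir, "hotspots.bed"),
    omim = file.path(dir, "omim.gmt"),
    go = file.path(dir, "go.gmt"),
    mpd = file.path(dir, "mpd.gmt"),
    features = file.path(dir, "features.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(genome, paths["genes"])
  readr::write_tsv(trait$tags, paths["tags"])
  ld <- trait$ld
  readr::write_delim(
    tibble(SNP_A = ld$rsid_a, SNP_B = ld$rsid_b, CHR_B = ld$chrom_b,
           BP_B = ld$pos_b, R2 = ld$r2),
    paths["ld"], delim = " "
  )
  readr::write_tsv(
    tibble(chrom = trait$hotspots$chrom, start = trait$hotspots$pos,
           end = trait$hotspots$pos + 1L),
    paths["hotspots"], col_names = FALSE
  )
  write_gmt(list(omim_trait = trait$omim_genes), paths["omim"])
  write_gmt(trait$go_sets, paths["go"])
  write_gmt(trait$mpd_sets, paths["mpd"])
  write_feature_triplets(trait$features, paths["features"])
  jsonlite::write_json(
    list(
      causal = setNames(as.list(trait$truth$loci$causal_gene),
                        trait$truth$loci$tag_rsid),
      planted_features = trait$truth$planted_features,
      q_causal = trait$truth$q_causal,
      q_background = trait$truth$q_background,
      seed = trait$truth$seed
    ),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
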