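# Shared in-code fixtures. Everything is built at test time; nothing is
# read from disk except through the package's own writers.

# A hand-laid annotation on one chromosome: TSS at regular 100 kb steps.
tiny_genes <- function(n = 10, chrom = "chr1", spacing = 100000L) {
  tss <- spacing * seq_len(n)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = chrom,
    tx_start = tss,
    tx_end = tss + 10000L,
    strand = "+",
    tss = tss
  )
}

tag_at <- function(pos, rsid = "rs1", chrom = "chr1", trait = "t") {
  tibble::tibble(rsid = rsid, chrom = chrom, pos = as.integer(pos),
                 trait = trait)
}

ld_partners <- function(rsid, pos_b, r2, chrom = "chr1") {
  tibble::tibble(rsid_a = rsid, rsid_b = paste0(rsid, "_p", seq_along(pos_b)),
                 pos_b = as.integer(pos_b), r2 = r2, chrom_b = chrom)
}

# A small planted-signal scenario that keeps unit tests fast; the default
# sim_config() scenario is reserved for the acceptance suite.
small_scenario <- function(seed = 42L) {
  cfg <- sim_config(n_genes = 600L, n_loci = 8L, n_features = 60L,
                    n_planted = 8L, seed = seed)
  genome <- make_genome(cfg)
  trait <- make_trait(genome, cfg)
  list(cfg = cfg, genome = genome, trait = trait)
}

fast_config <- function(mode = "gwa") {
  training_config(mode = mode, n_rounds = 1L, n_folds = 4L,
                  n_main_trees = 10L, n_burnin_trees = 5L)
}

# Weighted loci + negatives pool for a scenario, mirroring the pipeline.
weighted_from_scenario <- function(sc) {
  loci <- map_loci(sc$trait$tags, sc$trait$ld, sc$trait$hotspots, sc$genome)
  w <- weigh_loci(loci, sc$genome, omim_genes = sc$trait$omim_genes)
  pool <- setdiff(sc$genome$gene_id, unique(w$gene_id))
  list(loci = loci, weighted = w, pool = pool)
}
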