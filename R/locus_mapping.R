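#' Delimit the LD block around a tag SNP
#'
#' The block is the minimal interval covering the tag position and every
#' partner SNP with `r2 >= r2_min` (the boundary is inclusive). With no
#' qualifying partner the block degenerates to the single base at the tag.
#'
#' @param tag One-row tibble (or list) with `rsid`, `chrom`, `pos`.
#' @param ld LD tibble (`rsid_a`, `rsid_b`, `pos_b`, `r2`, optional
#'   `chrom_b`); rows are used when either side names the tag rsid.
#' @param r2_min Inclusive squared-correlation threshold, default 0.5.
#' @return A list with `start`, `end` (0-based, half-open).
#' @export
ld_block <- function(tag, ld, r2_min = 0.5) {
  stopifnot(r2_min > 0, r2_min <= 1)
  partners <- dplyr::filter(ld, .data$rsid_a == tag$rsid)
  if ("chrom_b" %in% names(partners) && nrow(partners) > 0) {
    off <- partners$chrom_b != tag$chrom
    if (any(off)) {
      abort(paste0("LD partner(s) of ", tag$rsid, " on a different chromosome: ",
                   paste(partners$rsid_b[off], collapse = ", ")))
    }
  }
  partners <- dplyr::filter(partners, .data$r2 >= r2_min)
  pos <- c(tag$pos, partners$pos_b)
  list(start = min(pos), end = max(pos) + 1L)
}

#' Extend an interval to the flanking recombination hotspots
#'
#' The start moves left to the nearest hotspot at or before it, the end
#' right to the nearest hotspot at or beyond it. Hotspots strictly inside
#' the interval are ignored; with no flanking hotspot an end is unchanged.
#'
#' @param interval List with `start`, `end`.
#' @param hotspots Sorted ascending hotspot positions on the interval's
#'   chromosome (may be empty).
#' @return The extended interval.
#' @export
extend_to_hotspots <- function(interval, hotspots) {
  hotspots <- sort(hotspots)
  left <- hotspots[hotspots <= interval$start]
  right <- hotspots[hotspots >= interval$end]
  list(
    start = if (length(left) > 0) max(left) else interval$start,
    end = if (length(right) > 0) min(right) else interval$end
  )
}

#' Add a fixed flank to both sides of an interval
#'
#' @param interval List with `start`, `end`.
#' @param flank_bp Flank length in bp (default 250,000).
#' @param chrom_len Chromosome length for right clipping (default `Inf`).
#' @return The flanked interval, clipped to `[0, chrom_len)`.
#' @export
extend_flank <- function(interval, flank_bp = 250000L, chrom_len = Inf) {
  stopifnot(flank_bp >= 0)
  list(
    start = max(0L, interval$start - flank_bp),
    end = min(chrom_len, interval$end + flank_bp)
  )
}

#' Assign candidate genes to a locus interval
#'
#' A gene is a member when its TSS falls inside the interval, or when the
#' tag SNP lies inside the gene body `[tx_start, tx_end)`. If no gene
#' qualifies the interval is widened once by `fallback_bp` on each side and
#' the search repeated; a locus still empty after that is kept but flagged.
#' Members are ordered by ascending TSS, ties by gene id.
#'
#' @param interval List with `start`, `end`.
#' @param tag One-row tibble/list with `rsid`, `chrom`, `pos`.
#' @param genes Gene annotation tibble (see [read_gene_annotation()]).
#' @param fallback_bp Fallback widening in bp, default 50,000.
#' @return A one-row tibble: `tag_rsid`, `chrom`, `start`, `end`,
#'   `member_genes` (list column), `n_genes`, `empty`.
#' @export
assign_genes <- function(interval, tag, genes, fallback_bp = 50000L) {
  genes <- dplyr::filter(genes, .data$chrom == tag$chrom)
  members_in <- function(iv) {
    hit <- (genes$tss >= iv$start & genes$tss < iv$end) |
      (genes$tx_start <= tag$pos & tag$pos < genes$tx_end)
    g <- genes[hit, ]
    g <- g[order(g$tss, g$gene_id), ]
    g$gene_id
  }
  ids <- members_in(interval)
  if (length(ids) == 0) {
    ids <- members_in(list(start = max(0L, interval$start - fallback_bp),
                           end = interval$end + fallback_bp))
  }
  tibble(
    tag_rsid = tag$rsid,
    chrom = tag$chrom,
    start = interval$start,
    end = interval$end,
    member_genes = list(ids),
    n_genes = length(ids),
    empty = length(ids) == 0
  )
}

#' Build the locus for one tag SNP
#'
#' Composition of [ld_block()], [extend_to_hotspots()], [extend_flank()]
#' and [assign_genes()]; purely deterministic.
#'
#' @inheritParams ld_block
#' @inheritParams assign_genes
#' @param hotspots Hotspot tibble (`chrom`, `pos`) or a bare position
#'   vector on the tag's chromosome.
#' @param r2_min,flank_bp,fallback_bp Mapping parameters (defaults 0.5,
#'   250,000 and 50,000).
#' @param chrom_len Optional chromosome length for clipping.
#' @return A one-row locus tibble (see [assign_genes()]).
#' @export
build_locus <- function(tag, ld, hotspots, genes, r2_min = 0.5,
                        flank_bp = 250000L, fallback_bp = 50000L,
                        chrom_len = Inf) {
  if (is.data.frame(hotspots)) {
    hotspots <- hotspots$pos[hotspots$chrom == tag$chrom]
  }
  iv <- ld_block(tag, ld, r2_min = r2_min)
  iv <- extend_to_hotspots(iv, hotspots)
  iv <- extend_flank(iv, flank_bp = flank_bp, chrom_len = chrom_len)
  assign_genes(iv, tag, genes, fallback_bp = fallback_bp)
}

#' Map every tag SNP of a table to its locus
#'
#' Data-frame-first wrapper over [build_locus()]; one output row per tag
#' SNP. Overlapping loci are kept distinct (no merging), so a gene may be a
#' member of several loci.
#'
#' @param tags Tag SNP tibble (`rsid`, `chrom`, `pos`, `trait`).
#' @param ld LD tibble.
#' @param hotspots Hotspot tibble (`chrom`, `pos`).
#' @param genes Gene annotation tibble.
#' @inheritParams build_locus
#' @return A tibble with one row per tag: `locus_id`, `trait`, `tag_rsid`,
#'   `tag_pos`, `chrom`, `start`, `end`, `member_genes` (list column),
#'   `n_genes`, `empty`.
#' @export
map_loci <- function(tags, ld, hotspots, genes, r2_min = 0.5,
                     flank_bp = 250000L, fallback_bp = 50000L,
                     chrom_len = Inf) {
  rows <- purrr::pmap(
    list(seq_len(nrow(tags)), split(tags, seq_len(nrow(tags)))),
    function(i, tag) {
      loc <- build_locus(tag, ld, hotspots, genes, r2_min = r2_min,
                         flank_bp = flank_bp, fallback_bp = fallback_bp,
                         chrom_len = chrom_len)
      loc$locus_id <- paste0("locus_", sprintf("%03d", i))
      loc$trait <- tag$trait %||% NA_character_
      loc$tag_pos <- tag$pos
      loc
    }
  )
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "locus_id", "trait", "tag_rsid", "tag_pos", "chrom",
                "start", "end", "member_genes", "n_genes", "empty")
}
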