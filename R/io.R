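#' Read a gene annotation table
#'
#' Accepts either the native 6-column TSV (`gene_id`, `chrom`, `tx_start`,
#' `tx_end`, `strand`, `tss`) or BED6 (`chrom`, `start`, `end`, `name`,
#' `score`, `strand`), in which case the TSS is derived from strand:
#' `tx_start` on `+`, `tx_end - 1` on `-`. All coordinates are 0-based,
#' half-open, BED-style.
#'
#' @param path Path to a TSV/BED file.
#' @param format `"tsv"` (native, with header) or `"bed"` (BED6, headerless).
#' @return A tibble with columns `gene_id`, `chrom`, `tx_start`, `tx_end`,
#'   `strand`, `tss`.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    x <- readr::read_tsv(path,
      col_names = c("chrom", "tx_start", "tx_end", "gene_id", "score", "strand"),
      col_types = "ciicdc", progress = FALSE
    )
    x <- dplyr::mutate(x,
      tss = ifelse(.data$strand == "+", .data$tx_start, .data$tx_end - 1L)
    )
    x <- dplyr::select(x, "gene_id", "chrom", "tx_start", "tx_end", "strand", "tss")
  } else {
    x <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = "c", chrom = "c", tx_start = "i", tx_end = "i",
      strand = "c", tss = "i"
    ), progress = FALSE)
  }
  validate_gene_annotation(x)
}

validate_gene_annotation <- function(genes) {
  genes <- as_tibble(genes)
  req <- c("gene_id", "chrom", "tx_start", "tx_end", "strand", "tss")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("gene annotation lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("gene annotation has duplicated gene_id values")
  }
  bad <- genes$tx_start >= genes$tx_end
  if (any(bad)) {
    abort(paste0("tx_start >= tx_end for: ", paste(genes$gene_id[bad], collapse = ", ")))
  }
  bad <- genes$tss < genes$tx_start | genes$tss >= genes$tx_end
  if (any(bad)) {
    abort(paste0("tss outside [tx_start, tx_end) for: ",
                 paste(genes$gene_id[bad], collapse = ", ")))
  }
  genes
}

#' Read tag SNPs
#'
#' TSV with header columns `rsid`, `chrom`, `pos`, `trait` and optionally
#' `assoc_p`. Positions are 0-based.
#'
#' @param path Path to the TSV file.
#' @return A tibble of tag SNPs.
#' @export
read_tag_snps <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    rsid = "c", chrom = "c", pos = "i", trait = "c", .default = "d"
  ), progress = FALSE)
  dup <- dplyr::count(x, .data$trait, .data$rsid) |> dplyr::filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated rsid within trait: ",
                 paste(dup$rsid, collapse = ", ")))
  }
  x
}

#' Read a pairwise LD table
#'
#' Whitespace-delimited with header; the PLINK `.ld` dialect
#' (`CHR_A BP_A SNP_A CHR_B BP_B SNP_B R2`) is accepted, as is the minimal
#' four-column form (`SNP_A SNP_B BP_B R2`).
#'
#' @param path Path to the LD table.
#' @return A tibble with columns `rsid_a`, `rsid_b`, `pos_b`, `r2` (plus
#'   `chrom_b` when the input carries it).
#' @export
read_ld_pairs <- function(path) {
  x <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  nm <- toupper(names(x))
  pick <- function(candidates) {
    hit <- match(candidates, nm)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  ia <- pick("SNP_A"); ib <- pick("SNP_B"); ip <- pick("BP_B"); ir <- pick("R2")
  if (any(is.na(c(ia, ib, ip, ir)))) {
    abort(paste0("LD table must have columns SNP_A, SNP_B, BP_B, R2; got: ",
                 paste(names(x), collapse = ", ")))
  }
  out <- tibble(
    rsid_a = x[[ia]],
    rsid_b = x[[ib]],
    pos_b = as.integer(x[[ip]]),
    r2 = as.numeric(x[[ir]])
  )
  ic <- pick("CHR_B")
  if (!is.na(ic)) out$chrom_b <- x[[ic]]
  if (any(out$r2 < 0 | out$r2 > 1, na.rm = TRUE)) {
    abort("LD r2 values must lie in [0, 1]")
  }
  out
}

#' Read recombination hotspots (BED3)
#'
#' Each row contributes one hotspot position: the interval start coordinate.
#'
#' @param path Path to a headerless BED3 file.
#' @return A tibble with columns `chrom`, `pos`.
#' @export
read_hotspots <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                       col_types = "cii", progress = FALSE)
  tibble(chrom = x$chrom, pos = x$start) |> dplyr::arrange(.data$chrom, .data$pos)
}

#' Read gene sets in GMT format
#'
#' One set per line: `term_id TAB description TAB gene1 TAB gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (term_id -> gene ids), with the
#'   descriptions in a `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) {
    abort(paste0("GMT line(s) with fewer than 3 fields: line ",
                 paste(which(short), collapse = ", ")))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2), names(sets))
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to term ids).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a binary gene-by-feature matrix
#'
#' Three dialects: dense TSV (first column `gene_id`, one column per feature),
#' sparse triplet TSV (`gene_id`, `feature_id`, `value`, with header), or
#' MatrixMarket (`.mtx`) with sidecar `<path>.genes` / `<path>.features`
#' id lists (one id per line).
#'
#' @param path Path to the matrix file.
#' @param format One of `"dense"`, `"triplet"`, `"mtx"`; guessed from the
#'   extension by default.
#' @return A base 0/1 integer matrix with gene ids as rownames and feature
#'   ids as colnames.
#' @export
read_feature_matrix <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  }
  format <- match.arg(format, c("dense", "triplet", "mtx"))
  if (format == "mtx") {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      abort("reading MTX requires the Matrix package")
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readr::read_lines(paste0(path, ".genes"), progress = FALSE)
    colnames(m) <- readr::read_lines(paste0(path, ".features"), progress = FALSE)
    storage.mode(m) <- "integer"
    return(validate_feature_matrix(m))
  }
  if (format == "triplet") {
    x <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = "c", feature_id = "c", value = "i"
    ), progress = FALSE)
    return(feature_matrix_from_triplets(x))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "i"
  ), progress = FALSE)
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "integer"
  validate_feature_matrix(m)
}

#' Build a feature matrix from sparse triplets
#'
#' @param triplets Tibble with `gene_id`, `feature_id` and optionally `value`
#'   (defaults to 1); absent (gene, feature) pairs are 0.
#' @param gene_ids,feature_ids Optional full id universes fixing row/column
#'   order; ids absent from `triplets` become all-zero rows/columns.
#' @return A 0/1 integer matrix (genes x features).
#' @export
feature_matrix_from_triplets <- function(triplets, gene_ids = NULL,
                                         feature_ids = NULL) {
  triplets <- as_tibble(triplets)
  if (!"value" %in% names(triplets)) triplets$value <- 1L
  gene_ids <- gene_ids %||% sort(unique(triplets$gene_id))
  feature_ids <- feature_ids %||% sort(unique(triplets$feature_id))
  m <- matrix(0L, length(gene_ids), length(feature_ids),
              dimnames = list(gene_ids, feature_ids))
  keep <- triplets$gene_id %in% gene_ids & triplets$feature_id %in% feature_ids
  triplets <- triplets[keep, ]
  m[cbind(triplets$gene_id, triplets$feature_id)] <- as.integer(triplets$value)
  validate_feature_matrix(m)
}

validate_feature_matrix <- function(m) {
  if (!all(m %in% c(0L, 1L))) abort("feature matrix entries must be 0/1")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("feature matrix row/column ids must be unique")
  }
  m
}

#' Write a feature matrix as sparse triplets
#' @param m 0/1 matrix with dimnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_triplets <- function(m, path) {
  idx <- which(m != 0L, arr.ind = TRUE)
  out <- tibble(
    gene_id = rownames(m)[idx[, 1]],
    feature_id = colnames(m)[idx[, 2]],
    value = 1L
  ) |> dplyr::arrange(.data$gene_id, .data$feature_id)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write loci as BED6+
#'
#' Columns: chrom, start, end, tag rsid, number of member genes, `.`,
#' comma-joined member gene ids.
#'
#' @param loci Loci tibble from [map_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  out <- tibble(
    chrom = loci$chrom,
    start = loci$start,
    end = loci$end,
    name = loci$tag_rsid,
    score = loci$n_genes,
    strand = ".",
    genes = vapply(loci$member_genes, paste, "", collapse = ",")
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read DNA sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Read position frequency matrices
#'
#' JASPAR-style PFM text: a `>motif_id` header line followed by four rows
#' (A, C, G, T), either bare counts or `A [ 1 2 3 ]` bracketed rows. MEME
#' minimal format (`MOTIF` blocks with a letter-probability matrix) is also
#' accepted.
#'
#' @param path Path to the PFM/MEME file.
#' @param format `"jaspar"` or `"meme"`; guessed from content by default.
#' @return A named list of 4 x L column-normalized frequency matrices with
#'   rownames A, C, G, T.
#' @export
read_pwms <- function(path, format = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(format)) {
    format <- if (any(grepl("^MEME version", lines))) "meme" else "jaspar"
  }
  format <- match.arg(format, c("jaspar", "meme"))
  if (format == "meme") return(read_pwms_meme(lines))
  read_pwms_jaspar(lines)
}

read_pwms_jaspar <- function(lines) {
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort("no '>' motif headers found in PFM file")
  pwms <- list()
  for (k in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[k]])
    id <- strsplit(id, "\\s+")[[1]][1]
    end <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    body <- lines[(starts[k] + 1):end]
    if (length(body) != 4) {
      abort(paste0("motif ", id, ": expected 4 base rows, got ", length(body)))
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(vals)) abort(paste0("motif ", id, ": malformed count row"))
      vals
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(paste0("motif ", id, ": ragged count rows"))
    }
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    cs <- colSums(m)
    if (any(cs <= 0)) abort(paste0("motif ", id, ": zero column sum"))
    pwms[[id]] <- sweep(m, 2, cs, "/")
  }
  pwms
}

read_pwms_meme <- function(lines) {
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) abort("no MOTIF blocks found in MEME file")
  pwms <- list()
  for (k in seq_along(starts)) {
    id <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > starts[k]][1]
    if (is.na(hdr)) abort(paste0("motif ", id, ": no letter-probability matrix"))
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    body <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(body, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    m <- t(m)  # 4 x L
    rownames(m) <- c("A", "C", "G", "T")
    pwms[[id]] <- sweep(m, 2, colSums(m), "/")
  }
  pwms
}

#' Write motif hits as BED6+
#'
#' Score column carries the match score scaled by 100 and clamped to
#' 0-1000; the raw score is kept in a 7th column.
#'
#' @param hits Hits tibble from [scan_pwm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  out <- tibble(
    chrom = hits$seq_id,
    start = hits$pos,
    end = hits$pos + hits$width,
    name = hits$motif_id,
    score = pmin(pmax(round(hits$mms * 100), 0), 1000),
    strand = hits$strand,
    mms = hits$mms
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Serialize a boosted model to JSON
#'
#' Versioned JSON carrying the initial constant, shrinkage and the tree
#' array (node records with split feature ids and leaf values).
#'
#' @param model A `lb_boost` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "lb_boost"))
  payload <- list(
    format = "locusboost-model",
    version = 1L,
    f0 = model$f0,
    shrinkage = model$shrinkage,
    trees = lapply(model$trees, function(tr) {
      list(nodes = tr$nodes)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a boosted model from JSON
#' @param path Path written by [write_model_json()].
#' @return A `lb_boost` object.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "locusboost-model")) {
    abort("not a locusboost model JSON file")
  }
  trees <- lapply(x$trees, function(tr) {
    nodes <- dplyr::bind_rows(lapply(tr$nodes, function(nd) {
      tibble(
        id = as.integer(nd$id),
        is_leaf = isTRUE(nd$is_leaf),
        feature = if (is.null(nd$feature)) NA_character_ else nd$feature,
        left = if (is.null(nd$left)) NA_integer_ else as.integer(nd$left),
        right = if (is.null(nd$right)) NA_integer_ else as.integer(nd$right),
        value = if (is.null(nd$value)) NA_real_ else as.numeric(nd$value)
      )
    }))
    new_lad_tree(nodes)
  })
  new_lb_boost(f0 = as.numeric(x$f0), shrinkage = as.numeric(x$shrinkage),
               trees = trees)
}
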