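#' Construct a gene-model tibble from per-exon records
#'
#' The package represents a set of single-isoform gene models as a nested
#' tibble: one row per gene with an `exons` list-column of `(start, end)`
#' tibbles (0-based half-open, sorted, non-overlapping), a `junctions`
#' list-column of the junctions joining adjacent exons, and derived columns
#' `n_exons`, `footprint_nt` (summed exonic length), `read_count` and `rpke`.
#'
#' @param exons Long tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand`.
#' @param junctions Optional long tibble with columns `gene_id`, `chrom`,
#'   `donor_end`, `acceptor_start`, `support`.
#' @param read_count,rpke Optional named vectors (names = gene_id) of read
#'   counts and RPKE values; missing entries become `NA`.
#' @return A gene-model tibble.
#' @examples
#' ex <- tibble::tibble(gene_id = "g1", chrom = "chr1",
#'                      start = c(0L, 200L), end = c(100L, 300L))
#' gene_models(ex)
#' @export
gene_models <- function(exons, junctions = NULL, read_count = NULL, rpke = NULL) {
  exons <- as_tibble(exons)
  if (nrow(exons) == 0) {
    return(empty_gene_models())
  }
  if (!"strand" %in% names(exons)) exons$strand <- "."
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start)) {
    abort("exons must satisfy end > start", class = "txtile_input_error")
  }
  exons <- dplyr::arrange(exons, .data$gene_id, .data$start)
  nested <- exons |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(
      exons = list(tibble(start = start, end = end)),
      .groups = "drop"
    )
  if (anyDuplicated(nested$gene_id)) {
    abort("a gene_id maps to more than one chromosome or strand",
          class = "txtile_input_error")
  }
  jl <- rep(list(tibble(chrom = character(), donor_end = integer(),
                        acceptor_start = integer(), support = integer())),
            nrow(nested))
  if (!is.null(junctions) && nrow(junctions) > 0) {
    jn <- split(as_tibble(junctions), junctions$gene_id)
    hit <- match(nested$gene_id, names(jn))
    for (i in which(!is.na(hit))) {
      j <- jn[[hit[i]]]
      jl[[i]] <- tibble(chrom = j$chrom, donor_end = j$donor_end,
                        acceptor_start = j$acceptor_start,
                        support = j$support)
    }
  }
  genes <- nested |>
    dplyr::mutate(
      junctions = jl,
      n_exons = map_int(.data$exons, nrow),
      footprint_nt = map_int(.data$exons, ~ sum(.x$end - .x$start)),
      read_count = if (is.null(read_count)) NA_integer_ else
        as.integer(unname(read_count[.data$gene_id])),
      rpke = if (is.null(rpke)) NA_real_ else as.numeric(unname(rpke[.data$gene_id]))
    ) |>
    dplyr::mutate(span_start = map_int(.data$exons, ~ min(.x$start)),
                  span_end = map_int(.data$exons, ~ max(.x$end))) |>
    dplyr::arrange(.data$chrom, .data$span_start, .data$gene_id)
  bad <- map_lgl(genes$exons, function(e) {
    nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])
  })
  if (any(bad)) {
    abort("exons of a gene must be non-overlapping", class = "txtile_input_error")
  }
  genes
}

empty_gene_models <- function() {
  tibble(
    gene_id = character(), chrom = character(), strand = character(),
    exons = list(), junctions = list(), n_exons = integer(),
    footprint_nt = integer(), read_count = integer(), rpke = numeric(),
    span_start = integer(), span_end = integer()
  )
}

# Long (one row per exon) view of a gene-model tibble.
unnest_exons <- function(genes) {
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer()))
  }
  genes |>
    dplyr::select("gene_id", "chrom", "strand", "exons") |>
    tidyr::unnest("exons")
}

#' Read aligned read blocks from a SAM/BAM file
#'
#' Each aligned record contributes one block per contiguous match on the
#' reference; `N` gaps (introns) split a spliced read into multiple blocks.
#' Unmapped, secondary and supplementary records are skipped; paired mates are
#' distinguished by a `/1` / `/2` suffix on the read id. All coordinates are
#' returned 0-based half-open.
#'
#' @param path Path to a SAM or BAM file (SAM is converted on the fly and must
#'   carry `@SQ` header lines).
#' @param min_mapq Minimum mapping quality; records below it are skipped.
#' @return Tibble of read blocks (`chrom`, `start`, `end`, `read_id`).
#' @seealso [junctions_from_blocks()] to derive junction evidence when no
#'   junction file is available.
#' @export
read_alignments <- function(path, min_mapq = 0) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path), class = "txtile_input_error")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flg <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flg, what = c("qname", "flag", "rname", "pos", "mapq", "cigar")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$pos) & (is.na(rec$mapq) | rec$mapq >= min_mapq)
  if (!any(keep)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  read_id = character()))
  }
  qname <- rec$qname[keep]
  flag <- rec$flag[keep]
  mate <- dplyr::case_when(
    bitwAnd(flag, 64L) > 0L ~ "/1",
    bitwAnd(flag, 128L) > 0L ~ "/2",
    TRUE ~ ""
  )
  read_id <- paste0(qname, mate)
  rngs <- GenomicAlignments::extractAlignmentRangesOnReference(
    rec$cigar[keep], pos = rec$pos[keep], drop.D.ranges = FALSE
  )
  nb <- S4Vectors::elementNROWS(rngs)
  flat <- unlist(rngs, use.names = FALSE)
  tibble(
    chrom = rep(as.character(rec$rname[keep]), nb),
    start = IRanges::start(flat) - 1L,
    end = IRanges::end(flat),
    read_id = rep(read_id, nb)
  )
}

#' Derive junction evidence from spliced read blocks
#'
#' Fallback used when no junction file accompanies the alignments: every gap
#' between consecutive blocks of one read is treated as an intron call, and
#' identical gaps are aggregated into a support count.
#'
#' @param blocks Read-block tibble as returned by [read_alignments()].
#' @return Junction tibble (`chrom`, `donor_end`, `acceptor_start`,
#'   `support`, `span`).
#' @export
junctions_from_blocks <- function(blocks) {
  empty <- tibble(chrom = character(), donor_end = integer(),
                  acceptor_start = integer(), support = integer(),
                  span = integer())
  if (nrow(blocks) == 0) return(empty)
  ord <- order(blocks$read_id, blocks$chrom, blocks$start)
  rid <- blocks$read_id[ord]
  chm <- blocks$chrom[ord]
  st <- blocks$start[ord]
  en <- blocks$end[ord]
  n <- length(ord)
  adj <- which(rid[-n] == rid[-1] & chm[-n] == chm[-1])
  if (length(adj) == 0) return(empty)
  don <- en[adj]
  acc <- st[adj + 1L]
  keep <- acc - don >= 1L
  if (!any(keep)) return(empty)
  key <- paste0(chm[adj][keep], "\r", don[keep], "\r", acc[keep])
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- tibble(
    chrom = vapply(parts, `[`, "", 1),
    donor_end = as.integer(vapply(parts, `[`, "", 2)),
    acceptor_start = as.integer(vapply(parts, `[`, "", 3)),
    support = as.integer(tab)
  )
  out$span <- out$acceptor_start - out$donor_end
  out[order(out$chrom, out$donor_end, out$acceptor_start), ]
}

#' Read splice junctions from a BED12 junctions file
#'
#' Parses the two-block BED12 dialect written by junction-aware aligners: each
#' record's blocks are the exonic anchors on either side of an intron, the
#' score is the number of reads mapped across the junction. Records with a
#' block count other than two are skipped with a warning.
#'
#' @param path Path to the BED12 file (a leading `track` line is allowed).
#' @return Junction tibble (`chrom`, `donor_end`, `acceptor_start`,
#'   `support`, `span`), 0-based half-open exon-side coordinates: `donor_end`
#'   is the exclusive end of the upstream exonic anchor, `acceptor_start` the
#'   inclusive start of the downstream one.
#' @export
read_junctions_bed <- function(path) {
  empty <- tibble(chrom = character(), donor_end = integer(),
                  acceptor_start = integer(), support = integer(),
                  span = integer())
  if (!file.exists(path)) {
    abort(paste0("junction file not found: ", path), class = "txtile_input_error")
  }
  if (length(readLines(path, n = 1, warn = FALSE)) == 0) return(empty)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) return(empty)
  nb <- S4Vectors::elementNROWS(gr$blocks)
  if (any(nb != 2)) {
    warn(sprintf("skipping %d junction record(s) without exactly 2 blocks",
                 sum(nb != 2)))
    gr <- gr[nb == 2]
  }
  if (length(gr) == 0) return(empty)
  chrom_start0 <- GenomicRanges::start(gr) - 1L
  b <- gr$blocks
  first_end <- vapply(b, function(x) IRanges::end(x)[1], integer(1))
  second_start <- vapply(b, function(x) IRanges::start(x)[2], integer(1))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    donor_end = chrom_start0 + first_end,
    acceptor_start = chrom_start0 + second_start - 1L,
    support = as.integer(gr$score)
  ) |>
    dplyr::mutate(span = .data$acceptor_start - .data$donor_end) |>
    dplyr::arrange(.data$chrom, .data$donor_end)
  if (any(out$span < 1)) {
    abort("malformed junction record: intron span < 1", class = "txtile_input_error")
  }
  out
}

#' Write gene models to GTF
#'
#' Emits one `transcript` feature plus per-exon `exon` features per gene,
#' 1-based inclusive coordinates, with `gene_id`/`transcript_id` attributes
#' and `rpke`/`read_count` carried on the transcript line. The file
#' round-trips losslessly through [read_gtf()].
#'
#' @param genes Gene-model tibble (see [gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  if (nrow(genes) == 0) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  ex <- unnest_exons(genes)
  tx <- genes |>
    dplyr::transmute(
      chrom = .data$chrom, start = .data$span_start, end = .data$span_end,
      strand = .data$strand, type = "transcript", gene_id = .data$gene_id,
      rpke = .data$rpke, read_count = .data$read_count
    )
  exr <- ex |>
    dplyr::transmute(
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand, type = "exon", gene_id = .data$gene_id,
      rpke = NA_real_, read_count = NA_integer_
    )
  all <- dplyr::bind_rows(tx, exr) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id,
                   dplyr::desc(.data$type))
  gr <- GenomicRanges::GRanges(
    seqnames = all$chrom,
    ranges = IRanges::IRanges(start = all$start + 1L, end = all$end),
    strand = ifelse(all$strand == ".", "*", all$strand)
  )
  gr$source <- "txtile"
  gr$type <- all$type
  gr$gene_id <- all$gene_id
  gr$transcript_id <- all$gene_id
  gr$rpke <- all$rpke
  gr$read_count <- all$read_count
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from GTF
#'
#' Inverse of [write_gtf()]: exons are grouped by `transcript_id` (one model
#' per transcript), junctions are reconstructed from the gaps between
#' adjacent exons, and `rpke`/`read_count` attributes are recovered when
#' present.
#'
#' @param path Path to a GTF file.
#' @return Gene-model tibble.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) return(empty_gene_models())
  ex <- tibble(
    gene_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |>
    dplyr::mutate(strand = ifelse(.data$strand == "*", ".", .data$strand))
  genes <- gene_models(ex)
  genes$junctions <- map2(genes$exons, genes$chrom, function(e, ch) {
    if (nrow(e) < 2) {
      return(tibble(chrom = character(), donor_end = integer(),
                    acceptor_start = integer(), support = integer()))
    }
    tibble(chrom = ch, donor_end = e$end[-nrow(e)],
           acceptor_start = e$start[-1], support = NA_integer_)
  })
  gr2 <- rtracklayer::import(path, format = "gtf")
  tx <- gr2[gr2$type == "transcript"]
  if (length(tx) > 0) {
    meta <- S4Vectors::mcols(tx)
    id <- as.character(meta$transcript_id)
    if ("rpke" %in% names(meta)) {
      genes$rpke <- as.numeric(meta$rpke[match(genes$gene_id, id)])
    }
    if ("read_count" %in% names(meta)) {
      genes$read_count <- as.integer(meta$read_count[match(genes$gene_id, id)])
    }
  }
  genes
}

#' Read an annotation file into gene spans
#'
#' Accepts GFF3 or GTF. `gene` features are used directly when present;
#' otherwise exon/transcript features are grouped by gene id and their span
#' taken. Used as the comparison set for annotation-overlap classification.
#'
#' @param path Path to a GFF3/GTF annotation.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open spans).
#' @export
read_annotation <- function(path) {
  fmt <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- rtracklayer::import(path, format = fmt)
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character())
  if (length(gr) == 0) return(empty)
  meta <- S4Vectors::mcols(gr)
  ids <- if ("gene_id" %in% names(meta)) {
    as.character(meta$gene_id)
  } else if ("ID" %in% names(meta)) {
    as.character(meta$ID)
  } else {
    as.character(seq_along(gr))
  }
  has_gene <- "type" %in% names(meta) && any(meta$type == "gene")
  if (has_gene) {
    keep <- meta$type == "gene"
    gr <- gr[keep]
    ids <- ids[keep]
  }
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$start), end = max(.data$end),
                     strand = dplyr::first(.data$strand), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start)
}
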