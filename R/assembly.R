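#' Filter junctions by span and exon skipping
#'
#' Very long junctions are usually mapping artefacts caused by sequence
#' similarity elsewhere in the genome. Two caps are applied: junctions whose
#' intron span exceeds `max_span` are dropped outright, and junctions whose
#' intron fully contains at least one detected exon fragment (an exon-skipping
#' junction) are dropped when their span exceeds `max_skip_span`. Both
#' comparisons are strict, so a span of exactly the cap is kept.
#'
#' @param junctions Junction tibble.
#' @param exons Fragment tibble of detected exons (used for the skip test).
#' @param max_span Maximum intron span in nt (default 50,000).
#' @param max_skip_span Maximum span for exon-skipping junctions (default
#'   50,000).
#' @return Filtered junction tibble.
#' @export
filter_junctions <- function(junctions, exons, max_span = 50000,
                             max_skip_span = 50000) {
  if (nrow(junctions) == 0) return(junctions)
  j <- junctions |>
    dplyr::mutate(span = .data$acceptor_start - .data$donor_end) |>
    dplyr::filter(.data$span <= max_span)
  if (nrow(j) == 0 || nrow(exons) == 0) return(j)
  skips <- logical(nrow(j))
  for (ch in unique(j$chrom)) {
    ji <- which(j$chrom == ch)
    e <- exons[exons$chrom == ch, ]
    if (nrow(e) == 0) next
    intr <- IRanges::IRanges(j$donor_end[ji] + 1L, j$acceptor_start[ji])
    ex <- IRanges::IRanges(e$start + 1L, e$end)
    skips[ji] <- IRanges::countOverlaps(intr, ex, type = "any") > 0 &
      vapply(seq_along(ji), function(k) {
        any(IRanges::start(ex) >= IRanges::start(intr)[k] &
              IRanges::end(ex) <= IRanges::end(intr)[k])
      }, logical(1))
  }
  j[!(skips & j$span > max_skip_span), ]
}

# Match junction edges to fragment boundaries. Returns a tibble with one row
# per junction that connects two distinct fragments: frag index of donor and
# acceptor side plus the junction row index.
match_junction_edges <- function(frags, junctions, tol = 0) {
  out <- tibble(donor_frag = integer(), acceptor_frag = integer(),
                junction = integer())
  if (nrow(frags) == 0 || nrow(junctions) == 0) return(out)
  res <- vector("list", 0)
  for (ch in unique(junctions$chrom)) {
    ji <- which(junctions$chrom == ch)
    fi <- which(frags$chrom == ch)
    if (length(fi) == 0) next
    j <- junctions[ji, ]
    don <- vapply(seq_along(ji), function(k) {
      d <- abs(frags$end[fi] - j$donor_end[k])
      i <- which(d <= tol)
      if (length(i) == 0) NA_integer_ else fi[i[which.min(d[i])]]
    }, integer(1))
    acc <- vapply(seq_along(ji), function(k) {
      d <- abs(frags$start[fi] - j$acceptor_start[k])
      i <- which(d <= tol)
      if (length(i) == 0) NA_integer_ else fi[i[which.min(d[i])]]
    }, integer(1))
    ok <- !is.na(don) & !is.na(acc) & don != acc
    if (any(ok)) {
      res[[length(res) + 1]] <- tibble(donor_frag = don[ok],
                                       acceptor_frag = acc[ok],
                                       junction = ji[ok])
    }
  }
  dplyr::bind_rows(out, dplyr::bind_rows(res))
}

#' Link exon fragments into gene models through junction edges
#'
#' Builds the splice graph whose nodes are exon fragments and whose edges are
#' junctions matching a fragment end (donor) and another fragment's start
#' (acceptor) within `tol` nt, then emits one gene model per connected
#' component containing all of the component's exons in coordinate order —
#' the single longest isoform. Fragments touched by no junction become
#' single-exon genes.
#'
#' @param frags Fragment tibble (sorted, disjoint).
#' @param junctions Junction tibble (already filtered).
#' @param cov Optional [coverage_index()]; when given, per-gene `read_count`
#'   (distinct reads overlapping any exon) and `rpke` are filled in.
#' @param tol Boundary-matching tolerance in nt. Fragment boundaries are
#'   snapped to junction edges during splitting, so the default is exact
#'   matching; a small tolerance (e.g. 5) guards off-by-ones in dirty inputs.
#' @return Gene-model tibble (see [gene_models()]).
#' @export
link_genes <- function(frags, junctions, cov = NULL, tol = 0) {
  if (nrow(frags) == 0) return(empty_gene_models())
  edges <- match_junction_edges(frags, junctions, tol = tol)
  g <- igraph::make_empty_graph(n = nrow(frags), directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$donor_frag, edges$acceptor_frag))
  }
  comp <- igraph::components(g)$membership
  ord <- order(frags$chrom, frags$start)
  comp_rank <- match(comp, unique(comp[ord]))
  n_genes <- max(comp_rank)
  uid <- sprintf("gene_%05d", seq_len(n_genes))
  row_by_gene <- split(ord, comp_rank[ord])  # rows sorted by coordinate
  exons <- lapply(row_by_gene, function(idx) {
    idx <- idx[order(frags$start[idx])]
    tibble::new_tibble(list(start = frags$start[idx], end = frags$end[idx]),
                       nrow = length(idx))
  })
  empty_jn <- tibble(chrom = character(), donor_end = integer(),
                     acceptor_start = integer(), support = integer())
  jn_by_gene <- rep(list(empty_jn), n_genes)
  if (nrow(edges) > 0) {
    jg <- comp_rank[edges$donor_frag]
    for (grp in split(seq_len(nrow(edges)), jg)) {
      j <- junctions[edges$junction[grp], ]
      jn_by_gene[[jg[grp[1]]]] <- tibble::new_tibble(list(
        chrom = j$chrom, donor_end = j$donor_end,
        acceptor_start = j$acceptor_start, support = j$support
      ), nrow = nrow(j))
    }
  }
  fp <- vapply(exons, function(e) sum(e$end - e$start), numeric(1))
  genes <- tibble::new_tibble(list(
    gene_id = uid,
    chrom = unname(vapply(row_by_gene, function(idx) frags$chrom[idx[1]], "")),
    strand = rep(".", n_genes),
    exons = unname(exons),
    junctions = unname(jn_by_gene),
    n_exons = unname(lengths(row_by_gene)),
    footprint_nt = unname(as.integer(fp)),
    read_count = rep(NA_integer_, n_genes),
    rpke = rep(NA_real_, n_genes),
    span_start = unname(vapply(exons, function(e) e$start[1], integer(1))),
    span_end = unname(vapply(exons, function(e) e$end[nrow(e)], integer(1)))
  ), nrow = n_genes)
  if (!is.null(cov)) genes <- gene_rpke(genes, cov)
  genes
}

#' Compute gene-level read counts and RPKE
#'
#' A gene's RPKE is the number of distinct reads overlapping any of its exons
#' (a junction-spanning read overlapping two exons counts once), scaled per
#' kilobase of exonic footprint.
#'
#' @param genes Gene-model tibble.
#' @param cov A [coverage_index()].
#' @return `genes` with `read_count` and `rpke` filled in.
#' @export
gene_rpke <- function(genes, cov) {
  if (nrow(genes) == 0) return(genes)
  n_ex <- genes$n_exons
  ex_gene <- rep(seq_len(nrow(genes)), n_ex)
  ex_start <- unlist(lapply(genes$exons, `[[`, "start"), use.names = FALSE)
  ex_end <- unlist(lapply(genes$exons, `[[`, "end"), use.names = FALSE)
  ex_chrom <- rep(genes$chrom, n_ex)
  n <- integer(nrow(genes))
  for (ch in unique(ex_chrom)) {
    cc <- cov$chroms[[ch]]
    if (is.null(cc)) next
    sel <- which(ex_chrom == ch)
    q <- IRanges::IRanges(ex_start[sel] + 1L, ex_end[sel])
    hits <- IRanges::findOverlaps(q, cc$ir)
    if (length(hits) == 0) next
    gidx <- ex_gene[sel][S4Vectors::queryHits(hits)]
    ids <- cc$read_id[S4Vectors::subjectHits(hits)]
    dup <- duplicated(paste0(gidx, "\r", ids))
    cnt <- tabulate(gidx[!dup], nbins = nrow(genes))
    n <- n + cnt
  }
  genes$read_count <- n
  genes$rpke <- n * 1000 / genes$footprint_nt
  genes
}

#' Remove gene models below a minimum exonic footprint
#'
#' Multimapping noise tends to produce very small high-coverage islands;
#' models whose summed exonic length is below `min_nt` are discarded.
#'
#' @param genes Gene-model tibble.
#' @param min_nt Minimum footprint in nt (default 140); a footprint of exactly
#'   `min_nt` is kept.
#' @return Filtered gene-model tibble; the number removed is reported via a
#'   message when any are.
#' @export
filter_min_footprint <- function(genes, min_nt = 140) {
  drop <- genes$footprint_nt < min_nt
  if (any(drop)) {
    inform(sprintf("removed %d gene model(s) with footprint < %d nt",
                   sum(drop), as.integer(min_nt)))
  }
  genes[!drop, ]
}

#' Assemble gene models from read blocks and junctions
#'
#' Runs the full pipeline: coverage tiling at `min_exon_rpke`, short-exon
#' inference from junction pairs, merging of fragments within `merge_gap`,
#' splitting/trimming at internal junctions under the `density_ratio` rule,
#' junction span/skip filtering, linking into connected components, gene-level
#' RPKE, and the minimum-footprint filter. Per-stage fragment/gene counts are
#' recorded.
#'
#' @param blocks Read-block tibble (see [read_alignments()]).
#' @param junctions Junction tibble; when `NULL`, junction evidence is derived
#'   from the gaps of spliced read blocks via [junctions_from_blocks()].
#' @param config An [assembly_config()].
#' @return An object of class `"txtile_assembly"`: a list with `genes` (the
#'   gene-model tibble), `stages` (per-stage counts), `junctions` (the
#'   filtered junction set) and `config`.
#' @examples
#' blocks <- tibble::tibble(
#'   chrom = "chr1",
#'   start = rep(seq(0L, 150L, by = 10L), each = 5),
#'   end = rep(seq(50L, 200L, by = 10L), each = 5),
#'   read_id = sprintf("r%03d", seq_len(80))
#' )
#' asm <- assemble_transcripts(blocks, config = assembly_config(min_footprint = 100))
#' asm$genes
#' @export
assemble_transcripts <- function(blocks, junctions = NULL,
                                 config = assembly_config()) {
  stopifnot(inherits(config, "assembly_config"))
  if (is.null(junctions)) junctions <- junctions_from_blocks(blocks)
  cov <- coverage_index(blocks)
  tiled <- tile_fragments(cov, min_rpke = config$min_exon_rpke)
  inferred <- infer_short_exons(junctions, read_len = config$read_len,
                                cov = cov, existing = tiled)
  frags <- dplyr::bind_rows(tiled, inferred)
  frags <- frags[order(frags$chrom, frags$start), ]
  merged <- merge_close_fragments(frags, max_gap = config$merge_gap)
  split <- split_at_internal_junctions(
    merged, junctions, cov,
    density_ratio = config$density_ratio,
    flank_window = config$read_len, read_len = config$read_len
  )
  jf <- filter_junctions(junctions, split,
                         max_span = config$max_junction_span,
                         max_skip_span = config$max_skip_span)
  genes <- link_genes(split, jf, cov = cov, tol = config$link_tol)
  n_linked <- nrow(genes)
  genes <- suppressMessages(filter_min_footprint(genes, config$min_footprint))
  stages <- tibble(
    stage = c("tiled_fragments", "with_inferred_exons", "after_merge",
              "after_split", "junctions_kept", "genes_linked",
              "genes_after_footprint"),
    n = c(nrow(tiled), nrow(frags), nrow(merged), nrow(split), nrow(jf),
          n_linked, nrow(genes))
  )
  structure(
    list(genes = genes, stages = stages, junctions = jf, config = config),
    class = "txtile_assembly"
  )
}

#' @export
print.txtile_assembly <- function(x, ...) {
  cat("<txtile_assembly>\n")
  cat(sprintf("  %d gene model(s), %d exon(s), %d junction(s) used\n",
              nrow(x$genes), sum(x$genes$n_exons), nrow(x$junctions)))
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-24s %d\n", x$stages$stage[i], x$stages$n[i]))
  }
  invisible(x)
}

#' @rdname assemble_transcripts
#' @param x A `txtile_assembly` object.
#' @param ... Unused.
#' @return `tidy()`: the gene-model tibble; `glance()`: a one-row summary.
#' @method tidy txtile_assembly
#' @export
tidy.txtile_assembly <- function(x, ...) x$genes

#' @rdname assemble_transcripts
#' @method glance txtile_assembly
#' @export
glance.txtile_assembly <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_exons = sum(x$genes$n_exons),
    total_footprint_nt = sum(x$genes$footprint_nt),
    median_rpke = if (nrow(x$genes)) median(x$genes$rpke) else NA_real_,
    n_junctions = nrow(x$junctions)
  )
}
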