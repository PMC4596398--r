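#' Classify assembled genes by annotation overlap
#'
#' For each assembled gene, the fraction of its exonic footprint covered by
#' any annotated gene span is computed and the gene is classed as `annotated`
#' (fraction >= `hi`), `novel` (fraction < `lo`) or `intermediate` (anything
#' between — often undiscovered alternatively spliced forms of known genes).
#' Overlap is computed against annotated gene spans, not exon structures,
#' i.e. against the annotated start/termination extent.
#'
#' @param genes Gene-model tibble.
#' @param annotation Annotation tibble from [read_annotation()] (`gene_id`,
#'   `chrom`, `start`, `end`).
#' @param hi,lo Class boundaries (defaults 0.75 and 0.05).
#' @return `genes` with added columns `best_overlap_fraction` and `class`.
#' @export
classify_overlap <- function(genes, annotation, hi = 0.75, lo = 0.05) {
  if (nrow(genes) == 0) {
    return(dplyr::mutate(genes, best_overlap_fraction = numeric(),
                         class = character()))
  }
  frac <- numeric(nrow(genes))
  ex <- unnest_exons(genes)
  for (ch in unique(genes$chrom)) {
    a <- annotation[annotation$chrom == ch, ]
    if (nrow(a) == 0) next
    ann <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
    e <- ex[ex$chrom == ch, ]
    eir <- IRanges::IRanges(e$start + 1L, e$end)
    ov <- IRanges::pintersect(IRanges::findOverlapPairs(eir, ann))
    hits <- IRanges::findOverlaps(eir, ann)
    if (length(hits) == 0) next
    w <- tibble(gene_id = e$gene_id[S4Vectors::queryHits(hits)],
                w = IRanges::width(ov)) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(w = sum(.data$w), .groups = "drop")
    frac[match(w$gene_id, genes$gene_id)] <- w$w
  }
  frac <- frac / genes$footprint_nt
  genes |>
    dplyr::mutate(
      best_overlap_fraction = pmin(frac, 1),
      class = dplyr::case_when(
        .data$best_overlap_fraction >= hi ~ "annotated",
        .data$best_overlap_fraction < lo ~ "novel",
        TRUE ~ "intermediate"
      )
    )
}

#' Drop transcripts completely contained within another transcript
#'
#' Multi-isoform input (e.g. another assembler's GTF) over-represents genes;
#' a transcript whose exonic footprint is entirely inside another transcript's
#' footprint on the same chromosome is removed. Identical footprints keep the
#' first transcript in (chrom, start, gene_id) sort order.
#'
#' @param genes Gene-model tibble.
#' @return Filtered gene-model tibble.
#' @export
dedupe_contained <- function(genes) {
  if (nrow(genes) <= 1) return(genes)
  genes <- dplyr::arrange(genes, .data$chrom, .data$span_start,
                          dplyr::desc(.data$footprint_nt), .data$gene_id)
  drop <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    if (length(gi) < 2) next
    spans <- IRanges::IRanges(genes$span_start[gi] + 1L, genes$span_end[gi])
    cand <- IRanges::findOverlaps(spans, spans, type = "within")
    cand <- cand[S4Vectors::queryHits(cand) != S4Vectors::subjectHits(cand)]
    for (k in seq_along(cand)) {
      qi <- gi[S4Vectors::queryHits(cand)[k]]
      si <- gi[S4Vectors::subjectHits(cand)[k]]
      if (drop[qi] || drop[si]) next
      a <- IRanges::IRanges(genes$exons[[qi]]$start + 1L, genes$exons[[qi]]$end)
      b <- IRanges::IRanges(genes$exons[[si]]$start + 1L, genes$exons[[si]]$end)
      uncovered <- IRanges::setdiff(a, b)
      if (sum(IRanges::width(uncovered)) == 0) {
        identical_fp <- sum(IRanges::width(IRanges::setdiff(b, a))) == 0
        if (identical_fp) {
          # keep the earlier row in sort order
          drop[max(qi, si)] <- TRUE
        } else {
          drop[qi] <- TRUE
        }
      }
    }
  }
  genes[!drop, ]
}

#' Filter genes by minimum expression
#'
#' @param genes Gene-model tibble with an `rpke` column.
#' @param min_rpke Minimum RPKE (default 100); a gene at exactly the threshold
#'   is kept.
#' @return Filtered gene-model tibble.
#' @export
filter_expression <- function(genes, min_rpke = 100) {
  genes[!is.na(genes$rpke) & genes$rpke >= min_rpke, ]
}

#' Screen gene sequences for similarity elsewhere in the genome
#'
#' Reads mapping ambiguously between near-identical loci produce false novel
#' genes. For each gene, the spliced transcript sequence is seeded against the
#' whole genome with exact `word_size`-mers, seed hits on the same diagonal
#' are chained and extended ungapped while identity stays at or above
#' `min_identity`, hits overlapping the gene's own locus are discarded, and
#' the percent similarity is the fraction of the gene's bases covered by any
#' remaining alignment, times 100. Genes under `max_percent` pass the screen.
#'
#' @param genes Gene-model tibble.
#' @param genome A [Biostrings::DNAStringSet] (names = chromosomes) or path to
#'   a FASTA file.
#' @param max_percent Maximum percent similarity to pass (default 25).
#' @param word_size Exact-match seed length (default 16).
#' @param min_identity Minimum identity for ungapped extension (default 0.9).
#' @return Tibble with `gene_id`, `percent_similarity`, `passes`, `method`.
#' @export
similarity_screen <- function(genes, genome, max_percent = 25,
                              word_size = 16, min_identity = 0.9) {
  genome <- load_genome(genome)
  out <- tibble(gene_id = character(), percent_similarity = numeric(),
                passes = logical(), method = character())
  if (nrow(genes) == 0) return(out)
  chrseq <- lapply(as.character(names(genome)), function(n) {
    as.character(genome[[n]])
  })
  names(chrseq) <- names(genome)
  res <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (is.null(chrseq[[g$chrom]])) {
      abort(sprintf("gene %s: chromosome %s not in genome", g$gene_id, g$chrom),
            class = "txtile_input_error")
    }
    q <- splice_sequence(g, genome)
    L <- nchar(q)
    covered <- rep(FALSE, L)
    if (L >= word_size) {
      pd_starts <- seq_len(L - word_size + 1L)
      pdict <- Biostrings::PDict(Biostrings::DNAStringSet(
        Biostrings::DNAString(q), start = pd_starts, width = word_size
      ))
      for (ch in names(genome)) {
        m <- Biostrings::matchPDict(pdict, genome[[ch]])
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0) next
        hit_q <- rep(pd_starts, nh)
        hit_g <- IRanges::start(unlist(m, use.names = FALSE))
        # discard hits overlapping the gene's own genomic span
        if (ch == g$chrom) {
          own <- hit_g <= g$span_end & (hit_g + word_size - 1L) >= (g$span_start + 1L)
          hit_q <- hit_q[!own]
          hit_g <- hit_g[!own]
        }
        if (length(hit_q) == 0) next
        covered <- mark_chained_coverage(covered, hit_q, hit_g, word_size,
                                         q, chrseq[[ch]], min_identity)
      }
    }
    pct <- 100 * sum(covered) / L
    res[[i]] <- tibble(gene_id = g$gene_id, percent_similarity = pct,
                       passes = pct < max_percent, method = "internal")
  }
  dplyr::bind_rows(res)
}

# Chain seed hits along each diagonal, extend ends ungapped while identity
# stays >= min_identity, and mark covered query positions.
mark_chained_coverage <- function(covered, hit_q, hit_g, word_size,
                                  qseq, gseq, min_identity,
                                  max_ext = 500L) {
  diag <- hit_g - hit_q
  L <- length(covered)
  gl <- nchar(gseq)
  for (d in unique(diag)) {
    qs <- sort(hit_q[diag == d])
    seg <- IRanges::reduce(IRanges::IRanges(qs, width = word_size))
    for (k in seq_along(seg)) {
      s <- IRanges::start(seg)[k]
      e <- IRanges::end(seg)[k]
      # extend left
      mism <- 0L; tot <- e - s + 1L; best <- s
      p <- s - 1L
      while (p >= 1L && p >= s - max_ext && p + d >= 1L) {
        tot <- tot + 1L
        if (substr(qseq, p, p) != substr(gseq, p + d, p + d)) mism <- mism + 1L
        if ((tot - mism) / tot < min_identity) break
        if (substr(qseq, p, p) == substr(gseq, p + d, p + d)) best <- p
        p <- p - 1L
      }
      s2 <- best
      # extend right
      mism <- 0L; tot <- e - s + 1L; best <- e
      p <- e + 1L
      while (p <= L && p <= e + max_ext && p + d <= gl) {
        tot <- tot + 1L
        if (substr(qseq, p, p) != substr(gseq, p + d, p + d)) mism <- mism + 1L
        if ((tot - mism) / tot < min_identity) break
        if (substr(qseq, p, p) == substr(gseq, p + d, p + d)) best <- p
        p <- p + 1L
      }
      covered[s2:best] <- TRUE
    }
  }
  covered
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Run the novel-gene filter cascade and cross-assembler accounting
#'
#' Applies, per source, the full cascade: annotation-overlap classification
#' (keep class `novel`, overlap < `overlap_lo`), containment de-duplication,
#' minimum footprint, minimum expression, and (when a genome is supplied) the
#' genome-similarity screen. Sources are then matched by any same-chromosome
#' footprint overlap of at least 1 nt, and exclusive/shared counts plus the
#' union are reported; the union is the high-confidence novel gene set.
#'
#' @param ta_genes Gene-model tibble from this assembler.
#' @param other_genes Optional gene-model tibble from a second assembler
#'   (e.g. read in with [read_gtf()]).
#' @param annotation Annotation tibble from [read_annotation()].
#' @param genome Optional genome (`DNAStringSet` or FASTA path) enabling the
#'   similarity screen.
#' @param config An [assembly_config()] supplying the thresholds.
#' @return An object of class `"novel_gene_report"`: list with `stages`
#'   (per-source per-stage counts), `genes` (the union set with a `source`
#'   column: `"a"`, `"b"` or `"both"`), `exclusive_a`, `exclusive_b`,
#'   `shared`, `n_union`, and `similarity` (per-gene similarity results with
#'   quartile bins, when computed).
#' @export
combine_and_report <- function(ta_genes, other_genes = NULL, annotation,
                               genome = NULL, config = assembly_config()) {
  run_cascade <- function(genes, label) {
    counts <- tibble(source = label, stage = "input", n = nrow(genes))
    g <- classify_overlap(genes, annotation,
                          hi = config$overlap_hi, lo = config$overlap_lo)
    g <- g[g$class == "novel", ]
    counts <- dplyr::add_row(counts, source = label, stage = "novel_class",
                             n = nrow(g))
    g <- dedupe_contained(g)
    counts <- dplyr::add_row(counts, source = label, stage = "deduped",
                             n = nrow(g))
    g <- suppressMessages(filter_min_footprint(g, config$min_footprint))
    counts <- dplyr::add_row(counts, source = label, stage = "min_footprint",
                             n = nrow(g))
    g <- filter_expression(g, config$min_gene_rpke)
    counts <- dplyr::add_row(counts, source = label, stage = "min_expression",
                             n = nrow(g))
    sim <- NULL
    if (!is.null(genome)) {
      sim <- similarity_screen(g, genome, max_percent = config$max_similarity)
      if (nrow(sim) > 0) {
        sim$source <- label
        sim$similarity_bin <- cut(
          sim$percent_similarity, breaks = c(-Inf, 25, 50, 75, Inf),
          labels = c("<25", "25-50", "50-75", ">75"), right = FALSE
        )
      }
      g <- g[g$gene_id %in% sim$gene_id[sim$passes], ]
      counts <- dplyr::add_row(counts, source = label, stage = "max_similarity",
                               n = nrow(g))
    }
    list(genes = g, counts = counts, similarity = sim)
  }
  a <- run_cascade(ta_genes, "a")
  stages <- a$counts
  sims <- a$similarity
  ga <- a$genes
  if (!is.null(other_genes)) {
    b <- run_cascade(other_genes, "b")
    stages <- dplyr::bind_rows(stages, b$counts)
    sims <- dplyr::bind_rows(sims, b$similarity)
    gb <- b$genes
    ov_ab <- cross_source_overlap(ga, gb)
    shared_a <- ov_ab$a
    shared_b <- ov_ab$b
    exclusive_a <- sum(!shared_a)
    exclusive_b <- sum(!shared_b)
    shared <- sum(shared_a)
    union_genes <- dplyr::bind_rows(
      dplyr::mutate(ga, source = ifelse(shared_a, "both", "a")),
      dplyr::mutate(gb[!shared_b, ], source = "b")
    )
  } else {
    exclusive_a <- nrow(ga)
    exclusive_b <- 0L
    shared <- 0L
    union_genes <- dplyr::mutate(ga, source = "a")
  }
  structure(
    list(stages = stages, genes = union_genes, exclusive_a = exclusive_a,
         exclusive_b = exclusive_b, shared = shared,
         n_union = nrow(union_genes), similarity = sims),
    class = "novel_gene_report"
  )
}

# For two gene sets, flags per row whether any same-chromosome footprint
# overlap (>= 1 nt) with the other set exists.
cross_source_overlap <- function(ga, gb) {
  fa <- logical(nrow(ga))
  fb <- logical(nrow(gb))
  if (nrow(ga) == 0 || nrow(gb) == 0) return(list(a = fa, b = fb))
  exa <- unnest_exons(ga)
  exb <- unnest_exons(gb)
  for (ch in intersect(unique(exa$chrom), unique(exb$chrom))) {
    ea <- exa[exa$chrom == ch, ]
    eb <- exb[exb$chrom == ch, ]
    ia <- IRanges::IRanges(ea$start + 1L, ea$end)
    ib <- IRanges::IRanges(eb$start + 1L, eb$end)
    hits <- IRanges::findOverlaps(ia, ib)
    if (length(hits) == 0) next
    fa[match(unique(ea$gene_id[S4Vectors::queryHits(hits)]), ga$gene_id)] <- TRUE
    fb[match(unique(eb$gene_id[S4Vectors::subjectHits(hits)]), gb$gene_id)] <- TRUE
  }
  list(a = fa, b = fb)
}

#' @export
print.novel_gene_report <- function(x, ...) {
  cat("<novel_gene_report>\n")
  cat(sprintf("  union: %d  (exclusive A: %d, exclusive B: %d, shared: %d)\n",
              x$n_union, x$exclusive_a, x$exclusive_b, x$shared))
  print(x$stages, n = nrow(x$stages))
  invisible(x)
}

#' @rdname combine_and_report
#' @param x A `novel_gene_report`.
#' @param ... Unused.
#' @method tidy novel_gene_report
#' @export
tidy.novel_gene_report <- function(x, ...) x$stages

#' @rdname combine_and_report
#' @method glance novel_gene_report
#' @export
glance.novel_gene_report <- function(x, ...) {
  tibble(exclusive_a = x$exclusive_a, exclusive_b = x$exclusive_b,
         shared = x$shared, n_union = x$n_union)
}
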