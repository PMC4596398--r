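#' Match assembled genes to reference transcript models
#'
#' Pairs each assembled gene with a reference transcript (e.g. a genome-aligned
#' full-length cDNA) when the overlap between their exonic footprints exceeds
#' `min_overlap` of the gene's footprint. When several reference variants
#' qualify, the variant with the same exon count as the assembled gene is
#' preferred; otherwise the best-overlapping variant is taken.
#'
#' @param genes Gene-model tibble (assembled).
#' @param refs Gene-model tibble of reference transcripts (e.g. from
#'   [read_gtf()]).
#' @param min_overlap Minimum overlap fraction of the gene's footprint,
#'   exclusive (default 0.90, i.e. >90% required).
#' @return Tibble of pairs: `gene_id`, `ref_id`, `overlap_fraction`,
#'   `exon_count_match`, plus span columns used by [tss_tts_offsets()].
#' @export
match_references <- function(genes, refs, min_overlap = 0.90) {
  empty <- tibble(gene_id = character(), ref_id = character(),
                  overlap_fraction = numeric(), exon_count_match = logical(),
                  gene_start = integer(), gene_end = integer(),
                  ref_start = integer(), ref_end = integer())
  if (nrow(genes) == 0 || nrow(refs) == 0) return(empty)
  exg <- unnest_exons(genes)
  exr <- unnest_exons(refs)
  pairs <- list()
  for (ch in intersect(unique(exg$chrom), unique(exr$chrom))) {
    eg <- exg[exg$chrom == ch, ]
    er <- exr[exr$chrom == ch, ]
    ig <- IRanges::IRanges(eg$start + 1L, eg$end)
    ir <- IRanges::IRanges(er$start + 1L, er$end)
    hits <- IRanges::findOverlaps(ig, ir)
    if (length(hits) == 0) next
    ov <- IRanges::pintersect(ig[S4Vectors::queryHits(hits)],
                              ir[S4Vectors::subjectHits(hits)])
    pairs[[length(pairs) + 1]] <- tibble(
      gene_id = eg$gene_id[S4Vectors::queryHits(hits)],
      ref_id = er$gene_id[S4Vectors::subjectHits(hits)],
      w = IRanges::width(ov)
    )
  }
  if (length(pairs) == 0) return(empty)
  cand <- dplyr::bind_rows(pairs) |>
    dplyr::group_by(.data$gene_id, .data$ref_id) |>
    dplyr::summarise(w = sum(.data$w), .groups = "drop") |>
    dplyr::left_join(
      dplyr::select(genes, "gene_id", g_fp = "footprint_nt", g_n = "n_exons",
                    gene_start = "span_start", gene_end = "span_end"),
      by = "gene_id"
    ) |>
    dplyr::left_join(
      dplyr::select(refs, ref_id = "gene_id", r_n = "n_exons",
                    ref_start = "span_start", ref_end = "span_end"),
      by = "ref_id"
    ) |>
    dplyr::mutate(overlap_fraction = .data$w / .data$g_fp,
                  exon_count_match = .data$g_n == .data$r_n) |>
    dplyr::filter(.data$overlap_fraction > min_overlap)
  cand |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$exon_count_match),
                   dplyr::desc(.data$overlap_fraction), .data$ref_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "ref_id", "overlap_fraction", "exon_count_match",
                  "gene_start", "gene_end", "ref_start", "ref_end")
}

#' Classify the discrepancy between one assembled gene and its reference
#'
#' Exon structures are compared by overlap. Elementary discrepancies are:
#' `extra_exon` (assembled exon overlapping no reference exon), `missing_exon`
#' (reference exon overlapping no assembled exon), `extra_intron` (one
#' reference exon split across two assembled exons joined by a junction),
#' `gap` (the same split without junction support — a coverage hole),
#' `missing_intron` (one assembled exon fusing two reference exons), and
#' `missing_junction` (the reference continues into a neighbouring assembled
#' gene whose exons a reference junction would join). The report category is
#' `match` for zero discrepancies, the single category for one, and
#' `multiple` for two or more.
#'
#' @param gene One-row gene-model tibble.
#' @param ref One-row gene-model tibble (reference transcript).
#' @param neighbors Optional gene-model tibble of other assembled genes; used
#'   to distinguish `missing_junction`/cross-gene `gap` cases where a
#'   reference transcript is split across assembled genes.
#' @return One-row tibble: `gene_id`, `ref_id`, `category`, `n_discrepancies`
#'   plus the per-type counts.
#' @export
classify_discrepancy <- function(gene, ref, neighbors = NULL) {
  stopifnot(nrow(gene) == 1, nrow(ref) == 1)
  a <- gene$exons[[1]]
  r <- ref$exons[[1]]
  ia <- IRanges::IRanges(a$start + 1L, a$end)
  ir <- IRanges::IRanges(r$start + 1L, r$end)
  hits <- IRanges::findOverlaps(ia, ir)
  qa <- S4Vectors::queryHits(hits)
  sr <- S4Vectors::subjectHits(hits)
  jn <- gene$junctions[[1]]

  extra_exon <- sum(!seq_along(ia) %in% qa)
  missing_exon_idx <- setdiff(seq_along(ir), sr)

  # reference exons split across several assembled exons
  extra_intron <- 0L
  gap <- 0L
  for (re in unique(sr[duplicated(sr)])) {
    a_idx <- sort(qa[sr == re])
    for (k in seq_len(length(a_idx) - 1)) {
      e1 <- a$end[a_idx[k]]
      s2 <- a$start[a_idx[k + 1]]
      supported <- !is.null(jn) && nrow(jn) > 0 &&
        any(abs(jn$donor_end - e1) <= 5 & abs(jn$acceptor_start - s2) <= 5)
      if (supported) extra_intron <- extra_intron + 1L else gap <- gap + 1L
    }
  }

  # assembled exons fusing several reference exons
  missing_intron <- sum(pmax(table(factor(qa, levels = seq_along(ia))) - 1L, 0L))

  # reference exons untouched by this gene: neighbouring assembled genes may
  # carry them (missing junction between genes), else they are missing exons
  missing_junction <- 0L
  missing_exon <- length(missing_exon_idx)
  if (length(missing_exon_idx) > 0 && !is.null(neighbors) && nrow(neighbors) > 0) {
    nb <- neighbors[neighbors$gene_id != gene$gene_id &
                      neighbors$chrom == gene$chrom, ]
    if (nrow(nb) > 0) {
      nex <- unnest_exons(nb)
      inb <- IRanges::IRanges(nex$start + 1L, nex$end)
      cov_by_nb <- IRanges::overlapsAny(ir[missing_exon_idx], inb)
      missing_junction <- sum(cov_by_nb)
      missing_exon <- sum(!cov_by_nb)
      # a neighbour splitting a shared reference exon is a cross-gene gap
      shared <- intersect(unique(sr), which(IRanges::overlapsAny(ir, inb)))
      gap <- gap + length(shared)
    }
  }

  counts <- c(extra_exon = extra_exon, missing_exon = missing_exon,
              extra_intron = extra_intron, missing_intron = as.integer(missing_intron),
              missing_junction = missing_junction, gap = gap)
  total <- sum(counts)
  category <- if (total == 0) {
    "match"
  } else if (total == 1) {
    names(counts)[counts == 1]
  } else {
    "multiple"
  }
  tibble(gene_id = gene$gene_id, ref_id = ref$gene_id, category = category,
         n_discrepancies = as.integer(total), !!!as.list(counts))
}

#' Evaluate an assembly against reference transcripts
#'
#' Matches genes to references with [match_references()] and classifies every
#' pair with [classify_discrepancy()], passing the full gene set as neighbour
#' context.
#'
#' @param genes Gene-model tibble (assembled).
#' @param refs Gene-model tibble of reference transcripts.
#' @param min_overlap Overlap threshold passed to [match_references()].
#' @return List of class `"txtile_evaluation"`: `pairs`, `reports` (one row
#'   per pair), `offsets` (from [tss_tts_offsets()]) and a `category_counts`
#'   table.
#' @export
evaluate_assembly <- function(genes, refs, min_overlap = 0.90) {
  pairs <- match_references(genes, refs, min_overlap = min_overlap)
  reports <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    classify_discrepancy(
      genes[genes$gene_id == pairs$gene_id[i], ],
      refs[refs$gene_id == pairs$ref_id[i], ],
      neighbors = genes
    )
  }))
  if (nrow(pairs) == 0) {
    reports <- tibble(gene_id = character(), ref_id = character(),
                      category = character(), n_discrepancies = integer())
  }
  cats <- c("match", "extra_exon", "missing_exon", "extra_intron",
            "missing_intron", "missing_junction", "gap", "multiple")
  category_counts <- reports |>
    dplyr::count(category = factor(.data$category, levels = cats),
                 .drop = FALSE, name = "n")
  structure(
    list(pairs = pairs, reports = reports,
         offsets = tss_tts_offsets(pairs), category_counts = category_counts),
    class = "txtile_evaluation"
  )
}

#' @export
print.txtile_evaluation <- function(x, ...) {
  cat(sprintf("<txtile_evaluation> %d matched pair(s)\n", nrow(x$pairs)))
  print(x$category_counts, n = Inf)
  invisible(x)
}

#' @rdname evaluate_assembly
#' @param x A `txtile_evaluation`.
#' @param ... Unused.
#' @method tidy txtile_evaluation
#' @export
tidy.txtile_evaluation <- function(x, ...) x$reports

#' @rdname evaluate_assembly
#' @method glance txtile_evaluation
#' @export
glance.txtile_evaluation <- function(x, ...) {
  m <- sum(x$reports$category == "match")
  tibble(n_pairs = nrow(x$pairs), n_match = m,
         discrepant_fraction = if (nrow(x$pairs)) 1 - m / nrow(x$pairs) else NA_real_)
}

#' Transcript start/termination offsets against references
#'
#' For each matched pair, the offset of the assembled transcription start and
#' termination sites from the reference, in nt. Sign convention: positive
#' means the assembled gene is longer (starts upstream / ends downstream of
#' the reference); negative means shorter.
#'
#' @param pairs Pair tibble from [match_references()].
#' @return List with `offsets` (per-pair `start_offset`, `end_offset`) and
#'   `summary` (means and the fraction of offsets within 100 nt).
#' @export
tss_tts_offsets <- function(pairs) {
  offsets <- tibble(
    gene_id = pairs$gene_id, ref_id = pairs$ref_id,
    start_offset = pairs$ref_start - pairs$gene_start,
    end_offset = pairs$gene_end - pairs$ref_end
  )
  summary <- tibble(
    mean_start_offset = if (nrow(offsets)) mean(offsets$start_offset) else NA_real_,
    mean_end_offset = if (nrow(offsets)) mean(offsets$end_offset) else NA_real_,
    frac_start_within_100 = if (nrow(offsets)) mean(abs(offsets$start_offset) <= 100) else NA_real_,
    frac_end_within_100 = if (nrow(offsets)) mean(abs(offsets$end_offset) <= 100) else NA_real_
  )
  list(offsets = offsets, summary = summary)
}

#' Minimum sample size under a finite-population correction
#'
#' Computes the minimum number of genes to sample from a finite pool so that a
#' proportion estimated at an expected rate `r` (percent) is within margin of
#' error `E` at the confidence level implied by the critical value `Zc`:
#' \deqn{n = \frac{N x}{(N-1)E^2 + x}, \quad x = Z_c^2\, r(100-r)/100^2,}
#' rounded up to a whole unit.
#'
#' @param N Population size (e.g. number of discrepant genes).
#' @param E Margin of error as a fraction (e.g. 0.05).
#' @param Zc Critical value (1.96 for 95% confidence).
#' @param r Expected rate in percent (0 < r < 100; r = 0 degenerates to 0).
#' @return Integer sample size.
#' @examples
#' sample_size(N = 1337, E = 0.05, Zc = 1.96, r = 60)  # 290
#' @export
sample_size <- function(N, E = 0.05, Zc = 1.96, r = 60) {
  stopifnot(N >= 1, E > 0, E < 1, r >= 0, r < 100)
  x <- Zc^2 * r * (100 - r) / 100^2
  n <- N * x / ((N - 1) * E^2 + x)
  as.integer(ceiling(n))
}

#' Extrapolate sampled discrepancy attribution to the full pool
#'
#' Scales the attribution rate measured on a manually analysed sample up to
#' the full set of discrepant genes: `expected = round(total * rate)`
#' discrepancies attributed (e.g. to alternative splicing), the residual is
#' the remainder, the residual percent (1 decimal place) is taken of all
#' matched genes, and the accuracy bound is 100 minus that.
#'
#' @param total_discrepant Total number of discrepant genes.
#' @param sampled_rate Attribution rate measured on the sample (fraction).
#' @param matched_total Number of genes matched to a reference (the
#'   denominator of the residual percentage).
#' @return One-row tibble: `expected_alt_splice`, `residual`,
#'   `residual_pct_of_matched`, `accuracy_bound_pct`.
#' @examples
#' extrapolate_rates(1337, 0.967, 7104)  # 1293 expected, 99.4% bound
#' @export
extrapolate_rates <- function(total_discrepant, sampled_rate, matched_total) {
  stopifnot(sampled_rate >= 0, sampled_rate <= 1, matched_total > 0)
  expected <- round(total_discrepant * sampled_rate)
  residual <- total_discrepant - expected
  residual_pct <- round(100 * residual / matched_total, 1)
  tibble(
    expected_alt_splice = as.integer(expected),
    residual = as.integer(residual),
    residual_pct_of_matched = residual_pct,
    accuracy_bound_pct = 100 - residual_pct
  )
}
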