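#' Generate a random test genome with inserted single-isoform genes
#'
#' Builds the synthetic benchmark: a uniformly random nucleotide genome into
#' which single-isoform genes are inserted non-overlapping, separated by at
#' least `spacing` nt. Gene categories are defined by exon count (default 1-4
#' exons, 20 genes each, i.e. 80 genes). Exon and intron lengths are drawn
#' uniformly from the given ranges; the defaults (exons 150-600 nt, introns
#' 100-2,000 nt) keep every exon longer than a read while letting 50 nt reads
#' span junctions. Because no real reads align to random sequence, any gene
#' call outside the inserted loci is by construction a false positive.
#'
#' @param seed Integer seed; output is deterministic given the seed.
#' @param genes_per_category Genes per exon-count category (default 20).
#' @param categories Exon counts to generate (default `1:4`).
#' @param exon_len_range,intron_len_range Uniform sampling ranges in nt.
#' @param spacing Minimum intergenic distance in nt (default 10,000).
#' @param read_len Read length the benchmark will simulate (recorded only).
#' @param sequence Generate the nucleotide sequence? Read simulation only
#'   needs coordinates, so sequence generation can be skipped for speed.
#' @param dir Optional directory: writes `genome.fa` (if `sequence`) and
#'   `truth.gtf` there.
#' @return List of class `"txtile_test_genome"`: `genes` (truth gene-model
#'   tibble with a `category` column), `genome` (`DNAStringSet` or `NULL`),
#'   `genome_length`, `read_len`, and file paths when written.
#' @export
generate_test_genome <- function(seed = 1, genes_per_category = 20,
                                 categories = 1:4,
                                 exon_len_range = c(150, 600),
                                 intron_len_range = c(100, 2000),
                                 spacing = 10000, read_len = 50,
                                 sequence = TRUE, dir = NULL) {
  set.seed(seed)
  specs <- tibble(
    category = rep(categories, each = genes_per_category),
    idx = seq_len(length(categories) * genes_per_category)
  )
  pos <- spacing
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    k <- specs$category[i]
    ex_len <- as.integer(round(runif(k, exon_len_range[1], exon_len_range[2])))
    in_len <- if (k > 1) {
      as.integer(round(runif(k - 1, intron_len_range[1], intron_len_range[2])))
    } else {
      integer(0)
    }
    starts <- pos + cumsum(c(0L, ex_len[-k] + in_len))
    ends <- starts + ex_len
    rows[[i]] <- tibble(
      gene_id = sprintf("sim_gene_%03d", specs$idx[i]), chrom = "chrT",
      start = starts, end = ends
    )
    pos <- max(ends) + spacing
  }
  ex <- dplyr::bind_rows(rows)
  genes <- gene_models(ex)
  genes$category <- genes$n_exons
  genome_length <- pos
  genome <- NULL
  if (sequence) {
    genome <- Biostrings::DNAStringSet(paste(
      sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
      collapse = ""
    ))
    names(genome) <- "chrT"
  }
  out <- structure(
    list(genes = genes, genome = genome, genome_length = genome_length,
         read_len = read_len, seed = seed),
    class = "txtile_test_genome"
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (sequence) {
      out$genome_path <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(genome, out$genome_path)
    }
    out$truth_path <- file.path(dir, "truth.gtf")
    write_gtf(genes, out$truth_path)
  }
  out
}

#' @export
print.txtile_test_genome <- function(x, ...) {
  cat(sprintf("<txtile_test_genome> %d genes (%s exons), %d nt, seed %s\n",
              nrow(x$genes),
              paste(sort(unique(x$genes$category)), collapse = "/"),
              x$genome_length, format(x$seed)))
  invisible(x)
}

#' Simulate uniform reads over one gene's transcript
#'
#' Read start positions are uniform over the spliced transcript. The simulator
#' emulates two-part junction alignment: a read spanning more than two exons,
#' or anchoring with fewer than `min_anchor` nt on either side of a junction,
#' is unmappable and resampled, so that exactly `n_reads` aligned reads are
#' produced. Reads crossing one junction yield two blocks and support that
#' junction; short middle exons therefore receive only partial coverage from
#' half-alignments, as with a real junction-aware aligner.
#'
#' @param gene One-row gene-model tibble (the truth structure).
#' @param n_reads Number of aligned reads to produce.
#' @param read_len Read length (nt).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param min_anchor Minimum exonic anchor on each side of a junction (nt).
#' @return List: `blocks` (with a `read_index` column, 1..n in sampling
#'   order — nested subsets of the pool are the first k reads), `junctions`
#'   (aggregated support), `transcript_length`.
#' @export
simulate_reads <- function(gene, n_reads, read_len = 50, seed = NULL,
                           min_anchor = 8) {
  if (!is.null(seed)) set.seed(seed)
  ex <- gene$exons[[1]]
  widths <- ex$end - ex$start
  txlen <- sum(widths)
  no_blocks <- tibble(chrom = character(), start = integer(), end = integer(),
                      read_id = character(), read_index = integer())
  empty <- list(blocks = no_blocks, junctions = junctions_from_blocks(no_blocks),
                transcript_length = txlen)
  if (n_reads == 0) return(empty)
  if (txlen < read_len) {
    abort("transcript shorter than the read length", class = "txtile_input_error")
  }
  # transcript offsets of exon starts/ends
  cum_end <- cumsum(widths)
  cum_start <- cum_end - widths
  p_all <- 0:(txlen - read_len)
  first_ex <- findInterval(p_all, cum_start)
  last_ex <- findInterval(p_all + read_len - 1L, cum_start)
  span2 <- last_ex == first_ex + 1L
  anchor_ok <- !span2 |
    (cum_end[first_ex] - p_all >= min_anchor &
       p_all + read_len - cum_end[first_ex] >= min_anchor)
  mappable <- p_all[(last_ex - first_ex) <= 1L & anchor_ok]
  if (length(mappable) == 0) {
    abort("no mappable read positions on this transcript",
          class = "txtile_input_error")
  }
  p <- sample(mappable, n_reads, replace = TRUE)
  fe <- findInterval(p, cum_start)
  le <- findInterval(p + read_len - 1L, cum_start)
  g1_start <- ex$start[fe] + (p - cum_start[fe])
  one <- le == fe
  b1_end <- ifelse(one, g1_start + read_len, ex$end[fe])
  ids <- sprintf("simread_%06d", seq_len(n_reads))
  blocks1 <- tibble(chrom = gene$chrom, start = as.integer(g1_start),
                    end = as.integer(b1_end), read_id = ids,
                    read_index = seq_len(n_reads))
  two <- which(!one)
  blocks2 <- NULL
  if (length(two) > 0) {
    left_len <- cum_end[fe[two]] - p[two]
    blocks2 <- tibble(
      chrom = gene$chrom,
      start = as.integer(ex$start[le[two]]),
      end = as.integer(ex$start[le[two]] + (read_len - left_len)),
      read_id = ids[two], read_index = two
    )
  }
  blocks <- dplyr::arrange(dplyr::bind_rows(blocks1, blocks2),
                           .data$read_index, .data$start)
  list(blocks = blocks, junctions = junctions_from_blocks(blocks),
       transcript_length = txlen)
}

#' Titrate read depth for one gene and find its point of first failure
#'
#' Simulates one pool of reads at the highest level and re-assembles nested
#' subsamples at each level, from deep to shallow. A level fails when the
#' assembly is not exactly one gene with the true exon count. The point of
#' first failure (PoFF) is the highest expression level (in RPKE) at which a
#' failure occurs; identification is considered reliable only above it.
#'
#' @param gene One-row truth gene-model tibble.
#' @param levels Read counts to test (default
#'   `c(1000, 800, 600, 400, 200, 150, 100, 75, 50)`).
#' @param config An [assembly_config()].
#' @param seed Optional seed for the read pool.
#' @return List: `levels` (tibble with `reads`, `rpke`, `ok`) and `poff`
#'   (RPKE; `-Inf` when the gene never fails).
#' @export
titrate_gene <- function(gene, levels = c(1000, 800, 600, 400, 200, 150, 100, 75, 50),
                         config = assembly_config(), seed = NULL) {
  levels <- sort(unique(levels), decreasing = TRUE)
  sim <- simulate_reads(gene, max(levels), read_len = config$read_len,
                        seed = seed)
  res <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    k <- levels[i]
    blocks <- sim$blocks[sim$blocks$read_index <= k, ]
    asm <- assemble_transcripts(blocks, junctions_from_blocks(blocks), config)
    ok <- nrow(asm$genes) == 1 && asm$genes$n_exons[1] == gene$n_exons
    res[[i]] <- tibble(reads = k, rpke = k * 1000 / gene$footprint_nt, ok = ok)
  }
  lv <- dplyr::bind_rows(res)
  poff <- if (any(!lv$ok)) max(lv$rpke[!lv$ok]) else -Inf
  list(levels = lv, poff = poff)
}

#' Run the synthetic-genome assembly benchmark
#'
#' Generates the benchmark design (by default 20 genes in each of the 1-4 exon
#' categories) for each seed, titrates every gene over the read-count levels,
#' and scores per-category accuracy by point of first failure: a gene counts
#' as accurately identified at an expression level `L` when its PoFF is below
#' `L` RPKE.
#'
#' @param seeds Integer vector of genome seeds (default `1:5`).
#' @param genes_per_category,categories Passed to [generate_test_genome()].
#' @param levels Read-count titration levels (see [titrate_gene()]).
#' @param config An [assembly_config()].
#' @param at_rpke Expression level (RPKE) at which headline accuracy is
#'   reported (default 100).
#' @return Object of class `"txtile_benchmark"`: `per_gene` (seed, gene,
#'   category, PoFF, whether the deepest level assembled correctly),
#'   `accuracy` (per category, pooled over seeds, at `at_rpke`),
#'   `accuracy_by_seed`, `accuracy_curve` (accuracy versus RPKE grid) and the
#'   run parameters.
#' @export
benchmark_assembly <- function(seeds = 1:5, genes_per_category = 20,
                               categories = 1:4,
                               levels = c(1000, 800, 600, 400, 200, 150, 100, 75, 50),
                               config = assembly_config(), at_rpke = 100) {
  per_gene <- vector("list", 0)
  for (sd in seeds) {
    tg <- generate_test_genome(seed = sd, genes_per_category = genes_per_category,
                               categories = categories,
                               read_len = config$read_len, sequence = FALSE)
    for (i in seq_len(nrow(tg$genes))) {
      g <- tg$genes[i, ]
      tt <- titrate_gene(g, levels = levels, config = config)
      per_gene[[length(per_gene) + 1]] <- tibble(
        seed = sd, gene_id = g$gene_id, category = g$category,
        footprint_nt = g$footprint_nt, poff = tt$poff,
        ok_at_max = tt$levels$ok[1]
      )
    }
  }
  per_gene <- dplyr::bind_rows(per_gene)
  accuracy <- per_gene |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$poff < at_rpke),
                     .groups = "drop")
  accuracy_by_seed <- per_gene |>
    dplyr::group_by(.data$seed, .data$category) |>
    dplyr::summarise(accuracy = mean(.data$poff < at_rpke), .groups = "drop")
  grid <- sort(unique(c(at_rpke, 50, 75, 100, 150, 200, 400, 600, 800, 1000)))
  accuracy_curve <- tidyr::expand_grid(category = sort(unique(per_gene$category)),
                                       rpke = grid) |>
    dplyr::rowwise() |>
    dplyr::mutate(accuracy = mean(
      per_gene$poff[per_gene$category == .data$category] < .data$rpke
    )) |>
    dplyr::ungroup()
  structure(
    list(per_gene = per_gene, accuracy = accuracy,
         accuracy_by_seed = accuracy_by_seed, accuracy_curve = accuracy_curve,
         at_rpke = at_rpke, levels = levels, seeds = seeds, config = config),
    class = "txtile_benchmark"
  )
}

#' @export
print.txtile_benchmark <- function(x, ...) {
  cat(sprintf("<txtile_benchmark> %d genes x %d seeds, accuracy at %g RPKE:\n",
              nrow(x$per_gene) / length(x$seeds), length(x$seeds), x$at_rpke))
  print(x$accuracy, n = Inf)
  invisible(x)
}

#' @rdname benchmark_assembly
#' @param x A `txtile_benchmark`.
#' @param ... Unused.
#' @method tidy txtile_benchmark
#' @export
tidy.txtile_benchmark <- function(x, ...) x$per_gene

#' @rdname benchmark_assembly
#' @method glance txtile_benchmark
#' @export
glance.txtile_benchmark <- function(x, ...) {
  tibble(
    n_genes = nrow(x$per_gene), at_rpke = x$at_rpke,
    min_category_accuracy = min(x$accuracy$accuracy),
    overall_accuracy = mean(x$per_gene$poff < x$at_rpke),
    plateau_accuracy = mean(x$per_gene$ok_at_max)
  )
}

#' Audit false positives against the truth set
#'
#' Counts assembled genes overlapping no truth locus (`extra`), truth loci
#' reported as more than one assembled gene (`split`, itemized by whether the
#' pieces could have been joined by a truth junction — a missing junction — or
#' reflect an internal coverage hole, a gap), and truth loci with no assembled
#' gene (`missed`).
#'
#' @param truth Truth gene-model tibble.
#' @param assembled Assembled gene-model tibble.
#' @return One-row tibble: `extra`, `split_loci`, `split_missing_junction`,
#'   `split_gap`, `missed`.
#' @export
false_positive_audit <- function(truth, assembled) {
  n_extra <- 0L
  split_loci <- 0L
  split_mj <- 0L
  split_gap <- 0L
  missed <- 0L
  if (nrow(assembled) > 0) {
    hit <- logical(nrow(assembled))
    for (ch in unique(assembled$chrom)) {
      ai <- which(assembled$chrom == ch)
      t <- truth[truth$chrom == ch, ]
      if (nrow(t) == 0) next
      ia <- IRanges::IRanges(assembled$span_start[ai] + 1L, assembled$span_end[ai])
      it <- IRanges::IRanges(t$span_start + 1L, t$span_end)
      hit[ai] <- IRanges::overlapsAny(ia, it)
    }
    n_extra <- sum(!hit)
  }
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    ov <- assembled[assembled$chrom == t$chrom &
                      assembled$span_start < t$span_end &
                      assembled$span_end > t$span_start, ]
    if (nrow(ov) == 0) {
      missed <- missed + 1L
    } else if (nrow(ov) > 1) {
      split_loci <- split_loci + 1L
      # boundary between adjacent pieces falls at a truth junction ->
      # missing junction; inside a truth exon -> gap
      ov <- dplyr::arrange(ov, .data$span_start)
      te <- t$exons[[1]]
      donors <- if (nrow(te) > 1) te$end[-nrow(te)] else integer(0)
      at_junction <- FALSE
      for (k in seq_len(nrow(ov) - 1)) {
        cutpos <- ov$span_end[k]
        if (any(abs(donors - cutpos) <= 5)) at_junction <- TRUE
      }
      if (at_junction) split_mj <- split_mj + 1L else split_gap <- split_gap + 1L
    }
  }
  tibble(extra = n_extra, split_loci = split_loci,
         split_missing_junction = split_mj, split_gap = split_gap,
         missed = missed)
}
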