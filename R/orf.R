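#' Extract the spliced transcript sequence of a gene model
#'
#' Concatenates the genomic sequence of each exon in coordinate order (introns
#' removed). Reverse-strand reading is handled downstream by the six-frame ORF
#' scan, not here.
#'
#' @param gene One-row gene-model tibble.
#' @param genome Genome as a `DNAStringSet` or FASTA path.
#' @return The spliced nucleotide sequence as a character string.
#' @export
splice_sequence <- function(gene, genome) {
  genome <- load_genome(genome)
  if (nrow(gene) != 1) {
    abort("splice_sequence() expects exactly one gene", class = "txtile_input_error")
  }
  ex <- gene$exons[[1]]
  if (is.null(ex) || nrow(ex) == 0) {
    abort("gene has no exons", class = "txtile_input_error")
  }
  chr <- genome[[gene$chrom]]
  if (is.null(chr)) {
    abort(sprintf("chromosome %s not in genome", gene$chrom),
          class = "txtile_input_error")
  }
  if (max(ex$end) > length(chr)) {
    abort("gene coordinates exceed chromosome length", class = "txtile_input_error")
  }
  parts <- Biostrings::extractAt(
    chr, IRanges::IRanges(ex$start + 1L, ex$end)
  )
  paste(as.character(parts), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Best ORF in the three forward frames of one oriented sequence. Returns NULL
# when no ATG exists.
scan_frames <- function(s) {
  n <- nchar(s)
  best <- NULL
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3
    if (n_codons < 1) next
    codons <- substring(s, frame + 1 + 3 * (seq_len(n_codons) - 1),
                        frame + 3 * seq_len(n_codons))
    atg <- which(codons == "ATG")
    if (length(atg) == 0) next
    stops <- which(codons %in% STOP_CODONS)
    # first ATG of each stop-free stretch gives the longest ORF in it
    nxt <- if (length(stops)) {
      stops[findInterval(atg, stops) + 1L]
    } else {
      rep(NA_integer_, length(atg))
    }
    len <- ifelse(is.na(nxt), n_codons - atg + 1L, nxt - atg)
    has_stop <- !is.na(nxt)
    k <- which.max(len)
    start0 <- frame + 3L * (atg[k] - 1L)
    cand <- tibble(
      frame = frame, start0 = start0,
      end0 = start0 + 3L * len[k] + if (has_stop[k]) 3L else 0L,
      length_codons = as.integer(len[k]), has_stop = has_stop[k]
    )
    if (is.null(best) ||
        cand$length_codons > best$length_codons ||
        (cand$length_codons == best$length_codons && cand$start0 < best$start0)) {
      best <- cand
    }
  }
  best
}

#' Find the longest open reading frame in a transcript sequence
#'
#' Scans three frames on both strands (the transcript strand is unknown for
#' unstranded data). An ORF runs from an ATG to the first in-frame stop codon;
#' its length in codons excludes the stop. An ATG with no downstream in-frame
#' stop yields an open-ended ORF flagged `has_stop = FALSE`. Ties are broken
#' in favour of the forward strand, then the earliest transcript coordinate.
#' A sequence with no ATG on either strand returns a zero-length call.
#'
#' @param seq Nucleotide sequence (character string, length >= 3).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return One-row tibble: `strand`, `frame` (0-2 on the reported strand),
#'   `start`, `end` (0-based half-open, forward-transcript coordinates of the
#'   ORF including its stop codon when present), `length_codons`, `has_stop`.
#' @examples
#' longest_orf("ATGAAATAG")  # 2 codons
#' @export
longest_orf <- function(seq, both_strands = TRUE) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 3) {
    abort("sequence must be at least 3 nt", class = "txtile_input_error")
  }
  n <- nchar(s)
  fw <- scan_frames(s)
  cands <- list()
  if (!is.null(fw)) {
    fw$strand <- "+"
    fw$start <- fw$start0
    fw$end <- fw$end0
    cands <- c(cands, list(fw))
  }
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rv <- scan_frames(rc)
    if (!is.null(rv)) {
      rv$strand <- "-"
      # map back to forward-transcript coordinates
      rv$start <- n - rv$end0
      rv$end <- n - rv$start0
      cands <- c(cands, list(rv))
    }
  }
  if (length(cands) == 0) {
    return(tibble(strand = "+", frame = NA_integer_, start = NA_integer_,
                  end = NA_integer_, length_codons = 0L, has_stop = FALSE))
  }
  all <- dplyr::bind_rows(cands) |>
    dplyr::arrange(dplyr::desc(.data$length_codons),
                   .data$strand != "+", .data$start)
  all[1, c("strand", "frame", "start", "end", "length_codons", "has_stop")]
}

#' Longest ORF per gene model
#'
#' Convenience wrapper: splices each gene's sequence and reports its longest
#' ORF.
#'
#' @param genes Gene-model tibble.
#' @param genome Genome (`DNAStringSet` or FASTA path).
#' @param both_strands Scan both strands (default `TRUE`).
#' @return Tibble with one row per gene: `gene_id` plus the [longest_orf()]
#'   columns.
#' @export
longest_orfs <- function(genes, genome, both_strands = TRUE) {
  genome <- load_genome(genome)
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), strand = character(),
                  frame = integer(), start = integer(), end = integer(),
                  length_codons = integer(), has_stop = logical()))
  }
  calls <- lapply(seq_len(nrow(genes)), function(i) {
    s <- splice_sequence(genes[i, ], genome)
    dplyr::mutate(longest_orf(s, both_strands = both_strands),
                  gene_id = genes$gene_id[i], .before = 1)
  })
  dplyr::bind_rows(calls)
}

#' Classify ORF calls by codon length
#'
#' ORFs below `min_codons` are unlikely to encode proteins and are classed as
#' likely non-coding; random sequence is statistically unlikely to stay
#' stop-free for more than ~50 codons, so longer ORFs suggest real coding
#' genes. Calls are additionally binned by codon length for histogramming.
#'
#' @param calls ORF-call tibble from [longest_orfs()].
#' @param min_codons Coding cutoff in codons (default 40); a call at exactly
#'   the cutoff is classed coding.
#' @param bin_width Width of the histogram bins in codons (default 80).
#' @return `calls` with added `class` and `length_bin` columns.
#' @export
classify_coding <- function(calls, min_codons = 40, bin_width = 80) {
  breaks <- seq(0, max(c(calls$length_codons, bin_width)) + bin_width, bin_width)
  calls |>
    dplyr::mutate(
      class = ifelse(.data$length_codons < min_codons,
                     "likely non-coding", "likely coding"),
      length_bin = cut(.data$length_codons, breaks = breaks, right = FALSE)
    )
}

#' Write ORF peptides to FASTA
#'
#' Translates each called ORF (standard genetic code) and writes a peptide
#' FASTA; zero-length calls are skipped.
#'
#' @param calls ORF-call tibble from [longest_orfs()].
#' @param genes The gene-model tibble the calls came from.
#' @param genome Genome (`DNAStringSet` or FASTA path).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(calls, genes, genome, path) {
  genome <- load_genome(genome)
  keep <- calls[calls$length_codons > 0, ]
  peps <- character(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    g <- genes[genes$gene_id == keep$gene_id[i], ]
    s <- splice_sequence(g, genome)
    orf <- substr(s, keep$start[i] + 1, keep$end[i])
    if (keep$strand[i] == "-") {
      orf <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
    }
    nt <- substr(orf, 1, 3 * keep$length_codons[i])
    peps[i] <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  }
  aa <- Biostrings::AAStringSet(peps)
  names(aa) <- keep$gene_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
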