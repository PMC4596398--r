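# Fixture builders shared across test files. Everything is generated in code;
# no binary files are stored.

# Uniform read blocks over a genomic interval (unspliced), step chosen so
# coverage is contiguous.
make_tiled_blocks <- function(chrom, start, end, n_reads, read_len = 50,
                              prefix = "r") {
  stopifnot(end - start >= read_len)
  pos <- round(seq(start, end - read_len, length.out = n_reads))
  tibble::tibble(
    chrom = chrom, start = as.integer(pos), end = as.integer(pos + read_len),
    read_id = sprintf("%s%05d", prefix, seq_len(n_reads))
  )
}

# Write a SAM file with the given records (list of lists with qname, flag,
# pos (1-based), mapq, cigar).
write_test_sam <- function(records, path, chrom = "chr1", chrom_len = 1000000L) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(records, function(r) {
    mapped <- !bitwAnd(r$flag, 4L)
    paste(r$qname, r$flag, if (mapped) chrom else "*",
          if (mapped) r$pos else 0L, r$mapq %||% 60L,
          if (mapped) r$cigar else "*", "*", 0L, 0L, "*", "*", sep = "\t")
  }, "")
  ord <- order(vapply(records, function(r) {
    if (bitwAnd(r$flag, 4L)) .Machine$integer.max else as.integer(r$pos)
  }, integer(1)))
  writeLines(c(header, body[ord]), path)
  path
}

random_cigar <- function() {
  n_seg <- sample(1:4, 1)
  parts <- character(0)
  if (runif(1) < 0.3) parts <- c(parts, paste0(sample(1:10, 1), "S"))
  for (i in seq_len(n_seg)) {
    m <- sample(10:60, 1)
    seg <- paste0(m, "M")
    if (runif(1) < 0.3) {
      seg <- paste0(seg, sample(1:5, 1), if (runif(1) < 0.5) "I" else "D",
                    sample(5:30, 1), "M")
    }
    parts <- c(parts, seg)
    if (i < n_seg) parts <- c(parts, paste0(sample(60:800, 1), "N"))
  }
  if (runif(1) < 0.3) parts <- c(parts, paste0(sample(1:10, 1), "S"))
  paste(parts, collapse = "")
}

# A gene-model tibble built from a list of exon matrices (2 columns).
make_genes <- function(exon_sets, chrom = "chr1", ids = NULL, rpke = NULL) {
  ids <- ids %||% sprintf("g%02d", seq_along(exon_sets))
  ex <- dplyr::bind_rows(lapply(seq_along(exon_sets), function(i) {
    m <- exon_sets[[i]]
    tibble::tibble(gene_id = ids[i], chrom = chrom,
                   start = m[, 1], end = m[, 2])
  }))
  g <- gene_models(ex)
  if (!is.null(rpke)) g$rpke <- rpke[match(g$gene_id, ids)]
  g
}

# Random DNA of length n as a character string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
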