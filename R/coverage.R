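#' Build an in-memory coverage index from read blocks
#'
#' Indexes aligned read blocks per chromosome for fast depth, read-start and
#' overlap queries. This is the in-memory equivalent of the database the
#' assembler queries: every downstream stage (tiling, short-exon inference,
#' splitting, gene RPKE) reads from it rather than rescanning the alignments.
#'
#' @param blocks Tibble of read blocks with columns `chrom`, `start` (0-based
#'   inclusive), `end` (0-based exclusive) and `read_id`. Spliced reads
#'   contribute one row per aligned block, sharing a `read_id`.
#' @return An object of class `"coverage_index"`.
#' @examples
#' blocks <- tibble::tibble(chrom = "chr1", start = c(0L, 30L),
#'                          end = c(50L, 80L), read_id = c("r1", "r2"))
#' cov <- coverage_index(blocks)
#' cov$n_blocks
#' @export
coverage_index <- function(blocks) {
  blocks <- as_tibble(blocks)
  need <- c("chrom", "start", "end", "read_id")
  if (!all(need %in% names(blocks))) {
    abort("blocks must have columns chrom, start, end, read_id",
          class = "txtile_input_error")
  }
  if (nrow(blocks) > 0 && any(blocks$end <= blocks$start)) {
    abort("read blocks must satisfy end > start", class = "txtile_input_error")
  }
  chroms <- list()
  if (nrow(blocks) > 0) {
    bc <- blocks$chrom
    bs <- blocks$start
    be <- blocks$end
    bid <- blocks$read_id
    for (ch in unique(bc)) {
      sel <- bc == ch
      ir <- IRanges::IRanges(start = bs[sel] + 1L, end = be[sel])
      chroms[[ch]] <- list(
        ir = ir,
        read_id = bid[sel],
        depth = IRanges::coverage(ir),
        starts = IRanges::coverage(IRanges::IRanges(start = bs[sel] + 1L, width = 1L))
      )
    }
  }
  structure(
    list(blocks = blocks, chroms = chroms, n_blocks = nrow(blocks)),
    class = "coverage_index"
  )
}

#' @export
print.coverage_index <- function(x, ...) {
  cat(sprintf("<coverage_index> %d blocks, %d reads, %d chromosome(s)\n",
              x$n_blocks, dplyr::n_distinct(x$blocks$read_id),
              length(x$chroms)))
  invisible(x)
}

# Distinct reads overlapping each interval (0-based half-open), per row of
# `ivs` (tibble with chrom, start, end). A spliced read overlapping through
# two of its blocks is counted once.
count_reads_in <- function(cov, ivs) {
  n <- nrow(ivs)
  out <- integer(n)
  if (n == 0) return(out)
  for (ch in unique(ivs$chrom)) {
    idx <- which(ivs$chrom == ch)
    cc <- cov$chroms[[ch]]
    if (is.null(cc)) next
    q <- IRanges::IRanges(start = ivs$start[idx] + 1L, end = ivs$end[idx])
    hits <- IRanges::findOverlaps(q, cc$ir)
    if (length(hits) == 0) next
    ids <- cc$read_id[S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    dup <- duplicated(paste0(qh, "\r", ids))
    cnt <- tabulate(qh[!dup], nbins = length(idx))
    out[idx] <- cnt
  }
  out
}

# Number of read-block start positions falling in each interval
# (0-based half-open).
count_starts_in <- function(cov, ivs) {
  n <- nrow(ivs)
  out <- integer(n)
  if (n == 0) return(out)
  for (ch in unique(ivs$chrom)) {
    idx <- which(ivs$chrom == ch)
    cc <- cov$chroms[[ch]]
    if (is.null(cc)) next
    rl <- cc$starts
    len <- length(rl)
    s1 <- pmin(pmax(ivs$start[idx] + 1L, 1L), len + 1L)
    e1 <- pmin(ivs$end[idx], len)
    ok <- which(e1 >= s1)
    if (length(ok) == 0) next
    v <- IRanges::Views(rl, start = s1[ok], end = e1[ok])
    out[idx[ok]] <- as.integer(IRanges::viewSums(v))
  }
  out
}

# Recompute read_count and rpke columns of a fragment tibble from coverage.
refresh_fragment_counts <- function(frags, cov) {
  if (nrow(frags) == 0) return(frags)
  frags$read_count <- count_reads_in(cov, frags)
  frags$rpke <- frags$read_count * 1000 / (frags$end - frags$start)
  frags
}
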