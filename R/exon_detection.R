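#' Tile read coverage into candidate exon fragments
#'
#' Segments each chromosome into maximal intervals of read coverage (depth
#' >= 1) and keeps those whose expression is at least `min_rpke`. RPKE (reads
#' per kilobase of exon) is the number of distinct reads overlapping the
#' fragment, scaled to a 1 kb footprint: `read_count * 1000 / width`. A
#' fragment exactly at the threshold is kept.
#'
#' @param cov A [coverage_index()].
#' @param min_rpke Minimum RPKE for a fragment to be retained (default 50;
#'   lower values admit noise reads as exons).
#' @return Fragment tibble (`chrom`, `start`, `end`, `read_count`, `rpke`,
#'   `origin = "tiling"`), sorted and disjoint.
#' @export
tile_fragments <- function(cov, min_rpke = 50) {
  if (cov$n_blocks == 0) return(empty_fragments())
  chs <- character(0)
  sts <- integer(0)
  ens <- integer(0)
  for (ch in names(cov$chroms)) {
    sl <- IRanges::slice(cov$chroms[[ch]]$depth, lower = 1, rangesOnly = TRUE)
    if (length(sl) == 0) next
    chs <- c(chs, rep(ch, length(sl)))
    sts <- c(sts, IRanges::start(sl) - 1L)
    ens <- c(ens, IRanges::end(sl))
  }
  if (length(sts) == 0) return(empty_fragments())
  frags <- new_fragments(chs, sts, ens, origin = "tiling")
  frags <- refresh_fragment_counts(frags, cov)
  frags <- frags[frags$rpke >= min_rpke, ]
  frags[order(frags$chrom, frags$start), ]
}

empty_fragments <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         read_count = integer(), rpke = numeric(), origin = character())
}

new_fragments <- function(chrom, start, end, read_count = NA_integer_,
                          rpke = NA_real_, origin = NA_character_) {
  n <- length(start)
  tibble::new_tibble(list(
    chrom = unname(chrom),
    start = as.integer(unname(start)),
    end = as.integer(unname(end)),
    read_count = rep_len(as.integer(unname(read_count)), n),
    rpke = rep_len(as.numeric(unname(rpke)), n),
    origin = rep_len(unname(origin), n)
  ), nrow = n)
}

#' Recover short exons from junction half-alignments
#'
#' Exons shorter than the read length attract few or no direct alignments and
#' are missed by tiling. They are, however, bracketed by junctions: whenever
#' the acceptor of one junction and the donor of a downstream junction on the
#' same chromosome are closer than the read length, the interval between them
#' is emitted as an inferred exon. Inferred exons take whatever read coverage
#' exists (possibly zero) and are exempt from the RPKE filter. Inferred
#' fragments fully contained in an existing fragment are suppressed as
#' duplicates.
#'
#' @param junctions Junction tibble.
#' @param read_len Read length in nt; only gaps strictly shorter than this are
#'   inferred (longer exons are expected to be found by tiling).
#' @param cov A [coverage_index()] used to attach read counts.
#' @param existing Optional fragment tibble already detected (for duplicate
#'   suppression).
#' @return Fragment tibble with `origin = "junction_inferred"`.
#' @export
infer_short_exons <- function(junctions, read_len, cov, existing = NULL) {
  out <- empty_fragments()
  if (is.null(junctions) || nrow(junctions) < 2) return(out)
  chs <- character(0)
  sts <- integer(0)
  ens <- integer(0)
  for (ch in unique(junctions$chrom)) {
    sel <- junctions$chrom == ch
    acc <- sort(unique(junctions$acceptor_start[sel]))
    don <- sort(unique(junctions$donor_end[sel]))
    for (a in acc) {
      d <- don[don > a & don - a < read_len]
      if (length(d) > 0) {
        chs <- c(chs, rep(ch, length(d)))
        sts <- c(sts, rep(as.integer(a), length(d)))
        ens <- c(ens, as.integer(d))
      }
    }
  }
  if (length(sts) == 0) return(out)
  cands <- new_fragments(chs, sts, ens, origin = "junction_inferred")
  cands <- cands[!duplicated(paste0(cands$chrom, "\r", cands$start, "\r",
                                    cands$end)), ]
  if (!is.null(existing) && nrow(existing) > 0) {
    contained <- logical(nrow(cands))
    for (ch in unique(cands$chrom)) {
      ci <- which(cands$chrom == ch)
      ei <- which(existing$chrom == ch)
      if (length(ei) == 0) next
      q <- IRanges::IRanges(cands$start[ci] + 1L, cands$end[ci])
      s <- IRanges::IRanges(existing$start[ei] + 1L, existing$end[ei])
      contained[ci] <- IRanges::overlapsAny(q, s, type = "within")
    }
    cands <- cands[!contained, ]
  }
  if (nrow(cands) == 0) return(out)
  cands <- refresh_fragment_counts(cands, cov)
  cands[order(cands$chrom, cands$start), ]
}

#' Merge closely spaced exon fragments
#'
#' Coverage gaps inside weakly expressed exons fragment them; fragments on the
#' same chromosome whose gap is at most `max_gap` nt are coalesced into one
#' fragment spanning the gap (a read-through assumption). Overlapping inputs
#' are unioned. Read counts are summed and RPKE recomputed on the merged
#' width. The operation is idempotent.
#'
#' @param frags Fragment tibble (sorted; overlaps allowed).
#' @param max_gap Maximum gap (nt) closed by merging; a gap of exactly
#'   `max_gap` merges.
#' @return Fragment tibble, sorted and disjoint; merged rows get
#'   `origin = "merged"`.
#' @export
merge_close_fragments <- function(frags, max_gap = 50) {
  if (nrow(frags) <= 1) return(frags)
  ord <- order(frags$chrom, frags$start, frags$end)
  chm <- frags$chrom[ord]
  st <- frags$start[ord]
  en <- frags$end[ord]
  rc <- frags$read_count[ord]
  og <- frags$origin[ord]
  n <- length(ord)
  run_max <- en
  grp <- integer(n)
  g <- 1L
  grp[1] <- 1L
  for (i in seq_len(n)[-1]) {
    if (chm[i] != chm[i - 1] || st[i] - run_max[i - 1] > max_gap) {
      g <- g + 1L
    } else {
      run_max[i] <- max(run_max[i], run_max[i - 1])
    }
    grp[i] <- g
  }
  first <- which(!duplicated(grp))
  sizes <- tabulate(grp)
  out <- new_fragments(
    chrom = chm[first],
    start = st[first],
    end = vapply(split(en, grp), max, numeric(1)),
    read_count = as.integer(rowsum(as.numeric(rc), grp)[, 1]),
    origin = ifelse(sizes > 1, "merged", og[first])
  )
  out$rpke <- out$read_count * 1000 / (out$end - out$start)
  out
}

#' Split merged fragments at internal junctions and trim to junction edges
#'
#' Intron retention, pre-mRNA and noise put reads inside introns, which can
#' weld two exons into one fragment. For every junction whose donor and
#' acceptor both fall strictly inside one fragment, the read-start density
#' inside the putative intron is compared with the density in the exonic
#' windows flanking it: when the intronic density is below `density_ratio`
#' times the flank density, junction evidence dominates and the fragment is
#' split into `[start, donor_end)` and `[acceptor_start, end)`, discarding the
#' intronic reads as retention/noise. Otherwise the retained intron is kept
#' (longest-isoform policy). Afterwards, fragment boundaries that overshoot a
#' connecting junction edge by less than `read_len` are snapped to the edge;
#' terminal gene ends (no junction on that side) are never trimmed. The
#' operation is a no-op on its own output.
#'
#' @param frags Fragment tibble (sorted, disjoint).
#' @param junctions Junction tibble.
#' @param cov A [coverage_index()] (provides the read-start densities and the
#'   recomputed counts).
#' @param density_ratio Intron call threshold in (0, 1]; default 0.5, i.e. an
#'   intron is called when intronic read density is below 50% of the flanks.
#' @param flank_window Width (nt) of the flanking windows used for the density
#'   comparison; defaults to `read_len`.
#' @param read_len Read length (nt), the trimming distance.
#' @return Fragment tibble; split pieces get `origin = "split"`.
#' @export
split_at_internal_junctions <- function(frags, junctions, cov,
                                        density_ratio = 0.5,
                                        flank_window = NULL,
                                        read_len = 50) {
  if (nrow(frags) == 0 || is.null(junctions) || nrow(junctions) == 0) {
    return(frags)
  }
  flank_window <- flank_window %||% read_len
  jc <- junctions$chrom
  jd <- junctions$donor_end
  ja <- junctions$acceptor_start
  n <- nrow(frags)
  chs <- character(0); sts <- integer(0); ens <- integer(0); ogs <- character(0)
  for (i in seq_len(n)) {
    fch <- frags$chrom[i]
    fst <- frags$start[i]
    fen <- frags$end[i]
    inside <- which(jc == fch & jd > fst & jd < fen & ja > fst & ja < fen & jd < ja)
    if (length(inside) == 0) {
      chs <- c(chs, fch); sts <- c(sts, fst); ens <- c(ens, fen)
      ogs <- c(ogs, frags$origin[i])
      next
    }
    d <- jd[inside]
    a <- ja[inside]
    intr <- tibble(chrom = fch, start = d, end = a)
    intr_dens <- count_starts_in(cov, intr) / (a - d)
    fl <- tibble(
      chrom = fch,
      start = c(pmax(fst, d - flank_window), a),
      end = c(d, pmin(fen, a + flank_window))
    )
    fl_starts <- count_starts_in(cov, fl)
    k <- length(inside)
    flank_len <- (fl$end - fl$start)[1:k] + (fl$end - fl$start)[(k + 1):(2 * k)]
    flank_cnt <- fl_starts[1:k] + fl_starts[(k + 1):(2 * k)]
    flank_dens <- ifelse(flank_len > 0, flank_cnt / flank_len, 0)
    ratio <- ifelse(intr_dens == 0, 0,
                    ifelse(flank_dens == 0, Inf, intr_dens / flank_dens))
    cut_i <- inside[ratio < density_ratio]
    if (length(cut_i) == 0) {
      chs <- c(chs, fch); sts <- c(sts, fst); ens <- c(ens, fen)
      ogs <- c(ogs, frags$origin[i])
      next
    }
    o <- order(jd[cut_i], ja[cut_i])
    cd <- jd[cut_i][o]
    ca <- ja[cut_i][o]
    # greedy non-overlapping intron selection, left to right
    sel <- logical(length(cd))
    last_end <- fst
    for (r in seq_along(cd)) {
      if (cd[r] > last_end) {
        sel[r] <- TRUE
        last_end <- ca[r]
      }
    }
    cd <- cd[sel]; ca <- ca[sel]
    piece_st <- c(fst, ca)
    piece_en <- c(cd, fen)
    chs <- c(chs, rep(fch, length(piece_st)))
    sts <- c(sts, piece_st)
    ens <- c(ens, piece_en)
    ogs <- c(ogs, rep("split", length(piece_st)))
  }
  out <- new_fragments(chs, sts, ens, origin = ogs)
  out <- trim_to_junctions(out, junctions, read_len)
  out <- out[out$end > out$start, ]
  out <- refresh_fragment_counts(out, cov)
  out[order(out$chrom, out$start), ]
}

# Snap fragment boundaries that overshoot a junction edge by < read_len to
# that edge, but only when the junction connects the fragment to another
# fragment on its far side (terminal ends stay untouched).
trim_to_junctions <- function(frags, junctions, read_len) {
  if (nrow(frags) == 0 || nrow(junctions) == 0) return(frags)
  fst <- frags$start
  fen <- frags$end
  fch <- frags$chrom
  for (ch in unique(fch)) {
    fi <- which(fch == ch)
    ji <- which(junctions$chrom == ch)
    if (length(ji) == 0) next
    for (r in ji) {
      de <- junctions$donor_end[r]
      ac <- junctions$acceptor_start[r]
      acc_ok <- any(fst[fi] < ac + read_len & fen[fi] > ac)
      don_ok <- any(fst[fi] < de & fen[fi] > de - read_len)
      over <- fi[fst[fi] < de & fen[fi] > de & fen[fi] - de < read_len]
      if (length(over) > 0 && acc_ok) fen[over] <- de
      under <- fi[fen[fi] > ac & fst[fi] < ac & ac - fst[fi] < read_len]
      if (length(under) > 0 && don_ok) fst[under] <- ac
    }
  }
  frags$start <- as.integer(fst)
  frags$end <- as.integer(fen)
  frags
}
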