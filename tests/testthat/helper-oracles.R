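# Independent oracles used to cross-check the implementation. These are
# deliberately naive (per-base arrays, exhaustive enumeration) and share no
# code with the package internals.

# Walk a CIGAR string against the reference: returns 0-based half-open blocks.
# M/=/X/D consume reference (D stays inside a block); N splits blocks;
# I/S/H/P consume none.
oracle_cigar_blocks <- function(cigar, pos1) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  ref <- pos1 - 1L  # 0-based cursor
  blocks <- list()
  cur_start <- NA_integer_
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    type <- sub("^\\d+", "", op)
    if (type %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- ref
      ref <- ref + n
    } else if (type == "N") {
      if (!is.na(cur_start)) {
        blocks[[length(blocks) + 1]] <- c(cur_start, ref)
        cur_start <- NA_integer_
      }
      ref <- ref + n
    }
    # I, S, H, P: no reference advance
  }
  if (!is.na(cur_start)) blocks[[length(blocks) + 1]] <- c(cur_start, ref)
  do.call(rbind, blocks)
}

# Per-base coverage segmentation: maximal runs of depth >= 1 from an explicit
# position array.
oracle_coverage_islands <- function(starts, ends, len) {
  depth <- integer(len)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):ends[i]
    depth[idx] <- depth[idx] + 1L
  }
  r <- rle(depth >= 1)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  keep <- r$values
  cbind(start = begins[keep] - 1L, end = stops[keep])
}

# Transitive-closure interval merging with a gap threshold: repeatedly union
# any two intervals within max_gap until a fixed point.
oracle_merge_gap <- function(iv, max_gap) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  repeat {
    changed <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      if (iv[i + 1, 1] - iv[i, 2] <= max_gap) {
        iv[i, 2] <- max(iv[i, 2], iv[i + 1, 2])
        iv <- iv[-(i + 1), , drop = FALSE]
        changed <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!changed) break
  }
  iv
}

# Connected components by label propagation to a fixed point.
oracle_union_find <- function(n, edges) {
  comp <- seq_len(n)
  if (length(edges) > 0) {
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(edges))) {
        a <- comp[edges[k, 1]]
        b <- comp[edges[k, 2]]
        if (a != b) {
          comp[comp == max(a, b)] <- min(a, b)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  comp
}

# Exhaustive longest-ORF search: every ATG in every frame on both strands,
# walking codon by codon to the first stop.
oracle_longest_orf <- function(seq) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  stops <- c("TAA", "TAG", "TGA")
  best <- list(len = 0L, has_stop = FALSE)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n <- nchar(s)
    for (i in seq_len(max(n - 2, 0))) {
      if (substr(s, i, i + 2) != "ATG") next
      len <- 0L
      has_stop <- FALSE
      p <- i
      while (p + 2 <= n) {
        cod <- substr(s, p, p + 2)
        if (p > i && cod %in% stops) {
          has_stop <- TRUE
          break
        }
        len <- len + 1L
        p <- p + 3
      }
      if (len > best$len) best <- list(len = len, has_stop = has_stop)
    }
  }
  best
}

# Pairwise containment: drop intervals-set A when fully covered by another
# transcript's interval set.
oracle_contained <- function(exon_sets) {
  covered_by <- function(a, b) {
    pos_a <- unlist(mapply(function(s, e) (s + 1):e, a$start, a$end,
                           SIMPLIFY = FALSE))
    pos_b <- unlist(mapply(function(s, e) (s + 1):e, b$start, b$end,
                           SIMPLIFY = FALSE))
    all(pos_a %in% pos_b)
  }
  n <- length(exon_sets)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      if (covered_by(exon_sets[[i]], exon_sets[[j]])) {
        ident <- covered_by(exon_sets[[j]], exon_sets[[i]])
        if (!ident || j < i) {
          drop[i] <- TRUE
          break
        }
      }
    }
  }
  drop
}
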