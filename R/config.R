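#' Assembly and filtering configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated list.
#' Defaults are the values used throughout the package's analyses: exon
#' detection at 50 RPKE, a 50 nt merge gap matched to the read length, a
#' 50,000 nt cap on junction spans, a 140 nt minimum gene footprint, a
#' 100 RPKE minimum for calling an expressed gene, 75%/5% annotation-overlap
#' bounds, a 25% genome-similarity ceiling for novel genes, a 50% relative
#' read-density rule for intron retention, and a 40-codon coding cutoff.
#'
#' @param min_exon_rpke Minimum reads per kilobase of exon (RPKE) for a tiled
#'   coverage island to be kept as a candidate exon.
#' @param min_gene_rpke Minimum gene-level RPKE for the expression filter used
#'   in novel-gene screening.
#' @param merge_gap Maximum gap (nt) between adjacent exon fragments that is
#'   closed by merging.
#' @param read_len Read length (nt); also the default flank window for the
#'   intron-retention density rule and the trimming distance.
#' @param max_junction_span Junctions with intron span greater than this (nt)
#'   are discarded as likely mapping artefacts.
#' @param max_skip_span Junctions whose intron fully contains another exon
#'   fragment are discarded when their span exceeds this (nt).
#' @param min_footprint Minimum summed exonic length (nt) of a gene model.
#' @param overlap_hi Annotation-overlap fraction at or above which an
#'   assembled gene is classed as annotated.
#' @param overlap_lo Annotation-overlap fraction below which an assembled gene
#'   is classed as novel.
#' @param max_similarity Maximum percent of a gene's spliced sequence allowed
#'   to align elsewhere in the genome for it to remain a novel-gene candidate.
#' @param density_ratio Intron-retention rule: a junction inside a fragment is
#'   treated as a real intron (and the fragment split) when the read-start
#'   density inside the putative intron is below this fraction of the density
#'   in the flanking exonic windows.
#' @param min_orf_codons ORFs shorter than this many codons are classed as
#'   likely non-coding.
#' @param link_tol Tolerance (nt) when matching exon-fragment boundaries to
#'   junction donor/acceptor coordinates during gene linking. Boundaries are
#'   snapped to junction edges during splitting, so 0 is exact; a small value
#'   (e.g. 5) tolerates off-by-ones in externally produced inputs.
#' @param seed Optional integer seed recorded in the config and used by
#'   simulation helpers when they are not given one explicitly.
#'
#' @return A list of class `"assembly_config"`.
#' @examples
#' cfg <- assembly_config(min_exon_rpke = 50)
#' cfg$merge_gap
#' @export
assembly_config <- function(min_exon_rpke = 50,
                            min_gene_rpke = 100,
                            merge_gap = 50,
                            read_len = 50,
                            max_junction_span = 50000,
                            max_skip_span = 50000,
                            min_footprint = 140,
                            overlap_hi = 0.75,
                            overlap_lo = 0.05,
                            max_similarity = 25,
                            density_ratio = 0.5,
                            min_orf_codons = 40,
                            link_tol = 0,
                            seed = NULL) {
  cfg <- list(
    min_exon_rpke = min_exon_rpke, min_gene_rpke = min_gene_rpke,
    merge_gap = merge_gap, read_len = read_len,
    max_junction_span = max_junction_span, max_skip_span = max_skip_span,
    min_footprint = min_footprint, overlap_hi = overlap_hi,
    overlap_lo = overlap_lo, max_similarity = max_similarity,
    density_ratio = density_ratio, min_orf_codons = min_orf_codons,
    link_tol = link_tol, seed = seed
  )
  num <- cfg[setdiff(names(cfg), "seed")]
  if (!all(vapply(num, is.numeric, logical(1))) ||
      any(vapply(num, function(x) length(x) != 1 || is.na(x) || x < 0, logical(1)))) {
    abort("all configuration thresholds must be single non-negative numbers",
          class = "txtile_config_error")
  }
  if (cfg$read_len < 1) {
    abort("read_len must be at least 1", class = "txtile_config_error")
  }
  if (cfg$density_ratio > 1 || cfg$density_ratio <= 0) {
    abort("density_ratio must be in (0, 1]", class = "txtile_config_error")
  }
  if (cfg$overlap_lo >= cfg$overlap_hi) {
    abort("overlap_lo must be below overlap_hi", class = "txtile_config_error")
  }
  structure(cfg, class = "assembly_config")
}

#' @export
print.assembly_config <- function(x, ...) {
  cat("<assembly_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  }
  invisible(x)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Unknown keys are rejected so that typos fail loudly.
#'
#' @param path Path to the configuration file.
#' @return An [assembly_config()] object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(assembly_config())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(paste0("malformed config line: ", lines[which(bad)[1]]),
          class = "txtile_config_error")
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  allowed <- names(formals(assembly_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "txtile_config_error")
  }
  do.call(assembly_config, as.list(setNames(vals, keys)))
}
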