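---
title: "Read-tiling transcript assembly: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-tiling transcript assembly: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txtile)
```

## The problem and the approach

Genome-guided transcript assemblers reconstruct transcribed gene models from
short-read RNA-seq alignments without relying on existing annotation. txtile
implements a deliberately heuristic, single-isoform assembler built on two
kinds of evidence:

* **read tiling** — contiguous islands of overlapping read alignments mark
  exons;
* **splice-junction alignments** — reads split across an intron by the
  aligner mark exon–exon joins.

The pipeline has a fixed order (each stage consumes the previous stage's
output):

1. **Tile**: maximal coverage islands become exon fragments, kept when their
   expression is at least `min_exon_rpke` RPKE. RPKE — reads per kilobase of
   exon — is `reads × 1000 / exonic length`; it is deliberately
   library-size-unnormalized, because the threshold is about absolute read
   support, not relative abundance.
2. **Recover short exons**: an exon shorter than the read length attracts few
   or no whole-read alignments regardless of expression, but it is bracketed
   by two junctions whose inner edges are closer than a read length. The
   interval between such junction pairs is emitted as an inferred exon,
   exempt from the RPKE filter (its direct coverage may legitimately be
   zero).
3. **Merge**: fragments separated by at most `merge_gap` nt are coalesced,
   closing coverage holes in weakly expressed exons. The merged fragment
   spans the gap (a read-through assumption); read counts are summed.
4. **Split and trim**: intron retention, pre-mRNA and noise place reads
   inside introns and can weld two exons into one fragment. For a junction
   whose two edges both fall strictly inside a fragment, we compare
   read-*start* density inside the putative intron with the density in the
   `flank_window` of exonic sequence on either side. When the intronic
   density is below `density_ratio` (default 50%) of the flank density, the
   junction wins: the fragment is split at the junction edges and the
   intronic reads are discarded as retention/noise. Otherwise the retained
   intron is kept — the assembler's goal is the most common isoform, and
   intron retention is the most common alternative form. Fragment ends that
   overshoot a connecting junction edge by less than a read length are
   snapped to the edge; terminal gene ends are never trimmed because no
   junction defines them.
5. **Link**: junctions whose donor matches one fragment's end and whose
   acceptor matches another fragment's start (within `link_tol`) become
   edges of a splice graph. Each connected component is reported as one gene
   containing *all* of the component's exons — the longest possible single
   isoform, by design. Isoform enumeration is explicitly out of scope.

Junctions are vetted before linking: spans above `max_junction_span` are
discarded as mapping artefacts, and junctions that skip over a detected exon
are discarded above `max_skip_span`. After linking, models with less than
`min_footprint` nt of exonic sequence are dropped; such tiny high-coverage
islands are the signature of multimapping noise.

### Why read-start density for the intron-retention rule

The 50% rule compares "density of reads aligning" in the putative intron
against the adjacent regions. Mean *depth* depends on fragment length and
read length; mean *read-start count per nt* is length-independent and equals
depth/read-length in expectation, so the ratio of the two densities is the
same in expectation but better behaved on short windows. The window width
defaults to the read length and is configurable (`flank_window`).

### Coordinates and containers

All internal coordinates are 0-based half-open; GTF and BED conventions are
converted at the boundary (GTF in/out is 1-based inclusive). Gene models are
a nested tibble — one row per gene, an `exons` list-column — so results chain
through dplyr verbs; alignment, junction and fragment tables are flat
tibbles. Coverage queries run on run-length encodings (IRanges) built once
per assembly.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_exon_rpke` | 50 | RPKE | tiling threshold; below it, noise islands become exons |
| `min_gene_rpke` | 100 | RPKE | expression floor for calling an expressed/novel gene |
| `merge_gap` | 50 | nt | maximum coverage hole closed by merging (≈ one read) |
| `read_len` | 50 | nt | read length; also flank window and trim distance |
| `max_junction_span` | 50,000 | nt | hard cap on intron span |
| `max_skip_span` | 50,000 | nt | cap on exon-skipping junction span |
| `min_footprint` | 140 | nt | minimum exonic length of a reported gene |
| `overlap_hi` / `overlap_lo` | 0.75 / 0.05 | fraction | annotated / novel class boundaries |
| `max_similarity` | 25 | % | genome-similarity ceiling for novel genes |
| `density_ratio` | 0.5 | fraction | intron-retention decision rule |
| `min_orf_codons` | 40 | codons | likely-coding boundary |

The defaults are a matched set: with 50 nt reads, a 50 nt merge gap is the
largest hole a single read could have covered, and 50 RPKE is the level at
which exon calls stop picking up scattered noise. The gene-level floor of
100 RPKE is where the synthetic benchmark (below) shows assembly accuracy of
at least 85% across exon-count categories. The footprint floor reflects the
observed size of multimapping noise islands (< 140 nt). All are
configurable through `assembly_config()`.

## The novel-gene cascade

Candidate novel genes are assembled genes whose exonic footprint overlaps
annotated gene spans by less than `overlap_lo`. Overlap is computed against
annotated gene *spans* (start to termination), not exon structures, because
the comparison asks whether the locus is known at all. Candidates then pass
through containment de-duplication (a transcript wholly inside another is
the same gene), the footprint and expression floors, and a genome-similarity
screen. Genes between the two overlap bounds are reported as `intermediate`
— plausibly unannotated splice forms of known genes — and not treated as
novel.

The similarity screen asks: what fraction of this gene's spliced sequence
also occurs elsewhere in the genome? Since reads that map equally well to
two loci are assigned arbitrarily, a high-similarity "novel" gene is likely
an alignment mirage. The built-in method seeds exact 16-mers of the spliced
sequence across the genome, chains seeds on the same diagonal, extends
ungapped while identity stays ≥ 0.9, discards hits overlapping the gene's
own locus, and reports covered-fraction × 100. We define "percent
similarity" as query coverage at high identity — the published figure could
also be read as alignment identity, but coverage is the quantity that
measures how much of the gene could be a mapping artefact. Word size and
identity are configurable, and a pre-computed tabular alignment can be
substituted by filtering on its coverage directly.

When a second assembler's GTF is supplied, both sources run the same cascade
and genes are matched across sources by any same-chromosome footprint
overlap (≥ 1 nt); exclusive and shared counts plus the union — the
high-confidence novel set — are reported. By construction
`exclusive_A + exclusive_B + shared = |union|`.

## ORF analysis

For each gene the introns are removed and the longest open reading frame is
taken over three frames on both strands (the data are treated as unstranded
throughout; strand is only decided here, by the ORF itself). An ORF runs
from ATG to the first in-frame stop; its length in codons excludes the stop,
and an unterminated ORF is reported with `has_stop = FALSE`. Calls below
`min_orf_codons` (default 40) are classed likely non-coding. A useful
calibration: a random in-frame stretch has stop probability 3/64 per codon,
so an individual ATG-initiated stretch runs 50 codons stop-free with
probability (61/64)^50 ≈ 9% — long ORFs in real transcripts are therefore
suggestive but not proof of coding function, which is why the classification
threshold sits at 40 codons rather than 50.

## Evaluation against reference transcripts

Assembled genes are matched to reference transcript models (e.g.
genome-aligned full-length cDNAs) when footprint overlap exceeds 90% of the
gene; among multiple reference variants the one with the assembled gene's
exon count is preferred. Structural disagreements are classified into seven
categories: extra exon, missing exon, extra intron, missing intron, missing
junction, gap, and multiple (two or more elementary discrepancies). One
ambiguity required a decision: an assembled split inside one reference exon
is an *extra intron* when the two pieces are joined by a junction and a
*gap* (coverage hole) when they are not — the assembler's own evidence
classes distinguish the two. Attribution of discrepancies to alternative
splicing is inherently manual; the package reports categories and provides
`sample_size()` (finite-population correction) to size a manual audit and
`extrapolate_rates()` to project audited rates back to the full pool.

Transcription start/termination offsets are reported with the convention
that positive means the assembled gene extends beyond the reference.

## The synthetic benchmark: what it does and does not show

`generate_test_genome()` builds an i.i.d. uniform random genome and inserts
single-isoform genes in four exon-count categories (1–4 exons, 20 genes
each by default), non-overlapping with ≥ 10 kb spacing. Exon lengths are
drawn from 150–600 nt and introns from 100–2,000 nt — sizes chosen so that
every exon is longer than a read (the short-exon path is exercised by
dedicated tests instead) while 50 nt reads regularly span junctions.
Because random sequence attracts no real reads, any call outside an
inserted locus is unambiguously a false positive.

`simulate_reads()` places read starts uniformly over the spliced transcript
and emulates two-part junction alignment: a read spanning more than two
exons, or with less than 8 nt of exonic anchor on either side of a junction,
is treated as unmappable and resampled. Reads carry no sequencing errors —
the benchmark isolates the effect of *depth*, not error tolerance.

`titrate_gene()` assembles nested subsamples of one read pool from 1,000
down to 50 reads per gene and scores the **point of first failure**: the
highest expression level (RPKE) at which the assembly is not exactly one
gene with the true exon count. Levels above the PoFF count as reliable;
accuracy at level L is the fraction of genes with PoFF < L. On this design,
accuracy at 100 RPKE is ≥ 85% in every category (checked over five seeds in
the test suite and recomputed by `scripts/acceptance.R`), and at 1,000 reads
per gene every model is recovered exactly. Problem sizes in the shipped
tests — 80 genes × 9 levels × 5 seeds — were chosen as the smallest design
that exercises all four categories with stable accuracy estimates.

What the benchmark does **not** emulate: non-uniform coverage (3'/5' bias),
sequencing errors and soft-clipping, multimapping ambiguity, overlapping
genes, and alternative isoforms. Passing it shows the assembler's logic is
correct under clean evidence at a given depth; it does not bound false
positive rates on repetitive real genomes — that is what the similarity
screen and footprint filter address downstream.

## Numerical choices and degenerate inputs

* Threshold comparisons are inclusive on the "keep" side everywhere: a
  fragment at exactly 50 RPKE, a gap of exactly 50 nt, a junction span of
  exactly 50,000 nt, a footprint of exactly 140 nt, a gene at exactly
  100 RPKE, and an ORF of exactly 40 codons all pass.
* Boundary matching at linking is exact by default (`link_tol = 0`) because
  splitting snaps fragment edges to junction coordinates; a tolerance of a
  few nt is available for externally produced fragment/junction sets.
* In the density rule, an intron with zero read starts always splits, and a
  flank with zero read starts never does (ratio 0 and ∞ respectively).
* Overlapping splitting junctions within one fragment are resolved greedily
  left-to-right (non-overlapping intron selection).
* Ties in ORF search break toward the forward strand, then the earliest
  transcript coordinate; identical duplicate transcripts in de-duplication
  keep the first in (chromosome, start, id) order.
* Empty inputs propagate cleanly: zero reads yield zero fragments and zero
  genes; an empty junction file disables splitting and linking but not
  tiling.
* Multimappers are counted once at the aligner's reported position;
  secondary and supplementary records are ignored.

## Known limitations

Single isoform per locus by construction; unstranded; merged read counts
can double-count a read that spans two merged fragments (gene-level RPKE
recounts distinct reads and is exact); interleaved genes without connecting
junctions are reported separately; the internal similarity method is an
ungapped screen, not a full local aligner — for publication-grade similarity
figures an external alignment can be substituted.
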