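test_that("tiling matches a per-base coverage oracle on random block sets", {
  set.seed(202)
  for (rep in 1:5) {
    n <- sample(20:80, 1)
    starts <- sample(0:3000, n, replace = TRUE)
    lens <- sample(20:80, n, replace = TRUE)
    blocks <- tibble::tibble(chrom = "chr1", start = starts,
                             end = starts + lens,
                             read_id = sprintf("r%03d", seq_len(n)))
    got <- tile_fragments(coverage_index(blocks), min_rpke = 0)
    want <- oracle_coverage_islands(blocks$start, blocks$end, 4000L)
    expect_equal(got$start, unname(want[, "start"]))
    expect_equal(got$end, unname(want[, "end"]))
  }
})

test_that("the RPKE threshold is inclusive and counts distinct reads", {
  # 50 reads of 50 nt tiled over 1,000 nt: one fragment at exactly 50 RPKE
  blocks <- make_tiled_blocks("chr1", 0L, 1000L, 50)
  frags <- tile_fragments(coverage_index(blocks), min_rpke = 50)
  expect_equal(nrow(frags), 1)
  expect_equal(frags$start, 0L)
  expect_equal(frags$end, 1000L)
  expect_equal(frags$read_count, 50L)
  expect_equal(frags$rpke, 50)
  # 49 reads fall just below the threshold
  blocks49 <- make_tiled_blocks("chr1", 0L, 1000L, 49)
  expect_equal(nrow(tile_fragments(coverage_index(blocks49), min_rpke = 50)), 0)
})

test_that("an RPKM-style screen maps onto an RPKE threshold", {
  # at ~151.5M mapped reads, 1.0 RPKM corresponds to ~150 RPKE: a 1 kb exon
  # needs ~152 overlapping reads, which survives tiling at min_rpke = 150
  total_mapped <- 151492182
  rpkm_equivalent_rpke <- 1.0 * total_mapped / 1e6
  expect_equal(round(rpkm_equivalent_rpke / 10) * 10, 150)
  blocks <- make_tiled_blocks("chr1", 0L, 1000L, 152)
  frags <- tile_fragments(coverage_index(blocks), min_rpke = 150)
  expect_equal(nrow(frags), 1)
})

test_that("short exons are inferred between close junction pairs only", {
  cov <- coverage_index(tibble::tibble(chrom = character(), start = integer(),
                                       end = integer(), read_id = character()))
  j <- tibble::tibble(chrom = "chr1",
                      donor_end = c(500L, 1030L),
                      acceptor_start = c(1000L, 2000L),
                      support = c(5L, 5L), span = c(500L, 970L))
  inf <- infer_short_exons(j, read_len = 50, cov = cov)
  expect_equal(nrow(inf), 1)
  expect_equal(inf$start, 1000L)
  expect_equal(inf$end, 1030L)
  expect_equal(inf$origin, "junction_inferred")
  expect_equal(inf$read_count, 0L)
  # a gap of exactly the read length is left for tiling
  j80 <- dplyr::mutate(j, donor_end = c(500L, 1050L))
  expect_equal(nrow(infer_short_exons(j80, read_len = 50, cov = cov)), 0)
})

test_that("a 25 nt middle exon is recovered only through junction inference", {
  gene <- make_genes(list(rbind(c(1000L, 1400L), c(1600L, 1625L),
                                c(1825L, 2225L))))
  gene$gene_id <- "toy"
  sim <- simulate_reads(gene, 800, read_len = 50, seed = 5)
  cov <- coverage_index(sim$blocks)
  tiled <- tile_fragments(cov, min_rpke = 50)
  # without inference the middle exon's full extent is not a tiled fragment
  asm <- assemble_transcripts(sim$blocks, sim$junctions,
                              assembly_config(min_footprint = 0))
  expect_equal(nrow(asm$genes), 1)
  expect_equal(asm$genes$n_exons, 3L)
  expect_equal(asm$genes$exons[[1]]$start[2], 1600L)
  expect_equal(asm$genes$exons[[1]]$end[2], 1625L)
})

test_that("merging follows the transitive-closure oracle and is idempotent", {
  set.seed(303)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    starts <- sort(sample(0:5000, n))
    iv <- cbind(starts, starts + sample(10:120, n, replace = TRUE))
    frags <- tibble::tibble(chrom = "chr1", start = iv[, 1], end = iv[, 2],
                            read_count = 1L, rpke = 1, origin = "tiling")
    gap <- sample(c(0L, 10L, 50L), 1)
    got <- merge_close_fragments(frags, max_gap = gap)
    want <- oracle_merge_gap(iv, gap)
    expect_equal(got$start, unname(want[, 1]))
    expect_equal(got$end, unname(want[, 2]))
    expect_equal(merge_close_fragments(got, max_gap = gap), got)
  }
})

test_that("merge gap boundary: 50 merges, 51 does not", {
  frags <- tibble::tibble(chrom = "chr1", start = c(100L, 240L),
                          end = c(200L, 300L), read_count = c(10L, 5L),
                          rpke = c(100, 83), origin = "tiling")
  m <- merge_close_fragments(frags, max_gap = 50)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 300L)
  expect_equal(m$read_count, 15L)
  expect_equal(m$rpke, 15 * 1000 / 200)
  expect_equal(m$origin, "merged")
  frags51 <- dplyr::mutate(frags, start = c(100L, 251L))
  expect_equal(nrow(merge_close_fragments(frags51, max_gap = 50)), 2)
})

test_that("a sparse retained intron is split out; a dense one is kept", {
  # exonic coverage ~1 read start/nt in the flanks; intron (200,300)
  exonic <- dplyr::bind_rows(
    make_tiled_blocks("chr1", 0L, 200L, 200, prefix = "e1"),
    make_tiled_blocks("chr1", 250L, 500L, 250, prefix = "e2")
  )
  # make the second cluster span (300,500) exonic part only after trim check:
  exonic <- dplyr::bind_rows(
    make_tiled_blocks("chr1", 0L, 200L, 200, prefix = "e1"),
    make_tiled_blocks("chr1", 300L, 500L, 200, prefix = "e2")
  )
  intronic_sparse <- make_tiled_blocks("chr1", 200L, 300L, 10, prefix = "n")
  jn <- tibble::tibble(chrom = "chr1", donor_end = 200L,
                       acceptor_start = 300L, support = 40L, span = 100L)
  blocks <- dplyr::bind_rows(exonic, intronic_sparse)
  cov <- coverage_index(blocks)
  frags <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L,
                          read_count = nrow(blocks), rpke = 100,
                          origin = "merged")
  out <- split_at_internal_junctions(frags, jn, cov, density_ratio = 0.5,
                                     read_len = 50)
  expect_equal(out$start, c(0L, 300L))
  expect_equal(out$end, c(200L, 500L))
  expect_true(all(out$origin == "split"))
  # re-running the split on its own output changes nothing
  expect_equal(split_at_internal_junctions(out, jn, cov, density_ratio = 0.5,
                                           read_len = 50), out)
  # intron retained when intronic density is ~60% of the flanks
  intronic_dense <- make_tiled_blocks("chr1", 200L, 300L, 60, prefix = "d")
  cov2 <- coverage_index(dplyr::bind_rows(exonic, intronic_dense))
  out2 <- split_at_internal_junctions(frags, jn, cov2, density_ratio = 0.5,
                                      read_len = 50)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$end, 500L)
})

test_that("fragments without internal junctions pass through unchanged", {
  blocks <- make_tiled_blocks("chr1", 0L, 300L, 100)
  cov <- coverage_index(blocks)
  frags <- tile_fragments(cov, min_rpke = 0)
  out <- split_at_internal_junctions(
    frags, tibble::tibble(chrom = "chr1", donor_end = 5000L,
                          acceptor_start = 6000L, support = 3L, span = 1000L),
    cov, read_len = 50
  )
  expect_equal(out, frags)
})

test_that("boundaries overshooting a junction edge are trimmed to it", {
  # noise pushes the first fragment 20 nt into the intron; the junction
  # connects it to the downstream exon, so the end snaps back to the donor
  exon1 <- make_tiled_blocks("chr1", 0L, 200L, 150, prefix = "a")
  overshoot <- make_tiled_blocks("chr1", 170L, 220L, 5, prefix = "o")
  exon2 <- make_tiled_blocks("chr1", 500L, 700L, 150, prefix = "b")
  blocks <- dplyr::bind_rows(exon1, overshoot, exon2)
  jn <- tibble::tibble(chrom = "chr1", donor_end = 200L,
                       acceptor_start = 500L, support = 30L, span = 300L)
  cov <- coverage_index(blocks)
  frags <- merge_close_fragments(tile_fragments(cov, min_rpke = 0), 50)
  out <- split_at_internal_junctions(frags, jn, cov, read_len = 50)
  expect_equal(out$end[1], 200L)
  expect_equal(out$start[2], 500L)
})

test_that("RPKE scales linearly with reads and inversely with length", {
  b1 <- make_tiled_blocks("chr1", 0L, 1000L, 100)
  f1 <- tile_fragments(coverage_index(b1), min_rpke = 0)
  b2 <- make_tiled_blocks("chr1", 0L, 1000L, 200)
  f2 <- tile_fragments(coverage_index(b2), min_rpke = 0)
  expect_equal(f2$rpke, 2 * f1$rpke)
  b3 <- make_tiled_blocks("chr1", 0L, 2000L, 100)
  f3 <- tile_fragments(coverage_index(b3), min_rpke = 0)
  expect_equal(f3$rpke, f1$rpke / 2)
})

test_that("all fragments stay disjoint through every stage", {
  set.seed(404)
  gene <- make_genes(list(rbind(c(0L, 400L), c(700L, 1000L), c(1500L, 1900L))))
  sim <- simulate_reads(gene, 400, seed = 9)
  cov <- coverage_index(sim$blocks)
  tiled <- tile_fragments(cov, 50)
  stages <- list(tiled)
  inf <- infer_short_exons(sim$junctions, 50, cov, existing = tiled)
  merged <- merge_close_fragments(dplyr::bind_rows(tiled, inf), 50)
  stages <- c(stages, list(merged))
  split <- split_at_internal_junctions(merged, sim$junctions, cov, read_len = 50)
  stages <- c(stages, list(split))
  for (st in stages) {
    st <- dplyr::arrange(st, .data$chrom, .data$start)
    if (nrow(st) > 1) {
      expect_true(all(st$start[-1] >= st$end[-nrow(st)]))
    }
  }
})
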