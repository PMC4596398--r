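frag_tbl <- function(starts, ends, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends), read_count = 10L, rpke = 100,
                 origin = "tiling")
}

jn_tbl <- function(donor, acceptor, chrom = "chr1", support = 10L) {
  tibble::tibble(chrom = chrom, donor_end = as.integer(donor),
                 acceptor_start = as.integer(acceptor),
                 support = as.integer(support),
                 span = as.integer(acceptor) - as.integer(donor))
}

test_that("junction span and skip caps apply strictly", {
  exons <- frag_tbl(c(0, 100000), c(500, 100500))
  j <- jn_tbl(donor = c(500, 500, 500),
              acceptor = c(60500, 50500, 10500))
  # spans: 60,000 (dropped), 50,000 (kept: strict >), 10,000 (kept)
  out <- filter_junctions(j, exons, max_span = 50000, max_skip_span = 50000)
  expect_equal(out$span, c(50000L, 10000L))
  # skipping an exon within the cap is allowed
  skipper <- jn_tbl(donor = 500, acceptor = 10500)
  mid_exon <- frag_tbl(c(0, 2000, 100000), c(500, 2400, 100500))
  expect_equal(nrow(filter_junctions(skipper, mid_exon,
                                     max_span = 50000, max_skip_span = 50000)), 1)
  # an exon-skipping junction beyond the skip cap is dropped even when the
  # overall span cap would keep it
  far <- jn_tbl(donor = 500, acceptor = 60500)
  far_exons <- frag_tbl(c(0, 2000, 60500), c(500, 2400, 61000))
  expect_equal(nrow(filter_junctions(far, far_exons,
                                     max_span = 100000, max_skip_span = 50000)), 0)
})

test_that("linking matches a label-propagation component oracle", {
  set.seed(505)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    starts <- cumsum(sample(200:500, n))
    frags <- frag_tbl(starts, starts + sample(80:150, n, replace = TRUE))
    # random subset of adjacent pairs joined by junctions
    pairs <- which(runif(n - 1) < 0.5)
    j <- if (length(pairs)) {
      jn_tbl(frags$end[pairs], frags$start[pairs + 1])
    } else {
      jn_tbl(integer(0), integer(0))
    }
    genes <- link_genes(frags, j, tol = 0)
    comp <- oracle_union_find(n, cbind(pairs, pairs + 1))
    expect_equal(nrow(genes), length(unique(comp)))
    # the partition property: every fragment appears in exactly one gene
    all_exons <- dplyr::bind_rows(genes$exons)
    expect_equal(sort(all_exons$start), sort(frags$start))
    expect_equal(sum(genes$n_exons), n)
    # per-component exon counts agree
    expect_equal(sort(as.integer(table(comp))), sort(genes$n_exons))
  }
})

test_that("three exons joined by two junctions form one gene in order", {
  frags <- frag_tbl(c(0, 500, 1000), c(100, 600, 1100))
  j <- jn_tbl(c(100, 600), c(500, 1000))
  genes <- link_genes(frags, j)
  expect_equal(nrow(genes), 1)
  expect_equal(genes$n_exons, 3L)
  expect_equal(genes$exons[[1]]$start, c(0L, 500L, 1000L))
  expect_equal(nrow(genes$junctions[[1]]), 2)
  expect_equal(genes$footprint_nt, 300L)
})

test_that("unlinked exons become separate single-exon genes", {
  frags <- frag_tbl(c(0, 5000), c(200, 5200))
  genes <- link_genes(frags, jn_tbl(integer(0), integer(0)))
  expect_equal(nrow(genes), 2)
  expect_equal(genes$n_exons, c(1L, 1L))
})

test_that("edge matching honours the tolerance setting", {
  frags <- frag_tbl(c(0, 500), c(103, 600))
  j <- jn_tbl(100, 500)  # donor is 3 nt off the fragment end
  expect_equal(nrow(link_genes(frags, j, tol = 0)), 2)
  expect_equal(nrow(link_genes(frags, j, tol = 5)), 1)
})

test_that("the footprint filter removes short models at the 140 nt boundary", {
  genes <- make_genes(list(cbind(0L, 139L), cbind(1000L, 1140L),
                           cbind(3000L, 3050L)))
  suppressMessages(kept <- filter_min_footprint(genes, 140))
  expect_equal(kept$footprint_nt, 140L)
  expect_equal(nrow(filter_min_footprint(make_genes(list()), 140)), 0)
  set.seed(42)
  sizes <- sample(50:400, 10)
  rand <- make_genes(lapply(seq_along(sizes), function(i) {
    cbind(i * 1000L, i * 1000L + sizes[i])
  }))
  suppressMessages(kept2 <- filter_min_footprint(rand, 140))
  expect_equal(nrow(kept2), sum(sizes >= 140))
})

test_that("gene RPKE counts junction-spanning reads once", {
  genes <- make_genes(list(rbind(c(0L, 300L), c(500L, 700L))))
  # 100 reads total on a 500 nt footprint -> 200 RPKE
  left <- make_tiled_blocks("chr1", 0L, 300L, 60, prefix = "l")
  right <- make_tiled_blocks("chr1", 500L, 700L, 39, prefix = "r")
  spanning <- tibble::tibble(chrom = "chr1", start = c(270L, 500L),
                             end = c(300L, 520L), read_id = "span1")
  cov <- coverage_index(dplyr::bind_rows(left, right, spanning))
  out <- gene_rpke(genes, cov)
  expect_equal(out$read_count, 100L)
  expect_equal(out$rpke, 200)
  # set-based oracle: distinct ids with any overlap
  expect_equal(out$read_count, length(unique(c(left$read_id, right$read_id,
                                               "span1"))))
  empty_cov <- coverage_index(tibble::tibble(chrom = character(),
                                             start = integer(),
                                             end = integer(),
                                             read_id = character()))
  expect_equal(gene_rpke(genes, empty_cov)$rpke, 0)
})

test_that("zero reads in yields zero genes out", {
  blocks <- tibble::tibble(chrom = character(), start = integer(),
                           end = integer(), read_id = character())
  asm <- assemble_transcripts(blocks)
  expect_equal(nrow(asm$genes), 0)
  expect_equal(asm$stages$n[asm$stages$stage == "genes_after_footprint"], 0L)
})

test_that("assembly is deterministic and stage counts are sensible", {
  gene <- make_genes(list(rbind(c(0L, 400L), c(900L, 1300L))))
  sim <- simulate_reads(gene, 300, seed = 21)
  a1 <- assemble_transcripts(sim$blocks, sim$junctions)
  a2 <- assemble_transcripts(sim$blocks, sim$junctions)
  expect_identical(a1$genes, a2$genes)
  st <- setNames(a1$stages$n, a1$stages$stage)
  expect_lte(st["after_merge"], st["with_inferred_exons"])
  expect_gte(st["after_split"], st["after_merge"])
  expect_lte(st["genes_after_footprint"], st["genes_linked"])
})

test_that("a perfectly covered simulated gene set is recovered exactly", {
  tg <- generate_test_genome(seed = 8, genes_per_category = 3, sequence = FALSE)
  all_blocks <- list()
  for (i in seq_len(nrow(tg$genes))) {
    n <- ceiling(tg$genes$footprint_nt[i] / 1000 * 400)  # ~400 RPKE
    sim <- simulate_reads(tg$genes[i, ], n, seed = 1000 + i)
    sim$blocks$read_id <- paste0("g", i, "_", sim$blocks$read_id)
    all_blocks[[i]] <- sim$blocks
  }
  blocks <- dplyr::bind_rows(all_blocks)
  asm <- assemble_transcripts(blocks)
  expect_equal(nrow(asm$genes), nrow(tg$genes))
  expect_equal(
    asm$genes$n_exons[order(asm$genes$span_start)],
    tg$genes$n_exons[order(tg$genes$span_start)]
  )
})
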