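ann_tbl <- function(starts, ends, chrom = "chr1") {
  tibble::tibble(gene_id = sprintf("LOC%02d", seq_along(starts)),
                 chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends), strand = "+")
}

test_that("annotation overlap classes split at 75% and 5%", {
  genes <- make_genes(list(cbind(0L, 100L), cbind(1000L, 1100L),
                           cbind(2000L, 2100L)))
  ann <- ann_tbl(c(0, 1060, 2097), c(80, 1500, 2500))
  out <- classify_overlap(genes, ann, hi = 0.75, lo = 0.05)
  expect_equal(out$best_overlap_fraction, c(0.80, 0.40, 0.03))
  expect_equal(out$class, c("annotated", "intermediate", "novel"))
  # boundary: exactly 75% is annotated, exactly 5% is intermediate
  b <- make_genes(list(cbind(0L, 100L), cbind(1000L, 1100L)))
  bann <- ann_tbl(c(25, 1095), c(200, 1200))
  outb <- classify_overlap(b, bann)
  expect_equal(outb$class, c("annotated", "intermediate"))
})

test_that("genes with no annotated chromosome are fully novel", {
  genes <- make_genes(list(cbind(0L, 100L)), chrom = "chr9")
  out <- classify_overlap(genes, ann_tbl(0, 1000))
  expect_equal(out$best_overlap_fraction, 0)
  expect_equal(out$class, "novel")
})

test_that("containment de-duplication matches the pairwise oracle", {
  contained <- list(cbind(0L, 100L), cbind(0L, 200L))  # first inside second
  g <- make_genes(contained)
  out <- dedupe_contained(g)
  expect_equal(nrow(out), 1)
  expect_equal(out$footprint_nt, 200L)
  partial <- make_genes(list(cbind(0L, 150L), cbind(100L, 250L)))
  expect_equal(nrow(dedupe_contained(partial)), 2)
  # multi-exon containment: footprint inside footprint, not just spans
  spliced <- make_genes(list(rbind(c(0L, 100L), c(300L, 400L)),
                             cbind(0L, 400L),
                             cbind(150L, 250L)))
  out2 <- dedupe_contained(spliced)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$n_exons, 1L)
  set.seed(707)
  for (rep in 1:4) {
    n <- sample(4:9, 1)
    sets <- lapply(seq_len(n), function(i) {
      s <- sample(0:500, 1)
      w <- sample(50:400, 1)
      cbind(s, s + w)
    })
    g <- make_genes(sets)
    out <- dedupe_contained(g)
    exon_sets <- lapply(g$exons, as.data.frame)
    drop <- oracle_contained(exon_sets)
    expect_setequal(out$gene_id, g$gene_id[!drop])
  }
})

test_that("expression filter keeps genes at exactly the threshold", {
  g <- make_genes(list(cbind(0L, 100L), cbind(500L, 600L), cbind(900L, 999L)),
                  rpke = c(100, 99.9, 350))
  out <- filter_expression(g, 100)
  expect_setequal(out$rpke, c(100, 350))
  expect_equal(nrow(filter_expression(g[0, ], 100)), 0)
})

test_that("similarity screen separates unique and duplicated genes", {
  set.seed(808)
  gene_seq <- random_dna(400)
  cassette <- substr(gene_seq, 1, 120)  # 30% of the gene
  chr1 <- paste0(random_dna(500), gene_seq, random_dna(500))
  genome_unique <- Biostrings::DNAStringSet(c(chr1 = chr1,
                                              chr2 = random_dna(1500)))
  g <- make_genes(list(cbind(500L, 900L)))
  res <- similarity_screen(g, genome_unique, max_percent = 25)
  expect_lt(res$percent_similarity, 5)
  expect_true(res$passes)
  # verbatim copy elsewhere -> ~100%, fails
  genome_dup <- Biostrings::DNAStringSet(c(
    chr1 = chr1, chr2 = paste0(random_dna(300), gene_seq, random_dna(300))
  ))
  res_dup <- similarity_screen(g, genome_dup, max_percent = 25)
  expect_gte(res_dup$percent_similarity, 99)
  expect_false(res_dup$passes)
  # a 30%-length cassette duplicated -> ~30%, fails at the 25% ceiling
  genome_cas <- Biostrings::DNAStringSet(c(
    chr1 = chr1, chr2 = paste0(random_dna(300), cassette, random_dna(300))
  ))
  res_cas <- similarity_screen(g, genome_cas, max_percent = 25)
  # the exact copy covers 30% of the gene; identity-bounded extension may add
  # a little noisy flank on each side
  expect_gte(res_cas$percent_similarity, 30)
  expect_lt(res_cas$percent_similarity, 40)
  expect_false(res_cas$passes)
})

test_that("similarity ignores the gene's own locus but errors off-genome", {
  set.seed(809)
  chr1 <- random_dna(1000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1))
  g <- make_genes(list(cbind(200L, 600L)))
  res <- similarity_screen(g, genome)
  expect_equal(res$percent_similarity, 0)
  off <- make_genes(list(cbind(0L, 100L)), chrom = "chrX")
  expect_error(similarity_screen(off, genome), "not in genome")
})

test_that("cascade accounting: disjoint, identical and mixed source sets", {
  ann <- ann_tbl(10000, 11000)
  cfg <- assembly_config(min_footprint = 140, min_gene_rpke = 100)
  mk <- function(starts) {
    make_genes(lapply(starts, function(s) cbind(s, s + 200L)),
               rpke = rep(150, length(starts)))
  }
  a <- mk(c(0L, 1000L, 2000L))
  b_disjoint <- mk(c(5000L, 6000L))
  b_disjoint$gene_id <- paste0("cl_", b_disjoint$gene_id)
  rep1 <- combine_and_report(a, b_disjoint, ann, config = cfg)
  expect_equal(rep1$shared, 0)
  expect_equal(rep1$exclusive_a, 3)
  expect_equal(rep1$exclusive_b, 2)
  expect_equal(rep1$exclusive_a + rep1$exclusive_b + rep1$shared, rep1$n_union)

  b_same <- mk(c(0L, 1000L, 2000L))
  b_same$gene_id <- paste0("cl_", b_same$gene_id)
  rep2 <- combine_and_report(a, b_same, ann, config = cfg)
  expect_equal(rep2$shared, 3)
  expect_equal(rep2$exclusive_a, 0)
  expect_equal(rep2$exclusive_b, 0)
  expect_equal(rep2$n_union, 3)

  # hand-enumerated three-way fixture: one shared, two exclusive to a,
  # one exclusive to b
  a3 <- mk(c(0L, 1000L, 2000L))
  b3 <- mk(c(2050L, 7000L))
  b3$gene_id <- paste0("cl_", b3$gene_id)
  rep3 <- combine_and_report(a3, b3, ann, config = cfg)
  expect_equal(rep3$shared, 1)
  expect_equal(rep3$exclusive_a, 2)
  expect_equal(rep3$exclusive_b, 1)
  expect_equal(rep3$n_union, 4)
  expect_equal(rep3$exclusive_a + rep3$exclusive_b + rep3$shared, rep3$n_union)
})

test_that("the cascade drops annotated, contained, short and weak genes", {
  ann <- ann_tbl(0, 1000)
  genes <- make_genes(
    list(cbind(100L, 500L),            # annotated overlap -> dropped
         cbind(5000L, 5400L),          # survives everything
         cbind(5050L, 5350L),          # contained in the previous -> dropped
         cbind(8000L, 8100L),          # footprint 100 < 140 -> dropped
         cbind(9000L, 9400L)),         # rpke 50 < 100 -> dropped
    rpke = c(500, 200, 180, 300, 50)
  )
  rep <- combine_and_report(genes, NULL, ann,
                            config = assembly_config())
  expect_equal(rep$n_union, 1)
  expect_equal(rep$genes$span_start, 5000L)
  st <- rep$stages
  expect_equal(st$n[st$stage == "input"], 5L)
  expect_equal(st$n[st$stage == "novel_class"], 4L)
  expect_equal(st$n[st$stage == "deduped"], 3L)
  expect_equal(st$n[st$stage == "min_footprint"], 2L)
  expect_equal(st$n[st$stage == "min_expression"], 1L)
})

test_that("filter order does not change the final set", {
  ann <- ann_tbl(0, 1000)
  set.seed(909)
  starts <- seq(3000L, 20000L, by = 600L)
  genes <- make_genes(lapply(starts, function(s) {
    cbind(s, s + sample(c(100L, 200L, 300L), 1))
  }), rpke = sample(c(50, 150, 250), length(starts), replace = TRUE))
  cfg <- assembly_config()
  via_cascade <- combine_and_report(genes, NULL, ann, config = cfg)$genes$gene_id
  # apply the same predicates in a different order
  reordered <- filter_expression(genes, cfg$min_gene_rpke)
  suppressMessages(reordered <- filter_min_footprint(reordered, cfg$min_footprint))
  reordered <- dedupe_contained(reordered)
  reordered <- classify_overlap(reordered, ann, cfg$overlap_hi, cfg$overlap_lo)
  reordered <- reordered$gene_id[reordered$class == "novel"]
  expect_setequal(via_cascade, reordered)
})
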