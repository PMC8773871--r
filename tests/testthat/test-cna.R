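test_that("ploidy-adjusted state: tetraploid anchor and diploid reduction", {
  # total CN 4 at ploidy 4 is copy neutral; with minor 0 it is neutral-LOH
  expect_equal(effective_copy_state(4, ploidy = 4), "neutral")
  expect_equal(effective_copy_state(1, ploidy = 2), "loss")
  expect_equal(effective_copy_state(4, ploidy = 2), "amplification") # r = 2
  expect_equal(effective_copy_state(0:4, ploidy = 2),
               c("loss", "loss", "neutral", "gain", "amplification"))
  expect_error(effective_copy_state(-1, 2), "non-negative")
})

test_that("state is monotone non-decreasing in total CN at fixed ploidy", {
  lv <- c("loss", "neutral", "gain", "amplification")
  for (pl in c(1.8, 2, 3.1, 4)) {
    states <- factor(effective_copy_state(0:12, ploidy = pl), levels = lv)
    expect_true(all(diff(as.integer(states)) >= 0L))
  }
})

test_that("gene takes the segment with the largest overlap; ties go low", {
  genes <- data.frame(gene = "G1", chrom = "chr1", start = 100L, end = 199L)
  segs <- data.frame(chrom = "chr1", start = c(1L, 170L),
                     end = c(169L, 400L), total_cn = c(1L, 2L),
                     minor_cn = c(0L, 1L))
  out <- assign_segments_to_genes(segs, genes, ploidy = 2)
  expect_equal(out$total_cn, 1L) # 70-base overlap beats 30
  expect_equal(out$effective_state, "loss")
  expect_true(out$loh)
  # exact 50/50 tie: lower-coordinate segment wins
  segs2 <- data.frame(chrom = "chr1", start = c(1L, 150L),
                      end = c(149L, 400L), total_cn = c(3L, 2L),
                      minor_cn = c(1L, 1L))
  out2 <- assign_segments_to_genes(segs2, genes, ploidy = 2)
  expect_equal(out2$total_cn, 3L)
  # gene fully inside one segment
  segs3 <- data.frame(chrom = "chr1", start = 1L, end = 1000L,
                      total_cn = 2L, minor_cn = 1L)
  out3 <- assign_segments_to_genes(segs3, genes, ploidy = 2)
  expect_equal(out3$seg_start, 1L)
  expect_false(out3$loh)
})

test_that("uncovered genes are flagged; overlapping segments error", {
  genes <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                      start = c(100L, 5000L), end = c(199L, 5100L))
  segs <- data.frame(chrom = "chr1", start = 1L, end = 1000L,
                     total_cn = 2L, minor_cn = 1L)
  out <- assign_segments_to_genes(segs, genes, ploidy = 2)
  expect_equal(out$covered, c(TRUE, FALSE))
  expect_true(is.na(out$effective_state[2]))
  bad <- data.frame(chrom = "chr1", start = c(1L, 500L), end = c(600L, 900L),
                    total_cn = 2L, minor_cn = 1L)
  expect_error(assign_segments_to_genes(bad, genes), "overlap")
})

test_that("assignment is invariant under segment input order", {
  set.seed(9)
  bounds <- sort(sample(2:9999, 19))
  segs <- data.frame(chrom = "chr1", start = c(1L, bounds + 1L),
                     end = c(bounds, 10000L),
                     total_cn = sample(0:5, 20, replace = TRUE))
  segs$minor_cn <- pmin(segs$total_cn, sample(0:2, 20, replace = TRUE))
  genes <- data.frame(gene = paste0("G", 1:8), chrom = "chr1",
                      start = seq(100L, 8000L, length.out = 8),
                      end = seq(100L, 8000L, length.out = 8) + 900L)
  a <- assign_segments_to_genes(segs, genes, ploidy = 2)
  b <- assign_segments_to_genes(segs[sample(20), ], genes, ploidy = 2)
  expect_equal(a, b)
})

test_that("BED segments convert at the boundary and round trip", {
  seg <- data.frame(chrom = "chr1", start = c(1L, 101L), end = c(100L, 250L),
                    total_cn = c(2L, 1L), minor_cn = c(1L, 0L))
  d <- withr::local_tempdir()
  bed <- file.path(d, "seg.bed")
  write_segment_bed(seg, bed)
  raw <- read.delim(bed, header = FALSE)
  expect_equal(raw$V2, c(0L, 100L)) # 0-based half-open on disk
  back <- read_segment_table(bed, format = "bed")
  expect_equal(back$start, seg$start)
  expect_equal(back$end, seg$end)
  tsv <- file.path(d, "seg.tsv")
  write.table(seg, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_segment_table(tsv)$start, seg$start)
  expect_error(read_segment_table(tsv, format = "bed"))
})

test_that("planted differential events are recovered, including neutral-LOH", {
  ref <- test_reference()
  events <- data.frame(
    gene = c("CDH1", "CTNNA1"), component = c("Neg", "Neg"),
    total_cn = c(1L, 4L), minor_cn = c(0L, 0L)
  )
  cfg <- simulation_config(seed = 5L, n_genes = 40L, cna_events = events,
                           ploidy = c(Neg = 4, Abr = 2))
  withr::with_seed(5, {
    genes <- simulate_genes(ref, 40L)
    cna <- simulate_cna_segments(cfg, ref, genes)
  })
  st_neg <- assign_segments_to_genes(cna$Neg, genes, ploidy = 4)
  st_abr <- assign_segments_to_genes(cna$Abr, genes, ploidy = 2)
  # CN 4 at ploidy 4 with minor 0: copy neutral with LOH
  ctnna1 <- st_neg[st_neg$gene == "CTNNA1", ]
  expect_equal(ctnna1$effective_state, "neutral")
  expect_true(ctnna1$loh)
  diff <- differential_gene_states(st_neg, st_abr)
  expect_true(all(c("CDH1", "CTNNA1") %in% diff$gene))
  expect_equal(diff$state_neg[diff$gene == "CDH1"], "loss")
  # identical inputs give an empty table
  expect_equal(nrow(differential_gene_states(st_abr, st_abr)), 0L)
})

test_that("no planted events at ploidy 2 leaves every covered gene neutral", {
  ref <- test_reference()
  cfg <- simulation_config(seed = 6L, n_genes = 30L)
  withr::with_seed(6, {
    genes <- simulate_genes(ref, 30L)
    cna <- simulate_cna_segments(cfg, ref, genes)
  })
  for (comp in c("Neg", "Abr")) {
    st <- assign_segments_to_genes(cna[[comp]], genes, ploidy = 2)
    expect_true(all(st$effective_state[st$covered] == "neutral"))
    expect_false(any(st$loh[st$covered]))
  }
  diff <- differential_gene_states(
    assign_segments_to_genes(cna$Neg, genes, ploidy = 2),
    assign_segments_to_genes(cna$Abr, genes, ploidy = 2))
  expect_equal(nrow(diff), 0L)
})
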