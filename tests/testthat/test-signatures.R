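test_that("single SNVs land in the right channel, purines fold", {
  # build a reference where position 3 has context ACG on the + strand
  ref <- literal_reference(chr1 = "AACGTTTTTT", chr2 = "TTCGTAAAAA")
  p1 <- build_sbs_profile(data.frame(chrom = "chr1", pos = 3L,
                                     ref = "C", alt = "T"), ref)
  expect_equal(sum(p1), 1L)
  expect_equal(unname(p1["A[C>T]G"]), 1L)
  # G>A at chr2:4 (context CGT) is the reverse complement of A[C>T]G
  p2 <- build_sbs_profile(data.frame(chrom = "chr2", pos = 4L,
                                     ref = "G", alt = "A"), ref)
  expect_equal(unname(p2["A[C>T]G"]), 1L)
})

test_that("contig-edge SNVs are skipped with a warning, counts conserved", {
  ref <- literal_reference(chr1 = "CACGTTTTTT")
  snvs <- data.frame(chrom = "chr1", pos = c(1L, 3L, 10L),
                     ref = c("C", "C", "T"), alt = c("A", "T", "G"))
  expect_warning(p <- build_sbs_profile(snvs, ref), "skipped")
  expect_equal(attr(p, "n_skipped"), 2L)
  expect_equal(sum(p), 1L)
  # stated ref disagreeing with the reference is an error
  bad <- data.frame(chrom = "chr1", pos = 4L, ref = "C", alt = "T")
  expect_error(build_sbs_profile(bad, ref), "mismatch")
})

test_that("profile counts total the number of non-skipped SNVs", {
  ref <- test_reference()
  cfg <- clean_config(seed = 77L, n_mutations = 200L, trunk_fraction = 1)
  sim <- simulate_mutation_set(cfg, ref)
  snvs <- sim$truth[sim$truth$class == "SNV", ]
  p <- build_sbs_profile(snvs, ref)
  expect_equal(sum(p), nrow(snvs))
  # simulated channels are reproduced exactly (placement conditions on context)
  tab <- table(snvs$channel)
  expect_equal(unname(unclass(p)[names(tab)]), as.integer(tab))
})

test_that("cosine similarity: hand values, scale invariance, errors", {
  expect_equal(cosine_similarity(c(1, 2, 0), c(2, 1, 0)), 4 / 5)
  v <- runif(96)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_similarity(3.7 * v, v), cosine_similarity(v, v))
  expect_error(cosine_similarity(rep(0, 3), c(1, 2, 3)), "zero vector")
  expect_error(cosine_similarity(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("catalogue loader round-trips the bundled synthetic catalogue", {
  cat_mem <- synthetic_signature_catalog()
  cat_file <- load_signature_catalog()
  expect_equal(dim(cat_file), c(96L, 12L))
  expect_equal(rownames(cat_file), sbs_channels())
  expect_equal(unname(colSums(cat_file)), rep(1, 12), tolerance = 1e-9)
  expect_equal(cat_file, cat_mem, ignore_attr = TRUE, tolerance = 1e-12)
  expect_match(attr(cat_file, "checksum"), "^[0-9a-f]{32}$")
  # corrupt catalogue: column no longer sums to 1
  bad <- data.frame(Channel = rownames(cat_mem), cat_mem, check.names = FALSE)
  bad[1, 2] <- bad[1, 2] + 0.5
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_signature_catalog(tf), "sum to 1")
})

test_that("catalogue similarity: identity column, mixtures, channel check", {
  catalog <- synthetic_signature_catalog()
  mk_profile <- function(x, id) {
    structure(as.integer(round(x * 1e6)), names = rownames(catalog),
              class = "sbs_profile", sample_id = id, n_skipped = 0L)
  }
  p_sbs2 <- mk_profile(catalog[, "SBS2"], "pure2")
  sim <- profile_catalog_similarity(p_sbs2, catalog)
  expect_gt(sim["pure2", "SBS2"], 0.999)
  expect_equal(unname(attr(sim, "best_match")["pure2"]), "SBS2")
  half <- mk_profile(0.5 * catalog[, "SBS1"] + 0.5 * catalog[, "SBS2"], "mix")
  sim2 <- profile_catalog_similarity(half, catalog)
  others <- setdiff(colnames(catalog), c("SBS1", "SBS2"))
  expect_true(all(sim2["mix", c("SBS1", "SBS2")] >
                    max(sim2["mix", others])))
  # channel mismatch names the first discordant channel
  p_bad <- p_sbs2
  names(p_bad)[5] <- "X[C>A]A"
  expect_error(profile_catalog_similarity(p_bad, catalog), "X\\[C>A\\]A")
})

test_that("complete-linkage clustering: identical rows, known heights", {
  # identical rows merge at height 0
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  cl <- cluster_similarity(m)
  expect_equal(min(cl$row_hclust$height), 0)
  # 1-d points 0, 1, 3: merge (a,b) at 1, then c at max(3, 2) = 3
  m2 <- cbind(x = c(a = 0, b = 1, c = 3), y = c(0, 0, 0))
  cl2 <- cluster_similarity(m2)
  expect_equal(cl2$row_hclust$height, c(1, 3))
  # permuting rows leaves merge heights unchanged
  cl3 <- cluster_similarity(m2[c(3, 1, 2), ])
  expect_equal(cl3$row_hclust$height, cl2$row_hclust$height)
  expect_error(cluster_similarity(m2[1, , drop = FALSE]), "at least 2")
  m_bad <- m2; m_bad[1, 1] <- NaN
  expect_error(cluster_similarity(m_bad), "non-finite")
})
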