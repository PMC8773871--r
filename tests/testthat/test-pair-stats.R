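test_that("overlap coefficient matches set arithmetic", {
  expect_equal(overlap_coefficient(letters[1:5],
                                   c(letters[1:3], "x")), 3 / 4)
  a <- paste0("k", 1:100)
  expect_equal(overlap_coefficient(a, a), 1.0)
  expect_equal(overlap_coefficient(a, paste0("j", 1:50)), 0.0)
  expect_equal(overlap_coefficient(character(0), a), 0.0)
  expect_equal(overlap_coefficient(character(0), character(0)), 0.0)
})

test_that("overlap coefficient is symmetric and equals brute force", {
  set.seed(12)
  for (i in 1:100) {
    a <- sample(paste0("v", 1:40), sample(0:25, 1))
    b <- sample(paste0("v", 1:40), sample(1:25, 1))
    brute <- if (!length(a) || !length(b)) 0 else {
      length(intersect(a, b)) / min(length(unique(a)), length(unique(b)))
    }
    expect_equal(overlap_coefficient(a, b), brute)
    expect_equal(overlap_coefficient(a, b), overlap_coefficient(b, a))
  }
})

test_that("component pair partitions are disjoint and exhaustive", {
  mk <- function(keys, classes) {
    data.frame(key = keys, class = classes, stringsAsFactors = FALSE)
  }
  neg <- mk(c("s1", "s2", "s3", "i1"), c("SNV", "SNV", "SNV", "indel"))
  abr <- mk(c("s2", "s3", "s4", "i2"), c("SNV", "SNV", "SNV", "indel"))
  p <- component_pair(neg, abr, "T1")
  expect_setequal(p$shared$SNV, c("s2", "s3"))
  expect_setequal(p$private_neg$SNV, "s1")
  expect_setequal(p$private_abr$SNV, "s4")
  expect_equal(p$overlap_snv, 2 / 3)
  expect_equal(p$overlap_indel, 0)
  expect_length(intersect(p$shared$SNV, p$private_neg$SNV), 0L)
  expect_setequal(c(p$shared$SNV, p$private_neg$SNV),
                  neg$key[neg$class == "SNV"])
  # identical callsets: no private variants
  p2 <- component_pair(neg, neg)
  expect_length(p2$private_neg$SNV, 0L)
  expect_equal(p2$overlap_snv, 1)
  # one empty callset
  p3 <- component_pair(neg[0, ], abr)
  expect_length(p3$shared$SNV, 0L)
  expect_equal(p3$overlap_snv, 0)
})

test_that("substitution spectrum folds strands and normalizes", {
  snvs <- data.frame(ref = c("C", "G", "G", "C"), alt = c("T", "A", "A", "T"))
  sp <- substitution_spectrum(snvs)
  expect_equal(unname(sp[["C>T"]]), 1)
  expect_equal(sum(sp), 1)
  # empty input flagged
  sp0 <- substitution_spectrum(snvs[0, ])
  expect_true(attr(sp0, "empty"))
  expect_equal(sum(sp0), 0)
  # mixed input
  snvs2 <- data.frame(ref = c("C", "A", "T"), alt = c("A", "G", "G"))
  sp2 <- substitution_spectrum(snvs2)
  expect_equal(unname(sp2[["C>A"]]), 1 / 3)
  expect_equal(unname(sp2[["T>C"]]), 1 / 3) # A>G folds to T>C
  expect_equal(unname(sp2[["T>G"]]), 1 / 3)
  expect_error(substitution_spectrum(data.frame(ref = "CT", alt = "C")),
               "SNVs only")
  expect_error(substitution_spectrum(data.frame(ref = "N", alt = "A")),
               "A/C/G/T")
})

test_that("spectrum is invariant under reverse-complement representation", {
  set.seed(4)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 200, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  fwd <- substitution_spectrum(data.frame(ref = ref, alt = alt))
  rc <- substitution_spectrum(data.frame(ref = hetpair:::dna_complement(ref),
                                         alt = hetpair:::dna_complement(alt)))
  expect_equal(fwd, rc)
})

test_that("recurrence test gates on absolute difference then tests proportions", {
  mk_sample <- function(genes) {
    data.frame(gene = genes,
               func_class = rep("nonsynonymous", length(genes)),
               stringsAsFactors = FALSE)
  }
  # group1: GENEA mutated in 4/9 samples, GENEB in 2/9
  g1 <- c(lapply(1:4, function(i) mk_sample("GENEA")),
          lapply(1:2, function(i) mk_sample("GENEB")),
          lapply(1:3, function(i) mk_sample(character(0))))
  # group2: GENEA in 1/9, GENEB in 1/9
  g2 <- c(lapply(1, function(i) mk_sample("GENEA")),
          lapply(1, function(i) mk_sample("GENEB")),
          lapply(1:7, function(i) mk_sample(character(0))))
  res <- recurrence_test(g1, g2)
  a <- res[res$gene == "GENEA", ]
  b <- res[res$gene == "GENEB", ]
  expect_true(a$tested)   # |4-1| = 3 reaches the threshold
  expect_false(b$tested)  # |2-1| = 1 does not
  expect_true(is.na(b$p_value))
  # p-value equals the standard two-sample proportion test
  oracle <- suppressWarnings(prop.test(c(4, 1), c(9, 9))$p.value)
  expect_equal(a$p_value, oracle)
  # equal proportions are never significant
  g3 <- c(lapply(1:5, function(i) mk_sample("GENEC")),
          lapply(1:4, function(i) mk_sample(character(0))))
  res2 <- recurrence_test(g3, g3, min_diff = 0L)
  expect_gt(res2$p_value[res2$gene == "GENEC"], 0.99)
  expect_error(recurrence_test(list(), g1), "at least one sample")
})

test_that("non-genic variants are excluded from recurrence counting", {
  s1 <- data.frame(gene = c("GENEA", "GENEB"),
                   func_class = c("nonsynonymous", "intergenic"))
  res <- recurrence_test(list(s1), list(s1), min_diff = 0L)
  expect_true("GENEA" %in% res$gene)
  expect_false("GENEB" %in% res$gene)
})
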