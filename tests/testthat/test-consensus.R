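# Consensus rule: SNV kept iff >= 2 of the 3 SNV callers support it; indel
# kept iff both indel-capable callers do. Verified by exhaustive
# enumeration against an independent evaluation of the rule.

callers3 <- c("mutect2", "strelka2", "muse")

# build a one-variant callset list for a given supporting-caller subset
subset_callsets <- function(support, ref, pos, refb, altb) {
  lapply(support, function(ca) call_row(ca, pos = pos, ref = refb, alt = altb))
}

test_that("all 8 caller-support subsets follow the consensus rule table", {
  ref <- test_reference()
  pos <- 1000L
  b <- ref_seq(ref, "chr1", pos)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  subsets <- unlist(lapply(0:3, function(k) {
    combn(callers3, k, simplify = FALSE)
  }), recursive = FALSE)
  for (support in subsets) {
    cs <- subset_callsets(support, ref, pos, b, alt)
    got <- if (length(cs)) nrow(build_consensus(cs, ref)) else 0L
    expected <- as.integer(length(support) >= 2L) # independent rule check
    expect_equal(got, expected,
                 info = paste("SNV support:", paste(support, collapse = "+")))
  }
})

test_that("indels require exactly the two indel-capable callers", {
  ref <- literal_reference(chr1 = strrep("GCATTAGCGTAC", 200))
  pos <- 25L
  refb <- ref_seq(ref, "chr1", pos, pos + 2L)
  altb <- substr(refb, 1L, 1L)
  subsets <- unlist(lapply(0:3, function(k) {
    combn(callers3, k, simplify = FALSE)
  }), recursive = FALSE)
  for (support in subsets) {
    cs <- subset_callsets(support, ref, pos, refb, altb)
    got <- if (length(cs)) nrow(build_consensus(cs, ref)) else 0L
    expected <- as.integer(all(c("mutect2", "strelka2") %in% support))
    expect_equal(got, expected,
                 info = paste("indel support:", paste(support, collapse = "+")))
  }
})

test_that("consensus is monotone in caller support", {
  ref <- test_reference()
  pos <- 2000L
  b <- ref_seq(ref, "chr1", pos)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  for (base_support in list(c("muse"), c("muse", "strelka2"))) {
    before <- build_consensus(subset_callsets(base_support, ref, pos, b, alt),
                              ref)
    extra <- c(base_support, setdiff(callers3, base_support)[1])
    after <- build_consensus(subset_callsets(extra, ref, pos, b, alt), ref)
    expect_true(all(before$key %in% after$key))
  }
})

test_that("VAF precedence: mutect2, then strelka2, then computed fallback", {
  ref <- test_reference()
  pos <- 3000L
  b <- ref_seq(ref, "chr1", pos)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  mk <- function(caller, vaf) call_row(caller, pos = pos, ref = b, alt = alt,
                                       vaf = vaf, tumour_depth = 50L,
                                       tumour_alt = 15L)
  all3 <- build_consensus(list(mk("mutect2", 0.41), mk("strelka2", 0.33),
                               mk("muse", NA)), ref)
  expect_equal(all3$vaf, 0.41)
  no_m2 <- build_consensus(list(mk("strelka2", 0.33), mk("muse", NA)), ref)
  expect_equal(no_m2$vaf, 0.33)
  none <- build_consensus(list(mk("strelka2", NA), mk("muse", NA)), ref)
  expect_equal(none$vaf, 15 / 50) # alt/depth fallback
})

test_that("caller-discordant indel representations match through one key", {
  ref <- literal_reference(chr1 = paste0(strrep("GCAT", 10), "AATTTTTTGC",
                                         strrep("GCAT", 10)))
  # left-aligned deletion of one T out of the T-run
  left <- call_row("mutect2", pos = 42L, ref = "AT", alt = "A")
  # the same event, right-shifted as an imperfectly normalized caller emits it
  right <- call_row("strelka2", pos = 47L, ref = "TT", alt = "T")
  out <- build_consensus(list(left, right), ref)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_callers, 2L)
})

test_that("non-PASS records never reach consensus; duplicate keys error", {
  ref <- test_reference()
  pos <- 4000L
  b <- ref_seq(ref, "chr1", pos)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  lq <- call_row("mutect2", pos = pos, ref = b, alt = alt, filter = "LowQual")
  ok <- call_row("strelka2", pos = pos, ref = b, alt = alt)
  ok2 <- call_row("muse", pos = pos, ref = b, alt = alt)
  out <- build_consensus(list(lq, ok, ok2), ref)
  expect_equal(out$callers, "muse,strelka2")
  dup <- rbind(call_row("mutect2", pos = pos, ref = b, alt = alt),
               call_row("mutect2", pos = pos, ref = b, alt = alt))
  expect_error(build_consensus(list(dup, ok), ref), "duplicate")
})

test_that("with perfect callers, consensus recovers the truth set exactly", {
  ref <- test_reference()
  cfg <- clean_config(seed = 31L, n_mutations = 150L, n_genes = 30L)
  sim <- simulate_mutation_set(cfg, ref)
  cs <- consensus_from_simulation(sim)
  for (comp in c("Neg", "Abr")) {
    expect_setequal(cs[[comp]]$key, true_component_keys(sim, comp))
  }
})
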