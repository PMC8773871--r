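test_that("config validation rejects malformed study parameters", {
  expect_error(simulation_config(trunk_fraction = 1.2), "trunk_fraction")
  expect_error(simulation_config(signature_mixture = c(SBS1 = 0.6, SBS5 = 0.5)),
               "sum to")
  expect_error(simulation_config(signature_mixture = c(BOGUS = 1)),
               "not in catalogue")
  expect_error(simulation_config(purity = 0))
  expect_silent(simulation_config(trunk_fraction = 0))
  expect_silent(simulation_config(trunk_fraction = 1))
})

test_that("identical config and seed give identical simulations", {
  ref <- test_reference()
  cfg <- simulation_config(seed = 55L, n_mutations = 120L, n_genes = 30L)
  s1 <- simulate_mutation_set(cfg, ref)
  s2 <- simulate_mutation_set(cfg, ref)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$callsets, s2$callsets)
  s3 <- simulate_mutation_set(simulation_config(seed = 56L,
                                                n_mutations = 120L,
                                                n_genes = 30L), ref)
  expect_false(identical(s1$truth$key, s3$truth$key))
})

test_that("written artifacts are byte-identical across reruns", {
  ref <- test_reference()
  cfg <- simulation_config(seed = 60L, n_mutations = 60L, n_genes = 20L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_mutation_set(cfg, ref), d1)
  write_simulation(simulate_mutation_set(cfg, ref), d2)
  for (f in c("Neg.mutect2.vcf", "Abr.strelka2.vcf", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("every emitted call carries exactly one truth label", {
  ref <- test_reference()
  cfg <- simulation_config(seed = 42L, n_mutations = 100L, n_genes = 30L)
  sim <- simulate_mutation_set(cfg, ref)
  expect_false(anyDuplicated(sim$truth$key) > 0)
  labels <- c("truncal", "private_Neg", "private_Abr", "false_positive")
  expect_true(all(sim$truth$label %in% labels))
  for (comp in c("Neg", "Abr")) {
    for (caller in names(sim$callsets[[comp]])) {
      calls <- sim$callsets[[comp]][[caller]]
      norm <- normalize_variants(calls, ref)
      expect_true(all(norm$key %in% sim$truth$key),
                  info = paste(comp, caller))
    }
  }
  expect_true(all(sim$truth$true_vaf_Neg >= 0 & sim$truth$true_vaf_Neg <= 1))
})

test_that("trunk fraction extremes give full sharing and full collision", {
  ref <- test_reference()
  for (tf in c(0, 1)) {
    cfg <- clean_config(seed = 70L + tf, n_mutations = 150L,
                        trunk_fraction = tf, n_genes = 20L)
    sim <- simulate_mutation_set(cfg, ref)
    cs <- consensus_from_simulation(sim)
    ov <- overlap_coefficient(cs$Neg$key, cs$Abr$key)
    expect_equal(ov, tf)
  }
})

test_that("mean VAF of truncal diploid-het mutations converges to purity/2", {
  ref <- big_reference()
  cfg <- clean_config(seed = 81L, n_mutations = 1000L, trunk_fraction = 1,
                      purity = 0.8, mean_depth_tumour = 500)
  sim <- simulate_mutation_set(cfg, ref)
  reads <- sim$reads$Neg
  truncal <- sim$truth$key[sim$truth$label == "truncal"]
  obs <- reads$tumour_alt[reads$key %in% truncal] /
    reads$tumour_depth[reads$key %in% truncal]
  expect_lt(abs(mean(obs) - 0.4), 0.01)
})

test_that("caller error profiles shape the callsets as configured", {
  ref <- test_reference()
  cp <- default_caller_profiles()
  cp$sensitivity <- c(1, 0.5, 1)
  cp$fp_count <- c(0L, 0L, 40L)
  cfg <- simulation_config(seed = 90L, n_mutations = 200L,
                           caller_profiles = cp, indel_fraction = 0,
                           n_common = 0L, n_multiallelic = 0L,
                           n_shared_artifacts = 0L, n_lowqual = 0L,
                           n_genes = 20L)
  sim <- simulate_mutation_set(cfg, ref)
  n_true_neg <- length(true_component_keys(sim, "Neg"))
  expect_equal(nrow(sim$callsets$Neg$mutect2), n_true_neg)
  # ~50% sensitivity caller misses about half
  frac <- nrow(sim$callsets$Neg$strelka2) / n_true_neg
  expect_gt(frac, 0.35); expect_lt(frac, 0.65)
  # FP-only surplus for muse
  expect_equal(nrow(sim$callsets$Neg$muse), n_true_neg + 40L)
  fp_truth <- sim$truth[sim$truth$label == "false_positive", ]
  expect_true(all(fp_truth$true_vaf_Neg == 0))
})

test_that("subclonal mutations appear at purity * ccf / 2", {
  ref <- test_reference()
  cfg <- clean_config(seed = 95L, n_mutations = 50L, purity = 0.6,
                      subclones = list(Neg = data.frame(ccf = 0.5, n = 80L),
                                       Abr = NULL),
                      n_genes = 20L)
  sim <- simulate_mutation_set(cfg, ref)
  sub <- sim$truth[grepl("^subclone_Neg", sim$truth$label), ]
  expect_equal(nrow(sub), 80L)
  expect_true(all(sub$true_vaf_Neg == 0.6 * 0.5 / 2))
  expect_true(all(sub$true_vaf_Abr == 0))
})
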