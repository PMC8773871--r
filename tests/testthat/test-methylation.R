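probe_row <- function(probe_id = "cg1", chrom = "chr1", gene = "CDH1",
                      promoter = TRUE, beta_Neg = 0.1, beta_Abr = 0.1,
                      detp_Neg = 0.001, detp_Abr = 0.001,
                      snp_at_cpg = FALSE, cross_reactive = FALSE) {
  data.frame(probe_id = probe_id, chrom = chrom, pos = 1000L, gene = gene,
             region = "TSS200", promoter = promoter, snp_at_cpg = snp_at_cpg,
             cross_reactive = cross_reactive, beta_Neg = beta_Neg,
             beta_Abr = beta_Abr, detp_Neg = detp_Neg, detp_Abr = detp_Abr,
             stringsAsFactors = FALSE)
}

test_that("status call is strict at the 0.3 boundary", {
  expect_equal(call_status(c(0.31, 0.30, 0)),
               c("methylated", "unmethylated", "unmethylated"))
  expect_error(call_status(1.2), "\\[0, 1\\]")
  expect_error(call_status(NA_real_), "\\[0, 1\\]")
})

test_that("probe filter: one removal per criterion, boundary p kept", {
  fx <- rbind(
    probe_row("f_detp", detp_Abr = 0.06),
    probe_row("f_chry", chrom = "chrY"),
    probe_row("f_snp", snp_at_cpg = TRUE),
    probe_row("f_cross", cross_reactive = TRUE),
    probe_row("k1"), probe_row("k2"), probe_row("k3"),
    probe_row("k4", detp_Neg = 0.05), # strict >: exactly 0.05 is kept
    probe_row("k5"), probe_row("k6")
  )
  res <- filter_probes(fx)
  expect_equal(res$report$n_pass, 6L)
  expect_setequal(res$probes$probe_id, paste0("k", 1:6))
  expect_equal(res$report$per_criterion$removed, rep(1L, 4L))
  expect_equal(sum(res$report$per_criterion$removed) + res$report$n_pass,
               res$report$n_input)
  # idempotent
  again <- filter_probes(res$probes)
  expect_equal(sum(again$report$per_criterion$removed), 0L)
  # missing detection p is an error
  fx_na <- probe_row("na1"); fx_na$detp_Neg <- NA_real_
  expect_error(filter_probes(fx_na), "missing detection p-value")
})

test_that("differential probes need opposite status AND delta >= 0.1", {
  fx <- rbind(
    probe_row("in1", beta_Neg = 0.45, beta_Abr = 0.25),  # opposite, 0.20
    probe_row("out_delta", beta_Neg = 0.35, beta_Abr = 0.28), # 0.07 too small
    probe_row("out_status", beta_Neg = 0.50, beta_Abr = 0.80), # same status
    probe_row("out_body", beta_Neg = 0.45, beta_Abr = 0.25, promoter = FALSE),
    probe_row("in2", gene = "CDH3", beta_Neg = 0.05, beta_Abr = 0.62)
  )
  dp <- differential_probes(fx)
  expect_setequal(dp$probe_id, c("in1", "in2"))
  expect_equal(dp$delta[dp$probe_id == "in1"], 0.20)
  expect_equal(dp$status_neg[dp$probe_id == "in1"], "methylated")
  # gene filter restricts
  dp2 <- differential_probes(fx, gene_filter = "CDH3")
  expect_equal(dp2$probe_id, "in2")
  # symmetric up to field swap
  rev <- differential_probes(fx, neg = "Abr", abr = "Neg")
  expect_setequal(rev$probe_id, dp$probe_id)
  expect_equal(rev$beta_neg[rev$probe_id == "in1"],
               dp$beta_abr[dp$probe_id == "in1"])
  expect_error(differential_probes(fx, neg = "XX"), "unknown sample")
})

test_that("promoter summary flags planted hypermethylation, reports no-data", {
  fx <- rbind(
    probe_row("a1", gene = "CTNNA1", beta_Neg = 0.7, beta_Abr = 0.1),
    probe_row("a2", gene = "CTNNA1", beta_Neg = 0.8, beta_Abr = 0.05),
    probe_row("a3", gene = "CTNNA1", beta_Neg = 0.75, beta_Abr = 0.2),
    probe_row("b1", gene = "CDH1", beta_Neg = 0.05, beta_Abr = 0.05)
  )
  s <- promoter_methylation_summary(fx, genes = c("CTNNA1", "CDH1", "APC"))
  neg_a <- s[s$gene == "CTNNA1" & s$sample == "Neg", ]
  expect_true(neg_a$promoter_methylated)
  expect_equal(neg_a$fraction, 1)
  abr_a <- s[s$gene == "CTNNA1" & s$sample == "Abr", ]
  expect_false(abr_a$promoter_methylated)
  expect_false(s[s$gene == "CDH1" & s$sample == "Neg", "promoter_methylated"])
  nd <- s[s$gene == "APC", ]
  expect_equal(nd$n_probes, c(0L, 0L))
  expect_true(all(is.na(nd$promoter_methylated)))
})

test_that("simulator-planted differential probes are recovered exactly", {
  ref <- test_reference()
  cfg <- simulation_config(seed = 12L, n_probes = 2000L,
                           discordant_probe_fraction = 0.01,
                           methyl_events = data.frame(gene = "APC",
                                                      component = "Abr"))
  withr::with_seed(12, {
    genes <- simulate_genes(ref, 50L)
    meth <- simulate_methylation(cfg, genes)
  })
  filtered <- filter_probes(meth$probes)
  dp <- differential_probes(filtered$probes)
  # planted probe-level truth plus the gene-level event probes
  apc_probes <- meth$probes$probe_id[meth$probes$gene == "APC" &
                                       meth$probes$promoter]
  expect_setequal(dp$probe_id,
                  union(meth$truth$differential_probes, apc_probes))
  # gene-level event flagged in the right component
  s <- promoter_methylation_summary(filtered$probes, genes = "APC")
  expect_true(s[s$sample == "Abr", "promoter_methylated"])
  expect_false(s[s$sample == "Neg", "promoter_methylated"])
  # no discordance planted, none detected
  cfg0 <- simulation_config(seed = 13L, n_probes = 1000L,
                            discordant_probe_fraction = 0)
  withr::with_seed(13, meth0 <- simulate_methylation(cfg0, genes))
  dp0 <- differential_probes(filter_probes(meth0$probes)$probes)
  expect_equal(nrow(dp0), 0L)
})
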