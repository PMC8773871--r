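# Shared fixtures, built in code. The small reference serves most tests;
# the larger one (built lazily, once) serves the statistical recovery
# checks that need room for tens of thousands of context-matched sites.

test_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) {
      ref <<- simulate_reference(seed = 99L, n_contigs = 2L,
                                 contig_length = 60000L)
    }
    ref
  }
})

big_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) {
      ref <<- simulate_reference(seed = 5L, n_contigs = 5L,
                                 contig_length = 200000L)
    }
    ref
  }
})

# reference built from explicit sequence, for hand-constructed indel cases
literal_reference <- function(...) {
  seqs <- c(...)
  hetpair:::new_hp_reference(Biostrings::DNAStringSet(seqs))
}

# caller profiles with perfect sensitivity and no injected errors
perfect_callers <- function() {
  cp <- default_caller_profiles()
  cp$sensitivity <- 1
  cp$fp_count <- 0L
  cp$vaf_noise_sd <- 0
  cp
}

# config for clean statistical recovery runs (no contaminants)
clean_config <- function(seed, n_mutations, trunk_fraction = 0.6, ...) {
  simulation_config(
    seed = seed, n_mutations = n_mutations, trunk_fraction = trunk_fraction,
    caller_profiles = perfect_callers(), indel_fraction = 0,
    n_multiallelic = 0L, n_common = 0L, n_shared_artifacts = 0L,
    n_lowqual = 0L, ...
  )
}

# a consensus-shaped data.frame row for filter tests
consensus_row <- function(key = "chr1:1:C:T", multiallelic = FALSE,
                          pop_af = 0, vaf = 0.2, tumour_depth = 40L,
                          normal_depth = 35L, tumour_alt = 8L,
                          normal_alt = 0L, func_class = "nonsynonymous",
                          class = "SNV", gene = "GENE001") {
  data.frame(key = key, class = class, multiallelic = multiallelic,
             pop_af = pop_af, vaf = vaf, tumour_depth = tumour_depth,
             normal_depth = normal_depth, tumour_alt = tumour_alt,
             normal_alt = normal_alt, func_class = func_class, gene = gene,
             stringsAsFactors = FALSE)
}

# the twelve-variant filter fixture: one violation per rule + six clean
filter_fixture <- function() {
  rbind(
    consensus_row("v_multi", multiallelic = TRUE),
    consensus_row("v_common", pop_af = 0.02),
    consensus_row("v_lowvaf", vaf = 0.005),
    consensus_row("v_lowdepth", tumour_depth = 9L, normal_depth = 50L),
    consensus_row("v_altreads", tumour_alt = 4L),
    consensus_row("v_synon", func_class = "synonymous"),
    consensus_row("p1"),
    consensus_row("p2", vaf = 0.01),                    # boundary: kept
    consensus_row("p3", tumour_alt = 5L),               # boundary: kept
    consensus_row("p4", normal_alt = 2L),               # boundary: kept
    consensus_row("p5", tumour_depth = 10L, normal_depth = 10L), # boundary
    consensus_row("p6", pop_af = 0.01)                  # boundary: kept
  )
}

# one VariantCall-shaped row for consensus tests
call_row <- function(caller, chrom = "chr1", pos = 100L, ref = "C",
                     alt = "T", vaf = NA_real_, tumour_depth = 50L,
                     tumour_alt = 15L, normal_depth = 30L, normal_alt = 0L,
                     filter = "PASS") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             caller = caller, filter = filter, tumour_depth = tumour_depth,
             tumour_alt = tumour_alt, normal_depth = normal_depth,
             normal_alt = normal_alt, vaf = vaf, pop_af = 0,
             func_class = "nonsynonymous", gene = "GENE001",
             multiallelic = FALSE, stringsAsFactors = FALSE)
}
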