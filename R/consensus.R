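# Multi-caller consensus. High-confidence SNVs are those called by at least
# 2 of the 3 SNV callers; high-confidence indels are those shared by the two
# indel-capable callers. Cross-caller matching happens on normalized keys,
# and the resolved VAF follows a caller precedence (first caller reporting
# an allele fraction wins, falling back to tumour_alt/tumour_depth).

#' Build a consensus callset from per-caller calls
#'
#' @param callsets Named list of per-caller call data.frames (as returned by
#'   [read_caller_vcf()] or found in an `hp_simulation`); names are ignored,
#'   the `caller` column identifies the caller. Non-PASS records are
#'   dropped. Duplicate normalized keys within one caller are an error.
#' @param reference `hp_reference` used for key normalization.
#' @param snv_callers Callers whose SNV calls count towards the 2-of-3 rule.
#' @param indel_callers The pair of callers that must both support an indel.
#' @param vaf_precedence Caller order used to resolve the consensus VAF; the
#'   first listed caller with a reported allele fraction wins, otherwise the
#'   fraction is computed from the precedence caller's read counts.
#' @param min_snv_callers Minimum supporting SNV callers (default 2).
#' @return data.frame of class `consensus_callset`: one row per retained
#'   variant with `key`, normalized coordinates/alleles, `class`
#'   (`SNV`/`indel`), `callers` (comma-joined supporters), `n_callers`,
#'   resolved `vaf`, read counts, `pop_af`, `func_class`, `gene`,
#'   `multiallelic`.
#' @export
build_consensus <- function(callsets, reference,
                            snv_callers = c("mutect2", "strelka2", "muse"),
                            indel_callers = c("mutect2", "strelka2"),
                            vaf_precedence = c("mutect2", "strelka2"),
                            min_snv_callers = 2L) {
  stopifnot(length(indel_callers) == 2L)
  all_calls <- data.table::rbindlist(callsets, use.names = TRUE)
  if (!nrow(all_calls)) return(.empty_consensus())
  if ("filter" %in% names(all_calls)) {
    all_calls <- all_calls[all_calls$filter == "PASS", ]
  }
  all_calls <- as.data.frame(all_calls)
  all_calls <- normalize_variants(all_calls, reference)
  dup <- duplicated(all_calls[, c("caller", "key")])
  if (any(dup)) {
    stop("duplicate variant key within one caller: ",
         all_calls$caller[dup][1L], " ", all_calls$key[dup][1L])
  }
  dt <- data.table::as.data.table(all_calls)
  caller_rank <- c(vaf_precedence,
                   setdiff(unique(dt$caller), vaf_precedence))
  data.table::setorderv(dt[, rank := match(caller, caller_rank)], "rank")
  agg <- dt[, {
    vaf_res <- vaf[!is.na(vaf)][1L]
    if (is.na(vaf_res)) vaf_res <- tumour_alt[1L] / max(tumour_depth[1L], 1L)
    list(
      chrom = chrom[1L], pos = pos[1L], ref = ref[1L], alt = alt[1L],
      callers = paste(sort(unique(caller)), collapse = ","),
      n_callers = length(unique(caller)),
      vaf = vaf_res,
      tumour_depth = tumour_depth[1L], tumour_alt = tumour_alt[1L],
      normal_depth = normal_depth[1L], normal_alt = normal_alt[1L],
      pop_af = pop_af[1L], func_class = func_class[1L], gene = gene[1L],
      multiallelic = any(multiallelic),
      support = list(unique(caller))
    )
  }, by = "key"]
  agg$class <- variant_class(agg$ref, agg$alt)
  snv_support <- vapply(agg$support, function(s) {
    sum(s %in% snv_callers)
  }, integer(1))
  indel_support <- vapply(agg$support, function(s) {
    all(indel_callers %in% s)
  }, logical(1))
  keep <- ifelse(agg$class == "SNV",
                 snv_support >= min_snv_callers, indel_support)
  out <- as.data.frame(agg[keep, ])
  out$support <- NULL
  out <- out[order(out$chrom, out$pos, out$alt),
             c("key", "chrom", "pos", "ref", "alt", "class", "callers",
               "n_callers", "vaf", "tumour_depth", "tumour_alt",
               "normal_depth", "normal_alt", "pop_af", "func_class", "gene",
               "multiallelic")]
  rownames(out) <- NULL
  class(out) <- c("consensus_callset", "data.frame")
  out
}

.empty_consensus <- function() {
  out <- data.frame(
    key = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), class = character(0),
    callers = character(0), n_callers = integer(0), vaf = numeric(0),
    tumour_depth = integer(0), tumour_alt = integer(0),
    normal_depth = integer(0), normal_alt = integer(0), pop_af = numeric(0),
    func_class = character(0), gene = character(0), multiallelic = logical(0)
  )
  class(out) <- c("consensus_callset", "data.frame")
  out
}

#' Consensus callsets for both components of a simulation
#'
#' Convenience wrapper running [build_consensus()] on each component's
#' simulated caller callsets.
#'
#' @param sim An `hp_simulation`.
#' @param ... Passed to [build_consensus()].
#' @return Named list `list(Neg = , Abr = )` of consensus callsets.
#' @export
consensus_from_simulation <- function(sim, ...) {
  lapply(sim$callsets, function(cs) {
    build_consensus(cs, sim$reference, ...)
  })
}
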