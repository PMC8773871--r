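# Paired-component relatedness statistics: shared/private partition of the
# two callsets, overlap coefficients per variant class, six-class
# substitution spectra, and the per-gene recurrence proportion test.

#' Overlap coefficient of two key sets
#'
#' `|A intersect B| / min(|A|, |B|)`, the set-similarity statistic used to
#' compare the mutation repertoires of two tumour components; robust to
#' unequal set sizes. Defined as 0 when either set is empty.
#'
#' @param a,b Character vectors (duplicates ignored).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' overlap_coefficient(letters[1:5], letters[3:6])
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Partition two component callsets into shared and private sets
#'
#' Builds the `component_pair` summary: shared and private variant keys and
#' the overlap coefficient, computed separately for SNVs and indels.
#'
#' @param neg,abr `consensus_callset` data.frames for the two components
#'   (typically the filtered callsets).
#' @param tumour_id Label carried through to reports.
#' @return List of class `component_pair` with elements `tumour_id`,
#'   `shared`, `private_neg`, `private_abr` (each split by class),
#'   `overlap_snv`, `overlap_indel` and set sizes.
#' @export
component_pair <- function(neg, abr, tumour_id = "tumour") {
  split_keys <- function(cs) {
    list(SNV = cs$key[cs$class == "SNV"],
         indel = cs$key[cs$class == "indel"])
  }
  kn <- split_keys(neg); ka <- split_keys(abr)
  part <- lapply(c(SNV = "SNV", indel = "indel"), function(cl) {
    list(shared = intersect(kn[[cl]], ka[[cl]]),
         private_neg = setdiff(kn[[cl]], ka[[cl]]),
         private_abr = setdiff(ka[[cl]], kn[[cl]]))
  })
  structure(list(
    tumour_id = tumour_id,
    shared = lapply(part, `[[`, "shared"),
    private_neg = lapply(part, `[[`, "private_neg"),
    private_abr = lapply(part, `[[`, "private_abr"),
    overlap_snv = overlap_coefficient(kn$SNV, ka$SNV),
    overlap_indel = overlap_coefficient(kn$indel, ka$indel),
    n_neg = vapply(kn, length, integer(1)),
    n_abr = vapply(ka, length, integer(1))
  ), class = "component_pair")
}

#' @export
print.component_pair <- function(x, ...) {
  cat("component_pair", x$tumour_id, "\n")
  cat(sprintf("  SNV:   Neg %d, Abr %d, shared %d, overlap %.3f\n",
              x$n_neg[["SNV"]], x$n_abr[["SNV"]],
              length(x$shared$SNV), x$overlap_snv))
  cat(sprintf("  indel: Neg %d, Abr %d, shared %d, overlap %.3f\n",
              x$n_neg[["indel"]], x$n_abr[["indel"]],
              length(x$shared$indel), x$overlap_indel))
  invisible(x)
}

#' Six-class substitution spectrum in pyrimidine context
#'
#' Folds every SNV onto the pyrimidine strand (a `G>A` counts as `C>T`) and
#' returns the relative fraction of the six base-substitution classes
#' `C>A, C>G, C>T, T>A, T>C, T>G`.
#'
#' @param snvs data.frame with single-base `ref`/`alt` columns (indel rows
#'   are rejected); a reference allele outside A/C/G/T is an error.
#' @return Named numeric vector of six fractions summing to 1, or all zero
#'   (with attribute `empty = TRUE`) when no SNVs are supplied.
#' @export
substitution_spectrum <- function(snvs) {
  if (nrow(snvs) == 0L) {
    out <- stats::setNames(numeric(6L), SBS_SUBSTITUTIONS)
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (any(!is_snv(snvs$ref, snvs$alt))) {
    stop("substitution_spectrum expects SNVs only")
  }
  folded <- fold_pyrimidine(snvs$ref, snvs$alt)
  cls <- paste0(folded$ref, ">", folded$alt)
  counts <- table(factor(cls, levels = SBS_SUBSTITUTIONS))
  out <- as.numeric(counts) / sum(counts)
  names(out) <- SBS_SUBSTITUTIONS
  attr(out, "empty") <- FALSE
  out
}

#' Per-gene recurrence proportion test between two sample groups
#'
#' Counts, per gene, the samples in each group carrying at least one
#' qualifying variant (variants annotated to non-genic regions --
#' intergenic, upstream, downstream -- are excluded), keeps genes whose
#' absolute count difference between groups reaches `min_diff`, and runs a
#' two-sample proportion test (chi-squared with continuity correction, or
#' Fisher's exact) on those. Benjamini-Hochberg FDR is reported alongside
#' the raw p-values.
#'
#' @param group1,group2 Lists of callset data.frames (one per sample), each
#'   with `gene` and `func_class` columns.
#' @param min_diff Minimum absolute difference in carrier counts for a gene
#'   to be tested.
#' @param method `"prop"` (default) or `"fisher"`.
#' @param exclude_classes Functional classes treated as non-genic.
#' @return data.frame per gene: carrier counts and proportions per group,
#'   `diff`, `tested`, `p_value`, `fdr` (NA for untested genes), sorted by
#'   p-value then absolute difference.
#' @export
recurrence_test <- function(group1, group2, min_diff = 3L,
                            method = c("prop", "fisher"),
                            exclude_classes = c("intergenic", "upstream",
                                                "downstream")) {
  method <- match.arg(method)
  if (!length(group1) || !length(group2)) {
    stop("both groups must contain at least one sample")
  }
  carriers <- function(group) {
    per_sample <- lapply(group, function(cs) {
      g <- cs$gene[!is.na(cs$gene) & !(cs$func_class %in% exclude_classes)]
      unique(g)
    })
    table(unlist(per_sample))
  }
  c1 <- carriers(group1); c2 <- carriers(group2)
  genes <- sort(union(names(c1), names(c2)))
  x1 <- as.integer(ifelse(genes %in% names(c1), c1[genes], 0L))
  x2 <- as.integer(ifelse(genes %in% names(c2), c2[genes], 0L))
  n1 <- length(group1); n2 <- length(group2)
  diff <- x1 - x2
  tested <- abs(diff) >= min_diff
  p <- rep(NA_real_, length(genes))
  for (i in which(tested)) {
    p[i] <- if (method == "prop") {
      suppressWarnings(
        stats::prop.test(c(x1[i], x2[i]), c(n1, n2))$p.value)
    } else {
      m <- matrix(c(x1[i], n1 - x1[i], x2[i], n2 - x2[i]), nrow = 2L)
      stats::fisher.test(m)$p.value
    }
  }
  fdr <- rep(NA_real_, length(genes))
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(
    gene = genes, carriers1 = x1, n1 = n1, carriers2 = x2, n2 = n2,
    prop1 = x1 / n1, prop2 = x2 / n2, diff = diff, tested = tested,
    p_value = p, fdr = fdr, stringsAsFactors = FALSE
  )
  out[order(out$p_value, -abs(out$diff)), , drop = FALSE]
}
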