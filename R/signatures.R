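# 96-channel mutational-signature profiling: trinucleotide-context profiles
# from SNV callsets, cosine similarity against a signature catalogue, and
# complete-linkage clustering of the similarity matrix.

#' Build a 96-channel SBS profile from SNVs
#'
#' Looks up the trinucleotide context of every SNV in the reference, folds
#' purine-reference substitutions onto the pyrimidine strand (reverse
#' complementing the context), and counts occurrences over the 96 canonical
#' channels. SNVs at contig edges (no flanking base) are skipped and
#' counted in the `n_skipped` attribute with a warning.
#'
#' @param snvs data.frame with `chrom`, `pos`, `ref`, `alt` (single-base
#'   alleles; the stated ref must match the reference sequence).
#' @param reference A `hp_reference`.
#' @param sample_id Label attached to the profile.
#' @return Integer vector of length 96 (class `sbs_profile`) named by
#'   channel, with attributes `sample_id` and `n_skipped`. Counts total the
#'   number of non-skipped SNVs.
#' @export
build_sbs_profile <- function(snvs, reference, sample_id = "sample") {
  if (nrow(snvs) && any(!is_snv(snvs$ref, snvs$alt))) {
    stop("build_sbs_profile expects SNVs only")
  }
  channels <- sbs_channels()
  counts <- stats::setNames(integer(96L), channels)
  n_skipped <- 0L
  if (nrow(snvs)) {
    lens <- ref_lengths(reference)
    at_edge <- snvs$pos <= 1L | snvs$pos >= lens[snvs$chrom]
    n_skipped <- sum(at_edge)
    if (n_skipped) {
      warning(n_skipped, " SNV(s) at contig edges skipped (no flanking base)")
      snvs <- snvs[!at_edge, , drop = FALSE]
    }
    if (nrow(snvs)) {
      ctx <- character(nrow(snvs))
      for (chrom in unique(snvs$chrom)) {
        i <- snvs$chrom == chrom
        ctx[i] <- ref_context(reference, chrom, snvs$pos[i])
      }
      mismatch <- substr(ctx, 2L, 2L) != snvs$ref
      if (any(mismatch)) {
        j <- which(mismatch)[1L]
        stop("reference mismatch at ", snvs$chrom[j], ":", snvs$pos[j],
             " (stated ref ", snvs$ref[j], ", reference has ",
             substr(ctx[j], 2L, 2L), ")")
      }
      folded <- fold_pyrimidine(snvs$ref, snvs$alt, ctx)
      tab <- table(factor(folded$channel, levels = channels))
      counts <- stats::setNames(as.integer(tab), channels)
    }
  }
  structure(counts, class = "sbs_profile", sample_id = sample_id,
            n_skipped = n_skipped)
}

#' @export
print.sbs_profile <- function(x, ...) {
  cat("sbs_profile", attr(x, "sample_id"), ":", sum(x), "mutations")
  if (attr(x, "n_skipped") > 0L) cat(",", attr(x, "n_skipped"), "skipped")
  cat("\n")
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  cat("  top channels:",
      paste(names(top), top, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Cosine similarity of two non-negative vectors
#'
#' `dot(p, q) / (||p|| * ||q||)`; scale-invariant, so raw channel counts
#' and normalized probability profiles give identical results. Both inputs
#' must be non-negative and not all zero.
#'
#' @param p,q Numeric vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("vectors must be non-negative")
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) stop("cosine similarity undefined for zero vector")
  sum(p * q) / (np * nq)
}

#' Similarity of sample profiles to a signature catalogue
#'
#' Validates that profile and catalogue use the same channels (by name, in
#' order) and computes the full samples x signatures cosine-similarity
#' matrix with the best-matching signature per sample.
#'
#' @param profiles A single `sbs_profile` or list of them.
#' @param catalog 96 x S matrix from [load_signature_catalog()] or
#'   [synthetic_signature_catalog()].
#' @return Matrix of class `signature_similarity` (samples x signatures)
#'   with attribute `best_match` (named character vector).
#' @export
profile_catalog_similarity <- function(profiles, catalog) {
  if (inherits(profiles, "sbs_profile")) profiles <- list(profiles)
  chan <- rownames(catalog)
  for (pr in profiles) {
    mism <- names(pr) != chan
    if (any(mism)) {
      stop("channel order mismatch between profile and catalogue; first ",
           "discordant channel: profile '", names(pr)[which(mism)[1L]],
           "' vs catalogue '", chan[which(mism)[1L]], "'")
    }
  }
  ids <- vapply(seq_along(profiles), function(i) {
    attr(profiles[[i]], "sample_id") %||% paste0("sample", i)
  }, character(1))
  sim <- t(vapply(profiles, function(pr) {
    vapply(seq_len(ncol(catalog)), function(j) {
      cosine_similarity(as.numeric(pr), catalog[, j])
    }, numeric(1))
  }, numeric(ncol(catalog))))
  dimnames(sim) <- list(ids, colnames(catalog))
  best <- colnames(sim)[max.col(sim)]
  structure(sim, class = c("signature_similarity", "matrix"),
            best_match = stats::setNames(best, ids))
}

#' Complete-linkage clustering of a similarity matrix
#'
#' Agglomerative hierarchical clustering with complete linkage and
#' Euclidean distance, applied independently to the rows and the columns of
#' the matrix (the layout used for signature-similarity heatmaps). Requires
#' at least 2 rows and 2 columns; any non-finite entry is an error.
#'
#' @param mat Numeric matrix (e.g. a `signature_similarity`).
#' @return List with `row_hclust`, `col_hclust` (stats::hclust objects) and
#'   `row_order`, `col_order` (leaf orders as labels).
#' @export
cluster_similarity <- function(mat) {
  mat <- unclass(mat)
  attr(mat, "best_match") <- NULL
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("need at least 2 rows and 2 columns to cluster")
  }
  if (any(!is.finite(mat))) stop("similarity matrix contains non-finite values")
  rh <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  ch <- stats::hclust(stats::dist(t(mat), method = "euclidean"),
                      method = "complete")
  list(
    row_hclust = rh, col_hclust = ch,
    row_order = rownames(mat)[rh$order],
    col_order = colnames(mat)[ch$order]
  )
}
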