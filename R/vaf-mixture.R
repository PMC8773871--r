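# Subclone detection as a binomial mixture on (alt, depth) read counts.
# This is a deliberately simple clonality readout -- an EM fit of k binomial
# components with BIC model selection -- not a re-implementation of full
# subclonal-deconvolution machinery (no power-law tail for neutral drift,
# no copy-number-aware cancer-cell-fraction transformation). k-quantile
# initialization makes the fit deterministic.

#' Fit a binomial mixture to variant allele counts
#'
#' For each `k = 1..k_max`, fits a k-component binomial mixture to
#' `(alt, depth)` pairs by EM (success probabilities initialized at the k
#' interior quantiles of `alt/depth`, equal weights) and selects k by BIC.
#' Intended as a clonality readout: one component at the clonal VAF means a
#' homogeneous tumour sample, a second lower-VAF component suggests a
#' subclone.
#'
#' @param alt,depth Integer vectors of alternate-supporting reads and total
#'   depth per variant. At least 20 variants are required and at least one
#'   nonzero alt count; degenerate input is refused with a message.
#' @param k_max Largest number of components considered (>= 1).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return List of class `subclone_fit`: `k`, `means` (component VAFs,
#'   increasing), `weights` (sum to 1), `assignment` (per-variant component
#'   by maximum responsibility), `loglik`, `bic` (named vector over
#'   candidate k), `n`.
#' @export
fit_vaf_mixture <- function(alt, depth, k_max = 3L, max_iter = 500L,
                            tol = 1e-8) {
  stopifnot(length(alt) == length(depth), k_max >= 1L)
  if (length(alt) < 20L) {
    stop("refusing to fit a VAF mixture to fewer than 20 variants (got ",
         length(alt), ")")
  }
  if (any(alt < 0 | depth <= 0 | alt > depth)) {
    stop("invalid read counts: need 0 <= alt <= depth, depth > 0")
  }
  if (all(alt == 0L)) {
    stop("degenerate input: all alt counts are zero")
  }
  fits <- lapply(seq_len(k_max), function(k) .binom_mix_em(alt, depth, k,
                                                           max_iter, tol))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  names(bic) <- paste0("k", seq_len(k_max))
  best <- unname(which.min(bic))
  fit <- fits[[best]]
  structure(list(
    k = best, means = fit$p, weights = fit$w, assignment = fit$assignment,
    loglik = fit$loglik, bic = bic, n = length(alt)
  ), class = "subclone_fit")
}

.binom_mix_em <- function(alt, depth, k, max_iter, tol) {
  n <- length(alt)
  vaf <- alt / depth
  eps <- 1e-4
  p <- clip01(stats::quantile(vaf, probs = (seq_len(k) - 0.5) / k,
                              names = FALSE, type = 7), eps, 1 - eps)
  # coincident quantiles give a degenerate start; spread them minimally
  p <- sort(p + seq(0, k - 1) * 1e-6)
  w <- rep(1 / k, k)
  loglik_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      stats::dbinom(alt, depth, p[j], log = TRUE) + log(w[j])
    }, numeric(n))
    if (k == 1L) logd <- matrix(logd, ncol = 1L)
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    loglik <- sum(lse)
    resp <- exp(logd - lse)
    w <- colMeans(resp)
    p <- clip01(colSums(resp * alt) / colSums(resp * depth), eps, 1 - eps)
    if (is.finite(loglik_old) &&
        abs(loglik - loglik_old) < tol * (abs(loglik_old) + 1)) break
    loglik_old <- loglik
  }
  ord <- order(p)
  p <- p[ord]; w <- w[ord]
  resp <- resp[, ord, drop = FALSE]
  structure_free <- 2L * k - 1L # k means + k-1 free weights
  list(
    p = unname(p), w = unname(w),
    assignment = max.col(resp),
    loglik = loglik,
    bic = -2 * loglik + structure_free * log(n)
  )
}

#' @export
print.subclone_fit <- function(x, ...) {
  cat("subclone_fit: k =", x$k, "on", x$n, "variants\n")
  cat("  means:  ", paste(sprintf("%.3f", x$means), collapse = "  "), "\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = "  "), "\n")
  cat("  BIC:    ", paste(sprintf("%s=%.1f", names(x$bic), x$bic),
                          collapse = "  "), "\n")
  invisible(x)
}
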