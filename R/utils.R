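.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

# clip to [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

is_fraction <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

# variant key shared across the whole package
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

is_snv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L

variant_class <- function(ref, alt) ifelse(is_snv(ref, alt), "SNV", "indel")

# weighted sample of one value per draw, vectorised over n
sample_from <- function(values, n, prob = NULL) {
  values[sample.int(length(values), n, replace = TRUE, prob = prob)]
}
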