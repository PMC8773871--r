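# Canonical variant representation. Cross-caller matching of indels requires
# one representation per variant: left-aligned and parsimony-trimmed
# (the "vt normalize" convention). SNVs pass through unchanged and the
# operation is idempotent.

normalize_one <- function(ref_genome, chrom, pos, ref, alt) {
  seen <- ref_seq(ref_genome, chrom, pos, pos + nchar(ref) - 1L)
  if (!identical(seen, ref)) {
    stop("reference mismatch at ", chrom, ":", pos, " expected '", ref,
         "' but reference has '", seen, "'")
  }
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (rl > 0L && al > 0L &&
        substr(ref, rl, rl) == substr(alt, al, al)) {
      ref <- substr(ref, 1L, rl - 1L)
      alt <- substr(alt, 1L, al - 1L)
    } else if (rl == 0L || al == 0L) {
      if (pos == 1L) stop("cannot left-extend variant at ", chrom, ":1")
      pos <- pos - 1L
      b <- ref_seq(ref_genome, chrom, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else {
      break
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variants to left-aligned parsimonious form
#'
#' Left-aligns and trims indels against the reference so that equivalent
#' representations from different callers collapse onto one
#' `(chrom, pos, ref, alt)` key. SNVs are returned unchanged; the operation
#' is idempotent. A reference mismatch (the stated REF allele disagreeing
#' with the reference sequence) is an error naming the position and alleles.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (other columns pass through).
#' @param reference A `hp_reference`.
#' @return The data.frame with `pos`, `ref`, `alt` normalized and `key`
#'   recomputed.
#' @export
normalize_variants <- function(variants, reference) {
  if (nrow(variants) == 0L) {
    variants$key <- character(0)
    return(variants)
  }
  needs <- which(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)
  for (i in needs) {
    res <- normalize_one(reference, variants$chrom[i], variants$pos[i],
                         variants$ref[i], variants$alt[i])
    variants$pos[i] <- res$pos
    variants$ref[i] <- res$ref
    variants$alt[i] <- res$alt
  }
  # SNV ref check (indels were checked inside normalize_one)
  snv <- setdiff(seq_len(nrow(variants)), needs)
  if (length(snv)) {
    seen <- character(length(snv))
    sc <- variants$chrom[snv]
    for (cc in unique(sc)) {
      i <- sc == cc
      seen[i] <- ref_seq(reference, cc, variants$pos[snv][i])
    }
    bad <- seen != variants$ref[snv]
    if (any(bad)) {
      i <- snv[which(bad)[1L]]
      stop("reference mismatch at ", variants$chrom[i], ":", variants$pos[i],
           " expected '", variants$ref[i], "'")
    }
  }
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  variants
}

# Opposite of left-alignment: push an anchored parsimonious indel to its
# right-most equivalent representation. Used by the simulator to emit
# caller-discordant indel representations that consensus building must
# reconcile, and as the round-trip partner of normalization in tests.
shift_right_one <- function(ref_genome, chrom, pos, ref, alt,
                            max_shift = 100L) {
  ctg_len <- unname(ref_lengths(ref_genome)[chrom])
  shifts <- 0L
  if (nchar(ref) > 1L && nchar(alt) == 1L) { # deletion
    L <- nchar(ref) - 1L
    while (shifts < max_shift && pos + 1L + L <= ctg_len &&
           ref_seq(ref_genome, chrom, pos + 1L) ==
           ref_seq(ref_genome, chrom, pos + 1L + L)) {
      pos <- pos + 1L
      shifts <- shifts + 1L
    }
    ref <- ref_seq(ref_genome, chrom, pos, pos + L)
    alt <- substr(ref, 1L, 1L)
  } else if (nchar(alt) > 1L && nchar(ref) == 1L) { # insertion
    ins <- substr(alt, 2L, nchar(alt))
    while (shifts < max_shift && pos + 1L <= ctg_len &&
           substr(ins, 1L, 1L) == ref_seq(ref_genome, chrom, pos + 1L)) {
      pos <- pos + 1L
      ins <- paste0(substr(ins, 2L, nchar(ins)), substr(ins, 1L, 1L))
      shifts <- shifts + 1L
    }
    ref <- ref_seq(ref_genome, chrom, pos)
    alt <- paste0(ref, ins)
  }
  list(pos = pos, ref = ref, alt = alt)
}

shift_right_variants <- function(variants, reference) {
  idx <- which(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)
  for (i in idx) {
    res <- shift_right_one(reference, variants$chrom[i], variants$pos[i],
                           variants$ref[i], variants$alt[i])
    variants$pos[i] <- res$pos
    variants$ref[i] <- res$ref
    variants$alt[i] <- res$alt
  }
  variants
}
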