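# Post hoc somatic filter chain. Six rules applied in a fixed printed
# order, each a pure predicate; a variant is attributed to the FIRST rule it
# fails, so the survivor set is order-independent but the audit trail is
# not. Defaults are the conventional tumour/normal QC values; all of them
# are config so sensitivity analyses are possible.

#' Thresholds for the post hoc filter chain
#'
#' @param max_pop_af Remove variants with population allele frequency above
#'   this (common germline variants); missing AF is treated as 0 (kept).
#' @param min_vaf Remove variants with tumour allele frequency below this
#'   (strict `<`: a VAF exactly at the threshold is kept).
#' @param min_depth Required read depth.
#' @param depth_rule `"both"` (default) removes a variant unless BOTH the
#'   tumour and the matched normal reach `min_depth`; `"either"` requires
#'   only one of the two.
#' @param min_tumour_alt Minimum reads supporting the alternate allele in
#'   the tumour (inclusive: exactly `min_tumour_alt` is kept).
#' @param max_normal_alt Maximum alternate-supporting reads tolerated in the
#'   matched normal (inclusive: exactly `max_normal_alt` is kept).
#' @param drop_synonymous Remove variants annotated `synonymous` (exonic
#'   annotation only; intronic/promoter/intergenic classes pass this rule).
#' @return List of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_pop_af = 0.01,
                              min_vaf = 0.01,
                              min_depth = 10L,
                              depth_rule = c("both", "either"),
                              min_tumour_alt = 5L,
                              max_normal_alt = 2L,
                              drop_synonymous = TRUE) {
  depth_rule <- match.arg(depth_rule)
  structure(list(
    max_pop_af = max_pop_af, min_vaf = min_vaf, min_depth = min_depth,
    depth_rule = depth_rule, min_tumour_alt = min_tumour_alt,
    max_normal_alt = max_normal_alt, drop_synonymous = drop_synonymous
  ), class = "filter_thresholds")
}

.filter_rules <- function(th) {
  list(
    multiallelic = function(v) v$multiallelic,
    common_variant = function(v) !is.na(v$pop_af) & v$pop_af > th$max_pop_af,
    low_vaf = function(v) v$vaf < th$min_vaf,
    low_depth = function(v) {
      if (th$depth_rule == "both") {
        !(v$tumour_depth >= th$min_depth & v$normal_depth >= th$min_depth)
      } else {
        !(v$tumour_depth >= th$min_depth | v$normal_depth >= th$min_depth)
      }
    },
    alt_reads = function(v) {
      !(v$tumour_alt >= th$min_tumour_alt &
          v$normal_alt <= th$max_normal_alt)
    },
    synonymous = function(v) {
      if (!th$drop_synonymous) rep(FALSE, nrow(v))
      else !is.na(v$func_class) & v$func_class == "synonymous"
    }
  )
}

#' Apply the six post hoc filters with a per-variant audit trail
#'
#' Rules, in order: (1) remove multiallelic sites; (2) remove common
#' variants with population allele frequency above 1%; (3) remove variants
#' with tumour allele frequency below 0.01; (4) remove variants without
#' sufficient depth (default: at least 10x in both tumour and normal);
#' (5) keep variants with at least 5 alternate-supporting reads in the
#' tumour and at most 2 in the matched normal; (6) remove synonymous
#' variants. Each variant is attributed to the first rule it fails.
#'
#' @param variants A `consensus_callset` (or any data.frame with the
#'   evidence columns `multiallelic`, `pop_af`, `vaf`, `tumour_depth`,
#'   `normal_depth`, `tumour_alt`, `normal_alt`, `func_class`).
#' @param thresholds A [filter_thresholds()].
#' @return List with `variants` (the survivors, class preserved) and
#'   `report`: `per_filter` (data.frame of rule name and removed count, in
#'   application order) and `per_variant` (key + first failed rule or
#'   `"pass"`). `sum(removed) + passes == nrow(variants)` always holds.
#' @export
apply_post_hoc_filters <- function(variants,
                                   thresholds = filter_thresholds()) {
  rules <- .filter_rules(thresholds)
  needed <- c("multiallelic", "pop_af", "vaf", "tumour_depth",
              "normal_depth", "tumour_alt", "normal_alt", "func_class")
  miss <- setdiff(needed, names(variants))
  if (length(miss)) {
    stop("variants lack evidence fields required by the filter chain: ",
         paste(miss, collapse = ", "))
  }
  for (fld in c("vaf", "tumour_depth", "normal_depth", "tumour_alt",
                "normal_alt")) {
    if (nrow(variants) && anyNA(variants[[fld]])) {
      i <- which(is.na(variants[[fld]]))[1L]
      stop("variant ", variants$key[i] %||% i, " has missing field '", fld,
           "' required by an enabled filter")
    }
  }
  n <- nrow(variants)
  failed <- rep(NA_character_, n)
  for (rule in names(rules)) {
    hits <- rules[[rule]](variants) & is.na(failed)
    failed[hits] <- rule
  }
  per_filter <- data.frame(
    filter = names(rules),
    removed = vapply(names(rules), function(r) sum(failed == r, na.rm = TRUE),
                     integer(1)),
    row.names = NULL
  )
  per_variant <- data.frame(
    key = if ("key" %in% names(variants)) variants$key else as.character(seq_len(n)),
    result = ifelse(is.na(failed), "pass", failed),
    stringsAsFactors = FALSE
  )
  survivors <- variants[is.na(failed), , drop = FALSE]
  rownames(survivors) <- NULL
  list(
    variants = survivors,
    report = list(per_filter = per_filter, per_variant = per_variant,
                  n_input = n, n_pass = nrow(survivors))
  )
}
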