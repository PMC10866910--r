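# Genomic comparator covariates: TMB class, APOBEC enrichment class, clonal
# mutation fraction. The enrichment statistic E itself comes from upstream
# WGS pipelines and is consumed as input.

#' Classify tumor mutational burden
#'
#' TMB at or above the threshold (default 10 mutations per megabase, the
#' pan-cancer pembrolizumab cutoff) is high; below is low.
#'
#' @param tmb numeric vector, mutations per megabase, >= 0.
#' @param threshold classification threshold; default 10.
#' @return factor with levels `high`, `low`.
#' @export
classify_tmb <- function(tmb, threshold = 10) {
  if (any(tmb < 0, na.rm = TRUE)) stop("TMB must be non-negative")
  factor(ifelse(tmb >= threshold, "high", "low"), levels = c("high", "low"))
}

#' Classify APOBEC mutagenesis
#'
#' Fold-enrichment E for APOBEC-context mutations is classified as high when
#' E >= 3, medium when 2 <= E < 3 and low when E < 2 — provided enrichment
#' was detected at all; undetected samples are class `no` regardless of E.
#'
#' @param E numeric vector of fold-enrichment values, >= 0.
#' @param detected logical vector: was APOBEC enrichment detected.
#' @return factor with levels `no`, `low`, `medium`, `high`.
#' @export
classify_apobec <- function(E, detected) {
  if (any(E < 0, na.rm = TRUE)) stop("APOBEC enrichment E must be >= 0")
  if (length(E) != length(detected)) stop("E and detected lengths differ")
  cls <- ifelse(!detected, "no",
                ifelse(E >= 3, "high", ifelse(E >= 2, "medium", "low")))
  factor(cls, levels = c("no", "low", "medium", "high"))
}

#' Binary APOBEC grouping (high vs non-high)
#'
#' The two-group comparison used when contrasting high-APOBEC tumors against
#' all others.
#'
#' @param cls factor from [classify_apobec()].
#' @return factor with levels `high`, `non-high`.
#' @export
apobec_high_vs_rest <- function(cls) {
  factor(ifelse(cls == "high", "high", "non-high"),
         levels = c("high", "non-high"))
}

#' Clonal mutation fraction
#'
#' A mutation is clonal when its variant copy number is strictly greater
#' than the threshold (default 0.75); returns the fraction of clonal
#' mutations in a sample.
#'
#' @param variant_copy_numbers numeric vector, one entry per mutation.
#' @param threshold clonality threshold; default 0.75 (strict >).
#' @return fraction in \[0, 1\].
#' @export
clonal_fraction <- function(variant_copy_numbers, threshold = 0.75) {
  if (!length(variant_copy_numbers)) stop("empty variant copy-number list")
  mean(variant_copy_numbers > threshold)
}
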