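# TCR repertoire summaries from clonotype read counts: sample filter,
# relative proportions, clonotype size classes, Hill diversity.

TCR_CLASSES <- c("rare", "infrequent", "frequent", "hyper-frequent")

#' Read a clonotype table
#'
#' Tab-separated file with one row per clonotype. By default the columns are
#' `clonotype_id` and `reads` (MiXCR-export-like); AIRR-style or other column
#' names can be mapped via `col_map`.
#'
#' @param path TSV path.
#' @param sample_id sample identifier to attach; default the file stem.
#' @param col_map named character vector mapping the file's column names to
#'   `clonotype_id` and `reads`, e.g.
#'   `c(sequence_id = "clonotype_id", duplicate_count = "reads")`.
#' @return data.frame with columns `clonotype_id`, `reads` and attribute
#'   `sample_id`.
#' @export
read_clonotype_table <- function(path, sample_id = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    hit <- intersect(names(col_map), names(df))
    names(df)[match(hit, names(df))] <- col_map[hit]
  }
  if (!all(c("clonotype_id", "reads") %in% names(df)))
    stop("clonotype table needs columns clonotype_id and reads")
  df <- df[, c("clonotype_id", "reads")]
  validate_clonotypes(df)
  attr(df, "sample_id") <- if (is.null(sample_id))
    sub("\\.[^.]*$", "", basename(path)) else sample_id
  df
}

validate_clonotypes <- function(df) {
  if (anyDuplicated(df$clonotype_id))
    stop("duplicate clonotype ids within sample")
  if (nrow(df) && (any(df$reads < 1) || any(df$reads != round(df$reads))))
    stop("reads must be positive integers")
  invisible(df)
}

#' Filter samples by total TCR reads
#'
#' Retains samples whose total read count is strictly greater than
#' `min_reads` (default 100): a sample with exactly 100 reads is dropped.
#'
#' @param tables list of clonotype data.frames.
#' @param min_reads exclusive lower bound on total reads; default 100.
#' @return the retained sub-list, names preserved.
#' @export
filter_tcr_samples <- function(tables, min_reads = 100) {
  keep <- vapply(tables, function(t) sum(t$reads) > min_reads, TRUE)
  tables[keep]
}

#' Clonotype relative proportions
#'
#' R_i = reads_i / total reads; sums to one.
#'
#' @param table clonotype data.frame.
#' @return numeric vector of proportions, named by clonotype id.
#' @export
clonotype_proportions <- function(table) {
  validate_clonotypes(table)
  total <- sum(table$reads)
  if (total <= 0) stop("zero total reads")
  stats::setNames(table$reads / total, table$clonotype_id)
}

#' Clonotype size classes
#'
#' A clonotype is `rare` when a single read supports it (rare takes
#' precedence over the proportion rule, since any singleton in a filtered
#' sample also has R < 1%); otherwise `infrequent` when R < 1%, `frequent`
#' when 1% <= R <= 10%, `hyper-frequent` when R > 10%.
#'
#' @param reads integer vector of read counts (>= 1).
#' @param R matching vector of relative proportions in (0, 1].
#' @return factor with levels rare, infrequent, frequent, hyper-frequent.
#' @export
classify_clonotype <- function(reads, R) {
  if (length(reads) != length(R)) stop("reads and R lengths differ")
  if (any(reads < 1)) stop("reads must be >= 1")
  if (any(R <= 0 | R > 1)) stop("R must lie in (0, 1]")
  cls <- ifelse(reads == 1L, "rare",
                ifelse(R < 0.01, "infrequent",
                       ifelse(R <= 0.10, "frequent", "hyper-frequent")))
  factor(cls, levels = TCR_CLASSES)
}

#' Hill diversity (effective number of clonotypes)
#'
#' D_q = (sum p_i^q)^(1/(1-q)), with the Shannon limit exp(-sum p_i log p_i)
#' at q = 1. D_q lies between 1 and the number of clonotypes and is
#' non-increasing in q. The default order q = 1 ("true diversity") weights
#' clonotypes by their frequency.
#'
#' @param reads positive read counts (or any abundances).
#' @param q diversity order >= 0; default 1.
#' @return effective clonotype count.
#' @export
hill_diversity <- function(reads, q = 1) {
  if (!length(reads)) stop("empty read vector")
  if (any(reads <= 0)) stop("reads must be positive")
  if (q < 0) stop("diversity order q must be >= 0")
  p <- reads / sum(reads)
  if (abs(q - 1) < 1e-10) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Read-fraction per clonotype size class
#'
#' For a filtered sample, the fraction of total reads carried by each of the
#' four size classes; the four fractions sum to one.
#'
#' @param table clonotype data.frame (must pass [filter_tcr_samples()]).
#' @param min_reads the filter bound the sample must exceed; default 100.
#' @return named numeric vector over the four classes.
#' @export
class_abundance <- function(table, min_reads = 100) {
  validate_clonotypes(table)
  if (sum(table$reads) <= min_reads)
    stop("sample does not pass the total-read filter")
  R <- clonotype_proportions(table)
  cls <- classify_clonotype(table$reads, unname(R))
  frac <- vapply(TCR_CLASSES,
                 function(k) sum(table$reads[cls == k]) / sum(table$reads), 0)
  frac
}
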