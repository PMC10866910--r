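# ---- expression matrix ------------------------------------------------------

#' Validate a normalized expression matrix
#'
#' An expression matrix is a plain numeric matrix, genes in rows and samples in
#' columns, holding log-scale normalized expression (e.g. the output of a
#' variance-stabilizing transformation). Row and column names carry the gene
#' and sample identifiers and must be unique; all values must be finite.
#'
#' @param expr numeric matrix, genes x samples, with rownames and colnames.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample identifiers in expression matrix")
  if (!all(is.finite(expr)))
    stop("expression matrix contains non-finite values")
  invisible(expr)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header names the samples. Ragged rows, duplicate gene identifiers and
#' non-numeric cells are rejected.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene column and >= 1 sample")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num))
    stop("non-numeric expression values in ", path)
  dimnames(num) <- list(genes, colnames(df)[-1])
  validate_expression(num)
  num
}

#' Write an expression matrix to TSV
#'
#' @param expr numeric matrix, genes x samples.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- signature sets ---------------------------------------------------------

SIG_GROUPS <- c("T-cell", "other-immune", "stromal")

#' Construct a signature set
#'
#' A signature set bundles named gene lists with a group tag per signature
#' (T-cell, other-immune or stromal) and the two global membership lists: the
#' signatures averaged into the global T-cell score and those averaged into
#' the global stromal score.
#'
#' @param signatures named list of character vectors (gene identifiers).
#' @param group named character vector mapping signature name to one of
#'   `"T-cell"`, `"other-immune"`, `"stromal"`. Missing names default to
#'   `"other-immune"`.
#' @param global_T,global_S character vectors of signature names forming the
#'   global T-cell and global stromal signatures. Default: all signatures
#'   tagged `"T-cell"` and `"stromal"` respectively.
#' @return object of class `signature_set`.
#' @export
signature_set <- function(signatures, group = NULL,
                          global_T = NULL, global_S = NULL) {
  if (!is.list(signatures) || is.null(names(signatures)) ||
      anyDuplicated(names(signatures)))
    stop("signatures must be a uniquely named list of gene vectors")
  if (any(lengths(signatures) == 0L))
    stop("empty gene list for signature(s): ",
         paste(names(signatures)[lengths(signatures) == 0L], collapse = ", "))
  grp <- stats::setNames(rep("other-immune", length(signatures)),
                         names(signatures))
  if (!is.null(group)) {
    bad <- setdiff(group, SIG_GROUPS)
    if (length(bad)) stop("unknown signature group(s): ",
                          paste(unique(bad), collapse = ", "))
    grp[names(group)] <- group
  }
  if (is.null(global_T)) global_T <- names(signatures)[grp == "T-cell"]
  if (is.null(global_S)) global_S <- names(signatures)[grp == "stromal"]
  missing <- setdiff(c(global_T, global_S), names(signatures))
  if (length(missing))
    stop("global members absent from signatures: ",
         paste(missing, collapse = ", "))
  structure(list(signatures = signatures, group = grp,
                 global_T = global_T, global_S = global_S),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d signatures (%d T-cell, %d stromal, %d other)\n",
              length(x$signatures), sum(x$group == "T-cell"),
              sum(x$group == "stromal"), sum(x$group == "other-immune")))
  cat(sprintf("  global T members: %d; global stromal members: %d\n",
              length(x$global_T), length(x$global_S)))
  invisible(x)
}

#' Published global signature memberships
#'
#' The fixed global membership lists used to build the TSE score: seven T-cell
#' signatures and five stromal-resident-cell signatures. Only the names and
#' group assignments are shipped; gene lists come from a user-supplied GMT.
#'
#' @return data.frame with columns `name` and `group`.
#' @export
published_global_members <- function() {
  data.frame(
    name = c("Cytotoxic CD8 T cell", "T cell inflamed GEP", "tGE8",
             "T cell signature", "IFN gamma", "Immune gene signature",
             "Chemoattractants",
             "Stromal signature", "Fibroblasts", "EMT/stroma core genes",
             "CAF", "TBRS"),
    group = rep(c("T-cell", "stromal"), c(7L, 5L)),
    stringsAsFactors = FALSE)
}

#' Read a gene-set collection from GMT
#'
#' Standard GMT: one signature per line, tab-separated `name`, `description`,
#' then gene identifiers. When the description field is one of `"T-cell"`,
#' `"stromal"` or `"other-immune"` it is taken as the signature's group tag;
#' any other description maps to `"other-immune"`.
#'
#' @param path path to GMT file.
#' @return `signature_set`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line(s) with fewer than 3 tab-separated fields in ", path)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate signature names in ", path)
  desc <- vapply(fields, `[[`, "", 2L)
  sigs <- lapply(fields, function(f) f[-(1:2)])
  names(sigs) <- nm
  grp <- ifelse(desc %in% SIG_GROUPS, desc, "other-immune")
  signature_set(sigs, stats::setNames(grp, nm))
}

#' Write a signature set to GMT
#'
#' The group tag is written in the description field so that a round-trip
#' through [read_gmt()] preserves it.
#'
#' @param sigs `signature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_set"))
  lines <- vapply(names(sigs$signatures), function(nm) {
    paste(c(nm, sigs$group[[nm]], sigs$signatures[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Signature coverage against an expression matrix
#'
#' Reports, per signature, how many of its genes are present in the matrix
#' (exact, case-sensitive identifier match) and flags signatures whose
#' coverage falls below `min_coverage`. Reporting only; nothing is modified.
#'
#' @param sigs `signature_set`.
#' @param expr expression matrix.
#' @param min_coverage minimum fraction of signature genes that must be
#'   present; default 0.5.
#' @return data.frame with columns `name`, `group`, `n_genes`, `n_found`,
#'   `coverage`, `flagged`.
#' @export
validate_signatures <- function(sigs, expr, min_coverage = 0.5) {
  stopifnot(inherits(sigs, "signature_set"))
  validate_expression(expr)
  n_found <- vapply(sigs$signatures,
                    function(g) sum(g %in% rownames(expr)), 0L)
  n_genes <- lengths(sigs$signatures)
  cov <- n_found / n_genes
  data.frame(name = names(sigs$signatures),
             group = unname(sigs$group[names(sigs$signatures)]),
             n_genes = unname(n_genes), n_found = unname(n_found),
             coverage = unname(cov),
             flagged = unname(cov < min_coverage),
             stringsAsFactors = FALSE, row.names = NULL)
}
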