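# TSE scoring: median centering, signature scores, screening, global
# signatures, the TSE score and its three categories.

#' Median-center an expression matrix
#'
#' Centers every gene (row) on its median across the cohort's samples, so each
#' row has median zero. This makes downstream signature scores cohort-relative
#' enrichments: adding or removing samples changes every score.
#'
#' @param expr numeric matrix, genes x samples.
#' @return matrix of the same shape and dimnames.
#' @export
median_center <- function(expr) {
  if (is.matrix(expr) && ncol(expr) < 1L)
    stop("expression matrix has no samples")
  validate_expression(expr)
  med <- apply(expr, 1L, stats::median)
  expr - med
}

#' Score one signature
#'
#' The signature score of a sample is the unweighted mean of the
#' median-centered expression of the signature's genes present in the matrix.
#'
#' @param centered median-centered expression matrix.
#' @param genes character vector of gene identifiers.
#' @return named numeric vector, one score per sample.
#' @export
signature_score <- function(centered, genes) {
  validate_expression(centered)
  present <- intersect(genes, rownames(centered))
  if (!length(present))
    stop("no signature gene present in the expression matrix")
  colMeans(centered[present, , drop = FALSE])
}

#' Score all signatures in a set
#'
#' Applies [signature_score()] per signature. Signatures whose gene coverage
#' (fraction of genes present in the matrix) falls below `min_coverage` are
#' excluded from the output with a warning.
#'
#' @param centered median-centered expression matrix.
#' @param sigs `signature_set`.
#' @param min_coverage minimum coverage to score a signature; default 0.5.
#' @return numeric matrix, signatures x samples.
#' @export
score_all <- function(centered, sigs, min_coverage = 0.5) {
  stopifnot(inherits(sigs, "signature_set"))
  rep <- validate_signatures(sigs, centered, min_coverage)
  if (any(rep$flagged))
    warning("excluding ", sum(rep$flagged), " signature(s) below coverage ",
            min_coverage, ": ",
            paste(rep$name[rep$flagged], collapse = ", "))
  keep <- rep$name[!rep$flagged]
  if (!length(keep)) stop("no signature passes the coverage filter")
  out <- t(vapply(keep,
                  function(nm) signature_score(centered, sigs$signatures[[nm]]),
                  numeric(ncol(centered))))
  rownames(out) <- keep
  out
}

#' Screen signatures by AUC and dispersion
#'
#' Per signature, computes the midrank AUC of its scores against a binary
#' response label (oriented so AUC >= 0.5, with the direction recorded) and
#' the standard deviation of the scores across samples. A signature is
#' selected when its oriented AUC exceeds `auc_threshold`.
#'
#' @param scores signatures x samples matrix from [score_all()].
#' @param response binary vector (logical or 0/1), aligned with the columns.
#' @param auc_threshold selection threshold; default 0.7.
#' @return data.frame: `name`, `auc`, `direction` (+1 when higher score means
#'   response), `sd`, `selected`.
#' @export
screen_signatures <- function(scores, response, auc_threshold = 0.7) {
  response <- as_binary_label(response)
  if (length(response) != ncol(scores))
    stop("response length must match the number of samples")
  rows <- lapply(rownames(scores), function(nm) {
    a <- roc_auc(scores[nm, ], response)$auc
    dir <- if (a >= 0.5) 1L else -1L
    data.frame(name = nm, auc = max(a, 1 - a), direction = dir,
               sd = stats::sd(scores[nm, ]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$auc > auc_threshold
  rownames(out) <- NULL
  out
}

#' Global T-cell and stromal scores
#'
#' The global score of a compartment is, per sample, the unweighted mean of
#' the member signatures' scores.
#'
#' @param scores signatures x samples matrix.
#' @param members_T,members_S signature names forming each global signature.
#' @return list with numeric vectors `global_T` and `global_S` (named by
#'   sample).
#' @export
global_scores <- function(scores, members_T, members_S) {
  miss <- setdiff(c(members_T, members_S), rownames(scores))
  if (length(miss))
    stop("global member(s) absent from score matrix: ",
         paste(miss, collapse = ", "))
  if (!length(members_T) || !length(members_S))
    stop("global member lists must be non-empty")
  list(global_T = colMeans(scores[members_T, , drop = FALSE]),
       global_S = colMeans(scores[members_S, , drop = FALSE]))
}

#' The TSE score
#'
#' The T-cell-to-stroma enrichment score is the arithmetic difference between
#' the two global signatures: global T-cell score minus global stromal score.
#'
#' @param global_T,global_S named numeric vectors over the same samples.
#' @return named numeric vector of TSE scores.
#' @export
tse_score <- function(global_T, global_S) {
  if (length(global_T) != length(global_S))
    stop("global score vectors differ in length")
  if (!is.null(names(global_T)) && !is.null(names(global_S)) &&
      !identical(names(global_T), names(global_S)))
    stop("global score vectors have misaligned sample ids")
  global_T - global_S
}

#' Categorize TSE scores
#'
#' Scores at or above `cutoff` are positive, at or below `-cutoff` negative,
#' and strictly in between neutral. Both boundaries are closed, matching the
#' published rule (>= 0.5 positive, <= -0.5 negative).
#'
#' @param tse numeric vector of TSE scores.
#' @param cutoff positive cutoff; default 0.5.
#' @return factor with levels `positive`, `neutral`, `negative`.
#' @export
categorize_tse <- function(tse, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number")
  out <- ifelse(tse >= cutoff, "positive",
                ifelse(tse <= -cutoff, "negative", "neutral"))
  factor(out, levels = c("positive", "neutral", "negative"))
}

#' Compute the TSE score end to end
#'
#' Convenience wrapper: median-centers the matrix, scores all signatures,
#' averages the global T-cell and stromal members, takes their difference and
#' categorizes it. By default the global membership lists stored in the
#' signature set are used; with `rescreen = TRUE` the memberships are instead
#' re-derived from the data as the signatures with oriented AUC above
#' `auc_threshold`, split by their group tag (the screening route; it is
#' circular when applied to the evaluation cohort itself).
#'
#' @param expr normalized (not yet centered) expression matrix.
#' @param sigs `signature_set`.
#' @param cutoff category cutoff; default 0.5.
#' @param min_coverage signature coverage filter; default 0.5.
#' @param rescreen logical; re-derive global memberships from `response`.
#' @param response binary response labels (required when `rescreen = TRUE`).
#' @param auc_threshold screening threshold; default 0.7.
#' @return data.frame of class `tse_result`: `sample`, `global_T`,
#'   `global_S`, `tse`, `category`; the cutoff is stored as an attribute.
#' @export
compute_tse <- function(expr, sigs, cutoff = 0.5, min_coverage = 0.5,
                        rescreen = FALSE, response = NULL,
                        auc_threshold = 0.7) {
  centered <- median_center(expr)
  scores <- score_all(centered, sigs, min_coverage)
  if (rescreen) {
    if (is.null(response))
      stop("rescreen = TRUE requires response labels")
    scr <- screen_signatures(scores, response, auc_threshold)
    sel <- scr$name[scr$selected]
    members_T <- intersect(sel, names(sigs$group)[sigs$group == "T-cell"])
    members_S <- intersect(sel, names(sigs$group)[sigs$group == "stromal"])
    if (!length(members_T) || !length(members_S))
      stop("rescreening selected no signature for at least one compartment")
  } else {
    members_T <- intersect(sigs$global_T, rownames(scores))
    members_S <- intersect(sigs$global_S, rownames(scores))
  }
  gl <- global_scores(scores, members_T, members_S)
  tse <- tse_score(gl$global_T, gl$global_S)
  out <- data.frame(sample = colnames(expr),
                    global_T = unname(gl$global_T),
                    global_S = unname(gl$global_S),
                    tse = unname(tse),
                    category = categorize_tse(tse, cutoff),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cutoff") <- cutoff
  attr(out, "members_T") <- members_T
  attr(out, "members_S") <- members_S
  class(out) <- c("tse_result", "data.frame")
  out
}
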