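# Protein-level TSE analog from immunofluorescence quantifications: CD4/CD8
# cell densities versus FAP/PDPN marker-positive area fractions. Image
# segmentation and thresholding happen upstream; this module consumes the
# already-quantified values.

#' Cell density
#'
#' Number of cells divided by the tissue area.
#'
#' @param cell_count non-negative count.
#' @param tissue_area tissue area in mm^2, > 0.
#' @return cells per mm^2.
#' @export
cell_density <- function(cell_count, tissue_area) {
  if (any(tissue_area <= 0)) stop("tissue area must be positive")
  if (any(cell_count < 0)) stop("cell count must be non-negative")
  cell_count / tissue_area
}

#' Marker-positive area fraction
#'
#' Marker-positive area divided by total tissue area, as a percentage.
#'
#' @param marker_area marker-positive area in mm^2.
#' @param tissue_area total tissue area in mm^2, > 0.
#' @return percentage in \[0, 100\].
#' @export
area_fraction <- function(marker_area, tissue_area) {
  if (any(tissue_area <= 0)) stop("tissue area must be positive")
  if (any(marker_area < 0)) stop("marker area must be non-negative")
  if (any(marker_area > tissue_area))
    stop("marker area exceeds tissue area")
  100 * marker_area / tissue_area
}

#' TSE-protein score
#'
#' Each of the four marker values is transformed as log10(1 + value); the two
#' stromal markers (FAP, PDPN area percentages) are then subtracted from the
#' two T-cell markers (CD4, CD8 densities):
#' \deqn{[\log_{10}(1+CD4) + \log_{10}(1+CD8)] - [\log_{10}(1+FAP) +
#'   \log_{10}(1+PDPN)]}
#' Densities (cells/mm^2) and area percentages enter the log transform in
#' their native units — a deliberate mirror of the published construction;
#' ranks and AUC are unaffected by any common positive rescaling. Samples
#' with any missing marker get `NA` (quantification can fail per marker).
#'
#' @param cd4_density,cd8_density cells per mm^2.
#' @param fap_area_pct,pdpn_area_pct percent of tissue area in \[0, 100\].
#' @return numeric score (NA where any marker is missing).
#' @export
tse_protein <- function(cd4_density, cd8_density, fap_area_pct,
                        pdpn_area_pct) {
  n <- length(cd4_density)
  if (any(lengths(list(cd8_density, fap_area_pct, pdpn_area_pct)) != n))
    stop("marker vectors must have equal length")
  ok <- !(is.na(cd4_density) | is.na(cd8_density) |
            is.na(fap_area_pct) | is.na(pdpn_area_pct))
  if (any(c(cd4_density, cd8_density)[!is.na(c(cd4_density, cd8_density))] < 0))
    stop("densities must be non-negative")
  pct <- c(fap_area_pct, pdpn_area_pct)
  if (any(pct[!is.na(pct)] < 0 | pct[!is.na(pct)] > 100))
    stop("area percentages must lie in [0, 100]")
  out <- rep(NA_real_, n)
  out[ok] <- log10(1 + cd4_density[ok]) + log10(1 + cd8_density[ok]) -
    log10(1 + fap_area_pct[ok]) - log10(1 + pdpn_area_pct[ok])
  out
}

#' Categorize the TSE-protein score
#'
#' Scores at or above the cutoff (default 0; no numeric cutoff is published
#' for the protein score) are positive, below it negative.
#'
#' @param score numeric TSE-protein scores.
#' @param cutoff boundary; default 0 (closed on the positive side).
#' @return factor with levels `positive`, `negative` (NA preserved).
#' @export
categorize_protein <- function(score, cutoff = 0) {
  factor(ifelse(score >= cutoff, "positive", "negative"),
         levels = c("positive", "negative"))
}

#' TSE-protein scores for a marker table
#'
#' @param markers data.frame with columns `sample`, `cd4_density`,
#'   `cd8_density`, `fap_area_pct`, `pdpn_area_pct`.
#' @param cutoff category cutoff; default 0.
#' @return data.frame: `sample`, `tse_protein`, `category`.
#' @export
score_markers <- function(markers, cutoff = 0) {
  need <- c("sample", "cd4_density", "cd8_density", "fap_area_pct",
            "pdpn_area_pct")
  miss <- setdiff(need, names(markers))
  if (length(miss)) stop("marker table missing column(s): ",
                         paste(miss, collapse = ", "))
  s <- tse_protein(markers$cd4_density, markers$cd8_density,
                   markers$fap_area_pct, markers$pdpn_area_pct)
  data.frame(sample = markers$sample, tse_protein = s,
             category = categorize_protein(s, cutoff),
             stringsAsFactors = FALSE, row.names = NULL)
}
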