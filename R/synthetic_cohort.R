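# Synthetic cohort generator: expression with planted three-group structure
# (T-cell-high / mixed / stroma-high), gene-set definitions, clinical table,
# per-sample TCR clonotype counts and immunofluorescence marker levels, all
# linked to the planted group so the full pipeline is testable without
# controlled-access data.

#' Simulation configuration
#'
#' Defaults describe the stated world the generator emulates: a cohort split
#' into TSE-positive-like / neutral-like / negative-like groups in the
#' proportions observed clinically (15:14:12), response probabilities
#' (0.67, 0.21, 0) per group, VST-like homoskedastic log-scale expression
#' (per-gene baseline N(8, 2), noise SD 1), additive log-scale shifts of 1.5
#' on the planted signature genes, exponential survival with group hazard
#' ratios (1, 2.5, 6) around a 6-month positive-group survival of ~67%, and
#' independent exponential censoring (~30% censored).
#'
#' @param n_samples cohort size; default 300.
#' @param n_genes genes in the matrix; default 2000.
#' @param n_signatures_T,n_signatures_S,n_signatures_other generated gene
#'   sets per group; defaults 7 / 5 / 24 (36 total).
#' @param genes_per_signature genes per set; default 10.
#' @param group_probs probability triple over (positive-like, neutral-like,
#'   negative-like); default c(15, 14, 12)/41.
#' @param effect_T,effect_S log-scale expression shift planted on T-signature
#'   genes in the positive-like group and stromal-signature genes in the
#'   negative-like group; defaults 1.5.
#' @param response_probs response probability per group; default
#'   c(0.67, 0.21, 0).
#' @param baseline_hazard events per month in the positive-like group;
#'   default 0.0667.
#' @param hazard_ratio_by_group hazard multipliers per group; default
#'   c(1, 2.5, 6).
#' @param censoring_rate rate of the independent exponential censoring
#'   process; default 0.05 (~30% censored at the other defaults).
#' @param tcr_clones,tcr_reads clonotypes and total reads per sample;
#'   defaults 150 and 1000.
#' @param tcr_evenness_by_group symmetric Dirichlet concentration per group
#'   (larger = more even repertoire); default c(2, 1, 0.5).
#' @param noise_sd gene-level Gaussian noise SD; default 1.
#' @param overlap_frac fraction of each signature's genes shared with earlier
#'   signatures of the same group (sets are disjoint by default); default 0.
#' @param seed integer RNG seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 300L, n_genes = 2000L,
                              n_signatures_T = 7L, n_signatures_S = 5L,
                              n_signatures_other = 24L,
                              genes_per_signature = 10L,
                              group_probs = c(15, 14, 12) / 41,
                              effect_T = 1.5, effect_S = 1.5,
                              response_probs = c(0.67, 0.21, 0),
                              baseline_hazard = 0.0667,
                              hazard_ratio_by_group = c(1, 2.5, 6),
                              censoring_rate = 0.05,
                              tcr_clones = 150L, tcr_reads = 1000L,
                              tcr_evenness_by_group = c(2, 1, 0.5),
                              noise_sd = 1, overlap_frac = 0,
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_signatures_T = as.integer(n_signatures_T),
              n_signatures_S = as.integer(n_signatures_S),
              n_signatures_other = as.integer(n_signatures_other),
              genes_per_signature = as.integer(genes_per_signature),
              group_probs = group_probs, effect_T = effect_T,
              effect_S = effect_S, response_probs = response_probs,
              baseline_hazard = baseline_hazard,
              hazard_ratio_by_group = hazard_ratio_by_group,
              censoring_rate = censoring_rate,
              tcr_clones = as.integer(tcr_clones),
              tcr_reads = as.integer(tcr_reads),
              tcr_evenness_by_group = tcr_evenness_by_group,
              noise_sd = noise_sd, overlap_frac = overlap_frac,
              seed = as.integer(seed))
  with(cfg, {
    if (n_samples <= 0L || n_genes <= 0L || genes_per_signature <= 0L)
      stop("dimensions must be positive")
    n_sig_genes <- (n_signatures_T + n_signatures_S + n_signatures_other) *
      genes_per_signature
    if (n_sig_genes > n_genes)
      stop("signatures require more genes than n_genes provides")
    if (length(group_probs) != 3L || any(group_probs < 0) ||
        abs(sum(group_probs) - 1) > 1e-12)
      stop("group_probs must be a probability triple summing to 1")
    if (length(response_probs) != 3L ||
        any(response_probs < 0 | response_probs > 1))
      stop("response_probs must lie in [0, 1]")
    if (!is.finite(effect_T) || !is.finite(effect_S) ||
        effect_T < 0 || effect_S < 0)
      stop("effect sizes must be finite and >= 0")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (baseline_hazard <= 0 || censoring_rate <= 0 ||
        any(hazard_ratio_by_group <= 0))
      stop("hazard parameters must be positive")
    if (any(tcr_evenness_by_group <= 0))
      stop("Dirichlet concentrations must be positive")
    if (overlap_frac < 0 || overlap_frac >= 1)
      stop("overlap_frac must lie in [0, 1)")
  })
  structure(cfg, class = "simulation_config")
}

# deterministic per-modality sub-seed (kept below 2^31 - 1)
modality_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647)
}

GROUP_LEVELS <- c("positive", "neutral", "negative")

#' Generate a synthetic cohort
#'
#' Draws a cohort with planted three-group structure. Expression is per-gene
#' Gaussian noise around a gene baseline, plus `effect_T` on T-signature
#' genes of positive-like samples and `effect_S` on stromal-signature genes
#' of negative-like samples. Response is Bernoulli per group; overall and
#' progression-free survival are exponential with group-specific hazards and
#' independent exponential censoring; per-sample TCR reads follow a
#' Dirichlet-multinomial whose concentration is largest (most even) in the
#' positive-like group; CD4/CD8 densities and FAP/PDPN area fractions are
#' log-normal around group-dependent means concordant with the planted
#' expression shifts. The same seed reproduces the cohort bit-identically.
#'
#' @param config `simulation_config`.
#' @return list of class `tse_cohort`: `expression` (matrix), `signatures`
#'   (`signature_set`), `clinical` (data.frame), `tcr` (named list of
#'   clonotype data.frames), `markers` (data.frame), `truth` (data.frame
#'   with planted group per sample, plus effect sizes and seed as
#'   attributes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  samples <- sprintf("S%03d", seq_len(cf$n_samples))
  genes <- sprintf("G%05d", seq_len(cf$n_genes))

  # -- signature definitions (modality 0)
  set.seed(modality_seed(cf$seed, 0))
  n_sigs <- c(T = cf$n_signatures_T, S = cf$n_signatures_S,
              other = cf$n_signatures_other)
  pub <- published_global_members()
  name_pool <- list(
    T = c(pub$name[pub$group == "T-cell"],
          sprintf("T cell set %02d", seq_len(max(0, n_sigs["T"] - 7)))),
    S = c(pub$name[pub$group == "stromal"],
          sprintf("Stromal set %02d", seq_len(max(0, n_sigs["S"] - 5)))),
    other = sprintf("Immune set %02d", seq_len(n_sigs["other"])))
  grp_tag <- c(T = "T-cell", S = "stromal", other = "other-immune")
  sig_list <- list(); sig_grp <- character()
  cursor <- 0L
  for (g in c("T", "S", "other")) {
    prev_pool <- character()
    for (i in seq_len(n_sigs[[g]])) {
      gset <- genes[cursor + seq_len(cf$genes_per_signature)]
      cursor <- cursor + cf$genes_per_signature
      n_ov <- floor(cf$overlap_frac * cf$genes_per_signature)
      if (n_ov > 0L && length(prev_pool) >= n_ov)
        gset[seq_len(n_ov)] <- sample(prev_pool, n_ov)
      nm <- name_pool[[g]][i]
      sig_list[[nm]] <- unique(gset)
      sig_grp[nm] <- grp_tag[[g]]
      prev_pool <- union(prev_pool, gset)
    }
  }
  sigs <- signature_set(sig_list, sig_grp)
  t_genes <- unique(unlist(sigs$signatures[sigs$global_T]))
  s_genes <- unique(unlist(sigs$signatures[sigs$global_S]))

  # -- group labels (modality 1)
  set.seed(modality_seed(cf$seed, 1))
  group <- sample(GROUP_LEVELS, cf$n_samples, replace = TRUE,
                  prob = cf$group_probs)
  gidx <- match(group, GROUP_LEVELS)

  # -- expression (modality 2)
  set.seed(modality_seed(cf$seed, 2))
  baseline <- stats::rnorm(cf$n_genes, mean = 8, sd = 2)
  expr <- matrix(stats::rnorm(cf$n_genes * cf$n_samples, sd = cf$noise_sd),
                 nrow = cf$n_genes, dimnames = list(genes, samples))
  expr <- expr + baseline
  expr[t_genes, group == "positive"] <-
    expr[t_genes, group == "positive"] + cf$effect_T
  expr[s_genes, group == "negative"] <-
    expr[s_genes, group == "negative"] + cf$effect_S

  # -- clinical covariates (modality 3)
  set.seed(modality_seed(cf$seed, 3))
  response <- stats::rbinom(cf$n_samples, 1L, cf$response_probs[gidx])
  haz <- cf$baseline_hazard * cf$hazard_ratio_by_group[gidx]
  os_t <- stats::rexp(cf$n_samples, haz)
  os_c <- stats::rexp(cf$n_samples, cf$censoring_rate)
  pfs_t <- stats::rexp(cf$n_samples, haz * 1.5)
  pfs_c <- stats::rexp(cf$n_samples, cf$censoring_rate)
  tmb <- stats::rlnorm(cf$n_samples,
                       meanlog = log(7) + 0.3 * (response == 1), sdlog = 0.6)
  apobec_E <- stats::rlnorm(cf$n_samples,
                            meanlog = log(2) + 0.2 * (response == 1),
                            sdlog = 0.5)
  apobec_detected <- stats::runif(cf$n_samples) < 0.8
  clinical <- data.frame(
    sample = samples,
    response = response,
    os_time = pmin(os_t, os_c), os_event = as.integer(os_t <= os_c),
    pfs_time = pmin(pfs_t, pfs_c), pfs_event = as.integer(pfs_t <= pfs_c),
    tmb = tmb, apobec_E = apobec_E, apobec_detected = apobec_detected,
    cps = round(100 * stats::rbeta(cf$n_samples, 1.2, 4), 1),
    pretreated = stats::runif(cf$n_samples) < 0.5,
    biopsy_site = sample(c("lymph_node", "liver", "bone", "other"),
                         cf$n_samples, replace = TRUE,
                         prob = c(0.4, 0.25, 0.1, 0.25)),
    sex = sample(c("F", "M"), cf$n_samples, replace = TRUE,
                 prob = c(0.25, 0.75)),
    age = round(stats::rnorm(cf$n_samples, 68, 9)),
    stringsAsFactors = FALSE)

  # -- TCR repertoires (modality 4)
  set.seed(modality_seed(cf$seed, 4))
  conc <- cf$tcr_evenness_by_group[gidx]
  tcr <- lapply(seq_len(cf$n_samples), function(i) {
    w <- stats::rgamma(cf$tcr_clones, shape = conc[i])
    if (sum(w) <= 0) w <- rep(1, cf$tcr_clones)
    reads <- as.integer(stats::rmultinom(1L, cf$tcr_reads, w / sum(w)))
    keep <- reads > 0L
    df <- data.frame(clonotype_id = sprintf("C%04d", which(keep)),
                     reads = reads[keep], stringsAsFactors = FALSE)
    attr(df, "sample_id") <- samples[i]
    df
  })
  names(tcr) <- samples

  # -- IF markers (modality 5): log-normal, concordant with planted groups
  set.seed(modality_seed(cf$seed, 5))
  dens_mu <- c(positive = log(150), neutral = log(50), negative = log(15))
  area_mu <- c(positive = log(2), neutral = log(6), negative = log(18))
  markers <- data.frame(
    sample = samples,
    cd4_density = stats::rlnorm(cf$n_samples, dens_mu[group], 0.5),
    cd8_density = stats::rlnorm(cf$n_samples, dens_mu[group], 0.5),
    fap_area_pct = pmin(100, stats::rlnorm(cf$n_samples, area_mu[group], 0.5)),
    pdpn_area_pct = pmin(100, stats::rlnorm(cf$n_samples, area_mu[group], 0.5)),
    tissue_area_mm2 = round(stats::runif(cf$n_samples, 1, 6), 2),
    stringsAsFactors = FALSE)

  truth <- data.frame(sample = samples,
                      group = factor(group, levels = GROUP_LEVELS),
                      stringsAsFactors = FALSE)
  attr(truth, "effect_T") <- cf$effect_T
  attr(truth, "effect_S") <- cf$effect_S
  attr(truth, "seed") <- cf$seed

  structure(list(expression = expr, signatures = sigs, clinical = clinical,
                 tcr = tcr, markers = markers, truth = truth,
                 config = cf),
            class = "tse_cohort")
}

#' @export
print.tse_cohort <- function(x, ...) {
  cat(sprintf("tse_cohort: %d samples x %d genes, %d signatures (seed %d)\n",
              ncol(x$expression), nrow(x$expression),
              length(x$signatures$signatures), x$config$seed))
  print(table(planted = x$truth$group))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Emits `expression.tsv` (first column `gene_id`, header = sample ids),
#' `signatures.gmt`, `clinical.tsv`, `markers.csv`, `truth.tsv` and one
#' `tcr/<sample>.tsv` per sample, in the dialects the readers of this
#' package consume.
#'
#' @param cohort `tse_cohort`.
#' @param dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tse_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tcr"), showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             gmt = file.path(dir, "signatures.gmt"),
             clinical = file.path(dir, "clinical.tsv"),
             markers = file.path(dir, "markers.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(cohort$expression, paths["expression"])
  write_gmt(cohort$signatures, paths["gmt"])
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$markers, paths["markers"], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tcr_paths <- vapply(names(cohort$tcr), function(s) {
    p <- file.path(dir, "tcr", paste0(s, ".tsv"))
    utils::write.table(cohort$tcr[[s]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, "")
  invisible(c(paths, stats::setNames(tcr_paths,
                                     paste0("tcr_", names(tcr_paths)))))
}
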