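test_that("config validation rejects impossible worlds", {
  expect_error(simulation_config(n_samples = 0), "positive")
  expect_error(simulation_config(group_probs = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(simulation_config(response_probs = c(0.5, 1.2, 0)),
               "\\[0, 1\\]")
  expect_error(simulation_config(effect_T = -1), "finite and >= 0")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(n_genes = 50), "more genes")
})

test_that("same seed gives bit-identical cohorts; seeds differ", {
  a <- generate_cohort(small_config(seed = 7))
  b <- generate_cohort(small_config(seed = 7))
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$tcr, b$tcr)
  expect_identical(a$markers, b$markers)
  c <- generate_cohort(small_config(seed = 8))
  expect_false(identical(a$expression, c$expression))
})

test_that("planted structure flows into every modality", {
  co <- generate_cohort(small_config(seed = 2))
  expect_identical(nrow(co$truth), ncol(co$expression))
  expect_false(anyNA(co$truth$group))           # exactly one label each
  # expression shift on T genes in the positive group
  t_genes <- unlist(co$signatures$signatures[co$signatures$global_T])
  pos <- co$truth$group == "positive"
  expect_gt(mean(co$expression[t_genes, pos]) -
              mean(co$expression[t_genes, !pos]), 1)
  # repertoires are most even in the positive group
  div <- vapply(co$tcr, function(t) hill_diversity(t$reads, 1), 0)
  expect_gt(mean(div[pos]), mean(div[co$truth$group == "negative"]))
  # markers concordant
  expect_gt(mean(co$markers$cd8_density[pos]),
            mean(co$markers$cd8_density[co$truth$group == "negative"]))
  expect_lt(mean(co$markers$fap_area_pct[pos]),
            mean(co$markers$fap_area_pct[co$truth$group == "negative"]))
})

test_that("zero effects give a null TSE (AUC near 0.5 across seeds)", {
  aucs <- vapply(1:20, function(s) {
    co <- generate_cohort(small_config(seed = s, effect_T = 0, effect_S = 0,
                                       response_probs = rep(0.3, 3)))
    res <- compute_tse(co$expression, co$signatures)
    if (sum(co$clinical$response) %in% c(0, nrow(co$clinical)))
      return(NA_real_)
    roc_auc(res$tse, co$clinical$response)$auc
  }, 0)
  aucs <- aucs[!is.na(aucs)]
  ci <- mean(aucs) + c(-1, 1) * qt(0.975, length(aucs) - 1) *
    sd(aucs) / sqrt(length(aucs))
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("gene sets are disjoint by default, overlapping on request", {
  co <- generate_cohort(small_config(seed = 1))
  genes <- unlist(co$signatures$signatures)
  expect_false(anyDuplicated(genes) > 0)
  co2 <- generate_cohort(small_config(seed = 1, overlap_frac = 0.25))
  genes2 <- unlist(co2$signatures$signatures)
  expect_gt(sum(duplicated(genes2)), 0)
})

test_that("written cohort round-trips through the readers", {
  co <- generate_cohort(small_config(seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths[c("expression", "gmt", "clinical",
                                      "markers", "truth")])))
  expect_equal(read_expression_matrix(paths["expression"]), co$expression)
  expect_identical(length(readLines(paths["gmt"])), 10L)  # 3+3+4 signatures
  clin <- read.delim(paths["clinical"])
  expect_identical(nrow(clin), 60L)
  mk <- read.csv(paths["markers"])
  expect_equal(mk$cd4_density, co$markers$cd4_density, tolerance = 1e-9)
  # write twice -> identical bytes (determinism through the writer)
  dir2 <- withr::local_tempdir()
  write_cohort(co, dir2)
  expect_identical(readLines(paths["expression"]),
                   readLines(file.path(dir2, "expression.tsv")))
})
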