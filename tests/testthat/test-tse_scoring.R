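test_that("median centering zeroes each gene's median and is idempotent", {
  m <- toy_expression()
  c1 <- median_center(m)
  expect_equal(unname(apply(c1, 1, median)), rep(0, 4))
  expect_equal(unname(c1["Ta", ]), c(-1, 0, 2))   # median of (1,2,4) is 2
  expect_equal(unname(c1["Tb", ]), c(0, 0, 0))    # constant row
  expect_equal(median_center(c1), c1)             # idempotent
  expect_error(median_center(m[, 0, drop = FALSE]), "no samples")
})

test_that("signature scores are per-sample means of present genes", {
  cen <- median_center(toy_expression())
  expect_equal(signature_score(cen, "Ta"), cen["Ta", ])
  s <- signature_score(cen, c("Ta", "Tb"))
  expect_equal(unname(s), unname(colMeans(cen[c("Ta", "Tb"), ])))
  # absent genes are ignored; all absent is an error
  expect_equal(signature_score(cen, c("Ta", "Tb", "NOPE")), s)
  expect_error(signature_score(cen, "NOPE"), "no signature gene")
  zero <- cen * 0
  expect_equal(unname(signature_score(zero, c("Ta", "Sb"))), c(0, 0, 0))
})

test_that("score_all matches per-signature calls and applies the filter", {
  cen <- median_center(toy_expression())
  ss <- toy_signatures()
  sc <- score_all(cen, ss)
  expect_identical(dim(sc), c(2L, 3L))
  expect_identical(rownames(sc), c("Tsig", "Ssig"))
  expect_equal(sc["Tsig", ], signature_score(cen, c("Ta", "Tb")))
  expect_equal(sc["Ssig", ], signature_score(cen, c("Sa", "Sb")))
  ss2 <- signature_set(list(Tsig = c("Ta", "Tb"), bad = c("Z1", "Z2", "Z3")))
  expect_warning(sc2 <- score_all(cen, ss2), "below coverage")
  expect_identical(rownames(sc2), "Tsig")
})

test_that("screening orients AUC and selects above the threshold", {
  sc <- rbind(perfect = c(1, 2, 3, 4), anti = c(4, 3, 2, 1),
              flat = c(1, 1, 1, 1))
  colnames(sc) <- paste0("P", 1:4)
  resp <- c(0, 0, 1, 1)
  rep <- screen_signatures(sc, resp, auc_threshold = 0.7)
  expect_equal(rep$auc[rep$name == "perfect"], 1)       # all-pairs concordant
  expect_equal(rep$direction[rep$name == "perfect"], 1L)
  expect_equal(rep$auc[rep$name == "anti"], 1)          # oriented
  expect_equal(rep$direction[rep$name == "anti"], -1L)
  expect_equal(rep$auc[rep$name == "flat"], 0.5)        # all ties
  expect_identical(rep$selected, c(TRUE, TRUE, FALSE))
  expect_error(screen_signatures(sc, c(1, 1, 1, 1)), "both classes")
})

test_that("global scores average member signatures, order-invariantly", {
  sc <- rbind(A = c(0.2, 1), B = c(0.4, 2), S1 = c(0, 0.5))
  gl <- global_scores(sc, c("A", "B"), "S1")
  expect_equal(unname(gl$global_T), c(0.3, 1.5))
  expect_equal(unname(gl$global_S), c(0, 0.5))
  expect_equal(global_scores(sc, c("B", "A"), "S1")$global_T, gl$global_T)
  expect_equal(global_scores(sc, "A", "S1")$global_T, sc["A", ])
  expect_error(global_scores(sc, c("A", "missing"), "S1"), "absent")
  expect_error(global_scores(sc, character(), "S1"), "non-empty")
})

test_that("TSE score is the difference and categories partition", {
  expect_equal(tse_score(1.0, 0.2), 0.8)
  expect_equal(tse_score(0.7, 0.7), 0)
  expect_equal(tse_score(c(a = 1), c(a = 2)), -tse_score(c(a = 2), c(a = 1)))
  expect_error(tse_score(c(a = 1), c(b = 1)), "misaligned")

  x <- c(0.5, -0.5, 0, 0.49999, -0.49999, 3, -3)
  cat <- categorize_tse(x)
  expect_identical(as.character(cat),
                   c("positive", "negative", "neutral", "neutral", "neutral",
                     "positive", "negative"))
  expect_false(anyNA(cat))                      # every sample gets a category
  expect_error(categorize_tse(0, cutoff = 0), "positive")
})

test_that("end-to-end TSE matches an independent hand computation", {
  # toy matrix, spreadsheet-style arithmetic:
  # medians per row: Ta 2, Tb 2, Sa 3, Sb 1
  # centered: Ta(-1,0,2) Tb(0,0,0) Sa(2,0,-2) Sb(-1,0,1)
  # Tsig = (-0.5, 0, 1); Ssig = (0.5, 0, -0.5); TSE = (-1, 0, 1.5)
  res <- compute_tse(toy_expression(), toy_signatures())
  expect_equal(res$global_T, c(-0.5, 0, 1))
  expect_equal(res$global_S, c(0.5, 0, -0.5))
  expect_equal(res$tse, c(-1, 0, 1.5))
  expect_identical(as.character(res$category),
                   c("negative", "neutral", "positive"))
})

test_that("TSE is invariant to per-gene translation, equivariant to scale", {
  co <- generate_cohort(small_config(seed = 11))
  base <- compute_tse(co$expression, co$signatures)
  shift <- co$expression + rnorm(nrow(co$expression)) * 5
  shifted <- compute_tse(shift, co$signatures)
  expect_equal(shifted$tse, base$tse, tolerance = 1e-12)
  expect_identical(as.character(shifted$category),
                   as.character(base$category))
  scaled <- compute_tse(co$expression * 3, co$signatures)
  expect_equal(scaled$tse, base$tse * 3, tolerance = 1e-12)
})

test_that("rescreening derives memberships from the data", {
  co <- generate_cohort(small_config(seed = 5))
  res <- compute_tse(co$expression, co$signatures, rescreen = TRUE,
                     response = co$clinical$response, auc_threshold = 0.6)
  expect_true(all(attr(res, "members_T") %in% co$signatures$global_T))
  expect_true(all(attr(res, "members_S") %in% co$signatures$global_S))
  expect_error(compute_tse(co$expression, co$signatures, rescreen = TRUE),
               "requires response")
})
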