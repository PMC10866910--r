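# Shared fixtures: tiny hand-built matrices and a small, fast cohort config.

# 4 genes x 3 samples, two 2-gene signatures; used by the hand-computed
# end-to-end oracle.
toy_expression <- function() {
  m <- matrix(c(1, 2, 4,    # Ta
                2, 2, 2,    # Tb
                5, 3, 1,    # Sa
                0, 1, 2),   # Sb
              nrow = 4, byrow = TRUE,
              dimnames = list(c("Ta", "Tb", "Sa", "Sb"),
                              c("P1", "P2", "P3")))
  m
}

toy_signatures <- function() {
  signature_set(list(Tsig = c("Ta", "Tb"), Ssig = c("Sa", "Sb")),
                c(Tsig = "T-cell", Ssig = "stromal"))
}

# cohort small enough for per-test use but with the default effect structure
small_config <- function(seed = 1, ...) {
  simulation_config(n_samples = 60L, n_genes = 400L, n_signatures_T = 3L,
                    n_signatures_S = 3L, n_signatures_other = 4L,
                    genes_per_signature = 8L, seed = seed, ...)
}

# brute-force all-pairs AUC oracle (ties count one half)
auc_pairs_oracle <- function(score, pos) {
  x <- score[pos]; y <- score[!pos]
  g <- outer(x, y, ">"); e <- outer(x, y, "==")
  (sum(g) + 0.5 * sum(e)) / (length(x) * length(y))
}

# two-sided Fisher p by direct hypergeometric enumeration
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
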