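# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# marginal summary statistics of a phenotype against every panel variant
sumstats_of <- function(panel, y, n = NULL) {
  fit <- sumgwas:::marginal_ols(panel$dosages, y)
  v <- panel$variants
  tibble::tibble(marker = v$marker, chr = v$chr, pos = v$pos,
                 ea = v$alt, nea = v$ref,
                 eaf = fit$eaf, beta = fit$beta, se = fit$se, p = fit$p,
                 n = n %||% fit$n)
}

# random single-variant meta "studies" for IVW oracle checks
random_study_row <- function(k, beta_sd = 0.2) {
  tibble::tibble(marker = "x", chr = "1", pos = 1L, ea = "G", nea = "A",
                 eaf = runif(k, 0.05, 0.95),
                 beta = rnorm(k, 0, beta_sd),
                 se = runif(k, 0.01, 0.5),
                 p = NA_real_, n = sample(500:5000, k, replace = TRUE))
}

# brute-force five-hypothesis coloc oracle: direct summation over variant
# assignments (O(n^2) over ordered pairs), independent of the package path
coloc_bruteforce <- function(l1, l2, p1, p2, p12) {
  b1 <- exp(l1); b2 <- exp(l2)
  n <- length(b1)
  L0 <- 1
  L1 <- p1 * sum(b1)
  L2 <- p2 * sum(b2)
  L3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) L3 <- L3 + p1 * p2 * b1[i] * b2[j]
  }
  L4 <- p12 * sum(b1 * b2)
  L <- c(L0, L1, L2, L3, L4)
  L / sum(L)
}

# one-row summary table (p derived from the z-score unless supplied)
mk_row <- function(marker, beta, se, p = NULL) {
  tibble::tibble(marker = marker, beta = beta, se = se,
                 p = p %||% sumgwas:::z_to_p(beta / se))
}

# hand-built panel whose two focal columns are exactly orthogonal
orthogonal_panel <- function() {
  g1 <- rep(c(0L, 0L, 1L, 1L, 2L, 2L), times = 50)
  g2 <- rep(c(0L, 2L, 1L, 1L, 0L, 2L), times = 50)  # cov(g1, g2) = 0 exactly
  as_ld_panel(cbind(s1 = g1, s2 = g2),
              variants = tibble::tibble(marker = c("s1", "s2"), chr = "1",
                                        pos = c(1000L, 2000L)))
}
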