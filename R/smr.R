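# Summary-data Mendelian randomization of expression on trait, with the
# HEIDI heterogeneity test separating one shared (pleiotropic) causal
# variant from two linked causal variants.

#' SMR test at the top cis-eQTL
#'
#' Uses the top cis-eQTL variant as an instrument: `b_xy = b_zy / b_zx`
#' (trait change per unit expression), with test statistic
#' `T = z_zy^2 z_zx^2 / (z_zy^2 + z_zx^2)` referred to chi-square(1).
#'
#' @param gwas,eqtl Summary tibbles (`marker, beta, se`, and `p` for the
#'   instrument screen) for the trait and the gene's expression.
#' @param top Instrument marker; default the smallest-p eQTL variant.
#' @param instrument_p Required eQTL significance of the instrument.
#' @param bonferroni_p Experiment-wide SMR significance threshold; when
#'   `n_tests` is supplied it is recomputed as `0.05/n_tests`.
#' @param n_tests Optional number of genes tested.
#' @param gene Gene label.
#' @return One-row `smr_result` tibble: `gene, top, b_xy, se_xy, p_smr,
#'   passes_bonferroni`, plus the underlying `b_zy, b_zx` pairs.
#' @export
smr_test <- function(gwas, eqtl, top = NULL, instrument_p = 5e-8,
                     bonferroni_p = 0.0029, n_tests = NULL, gene = NA) {
  assert_cols(gwas, c("marker", "beta", "se"), "gwas")
  assert_cols(eqtl, c("marker", "beta", "se", "p"), "eqtl")
  top <- top %||% eqtl$marker[order(eqtl$p, eqtl$marker)][1]
  ie <- match(top, eqtl$marker)
  ig <- match(top, gwas$marker)
  if (is.na(ie) || is.na(ig)) stop("instrument absent from gwas or eqtl table")
  if (eqtl$beta[ie] == 0) stop("instrument has zero eQTL effect")
  if (!is.na(eqtl$p[ie]) && eqtl$p[ie] >= instrument_p) {
    stop(sprintf("top cis-eQTL %s not significant (p = %.3g >= %.1g)",
                 top, eqtl$p[ie], instrument_p))
  }
  b_zx <- eqtl$beta[ie]; se_zx <- eqtl$se[ie]
  b_zy <- gwas$beta[ig]; se_zy <- gwas$se[ig]
  z_zx <- b_zx / se_zx
  z_zy <- b_zy / se_zy
  b_xy <- b_zy / b_zx
  se_xy <- sqrt(se_zy^2 / b_zx^2 + b_zy^2 * se_zx^2 / b_zx^4)
  t_smr <- z_zy^2 * z_zx^2 / (z_zy^2 + z_zx^2)
  p_smr <- pchisq(t_smr, df = 1, lower.tail = FALSE)
  thr <- if (!is.null(n_tests)) 0.05 / n_tests else bonferroni_p
  out <- tibble::tibble(gene = gene, top = top, b_xy = b_xy, se_xy = se_xy,
                        t_smr = t_smr, p_smr = p_smr,
                        b_zy = b_zy, se_zy = se_zy, b_zx = b_zx,
                        se_zx = se_zx,
                        passes_bonferroni = p_smr < thr)
  class(out) <- c("smr_result", class(out))
  out
}

#' HEIDI heterogeneity test
#'
#' Tests whether the `b_xy` estimates implied by the cis-SNPs surrounding
#' the top eQTL are mutually consistent (one shared causal variant) or
#' heterogeneous (linkage between distinct causal variants). Eligible SNPs
#' have eQTL chi-square above `instrument_chisq` and LD r² with the top SNP
#' inside `r2_range` (avoiding both collinearity and independence); the 20
#' strongest are used. The statistic `sum(z_d^2)` is referred to an
#' eigenvalue-weighted sum of chi-square(1) evaluated by Imhof's method.
#'
#' @param gwas,eqtl Summary tibbles over the cis-window.
#' @param panel [ld_panel] supplying signed LD between cis-SNPs.
#' @param top Instrument marker (default: smallest eQTL p).
#' @param r2_range Eligible LD window with the top SNP.
#' @param max_snps Cap on eligible SNPs (strongest eQTL first).
#' @param instrument_chisq eQTL chi-square eligibility threshold
#'   (10 ~ p < 1.6e-3).
#' @return One-row tibble `p_heidi, n_heidi_snps, reason` (`p_heidi = NA`
#'   with a reason when fewer than 3 SNPs are eligible).
#' @export
heidi_test <- function(gwas, eqtl, panel, top = NULL,
                       r2_range = c(0.05, 0.9), max_snps = 20,
                       instrument_chisq = 10) {
  assert_cols(gwas, c("marker", "beta", "se"), "gwas")
  assert_cols(eqtl, c("marker", "beta", "se"), "eqtl")
  top <- top %||% eqtl$marker[order(eqtl$p, eqtl$marker)][1]
  shared <- intersect(intersect(gwas$marker, eqtl$marker),
                      panel$variants$marker)
  if (!top %in% shared) {
    return(tibble::tibble(p_heidi = NA_real_, n_heidi_snps = 0L,
                          reason = "instrument not shared across inputs"))
  }
  e <- eqtl[match(shared, eqtl$marker), ]
  g <- gwas[match(shared, gwas$marker), ]
  chi <- (e$beta / e$se)^2
  r2 <- panel_r2(panel, shared, top)
  elig <- shared != top & chi >= instrument_chisq &
    !is.na(r2) & r2 >= r2_range[1] & r2 <= r2_range[2]
  elig[is.na(elig)] <- FALSE
  cand <- order(-chi * elig)[seq_len(min(max_snps, sum(elig)))]
  cand <- cand[elig[cand]]
  if (length(cand) < 3) {
    return(tibble::tibble(p_heidi = NA_real_, n_heidi_snps = length(cand),
                          reason = "insufficient instruments"))
  }
  sel <- c(match(top, shared), cand)
  R <- panel_cor(panel, shared[sel])
  bzx <- e$beta[sel]; szx <- e$se[sel]
  bzy <- g$beta[sel]; szy <- g$se[sel]
  bxy <- bzy / bzx
  m <- length(sel)
  # delta-method covariance of b_xy(i); GWAS and eQTL samples independent
  cov_bxy <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    cov_bxy[i, j] <- R[i, j] * szy[i] * szy[j] / (bzx[i] * bzx[j]) +
      R[i, j] * szx[i] * szx[j] * bzy[i] * bzy[j] / (bzx[i]^2 * bzx[j]^2)
  }
  k <- m - 1
  d <- bxy[-1] - bxy[1]
  V <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    V[i, j] <- cov_bxy[i + 1, j + 1] - cov_bxy[i + 1, 1] -
      cov_bxy[1, j + 1] + cov_bxy[1, 1]
  }
  sdv <- sqrt(pmax(diag(V), 1e-30))
  zd <- d / sdv
  Cmat <- V / tcrossprod(sdv)
  stat <- sum(zd^2)
  lam <- eigen(Cmat, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  p <- imhof_tail(stat, lam)
  tibble::tibble(p_heidi = p, n_heidi_snps = k, reason = NA_character_)
}

#' SMR plus HEIDI for one gene
#'
#' @inheritParams smr_test
#' @inheritParams heidi_test
#' @param heidi_flag_p Heterogeneity is flagged when `p_heidi` falls below
#'   this threshold.
#' @return One-row `smr_result` tibble with `p_heidi`, `n_heidi_snps` and
#'   `heidi_flag` appended.
#' @export
smr_heidi <- function(gwas, eqtl, panel, top = NULL, gene = NA,
                      instrument_p = 5e-8, bonferroni_p = 0.0029,
                      n_tests = NULL, r2_range = c(0.05, 0.9),
                      max_snps = 20, instrument_chisq = 10,
                      heidi_flag_p = 0.0029) {
  smr <- smr_test(gwas, eqtl, top = top, instrument_p = instrument_p,
                  bonferroni_p = bonferroni_p, n_tests = n_tests,
                  gene = gene)
  hd <- heidi_test(gwas, eqtl, panel, top = smr$top, r2_range = r2_range,
                   max_snps = max_snps, instrument_chisq = instrument_chisq)
  out <- dplyr::bind_cols(smr, hd[, c("p_heidi", "n_heidi_snps")])
  out$heidi_flag <- !is.na(out$p_heidi) & out$p_heidi < heidi_flag_p
  out$heidi_reason <- hd$reason
  class(out) <- c("smr_result", class(out))
  out
}

#' @method tidy smr_result
#' @export
tidy.smr_result <- function(x, ...) tibble::as_tibble(x)
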