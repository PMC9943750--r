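# Approximate conditional/joint analysis from summary statistics.
#
# The joint model is assembled from the standard normal-equations
# construction: X'X is approximated by panel dosage covariances scaled by
# per-variant sample size, X'y by the marginal effects, and the phenotypic
# variance by the median across window variants of the per-variant implied
# value. When the panel *is* the GWAS sample, the joint estimates equal the
# exact multiple-regression OLS coefficients.

# Build the normal-equation pieces for a meta window against a panel.
sumstat_normal_eq <- function(meta, panel, coverage_warn = 0.95) {
  dat <- dplyr::filter(meta, is.finite(.data$beta), is.finite(.data$se),
                       .data$se > 0)
  common <- intersect(dat$marker, panel$variants$marker)
  if (nrow(dat) && length(common) < coverage_warn * nrow(dat)) {
    warning(sprintf("panel '%s' covers %d/%d window variants (< %.0f%%)",
                    panel$source, length(common), nrow(dat),
                    100 * coverage_warn))
  }
  dat <- dat[match(common, dat$marker), , drop = FALSE]
  G <- panel$dosages[, common, drop = FALSE]
  np <- nrow(G)
  mu <- colMeans(G)
  v <- (colSums(G^2) - np * mu^2) / (np - 1)
  keep <- v > 0
  dat <- dat[keep, , drop = FALSE]
  G <- G[, keep, drop = FALSE]
  v <- v[keep]
  if (!nrow(dat)) {
    return(list(dat = dat, W = matrix(0, 0, 0), xy = numeric(0),
                R = matrix(0, 0, 0), yty = NA_real_, N = NA_real_,
                sigma2y = NA_real_))
  }
  R <- suppressWarnings(cor(G))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  nj <- if ("n" %in% names(dat)) dat$n else dat$n_total
  if (is.null(nj)) stop("meta window needs an 'n' or 'n_total' column")
  sc <- sqrt(v * (nj - 1))
  W <- unname(R * tcrossprod(sc))
  xy <- unname(v * (nj - 1) * dat$beta)
  s2y <- v * ((nj - 1) * dat$se^2 + dat$beta^2)
  sigma2y <- median(s2y)
  N <- median(nj)
  list(dat = dat, W = W, xy = xy, R = R, yty = sigma2y * (N - 1), N = N,
       sigma2y = sigma2y)
}

# Joint fit of the variants indexed by `sel` (indices into ne$dat rows).
joint_fit <- function(ne, sel) {
  Wss <- ne$W[sel, sel, drop = FALSE]
  A <- unname(solve(Wss))
  b <- drop(A %*% ne$xy[sel])
  rss <- max(ne$yty - sum(b * ne$xy[sel]), 1e-12)
  sigma2 <- rss / (ne$N - length(sel) - 1)
  se <- sqrt(pmax(diag(A) * sigma2, 0))
  list(beta = b, se = se, p = z_to_p(b / se), A = A, rss = rss,
       sigma2 = sigma2)
}

#' Stepwise model selection from summary statistics (COJO-style)
#'
#' Forward stepwise selection seeded with the smallest-p variant: at each
#' step the conditional estimate of every remaining candidate given the
#' selected set is computed from the summary-statistics normal equations
#' (panel LD, panel allele-frequency variances, marginal betas, per-variant
#' sample sizes); the candidate with the smallest conditional p is added if
#' it passes `p_threshold`. Candidates whose multiple-regression r² on the
#' selected set exceeds `collinearity_r2` are skipped, and at most
#' `max_signals` signals are reported per window.
#'
#' @param meta Meta-analysis window (a `meta_result` subset; typically the
#'   lead ± 1 Mb or the extended locus region, whichever is larger).
#' @param panel [ld_panel] LD reference.
#' @param p_threshold Conditional significance threshold.
#' @param collinearity_r2 Multiple-regression r² exclusion threshold.
#' @param max_signals Cap on signals per window.
#' @return Tibble with one row per selected signal: marginal `beta, se, p`;
#'   joint `bJ, bJ_se, pJ`; conditional-on-the-others `bC, bC_se, pC`;
#'   `ld_with_primary` (panel r² with the first-selected signal); `step`
#'   (selection order); and `panel` (source label). For a single-signal
#'   window the conditional statistics equal the marginal ones (conditioning
#'   on nothing). Attribute `"dropped"` logs candidates discarded for
#'   numerical singularity.
#' @export
cojo_select <- function(meta, panel, p_threshold = 5e-8,
                        collinearity_r2 = 0.8, max_signals = 3) {
  ne <- sumstat_normal_eq(meta, panel)
  dat <- ne$dat
  empty <- dat[0, c("marker", "chr", "pos", "ea", "nea", "eaf",
                    "beta", "se", "p")] |>
    dplyr::mutate(bJ = double(), bJ_se = double(), pJ = double(),
                  bC = double(), bC_se = double(), pC = double(),
                  ld_with_primary = double(), step = integer(),
                  panel = character())
  if (!nrow(dat)) return(empty)
  m <- nrow(dat)
  wdiag <- diag(ne$W)
  ord <- order(dat$p, dat$se, dat$marker)
  if (!(dat$p[ord[1]] < p_threshold)) return(empty)
  sel <- ord[1]
  dropped <- character(0)
  while (length(sel) < max_signals) {
    cand <- setdiff(seq_len(m), sel)
    if (!length(cand)) break
    A <- tryCatch(solve(ne$W[sel, sel, drop = FALSE]), error = function(e) NULL)
    if (is.null(A)) {
      dropped <- c(dropped, dat$marker[sel[length(sel)]])
      sel <- sel[-length(sel)]
      if (!length(sel)) break
      next
    }
    Axy <- drop(A %*% ne$xy[sel])
    rss_s <- max(ne$yty - sum(Axy * ne$xy[sel]), 1e-12)
    Wsc <- ne$W[sel, cand, drop = FALSE]
    M <- A %*% Wsc
    schur <- wdiag[cand] - colSums(Wsc * M)
    # pure-LD multiple regression r^2 of each candidate on the selected set
    AR <- solve(ne$R[sel, sel, drop = FALSE])
    Rsc <- ne$R[sel, cand, drop = FALSE]
    r2multi <- colSums(Rsc * (AR %*% Rsc))
    num <- ne$xy[cand] - drop(crossprod(Wsc, Axy))
    ok <- r2multi <= collinearity_r2 & schur > 1e-10 * wdiag[cand]
    if (!any(ok)) break
    rss_c <- pmax(rss_s - num^2 / schur, 1e-12)
    sigma2 <- rss_c / (ne$N - length(sel) - 2)
    bc <- num / schur
    sec <- sqrt(sigma2 / schur)
    pc <- z_to_p(bc / sec)
    pc[!ok] <- Inf
    j <- order(pc, dat$marker[cand])[1]
    if (!(pc[j] < p_threshold)) break
    sel <- c(sel, cand[j])
  }
  fit <- joint_fit(ne, sel)
  k <- length(sel)
  bC <- dat$beta[sel]; bC_se <- dat$se[sel]; pC <- dat$p[sel]
  if (k > 1) {
    for (i in seq_len(k)) {
      oth <- sel[-i]
      fo <- joint_fit(ne, oth)
      w_io <- ne$W[sel[i], oth]
      bC[i] <- (ne$xy[sel[i]] - sum(w_io * fo$beta)) / wdiag[sel[i]]
      sig2_o <- fo$rss / (ne$N - k - 1)
      bC_se[i] <- sqrt(sig2_o / wdiag[sel[i]])
      pC[i] <- z_to_p(bC[i] / bC_se[i])
    }
  }
  primary <- dat$marker[sel[1]]
  out <- dat[sel, c("marker", "chr", "pos", "ea", "nea", "eaf",
                    "beta", "se", "p")] |>
    dplyr::mutate(
      bJ = fit$beta, bJ_se = fit$se, pJ = fit$p,
      bC = bC, bC_se = bC_se, pC = pC,
      ld_with_primary = ne$R[cbind(sel, rep(sel[1], k))]^2,
      step = seq_len(k),
      panel = panel$source
    )
  attr(out, "dropped") <- dropped
  attr(out, "sigma2y") <- ne$sigma2y
  out
}

#' Multi-panel consensus over conditionally distinct signals
#'
#' Signals from different reference panels are grouped by the proxy relation
#' (r² > `proxy_r2` in the designated LD source); groups supported by at
#' least `min_panels` panels are accepted, represented by the member with
#' the smallest conditional p.
#'
#' @param per_panel Named list of signal tibbles from [cojo_select()] (one
#'   per reference panel).
#' @param ld_panel [ld_panel] used for the proxy grouping (default source for
#'   proxy r² is this panel).
#' @param proxy_r2 Proxy threshold.
#' @param min_panels Minimum supporting panels.
#' @return Tibble of accepted representatives with list-column
#'   `panel_support`; attribute `"rejected"` holds the single-panel groups.
#' @export
consensus_signals <- function(per_panel, ld_panel, proxy_r2 = 0.8,
                              min_panels = 2) {
  stopifnot(length(per_panel) >= 2)
  if (is.null(names(per_panel)) || any(!nzchar(names(per_panel)))) {
    names(per_panel) <- sprintf("panel%d", seq_along(per_panel))
  }
  rows <- dplyr::bind_rows(per_panel, .id = "ref_panel")
  if (!nrow(rows)) {
    return(structure(rows, rejected = rows))
  }
  mk <- sort(unique(rows$marker))
  k <- length(mk)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  present <- mk %in% ld_panel$variants$marker
  if (k > 1 && any(present)) {
    C2 <- panel_cor(ld_panel, mk[present])^2
    pres_idx <- which(present)
    for (a in seq_along(pres_idx)) {
      for (b in seq_along(pres_idx)) {
        if (a < b && C2[a, b] > proxy_r2) {
          parent[find(pres_idx[b])] <- find(pres_idx[a])
        }
      }
    }
  }
  grp <- vapply(match(rows$marker, mk), find, integer(1))
  rows$group <- grp
  summ <- rows |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(n_panels = dplyr::n_distinct(.data$ref_panel)) |>
    dplyr::arrange(.data$pC, .data$marker, .by_group = TRUE) |>
    dplyr::ungroup()
  support <- rows |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(panel_support = list(sort(unique(.data$ref_panel))),
                     .groups = "drop")
  reps <- summ |>
    dplyr::distinct(.data$group, .keep_all = TRUE) |>
    dplyr::left_join(support, by = "group")
  accepted <- dplyr::filter(reps, .data$n_panels >= min_panels)
  rejected <- dplyr::filter(reps, .data$n_panels < min_panels)
  structure(accepted, rejected = rejected)
}

#' MAF-consistency screen between meta-analysis and reference panels
#'
#' A signal is excluded when its meta-analysis MAF differs from the panel MAF
#' by more than `tol` in a majority of the panels that contain the variant,
#' or when no panel contains it at all.
#'
#' @param signals Tibble with `marker` and `eaf` (meta-analysis EAF).
#' @param panels Named list of [ld_panel]s.
#' @param tol Absolute MAF difference tolerance.
#' @return Tibble: `marker, meta_maf, n_panels, n_discordant, keep, reason`,
#'   plus list-column `panel_maf` of per-panel MAFs.
#' @export
maf_consistency <- function(signals, panels, tol = 0.05) {
  assert_cols(signals, c("marker", "eaf"), "signals")
  purrr::map_dfr(seq_len(nrow(signals)), function(i) {
    mk <- signals$marker[i]
    meta_maf <- min(signals$eaf[i], 1 - signals$eaf[i])
    pm <- purrr::map_dbl(panels, function(p) {
      if (mk %in% p$variants$marker) unname(panel_maf(p, mk)) else NA_real_
    })
    have <- sum(!is.na(pm))
    if (have == 0) {
      return(tibble::tibble(marker = mk, meta_maf = meta_maf,
                            panel_maf = list(pm), n_panels = 0L,
                            n_discordant = 0L, keep = FALSE,
                            reason = "no panel frequency"))
    }
    disc <- sum(abs(pm - meta_maf) > tol, na.rm = TRUE)
    keep <- disc <= have / 2
    tibble::tibble(marker = mk, meta_maf = meta_maf, panel_maf = list(pm),
                   n_panels = have, n_discordant = disc, keep = keep,
                   reason = ifelse(keep, NA_character_, "MAF discordant"))
  })
}
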