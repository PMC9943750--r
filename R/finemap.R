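#' Approximate-Bayes-factor posteriors over a window
#'
#' Per-variant evidence is `ln BF = 0.5 * (beta/se)^2` (the prior-variance
#' constant cancels under normalisation); posteriors are the normalised BFs
#' computed in the log domain.
#'
#' @param assocs Window tibble with `beta` and `se` (> 0).
#' @return The input with columns `lnbf` and `posterior` appended; posteriors
#'   sum to one over the window.
#' @export
#' @examples
#' abf_posteriors(tibble::tibble(marker = c("a", "b", "c"),
#'                               beta = c(3, 2, 1), se = 1))
abf_posteriors <- function(assocs) {
  assert_cols(assocs, c("beta", "se"), "assocs")
  if (!nrow(assocs)) stop("empty window: no variants to score")
  if (any(assocs$se <= 0, na.rm = TRUE)) stop("all standard errors must be > 0")
  z <- assocs$beta / assocs$se
  lnbf <- 0.5 * z^2
  assocs$lnbf <- lnbf
  assocs$posterior <- exp(lnbf - logsumexp(lnbf))
  assocs
}

#' Credible set from normalised posteriors
#'
#' Variants are sorted by descending posterior (ties broken by marker id for
#' determinism) and included until the cumulative posterior reaches
#' `coverage`.
#'
#' @param x Tibble with `posterior` (and ideally `marker`).
#' @param coverage Target coverage (default 0.99).
#' @return A `credible_set` tibble sorted by posterior with `cumulative` and
#'   `in_set` columns.
#' @export
credible_set <- function(x, coverage = 0.99) {
  assert_cols(x, "posterior", "x")
  if (is.null(x$marker)) x$marker <- sprintf("v%05d", seq_len(nrow(x)))
  out <- dplyr::arrange(x, dplyr::desc(.data$posterior), .data$marker)
  out$cumulative <- cumsum(out$posterior)
  cut <- match(TRUE, out$cumulative >= coverage - 1e-12)
  if (is.na(cut)) cut <- nrow(out)
  out$in_set <- seq_len(nrow(out)) <= cut
  attr(out, "coverage") <- coverage
  class(out) <- c("credible_set", class(out))
  out
}

#' Conditional credible set for one signal of a multi-signal locus
#'
#' For loci with several conditionally distinct signals, the target signal's
#' window statistics are replaced by estimates conditional on the locus's
#' other accepted signals (computed from the summary-statistics normal
#' equations against the reference panel), and the ABF machinery is applied
#' to those.
#'
#' @param meta `meta_result` rows (at least the lead ± `flank` window plus
#'   the conditioning signals).
#' @param panel [ld_panel] reference (the panel used for conditional
#'   analysis).
#' @param lead Target signal marker.
#' @param condition_on Markers of the locus's other signals (may be empty,
#'   in which case the set equals the unconditional one).
#' @param coverage Credible-set coverage.
#' @param flank Window half-width around the lead.
#' @return A `credible_set` tibble (see [credible_set()]); columns `bC` and
#'   `bC_se` hold the statistics actually scored.
#' @export
conditional_credible_set <- function(meta, panel, lead,
                                     condition_on = character(),
                                     coverage = 0.99, flank = 5e5) {
  condition_on <- setdiff(condition_on, lead)
  lead_row <- meta[meta$marker == lead, ]
  if (!nrow(lead_row)) stop("lead variant absent from the meta window")
  win <- meta[meta$chr == lead_row$chr[1] &
                abs(meta$pos - lead_row$pos[1]) <= flank, ]
  if (!length(condition_on)) {
    scored <- dplyr::mutate(win, bC = .data$beta, bC_se = .data$se)
    return(credible_set(abf_posteriors(scored), coverage))
  }
  need <- unique(c(win$marker, condition_on))
  ne <- sumstat_normal_eq(meta[meta$marker %in% need, ], panel)
  oth <- match(condition_on, ne$dat$marker)
  oth <- oth[!is.na(oth)]
  if (!length(oth)) {
    scored <- dplyr::mutate(win, bC = .data$beta, bC_se = .data$se)
    return(credible_set(abf_posteriors(scored), coverage))
  }
  fo <- joint_fit(ne, oth)
  sig2 <- fo$rss / (ne$N - length(oth) - 2)
  targets <- setdiff(intersect(win$marker, ne$dat$marker),
                     ne$dat$marker[oth])
  ti <- match(targets, ne$dat$marker)
  wdiag <- diag(ne$W)
  bC <- (ne$xy[ti] - drop(ne$W[ti, oth, drop = FALSE] %*% fo$beta)) / wdiag[ti]
  bC_se <- sqrt(sig2 / wdiag[ti])
  scored <- ne$dat[ti, c("marker", "chr", "pos", "eaf")] |>
    dplyr::mutate(beta = ne$dat$beta[ti], se = ne$dat$se[ti],
                  bC = bC, bC_se = bC_se)
  scored <- abf_posteriors(dplyr::mutate(scored, beta = bC, se = bC_se))
  # keep the marginal stats visible alongside the conditional ones
  scored$beta <- ne$dat$beta[ti]
  scored$se <- ne$dat$se[ti]
  credible_set(scored, coverage)
}

#' Extend a credible set with LD proxies of the lead
#'
#' The extended set is the union of the Bayesian credible set and every panel
#' variant with r² >= `r2_threshold` with the lead inside the window. Panel
#' variants absent from the meta-analysis (unscored) join with `posterior =
#' NA` and `extension_only = TRUE`; scored variants pulled in only by LD are
#' likewise flagged `extension_only`.
#'
#' @param cs A `credible_set` (from [credible_set()] or
#'   [conditional_credible_set()]).
#' @param lead Lead marker of the signal.
#' @param panel [ld_panel] supplying the proxies (a 1000-Genomes-like
#'   reference; may contain variants missing from the meta-analysis).
#' @param r2_threshold Proxy threshold; the boundary is inclusive by default
#'   (`inclusive = TRUE`).
#' @param inclusive Use `>=` (default) rather than strict `>`.
#' @param flank Restrict proxies to within `flank` bp of the lead.
#' @return The credible-set tibble with columns `r2_with_lead`,
#'   `extension_only` and `in_extended`; extension rows appended at the end.
#' @export
extend_credible_set <- function(cs, lead, panel, r2_threshold = 0.8,
                                inclusive = TRUE, flank = 5e5) {
  out <- cs
  out$extension_only <- FALSE
  if (!lead %in% panel$variants$marker) {
    warning("lead variant absent from extension panel; set returned unchanged")
    out$r2_with_lead <- NA_real_
    out$in_extended <- out$in_set
    return(out)
  }
  lead_pos <- panel$variants$pos[match(lead, panel$variants$marker)]
  lead_chr <- panel$variants$chr[match(lead, panel$variants$marker)]
  prox <- panel_proxies(panel, lead, r2_threshold, inclusive = inclusive,
                        include_self = TRUE)
  pv <- panel$variants[match(prox, panel$variants$marker), ]
  prox <- prox[pv$chr == lead_chr & abs(pv$pos - lead_pos) <= flank]
  in_panel <- out$marker %in% panel$variants$marker
  out$r2_with_lead <- NA_real_
  out$r2_with_lead[in_panel] <- panel_r2(panel, out$marker[in_panel], lead)
  new <- setdiff(prox, out$marker)
  if (length(new)) {
    nv <- panel$variants[match(new, panel$variants$marker), ]
    add <- tibble::tibble(marker = nv$marker, chr = nv$chr, pos = nv$pos,
                          posterior = NA_real_, cumulative = NA_real_,
                          in_set = FALSE, extension_only = TRUE,
                          r2_with_lead = panel_r2(panel, new, lead))
    out <- dplyr::bind_rows(out, add)
  }
  ext <- !is.na(out$r2_with_lead) &
    (if (inclusive) out$r2_with_lead >= r2_threshold
     else out$r2_with_lead > r2_threshold)
  out$extension_only <- !out$in_set & (ext | out$extension_only)
  out$in_extended <- out$in_set | out$extension_only
  attr(out, "coverage") <- attr(cs, "coverage")
  class(out) <- unique(c("credible_set", class(out)))
  out
}
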