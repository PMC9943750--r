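#' Wakefield log approximate Bayes factors
#'
#' `ln ABF = 0.5 * (ln(se^2/(se^2+W)) + W z^2/(se^2+W))` with `W =
#' prior_sd^2`, the evidence for association at a variant given only its
#' effect estimate and standard error.
#'
#' @param beta,se Effect estimates and standard errors (`se > 0`).
#' @param prior_sd Prior standard deviation of the true effect (0.15 is the
#'   usual default for quantitative traits, 0.2 for case-control log-odds).
#' @return Numeric vector of log ABFs.
#' @export
trait_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0, na.rm = TRUE)) stop("all standard errors must be > 0")
  W <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * (log(se^2 / (se^2 + W)) + W * z2 / (se^2 + W))
}

#' Pairwise Bayesian colocalization
#'
#' Standard five-hypothesis enumeration over per-variant Wakefield ABFs:
#' H0 no association, H1/H2 one trait only, H3 both traits with distinct
#' causal variants, H4 a shared causal variant. Computed in the log domain;
#' posteriors match brute-force summation over all variant assignments.
#'
#' @param trait_a,trait_b Summary tibbles sharing a `marker` column with
#'   `beta` and `se`; only shared markers are used.
#' @param p1,p2,p12 Per-variant prior probabilities of association with
#'   trait A only, trait B only, and both (coloc defaults).
#' @param prior_sd_a,prior_sd_b Wakefield prior SDs per trait.
#' @return A one-row `coloc_result` tibble: `nsnps, pp0, pp1, pp2, pp3,
#'   pp4, candidate, candidate_pp` (best shared variant under H4 and its
#'   posterior within H4). Attribute `"by_variant"` holds the per-variant
#'   log ABFs and H4 posteriors.
#' @export
coloc_pair <- function(trait_a, trait_b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd_a = 0.15, prior_sd_b = 0.15) {
  assert_cols(trait_a, c("marker", "beta", "se"), "trait_a")
  assert_cols(trait_b, c("marker", "beta", "se"), "trait_b")
  shared <- dplyr::inner_join(
    dplyr::select(trait_a, "marker", beta_a = "beta", se_a = "se"),
    dplyr::select(trait_b, "marker", beta_b = "beta", se_b = "se"),
    by = "marker")
  if (!nrow(shared)) stop("no shared variants between the two traits")
  if (nrow(shared) < 50) {
    warning("fewer than 50 shared variants; colocalization may be unstable")
  }
  l1 <- trait_abf(shared$beta_a, shared$se_a, prior_sd_a)
  l2 <- trait_abf(shared$beta_b, shared$se_b, prior_sd_b)
  l12 <- l1 + l2
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l12)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
    h4 = log(p12) + s12
  )
  pp <- exp(lh - logsumexp(lh))
  snp_pp <- exp(l12 - s12)
  best <- order(-snp_pp, shared$marker)[1]
  out <- tibble::tibble(
    nsnps = nrow(shared),
    pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
    pp3 = pp[["h3"]], pp4 = pp[["h4"]],
    candidate = shared$marker[best],
    candidate_pp = snp_pp[best]
  )
  attr(out, "by_variant") <- tibble::tibble(
    marker = shared$marker, labf_a = l1, labf_b = l2, h4_pp = snp_pp)
  attr(out, "priors") <- c(p1 = p1, p2 = p2, p12 = p12)
  class(out) <- c("coloc_result", class(out))
  out
}

# Evaluate one candidate trait cluster: regional statistic (all traits
# associated somewhere in the block) and alignment statistic (they share one
# causal variant, given all are associated). Hypothesis space: any subset of
# traits associated, each at its own variant, plus "all share one variant";
# partial sharing is not modelled (single causal configuration per trait).
multi_coloc_eval <- function(labf, prior1, prior2) {
  m <- ncol(labf)
  ls_t <- apply(labf, 2, logsumexp)
  lpb <- logsumexp(rowSums(labf))
  l_shared <- log(prior1) + (m - 1) * log(prior2) + lpb
  l_distinct <- m * log(prior1) + logdiffexp(sum(ls_t), lpb)
  # log Z over all subset hypotheses with per-trait independent variants,
  # then swap the all-associated shared-tuple mass to the coloc prior
  l_subsets <- sum(log1pexp(log(prior1) + ls_t))
  lz <- logsumexp(c(logdiffexp(l_subsets, m * log(prior1) + lpb), l_shared))
  l_assoc <- logsumexp(c(l_distinct, l_shared))
  pr <- exp(l_assoc - lz)
  pa <- exp(l_shared - l_assoc)
  snp_l <- rowSums(labf)
  best <- which.max(snp_l)
  list(pr = pr, pa = pa, ppfc = exp(l_shared - lz), candidate = best,
       candidate_pp = exp(snp_l[best] - lpb))
}

#' Multi-trait Bayesian colocalization with divisive clustering
#'
#' For a block of traits (each with per-variant `beta`/`se` over shared
#' variants), computes per candidate cluster a regional association
#' statistic (posterior that all cluster traits are associated within the
#' block) and an alignment statistic (posterior that they share one causal
#' variant given association); their product is the posterior probability of
#' full colocalization (PPFC). If the full set fails the thresholds, the
#' trait whose removal most improves the PPFC is peeled off and the
#' remainder re-evaluated, recursively, reporting the largest colocalizing
#' cluster(s).
#'
#' @param traits Named list (>= 2) of tibbles with `marker`, `beta`, `se`;
#'   only markers shared by all traits are used.
#' @param prior1 Prior probability a variant is associated with one trait.
#' @param prior2 Conditional colocalization prior: probability a variant
#'   causal for one trait is causal for an additional trait.
#' @param regional_thresh,align_thresh Acceptance thresholds on the regional
#'   and alignment statistics.
#' @param prior_sd Wakefield prior SD (scalar or per-trait named vector).
#' @return A `multi_coloc` tibble with one row per evaluated trait set:
#'   `traits` (list), `n_traits`, `pr`, `pa`, `ppfc`, `candidate`,
#'   `selected` (accepted cluster flag).
#' @export
multi_coloc <- function(traits, prior1 = 1e-4, prior2 = 0.98,
                        regional_thresh = 0.6, align_thresh = 0.6,
                        prior_sd = 0.15) {
  if (length(traits) < 2) stop("multi-trait colocalization needs >= 2 traits")
  if (is.null(names(traits)) || any(!nzchar(names(traits)))) {
    names(traits) <- sprintf("trait%d", seq_along(traits))
  }
  shared <- Reduce(intersect, lapply(traits, function(x) x$marker))
  if (!length(shared)) stop("no variants shared by all traits")
  psd <- rep_len(prior_sd, length(traits))
  if (!is.null(names(prior_sd))) psd <- prior_sd[names(traits)]
  labf <- vapply(seq_along(traits), function(i) {
    x <- traits[[i]][match(shared, traits[[i]]$marker), ]
    trait_abf(x$beta, x$se, psd[i])
  }, numeric(length(shared)))
  colnames(labf) <- names(traits)
  rows <- list()
  explore <- function(set) {
    ev <- multi_coloc_eval(labf[, set, drop = FALSE], prior1, prior2)
    pass <- ev$pr >= regional_thresh && ev$pa >= align_thresh
    rows[[length(rows) + 1]] <<- tibble::tibble(
      traits = list(set), n_traits = length(set), pr = ev$pr, pa = ev$pa,
      ppfc = ev$ppfc, candidate = shared[ev$candidate],
      candidate_pp = ev$candidate_pp, selected = pass)
    if (pass || length(set) <= 2) return(invisible(NULL))
    drop_ppfc <- vapply(seq_along(set), function(i) {
      multi_coloc_eval(labf[, set[-i], drop = FALSE], prior1, prior2)$ppfc
    }, numeric(1))
    worst <- which.max(drop_ppfc)
    explore(set[-worst])
  }
  explore(names(traits))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("multi_coloc", class(out))
  out
}

#' Sensitivity score over a prior/threshold grid
#'
#' Reruns a colocalization engine across a grid and reports the proportion
#' of runs that still call a colocalization. For the pairwise engine the
#' default grid is 100 values of `p12`, log-uniform between 1e-8 and 1e-4;
#' for the multi-trait engine it crosses regional and alignment thresholds
#' 0.6-0.9 with `prior2` 0.98-0.995.
#'
#' @param traits For `engine = "pair"`, a list of two trait tibbles; for
#'   `engine = "multi"`, a named list of >= 2.
#' @param engine `"pair"` or `"multi"`.
#' @param grid Optional data frame overriding the default grid (`p12` for
#'   pair; `regional_thresh`, `align_thresh`, `prior2` for multi).
#' @param pp_threshold Pairwise PP4 threshold counting as a colocalization.
#' @param ... Passed to the engine.
#' @return Proportion of passing runs in `[0, 1]`, with attribute `"runs"`.
#' @export
sensitivity_score <- function(traits, engine = c("pair", "multi"),
                              grid = NULL, pp_threshold = 0.6, ...) {
  engine <- match.arg(engine)
  if (engine == "pair") {
    grid <- grid %||% data.frame(
      p12 = 10^seq(log10(1e-8), log10(1e-4), length.out = 100))
    pass <- vapply(grid$p12, function(p12) {
      res <- suppressWarnings(coloc_pair(traits[[1]], traits[[2]],
                                         p12 = p12, ...))
      res$pp4 > pp_threshold
    }, logical(1))
  } else {
    grid <- grid %||% expand.grid(
      regional_thresh = seq(0.6, 0.9, by = 0.1),
      align_thresh = seq(0.6, 0.9, by = 0.1),
      prior2 = c(0.98, 0.985, 0.99, 0.995))
    pass <- vapply(seq_len(nrow(grid)), function(i) {
      res <- multi_coloc(traits,
                         prior2 = grid$prior2[i],
                         regional_thresh = grid$regional_thresh[i],
                         align_thresh = grid$align_thresh[i], ...)
      any(res$selected & res$n_traits == length(traits))
    }, logical(1))
  }
  out <- mean(pass)
  attr(out, "runs") <- cbind(grid, pass = pass)
  out
}

#' Composite colocalization decision rule
#'
#' Signals are called colocalized when the Bayesian posterior exceeds 0.6
#' and either the sensitivity score exceeds 0.4 or the lead variants are in
#' strong LD (r² > 0.8). A missing lead-pair r² is treated as 0.
#'
#' @param pp Posterior probability of colocalization (PP4 or PPFC).
#' @param sensitivity Sensitivity score in `[0, 1]`.
#' @param lead_pair_r2 LD r² between the two lead variants.
#' @param pp_min,sens_min,r2_min Rule constants.
#' @return Logical vector.
#' @export
coloc_decision <- function(pp, sensitivity, lead_pair_r2,
                           pp_min = 0.6, sens_min = 0.4, r2_min = 0.8) {
  if (any(is.na(lead_pair_r2))) {
    message("missing lead-pair r² treated as 0")
    lead_pair_r2[is.na(lead_pair_r2)] <- 0
  }
  pp > pp_min & (sensitivity > sens_min | lead_pair_r2 > r2_min)
}

#' Consensus direction of effect across companion traits
#'
#' Primary rule: if the lead is associated with T2D or fasting glucose at
#' p < 1e-4, their effect sign (on the proinsulin effect allele) is the
#' consensus direction. Fallback: at least two companion outcomes sharing a
#' sign at p < 0.01. Conflicting qualifying signs yield `unclassified` with
#' `conflict = TRUE`.
#'
#' @param lookups Tibble with columns `trait`, `beta`, `p`, effect alleles
#'   already harmonised to the proinsulin effect allele.
#' @param primary_traits Traits driving the primary rule.
#' @param p_primary,p_fallback Rule thresholds.
#' @return One-row tibble: `direction` (`"higher"`, `"lower"`,
#'   `"unclassified"`), `rule` (`"primary"`, `"fallback"`, `"none"`),
#'   `conflict`.
#' @export
classify_direction <- function(lookups, primary_traits = c("T2D", "FG"),
                               p_primary = 1e-4, p_fallback = 0.01) {
  assert_cols(lookups, c("trait", "beta", "p"), "lookups")
  dir_of <- function(b) ifelse(b > 0, "higher", "lower")
  prim <- lookups[toupper(lookups$trait) %in% toupper(primary_traits) &
                    lookups$p < p_primary & !is.na(lookups$p), ]
  if (nrow(prim)) {
    signs <- unique(dir_of(prim$beta))
    if (length(signs) == 1) {
      return(tibble::tibble(direction = signs, rule = "primary",
                            conflict = FALSE))
    }
    return(tibble::tibble(direction = "unclassified", rule = "primary",
                          conflict = TRUE))
  }
  fb <- lookups[lookups$p < p_fallback & !is.na(lookups$p), ]
  if (nrow(fb)) {
    tab <- table(dir_of(fb$beta))
    qual <- names(tab)[tab >= 2]
    if (length(qual) == 1) {
      return(tibble::tibble(direction = qual, rule = "fallback",
                            conflict = FALSE))
    }
    if (length(qual) > 1) {
      return(tibble::tibble(direction = "unclassified", rule = "fallback",
                            conflict = TRUE))
    }
  }
  tibble::tibble(direction = "unclassified", rule = "none", conflict = FALSE)
}

#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(hypothesis = c("H0", "H1", "H2", "H3", "H4"),
                 posterior = c(x$pp0, x$pp1, x$pp2, x$pp3, x$pp4))
}

#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble::as_tibble(x)
}
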