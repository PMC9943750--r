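#' Study-level quality-control filter
#'
#' Removes variants failing any of, in order of precedence: minor allele
#' count < 3, MAF < 0.005, call rate < 0.95, Hardy-Weinberg p < 1e-5,
#' imputation quality < 0.3, or standard error strictly > 10. The exclusion
#' log records the first failing rule per removed variant.
#'
#' @param study Summary-statistic tibble with columns `marker, eaf, n,
#'   callrate, hwe_p, info, se`.
#' @param mac_min,maf_min,callrate_min,hwe_min,info_min,se_max Thresholds.
#' @return List with `kept` (filtered tibble) and `excluded`
#'   (tibble `marker`, `reason`).
#' @export
qc_filter <- function(study, mac_min = 3, maf_min = 0.005,
                      callrate_min = 0.95, hwe_min = 1e-5,
                      info_min = 0.3, se_max = 10) {
  assert_cols(study, c("marker", "eaf", "n", "callrate", "hwe_p", "info", "se"),
              "study")
  maf <- pmin(study$eaf, 1 - study$eaf)
  mac <- 2 * study$n * maf
  reason <- rep(NA_character_, nrow(study))
  rule <- function(cond, code) ifelse(is.na(reason) & cond, code, reason)
  reason <- rule(mac < mac_min, "MAC")
  reason <- rule(maf < maf_min, "MAF")
  reason <- rule(study$callrate < callrate_min, "CALLRATE")
  reason <- rule(study$hwe_p < hwe_min, "HWE")
  reason <- rule(study$info < info_min, "INFO")
  reason <- rule(study$se > se_max, "SE")
  keep <- is.na(reason)
  # NA in a QC field never passes silently: treat as missing-data failure
  keep[is.na(keep)] <- FALSE
  list(
    kept = study[keep, , drop = FALSE],
    excluded = tibble::tibble(marker = study$marker[!keep],
                              reason = reason[!keep])
  )
}

# median of the chi-square(1) distribution (qchisq(0.5, 1)), fixed for
# reproducibility across platforms
CHISQ1_MEDIAN <- 0.4549364

#' Genomic-control correction
#'
#' `lambda = median((beta/se)^2) / 0.4549364`. When `lambda > 1`, standard
#' errors are inflated by `sqrt(lambda)` and p-values recomputed from the
#' deflated z-scores; statistics are never deflated when `lambda <= 1`
#' (standard METAL behaviour), but lambda is always reported.
#'
#' @param assocs Summary-statistic tibble with `beta` and `se`.
#' @return The corrected tibble, with attribute `"lambda"` (see
#'   [gc_lambda()]).
#' @export
genomic_control <- function(assocs) {
  assert_cols(assocs, c("beta", "se"), "assocs")
  z <- assocs$beta / assocs$se
  z <- z[is.finite(z)]
  if (!length(z)) stop("no finite z-scores; cannot estimate lambda")
  if (length(z) < 100) {
    warning("fewer than 100 informative variants; lambda estimate unreliable")
  }
  lambda <- median(z^2) / CHISQ1_MEDIAN
  out <- assocs
  if (lambda > 1) {
    out$se <- out$se * sqrt(lambda)
    out$p <- z_to_p(out$beta / out$se)
  }
  attr(out, "lambda") <- lambda
  out
}

#' @rdname genomic_control
#' @param x A tibble returned by [genomic_control()] or [ivw_meta()].
#' @export
gc_lambda <- function(x) attr(x, "lambda")

#' Harmonise alleles against a reference orientation
#'
#' Effect/non-effect alleles are matched to the reference map (allowing a
#' strand flip); swapped records have their beta sign and EAF flipped.
#' Strand-ambiguous (A/T, C/G) variants with MAF > 0.4 are dropped, as are
#' records whose allele pair cannot be reconciled with the reference.
#'
#' @param study Summary-statistic tibble (`marker, ea, nea, eaf, beta`).
#' @param reference Tibble `marker, ea, nea` giving the target orientation.
#' @param ambiguous_maf Drop threshold for palindromic variants.
#' @return List with `harmonized` and `excluded` (tibble `marker`, `reason`).
#' @export
align_alleles <- function(study, reference, ambiguous_maf = 0.4) {
  assert_cols(study, c("marker", "ea", "nea", "eaf", "beta"), "study")
  assert_cols(reference, c("marker", "ea", "nea"), "reference")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  i <- match(study$marker, reference$marker)
  rea <- reference$ea[i]; rnea <- reference$nea[i]
  ea <- toupper(study$ea); nea <- toupper(study$nea)
  palindromic <- ea == comp[nea]
  maf <- pmin(study$eaf, 1 - study$eaf)
  same <- ea == rea & nea == rnea
  swap <- ea == rnea & nea == rea
  flip_same <- comp[ea] == rea & comp[nea] == rnea
  flip_swap <- comp[ea] == rnea & comp[nea] == rea
  reason <- rep(NA_character_, nrow(study))
  reason[is.na(i)] <- "no_reference"
  amb <- is.na(reason) & palindromic & maf > ambiguous_maf
  reason[amb] <- "ambiguous"
  ok <- is.na(reason) & (same | swap | flip_same | flip_swap)
  reason[is.na(reason) & !ok] <- "irreconcilable"
  out <- study[ok, , drop = FALSE]
  # retained palindromic pairs (MAF <= threshold) are read as same-strand:
  # a same-orientation match is preferred over a strand-flip swap
  need_flip <- ((swap | flip_swap) & !(same | flip_same))[ok]
  out$beta[need_flip] <- -out$beta[need_flip]
  out$eaf[need_flip] <- 1 - out$eaf[need_flip]
  out$ea <- rea[ok]
  out$nea <- rnea[ok]
  list(
    harmonized = out,
    excluded = tibble::tibble(marker = study$marker[!ok],
                              reason = reason[!ok])
  )
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' METAL-style pooling with double genomic control: each study is GC-corrected
#' first, then the pooled statistics are GC-corrected again. Per variant,
#' `w_i = 1/se_i^2`, pooled `beta = sum(w b)/sum(w)`, `se = sqrt(1/sum(w))`.
#' EAF is pooled as the sample-size-weighted mean.
#'
#' @param studies A list of harmonised summary-statistic tibbles (one per
#'   study), or a single tibble.
#' @param gc_studies,gc_meta Apply genomic control per study / post-meta.
#' @return A `meta_result` tibble (`marker, chr, pos, ea, nea, eaf, beta, se,
#'   p, n_total, n_studies`) with attributes `lambda_study` (named vector)
#'   and `lambda` (post-meta factor).
#' @export
ivw_meta <- function(studies, gc_studies = TRUE, gc_meta = TRUE) {
  if (is.data.frame(studies)) studies <- list(studies)
  stopifnot(length(studies) >= 1)
  if (is.null(names(studies)) || any(!nzchar(names(studies)))) {
    names(studies) <- sprintf("study%d", seq_along(studies))
  }
  lam <- setNames(rep(NA_real_, length(studies)), names(studies))
  prepped <- purrr::imap(studies, function(s, nm) {
    assert_cols(s, c("marker", "beta", "se", "n", "eaf"), nm)
    s <- dplyr::filter(s, is.finite(.data$beta), is.finite(.data$se),
                       .data$se > 0)
    if (gc_studies && nrow(s)) {
      s <- suppressWarnings(genomic_control(s))
      lam[[nm]] <<- gc_lambda(s)
    }
    s
  })
  all <- dplyr::bind_rows(prepped, .id = "study")
  pooled <- all |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      chr = dplyr::first(.data$chr),
      pos = dplyr::first(.data$pos),
      ea = dplyr::first(.data$ea),
      nea = dplyr::first(.data$nea),
      eaf = sum(.data$n * .data$eaf) / sum(.data$n),
      beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se = sqrt(1 / sum(1 / .data$se^2)),
      n_total = sum(.data$n),
      n_studies = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(p = z_to_p(.data$beta / .data$se)) |>
    dplyr::relocate("p", .after = "se")
  lambda_meta <- NA_real_
  if (gc_meta && nrow(pooled)) {
    pooled <- suppressWarnings(genomic_control(pooled))
    lambda_meta <- gc_lambda(pooled)
  }
  structure(pooled, lambda_study = lam, lambda = lambda_meta,
            class = c("meta_result", class(pooled)))
}

#' Post-meta-analysis inclusion filter
#'
#' Keeps variants represented by at least a quarter of the maximum sample
#' size, present in at least two studies, with pooled MAF strictly > 0.005.
#'
#' @param meta A `meta_result` tibble.
#' @param max_n Maximum per-variant total sample size (default: observed).
#' @param n_frac,min_studies,maf_min Thresholds.
#' @return Filtered `meta_result`.
#' @export
post_meta_filter <- function(meta, max_n = NULL, n_frac = 0.25,
                             min_studies = 2, maf_min = 0.005) {
  assert_cols(meta, c("n_total", "n_studies", "eaf"), "meta")
  max_n <- max_n %||% max(meta$n_total)
  keep <- meta$n_total >= n_frac * max_n &
    meta$n_studies >= min_studies &
    pmin(meta$eaf, 1 - meta$eaf) > maf_min
  out <- meta[keep, , drop = FALSE]
  attr(out, "lambda_study") <- attr(meta, "lambda_study")
  attr(out, "lambda") <- attr(meta, "lambda")
  out
}

#' Define association loci and merge by lead-variant LD
#'
#' Greedy lead selection by ascending p-value among genome-wide-significant
#' variants: each lead claims all variants within `flank` bp; loci whose
#' leads are in LD (`r² > merge_r2` in the reference panel) are combined into
#' one extended region led by the smallest-p lead. Ties on p are broken by
#' smaller SE, then marker id, so output is independent of row order.
#'
#' @param meta A filtered `meta_result`.
#' @param panel Optional [ld_panel] supplying lead-lead r²; leads absent from
#'   the panel are retained with `lead_in_panel = FALSE` and never merged.
#' @param p_threshold Lead significance threshold.
#' @param flank Locus half-width in bp.
#' @param merge_r2 Lead-lead r² above which adjacent loci merge.
#' @return Tibble: `locus, lead, chr, start, end, p, n_members,
#'   lead_in_panel`, plus list-columns `merged_from` (pre-merge leads) and
#'   `members` (marker ids within the span).
#' @export
define_loci <- function(meta, panel = NULL, p_threshold = 5e-8,
                        flank = 5e5, merge_r2 = 0.4) {
  sig <- meta |>
    dplyr::filter(.data$p < p_threshold) |>
    dplyr::arrange(.data$p, .data$se, .data$marker)
  if (!nrow(sig)) {
    return(tibble::tibble(locus = integer(), lead = character(),
                          chr = character(), start = double(), end = double(),
                          p = double(), n_members = integer(),
                          lead_in_panel = logical(),
                          merged_from = list(), members = list()))
  }
  leads <- sig[0, ]
  for (i in seq_len(nrow(sig))) {
    row <- sig[i, ]
    if (!nrow(leads) ||
        !any(leads$chr == row$chr & abs(leads$pos - row$pos) <= flank)) {
      leads <- dplyr::bind_rows(leads, row)
    }
  }
  k <- nrow(leads)
  in_panel <- if (is.null(panel)) rep(FALSE, k) else
    leads$marker %in% panel$variants$marker
  # union-find over leads connected by r^2 > merge_r2 on the same chromosome
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(panel) && k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (leads$chr[i] != leads$chr[j]) next
      if (!in_panel[i] || !in_panel[j]) next
      r2 <- panel_r2(panel, leads$marker[i], leads$marker[j])
      if (isTRUE(r2 > merge_r2)) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(k), find, integer(1))
  groups <- split(seq_len(k), comp)
  out <- purrr::map(groups, function(idx) {
    g <- leads[idx, ]
    best <- which.min(g$p)
    tibble::tibble(
      lead = g$marker[best], chr = g$chr[best],
      start = min(g$pos) - flank, end = max(g$pos) + flank,
      p = g$p[best],
      lead_in_panel = in_panel[idx[best]],
      merged_from = list(g$marker),
      members = list(meta$marker[meta$chr == g$chr[best] &
                                   meta$pos >= min(g$pos) - flank &
                                   meta$pos <= max(g$pos) + flank])
    )
  }) |> dplyr::bind_rows()
  out <- out |>
    dplyr::mutate(n_members = lengths(.data$members)) |>
    dplyr::arrange(.data$p) |>
    dplyr::mutate(locus = dplyr::row_number()) |>
    dplyr::relocate("locus")
  out
}

#' Per-variant proportion of trait variance explained
#'
#' `2 * beta^2 * f * (1 - f)` for a standardised trait, with `f` the effect
#' allele frequency. Sum over independent lead variants for the total.
#'
#' @param beta Effect size (trait SD per allele).
#' @param eaf Effect allele frequency, strictly inside (0, 1).
#' @return Proportion(s) of variance explained.
#' @export
#' @examples
#' variance_explained(0.26, 0.19)  # ~0.0208, i.e. 2.1%
variance_explained <- function(beta, eaf) {
  if (any(eaf <= 0 | eaf >= 1)) {
    stop("eaf must lie strictly within (0, 1); monomorphic variants carry none")
  }
  2 * beta^2 * eaf * (1 - eaf)
}

#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  lam <- attr(x, "lambda_study")
  tibble::tibble(
    n_variants = nrow(x),
    n_studies = max(x$n_studies),
    lambda_meta = attr(x, "lambda") %||% NA_real_,
    lambda_study_min = if (length(lam)) min(lam, na.rm = TRUE) else NA_real_,
    lambda_study_max = if (length(lam)) max(lam, na.rm = TRUE) else NA_real_
  )
}
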