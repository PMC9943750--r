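#' Simulated LD reference panels
#'
#' An `ld_panel` bundles a genotype dosage matrix (individuals by variants,
#' values 0/1/2 copies of the alternate allele) with per-variant metadata and
#' the block structure used to generate it. It stands in for the genotype-level
#' reference cohorts (study subsets, biobank extracts, 1000 Genomes Europeans)
#' that downstream stages query for allele frequencies and pairwise r².
#'
#' Linkage disequilibrium is simulated with a Gaussian copula per block:
#' haplotypes are thresholded latent AR(1) Gaussians, so correlation between
#' variants decays exponentially with index distance inside a block and is zero
#' (up to sampling noise) across blocks. This gives controllable r² targets for
#' proxy, consensus and credible-set-extension logic.
#'
#' @param n_samples Number of diploid individuals (>= 2).
#' @param blocks Block specification: a data frame with columns `n_variants`,
#'   `maf_low`, `maf_high`, `decay` (one row per LD block; `decay` is the
#'   latent AR(1) correlation between adjacent variants, 0 = independent).
#'   See [ld_blocks()].
#' @param seed Integer seed; the seed fully determines the panel.
#' @param chr Chromosome label for all blocks.
#' @param start_pos 1-based position of the first variant.
#' @param spacing Base pairs between adjacent variants within a block.
#' @param block_gap Base pairs between consecutive blocks.
#' @param source Label describing the panel (e.g. a cohort name).
#'
#' @return An object of class `ld_panel`: a list with elements `dosages`
#'   (matrix), `variants` (tibble: marker, chr, pos, ref, alt, maf, block),
#'   `n_samples`, `source`, and the generation spec for drawing fresh cohorts
#'   from the same population.
#' @export
#' @examples
#' pan <- simulate_ld_panel(200, ld_blocks(20, 0.1, 0.4, 0.9), seed = 1)
#' panel_maf(pan)[1:3]
simulate_ld_panel <- function(n_samples, blocks, seed = NULL, chr = "1",
                              start_pos = 1e6, spacing = 2000,
                              block_gap = 1e5, source = "simulated") {
  stopifnot(n_samples >= 2)
  blocks <- as_block_spec(blocks)
  if (!is.null(seed)) withr::local_seed(seed)
  maf <- unlist(lapply(seq_len(nrow(blocks)), function(b) {
    runif(blocks$n_variants[b], blocks$maf_low[b], blocks$maf_high[b])
  }))
  variants <- block_variant_meta(blocks, chr, start_pos, spacing, block_gap, maf)
  dos <- draw_dosages(n_samples, blocks, variants)
  new_ld_panel(dos, variants, source = source, blocks = blocks,
               geometry = list(chr = chr, start_pos = start_pos,
                               spacing = spacing, block_gap = block_gap))
}

#' Block specification helper
#'
#' @param n_variants,maf_low,maf_high,decay Vectors (recycled) giving, per LD
#'   block, the variant count, the planted minor-allele-frequency range in
#'   (0, 0.5], and the latent adjacent-variant correlation in [0, 1).
#' @return A data frame usable as the `blocks` argument of
#'   [simulate_ld_panel()].
#' @export
ld_blocks <- function(n_variants, maf_low = 0.05, maf_high = 0.5, decay = 0.9) {
  as_block_spec(data.frame(n_variants = n_variants, maf_low = maf_low,
                           maf_high = maf_high, decay = decay))
}

as_block_spec <- function(blocks) {
  blocks <- as.data.frame(blocks)
  assert_cols(blocks, c("n_variants", "maf_low", "maf_high", "decay"), "blocks")
  if (any(blocks$n_variants < 1)) {
    stop("degenerate block: each block must contain at least one variant")
  }
  if (any(blocks$maf_low <= 0 | blocks$maf_high > 0.5 |
          blocks$maf_low > blocks$maf_high)) {
    stop("maf range must lie within (0, 0.5]")
  }
  if (any(blocks$decay < 0 | blocks$decay >= 1)) {
    stop("decay must lie in [0, 1)")
  }
  blocks
}

block_variant_meta <- function(blocks, chr, start_pos, spacing, block_gap, maf) {
  m_tot <- sum(blocks$n_variants)
  pos <- integer(0)
  cur <- start_pos
  for (b in seq_len(nrow(blocks))) {
    m <- blocks$n_variants[b]
    pos <- c(pos, cur + spacing * (seq_len(m) - 1L))
    cur <- cur + spacing * m + block_gap
  }
  tibble::tibble(
    marker = sprintf("var%06d", seq_len(m_tot)),
    chr = as.character(chr),
    pos = as.integer(pos),
    ref = "A",
    alt = "G",
    maf = maf,
    block = rep(seq_len(nrow(blocks)), blocks$n_variants)
  )
}

draw_dosages <- function(n, blocks, variants) {
  cols <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    idx <- which(variants$block == b)
    maf <- variants$maf[idx]
    d <- blocks$decay[b]
    m <- length(idx)
    if (d <= 0) {
      dos <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    } else {
      dos <- ar1_haplotypes(n, maf, d) + ar1_haplotypes(n, maf, d)
    }
    cols[[b]] <- dos
  }
  dos <- do.call(cbind, cols)
  colnames(dos) <- variants$marker
  storage.mode(dos) <- "integer"
  dos
}

# one haplotype per individual: AR(1) latent Gaussian thresholded at qnorm(maf)
ar1_haplotypes <- function(n, maf, rho) {
  m <- length(maf)
  e <- matrix(rnorm(n * m), n, m)
  if (m > 1) {
    s <- sqrt(1 - rho^2)
    for (k in 2:m) e[, k] <- rho * e[, k - 1] + s * e[, k]
  }
  (e < rep(qnorm(maf), each = n)) + 0L
}

new_ld_panel <- function(dosages, variants, source = "panel", blocks = NULL,
                         geometry = NULL) {
  structure(
    list(dosages = dosages, variants = variants,
         n_samples = nrow(dosages), source = source,
         blocks = blocks, geometry = geometry,
         cache = new.env(parent = emptyenv())),
    class = "ld_panel")
}

#' Wrap an existing dosage matrix as an LD panel
#'
#' Useful for hand-built fixtures and for real reference data read from disk.
#'
#' @param dosages Numeric matrix, individuals by variants, values in `{0,1,2}`.
#'   Column names are used as markers when `variants` is `NULL`.
#' @param variants Optional tibble with columns `marker`, `chr`, `pos`
#'   (and optionally `ref`, `alt`, `block`).
#' @param source Panel label.
#' @return An `ld_panel`.
#' @export
as_ld_panel <- function(dosages, variants = NULL, source = "user") {
  dosages <- as.matrix(dosages)
  if (!all(dosages %in% 0:2)) stop("dosage values must be in {0, 1, 2}")
  if (is.null(variants)) {
    mk <- colnames(dosages) %||% sprintf("var%06d", seq_len(ncol(dosages)))
    variants <- tibble::tibble(marker = mk, chr = "1",
                               pos = as.integer(seq_len(ncol(dosages)) * 1000),
                               ref = "A", alt = "G",
                               maf = pmin(colMeans(dosages) / 2,
                                          1 - colMeans(dosages) / 2),
                               block = 1L)
  }
  variants <- tibble::as_tibble(variants)
  assert_cols(variants, c("marker", "chr", "pos"), "variants")
  if (!"block" %in% names(variants)) variants$block <- 1L
  if (!"ref" %in% names(variants)) variants$ref <- "A"
  if (!"alt" %in% names(variants)) variants$alt <- "G"
  colnames(dosages) <- variants$marker
  new_ld_panel(dosages, variants, source = source)
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel '%s': %d samples x %d variants, %d block(s)>\n",
              x$source, x$n_samples, ncol(x$dosages),
              length(unique(x$variants$block))))
  invisible(x)
}

#' Draw a fresh cohort from the population behind a simulated panel
#'
#' Regenerates genotypes from the stored block structure and planted allele
#' frequencies, so per-cohort samples are independent draws from the same
#' population (the assumption behind fixed-effects meta-analysis).
#'
#' @param panel An `ld_panel` created by [simulate_ld_panel()].
#' @param n_samples Cohort size.
#' @param seed Integer seed.
#' @return A new `ld_panel` with identical variant metadata.
#' @export
regenerate_panel <- function(panel, n_samples, seed = NULL,
                             source = paste0(panel$source, "-cohort")) {
  if (is.null(panel$blocks)) {
    stop("panel lacks a generation spec; only simulated panels can be redrawn")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  dos <- draw_dosages(n_samples, panel$blocks, panel$variants)
  new_ld_panel(dos, panel$variants, source = source, blocks = panel$blocks,
               geometry = panel$geometry)
}

#' Allele frequencies and r-squared queries on a panel
#'
#' `panel_freq()` returns alternate (effect) allele frequencies, `panel_maf()`
#' minor allele frequencies, `panel_cor()` the signed dosage correlation matrix
#' for a set of markers, and `panel_r2()` pairwise r² between two marker
#' vectors (element-wise).
#'
#' @param panel An `ld_panel`.
#' @param markers Marker ids; default all.
#' @return Named numeric vector (frequencies) or matrix (correlations).
#' @export
panel_freq <- function(panel, markers = NULL) {
  markers <- markers %||% panel$variants$marker
  colMeans(panel$dosages[, markers, drop = FALSE]) / 2
}

#' @rdname panel_freq
#' @export
panel_maf <- function(panel, markers = NULL) {
  f <- panel_freq(panel, markers)
  pmin(f, 1 - f)
}

#' @rdname panel_freq
#' @export
panel_cor <- function(panel, markers = NULL) {
  markers <- markers %||% panel$variants$marker
  x <- panel$dosages[, markers, drop = FALSE]
  C <- suppressWarnings(cor(x))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}

#' @rdname panel_freq
#' @param a,b Marker vectors of equal length (or one of length 1, recycled).
#' @export
panel_r2 <- function(panel, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    if (!(a[i] %in% colnames(panel$dosages)) ||
        !(b[i] %in% colnames(panel$dosages))) return(NA_real_)
    r <- suppressWarnings(cor(panel$dosages[, a[i]], panel$dosages[, b[i]]))
    if (!is.finite(r)) 0 else r^2
  }, numeric(1))
}

# Per-block correlation matrix, cached. Cross-block LD is structurally zero in
# the generator, so proxy lookups only ever scan within a block.
block_cor <- function(panel, b) {
  key <- paste0("blockcor_", b)
  if (!is.null(panel$cache[[key]])) return(panel$cache[[key]])
  idx <- panel$variants$marker[panel$variants$block == b]
  C <- panel_cor(panel, idx)
  panel$cache[[key]] <- C
  C
}

#' LD proxies of a variant within its block
#'
#' @param panel An `ld_panel`.
#' @param marker Marker id.
#' @param r2_threshold Proxy threshold on empirical r².
#' @param inclusive Treat the threshold as `>=` (`TRUE`) or strict `>`.
#' @param include_self Include the marker itself.
#' @return Character vector of proxy markers.
#' @export
panel_proxies <- function(panel, marker, r2_threshold = 0.8,
                          inclusive = FALSE, include_self = FALSE) {
  v <- panel$variants
  if (!marker %in% v$marker) return(character(0))
  b <- v$block[match(marker, v$marker)]
  C <- block_cor(panel, b)
  r2 <- C[, marker]^2
  sel <- if (inclusive) r2 >= r2_threshold else r2 > r2_threshold
  out <- names(r2)[sel]
  if (!include_self) out <- setdiff(out, marker)
  out
}

# Number of proxies (r2 > threshold) for every panel variant; cached.
proxy_counts <- function(panel, r2_threshold = 0.8) {
  key <- paste0("proxyn_", format(r2_threshold))
  if (!is.null(panel$cache[[key]])) return(panel$cache[[key]])
  v <- panel$variants
  out <- setNames(integer(nrow(v)), v$marker)
  for (b in unique(v$block)) {
    C <- block_cor(panel, b)
    cnt <- colSums(C^2 > r2_threshold) - 1L
    out[colnames(C)] <- cnt
  }
  panel$cache[[key]] <- out
  out
}
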