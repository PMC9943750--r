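# GREGOR-style enrichment of association signals in annotation tracks,
# against control variants matched on LD proxy count, MAF and distance to
# the nearest gene. The test statistic is exact: the observed count of
# overlapping index variants is referred to the Poisson-binomial
# distribution with per-index control overlap rates.

#' Does a signal (lead or LD proxy) overlap an annotation track?
#'
#' @param markers Lead marker(s); each must be in the panel.
#' @param panel [ld_panel].
#' @param track BED tibble (`chr`, `start` 0-based, `end` half-open).
#' @param proxy_r2 Strict r² threshold defining proxies.
#' @return Logical vector: lead or any proxy falls inside the track.
#' @export
signal_overlap <- function(markers, panel, track, proxy_r2 = 0.8) {
  merged <- bed_merge(track)
  vapply(markers, function(mk) {
    set <- c(mk, panel_proxies(panel, mk, proxy_r2, inclusive = FALSE))
    v <- panel$variants[match(set, panel$variants$marker), ]
    v <- v[!is.na(v$pos), ]
    if (!nrow(v)) return(FALSE)
    any(bed_overlaps_pos(v$chr, v$pos, merged))
  }, logical(1), USE.NAMES = FALSE)
}

# matching features for every panel variant: proxy-count bin, MAF decile,
# distance-to-nearest-gene quartile
variant_matching_features <- function(panel, gene_map, proxy_r2 = 0.8) {
  v <- panel$variants
  pc <- proxy_counts(panel, proxy_r2)
  maf <- panel_maf(panel)
  dist <- rep(NA_real_, nrow(v))
  for (ch in unique(v$chr)) {
    g <- gene_map[gene_map$chr == ch, ]
    sel <- which(v$chr == ch)
    if (!nrow(g)) { dist[sel] <- Inf; next }
    dist[sel] <- vapply(v$pos[sel], function(p) {
      p0 <- p - 1L
      inside <- any(p0 >= g$start & p0 < g$end)
      if (inside) 0 else min(pmax(g$start - p0, 0) + pmax(p0 - g$end + 1, 0))
    }, numeric(1))
  }
  proxy_bin <- cut(pc, c(-1, 0, 4, 9, 24, Inf),
                   labels = c("0", "1-4", "5-9", "10-24", "25+"))
  maf_bin <- cut(maf, breaks = unique(quantile(maf, seq(0, 1, 0.1))),
                 include.lowest = TRUE, labels = FALSE)
  dist_bin <- cut(dist, breaks = unique(quantile(dist, seq(0, 1, 0.25))),
                  include.lowest = TRUE, labels = FALSE)
  tibble::tibble(marker = v$marker,
                 proxy_count = as.integer(pc),
                 maf = unname(maf), dist = dist,
                 proxy_bin = as.integer(proxy_bin),
                 maf_bin = as.integer(maf_bin),
                 dist_bin = as.integer(dist_bin))
}

#' Matched control variants for an index variant
#'
#' Controls are drawn without replacement from panel variants in the same
#' (LD-proxy-count bin x MAF decile x distance-to-nearest-gene quartile)
#' cell as the index, excluding the index and its own proxies. When the cell
#' is too small, the bins are relaxed to neighbouring bins with a warning.
#'
#' @param lead Index marker.
#' @param panel [ld_panel].
#' @param gene_map Gene intervals (`chr`, `start`, `end`).
#' @param n_controls Controls to draw.
#' @param proxy_r2 Proxy threshold used for both matching and exclusion.
#' @param features Optional precomputed [variant_matching_features()] table
#'   (reused across leads for speed).
#' @param seed Integer seed.
#' @return Character vector of control markers.
#' @export
match_controls <- function(lead, panel, gene_map, n_controls = 500,
                           proxy_r2 = 0.8, features = NULL, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  features <- features %||%
    variant_matching_features(panel, gene_map, proxy_r2)
  idx <- match(lead, features$marker)
  if (is.na(idx)) stop("index variant absent from panel: ", lead)
  excl <- c(lead, panel_proxies(panel, lead, proxy_r2))
  pool <- features[!(features$marker %in% excl), ]
  radius <- 0
  repeat {
    cell <- pool[abs(pool$proxy_bin - features$proxy_bin[idx]) <= radius &
                   abs(pool$maf_bin - features$maf_bin[idx]) <= radius &
                   abs(pool$dist_bin - features$dist_bin[idx]) <= radius, ]
    if (nrow(cell) >= n_controls || radius >= 10) break
    radius <- radius + 1
  }
  if (radius > 0) {
    warning(sprintf(
      "matching cell for %s smaller than n_controls; bins relaxed by %d",
      lead, radius))
  }
  take <- min(n_controls, nrow(cell))
  cell$marker[sample.int(nrow(cell), take)]
}

#' Enrichment of index variants in an annotation track
#'
#' For each index variant, the fraction of its matched controls whose signal
#' (control or proxies) overlaps the track gives the expected overlap rate
#' `p_i`; `expected = sum(p_i)`, `observed` is the count of overlapping
#' index signals, `fold = observed/expected`, and the p-value is the exact
#' upper tail of the Poisson-binomial distribution with parameters `{p_i}`
#' at the observed count.
#'
#' @param leads Character vector of index markers (>= 1).
#' @param panel [ld_panel].
#' @param track BED tibble.
#' @param gene_map Gene intervals for distance matching.
#' @param n_controls Matched controls per index.
#' @param proxy_r2 Proxy threshold.
#' @param seed Integer seed for control sampling.
#' @param track_name Label recorded in the result.
#' @return One-row `enrichment_result` tibble: `track, n_leads, observed,
#'   expected, fold, p, n_controls`, with attribute `"by_lead"`.
#' @export
enrichment_test <- function(leads, panel, track, gene_map, n_controls = 500,
                            proxy_r2 = 0.8, seed = NULL,
                            track_name = "track") {
  stopifnot(length(leads) >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  features <- variant_matching_features(panel, gene_map, proxy_r2)
  merged <- bed_merge(track)
  # per-variant signal overlap (self or proxies), computed once for the pool
  v <- panel$variants
  self_hit <- bed_overlaps_pos(v$chr, v$pos, merged)
  names(self_hit) <- v$marker
  sig_hit <- self_hit
  for (b in unique(v$block)) {
    C <- block_cor(panel, b)
    adj <- C^2 > proxy_r2
    mk <- colnames(C)
    sig_hit[mk] <- as.vector(adj %*% self_hit[mk]) > 0
  }
  p_i <- numeric(length(leads))
  obs_i <- logical(length(leads))
  for (i in seq_along(leads)) {
    ctrl <- match_controls(leads[i], panel, gene_map, n_controls,
                           proxy_r2, features = features)
    p_i[i] <- mean(sig_hit[ctrl])
    obs_i[i] <- sig_hit[[leads[i]]]
  }
  observed <- sum(obs_i)
  expected <- sum(p_i)
  if (expected == 0 && observed > 0) {
    pval <- 1 / (n_controls + 1)
    fold <- Inf
  } else {
    pval <- poisson_binomial_tail(observed, p_i)
    fold <- if (expected > 0) observed / expected else NA_real_
  }
  out <- tibble::tibble(track = track_name, n_leads = length(leads),
                        observed = observed, expected = expected,
                        fold = fold, p = pval, n_controls = n_controls)
  attr(out, "by_lead") <- tibble::tibble(lead = leads, overlapped = obs_i,
                                         control_rate = p_i)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) tibble::as_tibble(x)
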