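#' Simulate covariates for a cohort
#'
#' Age, sex and a BMI-like column standing in for the nuisance covariates
#' (including population-structure proxies) that cohort analysts adjust for.
#'
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Tibble with columns `age`, `sex`, `bmi`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  tibble::tibble(
    age = rnorm(n, 55, 8),
    sex = rbinom(n, 1, 0.5),
    bmi = rnorm(n, 27, 4)
  )
}

#' Simulate a quantitative trait from a panel
#'
#' `trait = sum_j beta_j * dosage_j + covariate effects + Gaussian noise`.
#' Mirrors the generative model behind a log-transformed, covariate-adjusted
#' glycemic trait.
#'
#' @param panel An [ld_panel].
#' @param betas Named numeric vector of per-allele effects; names are panel
#'   markers. `NULL` for a null trait.
#' @param covariates Optional data frame of per-sample covariates.
#' @param covar_effects Named numeric vector of covariate effects (names match
#'   `covariates` columns).
#' @param noise_sd Residual standard deviation.
#' @param seed Integer seed.
#' @return Numeric vector of length `panel$n_samples`.
#' @export
simulate_phenotype <- function(panel, betas = NULL, covariates = NULL,
                               covar_effects = NULL, noise_sd = 1,
                               seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n <- panel$n_samples
  y <- rnorm(n, 0, noise_sd)
  if (!is.null(betas) && length(betas)) {
    miss <- setdiff(names(betas), colnames(panel$dosages))
    if (length(miss)) {
      stop("causal variant(s) not in panel: ", paste(miss, collapse = ", "))
    }
    y <- y + as.vector(panel$dosages[, names(betas), drop = FALSE] %*% betas)
  }
  if (!is.null(covariates) && !is.null(covar_effects) && length(covar_effects)) {
    X <- as.matrix(covariates[, names(covar_effects), drop = FALSE])
    y <- y + as.vector(X %*% covar_effects)
  }
  y
}

#' Two-step covariate adjustment with inverse-normal transform
#'
#' Step 1 residualises the trait on the covariates; the residuals are
#' rank-based inverse-normal transformed (Blom offset `(r - 3/8)/(n + 1/4)`,
#' ties share the average rank); step 2 residualises the transformed values on
#' the covariates again. The double residualisation removes any residual
#' trait-covariate correlation reintroduced by the non-linear transform and
#' controls type-I error at low-frequency variants.
#'
#' @param trait Numeric vector.
#' @param covariates Optional data frame; rows with missing covariate cells
#'   are dropped (their residuals are `NA`) with a message. Constant columns
#'   are dropped with a warning.
#' @return Numeric vector of final residuals, same length as `trait`
#'   (`NA` where rows were dropped).
#' @export
two_step_adjust <- function(trait, covariates = NULL) {
  n <- length(trait)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(inverse_normal(trait))
  }
  covariates <- as.data.frame(covariates)
  keep_col <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) > 1,
                     logical(1))
  if (any(!keep_col)) {
    warning("dropping constant covariate column(s): ",
            paste(names(covariates)[!keep_col], collapse = ", "))
    covariates <- covariates[, keep_col, drop = FALSE]
  }
  if (ncol(covariates) == 0) return(inverse_normal(trait))
  ok <- complete.cases(covariates) & !is.na(trait)
  if (any(!ok)) {
    message(sum(!ok), " row(s) dropped for missing trait/covariate values")
  }
  X <- cbind(1, as.matrix(covariates[ok, , drop = FALSE]))
  r1 <- stats::lm.fit(X, trait[ok])$residuals
  t1 <- inverse_normal(r1)
  r2 <- stats::lm.fit(X, t1)$residuals
  out <- rep(NA_real_, n)
  out[ok] <- r2
  out
}

# vectorised per-variant simple OLS of y on each dosage column
marginal_ols <- function(G, y) {
  ok <- !is.na(y)
  G <- G[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  yc <- y - mean(y)
  mu <- colMeans(G)
  sxx <- colSums(G^2) - n * mu^2
  sxy <- as.vector(crossprod(G, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  syy <- sum(yc^2)
  rss <- syy - beta^2 * sxx
  se <- ifelse(sxx > 0, sqrt(pmax(rss, 0) / ((n - 2) * sxx)), NA_real_)
  p <- z_to_p(beta / se)
  list(beta = unname(beta), se = unname(se), p = unname(p),
       eaf = unname(mu / 2), n = n)
}

#' Simulate one cohort's GWAS summary statistics
#'
#' Draws (or reuses) genotypes, builds the trait, applies the two-step
#' covariate adjustment, and regresses the adjusted residuals on each
#' variant's dosage. Simulated imputation-quality, HWE and call-rate columns
#' are attached as pure QC-filter fodder (independent of the genotypes).
#'
#' @param panel An [ld_panel]; the cohort's genotypes. Use
#'   [regenerate_panel()] for an independent cohort from the same population.
#' @param betas Named per-allele effects (see [simulate_phenotype()]).
#' @param noise_sd Residual standard deviation of the raw trait.
#' @param covariates `TRUE` (default) to auto-generate age/sex/BMI covariates
#'   with modest effects, `NULL`/`FALSE` for none, or a data frame.
#' @param covar_effects Named effects used when `covariates` is a data frame
#'   (and for the auto-generated ones).
#' @param adjust Apply the two-step adjustment (`TRUE`) or regress the raw
#'   trait (`FALSE`; useful for exact linear-model oracles).
#' @param seed Integer seed.
#' @param study Study label recorded in the `study` column.
#' @return Tibble with columns `marker, chr, pos, ea, nea, eaf, beta, se, p,
#'   n, info, hwe_p, callrate, study`; monomorphic variants carry `NA`
#'   effect estimates and `flag = "monomorphic"`.
#' @export
simulate_cohort_sumstats <- function(panel, betas = NULL, noise_sd = 1,
                                     covariates = TRUE, covar_effects = NULL,
                                     adjust = TRUE, seed = NULL,
                                     study = "study1") {
  if (!is.null(seed)) withr::local_seed(seed)
  n <- panel$n_samples
  covs <- NULL
  ce <- covar_effects
  if (isTRUE(covariates)) {
    covs <- simulate_covariates(n)
    ce <- ce %||% c(age = 0.003, sex = 0.05, bmi = 0.02)
  } else if (is.data.frame(covariates)) {
    covs <- covariates
  }
  y <- simulate_phenotype(panel, betas = betas, covariates = covs,
                          covar_effects = ce, noise_sd = noise_sd)
  if (adjust) y <- two_step_adjust(y, covs)
  fit <- marginal_ols(panel$dosages, y)
  v <- panel$variants
  m <- nrow(v)
  tibble::tibble(
    marker = v$marker, chr = v$chr, pos = v$pos,
    ea = v$alt, nea = v$ref,
    eaf = fit$eaf, beta = fit$beta, se = fit$se, p = fit$p,
    n = fit$n,
    info = runif(m, 0.85, 1),
    hwe_p = runif(m),
    callrate = runif(m, 0.95, 1),
    study = study,
    flag = ifelse(is.na(fit$beta), "monomorphic", NA_character_)
  )
}

#' Simulate cis-eQTL summary statistics for one gene
#'
#' Draws an independent expression cohort from the panel's population, plants
#' a causal variant (shared with, or distinct from, a trait's causal variant
#' at the caller's choice), inverse-normal transforms expression, and returns
#' cis-window marginal statistics in the same tabular dialect as the GWAS
#' tables.
#'
#' @param panel An [ld_panel] defining the population.
#' @param causal Marker of the causal cis-variant (`NULL` for no eQTL effect).
#' @param beta Effect size per allele on expression.
#' @param n Expression sample size (default 420, an islet-study scale).
#' @param noise_sd Residual standard deviation.
#' @param gene Gene label.
#' @param seed Integer seed.
#' @return Tibble like [simulate_cohort_sumstats()] plus a `gene` column.
#' @export
simulate_eqtl_sumstats <- function(panel, causal = NULL, beta = 0.5, n = 420,
                                   noise_sd = 1, gene = "GENE1", seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  cohort <- if (!is.null(panel$blocks)) {
    regenerate_panel(panel, n, source = paste0(panel$source, "-eqtl"))
  } else {
    panel
  }
  betas <- if (is.null(causal)) NULL else setNames(beta, causal)
  y <- simulate_phenotype(cohort, betas = betas, noise_sd = noise_sd)
  y <- inverse_normal(y)
  fit <- marginal_ols(cohort$dosages, y)
  v <- cohort$variants
  tibble::tibble(
    gene = gene,
    marker = v$marker, chr = v$chr, pos = v$pos,
    ea = v$alt, nea = v$ref,
    eaf = fit$eaf, beta = fit$beta, se = fit$se, p = fit$p, n = fit$n
  )
}

#' Simulate an annotation track with planted enrichment
#'
#' Scatters background intervals uniformly over the panel's span so that a
#' random variant falls in the track with probability ~`coverage`, then tops
#' up coverage at the `targets` so they overlap at rate
#' `min(1, fold * coverage)`. With `fold = 1` targets overlap at the
#' background rate.
#'
#' @param panel An [ld_panel] (defines the genomic span).
#' @param targets Markers whose overlap rate is boosted.
#' @param fold Target fold-enrichment (>= 1).
#' @param coverage Background fraction of the span covered.
#' @param width Interval width in bp.
#' @param seed Integer seed.
#' @return Tibble of BED-style intervals (`chr`, `start` 0-based, `end`
#'   half-open) with attribute `background_coverage` (realised merged
#'   background coverage fraction).
#' @export
simulate_annotations <- function(panel, targets = character(), fold = 1,
                                 coverage = 0.05, width = 500, seed = NULL) {
  stopifnot(fold >= 1, coverage > 0, coverage < 1)
  if (!is.null(seed)) withr::local_seed(seed)
  v <- panel$variants
  out <- list()
  bg_cov <- c()
  for (ch in unique(v$chr)) {
    pos <- v$pos[v$chr == ch]
    lo <- min(pos) - 10L * width
    hi <- max(pos) + 10L * width
    len <- hi - lo
    k <- max(1L, round(coverage * len / width))
    starts <- sort(sample.int(len - width, k) + lo - 1L)  # 0-based
    bed <- tibble::tibble(chr = ch, start = starts, end = starts + width)
    merged <- bed_merge(bed)
    bg_cov[ch] <- sum(merged$end - merged$start) / len
    out[[ch]] <- bed
  }
  bed <- dplyr::bind_rows(out)
  if (length(targets) && fold > 1) {
    c0 <- mean(bg_cov)
    p_extra <- (min(1, fold * coverage) - c0) / (1 - c0)
    p_extra <- min(max(p_extra, 0), 1)
    hit <- runif(length(targets)) < p_extra
    if (any(hit)) {
      tv <- v[match(targets[hit], v$marker), ]
      off <- sample.int(width, nrow(tv), replace = TRUE) - 1L
      extra <- tibble::tibble(chr = tv$chr,
                              start = tv$pos - 1L - off,
                              end = tv$pos - 1L - off + width)
      bed <- dplyr::bind_rows(bed, extra)
    }
  }
  bed <- dplyr::arrange(bed, .data$chr, .data$start)
  attr(bed, "background_coverage") <- mean(bg_cov)
  bed
}

#' Simulate a gene map
#'
#' Uniformly placed gene intervals over the panel span, used as the
#' distance-to-nearest-gene matching feature for enrichment controls.
#'
#' @param panel An [ld_panel].
#' @param n_genes Number of genes.
#' @param width Gene length in bp.
#' @param seed Integer seed.
#' @return Tibble `gene`, `chr`, `start` (0-based), `end`.
#' @export
simulate_gene_map <- function(panel, n_genes = 20, width = 20000,
                              seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  v <- panel$variants
  out <- list()
  for (ch in unique(v$chr)) {
    pos <- v$pos[v$chr == ch]
    lo <- min(pos) - 50000L
    hi <- max(pos) + 50000L
    starts <- sort(sample.int(max(hi - lo - width, 1L), n_genes) + lo - 1L)
    out[[ch]] <- tibble::tibble(
      gene = sprintf("gene_%s_%03d", ch, seq_len(n_genes)),
      chr = ch, start = starts, end = starts + width)
  }
  dplyr::bind_rows(out)
}
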