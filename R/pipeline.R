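# End-to-end orchestration over a synthetic scenario: simulate -> QC ->
# meta-analysis -> loci -> conditional signals (multi-panel consensus) ->
# credible sets -> colocalization & direction -> enrichment -> SMR/HEIDI.

pipeline_defaults <- function() {
  list(
    seed = 42,
    mode = "bmi_adjusted",            # or "bmi_unadjusted"; recorded in manifest
    n_cohorts = 16,
    cohort_size = 600,
    # causal effects sized for > 99.9% power at the total simulated N over
    # the whole planted-MAF range (worst case f = 0.15 gives z >= 6.3)
    blocks = ld_blocks(rep(60, 6), 0.15, 0.5, 0.9),
    causal = tibble::tibble(marker = c("var000010", "var000050", "var000150"),
                            beta = c(0.20, 0.13, 0.17)),
    companion = list(
      FG = list(causal = tibble::tibble(marker = "var000150", beta = 0.12),
                n = 20000),
      FI = list(causal = tibble::tibble(marker = "var000170", beta = 0.12),
                n = 20000)
    ),
    eqtl = list(gene = "GENE1", marker = "var000150", beta = 0.8, n = 420),
    panels = c(panel_a = 1000, panel_b = 900, panel_c = 800),
    noise_sd = 1,
    p_threshold = 5e-8,
    flank = 5e5,
    cojo_flank = 1e6,
    merge_r2 = 0.4,
    collinearity_r2 = 0.8,
    max_signals = 3,
    maf_tol = 0.05,
    proxy_r2 = 0.8,
    coverage = 0.99,
    coloc_priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
    decision = c(pp_min = 0.6, sens_min = 0.4, r2_min = 0.8),
    annotation = c(fold = 8, coverage = 0.05, width = 500),
    n_controls = 200,
    smr_n_tests = NULL
  )
}

#' Pipeline configuration
#'
#' Returns the default configuration, overridden by any named arguments.
#' Unknown keys are rejected; every threshold ends up in the run manifest.
#'
#' @param ... Named overrides of the defaults (see `pipeline_defaults`
#'   internals; e.g. `seed`, `n_cohorts`, `cohort_size`, `blocks`, `causal`,
#'   `p_threshold`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  if (!cfg$mode %in% c("bmi_adjusted", "bmi_unadjusted")) {
    stop("mode must be 'bmi_adjusted' or 'bmi_unadjusted'")
  }
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes every stage on a simulated scenario with known truth and returns
#' all intermediate and final tables. Reruns with the same configuration are
#' identical (every random draw is seeded from `config$seed`).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, tables are written as TSV,
#'   the lambda sidecar and manifest as JSON.
#' @return A list: `manifest`, `meta`, `loci`, `per_panel_signals`,
#'   `signals`, `maf_screen`, `credible_sets`, `coloc`, `directions`,
#'   `enrichment`, `smr`, plus the `panels` used.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # blocks are spaced > 2 * the conditional-analysis window so distinct
  # simulated loci never chain into one region
  base <- stage("simulate", simulate_ld_panel(
    200, config$blocks, seed = seed, block_gap = 2.2e6,
    source = "population"))
  panels <- stage("simulate", purrr::imap(
    as.list(config$panels),
    function(n, nm) {
      p <- regenerate_panel(base, n, seed = seed + match(nm, names(config$panels)),
                            source = nm)
      p
    }))
  ld_ref <- panels[[1]]

  causal_betas <- setNames(config$causal$beta, config$causal$marker)
  cohorts <- stage("ingest", purrr::map(seq_len(config$n_cohorts), function(i) {
    pan <- regenerate_panel(base, config$cohort_size, seed = seed + 100 + i,
                            source = sprintf("cohort%02d", i))
    simulate_cohort_sumstats(pan, betas = causal_betas,
                             noise_sd = config$noise_sd,
                             seed = seed + 200 + i,
                             study = sprintf("cohort%02d", i))
  }))
  names(cohorts) <- sprintf("cohort%02d", seq_len(config$n_cohorts))

  qc <- stage("qc", purrr::map(cohorts, qc_filter))
  kept <- purrr::map(qc, "kept")

  meta <- stage("meta", ivw_meta(kept) |> post_meta_filter())
  loci <- stage("loci", define_loci(meta, ld_ref,
                                    p_threshold = config$p_threshold,
                                    flank = config$flank,
                                    merge_r2 = config$merge_r2))

  per_panel <- list(); signals <- list(); maf_screen <- list()
  for (li in seq_len(nrow(loci))) {
    lead_pos <- meta$pos[match(loci$lead[li], meta$marker)]
    lo <- min(loci$start[li], lead_pos - config$cojo_flank)
    hi <- max(loci$end[li], lead_pos + config$cojo_flank)
    win <- meta[meta$chr == loci$chr[li] & meta$pos >= lo & meta$pos <= hi, ]
    pp <- stage("conditional", purrr::map(panels, function(p) {
      cojo_select(win, p, p_threshold = config$p_threshold,
                  collinearity_r2 = config$collinearity_r2,
                  max_signals = config$max_signals)
    }))
    cons <- stage("conditional", consensus_signals(
      pp, ld_ref, proxy_r2 = config$proxy_r2))
    if (nrow(cons)) {
      screen <- maf_consistency(cons, panels, tol = config$maf_tol)
      cons <- cons[screen$keep, , drop = FALSE]
      maf_screen[[li]] <- dplyr::mutate(screen, locus = loci$locus[li])
    }
    per_panel[[li]] <- pp
    signals[[li]] <- dplyr::mutate(cons, locus = loci$locus[li])
  }
  signals <- dplyr::bind_rows(signals)

  credible_sets <- stage("finemap", purrr::map(seq_len(nrow(signals)), function(si) {
    locus_sig <- signals$marker[signals$locus == signals$locus[si]]
    cs <- conditional_credible_set(
      meta, panels[[length(panels)]], lead = signals$marker[si],
      condition_on = setdiff(locus_sig, signals$marker[si]),
      coverage = config$coverage, flank = config$flank)
    extend_credible_set(cs, signals$marker[si], ld_ref,
                        r2_threshold = config$proxy_r2, flank = config$flank)
  }))
  names(credible_sets) <- signals$marker

  companion_sumstats <- stage("coloc", purrr::imap(config$companion, function(cc, nm) {
    pan <- regenerate_panel(base, cc$n,
                            seed = seed + 500 + match(nm, names(config$companion)),
                            source = nm)
    simulate_cohort_sumstats(pan, betas = setNames(cc$causal$beta, cc$causal$marker),
                             noise_sd = config$noise_sd, covariates = FALSE,
                             seed = seed + 600 + match(nm, names(config$companion)),
                             study = nm)
  }))

  pri <- config$coloc_priors
  dec <- config$decision
  coloc_tbl <- list(); directions <- list()
  for (li in seq_len(nrow(loci))) {
    win <- meta[meta$chr == loci$chr[li] & meta$pos >= loci$start[li] &
                  meta$pos <= loci$end[li], ]
    for (nm in names(companion_sumstats)) {
      tb <- companion_sumstats[[nm]]
      tb_win <- tb[tb$marker %in% win$marker, ]
      res <- suppressWarnings(coloc_pair(win, tb_win, p1 = pri[["p1"]],
                                         p2 = pri[["p2"]], p12 = pri[["p12"]]))
      sens <- suppressWarnings(
        sensitivity_score(list(win, tb_win), engine = "pair"))
      other_lead <- tb_win$marker[order(tb_win$p, tb_win$marker)][1]
      r2 <- panel_r2(ld_ref, loci$lead[li], other_lead)
      coloc_tbl[[length(coloc_tbl) + 1]] <- tibble::tibble(
        locus = loci$locus[li], trait = nm, pp4 = res$pp4, pp3 = res$pp3,
        candidate = res$candidate, sensitivity = as.numeric(sens),
        lead_pair_r2 = r2,
        colocalized = coloc_decision(res$pp4, as.numeric(sens), r2,
                                     dec[["pp_min"]], dec[["sens_min"]],
                                     dec[["r2_min"]]))
    }
    lookups <- purrr::imap_dfr(companion_sumstats, function(tb, nm) {
      i <- match(loci$lead[li], tb$marker)
      tibble::tibble(trait = nm, beta = tb$beta[i], p = tb$p[i])
    })
    directions[[li]] <- dplyr::mutate(classify_direction(lookups),
                                      locus = loci$locus[li],
                                      lead = loci$lead[li])
  }
  coloc_tbl <- dplyr::bind_rows(coloc_tbl)
  directions <- dplyr::bind_rows(directions)

  ann <- config$annotation
  track <- stage("enrich", simulate_annotations(
    base, targets = config$causal$marker, fold = ann[["fold"]],
    coverage = ann[["coverage"]], width = ann[["width"]],
    seed = seed + 900))
  gene_map <- simulate_gene_map(base, seed = seed + 901)
  enr <- stage("enrich", {
    if (nrow(loci)) {
      enrichment_test(loci$lead, ld_ref, track, gene_map,
                      n_controls = config$n_controls,
                      proxy_r2 = config$proxy_r2, seed = seed + 902,
                      track_name = "islet_like")
    } else NULL
  })

  eq <- config$eqtl
  eqtl_tbl <- stage("smr", simulate_eqtl_sumstats(
    base, causal = eq$marker, beta = eq$beta, n = eq$n, gene = eq$gene,
    seed = seed + 950))
  gene_chr <- base$variants$chr[match(eq$marker, base$variants$marker)]
  gene_pos <- base$variants$pos[match(eq$marker, base$variants$marker)]
  gwas_win <- meta[meta$chr == gene_chr & abs(meta$pos - gene_pos) <= 5e5, ]
  smr <- stage("smr", tryCatch(
    smr_heidi(gwas_win, eqtl_tbl[eqtl_tbl$marker %in% gwas_win$marker, ],
              panels[[length(panels)]], gene = eq$gene,
              n_tests = config$smr_n_tests),
    error = function(e) tibble::tibble(gene = eq$gene, error = conditionMessage(e))))

  manifest <- list(
    seed = seed,
    mode = config$mode,
    config_hash = rlang::hash(unclass(config)),
    thresholds = config[c("p_threshold", "flank", "cojo_flank", "merge_r2",
                          "collinearity_r2", "max_signals", "maf_tol",
                          "proxy_r2", "coverage", "n_controls")],
    coloc_priors = as.list(config$coloc_priors),
    decision = as.list(config$decision),
    rows = list(meta = nrow(meta), loci = nrow(loci),
                signals = nrow(signals), coloc = nrow(coloc_tbl))
  )

  out <- list(manifest = manifest, config = config, meta = meta, loci = loci,
              per_panel_signals = per_panel, signals = signals,
              maf_screen = dplyr::bind_rows(maf_screen),
              credible_sets = credible_sets, coloc = coloc_tbl,
              directions = directions, enrichment = enr, smr = smr,
              panels = panels, track = track)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta_plain <- tibble::as_tibble(run$meta)
  write_sumstats(meta_plain, file.path(out_dir, "meta.tsv.gz"))
  jsonlite::write_json(
    list(lambda_study = as.list(attr(run$meta, "lambda_study")),
         lambda_meta = attr(run$meta, "lambda")),
    file.path(out_dir, "lambda.json"), auto_unbox = TRUE, digits = NA)
  loci_flat <- run$loci |>
    dplyr::mutate(merged_from = purrr::map_chr(.data$merged_from, paste,
                                               collapse = ","),
                  members = lengths(.data$members))
  readr::write_tsv(loci_flat, file.path(out_dir, "loci.tsv"), progress = FALSE)
  if (nrow(run$signals)) {
    sig_flat <- run$signals |>
      dplyr::mutate(panel_support = purrr::map_chr(.data$panel_support, paste,
                                                   collapse = ","))
    readr::write_tsv(sig_flat, file.path(out_dir, "signals.tsv"),
                     progress = FALSE)
  }
  if (length(run$credible_sets)) {
    cs <- purrr::imap_dfr(run$credible_sets, function(x, nm) {
      dplyr::mutate(tibble::as_tibble(x), signal = nm)
    })
    keep <- intersect(c("signal", "marker", "chr", "pos", "posterior",
                        "cumulative", "in_set", "extension_only",
                        "in_extended", "r2_with_lead"), names(cs))
    readr::write_tsv(cs[, keep], file.path(out_dir, "credible_sets.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(run$coloc, file.path(out_dir, "coloc.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$directions, file.path(out_dir, "directions.tsv"),
                   progress = FALSE)
  if (!is.null(run$enrichment)) {
    readr::write_tsv(tibble::as_tibble(run$enrichment),
                     file.path(out_dir, "enrichment.tsv"), progress = FALSE)
  }
  readr::write_tsv(tibble::as_tibble(run$smr), file.path(out_dir, "smr.tsv"),
                   progress = FALSE)
  write_bed(run$track, file.path(out_dir, "annotations.bed"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
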