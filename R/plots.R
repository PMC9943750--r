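#' Regional association plot
#'
#' -log10(p) against position for a window of meta-analysis results, points
#' coloured by r² with the lead variant (when a panel is supplied), with
#' optional stacked panels for companion traits or eQTL statistics and an
#' annotation rug.
#'
#' @param meta Summary tibble (`marker, pos, p`); typically one locus window.
#' @param lead Lead marker (rendered as a diamond). Default: smallest p.
#' @param panel Optional [ld_panel] for LD colouring.
#' @param extra_traits Optional named list of additional summary tibbles
#'   (same columns) stacked as facets under the main trait.
#' @param track Optional BED tibble drawn as a rug of intervals.
#' @param trait_name Label for the primary trait facet.
#' @return A ggplot object.
#' @export
plot_locus <- function(meta, lead = NULL, panel = NULL, extra_traits = NULL,
                       track = NULL, trait_name = "trait") {
  stopifnot(nrow(meta) >= 1)
  lead <- lead %||% meta$marker[which.min(meta$p)]
  all_traits <- c(setNames(list(meta), trait_name),
                  extra_traits %||% list())
  dat <- dplyr::bind_rows(all_traits, .id = "panel_label")
  dat$panel_label <- factor(dat$panel_label,
                            levels = unique(c(trait_name, names(extra_traits))))
  if (!is.null(panel) && lead %in% panel$variants$marker) {
    dat$r2_lead <- panel_r2(panel, dat$marker, lead)
  } else {
    dat$r2_lead <- NA_real_
  }
  dat$is_lead <- dat$marker == lead
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos / 1e6,
                                         y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$r2_lead), size = 1.4,
                        na.rm = TRUE) +
    ggplot2::geom_point(data = dat[dat$is_lead, ], shape = 18, size = 3,
                        colour = "purple", na.rm = TRUE) +
    ggplot2::scale_colour_gradientn(
      colours = c("navy", "skyblue", "green3", "orange", "red"),
      limits = c(0, 1), name = expression(r^2), na.value = "grey60") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel_label),
                        scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_bw()
  if (!is.null(track) && nrow(track)) {
    p <- p + ggplot2::geom_rect(
      data = dplyr::mutate(track, panel_label = trait_name),
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -1, ymax = -0.2, inherit.aes = FALSE, fill = "darkgreen",
      alpha = 0.6)
  }
  p
}

#' Direction-of-effect plot
#'
#' Companion-trait effect against the primary-trait effect for each lead
#' variant (both harmonised to the primary effect allele): points left of
#' zero on x with positive y are glucose-raising/proinsulin-lowering
#' alleles, and so on.
#'
#' @param df Tibble with `lead`, `beta_primary`, `beta_other` and optionally
#'   `trait`.
#' @return A ggplot object.
#' @export
plot_direction <- function(df) {
  assert_cols(df, c("lead", "beta_primary", "beta_other"), "df")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_other,
                                   y = .data$beta_primary)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$lead), vjust = -0.8,
                       size = 2.6) +
    ggplot2::labs(x = "companion-trait effect", y = "primary-trait effect") +
    ggplot2::theme_bw()
}

#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$track, y = .data$fold)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p = %.2g", .data$p)),
                       vjust = -0.5, size = 3) +
    ggplot2::labs(x = NULL, y = "fold enrichment") +
    ggplot2::theme_bw()
}

#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy.coloc_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_bw()
}

#' @method autoplot credible_set
#' @export
autoplot.credible_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$posterior), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$posterior,
                                   colour = .data$in_set)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos / 1e6, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 name = "in 99% set") +
    ggplot2::labs(x = "position (Mb)", y = "posterior") +
    ggplot2::theme_bw()
}
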