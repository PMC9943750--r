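# Tabular and interval I/O. Summary statistics travel as (optionally
# gzipped) tab-delimited files with METAL-compatible headers; annotations as
# 3-column BED (0-based, half-open).

sumstat_header_map <- c(
  marker = "MARKER", chr = "CHR", pos = "POS", ea = "EA", nea = "NEA",
  eaf = "EAF", beta = "BETA", se = "SE", p = "P", n = "N",
  info = "INFO", hwe_p = "HWE_P", callrate = "CALLRATE"
)

#' Read and write summary-statistic tables
#'
#' Tab-delimited with header `MARKER CHR POS EA NEA EAF BETA SE P N INFO
#' HWE_P CALLRATE` (gzipped when the path ends in `.gz`). Columns beyond the
#' standard set round-trip unchanged.
#'
#' @param x Summary-statistic tibble (lower-case column names).
#' @param path File path; `.gz` suffix triggers compression.
#' @return `read_sumstats()` returns a tibble with lower-case names;
#'   `write_sumstats()` returns `x` invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- x
  idx <- match(names(sumstat_header_map), names(out))
  names(out)[idx[!is.na(idx)]] <- sumstat_header_map[!is.na(idx)]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  rev_map <- setNames(names(sumstat_header_map), sumstat_header_map)
  idx <- match(names(rev_map), names(x))
  names(x)[idx[!is.na(idx)]] <- rev_map[!is.na(idx)]
  x
}

#' Read and write BED interval tracks
#'
#' Three-column BED: chromosome, 0-based start, half-open end. No header.
#'
#' @param x Tibble with `chr`, `start`, `end`.
#' @param path File path.
#' @export
write_bed <- function(x, path) {
  readr::write_tsv(x[, c("chr", "start", "end")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(x)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chr", "start", "end"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Write a panel as VCFv4.2 with GT fields
#'
#' Phase is not tracked; dosages 0/1/2 are written as `0/0`, `0/1`, `1/1`.
#'
#' @param panel An [ld_panel].
#' @param path Output path (plain text).
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=sumgwas_%s", panel$source),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- sprintf("S%04d", seq_len(panel$n_samples))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gt <- matrix(gt_codes[t(panel$dosages) + 1L], nrow = nrow(v))
  body <- paste(v$chr, v$pos, v$marker, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(panel)
}

# sort + merge intervals per chromosome (0-based half-open)
bed_merge <- function(bed) {
  bed |>
    dplyr::arrange(.data$chr, .data$start, .data$end) |>
    dplyr::group_by(.data$chr) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) <= 1) return(df[, c("start", "end")])
      start <- df$start; end <- df$end
      out_s <- start[1]; out_e <- end[1]
      ks <- c(); ke <- c()
      for (i in 2:nrow(df)) {
        if (start[i] <= out_e) {
          out_e <- max(out_e, end[i])
        } else {
          ks <- c(ks, out_s); ke <- c(ke, out_e)
          out_s <- start[i]; out_e <- end[i]
        }
      }
      tibble::tibble(start = c(ks, out_s), end = c(ke, out_e))
    }) |>
    dplyr::ungroup()
}

# TRUE for each (chr, pos) (1-based) inside any merged interval
bed_overlaps_pos <- function(chr, pos, merged_bed) {
  out <- logical(length(pos))
  for (ch in unique(chr)) {
    iv <- merged_bed[merged_bed$chr == ch, ]
    sel <- which(chr == ch)
    if (!nrow(iv)) next
    idx <- findInterval(pos[sel] - 1L, iv$start)
    hit <- idx >= 1 & (pos[sel] - 1L) < iv$end[pmax(idx, 1L)]
    out[sel] <- hit
  }
  out
}
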