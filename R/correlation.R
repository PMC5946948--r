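#' Spearman correlation between two tracks
#'
#' Nonparametric Spearman correlation on the ranks of paired quantities
#' (average ranks for ties; two-sided asymptotic p-value). Pairs with a
#' missing value in either input — e.g. all-N GC windows — are removed
#' first.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `rho`, `p_value`, `n_pairs`. When either input
#'   is constant, `rho` and `p_value` are `NA` (flagged, not an error).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n_pairs = length(x)))
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n_pairs = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value,
         n_pairs = length(x))
}

#' Regional scan of the GC / gene-density correlation
#'
#' Slides a region along each chromosome and computes the Spearman
#' correlation between per-window gene counts and GC inside it. A region
#' collects `windows_per_region` consecutive windows of the shared 1-Mb /
#' 100-kb track (31 windows whose starts span 3 Mb, hence a 4-Mb sequence
#' footprint, at defaults); regions advance by `region_step`. Regions with
#' `rho > high_rho` and `p < high_p` are flagged high; `rho < low_rho`
#' flags low.
#'
#' @param track Window-track tibble with `gene_count` and `gc`, computed at
#'   1 Mb / 100 kb.
#' @param windows_per_region Consecutive track windows per region.
#' @param region_step Advance between region starts (bp; must be a
#'   multiple of the track step).
#' @param high_rho,high_p,low_rho Flagging thresholds.
#' @return Tibble: `chrom`, `region_start`, `region_end`, `rho`, `p_value`,
#'   `n_pairs`, `high_flag`, `low_flag`. Zero rows when no chromosome holds
#'   one full region.
#' @export
regional_scan <- function(track, windows_per_region = 31, region_step = 1e5,
                          high_rho = 0.95, high_p = 0.01, low_rho = 0.7) {
  if (!"gc" %in% names(track)) abort("track has no gc column")
  out <- list()
  for (chr in unique(track$seq_id)) {
    t <- track[track$seq_id == chr, ]
    step <- if (nrow(t) > 1) t$start[2] - t$start[1] else NA_real_
    by <- if (is.na(step)) 1L else max(1L, as.integer(round(region_step / step)))
    n <- nrow(t)
    if (n < windows_per_region) next
    starts <- seq(1L, n - windows_per_region + 1L, by = by)
    rows <- purrr::map(starts, function(s) {
      idx <- s:(s + windows_per_region - 1L)
      r <- spearman_cor(t$gene_count[idx], t$gc[idx])
      tibble(chrom = chr, region_start = t$start[idx[1]],
             region_end = t$end[idx[windows_per_region]],
             rho = r$rho, p_value = r$p_value, n_pairs = r$n_pairs)
    })
    out[[chr]] <- dplyr::bind_rows(rows)
  }
  if (!length(out)) {
    return(tibble(chrom = character(0), region_start = integer(0),
                  region_end = integer(0), rho = numeric(0),
                  p_value = numeric(0), n_pairs = integer(0),
                  high_flag = logical(0), low_flag = logical(0)))
  }
  dplyr::bind_rows(out) |>
    mutate(high_flag = !is.na(.data$rho) & .data$rho > high_rho &
             !is.na(.data$p_value) & .data$p_value < high_p,
           low_flag = !is.na(.data$rho) & .data$rho < low_rho)
}

#' Summarise flagged regions of a correlation scan
#'
#' @param scan Output of [regional_scan()].
#' @return One-row tibble: `n_regions`, `n_high`, `n_low`, `frac_high`,
#'   `frac_low`.
#' @export
flag_summary <- function(scan) {
  if (!nrow(scan)) abort("empty scan: no regions to summarise")
  tibble(n_regions = nrow(scan),
         n_high = sum(scan$high_flag),
         n_low = sum(scan$low_flag),
         frac_high = mean(scan$high_flag),
         frac_low = mean(scan$low_flag))
}

#' Export a regional correlation scan
#'
#' TSV of all regions, or BED of the high-correlation regions only (the
#' "green stick" layer of a circos view).
#'
#' @param scan Output of [regional_scan()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"` (high regions only).
#' @export
write_scan <- function(scan, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(scan, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    d <- scan[scan$high_flag, ]
    writeLines(sprintf("%s\t%d\t%d\thigh_cor\t%d", d$chrom,
                       d$region_start - 1L, d$region_end,
                       as.integer(round(1000 * pmax(d$rho, 0)))), path)
  }
  invisible(path)
}

#' Plot a window track with flagged regions
#'
#' Gene-count (and GC) profiles per chromosome, with high-correlation
#' regions overlaid when a scan is supplied.
#'
#' @param track Window-track tibble.
#' @param scan Optional [regional_scan()] output.
#' @return A ggplot object.
#' @export
plot_window_track <- function(track, scan = NULL) {
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(x = .data$start / 1e6,
                                    y = .data$gene_count)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::facet_wrap(~seq_id, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "genes per window")
  if (!is.null(scan) && nrow(scan)) {
    d <- scan[scan$high_flag, ]
    if (nrow(d)) {
      p <- p + ggplot2::geom_rect(
        data = dplyr::rename(d, seq_id = "chrom"),
        ggplot2::aes(xmin = .data$region_start / 1e6,
                     xmax = .data$region_end / 1e6,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "darkgreen", alpha = 0.2)
    }
  }
  p
}
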