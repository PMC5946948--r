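#' Sliding-window grid over a sequence
#'
#' Windows are `[start, start + window_size - 1]` with starts at
#' `1 + k * step`; only windows fully contained in the sequence are
#' emitted (trailing partial windows are dropped so that per-window gene
#' cutoffs stay comparable).
#'
#' @param seq_len Sequence length (bp).
#' @param window_size Window size (bp).
#' @param step Step between window starts (bp); `window_size >= step >= 1`.
#' @return Tibble with `start` and `end`; zero rows when
#'   `seq_len < window_size`.
#' @export
#' @examples
#' make_windows(1.5e6, 1e6, 1e5)
make_windows <- function(seq_len, window_size, step = window_size) {
  if (step < 1 || window_size < step) {
    abort("window_size >= step >= 1 is required")
  }
  if (seq_len < window_size) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  n <- floor((seq_len - window_size) / step) + 1
  starts <- 1 + (seq_len(n) - 1) * step
  tibble(start = as.integer(starts), end = as.integer(starts + window_size - 1))
}

#' Per-window gene counts
#'
#' Counts genes by start coordinate (point semantics): a gene contributes
#' to every window containing its start. Alternatives by midpoint or any
#' overlap are available through `assign`.
#'
#' @param genes Gene tibble (needs `seq_id`, `start`, `end`).
#' @param seq_id Sequence to count on.
#' @param seq_len Its length (bp).
#' @param window_size,step Window specification (bp).
#' @param assign `"start"` (default), `"midpoint"` or `"overlap"`.
#' @return A window-track tibble: `seq_id`, `start`, `end`, `gene_count`.
#' @export
count_genes_in_windows <- function(genes, seq_id, seq_len, window_size,
                                   step = 1e5, assign = c("start", "midpoint",
                                                          "overlap")) {
  assign <- match.arg(assign)
  g <- genes[genes$seq_id == seq_id, , drop = FALSE]
  if (any(g$start > seq_len)) {
    abort(paste0("gene start beyond the end of ", seq_id))
  }
  w <- make_windows(seq_len, window_size, step)
  if (!nrow(w)) {
    return(tibble(seq_id = character(0), start = integer(0),
                  end = integer(0), gene_count = integer(0)))
  }
  if (assign == "overlap") {
    cnt <- vapply(seq_len(nrow(w)), function(k) {
      sum(g$start <= w$end[k] & g$end >= w$start[k])
    }, integer(1))
  } else {
    pos <- if (assign == "start") g$start else floor((g$start + g$end) / 2)
    cnt <- count_points_in_windows(pos, w$start, w$end)
  }
  tibble(seq_id = seq_id, start = w$start, end = w$end,
         gene_count = as.integer(cnt))
}

# Count points within each [start, end] window via a sorted scan.
count_points_in_windows <- function(pos, starts, ends) {
  xs <- sort(pos)
  findInterval(ends, xs) - findInterval(starts - 1L, xs)
}

#' Per-window GC fraction
#'
#' GC is `(G + C) / (A + C + G + T)` per window; `N` bases are excluded
#' from the denominator so assembly gaps do not dilute GC. Windows made
#' entirely of `N` get `NA` and are dropped from downstream correlations.
#'
#' @param seq A `DNAString`, `DNAStringSet` element, or character sequence.
#' @param seq_id Identifier for the output.
#' @inheritParams count_genes_in_windows
#' @return Tibble `seq_id`, `start`, `end`, `gc`.
#' @export
gc_track <- function(seq, seq_id = "seq", window_size = 1e6, step = 1e5) {
  if (!methods::is(seq, "DNAString")) {
    seq <- tryCatch(Biostrings::DNAString(as.character(seq)),
                    error = function(e) {
                      abort("sequence contains characters outside the A/C/G/T/N alphabet")
                    })
  }
  fr <- Biostrings::alphabetFrequency(seq)
  if (sum(fr[c("A", "C", "G", "T", "N")]) != length(seq)) {
    abort("sequence contains characters outside the A/C/G/T/N alphabet")
  }
  w <- make_windows(length(seq), window_size, step)
  if (!nrow(w)) {
    return(tibble(seq_id = character(0), start = integer(0),
                  end = integer(0), gc = numeric(0)))
  }
  v <- Biostrings::Views(seq, start = w$start, end = w$end)
  lf <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
  denom <- rowSums(lf)
  gc <- ifelse(denom == 0, NA_real_, (lf[, "G"] + lf[, "C"]) / denom)
  tibble(seq_id = seq_id, start = w$start, end = w$end, gc = gc)
}

#' Combined gene-density / GC window track
#'
#' Computes the per-chromosome sliding-window gene-count track (and the GC
#' track when sequences are supplied) for every chromosome at once — the
#' substrate for ridge detection and correlation scans. Defaults follow the
#' 1-Mb window / 100-kb step convention.
#'
#' @param genes Gene tibble in chromosome coordinates.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param sequences Optional named `DNAStringSet` of chromosome sequences.
#' @inheritParams count_genes_in_windows
#' @return Tibble `seq_id`, `start`, `end`, `gene_count` (and `gc`).
#' @export
window_track <- function(genes, chrom_lengths, sequences = NULL,
                         window_size = 1e6, step = 1e5,
                         assign = "start") {
  tracks <- purrr::imap(as.list(chrom_lengths), function(L, chr) {
    t <- count_genes_in_windows(genes, chr, L, window_size, step, assign)
    if (!is.null(sequences) && chr %in% names(sequences)) {
      g <- gc_track(sequences[[chr]], chr, window_size, step)
      t$gc <- g$gc
    }
    t
  })
  dplyr::bind_rows(tracks)
}

#' Export a window track
#'
#' Writes the track as a tabular TSV (`seq_id`, `start`, `end`,
#' `gene_count`, `gc`) or as bedGraph (one file per measure; BED-style
#' 0-based half-open intervals).
#'
#' @param track A window-track tibble.
#' @param path Output path (TSV) or path prefix (bedGraph; files get
#'   `.gene_count.bedgraph` / `.gc.bedgraph` suffixes).
#' @param format `"tsv"` or `"bedgraph"`.
#' @return The written path(s), invisibly.
#' @export
write_track <- function(track, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(track, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  measures <- intersect(c("gene_count", "gc"), names(track))
  out <- character(0)
  for (m in measures) {
    f <- paste0(path, ".", m, ".bedgraph")
    d <- track[!is.na(track[[m]]), ]
    writeLines(c(paste0("track type=bedGraph name=", m),
                 sprintf("%s\t%d\t%d\t%g", d$seq_id, d$start - 1L, d$end,
                         d[[m]])), f)
    out <- c(out, f)
  }
  invisible(out)
}
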