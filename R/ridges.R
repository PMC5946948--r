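#' Detect gene-density ridges in a window track
#'
#' A ridge is a chromosome region of elevated gene density: at least `c_w`
#' consecutive sliding windows, each containing a gene number higher than
#' `c_h`. Detection reports maximal qualifying runs, one ridge per run.
#' Qualification defaults to the strict reading (`count > c_h`);
#' `strict = FALSE` switches to `count >= c_h` (the "lower limit" reading).
#' The choice is recorded in the output attributes.
#'
#' @param track Window-track tibble (`seq_id`, `start`, `end`,
#'   `gene_count`), possibly spanning several chromosomes.
#' @param c_h Gene-number cutoff per window (H).
#' @param c_w Minimum number of consecutive qualifying windows (W).
#' @param strict Use strict inequality `> c_h` (default) or `>= c_h`.
#' @return Tibble of ridges: `seq_id`, `first_window_start`,
#'   `last_window_end`, `n_windows`, `min_count`; attributes `c_h`, `c_w`,
#'   `strict`.
#' @export
detect_ridges <- function(track, c_h = 40, c_w = 5, strict = TRUE) {
  if (c_h < 0 || c_w < 1) abort("c_h >= 0 and c_w >= 1 are required")
  out <- list()
  for (chr in unique(track$seq_id)) {
    t <- track[track$seq_id == chr, ]
    cnt <- t$gene_count
    q <- if (strict) cnt > c_h else cnt >= c_h
    if (!length(q)) next
    r <- rle(q)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- r$values & r$lengths >= c_w
    if (!any(keep)) next
    out[[chr]] <- tibble(
      seq_id = chr,
      first_window_start = t$start[starts_i[keep]],
      last_window_end = t$end[ends_i[keep]],
      n_windows = r$lengths[keep],
      min_count = vapply(which(keep), function(i) {
        min(cnt[starts_i[i]:ends_i[i]])
      }, numeric(1))
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else {
    tibble(seq_id = character(0), first_window_start = integer(0),
           last_window_end = integer(0), n_windows = integer(0),
           min_count = numeric(0))
  }
  attr(res, "c_h") <- c_h; attr(res, "c_w") <- c_w; attr(res, "strict") <- strict
  res
}

# Ridge count of a bare count vector; the permutation-loop workhorse.
ridge_count_from_counts <- function(cnt, c_h, c_w, strict = TRUE) {
  q <- if (strict) cnt > c_h else cnt >= c_h
  if (!length(q)) return(0L)
  r <- rle(q)
  sum(r$values & r$lengths >= c_w)
}

#' Genome-wide ridge count
#'
#' The genome count N is the sum of per-chromosome ridge counts.
#'
#' @param tracks A window-track tibble covering disjoint chromosomes, or a
#'   list of such tibbles.
#' @inheritParams detect_ridges
#' @return Integer ridge count.
#' @export
count_ridges_genome <- function(tracks, c_h = 40, c_w = 5, strict = TRUE) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  ids <- unlist(purrr::map(tracks, \(t) unique(t$seq_id)))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate chromosome(s) across tracks: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sum(purrr::map_int(tracks, \(t) nrow(detect_ridges(t, c_h, c_w, strict))))
}

#' Write ridges as BED
#'
#' One row per ridge, 0-based half-open, score = the minimum window gene
#' count inside the ridge.
#'
#' @param ridges Output of [detect_ridges()].
#' @param path Output path.
#' @export
write_ridges_bed <- function(ridges, path) {
  writeLines(sprintf("%s\t%d\t%d\tridge%d\t%d", ridges$seq_id,
                     ridges$first_window_start - 1L, ridges$last_window_end,
                     seq_len(nrow(ridges)), as.integer(ridges$min_count)),
             path)
  invisible(path)
}

# Deterministic substream for one (permutation, chromosome) cell, so that
# results do not depend on chromosome iteration order and parallel or
# partial evaluation reproduces the same draws.
perm_stream_seed <- function(seed, perm, chrom_rank) {
  (as.double(seed) * 48271 + perm * 104729 + chrom_rank * 7919) %%
    2147483647
}

#' Permutation test of the genome-wide ridge count
#'
#' Tests whether the observed number of gene-density ridges N could arise
#' from genes placed at random. The null model permutes, independently for
#' each chromosome, its observed number of genes `i` uniformly over
#' positions 1..S (S the chromosome length), recomputes the window track
#' and the genome ridge count `n`, and repeats `n_perm` times. With
#' `f = #\{permutations with n >= N\}`, the p-value is `f / n_perm` when
#' `f > 0`; when `f = 0` it is censored and reported as `< 1/n_perm`
#' (never 0).
#'
#' @param genes Gene tibble in chromosome coordinates, or `NULL` if
#'   `chrom_table` is supplied directly.
#' @param chrom_lengths Named vector of chromosome lengths S (bp).
#' @param chrom_table Alternative input: tibble with `seq_id`, `n_genes`
#'   (and optionally a precomputed `observed_n` passed below).
#' @param observed_n Observed genome ridge count; computed from `genes`
#'   when omitted.
#' @param window_size,step Window specification (bp).
#' @inheritParams detect_ridges
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Seed; each (permutation, chromosome) pair draws from its own
#'   substream.
#' @param replace Sample null positions with replacement (default; at bp
#'   resolution collisions are negligible) or without.
#' @return A `cafs_ridge_test` object; see [tidy()], [glance()],
#'   [autoplot()].
#' @export
ridge_permutation_test <- function(genes = NULL, chrom_lengths,
                                   chrom_table = NULL, observed_n = NULL,
                                   window_size = 1e6, step = 1e5,
                                   c_h = 40, c_w = 5, strict = TRUE,
                                   n_perm = 10000, seed = 1L,
                                   replace = TRUE) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (is.null(chrom_table)) {
    if (is.null(genes)) abort("supply either genes or chrom_table")
    chrom_table <- tibble(seq_id = names(chrom_lengths)) |>
      mutate(n_genes = purrr::map_int(.data$seq_id,
                                      \(chr) sum(genes$seq_id == chr)))
  }
  chrom_table$length <- unname(chrom_lengths[chrom_table$seq_id])
  if (anyNA(chrom_table$length)) abort("missing chromosome length(s)")
  if (is.null(observed_n)) {
    if (is.null(genes)) abort("observed_n must be given when genes are not")
    tr <- window_track(genes, chrom_lengths, window_size = window_size,
                       step = step)
    observed_n <- count_ridges_genome(tr, c_h, c_w, strict)
  }
  # per-chromosome window grids, precomputed once
  grids <- purrr::map(chrom_table$length,
                      \(L) make_windows(L, window_size, step))
  ranks <- rank(chrom_table$seq_id, ties.method = "first")
  null_n <- integer(n_perm)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  for (j in seq_len(n_perm)) {
    tot <- 0L
    for (k in seq_len(nrow(chrom_table))) {
      w <- grids[[k]]
      if (!nrow(w)) next
      i <- chrom_table$n_genes[k]
      S <- chrom_table$length[k]
      set.seed(perm_stream_seed(seed, j, ranks[k]))
      pos <- if (replace) ceiling(runif(i) * S) else sample.int(S, i)
      cnt <- count_points_in_windows(pos, w$start, w$end)
      tot <- tot + ridge_count_from_counts(cnt, c_h, c_w, strict)
    }
    null_n[j] <- tot
  }
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  f <- sum(null_n >= observed_n)
  censored <- f == 0L
  structure(list(
    observed_n = as.integer(observed_n),
    n_perm = as.integer(n_perm),
    f = as.integer(f),
    p_value = if (censored) 1 / n_perm else f / n_perm,
    censored = censored,
    p_label = if (censored) paste0("<", format(1 / n_perm, scientific = FALSE))
              else format(f / n_perm, scientific = FALSE),
    per_chromosome = chrom_table,
    null_n = null_n,
    settings = list(window_size = window_size, step = step, c_h = c_h,
                    c_w = c_w, strict = strict, replace = replace,
                    seed = as.integer(seed))
  ), class = "cafs_ridge_test")
}

#' @export
print.cafs_ridge_test <- function(x, ...) {
  s <- x$settings
  cat("Gene-density ridge permutation test\n")
  cat(sprintf("  windows: %s / step %s, cutoffs C_H=%g (%s), C_W=%g\n",
              format(s$window_size, big.mark = ",", scientific = FALSE),
              format(s$step, big.mark = ",", scientific = FALSE), s$c_h,
              if (s$strict) ">" else ">=", s$c_w))
  cat(sprintf("  observed ridges N = %d on %d chromosome(s)\n",
              x$observed_n, nrow(x$per_chromosome)))
  cat(sprintf("  null: %d permutations, f = %d, P %s %s\n", x$n_perm, x$f,
              if (x$censored) "" else "=", x$p_label))
  invisible(x)
}

#' Tidy a ridge permutation test
#'
#' @param x A `cafs_ridge_test`.
#' @param ... Unused.
#' @return `tidy()`: the per-chromosome table (`seq_id`, `n_genes`,
#'   `length`); `glance()`: a one-row summary with `observed_n`, `f`,
#'   `p_value`, `censored`, `p_label`, `n_perm`, `seed`.
#' @export
tidy.cafs_ridge_test <- function(x, ...) as_tibble(x$per_chromosome)

#' @rdname tidy.cafs_ridge_test
#' @export
glance.cafs_ridge_test <- function(x, ...) {
  tibble(observed_n = x$observed_n, f = x$f, p_value = x$p_value,
         censored = x$censored, p_label = x$p_label, n_perm = x$n_perm,
         c_h = x$settings$c_h, c_w = x$settings$c_w,
         window_size = x$settings$window_size, step = x$settings$step,
         seed = x$settings$seed)
}

#' @rdname tidy.cafs_ridge_test
#' @param object A `cafs_ridge_test`.
#' @export
autoplot.cafs_ridge_test <- function(object, ...) {
  d <- tibble(n = object$null_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_n, colour = "red") +
    ggplot2::labs(
      x = "ridge count under the permutation null",
      y = "permutations",
      title = sprintf("Observed N = %d, P %s%s", object$observed_n,
                      if (object$censored) "" else "= ", object$p_label)
    )
}

#' Ridge counts and p-values over a cutoff grid
#'
#' Evaluates the permutation test over every combination of window size and
#' the two ridge cutoffs (the heat-map view of the statistic). The step is
#' held fixed (100 kb by default) across window sizes.
#'
#' @inheritParams ridge_permutation_test
#' @param c_h_values,c_w_values,window_sizes Grid axes.
#' @return Tibble with one row per grid cell: `window_size`, `step`, `c_h`,
#'   `c_w`, `observed_n`, `f`, `p_value`, `censored`, `p_label`.
#' @export
cutoff_grid <- function(genes, chrom_lengths, c_h_values, c_w_values,
                        window_sizes = c(0.2e6, 0.3e6, 0.5e6, 1e6, 2e6, 3e6),
                        step = 1e5, strict = TRUE, n_perm = 1000, seed = 1L) {
  grid <- tidyr::expand_grid(window_size = window_sizes, c_h = c_h_values,
                             c_w = c_w_values)
  purrr::pmap(grid, function(window_size, c_h, c_w) {
    r <- ridge_permutation_test(genes, chrom_lengths,
                                window_size = window_size, step = step,
                                c_h = c_h, c_w = c_w, strict = strict,
                                n_perm = n_perm, seed = seed)
    glance(r) |> select("window_size", "step", "c_h", "c_w", "observed_n",
                        "f", "p_value", "censored", "p_label")
  }) |> dplyr::bind_rows()
}
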