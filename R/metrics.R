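#' Nxx assembly statistics
#'
#' For each threshold t, the Nt length is the length of the record at
#' which the descending cumulative length first reaches t% of the total,
#' and the Nt count is the rank of that record. The summary also carries
#' the longest record, the total size, and the numbers of records of at
#' least 100 bp and at least 2 kb.
#'
#' @param lengths Positive record lengths (bp), any order.
#' @param thresholds Percent thresholds (default N50..N90).
#' @return A `cafs_nxx` object; `tidy()` gives the per-threshold rows,
#'   `glance()` the summary.
#' @export
#' @examples
#' tidy(nxx_table(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)))
nxx_table <- function(lengths, thresholds = c(50, 60, 70, 80, 90)) {
  if (!length(lengths)) abort("empty length list")
  if (any(lengths <= 0)) abort("record lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  total <- cs[length(cs)]
  rows <- purrr::map(sort(thresholds), function(t) {
    k <- which(cs >= total * t / 100)[1]
    tibble(threshold = t, length = s[k], count = k)
  })
  structure(list(
    table = dplyr::bind_rows(rows),
    longest = s[1],
    total_size = total,
    n_records_100bp = sum(s >= 100),
    n_records_2kb = sum(s >= 2000)
  ), class = "cafs_nxx")
}

#' @export
print.cafs_nxx <- function(x, ...) {
  cat("Assembly Nxx statistics\n")
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  N%d  %12s bp  at record %s\n", t$threshold[i],
                format(t$length[i], big.mark = ","),
                format(t$count[i], big.mark = ",")))
  }
  cat(sprintf("  longest %s bp, total %s bp, n>=100bp %d, n>=2kb %d\n",
              format(x$longest, big.mark = ","),
              format(x$total_size, big.mark = ","),
              x$n_records_100bp, x$n_records_2kb))
  invisible(x)
}

#' @rdname nxx_table
#' @param x,object A `cafs_nxx`.
#' @param ... Unused.
#' @export
tidy.cafs_nxx <- function(x, ...) x$table

#' @rdname nxx_table
#' @export
glance.cafs_nxx <- function(x, ...) {
  tibble(longest = x$longest, total_size = x$total_size,
         n_records_100bp = x$n_records_100bp, n_records_2kb = x$n_records_2kb)
}

#' Split a scaffold into contigs at N gaps
#'
#' Splits at every maximal run of at least `min_n_run` `N`s and drops
#' pieces shorter than `min_contig` (contigs below 100 bp are excluded
#' from assembly statistics by convention).
#'
#' @param seq Scaffold sequence (character, `DNAString`, or one-element
#'   `DNAStringSet`).
#' @param min_n_run Minimum N-run length that counts as a gap.
#' @param min_contig Minimum contig length retained (bp).
#' @return Integer vector of contig lengths, in scaffold order.
#' @export
split_contigs <- function(seq, min_n_run = 10, min_contig = 100) {
  s <- if (methods::is(seq, "DNAStringSet")) as.character(seq[[1]])
  else as.character(seq)
  pieces <- strsplit(s, sprintf("N{%d,}", as.integer(min_n_run)))[[1]]
  lens <- nchar(pieces)
  as.integer(lens[lens >= min_contig])
}

# 2-bit encode one concatenated base string; returns integer codes with NA
# for N/other. A=0 C=1 G=2 T=3.
base_codes <- function(s) {
  x <- utf8ToInt(s)
  code <- rep(NA_integer_, length(x))
  code[x == 65L] <- 0L; code[x == 67L] <- 1L
  code[x == 71L] <- 2L; code[x == 84L] <- 3L
  code
}

#' Canonical k-mer spectrum of a read set
#'
#' Counts every k-base window of every read with a 1-bp sliding window,
#' merging each k-mer with its reverse complement (canonical form: the
#' lexicographically smaller of the two). Windows containing `N` are
#' skipped. The histogram maps k-mer depth to the number of distinct
#' k-mers observed at that depth; `k_num` is the total number of counted
#' k-mer instances.
#'
#' @param reads Read tibble (`seq` column), character vector of reads, or
#'   a FASTQ path.
#' @param k K-mer size (default 17; must satisfy `4^k < 2^53` for exact
#'   double arithmetic, i.e. `k <= 26`).
#' @return A `cafs_kmer_spectrum` list: `k`, `histogram` (tibble `depth`,
#'   `n_kmers`), `k_num`, `n_distinct`.
#' @export
kmer_spectrum <- function(reads, k = 17) {
  if (k < 1) abort("k must be >= 1")
  if (k > 26) abort("k must be <= 26 for exact counting")
  seqs <- if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    read_fastq(reads)$seq
  } else if (is.data.frame(reads)) reads$seq else as.character(reads)
  lens <- nchar(seqs)
  if (any(lens < k)) {
    seqs <- seqs[lens >= k]
    lens <- lens[lens >= k]
  }
  if (!length(seqs)) abort("no read is at least k bases long")
  code <- base_codes(paste(seqs, collapse = ""))
  n <- length(code)
  # forward value: sum code[i+j] * 4^(k-1-j); reverse complement read in
  # reverse: sum (3 - code[i+j]) * 4^j. Exact in doubles for k <= 26.
  wf <- 4^((k - 1):0)
  wr <- 4^(0:(k - 1))
  codes_na <- is.na(code)
  code0 <- ifelse(codes_na, 0, code)
  fwd <- as.numeric(stats::filter(code0, rev(wf), sides = 1))
  rcv <- as.numeric(stats::filter(3 - code0, rev(wr), sides = 1))
  # filter() with sides=1 puts the window sum at its last element
  has_na <- as.numeric(stats::filter(as.numeric(codes_na), rep(1, k),
                                     sides = 1)) > 0
  last <- seq_len(n)
  valid <- last >= k & !has_na
  # exclude windows crossing read boundaries
  read_id <- rep.int(seq_along(lens), lens)
  valid <- valid & read_id == c(rep(NA, k - 1), read_id[seq_len(n - k + 1)])
  canon <- pmin(fwd[valid], rcv[valid])
  k_num <- length(canon)
  if (!k_num) abort("no valid k-mer windows")
  depth <- rle(sort(canon))$lengths
  h <- table(depth)
  structure(list(
    k = as.integer(k),
    histogram = tibble(depth = as.integer(names(h)),
                       n_kmers = as.integer(h)),
    k_num = k_num,
    n_distinct = length(depth)
  ), class = "cafs_kmer_spectrum")
}

#' @export
print.cafs_kmer_spectrum <- function(x, ...) {
  cat(sprintf("%d-mer spectrum: %s instances, %s distinct, depth 1..%d\n",
              x$k, format(x$k_num, big.mark = ","),
              format(x$n_distinct, big.mark = ","),
              max(x$histogram$depth)))
  invisible(x)
}

#' Write a k-mer spectrum as a two-column TSV
#'
#' @param spectrum A `cafs_kmer_spectrum`.
#' @param path Output path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(spectrum$histogram, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Depth of the first local minimum of the histogram (the boundary of the
# low-depth error slope), or NA when the histogram rises from the start.
spectrum_error_boundary <- function(h) {
  y <- h$n_kmers
  if (length(y) < 3 || y[2] > y[1]) return(NA_integer_)
  for (i in 2:(length(y) - 1)) {
    if (y[i] <= y[i - 1] && y[i] < y[i + 1]) return(h$depth[i])
  }
  NA_integer_
}

# Modal depth after excluding the error slope.
spectrum_peak <- function(histogram) {
  h <- dplyr::arrange(histogram, .data$depth)
  y <- h$n_kmers
  if (length(y) < 3) return(h$depth[which.max(y)])
  bnd <- spectrum_error_boundary(h)
  if (is.na(bnd)) {
    if (which.max(y) == length(y) || which.max(y) > 1L || y[1] < y[2]) {
      return(h$depth[which.max(y)])
    }
    abort(paste0("k-mer histogram decreases monotonically; no interior ",
                 "coverage peak (too little or error-dominated data)"))
  }
  idx <- which(h$depth >= bnd)
  h$depth[idx[which.max(y[idx])]]
}

#' Estimate genome size from a k-mer spectrum
#'
#' Genome size = K_num / Peak_depth, where Peak_depth is the modal k-mer
#' depth after excluding the low-depth error slope (depths below the first
#' local minimum of the histogram) and K_num counts the k-mer instances at
#' or above that boundary — sequencing-error k-mers, which pile up at
#' depths 1-3, belong to neither the peak nor the genome and would
#' otherwise inflate the estimate.
#'
#' @param spectrum A `cafs_kmer_spectrum`.
#' @return One-row tibble: `k`, `k_num` (all instances), `k_num_used`
#'   (instances above the error slope), `peak_depth`, `genome_size_bp`
#'   (= `k_num_used / peak_depth`).
#' @export
estimate_genome_size <- function(spectrum) {
  h <- dplyr::arrange(spectrum$histogram, .data$depth)
  peak <- spectrum_peak(h)
  if (peak < 1) abort("peak depth below 1; cannot estimate")
  bnd <- spectrum_error_boundary(h)
  used <- if (is.na(bnd)) spectrum$k_num else {
    sum(as.numeric(h$depth[h$depth >= bnd]) * h$n_kmers[h$depth >= bnd])
  }
  tibble(k = spectrum$k, k_num = spectrum$k_num, k_num_used = used,
         peak_depth = as.integer(peak),
         genome_size_bp = used / peak)
}

# Nearest integer, ties away from zero (the rounding that reproduces the
# printed per-chromosome densities).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-chromosome assembly summary
#'
#' The per-chromosome report: size in kb, scaffold count, gene count, and
#' gene density per 10 Mb (`round(n_genes / size_kb * 1e4)`, ties away
#' from zero), plus a totals row whose density is recomputed from the
#' totals.
#'
#' @param chrom_table Tibble with `chrom`, `size_kb`, `n_scaffolds`,
#'   `n_genes` — e.g. [monopterus_chromosomes()], or the output of
#'   [summarise_assembly()].
#' @return Tibble of the rows plus a `"Total"` row, with
#'   `density_per_10mb`.
#' @export
#' @examples
#' chromosome_summary(monopterus_chromosomes())
chromosome_summary <- function(chrom_table) {
  need <- c("chrom", "size_kb", "n_scaffolds", "n_genes")
  miss <- setdiff(need, names(chrom_table))
  if (length(miss)) abort(paste0("missing column(s): ",
                                 paste(miss, collapse = ", ")))
  rows <- chrom_table |>
    mutate(density_per_10mb = as.integer(
      round_half_away(.data$n_genes / .data$size_kb * 1e4)))
  total <- tibble(
    chrom = "Total",
    size_kb = sum(rows$size_kb),
    n_scaffolds = sum(rows$n_scaffolds),
    n_genes = sum(rows$n_genes),
    density_per_10mb = as.integer(
      round_half_away(sum(rows$n_genes) / sum(rows$size_kb) * 1e4))
  )
  dplyr::bind_rows(rows[c(need, "density_per_10mb")], total)
}

#' Summarise an assembly into a per-chromosome table
#'
#' Computes the [chromosome_summary()] input from a placement table and
#' projected genes: chromosome size = scaffold lengths + gaps, scaffold
#' and gene counts per chromosome.
#'
#' @param placements Placement table.
#' @param scaffold_lengths Named scaffold lengths (bp).
#' @param genes Gene tibble in chromosome coordinates (`seq_id` must match
#'   placement `chrom_id`s; genes elsewhere raise an error).
#' @param gap_length Inter-scaffold gap (bp).
#' @return Tibble `chrom`, `size_kb`, `n_scaffolds`, `n_genes`.
#' @export
summarise_assembly <- function(placements, scaffold_lengths, genes,
                               gap_length = 1000L) {
  lens <- assembly_lengths(placements, scaffold_lengths, gap_length)
  bad <- setdiff(unique(genes$seq_id), names(lens))
  if (length(bad)) {
    abort(paste0("gene(s) on unknown chromosome(s): ",
                 paste(bad, collapse = ", ")))
  }
  tibble(chrom = names(lens)) |>
    mutate(size_kb = unname(lens[.data$chrom]) / 1000,
           n_scaffolds = purrr::map_int(.data$chrom, \(c)
             sum(placements$chrom_id == c)),
           n_genes = purrr::map_int(.data$chrom, \(c)
             sum(genes$seq_id == c)))
}
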