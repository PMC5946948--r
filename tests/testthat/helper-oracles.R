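# Independent brute-force oracles the implementation is checked against.

# Exhaustive run-length enumeration of qualifying-window runs: walk every
# index, extend maximal runs by hand, keep those of length >= c_w.
brute_ridges <- function(cnt, c_h, c_w, strict = TRUE) {
  q <- if (strict) cnt > c_h else cnt >= c_h
  runs <- list()
  i <- 1L
  while (i <= length(q)) {
    if (q[i]) {
      j <- i
      while (j < length(q) && q[j + 1L]) j <- j + 1L
      if (j - i + 1L >= c_w) {
        runs[[length(runs) + 1L]] <- c(start = i, end = j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

# Per-window gene membership by scanning every (gene, window) pair.
brute_window_counts <- function(pos, starts, ends) {
  vapply(seq_along(starts), function(k) {
    sum(pos >= starts[k] & pos <= ends[k])
  }, numeric(1))
}

# Spearman rho from the explicit rank formula (average ranks, Pearson on
# ranks), written without cor().
rank_formula_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Per-species adjacency pairs by direct enumeration, then the triple
# intersection, independent of the package's string encoding.
brute_predicted_links <- function(anchors) {
  per_species <- lapply(split(anchors, anchors$species), function(a) {
    out <- character(0)
    for (rc in unique(a$ref_chrom)) {
      v <- a$scaffold_id[a$ref_chrom == rc][order(a$ref_index[a$ref_chrom == rc])]
      if (length(v) < 2) next
      for (i in seq_len(length(v) - 1)) {
        p <- sort(c(v[i], v[i + 1]))
        out <- c(out, paste(p[1], p[2], sep = "|"))
      }
    }
    unique(out)
  })
  sorted <- Reduce(intersect, per_species)
  sort(sorted)
}

# Small deterministic simulated world shared across tests.
tiny_config <- function(seed = 11, ...) {
  args <- list(...)
  defaults <- list(
    n_chromosomes = 3,
    chrom_lengths = c(chrA = 4e6, chrB = 3e6, chrC = 2.5e6),
    seed = seed
  )
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# Kendall tau between a recovered and a true scaffold order.
order_tau <- function(recovered_ids, true_ids) {
  cor(match(recovered_ids, true_ids), seq_along(recovered_ids),
      method = "kendall")
}
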