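#' Simulation settings for a synthetic telocentric genome
#'
#' Defines the study conditions the synthetic genome emulates: 12
#' telocentric chromosomes whose length ratios follow the published
#' per-chromosome sizes (scaled to desk scale, 1/10 by default, about a
#' 55.5-Mb genome), a background-plus-ridge point process for gene starts
#' averaging 33.6 genes/Mb genome-wide, GC content locally coupled to gene
#' intensity around a 0.408 baseline, a scaffold tiling of each chromosome,
#' tri-species synteny anchors with occasional rearrangements, and noisy
#' per-cell FISH distance measurements averaged over at least five cells.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths Chromosome lengths in bp. Default: the published
#'   per-chromosome sizes divided by `scale`.
#' @param scale Desk-scale divisor applied to the published lengths.
#' @param mean_density Target genome-wide mean gene density (genes/Mb).
#' @param background_rate Background gene rate (genes/Mb) outside ridges.
#'   Default: derived from `mean_density` so that the genome-wide mean,
#'   ridges included, equals `mean_density`.
#' @param ridge_blocks_per_chrom Number of elevated-density blocks planted
#'   per chromosome.
#' @param ridge_intensity_multiplier Rate multiplier inside ridge blocks
#'   (>= 1; 1 disables ridges).
#' @param ridge_span Length of each ridge block (bp).
#' @param gc_baseline Baseline GC fraction of the genome.
#' @param gc_coupling Added GC inside regions of maximal gene intensity
#'   (linear in the normalised local intensity); 0 decouples GC from genes.
#' @param gc_noise_sd Standard deviation of per-kilobase GC noise.
#' @param tile_size Tile (bp) at which GC is modulated.
#' @param scaffold_mean_length Mean scaffold length of the tiling (bp).
#' @param fish_noise_sd Per-cell FISH distance noise (relative 0-1 units).
#' @param cells_per_measurement Cells averaged per FISH measurement (>= 5).
#' @param rearrangement_rate Per-adjacency break probability per reference
#'   species.
#' @param seed Master seed; each generator derives its own stream from it.
#' @return A `cafs_sim_config` list.
#' @export
simulation_config <- function(n_chromosomes = 12,
                              chrom_lengths = NULL,
                              scale = 10,
                              mean_density = 33.6,
                              background_rate = NULL,
                              ridge_blocks_per_chrom = 2,
                              ridge_intensity_multiplier = 3,
                              ridge_span = 5e5,
                              gc_baseline = 0.408,
                              gc_coupling = 0.08,
                              gc_noise_sd = 0.01,
                              tile_size = 1000,
                              scaffold_mean_length = 2.1e5,
                              fish_noise_sd = 0.02,
                              cells_per_measurement = 5,
                              rearrangement_rate = 0.1,
                              seed = 1L) {
  if (is.null(chrom_lengths)) {
    sizes <- monopterus_chromosomes()$size_kb * 1000 / scale
    chrom_lengths <- round(sizes[seq_len(n_chromosomes)])
  }
  if (length(chrom_lengths) != n_chromosomes) {
    abort("chrom_lengths must have one entry per chromosome")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_len(n_chromosomes))
  }
  if (cells_per_measurement < 5) {
    abort("cells_per_measurement must be >= 5 (measurements average > 5 cells)")
  }
  if (ridge_intensity_multiplier < 1) abort("ridge_intensity_multiplier must be >= 1")
  if (any(chrom_lengths <= 0) || mean_density <= 0) {
    abort("lengths and rates must be positive")
  }
  total <- sum(chrom_lengths)
  ridge_total <- min(n_chromosomes * ridge_blocks_per_chrom * ridge_span, total)
  if (is.null(background_rate)) {
    frac <- ridge_total / total
    background_rate <- mean_density /
      (1 + frac * (ridge_intensity_multiplier - 1))
  }
  if (any(background_rate * chrom_lengths / 1e6 < 1)) {
    abort("expected gene count below 1 on some chromosome; enlarge it")
  }
  structure(list(
    n_chromosomes = n_chromosomes, chrom_lengths = chrom_lengths,
    mean_density = mean_density, background_rate = background_rate,
    ridge_blocks_per_chrom = ridge_blocks_per_chrom,
    ridge_intensity_multiplier = ridge_intensity_multiplier,
    ridge_span = ridge_span, gc_baseline = gc_baseline,
    gc_coupling = gc_coupling, gc_noise_sd = gc_noise_sd,
    tile_size = tile_size, scaffold_mean_length = scaffold_mean_length,
    fish_noise_sd = fish_noise_sd,
    cells_per_measurement = cells_per_measurement,
    rearrangement_rate = rearrangement_rate, seed = as.integer(seed)
  ), class = "cafs_sim_config")
}

# Run expr under a generator-specific RNG stream (seed + fixed offset),
# restoring the caller's RNG state afterwards.
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(expr)
}

# Sample n points uniformly from [1, L] minus the ridge blocks.
sample_outside_blocks <- function(n, L, blocks) {
  if (n == 0L) return(numeric(0))
  if (nrow(blocks) == 0L) return(ceiling(runif(n) * L))
  b <- blocks[order(blocks$start), , drop = FALSE]
  seg_start <- c(1, b$end + 1)
  seg_end <- c(b$start - 1, L)
  keep <- seg_end >= seg_start
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  seg_len <- seg_end - seg_start + 1
  seg <- sample.int(length(seg_len), n, replace = TRUE, prob = seg_len)
  floor(seg_start[seg] + runif(n) * seg_len[seg])
}

#' Simulate a telocentric genome with planted gene-density ridges
#'
#' Gene start positions are drawn from an inhomogeneous point process:
#' Poisson with rate `background_rate` per Mb outside ridge blocks and
#' `background_rate * ridge_intensity_multiplier` inside. Per-tile GC
#' equals `gc_baseline + gc_coupling * (normalised local gene intensity)`
#' plus bounded noise, clipped to (0, 1); chromosome sequences are sampled
#' base by base from the tile GC. The scaffold tiling partitions each
#' chromosome exactly, with random per-scaffold orientations recorded as
#' the truth the Cafs stages must recover. Deterministic under a fixed
#' seed.
#'
#' @param config A [simulation_config()].
#' @param sequences Generate chromosome sequences? Skipping them is much
#'   faster when only gene positions and the tiling are needed.
#' @return A `cafs_truth` list: `config`, `chrom_lengths`, `genes`
#'   (chromosome coordinates), `ridge_truth`, `tiling` (placements +
#'   `scaffold_lengths`), `tile_gc`, and `sequences`
#'   ([Biostrings::DNAStringSet] or `NULL`).
#' @export
simulate_genome <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "cafs_sim_config"))
  with_stream(config$seed, 11L, {
    chroms <- names(config$chrom_lengths)
    mult <- config$ridge_intensity_multiplier
    ridge_rows <- list(); gene_rows <- list(); tile_gc <- list()
    seqs <- if (sequences) vector("list", length(chroms))
    tiling_rows <- list(); scaf_lens <- list()
    for (ci in seq_along(chroms)) {
      chr <- chroms[ci]
      L <- config$chrom_lengths[[ci]]
      # non-overlapping ridge blocks
      nb <- config$ridge_blocks_per_chrom
      span <- config$ridge_span
      blocks <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
      if (nb > 0 && mult > 1 && L > nb * span) {
        repeat {
          starts <- sort(ceiling(runif(nb) * (L - span)))
          if (nb == 1L || all(diff(starts) > span)) break
        }
        blocks <- tibble(chrom = chr, start = starts, end = starts + span - 1)
      }
      ridge_rows[[ci]] <- blocks
      # gene positions
      bg <- config$background_rate
      block_len <- sum(blocks$end - blocks$start + 1)
      n_bg <- stats::rpois(1, bg * (L - block_len) / 1e6)
      pos_bg <- sample_outside_blocks(n_bg, L, blocks)
      pos_ridge <- numeric(0)
      if (nrow(blocks)) {
        n_r <- stats::rpois(nrow(blocks), bg * mult * span / 1e6)
        pos_ridge <- unlist(purrr::map2(blocks$start, n_r,
                                        \(s, n) floor(s + runif(n) * span)))
      }
      pos <- sort(c(pos_bg, pos_ridge))
      pos <- pmin(pos, L)
      gene_rows[[ci]] <- tibble(
        seq_id = chr, start = as.integer(pos),
        end = as.integer(pmin(pos + 999, L)),
        strand = sample(c("+", "-"), length(pos), replace = TRUE)
      )
      # per-tile GC from normalised local intensity (0 outside, 1 inside)
      nt <- ceiling(L / config$tile_size)
      tile_mid <- (seq_len(nt) - 0.5) * config$tile_size
      inten <- rep(0, nt)
      if (nrow(blocks)) {
        for (b in seq_len(nrow(blocks))) {
          inten[tile_mid >= blocks$start[b] & tile_mid <= blocks$end[b]] <- 1
        }
      }
      gc <- config$gc_baseline + config$gc_coupling * inten +
        rnorm(nt, 0, config$gc_noise_sd)
      gc <- pmin(pmax(gc, 0.01), 0.99)
      tile_gc[[ci]] <- tibble(seq_id = chr, tile = seq_len(nt),
                              start = as.integer((seq_len(nt) - 1) * config$tile_size + 1),
                              gc = gc, intensity = inten)
      if (sequences) {
        p <- rep(gc, each = config$tile_size)[seq_len(L)]
        is_gc <- runif(L) < p
        second <- runif(L) < 0.5
        # A/T for the AT pair, C/G for the GC pair
        codes <- c(65L, 84L, 67L, 71L)[1L + second + 2L * is_gc]
        seqs[[ci]] <- intToUtf8(codes)
      }
      # scaffold tiling: random cut points, mean length ~ scaffold_mean_length
      ns <- max(2L, round(L / config$scaffold_mean_length))
      cuts <- sort(sample.int(L - 1L, ns - 1L))
      s_start <- c(1L, cuts + 1L); s_end <- c(cuts, L)
      ids <- sprintf("%s_scaf%02d", chr, seq_len(ns))
      tiling_rows[[ci]] <- tibble(
        chrom_id = chr, scaffold_id = ids, order_index = seq_len(ns),
        orientation = sample(c("+", "-"), ns, replace = TRUE),
        evidence = NA_character_,
        rel_position = ((s_start + s_end) / 2) / L,
        chrom_start = s_start, chrom_end = s_end
      )
      scaf_lens[[ci]] <- setNames(as.numeric(s_end - s_start + 1), ids)
    }
    sequences_out <- NULL
    if (sequences) {
      sequences_out <- Biostrings::DNAStringSet(unlist(seqs))
      names(sequences_out) <- chroms
    }
    truth <- list(
      config = config,
      chrom_lengths = config$chrom_lengths,
      genes = dplyr::bind_rows(gene_rows) |>
        mutate(gene_id = sprintf("gene%05d", row_number()), .before = 1),
      ridge_truth = dplyr::bind_rows(ridge_rows),
      tiling = list(placements = dplyr::bind_rows(tiling_rows),
                    scaffold_lengths = unlist(unname(scaf_lens))),
      tile_gc = dplyr::bind_rows(tile_gc),
      sequences = sequences_out
    )
    class(truth) <- "cafs_truth"
    truth
  })
}

#' Extract scaffold sequences from a simulated genome
#'
#' Cuts each scaffold out of its chromosome sequence; scaffolds recorded
#' with `-` orientation in the truth tiling are stored reverse-complemented,
#' so that re-assembling them with the recorded orientations reconstructs
#' the chromosome.
#'
#' @param truth A `cafs_truth` from [simulate_genome()] (with sequences).
#' @return A named [Biostrings::DNAStringSet] of scaffold sequences.
#' @export
scaffold_sequences <- function(truth) {
  if (is.null(truth$sequences)) abort("truth was simulated without sequences")
  p <- truth$tiling$placements
  out <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    s <- Biostrings::subseq(truth$sequences[[p$chrom_id[i]]],
                            p$chrom_start[i], p$chrom_end[i])
    if (p$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
    out[[i]] <- as.character(s)
  }
  x <- Biostrings::DNAStringSet(unlist(out))
  names(x) <- p$scaffold_id
  x
}

#' Simulate FISH distance-to-centromere measurements
#'
#' For each probe scaffold, draws `cells_per_measurement` per-cell relative
#' distances from a normal around the true relative position (truncated to
#' \[0, 1\]) and reports their mean, emulating image-based distance
#' measurement averaged over cells.
#'
#' @param truth A `cafs_truth`.
#' @param probes Scaffold ids to measure (default: all tiled scaffolds).
#' @param config Simulation settings; defaults to `truth$config`.
#' @return Tibble: `probe_id`, `chrom_id`, `true_rel`, `mean_rel_distance`,
#'   `n_cells`, `cells` (list column of per-cell values).
#' @export
simulate_fish <- function(truth, probes = NULL, config = truth$config) {
  p <- truth$tiling$placements
  probes <- probes %||% p$scaffold_id
  missing <- setdiff(probes, p$scaffold_id)
  if (length(missing)) {
    abort(paste0("probe(s) not in tiling: ", paste(missing, collapse = ", ")))
  }
  with_stream(config$seed, 101L, {
    idx <- match(probes, p$scaffold_id)
    k <- config$cells_per_measurement
    cells <- purrr::map(p$rel_position[idx], function(mu) {
      x <- rnorm(k, mu, config$fish_noise_sd)
      # truncate by redrawing out-of-range cells
      while (any(bad <- x < 0 | x > 1)) {
        if (config$fish_noise_sd == 0) { x <- pmin(pmax(x, 0), 1); break }
        x[bad] <- rnorm(sum(bad), mu, config$fish_noise_sd)
      }
      x
    })
    tibble(
      probe_id = probes,
      chrom_id = p$chrom_id[idx],
      true_rel = p$rel_position[idx],
      mean_rel_distance = purrr::map_dbl(cells, mean),
      n_cells = k,
      cells = cells
    )
  })
}

#' A simulated co-hybridization oracle
#'
#' Wraps the simulated truth behind the interface through which wet-lab
#' evidence enters the Cafs algorithms: same-chromosome queries (exact —
#' probes either co-localise or they do not) and relative-order queries of
#' 2-3 probes on one chromosome, which return the true order when the mean
#' separation exceeds the per-cell noise and otherwise the order of noisy
#' means. Every query increments a hybridization budget; 2- and 3-probe
#' queries each count as one experiment.
#'
#' @param truth A `cafs_truth`.
#' @param config Simulation settings; defaults to `truth$config`.
#' @return A list of functions: `same_chromosome(a, b)`,
#'   `order_probes(ids)` (returns ids sorted centromere-first),
#'   `telomere_end(ordered_ids)` (`"head"`/`"tail"`: which end of the given
#'   ordered list lies at the telomere), `scaffold_orientation(id)`
#'   (direction of one scaffold from its two end probes), and `budget()`.
#' @export
fish_oracle <- function(truth, config = truth$config) {
  p <- truth$tiling$placements
  pos <- setNames(p$rel_position, p$scaffold_id)
  chr <- setNames(p$chrom_id, p$scaffold_id)
  budget <- 0L
  check <- function(ids) {
    missing <- setdiff(ids, names(pos))
    if (length(missing)) abort(paste0("unknown probe(s): ",
                                      paste(missing, collapse = ", ")))
  }
  list(
    same_chromosome = function(a, b) {
      check(c(a, b)); budget <<- budget + 1L
      unname(chr[a] == chr[b])
    },
    order_probes = function(ids) {
      check(ids)
      if (length(ids) < 2 || length(ids) > 3) {
        abort("order queries take 2 or 3 probes")
      }
      if (length(unique(chr[ids])) != 1) {
        abort("order query across chromosomes is not a hybridization")
      }
      budget <<- budget + 1L
      d <- pos[ids]
      if (config$fish_noise_sd > 0 && min(diff(sort(d))) <= config$fish_noise_sd) {
        d <- d + rnorm(length(d), 0, config$fish_noise_sd /
                         sqrt(config$cells_per_measurement))
      }
      ids[order(d)]
    },
    telomere_end = function(ordered_ids) {
      check(ordered_ids); budget <<- budget + 1L
      ends <- pos[c(ordered_ids[1], ordered_ids[length(ordered_ids)])]
      if (which.max(ends) == 1L) "head" else "tail"
    },
    scaffold_orientation = function(id) {
      # dual-colour FISH of the two scaffold-end probes resolves direction
      check(id); budget <<- budget + 1L
      unname(setNames(p$orientation, p$scaffold_id)[id])
    },
    budget = function() budget
  )
}

#' Simulate tri-species synteny anchor maps
#'
#' Each reference species starts from the true scaffold order; every true
#' adjacency is preserved with probability `1 - rearrangement_rate`,
#' independently per species. A broken adjacency relocates the downstream
#' neighbour — together with the scaffolds still attached to it — to a
#' random chromosome end of that species, so exactly the sampled
#' adjacencies are disrupted and all others survive intact.
#'
#' @param truth A `cafs_truth`.
#' @param config Simulation settings; defaults to `truth$config`.
#' @param species Labels for the three reference species.
#' @return Anchors tibble: `scaffold_id`, `species`, `ref_chrom`,
#'   `ref_index`.
#' @export
simulate_reference_species <- function(truth, config = truth$config,
                                       species = c("medaka", "stickleback",
                                                   "tetraodon")) {
  if (length(species) != 3) abort("exactly 3 reference species are expected")
  p <- truth$tiling$placements
  true_lists <- split(p$scaffold_id, p$chrom_id)
  with_stream(config$seed, 211L, {
    out <- purrr::map(species, function(sp) {
      # cut each chromosome at the sampled broken adjacencies; the first
      # segment keeps its place, downstream segments relocate as blocks
      chrom_lists <- list()
      floating <- list()
      for (chr in names(true_lists)) {
        ids <- true_lists[[chr]]
        cut_after <- if (length(ids) < 2) logical(0) else {
          runif(length(ids) - 1L) < config$rearrangement_rate
        }
        seg_id <- cumsum(c(1L, as.integer(cut_after)))
        segs <- split(ids, seg_id)
        chrom_lists[[chr]] <- segs[[1]]
        floating <- c(floating, unname(segs[-1]))
      }
      # append each floating block at a random chromosome end, never
      # re-joining a block to its true upstream neighbour
      if (length(floating)) {
        for (blk in floating[sample.int(length(floating))]) {
          pred_of <- function(sc) {
            for (ids in true_lists) {
              k <- match(sc, ids)
              if (!is.na(k)) return(if (k > 1) ids[k - 1L] else NA_character_)
            }
            NA_character_
          }
          pred <- pred_of(blk[1])
          repeat {
            tgt <- sample.int(length(chrom_lists), 1)
            at_start <- runif(1) < 0.5
            host <- chrom_lists[[tgt]]
            junction <- if (at_start) NULL else host[length(host)]
            if (is.na(pred) || !identical(junction, pred)) break
          }
          chrom_lists[[tgt]] <- if (at_start) c(blk, host) else c(host, blk)
        }
      }
      dplyr::bind_rows(purrr::imap(chrom_lists, function(ids, chr) {
        if (!length(ids)) return(NULL)
        tibble(scaffold_id = ids, species = sp,
               ref_chrom = paste0(sp, "_", chr),
               ref_index = seq_along(ids))
      }))
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate shotgun reads from a sequence
#'
#' Uniformly positioned fixed-length reads with independent per-base
#' substitution errors (no indels, no quality model).
#'
#' @param seq A single sequence (character or `DNAString`/`DNAStringSet`
#'   of length 1).
#' @param coverage Mean per-base coverage (> 0).
#' @param read_len Read length (bp, <= sequence length).
#' @param error_rate Per-base substitution probability.
#' @param seed Seed for this read set.
#' @return Tibble with `read_id` and `seq`.
#' @export
simulate_reads <- function(seq, coverage, read_len = 100, error_rate = 0,
                           seed = 1L) {
  if (coverage <= 0) abort("coverage must be positive")
  s <- if (methods::is(seq, "DNAStringSet")) as.character(seq[[1]])
  else if (methods::is(seq, "DNAString")) as.character(seq)
  else as.character(seq)
  L <- nchar(s)
  if (read_len > L) abort("read_len exceeds the sequence length")
  with_stream(seed, 0L, {
    n <- round(coverage * L / read_len)
    starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
    reads <- substring(s, starts, starts + read_len - 1L)
    if (error_rate > 0) {
      big <- utf8ToInt(paste(reads, collapse = ""))
      hit <- which(runif(length(big)) < error_rate)
      if (length(hit)) {
        bases <- c(65L, 67L, 71L, 84L) # A C G T
        alt <- rbind(c(67L, 71L, 84L), c(65L, 71L, 84L),
                     c(65L, 67L, 84L), c(65L, 67L, 71L))
        old <- match(big[hit], bases)
        big[hit] <- alt[cbind(old, sample.int(3L, length(hit), replace = TRUE))]
      }
      all_str <- intToUtf8(big)
      off <- (seq_len(n) - 1L) * read_len
      reads <- substring(all_str, off + 1L, off + read_len)
    }
    tibble(read_id = sprintf("read%07d", seq_len(n)), seq = reads)
  })
}
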