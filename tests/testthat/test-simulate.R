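test_that("simulation is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 21)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(t1$genes, t2$genes)
  expect_identical(t1$ridge_truth, t2$ridge_truth)
  expect_identical(t1$tiling, t2$tiling)
  expect_identical(as.character(t1$sequences), as.character(t2$sequences))
  expect_identical(simulate_fish(t1), simulate_fish(t2))
  expect_identical(simulate_reference_species(t1),
                   simulate_reference_species(t2))
  expect_identical(simulate_reads(t1$sequences[[1]], 2, seed = 5),
                   simulate_reads(t2$sequences[[1]], 2, seed = 5))
})

test_that("genes lie in their chromosomes and the tiling partitions them", {
  truth <- simulate_genome(tiny_config(seed = 22), sequences = FALSE)
  for (chr in names(truth$chrom_lengths)) {
    g <- truth$genes[truth$genes$seq_id == chr, ]
    expect_true(all(g$start >= 1 & g$end <= truth$chrom_lengths[[chr]]))
    p <- truth$tiling$placements[truth$tiling$placements$chrom_id == chr, ]
    p <- p[order(p$order_index), ]
    expect_equal(p$chrom_start[1], 1L)
    expect_equal(p$chrom_end[nrow(p)], unname(truth$chrom_lengths[[chr]]))
    if (nrow(p) > 1) {
      expect_equal(p$chrom_start[-1], p$chrom_end[-nrow(p)] + 1L)
    }
  }
  expect_equal(sum(truth$tiling$scaffold_lengths),
               sum(truth$chrom_lengths))
})

test_that("homogeneous gene counts in disjoint 1-Mb windows are Poisson", {
  # >= 200 disjoint windows: one 200-Mb chromosome, no ridges
  cfg <- simulation_config(n_chromosomes = 1,
                           chrom_lengths = c(chr1 = 2e8),
                           ridge_intensity_multiplier = 1,
                           scaffold_mean_length = 1e7, seed = 23)
  truth <- simulate_genome(cfg, sequences = FALSE)
  tr <- window_track(truth$genes, truth$chrom_lengths,
                     window_size = 1e6, step = 1e6)
  cnt <- tr$gene_count
  expect_gte(length(cnt), 200L)
  lambda <- cfg$background_rate
  # chi-square GOF against Poisson(lambda), tails pooled to expected >= 5
  ks <- 0:max(cnt)
  p <- dpois(ks, lambda)
  brk <- ks[cumsum(p) > 0.01 & rev(cumsum(rev(p))) > 0.01]
  obs <- vapply(brk, function(k) sum(cnt == k), numeric(1))
  obs <- c(sum(cnt < min(brk)), obs, sum(cnt > max(brk)))
  pr <- c(ppois(min(brk) - 1, lambda), dpois(brk, lambda),
          ppois(max(brk), lambda, lower.tail = FALSE))
  stat <- sum((obs - length(cnt) * pr)^2 / (length(cnt) * pr))
  pval <- pchisq(stat, df = length(pr) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("gc_coupling = 0 decouples GC from gene density", {
  cfg <- simulation_config(n_chromosomes = 1, chrom_lengths = c(chr1 = 5e5),
                           gc_coupling = 0, gc_noise_sd = 0.02,
                           ridge_blocks_per_chrom = 1, ridge_span = 1e5,
                           seed = 24)
  truth <- simulate_genome(cfg)
  tiles <- truth$tile_gc
  dens <- vapply(seq_len(nrow(tiles)), function(i) {
    sum(truth$genes$start >= tiles$start[i] &
          truth$genes$start < tiles$start[i] + cfg$tile_size)
  }, numeric(1))
  rho <- suppressWarnings(cor(tiles$gc, dens, method = "spearman"))
  expect_lt(abs(rho), 0.1)
})

test_that("positive gc_coupling produces a positive genome-wide correlation", {
  truth <- simulate_genome(tiny_config(seed = 25, gc_coupling = 0.08))
  tr <- window_track(truth$genes, truth$chrom_lengths, truth$sequences,
                     window_size = 5e5, step = 5e5)
  r <- spearman_cor(tr$gene_count, tr$gc)
  expect_gt(r$rho, 0)
  expect_lt(r$p_value, 0.01)
})

test_that("noise-free FISH measurements equal the true relative positions", {
  truth <- simulate_genome(tiny_config(seed = 26, fish_noise_sd = 0),
                           sequences = FALSE)
  obs <- simulate_fish(truth)
  expect_equal(obs$mean_rel_distance, obs$true_rel)
  expect_true(all(obs$mean_rel_distance >= 0 & obs$mean_rel_distance <= 1))
})

test_that("FISH mean error matches sd/sqrt(n) away from the boundaries", {
  # many probes on one chromosome stand in for replicate measurements
  cfg <- simulation_config(n_chromosomes = 1, chrom_lengths = c(chr1 = 2e7),
                           scaffold_mean_length = 1e4, fish_noise_sd = 0.02,
                           cells_per_measurement = 5, seed = 27)
  truth <- simulate_genome(cfg, sequences = FALSE)
  obs <- simulate_fish(truth)
  interior <- obs[obs$true_rel > 0.2 & obs$true_rel < 0.8, ]
  expect_gte(nrow(interior), 1000L)
  sem <- sd(interior$mean_rel_distance - interior$true_rel)
  expect_equal(sem, 0.02 / sqrt(5), tolerance = 0.08)
  expect_true(all(vapply(obs$cells, length, numeric(1)) == 5))
})

test_that("the oracle separates chromosomes exactly and orders probes", {
  truth <- simulate_genome(tiny_config(seed = 28, fish_noise_sd = 0),
                           sequences = FALSE)
  p <- truth$tiling$placements
  oracle <- fish_oracle(truth)
  a <- p$scaffold_id[p$chrom_id == "chrA"][1:3]
  b <- p$scaffold_id[p$chrom_id == "chrB"][1]
  expect_false(oracle$same_chromosome(a[1], b))
  expect_true(oracle$same_chromosome(a[1], a[2]))
  expect_equal(oracle$order_probes(rev(a)), a)
  expect_error(oracle$order_probes(c(a[1], b)), "chromosome")
  expect_equal(oracle$budget(), 3L)  # the rejected query is not an experiment
  expect_error(oracle$same_chromosome("nope", b), "unknown")
})

test_that("synteny maps preserve adjacencies at the configured rate", {
  truth0 <- simulate_genome(tiny_config(seed = 29, rearrangement_rate = 0),
                            sequences = FALSE)
  anchors0 <- simulate_reference_species(truth0)
  links0 <- predict_linked_scaffolds(anchors0)
  p <- truth0$tiling$placements
  true_adj <- sum(vapply(split(p, p$chrom_id), nrow, numeric(1)) - 1)
  expect_equal(nrow(links0), true_adj)

  # rate 0.1: adjacency survives in all three species with prob ~ 0.9^3
  cfg <- simulation_config(n_chromosomes = 12, scaffold_mean_length = 5.5e4,
                           rearrangement_rate = 0.1, seed = 30)
  truth <- simulate_genome(cfg, sequences = FALSE)
  p <- truth$tiling$placements
  n_adj <- sum(vapply(split(p, p$chrom_id), nrow, numeric(1)) - 1)
  expect_gte(n_adj, 900L)
  links <- predict_linked_scaffolds(simulate_reference_species(truth))
  expect_equal(nrow(links) / n_adj, 0.9^3, tolerance = 0.07)
})

test_that("read simulation respects coverage, purity and error rate", {
  cfg <- simulation_config(n_chromosomes = 1, chrom_lengths = c(chr1 = 1e5),
                           ridge_blocks_per_chrom = 0, seed = 31)
  truth <- simulate_genome(cfg)
  genome <- as.character(truth$sequences[[1]])

  reads <- simulate_reads(genome, coverage = 10, read_len = 100, seed = 32)
  expect_equal(nrow(reads), 10000L)
  expect_true(all(nchar(reads$seq) == 100L))
  expect_true(all(vapply(reads$seq[1:50], grepl, logical(1), x = genome,
                         fixed = TRUE)))

  noisy <- simulate_reads(genome, coverage = 1, read_len = 100,
                          error_rate = 0.01, seed = 33)
  clean <- simulate_reads(genome, coverage = 1, read_len = 100,
                          error_rate = 0, seed = 33)
  mm <- mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, noisy$seq, clean$seq)
  expect_equal(sum(mm) / (length(mm) * 100), 0.01, tolerance = 0.2)
  expect_error(simulate_reads(genome, coverage = 0), "positive")
})
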