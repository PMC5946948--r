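test_that("probe eligibility requires both ends on one scaffold above 90%", {
  ends <- tibble::tibble(
    bac_id = c("b1", "b1", "b2", "b2", "b3", "b3", "b4"),
    end = c(1, 2, 1, 2, 1, 2, 1),
    scaffold_id = c("s1", "s1", "s1", "s2", "s3", "s3", "s4"),
    identity = c(95, 97, 99, 99, 90, 95, 99)
  )
  expect_equal(probe_eligibility(ends), "b1")   # b3: 90.0 is not > 90
  dup <- tibble::tibble(bac_id = c("b1", "b1"), end = c(1, 1),
                        scaffold_id = "s1", identity = c(95, 96))
  expect_error(probe_eligibility(dup), "duplicate")
})

test_that("predicted links equal the brute-force triple intersection", {
  truth <- simulate_genome(tiny_config(seed = 81, rearrangement_rate = 0.2),
                           sequences = FALSE)
  anchors <- simulate_reference_species(truth)
  links <- predict_linked_scaffolds(anchors)
  got <- sort(paste(links$scaffold_a, links$scaffold_b, sep = "|"))
  expect_equal(got, brute_predicted_links(anchors))
  expect_true(all(links$n_supporting_species == 3L))
  # subset property: every link is an adjacency in every species
  for (sp in unique(anchors$species)) {
    a <- anchors[anchors$species == sp, ]
    sp_adj <- brute_predicted_links(dplyr::bind_rows(a, a, a) |>
      dplyr::mutate(species = rep(c("x", "y", "z"), each = nrow(a))))
    expect_true(all(got %in% sp_adj))
  }
  expect_error(predict_linked_scaffolds(anchors[anchors$species != "medaka", ]),
               "3 species")
})

test_that("a pair adjacent in only two species is not emitted", {
  anchors <- tibble::tibble(
    scaffold_id = c("a", "b", "a", "b", "a", "c", "b"),
    species = c("s1", "s1", "s2", "s2", "s3", "s3", "s3"),
    ref_chrom = c("c", "c", "c", "c", "c", "c", "d"),
    ref_index = c(1, 2, 1, 2, 1, 2, 1)
  )
  expect_equal(nrow(predict_linked_scaffolds(anchors)), 0L)
  anchors$ref_chrom[7] <- "c"; anchors$ref_index[7] <- 3
  expect_equal(nrow(predict_linked_scaffolds(anchors)), 0L) # a-b in 2/3 only
})

test_that("unhinted assignment of 12 singleton groups costs 66 queries", {
  truth <- simulate_genome(
    simulation_config(n_chromosomes = 12, scaffold_mean_length = 1e7,
                      seed = 82), sequences = FALSE)
  p <- truth$tiling$placements
  one_per_chrom <- p$scaffold_id[!duplicated(p$chrom_id)]
  expect_equal(length(one_per_chrom), 12L)
  oracle <- fish_oracle(truth)
  res <- assign_linkage_groups(one_per_chrom, oracle)
  expect_equal(res$n_queries, sum(0:11))
  expect_equal(length(unique(res$groups$group_id)), 12L)
})

test_that("perfect hints cost one confirmation query per hinted scaffold", {
  truth <- simulate_genome(tiny_config(seed = 83, rearrangement_rate = 0),
                           sequences = FALSE)
  p <- truth$tiling$placements
  hints <- predict_linked_scaffolds(simulate_reference_species(truth))
  oracle <- fish_oracle(truth)
  res <- assign_linkage_groups(p$scaffold_id, oracle, hints)
  n_groups <- length(unique(p$chrom_id))
  founding <- sum(seq_len(n_groups) - 1L)  # founders test all landmarks
  expect_equal(res$n_queries,
               (nrow(p) - n_groups) * 1L + founding)
  # recovered partition equals the true chromosome partition
  m <- merge(res$groups, p, by = "scaffold_id")
  tab <- table(m$group_id, m$chrom_id)
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("assignment recovers the true partition on 50 scaffolds", {
  truth <- simulate_genome(tiny_config(seed = 84, scaffold_mean_length = 2e5),
                           sequences = FALSE)
  p <- truth$tiling$placements
  expect_gte(nrow(p), 45L)
  oracle <- fish_oracle(truth)
  res <- assign_linkage_groups(p$scaffold_id, oracle,
                               expect_n_groups = 3)
  m <- merge(res$groups, p, by = "scaffold_id")
  tab <- table(m$group_id, m$chrom_id)
  expect_true(all(rowSums(tab > 0) == 1L))
  expect_true(all(colSums(tab > 0) == 1L))
})

test_that("hinted assignment never exceeds the unhinted budget", {
  for (s in 85:88) {
    truth <- simulate_genome(tiny_config(seed = s, rearrangement_rate = 0.15),
                             sequences = FALSE)
    p <- truth$tiling$placements
    hints <- predict_linked_scaffolds(simulate_reference_species(truth))
    with_h <- assign_linkage_groups(p$scaffold_id, fish_oracle(truth), hints)
    without <- assign_linkage_groups(p$scaffold_id, fish_oracle(truth))
    expect_lte(with_h$n_queries, without$n_queries)
    expect_identical(
      with_h$groups[order(with_h$groups$scaffold_id), c("scaffold_id", "group_id")],
      without$groups[order(without$groups$scaffold_id), c("scaffold_id", "group_id")])
  }
})

test_that("noise-free distances sort exactly with zero order queries", {
  truth <- simulate_genome(tiny_config(seed = 89, fish_noise_sd = 0),
                           sequences = FALSE)
  p <- truth$tiling$placements
  obs <- simulate_fish(truth)
  oracle <- fish_oracle(truth)
  members <- p$scaffold_id[p$chrom_id == "chrA"]
  res <- order_scaffolds(members, obs, oracle, resolution = 0)
  true_order <- p$scaffold_id[p$chrom_id == "chrA"][
    order(p$order_index[p$chrom_id == "chrA"])]
  expect_equal(res$order$scaffold_id, true_order)
  expect_equal(order_tau(res$order$scaffold_id, true_order), 1)
  expect_equal(res$n_queries, 0L)
  expect_error(order_scaffolds(c(members, "ghost"), obs, oracle),
               "ghost")
})

test_that("tied distances are broken by the order oracle", {
  obs <- tibble::tibble(probe_id = c("s1", "s2"),
                        mean_rel_distance = c(0.5, 0.5))
  oracle <- list(order_probes = function(ids) c("s2", "s1"))
  res <- order_scaffolds(c("s1", "s2"), obs, oracle, resolution = 0)
  expect_equal(res$order$scaffold_id, c("s2", "s1"))
  expect_equal(res$n_queries, 1L)
  # without an oracle the lexicographic fallback applies
  res2 <- order_scaffolds(c("s2", "s1"), obs, NULL, resolution = 0)
  expect_equal(res2$order$scaffold_id, c("s1", "s2"))
})

test_that("noisy ordering with oracle disambiguation recovers most of the order", {
  taus <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_chromosomes = 1, chrom_lengths = c(chr1 = 5e6),
                             scaffold_mean_length = 2e5, fish_noise_sd = 0.02,
                             cells_per_measurement = 5, seed = 900 + s)
    truth <- simulate_genome(cfg, sequences = FALSE)
    p <- truth$tiling$placements
    obs <- simulate_fish(truth)
    oracle <- fish_oracle(truth)
    res <- order_scaffolds(p$scaffold_id, obs, oracle,
                           resolution = 2 * 0.02 / sqrt(5))
    order_tau(res$order$scaffold_id, p$scaffold_id[order(p$order_index)])
  }, numeric(1))
  expect_gte(median(taus), 0.9)
})

test_that("orientation by the telomere landmark is an involution", {
  ord <- tibble::tibble(scaffold_id = c("a", "b", "c"), order_index = 1:3,
                        rel_position = c(0.1, 0.5, 0.9))
  expect_identical(orient_group(ord, "tail"), ord)
  flipped <- orient_group(ord, "head")
  expect_equal(flipped$scaffold_id, c("c", "b", "a"))
  expect_equal(flipped$rel_position, c(0.1, 0.5, 0.9))
  expect_identical(orient_group(orient_group(ord, "head"), "head")$scaffold_id,
                   ord$scaffold_id)
  expect_error(orient_group(ord[0, ], "head"), "empty")
})

test_that("chromosome building concatenates with 1-kb N gaps and reverse complements", {
  seqs <- Biostrings::DNAStringSet(c(s1 = "ACGTACGTAC", s2 = "GGGTTT"))
  pl <- tibble::tibble(chrom_id = "chr1", scaffold_id = c("s1", "s2"),
                       order_index = 1:2, orientation = c("+", "-"))
  built <- build_chromosome(pl, seqs, gap_length = 1000L)
  s <- as.character(built$sequences[["chr1"]])
  expect_equal(nchar(s), 10 + 1000 + 6)
  expect_equal(substr(s, 1, 10), "ACGTACGTAC")
  expect_equal(substr(s, 11, 1010), strrep("N", 1000))
  expect_equal(substr(s, 1011, 1016), "AAACCC")  # revcomp of GGGTTT
  one <- build_chromosome(pl[1, ], seqs)
  expect_equal(Biostrings::width(one$sequences), 10L)
  expect_error(build_chromosome(
    dplyr::mutate(pl, scaffold_id = c("s1", "sX")), seqs), "sX")
})

test_that("zero-noise end-to-end Cafs run reproduces the truth", {
  cfg <- simulation_config(seed = 91, fish_noise_sd = 0,
                           scaffold_mean_length = 4e5)
  truth <- simulate_genome(cfg, sequences = FALSE)
  p <- truth$tiling$placements
  obs <- simulate_fish(truth)
  oracle <- fish_oracle(truth)
  hints <- predict_linked_scaffolds(simulate_reference_species(truth))
  a <- cafs_assemble(p$scaffold_id, obs, oracle, hints,
                     expect_n_groups = 12)
  m <- merge(a$placements, p, by = "scaffold_id",
             suffixes = c("_got", "_true"))
  # partition, order, orientation all recovered on all 12 chromosomes
  tab <- table(m$chrom_id_got, m$chrom_id_true)
  expect_true(all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L))
  taus <- vapply(split(m, m$chrom_id_true), function(d) {
    cor(d$order_index_got, d$order_index_true, method = "kendall")
  }, numeric(1))
  expect_equal(unname(taus), rep(1, 12))
  expect_true(all(m$orientation_got == m$orientation_true))
  expect_true(all(a$placements$evidence %in% c("fish", "synteny")))
  expect_gt(sum(a$placements$evidence == "synteny"), 0)
})

test_that("anchored fraction reports placed over total scaffold length", {
  lens <- c(s1 = 600, s2 = 300, s3 = 100)
  pl <- tibble::tibble(chrom_id = "chr1", scaffold_id = c("s1", "s2"),
                       order_index = 1:2, orientation = "+")
  af <- anchored_fraction(pl, lens)
  expect_equal(af$anchored_bp, 900)
  expect_equal(af$anchored_fraction, 0.9)
})
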