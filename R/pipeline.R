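#' Pipeline configuration
#'
#' Collects the settings of a full run: either a simulation block (the
#' default study conditions of [simulation_config()]) or paths to real
#' inputs, plus window, ridge, correlation and Cafs settings. Can be read
#' from a YAML file; values given as arguments override file values.
#'
#' @param path Optional YAML file with any of the fields below.
#' @param simulation List of [simulation_config()] arguments, or `NULL`
#'   when real inputs are given.
#' @param inputs List of paths (`fasta`, `genes`, `agp`) for a real-data
#'   run; `NULL` to simulate.
#' @param window_size,step Track specification (bp).
#' @param c_h,c_w,n_perm Ridge cutoffs and permutation count.
#' @param high_rho,high_p,low_rho Regional-correlation thresholds.
#' @param resolution Cafs ordering resolution.
#' @param seed Master seed.
#' @return A `cafs_pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, simulation = list(), inputs = NULL,
                            window_size = 1e6, step = 1e5, c_h = 40,
                            c_w = 5, n_perm = 1000, high_rho = 0.95,
                            high_p = 0.01, low_rho = 0.7, resolution = 0,
                            seed = 1L) {
  cfg <- list(simulation = simulation, inputs = inputs,
              window_size = window_size, step = step, c_h = c_h, c_w = c_w,
              n_perm = n_perm, high_rho = high_rho, high_p = high_p,
              low_rho = low_rho, resolution = resolution, seed = seed)
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    given <- names(as.list(match.call())[-1])
    for (nm in setdiff(names(file_cfg), c(given, "path"))) {
      cfg[[nm]] <- file_cfg[[nm]]
    }
  }
  if (is.null(cfg$inputs) && is.null(cfg$simulation)) {
    abort("config needs either real input paths or a simulation block")
  }
  structure(cfg, class = "cafs_pipeline_config")
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate (when configured) -> window tracks -> ridge detection
#' and permutation test -> regional correlation scan -> Cafs assembly ->
#' assembly metrics, writing every stage artifact into `out_dir` together
#' with a JSON manifest recording the package version, seed, settings and
#' stage outputs. Any stage failure aborts with the stage name; artifacts
#' written so far are kept alongside a `FAILED` marker.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "cafs_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "cafs",
    version = as.character(utils::packageVersion("cafs")),
    seed = config$seed,
    settings = config[setdiff(names(config), c("simulation", "inputs"))],
    stages = list()
  )
  stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[cafs] stage %-10s seed=%s  %.1fs", name,
                    config$seed, elapsed))
    manifest$stages[[name]] <<- list(outputs = res$outputs,
                                     elapsed_s = round(elapsed, 2))
    res$value
  }

  sim <- NULL
  if (is.null(config$inputs)) {
    sim <- stage("simulate", function() {
      cfg <- do.call(simulation_config,
                     c(config$simulation, list(seed = config$seed)))
      truth <- simulate_genome(cfg)
      f_fa <- file.path(out_dir, "genome.fa")
      f_gff <- file.path(out_dir, "genes.gff3")
      f_agp <- file.path(out_dir, "truth_tiling.agp")
      write_fasta(truth$sequences, f_fa)
      write_genes(truth$genes, f_gff, "gff3")
      write_agp(truth$tiling$placements[, c("chrom_id", "scaffold_id",
                                            "order_index", "orientation")],
                truth$tiling$scaffold_lengths, f_agp, gap_length = 0L)
      list(value = truth, outputs = c(f_fa, f_gff, f_agp))
    })
    genes <- sim$genes
    chrom_lengths <- sim$chrom_lengths
    sequences <- sim$sequences
  } else {
    loaded <- stage("load", function() {
      sequences <- read_fasta(config$inputs$fasta)
      genes <- read_genes(config$inputs$genes)
      list(value = list(genes = genes, sequences = sequences),
           outputs = character(0))
    })
    genes <- loaded$genes
    sequences <- loaded$sequences
    chrom_lengths <- setNames(Biostrings::width(sequences),
                              names(sequences))
  }

  track <- stage("tracks", function() {
    tr <- window_track(genes, chrom_lengths, sequences,
                       config$window_size, config$step)
    f <- file.path(out_dir, "window_track.tsv")
    write_tsv_plain(tr, f)
    list(value = tr, outputs = f)
  })

  stage("ridges", function() {
    r <- detect_ridges(track, config$c_h, config$c_w)
    f_bed <- file.path(out_dir, "ridges.bed")
    write_ridges_bed(r, f_bed)
    pt <- ridge_permutation_test(genes, chrom_lengths,
                                 window_size = config$window_size,
                                 step = config$step, c_h = config$c_h,
                                 c_w = config$c_w, n_perm = config$n_perm,
                                 seed = config$seed)
    f_tsv <- file.path(out_dir, "ridge_test.tsv")
    write_tsv_plain(glance(pt), f_tsv)
    list(value = pt, outputs = c(f_bed, f_tsv))
  })

  stage("correlate", function() {
    sc <- regional_scan(track, high_rho = config$high_rho,
                        high_p = config$high_p, low_rho = config$low_rho)
    f <- file.path(out_dir, "regional_correlation.tsv")
    write_tsv_plain(sc, f)
    f_bed <- file.path(out_dir, "high_correlation.bed")
    write_scan(sc, f_bed, "bed")
    list(value = sc, outputs = c(f, f_bed))
  })

  asm <- NULL
  if (!is.null(sim)) {
    asm <- stage("cafs", function() {
      oracle <- fish_oracle(sim)
      obs <- simulate_fish(sim)
      anchors <- simulate_reference_species(sim)
      hints <- predict_linked_scaffolds(anchors)
      a <- cafs_assemble(sim$tiling$placements$scaffold_id, obs, oracle,
                         hints, resolution = config$resolution,
                         expect_n_groups = sim$config$n_chromosomes)
      f_agp <- file.path(out_dir, "assembly.agp")
      write_agp(a$placements, sim$tiling$scaffold_lengths, f_agp)
      f_groups <- write_tsv_plain(a$groups,
                                  file.path(out_dir, "groups.tsv"))
      f_budget <- write_tsv_plain(a$budget,
                                  file.path(out_dir, "budget.tsv"))
      list(value = a, outputs = c(f_agp, f_groups, f_budget))
    })
  }

  stage("metrics", function() {
    scaf_lens <- if (!is.null(sim)) sim$tiling$scaffold_lengths
    else setNames(Biostrings::width(sequences), names(sequences))
    nxx <- nxx_table(scaf_lens)
    f_nxx <- write_tsv_plain(tidy(nxx), file.path(out_dir, "nxx.tsv"))
    outputs <- f_nxx
    if (!is.null(sim)) {
      # summarise against the truth tiling, whose chromosome labels match
      # the simulated gene coordinates (the recovered assembly is reported
      # through the cafs stage artifacts)
      summ <- chromosome_summary(
        summarise_assembly(sim$tiling$placements, scaf_lens, genes,
                           gap_length = 0L))
      f_sum <- write_tsv_plain(summ, file.path(out_dir,
                                               "chromosome_summary.tsv"))
      outputs <- c(outputs, f_sum)
    }
    list(value = nxx, outputs = outputs)
  })

  manifest$config_hash <- digest_config(config)
  json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

# Stable hash of the configuration (no external digest dependency):
# serialise deterministically to JSON and sum a rolling polynomial.
digest_config <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        null = "null")
  x <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(x)) h <- (h * 31 + x[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}
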