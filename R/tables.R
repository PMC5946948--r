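#' Published per-chromosome assembly statistics of the swamp eel genome
#'
#' The printed per-chromosome summary of the *Monopterus albus*
#' chromosome-scale assembly: chromosome size (kb), number of anchored
#' scaffolds, number of protein-coding genes, and gene density per 10 Mb.
#' Twelve telocentric chromosomes; 555 Mb anchored in 328 scaffolds carrying
#' 18,660 genes. Used as a small worked dataset for
#' [chromosome_summary()] and as the length template (scaled down) for
#' [simulation_config()].
#'
#' @return A tibble with columns `chrom`, `size_kb`, `n_scaffolds`,
#'   `n_genes`, `density_per_10mb` (the printed, rounded density).
#' @export
#' @examples
#' monopterus_chromosomes()
monopterus_chromosomes <- function() {
  tibble::tibble(
    chrom = as.character(1:12),
    size_kb = c(75908.7, 65103.9, 51637.3, 51162.1, 50080.0, 48093.1,
                42410.1, 41999.7, 41928.7, 34690.8, 29285.5, 22774.4),
    n_scaffolds = c(33L, 32L, 21L, 30L, 27L, 27L, 29L, 30L, 23L, 30L, 23L, 23L),
    n_genes = c(2264L, 2133L, 1872L, 1791L, 1517L, 1659L, 1500L, 1456L,
                1241L, 1262L, 1086L, 879L),
    density_per_10mb = c(298L, 328L, 363L, 350L, 303L, 345L, 354L, 347L,
                         296L, 364L, 371L, 386L)
  )
}
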