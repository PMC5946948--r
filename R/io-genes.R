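#' Read gene annotations from GFF3 or BED
#'
#' Parses an annotation file into a tidy gene table. Coordinates are
#' normalised to the package-wide convention: 1-based, inclusive on both
#' ends. BED input (0-based, half-open) is converted on read; GFF3 is taken
#' as-is. Record order in the file is preserved.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`. Defaults to a guess from the file
#'   extension.
#' @return A tibble with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"*"` for unknown).
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tg1", f)
#' read_genes(f)
read_genes <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed",
                     abort(paste0("cannot guess annotation format from '", path, "'")))
  }
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) abort(paste0("failed to parse ", format, " file '",
                                     path, "': ", conditionMessage(e)))
  )
  df <- as.data.frame(gr)
  ids <- if (format == "gff3") {
    id <- df[["ID"]] %||% df[["Name"]] %||% rep(NA_character_, nrow(df))
    as.character(id)
  } else {
    as.character(df[["name"]] %||% rep(NA_character_, nrow(df)))
  }
  missing_id <- is.na(ids)
  if (any(missing_id)) ids[missing_id] <- paste0("gene_", which(missing_id))
  out <- tibble(
    gene_id = ids,
    seq_id = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand)
  )
  bad <- out$end < out$start | out$start < 1L
  if (any(bad)) {
    abort(paste0("invalid interval after coordinate conversion at record(s) ",
                 paste(which(bad), collapse = ", ")))
  }
  out
}

#' Write gene annotations to GFF3 or BED
#'
#' Inverse of [read_genes()]. Output is deterministic: records are sorted by
#' `seq_id`, then `start`. Internal 1-based inclusive coordinates are
#' converted to the BED convention on write; unknown strand is serialised
#' as `"."`.
#'
#' @param genes Tibble with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand`.
#' @param path Output path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  stopifnot(all(c("gene_id", "seq_id", "start", "end") %in% names(genes)))
  genes <- arrange(genes, .data$seq_id, .data$start)
  strand <- genes$strand %||% rep("*", nrow(genes))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seq_id,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = strand
  )
  if (format == "gff3") {
    gr$source <- "cafs"
    gr$type <- "gene"
    gr$ID <- genes$gene_id
  } else {
    gr$name <- genes$gene_id
  }
  rtracklayer::export(gr, path, format = if (format == "gff3") "gff3" else "bed")
  invisible(path)
}

#' Read and write FASTA sequences
#'
#' Thin wrappers around Biostrings keeping the package's conventions:
#' sequences are uppercased on read, restricted to the A/C/G/T/N alphabet,
#' and written wrapped at 60 columns sorted by record id.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ok <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  if (any(rowSums(ok[, c("A", "C", "G", "T"), drop = FALSE]) +
          Biostrings::letterFrequency(x, "N") != Biostrings::width(x))) {
    abort("sequence contains characters outside the A/C/G/T/N alphabet")
  }
  x
}

#' @rdname read_fasta
#' @param seqs Named character vector or `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  seqs <- seqs[order(names(seqs))]
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' @param reads Tibble with columns `read_id` and `seq` (see
#'   [simulate_reads()]).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), seq = as.character(x))
}
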