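#' Validate a scaffold placement table
#'
#' A placement table describes how scaffolds build chromosomes in a
#' telocentric karyotype: coordinate 1 of every chromosome is the centromere
#' end, `rel_position` is the relative distance from the centromere (0 =
#' centromere, 1 = telomere), and `order_index` counts scaffolds outward
#' from the centromere starting at 1.
#'
#' @param placements Tibble with columns `chrom_id`, `scaffold_id`,
#'   `order_index`, `orientation` (`"+"`/`"-"`), and optionally `evidence`
#'   (`"fish"` or `"synteny"`) and `rel_position` in \[0, 1\].
#' @return The validated tibble, invisibly ordered by chromosome and
#'   `order_index`.
#' @export
validate_placements <- function(placements) {
  need <- c("chrom_id", "scaffold_id", "order_index", "orientation")
  miss <- setdiff(need, names(placements))
  if (length(miss)) abort(paste0("placement table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (!all(placements$orientation %in% c("+", "-"))) {
    abort("orientation must be '+' or '-'")
  }
  placements <- arrange(placements, .data$chrom_id, .data$order_index)
  by_chr <- split(placements$order_index, placements$chrom_id)
  for (chr in names(by_chr)) {
    oi <- by_chr[[chr]]
    if (!identical(as.integer(oi), seq_along(oi))) {
      abort(paste0("order_index on ", chr,
                   " must be contiguous 1..n from the centromere"))
    }
  }
  if ("rel_position" %in% names(placements)) {
    rp <- placements$rel_position
    if (any(!is.na(rp) & (rp < 0 | rp > 1))) {
      abort("rel_position must lie in [0, 1]")
    }
    bad <- placements |>
      group_by(.data$chrom_id) |>
      summarise(mono = all(diff(.data$rel_position[order(.data$order_index)]) >= 0 |
                             is.na(diff(.data$rel_position[order(.data$order_index)])))) |>
      filter(!.data$mono)
    if (nrow(bad)) {
      abort(paste0("rel_position must increase with order_index on: ",
                   paste(bad$chrom_id, collapse = ", ")))
    }
  }
  invisible(placements)
}

#' Write a chromosome assembly as AGP v2.1
#'
#' Serialises a placement table as AGP: one `W` (component) row per
#' scaffold, alternating with `N` gap rows of `gap_length` bases
#' (gap type `scaffold`, linkage `yes`, evidence `map` — FISH and synteny
#' evidence are map evidence). Chromosome coordinates are contiguous and
#' 1-based; reverse placements carry orientation `-`.
#'
#' @param placements Placement table (see [validate_placements()]).
#' @param scaffold_lengths Named numeric vector, scaffold id to length (bp).
#' @param path Output path, or `NULL` to return the AGP lines.
#' @param gap_length Gap inserted between neighbouring scaffolds (bp).
#' @return The AGP lines as a character vector, invisibly when `path` is
#'   given.
#' @export
write_agp <- function(placements, scaffold_lengths, path = NULL,
                      gap_length = 1000L) {
  placements <- validate_placements(placements)
  unknown <- setdiff(placements$scaffold_id, names(scaffold_lengths))
  if (length(unknown)) {
    abort(paste0("no length known for scaffold(s): ",
                 paste(unknown, collapse = ", ")))
  }
  lines <- character(0)
  header <- "##agp-version\t2.1"
  for (chr in unique(placements$chrom_id)) {
    p <- placements[placements$chrom_id == chr, ]
    pos <- 1L
    part <- 1L
    for (k in seq_len(nrow(p))) {
      len <- as.integer(scaffold_lengths[[p$scaffold_id[k]]])
      lines <- c(lines, paste(chr, pos, pos + len - 1L, part, "W",
                              p$scaffold_id[k], 1L, len, p$orientation[k],
                              sep = "\t"))
      pos <- pos + len
      part <- part + 1L
      if (k < nrow(p) && gap_length > 0L) {
        lines <- c(lines, paste(chr, pos, pos + gap_length - 1L, part, "N",
                                gap_length, "scaffold", "yes", "map",
                                sep = "\t"))
        pos <- pos + as.integer(gap_length)
        part <- part + 1L
      }
    }
  }
  out <- c(header, lines)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read an AGP v2.1 file
#'
#' Inverse of [write_agp()] on its image. Object coordinates are checked
#' for contiguity; the gap length is taken from the gap rows (and must be
#' constant within the file).
#'
#' @param x Path to an AGP file, or a character vector of AGP lines.
#' @return A list with elements `placements` (tibble: `chrom_id`,
#'   `scaffold_id`, `order_index`, `orientation`, `rel_position` computed
#'   from the component midpoint), `scaffold_lengths` (named vector) and
#'   `gap_length`.
#' @export
read_agp <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) abort("AGP input contains no component rows")
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- vapply(f, length, 1L) == 9L
  if (!all(ncol_ok)) {
    abort(paste0("malformed AGP row(s) at line ",
                 paste(which(!ncol_ok), collapse = ", ")))
  }
  m <- do.call(rbind, f)
  obj <- m[, 1]; beg <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  type <- m[, 5]
  pos <- tapply(seq_along(obj), obj, function(i) {
    if (beg[i][1] != 1) abort(paste0("object ", obj[i][1], " does not start at 1"))
    if (any(beg[i][-1] != end[i][-length(i)] + 1)) {
      abort(paste0("non-contiguous object coordinates on ", obj[i][1]))
    }
    invisible(NULL)
  })
  comp <- type == "W"
  gaps <- type %in% c("N", "U")
  gap_length <- if (any(gaps)) unique(as.numeric(m[gaps, 6])) else 1000
  if (length(gap_length) > 1) {
    abort("gap rows carry differing lengths; one gap convention per file")
  }
  obj_len <- tapply(end, obj, max)
  placements <- tibble(
    chrom_id = obj[comp],
    scaffold_id = m[comp, 6],
    orientation = m[comp, 9],
    start = beg[comp],
    end = end[comp]
  ) |>
    group_by(.data$chrom_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(order_index = row_number(),
           rel_position = ((.data$start + .data$end) / 2 - 1) /
             pmax(obj_len[.data$chrom_id] - 1, 1)) |>
    ungroup() |>
    select("chrom_id", "scaffold_id", "order_index", "orientation",
           "rel_position")
  lens <- as.numeric(m[comp, 8])
  scaffold_lengths <- setNames(lens, m[comp, 6])
  scaffold_lengths <- scaffold_lengths[!duplicated(names(scaffold_lengths))]
  list(placements = validate_placements(placements),
       scaffold_lengths = scaffold_lengths,
       gap_length = as.numeric(gap_length))
}

#' Total length of an assembled chromosome
#'
#' Sum of scaffold lengths plus one inter-scaffold gap per junction.
#'
#' @inheritParams write_agp
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
assembly_lengths <- function(placements, scaffold_lengths, gap_length = 1000L) {
  placements <- validate_placements(placements)
  placements |>
    group_by(.data$chrom_id) |>
    summarise(len = sum(scaffold_lengths[.data$scaffold_id]) +
                gap_length * (n() - 1L)) |>
    (\(d) setNames(d$len, d$chrom_id))()
}

#' Project scaffold-space genes into chromosome coordinates
#'
#' Genes annotated on scaffolds acquire chromosome coordinates through the
#' scaffold's placement: coordinates are shifted by the cumulative length of
#' preceding scaffolds and gaps; genes on reverse-placed scaffolds are
#' reflected within the scaffold and their strand flipped. Genes on
#' unplaced scaffolds are returned unchanged with `anchored = FALSE`.
#'
#' @param genes Gene tibble in scaffold coordinates (see [read_genes()]).
#' @inheritParams write_agp
#' @return The gene tibble in chromosome coordinates, with an `anchored`
#'   logical column.
#' @export
project_to_chromosome <- function(genes, placements, scaffold_lengths,
                                  gap_length = 1000L) {
  placements <- validate_placements(placements)
  off <- placements |>
    group_by(.data$chrom_id) |>
    arrange(.data$order_index, .by_group = TRUE) |>
    mutate(len = scaffold_lengths[.data$scaffold_id],
           offset = cumsum(dplyr::lag(.data$len, default = 0) +
                             c(0, rep(gap_length, n() - 1L)))) |>
    ungroup() |>
    select("scaffold_id", "chrom_id", "orientation", "len", "offset")
  g <- left_join(genes, off, by = c(seq_id = "scaffold_id"))
  anchored <- !is.na(g$chrom_id)
  if (any(anchored & (g$end > g$len), na.rm = TRUE)) {
    abort("gene extends beyond its scaffold; cannot project")
  }
  minus <- anchored & g$orientation == "-"
  new_start <- ifelse(minus, g$len - g$end + 1L, g$start) + g$offset
  new_end <- ifelse(minus, g$len - g$start + 1L, g$end) + g$offset
  flip <- c("+" = "-", "-" = "+", "*" = "*")
  out <- genes
  out$seq_id[anchored] <- g$chrom_id[anchored]
  out$start[anchored] <- as.integer(new_start[anchored])
  out$end[anchored] <- as.integer(new_end[anchored])
  out$strand[minus] <- flip[out$strand[minus]]
  out$anchored <- anchored
  out
}
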