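#' Filter BACs eligible as FISH probes
#'
#' A BAC qualifies as a probe when both of its end sequences align to the
#' same scaffold and both alignments exceed 90% identity (strictly).
#'
#' @param bac_ends Tibble with columns `bac_id`, `end` (1 or 2),
#'   `scaffold_id`, `identity` (percent).
#' @param min_identity Identity threshold (strict `>`).
#' @return Character vector of eligible `bac_id`s.
#' @export
probe_eligibility <- function(bac_ends, min_identity = 90) {
  dup <- duplicated(bac_ends[c("bac_id", "end")])
  if (any(dup)) {
    abort(paste0("duplicate end record(s) for BAC(s): ",
                 paste(unique(bac_ends$bac_id[dup]), collapse = ", ")))
  }
  bac_ends |>
    group_by(.data$bac_id) |>
    summarise(ok = n() == 2L &&
                length(unique(.data$scaffold_id)) == 1L &&
                all(.data$identity > min_identity)) |>
    filter(.data$ok) |>
    dplyr::pull("bac_id")
}

# Unordered adjacency pairs of one species' anchor map.
species_adjacencies <- function(anchors_sp) {
  a <- arrange(anchors_sp, .data$ref_chrom, .data$ref_index)
  pairs <- a |>
    group_by(.data$ref_chrom) |>
    summarise(a = list(head(.data$scaffold_id, -1)),
              b = list(tail(.data$scaffold_id, -1))) |>
    tidyr::unnest(c("a", "b"))
  if (!nrow(pairs)) return(character(0))
  unique(paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b), sep = "\r"))
}

#' Predict linked scaffolds from tri-species synteny
#'
#' Two scaffolds are linked in a reference species when their anchors sit
#' at adjacent ordinals on one reference chromosome. A pair is emitted as a
#' predicted link only when it is linked in all three species (set
#' semantics: unordered pairs, no duplicates).
#'
#' @param anchors Anchor tibble (`scaffold_id`, `species`, `ref_chrom`,
#'   `ref_index`) covering exactly three species.
#' @return Tibble `scaffold_a`, `scaffold_b`, `n_supporting_species` (= 3).
#' @export
predict_linked_scaffolds <- function(anchors) {
  sp <- unique(anchors$species)
  if (length(sp) != 3) abort("anchors must cover exactly 3 species")
  adj <- purrr::map(sp, \(s) species_adjacencies(anchors[anchors$species == s, ]))
  common <- Reduce(intersect, adj)
  if (!length(common)) {
    return(tibble(scaffold_a = character(0), scaffold_b = character(0),
                  n_supporting_species = integer(0)))
  }
  parts <- strsplit(sort(common), "\r", fixed = TRUE)
  tibble(scaffold_a = purrr::map_chr(parts, 1),
         scaffold_b = purrr::map_chr(parts, 2),
         n_supporting_species = 3L)
}

#' Assign scaffolds to linkage groups by co-hybridization
#'
#' Incremental probe-combination mapping: the first scaffold founds group
#' A and becomes its landmark; each later candidate is tested first
#' against the landmark of the group predicted by its synteny hints (if
#' any), then against the remaining landmarks in group-founding order. A
#' candidate negative against every landmark founds the next group with
#' itself as landmark. Every oracle query counts one hybridization.
#'
#' @param scaffolds Scaffold ids, in processing order.
#' @param oracle A co-hybridization oracle (see [fish_oracle()]); only its
#'   `same_chromosome` query is used.
#' @param hints Optional predicted links from [predict_linked_scaffolds()].
#' @param expect_n_groups When non-`NULL`, founding more groups than this
#'   raises an inconsistency error (oracle/truth mismatch).
#' @return List: `groups` (tibble `scaffold_id`, `group_id`, `landmark`,
#'   `hinted` — whether a hint predicted the confirmed group) and
#'   `n_queries`.
#' @export
assign_linkage_groups <- function(scaffolds, oracle, hints = NULL,
                                  expect_n_groups = NULL) {
  landmark <- character(0)   # landmark per group, in founding order
  group_of <- character(0)   # group id per assigned scaffold (named)
  hinted <- logical(0)
  queries <- 0L
  link_partners <- function(sc) {
    if (is.null(hints) || !nrow(hints)) return(character(0))
    c(hints$scaffold_b[hints$scaffold_a == sc],
      hints$scaffold_a[hints$scaffold_b == sc])
  }
  for (sc in scaffolds) {
    if (!length(landmark)) {
      landmark <- sc
      group_of[sc] <- "A"
      hinted[sc] <- FALSE
      next
    }
    partners <- link_partners(sc)
    hint_groups <- unique(unname(group_of[intersect(partners, names(group_of))]))
    order_ids <- LETTERS[seq_along(landmark)]
    try_order <- c(hint_groups, setdiff(order_ids, hint_groups))
    assigned <- FALSE
    for (g in try_order) {
      lm <- landmark[match(g, order_ids)]
      queries <- queries + 1L
      if (oracle$same_chromosome(sc, lm)) {
        group_of[sc] <- g
        hinted[sc] <- g %in% hint_groups
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      if (!is.null(expect_n_groups) && length(landmark) >= expect_n_groups) {
        abort("scaffold matches no landmark but all expected groups exist")
      }
      landmark <- c(landmark, sc)
      group_of[sc] <- LETTERS[length(landmark)]
      hinted[sc] <- FALSE
    }
  }
  groups <- tibble(
    scaffold_id = names(group_of),
    group_id = unname(group_of),
    landmark = landmark[match(unname(group_of), LETTERS[seq_along(landmark)])],
    hinted = unname(hinted)
  )
  list(groups = groups, n_queries = queries)
}

#' Order the scaffolds of one linkage group by FISH walking
#'
#' Scaffolds are first ordered by ascending mean measured distance to the
#' centromere; adjacent pairs whose distances differ by no more than
#' `resolution` are disambiguated by relative-order oracle queries (each
#' counted as one hybridization), with lexicographic scaffold id as the
#' final tie-break when no oracle is available.
#'
#' @param members Scaffold ids of the group.
#' @param fish_obs FISH observation tibble (from [simulate_fish()] or any
#'   table with `probe_id` and `mean_rel_distance`).
#' @param oracle Order oracle (see [fish_oracle()]), or `NULL`.
#' @param resolution Distance below which means are considered unresolved.
#' @return List: `order` (tibble `scaffold_id`, `order_index`,
#'   `rel_position`) and `n_queries`.
#' @export
order_scaffolds <- function(members, fish_obs, oracle = NULL,
                            resolution = 0) {
  d <- fish_obs$mean_rel_distance[match(members, fish_obs$probe_id)]
  if (anyNA(d)) {
    abort(paste0("no FISH distance for: ",
                 paste(members[is.na(d)], collapse = ", ")))
  }
  ord <- members[order(d, members)]
  dist <- setNames(d, members)
  queries <- 0L
  cache <- new.env(parent = emptyenv())
  pair_before <- function(a, b) {
    # TRUE if a lies centromere-side of b
    if (abs(dist[a] - dist[b]) > resolution) return(dist[a] < dist[b])
    if (is.null(oracle)) return(a < b)
    key <- paste(min(a, b), max(a, b), sep = "\r")
    if (is.null(cache[[key]])) {
      queries <<- queries + 1L
      cache[[key]] <- oracle$order_probes(c(min(a, b), max(a, b)))
    }
    identical(cache[[key]][1], a)
  }
  passes <- 0L
  repeat { # bubble passes with oracle-resolved close pairs
    swapped <- FALSE
    for (k in seq_len(length(ord) - 1L)) {
      if (!pair_before(ord[k], ord[k + 1L])) {
        ord[c(k, k + 1L)] <- ord[c(k + 1L, k)]
        swapped <- TRUE
      }
    }
    passes <- passes + 1L
    if (!swapped || passes > length(ord)) break
  }
  list(order = tibble(scaffold_id = ord,
                      order_index = seq_along(ord),
                      rel_position = unname(dist[ord])),
       n_queries = queries)
}

#' Orient an ordered linkage group by the telomere landmark
#'
#' FISH walking orders scaffolds along the chromosome but leaves the
#' polarity of the list unknown; the telomere of the metaphase chromosome
#' fixes it. The list is emitted centromere-first and reversed exactly
#' when the observation says its head is telomeric (an involution:
#' applying the opposite observation restores the input).
#'
#' @param ordered Tibble from [order_scaffolds()] (`scaffold_id`,
#'   `order_index`, `rel_position`).
#' @param telomere_at `"head"` or `"tail"`: which end of the list the
#'   telomere observation marks.
#' @return The ordered tibble, centromere-first, with `order_index` and
#'   `rel_position` updated (positions reflect as `1 - rel` on reversal).
#' @export
orient_group <- function(ordered, telomere_at = c("tail", "head")) {
  if (!nrow(ordered)) abort("empty group cannot be oriented")
  telomere_at <- match.arg(telomere_at)
  if (telomere_at == "head") {
    ordered <- ordered[rev(seq_len(nrow(ordered))), ]
    ordered$rel_position <- 1 - ordered$rel_position
    ordered$order_index <- seq_len(nrow(ordered))
  }
  ordered
}

#' Build a chromosome sequence from oriented placements
#'
#' Concatenates scaffold sequences in placement order with `gap_length`
#' `N`s between neighbours, reverse-complementing `-` placements.
#'
#' @param placements Placement table for one or more chromosomes (see
#'   [validate_placements()]).
#' @param scaffold_seqs Named `DNAStringSet` (or character vector) of
#'   scaffold sequences.
#' @param gap_length Gap between neighbours (bp).
#' @return List: `sequences` (named `DNAStringSet`, one per chromosome),
#'   `placements`, `scaffold_lengths`, `gap_length`, and `agp` lines.
#' @export
build_chromosome <- function(placements, scaffold_seqs, gap_length = 1000L) {
  placements <- validate_placements(placements)
  if (!methods::is(scaffold_seqs, "DNAStringSet")) {
    scaffold_seqs <- Biostrings::DNAStringSet(unlist(scaffold_seqs))
  }
  missing <- setdiff(placements$scaffold_id, names(scaffold_seqs))
  if (length(missing)) {
    abort(paste0("no sequence for scaffold(s): ",
                 paste(missing, collapse = ", ")))
  }
  gap <- strrep("N", gap_length)
  seqs <- purrr::map_chr(split(placements, placements$chrom_id), function(p) {
    p <- arrange(p, .data$order_index)
    pieces <- purrr::map2_chr(p$scaffold_id, p$orientation, function(id, o) {
      s <- scaffold_seqs[[id]]
      if (o == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    })
    paste(pieces, collapse = gap)
  })
  sequences <- Biostrings::DNAStringSet(seqs)
  lens <- setNames(Biostrings::width(scaffold_seqs), names(scaffold_seqs))
  list(sequences = sequences,
       placements = placements,
       scaffold_lengths = lens[unique(placements$scaffold_id)],
       gap_length = as.integer(gap_length),
       agp = write_agp(placements, lens, gap_length = gap_length))
}

#' Fraction of scaffold sequence anchored to chromosomes
#'
#' @param placements Placement table of anchored scaffolds.
#' @param scaffold_lengths Named lengths of all scaffolds (anchored or
#'   not).
#' @return One-row tibble: `anchored_bp`, `total_bp`, `anchored_fraction`.
#' @export
anchored_fraction <- function(placements, scaffold_lengths) {
  a <- sum(scaffold_lengths[unique(placements$scaffold_id)])
  tibble(anchored_bp = a, total_bp = sum(scaffold_lengths),
         anchored_fraction = a / sum(scaffold_lengths))
}

#' Run the full Cafs assembly from simulated evidence
#'
#' Chains the Cafs stages: linkage-group assignment against landmarks
#' (synteny hints first), FISH-walking ordering within each group,
#' orientation by the telomere landmark, per-scaffold direction from the
#' end-probe query, and placement-table construction. Evidence is tagged
#' `"synteny"` for scaffolds whose hinted group was confirmed on the first
#' query and `"fish"` otherwise.
#'
#' @param scaffolds Scaffold ids to assemble.
#' @param fish_obs FISH observations covering `scaffolds`.
#' @param oracle Co-hybridization oracle (see [fish_oracle()]).
#' @param hints Optional predicted links.
#' @param resolution Ordering resolution (see [order_scaffolds()]).
#' @param expect_n_groups Expected number of linkage groups (chromosomes).
#' @return List: `placements` (with `evidence` and `rel_position`),
#'   `groups`, `budget` (tibble of per-stage query counts).
#' @export
cafs_assemble <- function(scaffolds, fish_obs, oracle, hints = NULL,
                          resolution = 0, expect_n_groups = 12) {
  asg <- assign_linkage_groups(scaffolds, oracle, hints, expect_n_groups)
  order_queries <- 0L
  chrom_names <- setNames(paste0("chr", seq_along(LETTERS)), LETTERS)
  placements <- purrr::map(split(asg$groups, asg$groups$group_id),
                           function(g) {
    o <- order_scaffolds(g$scaffold_id, fish_obs, oracle, resolution)
    order_queries <<- order_queries + o$n_queries
    oriented <- orient_group(o$order,
                             oracle$telomere_end(o$order$scaffold_id))
    tibble(
      chrom_id = chrom_names[[g$group_id[1]]],
      scaffold_id = oriented$scaffold_id,
      order_index = oriented$order_index,
      orientation = purrr::map_chr(oriented$scaffold_id,
                                   oracle$scaffold_orientation),
      evidence = ifelse(g$hinted[match(oriented$scaffold_id,
                                       g$scaffold_id)],
                        "synteny", "fish"),
      rel_position = oriented$rel_position
    )
  }) |> dplyr::bind_rows()
  list(
    placements = validate_placements(placements),
    groups = asg$groups,
    budget = tibble(stage = c("assign", "order"),
                    n_queries = c(asg$n_queries, order_queries))
  )
}
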