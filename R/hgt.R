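#' Insertion age policy for the HGT screen
#'
#' Classifies candidate insertions into age tiers from their identity to the
#' best bacterial hit and the indel content of that alignment: `recent` at
#' high identity (default >= 90%), `degrading` at low identity with indels
#' (default <= 80% and >= 1 indel event), `intermediate` otherwise. The
#' defaults generalize the canonical exemplars -- ~95% identity for recent
#' insertions versus 70-71% identity with indels for older, degrading ones --
#' into an explicit three-tier policy.
#'
#' @param recent_min_identity Minimum percent identity for `recent`.
#' @param degrading_max_identity Maximum percent identity for `degrading`;
#'   must be below `recent_min_identity`.
#' @param degrading_min_indels Minimum indel events for `degrading`.
#' @return A list of class `age_policy`.
#' @export
age_policy <- function(recent_min_identity = 90, degrading_max_identity = 80,
                       degrading_min_indels = 1L) {
  if (degrading_max_identity >= recent_min_identity) {
    abort("`degrading_max_identity` must be < `recent_min_identity`")
  }
  structure(list(recent_min_identity = recent_min_identity,
                 degrading_max_identity = degrading_max_identity,
                 degrading_min_indels = as.integer(degrading_min_indels)),
            class = "age_policy")
}

#' Merge significant bacterial hits into candidate regions
#'
#' The first stage of the DNA-based HGT screen: hits below the significance
#' threshold are dropped, and significant hits on the same scaffold with
#' overlapping query intervals are merged into one region (optionally
#' bridging gaps up to `gap` bases; default 0, plain overlap). Each region
#' carries its best bacterial hit (minimum E-value, ties by bit score then
#' subject id) whose identity and gap openings become the region's
#' `pct_identity` and `indel_events`.
#'
#' @param hits A bacterial hit tibble; `query_id` is the scaffold and
#'   `q_start`/`q_end` are 1-based scaffold coordinates.
#' @param policy A [homology_policy()]; hits with `evalue >=` threshold are
#'   dropped.
#' @param gap Maximum gap (bases) bridged when merging; default 0.
#' @return A tibble of regions: `scaffold`, `start`, `end` (0-based
#'   half-open), `pct_identity`, `indel_events`, `bact_subject_id`,
#'   `bact_evalue`, `bact_bit_score`, `n_hits`.
#' @export
find_bacterial_regions <- function(hits, policy = homology_policy(), gap = 0) {
  hits <- as_tibble(hits)
  sig <- hits[is_significant(hits, policy), , drop = FALSE]
  if (nrow(sig) == 0) return(empty_regions())
  sig <- sig |>
    mutate(.start = as.numeric(.data$q_start) - 1, .end = as.numeric(.data$q_end)) |>
    arrange(.data$query_id, .data$.start, .data$.end) |>
    group_by(.data$query_id) |>
    mutate(.new = .data$.start > lag(cummax(.data$.end),
                                     default = -Inf) + gap,
           .region = cumsum(.data$.new)) |>
    ungroup()
  sig |>
    group_by(.data$query_id, .data$.region) |>
    group_modify(function(df, key) {
      best <- best_hit(mutate(df, query_id = "region"))
      tibble(start = as.integer(min(df$.start)), end = as.integer(max(df$.end)),
             pct_identity = best$pct_identity,
             indel_events = best$gap_openings,
             bact_subject_id = best$subject_id,
             bact_evalue = best$evalue,
             bact_bit_score = best$bit_score,
             n_hits = nrow(df))
    }) |>
    ungroup() |>
    rename(scaffold = "query_id") |>
    select(-".region") |>
    arrange(.data$scaffold, .data$start)
}

empty_regions <- function() {
  tibble(scaffold = character(), start = integer(), end = integer(),
         pct_identity = numeric(), indel_events = integer(),
         bact_subject_id = character(), bact_evalue = numeric(),
         bact_bit_score = numeric(), n_hits = integer())
}

#' Compare candidate regions against animal hits
#'
#' The conserved-gene exclusion step: for each region, the best (minimum)
#' E-value among animal hits overlapping the region's interval is compared to
#' the region's bacterial E-value. A region is `excluded_conserved` iff the
#' animal E-value is strictly less than the bacterial one -- such a region is
#' a slowly evolving, highly conserved gene, not a transfer. Regions with no
#' overlapping animal hit, or tied E-values, are `retained`.
#'
#' @param regions Output of [find_bacterial_regions()].
#' @param animal_hits An animal hit tibble on the same scaffolds (any
#'   overlap with the region interval triggers the comparison).
#' @return `regions` with columns `animal_evalue` (`NA` when no overlap),
#'   `animal_subject_id`, and `status`.
#' @export
screen_region <- function(regions, animal_hits = NULL) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) {
    return(mutate(regions, animal_evalue = numeric(),
                  animal_subject_id = character(), status = character()))
  }
  if (is.null(animal_hits) || nrow(animal_hits) == 0) {
    return(mutate(regions, animal_evalue = NA_real_,
                  animal_subject_id = NA_character_, status = "retained"))
  }
  animal <- as_tibble(animal_hits) |>
    mutate(.astart = .data$q_start - 1L, .aend = .data$q_end)
  best_animal <- regions |>
    mutate(.rid = row_number()) |>
    left_join(animal, by = c(scaffold = "query_id"),
              relationship = "many-to-many") |>
    filter(!is.na(.data$.astart),
           .data$.astart < .data$end, .data$.aend > .data$start) |>
    group_by(.data$.rid) |>
    arrange(.data$evalue, dplyr::desc(.data$bit_score), .data$subject_id,
            .by_group = TRUE) |>
    summarise(animal_evalue = first(.data$evalue),
              animal_subject_id = first(.data$subject_id),
              .groups = "drop")
  regions |>
    mutate(.rid = row_number()) |>
    left_join(best_animal, by = ".rid") |>
    select(-".rid") |>
    mutate(status = if_else(!is.na(.data$animal_evalue) &
                              .data$animal_evalue < .data$bact_evalue,
                            "excluded_conserved", "retained"))
}

#' Classify insertion age from identity and indel content
#'
#' @param pct_identity Percent identity of the candidate to its best
#'   bacterial hit, in (0, 100].
#' @param indel_events Number of indel events (gap openings) in that
#'   alignment.
#' @param policy An [age_policy()].
#' @return A character vector over `recent` / `degrading` / `intermediate`,
#'   vectorized over the inputs.
#' @export
classify_age <- function(pct_identity, indel_events, policy = age_policy()) {
  stopifnot(all(pct_identity > 0 & pct_identity <= 100))
  case_when(
    pct_identity >= policy$recent_min_identity ~ "recent",
    pct_identity <= policy$degrading_max_identity &
      indel_events >= policy$degrading_min_indels ~ "degrading",
    TRUE ~ "intermediate"
  )
}

#' Confirm insertion junctions across sequencing libraries
#'
#' A genuine integration (as opposed to assembly contamination) leaves read
#' pairs spanning both junctions between the insertion and its flanking host
#' sequence, reproducibly across independent sequencing libraries. A library
#' supports a candidate iff it has junction evidence within `window` bases of
#' either interval boundary; the candidate is confirmed iff at least
#' `min_libraries` distinct libraries support *each* boundary ("multiple
#' libraries" read as >= 2, the weakest faithful reading).
#'
#' @param candidates A tibble with `scaffold`, `start`, `end` (0-based
#'   half-open), e.g. the output of [screen_region()].
#' @param evidence A junction-evidence tibble (see [read_junctions()]).
#' @param min_libraries Libraries required at each boundary (default 2).
#' @param window Distance tolerance in bases (default 50).
#' @return `candidates` with columns `junction_libraries` (distinct
#'   supporting libraries at either boundary) and `junction_confirmed`.
#' @export
confirm_junctions <- function(candidates, evidence, min_libraries = 2L,
                              window = 50L) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) {
    return(mutate(candidates, junction_libraries = integer(),
                  junction_confirmed = logical()))
  }
  if (is.null(evidence) || nrow(evidence) == 0) {
    return(mutate(candidates, junction_libraries = 0L,
                  junction_confirmed = FALSE))
  }
  joined <- candidates |>
    mutate(.cid = row_number()) |>
    left_join(as_tibble(evidence), by = "scaffold",
              relationship = "many-to-many") |>
    mutate(near_left = !is.na(.data$position) &
             abs(.data$position - .data$start) <= window,
           near_right = !is.na(.data$position) &
             abs(.data$position - .data$end) <= window)
  support <- joined |>
    filter(.data$near_left | .data$near_right) |>
    group_by(.data$.cid) |>
    summarise(
      junction_libraries = n_distinct(.data$library_id),
      n_left = n_distinct(.data$library_id[.data$near_left]),
      n_right = n_distinct(.data$library_id[.data$near_right]),
      .groups = "drop") |>
    mutate(junction_confirmed = .data$n_left >= min_libraries &
             .data$n_right >= min_libraries)
  candidates |>
    mutate(.cid = row_number()) |>
    left_join(select(support, ".cid", "junction_libraries",
                     "junction_confirmed"),
              by = ".cid") |>
    select(-".cid") |>
    mutate(junction_libraries = tidyr::replace_na(.data$junction_libraries, 0L),
           junction_confirmed = tidyr::replace_na(.data$junction_confirmed, FALSE))
}

#' Nearest non-overlapping flanking gene on each side of a candidate
#'
#' Reports the eukaryotic gene context of each candidate: the nearest gene
#' ending at or before the interval start (left) and the nearest gene
#' starting at or after the interval end (right). Genes overlapping the
#' interval are not flanking genes; an absent side is `NA`.
#'
#' @param candidates A tibble with `scaffold`, `start`, `end` (0-based
#'   half-open).
#' @param genes A gene-model tibble (see [read_gff3()]).
#' @return `candidates` with columns `left_gene_id`, `right_gene_id`.
#' @export
flanking_genes <- function(candidates, genes) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) {
    return(mutate(candidates, left_gene_id = character(),
                  right_gene_id = character()))
  }
  if (is.null(genes) || nrow(genes) == 0) {
    return(mutate(candidates, left_gene_id = NA_character_,
                  right_gene_id = NA_character_))
  }
  genes <- as_tibble(genes)
  flank <- candidates |>
    mutate(.cid = row_number()) |>
    left_join(genes, by = "scaffold", suffix = c("", "_gene"),
              relationship = "many-to-many") |>
    group_by(.data$.cid) |>
    summarise(
      left_gene_id = {
        left <- .data$end_gene <= .data$start & !is.na(.data$gene_id)
        if (any(left)) .data$gene_id[left][which.max(.data$end_gene[left])]
        else NA_character_
      },
      right_gene_id = {
        right <- .data$start_gene >= .data$end & !is.na(.data$gene_id)
        if (any(right)) .data$gene_id[right][which.min(.data$start_gene[right])]
        else NA_character_
      },
      .groups = "drop")
  candidates |>
    mutate(.cid = row_number()) |>
    left_join(flank, by = ".cid") |>
    select(-".cid")
}

#' Run the full bacterial-to-eukaryote HGT screen
#'
#' Composes the screen end to end: significant bacterial hits are merged into
#' candidate regions ([find_bacterial_regions()]); each region is compared to
#' overlapping animal hits and excluded when the animal E-value beats the
#' bacterial one ([screen_region()]); the survivors are age-classified from
#' identity and indels ([classify_age()]), checked for junction support
#' across libraries ([confirm_junctions()]), and annotated with flanking
#' genes ([flanking_genes()]). Every retained candidate satisfies the screen
#' invariant: its bacterial E-value is significant and no overlapping animal
#' hit strictly beats it.
#'
#' Candidate expression is out of scope for the verdict; an optional
#' `expression_flags` lookup (named logical vector by region id) is attached
#' for reporting only.
#'
#' @param bacterial_hits,animal_hits Hit tibbles (scaffold-query
#'   coordinates).
#' @param junctions Junction evidence tibble, or `NULL`.
#' @param genes Gene-model tibble, or `NULL`.
#' @param policy A [homology_policy()] for the bacterial gate.
#' @param age An [age_policy()].
#' @param min_libraries,window Junction confirmation parameters.
#' @param gap Region-merge gap tolerance in bases.
#' @param expression_flags Optional named logical vector keyed by
#'   `candidate_id`, attached as an `expressed` column (reporting only).
#' @return A tibble of class `hgt_candidates`, one row per candidate region.
#' @export
screen_hgt <- function(bacterial_hits, animal_hits = NULL, junctions = NULL,
                       genes = NULL, policy = homology_policy(),
                       age = age_policy(), min_libraries = 2L, window = 50L,
                       gap = 0, expression_flags = NULL) {
  out <- find_bacterial_regions(bacterial_hits, policy, gap = gap) |>
    screen_region(animal_hits) |>
    confirm_junctions(junctions, min_libraries = min_libraries,
                      window = window) |>
    flanking_genes(genes)
  if (nrow(out) > 0) {
    out <- out |>
      mutate(age_class = classify_age(.data$pct_identity, .data$indel_events,
                                      age),
             candidate_id = sprintf("%s:%d-%d", .data$scaffold, .data$start,
                                    .data$end)) |>
      relocate("candidate_id")
    out$expressed <- if (is.null(expression_flags)) NA else
      unname(expression_flags[out$candidate_id])
    bad <- out$status == "retained" &
      !(is_significant(out$bact_evalue, policy) &
          (is.na(out$animal_evalue) | !(out$animal_evalue < out$bact_evalue)))
    stopifnot("retained candidate violates the screen invariant" = !any(bad))
  } else {
    out <- mutate(out, age_class = character(), candidate_id = character(),
                  expressed = logical())
  }
  class(out) <- c("hgt_candidates", class(out))
  out
}

#' Write an HGT candidate report
#'
#' @param candidates Output of [screen_hgt()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hgt_report <- function(candidates, path) {
  readr::write_tsv(as_tibble(candidates), path)
  invisible(path)
}
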