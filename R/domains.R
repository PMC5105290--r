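#' Expansion flagging policy
#'
#' A domain family is a potential expansion when the maximum per-species gene
#' count strictly exceeds `min_max_count` (default 5, i.e. "more than five
#' genes" in at least one species).
#'
#' @param min_max_count Strict lower bound on the maximum count (>= 1).
#' @return A list of class `expansion_policy`.
#' @export
expansion_policy <- function(min_max_count = 5L) {
  check_scalar(min_max_count, "min_max_count")
  if (min_max_count < 1) abort("`min_max_count` must be >= 1")
  structure(list(min_max_count = as.integer(min_max_count)),
            class = "expansion_policy")
}

#' Build a domain-by-species gene-count matrix
#'
#' Counts, for every (domain accession, species) cell, the number of genes of
#' that species matching the domain. Counting is gene-level: a gene with a
#' domain contributes exactly 1 to the cell regardless of how many times the
#' domain matches along the gene, so repeated annotation rows for one
#' (gene, domain) pair are deduplicated. Absent cells are 0 and every species
#' of the supplied list gets a column even without annotations.
#'
#' @param annotations A tibble with columns `gene_id`, `species_id`,
#'   `domain_acc` (and optionally `domain_name`), one row per
#'   gene-domain match.
#' @param species Character vector of all species under study, fixing the
#'   species order; must cover every annotation species.
#' @return A long tibble of class `domain_count_matrix` with columns
#'   `domain_acc`, `species_id` (factor in the supplied order), `n_genes`,
#'   complete over the domain x species grid.
#' @export
build_count_matrix <- function(annotations, species) {
  annotations <- as_tibble(annotations)
  extra <- setdiff(unique(annotations$species_id), species)
  if (length(extra) > 0) {
    abort(sprintf("annotation species '%s' is not in the species list", extra[1]))
  }
  out <- annotations |>
    distinct(.data$gene_id, .data$species_id, .data$domain_acc) |>
    mutate(species_id = factor(.data$species_id, levels = species)) |>
    count(.data$domain_acc, .data$species_id, .drop = FALSE, name = "n_genes")
  if (nrow(annotations) == 0) {
    out <- tibble(domain_acc = character(),
                  species_id = factor(character(), levels = species),
                  n_genes = integer())
  }
  class(out) <- c("domain_count_matrix", class(out))
  out
}

#' Pivot a domain count matrix to wide (one column per species)
#'
#' @param matrix A [build_count_matrix()] result.
#' @return A wide tibble, `domain_acc` plus one integer column per species.
#' @export
count_matrix_wide <- function(matrix) {
  as_tibble(matrix) |>
    tidyr::pivot_wider(names_from = "species_id", values_from = "n_genes",
                       names_expand = TRUE, values_fill = 0L)
}

#' Flag potentially expanded domain families
#'
#' Reports every domain whose maximum per-species gene count strictly exceeds
#' the policy threshold, together with the species attaining the maximum
#' (all tied species are listed, comma-separated). The report is invariant
#' under species reordering.
#'
#' @param matrix A [build_count_matrix()] result.
#' @param policy An [expansion_policy()].
#' @return A tibble (`domain_acc`, `max_species`, `max_count`), one row per
#'   flagged domain.
#' @export
flag_expansions <- function(matrix, policy = expansion_policy()) {
  as_tibble(matrix) |>
    group_by(.data$domain_acc) |>
    summarise(
      max_count = max(.data$n_genes),
      max_species = paste(sort(as.character(
        .data$species_id[.data$n_genes == max(.data$n_genes)])),
        collapse = ","),
      .groups = "drop") |>
    filter(.data$max_count > policy$min_max_count) |>
    select("domain_acc", "max_species", "max_count") |>
    arrange(.data$domain_acc)
}

#' Orthology status of the genes matching one domain
#'
#' For each species, every gene matching the domain lands in exactly one bin:
#' `single_copy` when it is the sole gene of its species in its orthologous
#' group, `multi_copy` when its OG holds more than one gene of that species,
#' and `homology_only` when the gene matches the domain but is not classified
#' in any OG. Bins sum to the species' domain gene count.
#'
#' @param domain_acc The domain accession to partition.
#' @param annotations Domain annotation tibble (`gene_id`, `species_id`,
#'   `domain_acc`).
#' @param table An [ortho_table()].
#' @param species Character vector fixing the species order (defaults to the
#'   table's species universe).
#' @return A tibble (`species_id`, `single_copy`, `multi_copy`,
#'   `homology_only`).
#' @export
orthology_status_partition <- function(domain_acc, annotations, table,
                                       species = table$species_universe) {
  stopifnot(inherits(table, "ortho_table"))
  acc <- domain_acc
  genes <- as_tibble(annotations) |>
    filter(.data$domain_acc == acc) |>
    distinct(.data$gene_id, .data$species_id)
  og_sp_counts <- table$memberships |>
    count(.data$og_id, .data$species_id, name = "n_in_og")
  status <- genes |>
    left_join(distinct(table$memberships, .data$gene_id, .data$og_id),
              by = "gene_id") |>
    left_join(og_sp_counts, by = c("og_id", "species_id")) |>
    mutate(bin = case_when(
      is.na(.data$og_id) ~ "homology_only",
      .data$n_in_og == 1L ~ "single_copy",
      TRUE ~ "multi_copy"
    ),
    bin = factor(.data$bin, levels = c("single_copy", "multi_copy",
                                       "homology_only")),
    species_id = factor(.data$species_id, levels = species)) |>
    count(.data$species_id, .data$bin, .drop = FALSE, name = "n") |>
    tidyr::pivot_wider(names_from = "bin", values_from = "n",
                       values_fill = 0L) |>
    mutate(species_id = as.character(.data$species_id))
  status
}

#' Focal-species enrichment over the non-focal mean
#'
#' The headline enrichment statistic of the cross-species comparison: the
#' focal species' gene count for a domain (or a summed group of accessions,
#' e.g. a subfamily group) divided by the mean count across all other
#' species. A zero non-focal mean with a positive focal count yields `Inf`
#' (flagged degenerate); 0/0 is undefined and reported as `NaN`.
#'
#' @param matrix A [build_count_matrix()] result.
#' @param domain_acc Character vector of one or more accessions; counts are
#'   summed over the group before the ratio is taken.
#' @param focal_species The focal species id.
#' @return A one-row tibble (`focal_species`, `focal_count`, `other_mean`,
#'   `ratio`, `degenerate`).
#' @export
enrichment_vs_mean <- function(matrix, domain_acc, focal_species) {
  df <- as_tibble(matrix) |>
    filter(.data$domain_acc %in% .env$domain_acc) |>
    group_by(.data$species_id, .drop = FALSE) |>
    summarise(n_genes = sum(.data$n_genes), .groups = "drop")
  if (!focal_species %in% df$species_id) {
    abort(sprintf("focal species '%s' is not in the matrix", focal_species))
  }
  focal <- sum(df$n_genes[df$species_id == focal_species])
  others <- df$n_genes[df$species_id != focal_species]
  if (length(others) == 0) abort("at least one non-focal species is required")
  other_mean <- mean(others)
  ratio <- if (other_mean == 0 && focal == 0) NaN else focal / other_mean
  tibble(focal_species = focal_species, focal_count = focal,
         other_mean = other_mean, ratio = ratio,
         degenerate = other_mean == 0)
}

#' Built-in glycoside hydrolase family-to-accession mapping
#'
#' An editable starting point for grouping InterPro accessions into the
#' plant-cell-wall-degrading glycoside hydrolase (GH) families most often
#' compared across phytophagous insects. Supply any subset of its
#' `domain_acc` values to [enrichment_vs_mean()] to analyse a family group;
#' the shipped file (`extdata/gh_family_domains.tsv`) can be copied and
#' extended for other gene families.
#'
#' @return A tibble (`family`, `domain_acc`, `domain_name`).
#' @export
gh_family_domains <- function() {
  readr::read_tsv(system.file("extdata", "gh_family_domains.tsv",
                              package = "phytophagr"),
                  col_types = "ccc", progress = FALSE)
}

#' Write a domain count matrix and expansion report
#'
#' @param matrix A [build_count_matrix()] result.
#' @param path Output TSV path (wide orientation, one column per species).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path) {
  readr::write_tsv(count_matrix_wide(matrix), path)
  invisible(path)
}
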