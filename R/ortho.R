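#' Orthologous-group membership table
#'
#' The substrate of the three-set orthology classification: a set of
#' (orthologous group, species, gene) membership triples together with the
#' universe of species under study. Each gene may belong to at most one
#' orthologous group (OG) -- the per-gene classification assigns exactly one
#' category per gene, which a multi-OG gene would break -- and every species
#' appearing in a membership must belong to the universe.
#'
#' @param memberships A tibble/data frame with columns `og_id`, `species_id`,
#'   `gene_id`.
#' @param species_universe Optional character vector of all species under
#'   study (defaults to the species present in `memberships`). Species may be
#'   in the universe without any memberships.
#' @param gene_lengths Optional named numeric vector mapping gene ids to
#'   lengths in bases (carried, not used by the classification).
#' @return A list of class `ortho_table` with elements `memberships`,
#'   `species_universe`, `gene_lengths`.
#' @export
ortho_table <- function(memberships, species_universe = NULL,
                        gene_lengths = NULL) {
  memberships <- as_tibble(memberships)[c("og_id", "species_id", "gene_id")]
  memberships <- distinct(memberships)
  ogs_per_gene <- memberships |>
    distinct(.data$og_id, .data$gene_id) |>
    count(.data$gene_id)
  bad <- ogs_per_gene$gene_id[ogs_per_gene$n > 1]
  if (length(bad) > 0) {
    format_error(sprintf(
      "gene '%s' is assigned to %d orthologous groups; each gene may belong to at most one",
      bad[1], ogs_per_gene$n[ogs_per_gene$gene_id == bad[1]][1]))
  }
  species_universe <- sort(unique(c(species_universe,
                                    unique(memberships$species_id))))
  structure(list(memberships = memberships,
                 species_universe = species_universe,
                 gene_lengths = gene_lengths),
            class = "ortho_table")
}

#' @export
print.ortho_table <- function(x, ...) {
  cat(sprintf("<ortho_table> %d memberships, %d OGs, %d genes, %d species\n",
              nrow(x$memberships), n_distinct(x$memberships$og_id),
              n_distinct(x$memberships$gene_id), length(x$species_universe)))
  invisible(x)
}

#' Partition of the species universe into three sets
#'
#' The comparative design partitions the species under study into three
#' disjoint sets whose union is the whole universe; the default configuration
#' is three sets of five (Coleoptera; Lepidoptera/Diptera; outgroup insects).
#'
#' @param sets A named list of three character vectors of species ids; names
#'   are the set labels, in order.
#' @return A list of class `species_partition`.
#' @seealso [default_species_partition()]
#' @export
species_partition <- function(sets) {
  if (!is.list(sets) || length(sets) != 3 || is.null(names(sets)) ||
      any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list of three character vectors")
  }
  all_sp <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_sp)) {
    abort(sprintf("species sets must be disjoint ('%s' appears twice)",
                  all_sp[duplicated(all_sp)][1]))
  }
  structure(list(sets = sets, labels = names(sets)),
            class = "species_partition")
}

#' Default 15-species, three-set partition
#'
#' Five Coleoptera, five Lepidoptera/Diptera, and five outgroup insect
#' species, named by conventional 5-letter genome codes.
#'
#' @return A [species_partition()].
#' @export
default_species_partition <- function() {
  species_partition(list(
    coleoptera = c("AGLAB", "APLAN", "DPOND", "OTAUR", "TCAST"),
    lep_dip = c("AGAMB", "DMELA", "DPLEX", "MDEST", "PXYLO"),
    outgroup = c("AMELL", "APISU", "NVITR", "PHUMA", "ZNEVA")
  ))
}

#' Partition counting policy
#'
#' An OG "counts" in a species set iff it contains genes from at least
#' `min_species_per_set` distinct species of that set; the default 2 is the
#' standard sharing requirement of the three-set design.
#'
#' @param min_species_per_set Minimum distinct species per set (>= 1).
#' @return A list of class `partition_policy`.
#' @export
partition_policy <- function(min_species_per_set = 2L) {
  check_scalar(min_species_per_set, "min_species_per_set")
  if (min_species_per_set < 1) abort("`min_species_per_set` must be >= 1")
  structure(list(min_species_per_set = as.integer(min_species_per_set)),
            class = "partition_policy")
}

species_to_set <- function(partition) {
  tibble(
    species_id = unlist(partition$sets, use.names = FALSE),
    set_label = rep(partition$labels, lengths(partition$sets))
  )
}

#' Span of one orthologous group across the species sets
#'
#' Labels an OG by how many species sets it "counts" in: `three_set` (genes
#' from all three sets), `two_set`, `one_set`, or `unshared` (no set reaches
#' the per-set species threshold).
#'
#' @param species_ids Character vector of the species with genes in the OG
#'   (repeats allowed; distinct species are what count).
#' @param partition A [species_partition()].
#' @param policy A [partition_policy()].
#' @return One of `"three_set"`, `"two_set"`, `"one_set"`, `"unshared"`.
#' @export
og_span <- function(species_ids, partition, policy = partition_policy()) {
  if (length(species_ids) == 0) abort("og_span: empty orthologous group")
  sp <- unique(species_ids)
  counting <- sum(vapply(partition$sets,
                         function(set) sum(sp %in% set) >= policy$min_species_per_set,
                         logical(1)))
  c("unshared", "one_set", "two_set", "three_set")[counting + 1L]
}

# Vectorized span labelling for all OGs of a table.
og_spans <- function(table, partition, policy = partition_policy()) {
  lookup <- species_to_set(partition)
  missing_sp <- setdiff(table$species_universe, lookup$species_id)
  if (length(missing_sp) > 0) {
    abort(sprintf("species '%s' is in the universe but in no partition set",
                  missing_sp[1]))
  }
  table$memberships |>
    distinct(.data$og_id, .data$species_id) |>
    left_join(lookup, by = "species_id") |>
    group_by(.data$og_id, .data$set_label) |>
    summarise(n_species = n(), .groups = "drop") |>
    group_by(.data$og_id) |>
    summarise(n_counting = sum(.data$n_species >= policy$min_species_per_set),
              .groups = "drop") |>
    mutate(span = c("unshared", "one_set", "two_set",
                    "three_set")[.data$n_counting + 1L]) |>
    select("og_id", "span")
}

gene_categories <- c("universal_single", "universal_multi", "two_set",
                     "set_restricted_ortholog", "arthropod_homolog",
                     "self_homolog", "unique")

#' Classify every gene into one conservation category
#'
#' The per-gene classification of the three-set design. Genes in OGs spanning
#' all three sets are `universal_single` when their species has exactly one
#' gene in the OG, else `universal_multi` (together these form the derived
#' "widespread" super-class, see [summarize_partition()]). Genes in two-set
#' OGs are `two_set`; genes in one-set OGs are `set_restricted_ortholog`.
#' Genes in no OG -- or in OGs where no set reaches the sharing threshold --
#' fall through to the homology fallbacks: `arthropod_homolog` when they have
#' a significant hit to any other arthropod gene, else `self_homolog` when
#' they have a significant hit to a *different* gene of their own genome
#' (a gene's trivial hit to itself never counts), else `unique`. A gene with
#' both fallback hit kinds is `arthropod_homolog`. Categories are mutually
#' exclusive and exhaustive.
#'
#' @param table An [ortho_table()].
#' @param partition A [species_partition()].
#' @param policy A [partition_policy()].
#' @param arthropod_hits,self_hits Hit tibbles (see [read_tabular_hits()])
#'   whose queries are genes of this study; may be `NULL` for none.
#' @param hpolicy A [homology_policy()] applied to both hit sets.
#' @param genes Optional tibble (`gene_id`, `species_id`) enumerating the
#'   annotated genes of every species; defaults to the genes present in
#'   `table`. Genes listed here but absent from any OG are classified via
#'   the fallbacks.
#' @return A tibble (`gene_id`, `species_id`, `og_id`, `category`) with one
#'   row per gene; `og_id` is `NA` for genes without an OG.
#' @export
classify_genes <- function(table, partition, policy = partition_policy(),
                           arthropod_hits = NULL, self_hits = NULL,
                           hpolicy = homology_policy(), genes = NULL) {
  stopifnot(inherits(table, "ortho_table"))
  member_genes <- table$memberships |>
    distinct(.data$gene_id, .data$species_id, .data$og_id)
  if (is.null(genes)) {
    genes <- member_genes |> distinct(.data$gene_id, .data$species_id)
  } else {
    genes <- as_tibble(genes) |> distinct(.data$gene_id, .data$species_id)
    missing <- anti_join(member_genes, genes, by = c("gene_id", "species_id"))
    if (nrow(missing) > 0) {
      abort(sprintf("`genes` must cover every gene of the table ('%s' missing)",
                    missing$gene_id[1]))
    }
  }
  spans <- og_spans(table, partition, policy)

  # per-(OG, species) gene counts decide single vs multi copy
  og_sp_counts <- member_genes |>
    count(.data$og_id, .data$species_id, name = "n_in_og")

  classified <- genes |>
    left_join(member_genes, by = c("gene_id", "species_id")) |>
    left_join(spans, by = "og_id") |>
    left_join(og_sp_counts, by = c("og_id", "species_id"))

  orthologous <- classified |>
    filter(!is.na(.data$span) & .data$span != "unshared") |>
    mutate(category = case_when(
      span == "three_set" & n_in_og == 1L ~ "universal_single",
      span == "three_set" ~ "universal_multi",
      span == "two_set" ~ "two_set",
      span == "one_set" ~ "set_restricted_ortholog"
    ))

  fallback <- classified |>
    filter(is.na(.data$span) | .data$span == "unshared")
  if (nrow(fallback) > 0) {
    arth_q <- significant_queries(arthropod_hits, hpolicy)
    self_q <- significant_queries(self_hits, hpolicy)
    fallback <- fallback |>
      mutate(category = case_when(
        gene_id %in% arth_q ~ "arthropod_homolog",
        gene_id %in% self_q ~ "self_homolog",
        TRUE ~ "unique"
      ))
  } else {
    fallback <- mutate(fallback, category = character())
  }

  bind_rows(orthologous, fallback) |>
    mutate(category = factor(.data$category, levels = gene_categories)) |>
    select("gene_id", "species_id", "og_id", "category") |>
    arrange(.data$species_id, .data$gene_id)
}

# Queries with at least one significant non-self hit.
significant_queries <- function(hits, hpolicy) {
  if (is.null(hits) || nrow(hits) == 0) return(character())
  hits <- as_tibble(hits)
  hits |>
    filter(is_significant(hits, hpolicy),
           .data$subject_id != .data$query_id) |>
    pull(.data$query_id) |>
    unique()
}

#' Summarize a gene classification per species and per OG span
#'
#' Tabulates per-species category counts (rows sum to each species' total
#' gene count) and OG-level span counts (summing to the total OG count).
#' Two derived super-class columns accompany the species table: `widespread`,
#' the universal_single + universal_multi total over three-set OGs, and
#' `universal_core`, the genes in OGs containing every species of the
#' universe -- the two standard headline views of conservation breadth.
#'
#' @param categories Output of [classify_genes()], covering every gene of the
#'   table.
#' @param table The [ortho_table()] that was classified.
#' @param partition A [species_partition()].
#' @param policy A [partition_policy()].
#' @return A list of class `ortho_summary` with tibbles `species` (species x
#'   category counts, wide), `og` (span counts), and `superclass` (derived
#'   widespread / universal-core gene counts per species).
#' @export
summarize_partition <- function(categories, table, partition,
                                policy = partition_policy()) {
  stopifnot(inherits(table, "ortho_table"))
  table_genes <- distinct(table$memberships, .data$gene_id)
  uncovered <- anti_join(table_genes, categories, by = "gene_id")
  if (nrow(uncovered) > 0) {
    abort(sprintf("categories do not cover gene '%s'", uncovered$gene_id[1]))
  }

  species_long <- categories |>
    mutate(species_id = factor(.data$species_id,
                               levels = sort(unique(c(table$species_universe,
                                                      unique(categories$species_id)))))) |>
    count(.data$species_id, .data$category, .drop = FALSE, name = "n_genes")
  species_wide <- species_long |>
    tidyr::pivot_wider(names_from = "category", values_from = "n_genes",
                       values_fill = 0L) |>
    mutate(species_id = as.character(.data$species_id)) |>
    mutate(total = rowSums(across(dplyr::all_of(gene_categories))))

  spans <- og_spans(table, partition, policy)
  og_summary <- spans |>
    mutate(span = factor(.data$span, levels = c("three_set", "two_set",
                                                "one_set", "unshared"))) |>
    count(.data$span, .drop = FALSE, name = "n_ogs")

  core_ogs <- table$memberships |>
    distinct(.data$og_id, .data$species_id) |>
    count(.data$og_id, name = "n_species") |>
    filter(.data$n_species == length(table$species_universe)) |>
    pull(.data$og_id)
  core_counts <- table$memberships |>
    filter(.data$og_id %in% core_ogs) |>
    count(.data$species_id, name = "universal_core")

  superclass <- species_wide |>
    mutate(widespread = .data$universal_single + .data$universal_multi) |>
    select("species_id", "widespread") |>
    left_join(core_counts, by = "species_id") |>
    mutate(universal_core = tidyr::replace_na(.data$universal_core, 0L))

  structure(list(species = species_wide, og = og_summary,
                 superclass = superclass),
            class = "ortho_summary")
}

#' @export
print.ortho_summary <- function(x, ...) {
  cat("<ortho_summary>\nPer-species category counts:\n")
  print(x$species)
  cat("\nOG span counts:\n")
  print(x$og)
  invisible(x)
}

#' Single- versus multi-copy ortholog counts over shared OGs
#'
#' For each species, sums gene counts over all three-set ("shared") OGs
#' containing it: an OG contributes its per-species gene count to the
#' single-copy column when that count is 1 and to the multi-copy column when
#' it exceeds 1. Counts are gene counts, not OG counts.
#'
#' @inheritParams classify_genes
#' @return A tibble (`species_id`, `single_copy`, `multi_copy`) covering the
#'   whole species universe.
#' @export
copy_number_split <- function(table, partition, policy = partition_policy()) {
  stopifnot(inherits(table, "ortho_table"))
  spans <- og_spans(table, partition, policy)
  shared <- spans$og_id[spans$span == "three_set"]
  counts <- table$memberships |>
    filter(.data$og_id %in% shared) |>
    count(.data$og_id, .data$species_id, name = "n_in_og") |>
    group_by(.data$species_id) |>
    summarise(single_copy = sum(.data$n_in_og[.data$n_in_og == 1L]),
              multi_copy = sum(.data$n_in_og[.data$n_in_og > 1L]),
              .groups = "drop")
  tibble(species_id = table$species_universe) |>
    left_join(counts, by = "species_id") |>
    mutate(single_copy = as.integer(tidyr::replace_na(.data$single_copy, 0L)),
           multi_copy = as.integer(tidyr::replace_na(.data$multi_copy, 0L)))
}
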