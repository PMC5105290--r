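#' Default 15-species tree for family simulation
#'
#' A stylized ultrametric-ish topology over the default three-set species
#' partition (five Coleoptera, five Lepidoptera/Diptera, five outgroup
#' insects), with branch lengths on the scale of expected events per unit
#' rate. Tip labels match [default_species_partition()].
#'
#' @return An `ape` `phylo` object.
#' @export
default_species_tree <- function() {
  nwk <- paste0(
    "(((((AGLAB:0.2,DPOND:0.2):0.15,(TCAST:0.25,OTAUR:0.25):0.1):0.1,",
    "APLAN:0.45):0.25,((PXYLO:0.25,DPLEX:0.25):0.2,((DMELA:0.25,",
    "AGAMB:0.25):0.1,MDEST:0.35):0.1):0.25):0.15,((AMELL:0.35,",
    "NVITR:0.35):0.15,(APISU:0.4,(PHUMA:0.35,ZNEVA:0.35):0.05):0.1):0.2);")
  ape::read.tree(text = nwk)
}

#' Simulate gene families by duplication and loss on a species tree
#'
#' Each family starts with one copy at the root. Along every branch of
#' length `t`, each incoming copy is first lost with probability
#' `1 - exp(-loss_rate * t)`; each survivor then duplicates (gaining one
#' extra copy) with probability `1 - exp(-dup_rate * t)`. Copies surviving to
#' the leaves become genes, and a family's orthologous group is its leaf
#' genes. Ground-truth conservation categories are computed directly from
#' the realized presence pattern (never by the classifier under test): a
#' family's span over the species sets follows the same >= 2 species-per-set
#' counting rule, and genes of families below the sharing threshold
#' everywhere are labelled `arthropod_homolog` when the family survives in
#' another species, `self_homolog` when only same-species paralogs remain,
#' and `unique` when the gene is the family's sole survivor.
#'
#' Perfect homology fallback files accompany the table: every gene of an
#' unshared family gets a significant hit to a surviving family member in
#' another species (arthropod file) and to each same-species paralog (self
#' file), which is exactly the evidence an oracle homology search would
#' return.
#'
#' @param n_families Number of families to simulate (>= 1).
#' @param tree An `ape` `phylo` tree or a Newick string; default
#'   [default_species_tree()].
#' @param dup_rate,loss_rate Non-negative event rates per unit branch
#'   length.
#' @param partition A [species_partition()] used for the truth labels.
#' @param policy A [partition_policy()] used for the truth labels.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `table` (an [ortho_table()]), `truth` (tibble
#'   `gene_id`, `species_id`, `og_id`, `category`), `arthropod_hits`,
#'   `self_hits` (hit tibbles), and `tree`.
#' @export
simulate_gene_families <- function(n_families, tree = default_species_tree(),
                                   dup_rate = 0.1, loss_rate = 0.1,
                                   partition = default_species_partition(),
                                   policy = partition_policy(), seed = 1L) {
  if (n_families < 1) abort("`n_families` must be >= 1")
  if (dup_rate < 0 || loss_rate < 0) abort("rates must be >= 0")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  withr::with_seed(seed, {
    # cladewise edge order walks root-to-tip, so each edge's parent count
    # is final before the edge is drawn
    tree_cw <- ape::reorder.phylo(tree, "cladewise")
    n_nodes <- max(tree$edge)
    copies <- matrix(0L, nrow = n_families, ncol = n_nodes)
    root <- ntip + 1L
    copies[, root] <- 1L
    for (e in seq_len(nrow(tree_cw$edge))) {
      parent <- tree_cw$edge[e, 1]
      child <- tree_cw$edge[e, 2]
      t_br <- tree_cw$edge.length[e]
      n_in <- copies[, parent]
      surv <- rbinom(n_families, n_in, exp(-loss_rate * t_br))
      dup <- rbinom(n_families, surv, 1 - exp(-dup_rate * t_br))
      copies[, child] <- surv + dup
    }
    leaf_counts <- copies[, seq_len(ntip), drop = FALSE]
    colnames(leaf_counts) <- tree$tip.label

    fam_ids <- sprintf("OG%05d", seq_len(n_families))
    long <- tibble(
      og_id = rep(fam_ids, times = ntip),
      species_id = rep(tree$tip.label, each = n_families),
      n_copies = as.integer(leaf_counts)
    ) |>
      filter(.data$n_copies > 0)
    memberships <- long |>
      mutate(reps = purrr::map(.data$n_copies, seq_len)) |>
      tidyr::unnest("reps") |>
      mutate(gene_id = sprintf("%s_%s_g%d", .data$species_id, .data$og_id,
                               .data$reps)) |>
      select("og_id", "species_id", "gene_id")

    truth <- family_truth(memberships, tree$tip.label, partition, policy)
    hits <- perfect_fallback_hits(memberships, truth)
    table <- ortho_table(memberships, species_universe = tree$tip.label)
    list(table = table, truth = truth,
         arthropod_hits = hits$arthropod, self_hits = hits$self,
         genes = distinct(memberships, .data$gene_id, .data$species_id),
         tree = tree)
  })
}

# Truth categories by definition from the realized membership pattern.
family_truth <- function(memberships, tip_labels, partition, policy) {
  lookup <- species_to_set(partition)
  fam_set_counts <- memberships |>
    distinct(.data$og_id, .data$species_id) |>
    left_join(lookup, by = "species_id") |>
    count(.data$og_id, .data$set_label, name = "n_species")
  spans <- fam_set_counts |>
    group_by(.data$og_id) |>
    summarise(n_counting = sum(.data$n_species >= policy$min_species_per_set),
              .groups = "drop") |>
    mutate(span = c("unshared", "one_set", "two_set",
                    "three_set")[.data$n_counting + 1L])
  fam_stats <- memberships |>
    group_by(.data$og_id) |>
    summarise(n_species_total = n_distinct(.data$species_id),
              .groups = "drop")
  per_sp <- memberships |> count(.data$og_id, .data$species_id,
                                 name = "n_in_og")
  memberships |>
    left_join(spans, by = "og_id") |>
    left_join(fam_stats, by = "og_id") |>
    left_join(per_sp, by = c("og_id", "species_id")) |>
    mutate(category = case_when(
      span == "three_set" & n_in_og == 1L ~ "universal_single",
      span == "three_set" ~ "universal_multi",
      span == "two_set" ~ "two_set",
      span == "one_set" ~ "set_restricted_ortholog",
      n_species_total > 1L ~ "arthropod_homolog",
      n_in_og > 1L ~ "self_homolog",
      TRUE ~ "unique"
    )) |>
    select("gene_id", "species_id", "og_id", "category")
}

# Oracle homology evidence for genes of unshared families.
perfect_fallback_hits <- function(memberships, truth) {
  unshared <- truth |>
    filter(.data$category %in% c("arthropod_homolog", "self_homolog",
                                 "unique"))
  members <- memberships |>
    semi_join(unshared, by = "og_id")
  pairs <- members |>
    inner_join(members, by = "og_id", suffix = c("", "_subj"),
               relationship = "many-to-many") |>
    filter(.data$gene_id != .data$gene_id_subj)
  arth <- pairs |>
    filter(.data$species_id != .data$species_id_subj) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup()
  self <- pairs |>
    filter(.data$species_id == .data$species_id_subj) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup()
  list(arthropod = oracle_hit_rows(arth, "arthropod"),
       self = oracle_hit_rows(self, "self"))
}

oracle_hit_rows <- function(pairs, subject_db) {
  if (nrow(pairs) == 0) return(empty_hits())
  tibble(
    query_id = pairs$gene_id, subject_id = pairs$gene_id_subj,
    pct_identity = 90, aln_length = 500L, mismatches = 50L,
    gap_openings = 0L, q_start = 1L, q_end = 500L, s_start = 1L,
    s_end = 500L, evalue = 1e-30, bit_score = 200,
    subject_db = subject_db
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate a sequence with per-site substitutions and indels, tracking the
# implied alignment to the original: realized identity is matches over
# aligned columns (gap columns count as non-matches), indel_events counts
# events (not bases).
mutate_seq <- function(seq, divergence, indel_rate = 0, indel_geom_p = NULL) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  sub_at <- runif(n) < divergence
  if (any(sub_at)) {
    bases[sub_at] <- vapply(bases[sub_at], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  n_cols <- n
  n_del_bases <- 0L
  n_ins_bases <- 0L
  indel_events <- 0L
  keep <- rep(TRUE, n)
  insertions <- vector("list", n)
  if (indel_rate > 0) {
    ev_at <- which(runif(n) < indel_rate)
    for (i in ev_at) {
      len <- if (is.null(indel_geom_p)) 1L else rgeom(1, indel_geom_p) + 1L
      if (runif(1) < 0.5) {                      # deletion
        drop <- i:min(n, i + len - 1L)
        drop <- drop[keep[drop]]
        if (length(drop) == 0) next
        keep[drop] <- FALSE
        n_del_bases <- n_del_bases + length(drop)
      } else {                                   # insertion after site i
        insertions[[i]] <- c(insertions[[i]],
                             sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE))
        n_ins_bases <- n_ins_bases + len
      }
      indel_events <- indel_events + 1L
    }
  }
  pieces <- lapply(seq_len(n), function(i) {
    c(if (keep[i]) bases[i] else character(0), insertions[[i]])
  })
  out <- paste(unlist(pieces), collapse = "")
  matches <- sum(keep & !sub_at)
  columns <- n + n_ins_bases
  list(seq = out, identity = 100 * matches / columns,
       indel_events = indel_events)
}

#' Simulate a host genome with planted bacterial insertions
#'
#' Builds a uniform-random host scaffold and plants `n_insertions` diverged
#' copies of random bacterial source segments into it, each mutated at
#' per-site substitution probability `divergence` and (optionally) per-site
#' indel probability `indel_rate` (single-base indels by default, geometric
#' lengths when `indel_geom_p` is set). The realized identity of each
#' insertion is recomputed from the construction alignment, never assumed.
#' Junction-spanning evidence is emitted for every insertion at both
#' boundaries in all `n_libraries` libraries. Decoy "conserved genes" --
#' host segments whose exact copy is placed in the animal database and a
#' more diverged copy in the bacterial database, so the animal hit always
#' out-scores the bacterial one -- exercise the conserved-gene exclusion.
#' A window table covering every planted locus and decoy (plus `flank`
#' bases each side) supports desk-scale aligner runs.
#'
#' Planted loci are placed by rejection sampling with a minimum separation;
#' placement fails with an error after 1000 attempts.
#'
#' @param host_length Background host length in bases.
#' @param n_insertions Number of planted insertions.
#' @param insertion_length Length of each bacterial source segment.
#' @param divergence Per-site substitution probability in \[0, 0.5\].
#' @param indel_rate Per-site indel event probability.
#' @param indel_geom_p Geometric length parameter for indels (`NULL` =
#'   single-base).
#' @param n_libraries Sequencing libraries with junction evidence.
#' @param n_decoys Number of decoy conserved-gene segments.
#' @param decoy_length Length of each decoy segment.
#' @param decoy_divergence Divergence of the decoy's bacterial-database copy.
#' @param flank Window flank in bases.
#' @param seed Integer seed.
#' @return A list with `genome`, `bacterial_db`, `animal_db` (FASTA-ready
#'   tibbles), `truth` (planted intervals with realized identity and indel
#'   events), `decoys`, `junctions`, and `windows`.
#' @export
simulate_hgt_genome <- function(host_length = 1e6, n_insertions = 50,
                                insertion_length = 2000, divergence = 0.05,
                                indel_rate = 0, indel_geom_p = NULL,
                                n_libraries = 3, n_decoys = 10,
                                decoy_length = 1500, decoy_divergence = 0.12,
                                flank = 500, seed = 1L) {
  if (divergence < 0 || divergence > 0.5) abort("`divergence` must be in [0, 0.5]")
  n_loci <- n_insertions + n_decoys
  min_sep <- max(insertion_length, decoy_length) + 2 * flank + 100
  if (n_loci * min_sep > host_length - 2 * flank) {
    abort("insertions do not fit inside the host at the required separation")
  }
  withr::with_seed(seed, {
    host <- random_dna(host_length)

    # place loci one at a time, re-drawing any that would overlap an
    # accepted locus (with its separation margin)
    accepted <- integer(0)
    attempts <- 0L
    while (length(accepted) < n_loci) {
      attempts <- attempts + 1L
      if (attempts > 1000L * n_loci) {
        abort("failed to place non-overlapping insertions after 1000 attempts")
      }
      p <- sample.int(host_length - min_sep - flank, 1L) + flank
      if (all(abs(accepted - p) >= min_sep)) accepted <- c(accepted, p)
    }
    points <- sort(accepted)
    which_ins <- sort(sample(seq_len(n_loci), n_insertions))
    ins_points <- points[which_ins]
    dec_points <- points[-which_ins]

    sources <- tibble(
      id = sprintf("BACT_SRC%02d", seq_len(n_insertions)),
      seq = purrr::map_chr(seq_len(n_insertions),
                           ~ random_dna(insertion_length))
    )
    mut <- purrr::map(sources$seq, mutate_seq, divergence = divergence,
                      indel_rate = indel_rate, indel_geom_p = indel_geom_p)
    ins_seqs <- purrr::map_chr(mut, "seq")
    ins_lens <- nchar(ins_seqs)

    # decoy segments are host sequence in [p, p + decoy_length)
    dec_seqs <- purrr::map_chr(dec_points, function(p) {
      substr(host, p + 1, p + decoy_length)
    })

    # final coordinates: each insertion shifts everything after its point
    shift_before <- function(pos) {
      if (n_insertions == 0) return(rep(0L, length(pos)))
      vapply(pos, function(p) sum(ins_lens[ins_points <= p]), numeric(1))
    }
    ins_starts <- ins_points + c(0, cumsum(ins_lens))[seq_len(n_insertions)]
    ins_ends <- ins_starts + ins_lens

    pieces <- character(2 * n_insertions + 1)
    prev <- 0
    for (i in seq_len(n_insertions)) {
      pieces[2 * i - 1] <- substr(host, prev + 1, ins_points[i])
      pieces[2 * i] <- ins_seqs[i]
      prev <- ins_points[i]
    }
    pieces[2 * n_insertions + 1] <- substr(host, prev + 1, host_length)
    genome_seq <- paste(pieces, collapse = "")

    truth <- tibble(
      insertion_id = sprintf("INS%02d", seq_len(n_insertions)),
      source_id = sources$id,
      scaffold = "scaf1",
      start = as.integer(ins_starts),
      end = as.integer(ins_ends),
      true_identity = purrr::map_dbl(mut, "identity"),
      indel_events = purrr::map_int(mut, ~ as.integer(.x$indel_events)),
      divergence = divergence
    )

    dec_starts <- dec_points + shift_before(dec_points)
    decoys <- tibble(
      decoy_id = sprintf("DECOY%02d", seq_len(n_decoys)),
      scaffold = "scaf1",
      start = as.integer(dec_starts),
      end = as.integer(dec_starts + decoy_length)
    )
    dec_bact <- purrr::map(dec_seqs, mutate_seq, divergence = decoy_divergence)

    bacterial_db <- bind_rows(
      sources,
      tibble(id = paste0(decoys$decoy_id, "_bact"),
             seq = purrr::map_chr(dec_bact, "seq"))
    )
    animal_db <- tibble(id = paste0(decoys$decoy_id, "_animal"),
                        seq = dec_seqs)

    junctions <- tidyr::expand_grid(
      insertion_id = truth$insertion_id,
      library_id = sprintf("L%d", seq_len(n_libraries)),
      side = c("left", "right")
    ) |>
      left_join(select(truth, "insertion_id", "scaffold", "start", "end"),
                by = "insertion_id") |>
      mutate(position = if_else(.data$side == "left", .data$start, .data$end),
             supporting_pairs = sample(3:10, n(), replace = TRUE)) |>
      select("scaffold", "position", "library_id", "supporting_pairs")

    windows <- bind_rows(
      tibble(window_id = paste0("W_", truth$insertion_id), kind = "insertion",
             scaffold = "scaf1",
             start = pmax(0L, truth$start - as.integer(flank)),
             end = pmin(nchar(genome_seq), truth$end + as.integer(flank))),
      tibble(window_id = paste0("W_", decoys$decoy_id), kind = "decoy",
             scaffold = "scaf1",
             start = pmax(0L, decoys$start - as.integer(flank)),
             end = pmin(nchar(genome_seq), decoys$end + as.integer(flank)))
    )

    list(genome = tibble(id = "scaf1", seq = genome_seq),
         bacterial_db = bacterial_db, animal_db = animal_db,
         truth = truth, decoys = decoys, junctions = junctions,
         windows = windows)
  })
}

#' Simulate per-species domain annotations with planted expansions
#'
#' Background gene counts for every (domain, species) cell are drawn
#' uniformly on `0..background_max`; planted cells are set exactly to the
#' requested counts, which must exceed `background_max`.
#'
#' @param species Character vector of species ids.
#' @param n_domains Number of background domain accessions.
#' @param planted A tibble (`domain_acc`, `species_id`, `n_genes`) of
#'   planted expansions, or `NULL`.
#' @param background_max Maximum background count per cell.
#' @param seed Integer seed.
#' @return A list with `annotations` (tibble `gene_id`, `species_id`,
#'   `domain_acc`, `domain_name`) and `truth` (the planted tibble).
#' @export
simulate_domain_annotations <- function(species, n_domains = 20,
                                        planted = NULL, background_max = 2,
                                        seed = 1L) {
  planted <- if (is.null(planted)) {
    tibble(domain_acc = character(), species_id = character(),
           n_genes = integer())
  } else as_tibble(planted)
  if (nrow(planted) > 0) {
    bad <- setdiff(planted$species_id, species)
    if (length(bad) > 0) {
      abort(sprintf("planted species '%s' is not in the species list", bad[1]))
    }
    if (any(planted$n_genes <= background_max)) {
      abort("planted counts must exceed `background_max`")
    }
  }
  withr::with_seed(seed, {
    accs <- sprintf("IPR%06d", seq_len(n_domains))
    accs <- union(accs, planted$domain_acc)
    grid <- tidyr::expand_grid(domain_acc = accs, species_id = species) |>
      mutate(n_genes = sample(0:background_max, n(), replace = TRUE)) |>
      left_join(rename(planted, planted_n = "n_genes"),
                by = c("domain_acc", "species_id")) |>
      mutate(n_genes = if_else(!is.na(.data$planted_n),
                               as.integer(.data$planted_n),
                               as.integer(.data$n_genes))) |>
      select(-"planted_n")
    annotations <- grid |>
      filter(.data$n_genes > 0) |>
      mutate(reps = purrr::map(.data$n_genes, seq_len)) |>
      tidyr::unnest("reps") |>
      mutate(gene_id = sprintf("%s_%s_g%d", .data$species_id,
                               .data$domain_acc, .data$reps),
             domain_name = paste0("domain ", .data$domain_acc)) |>
      select("gene_id", "species_id", "domain_acc", "domain_name")
    list(annotations = annotations, truth = planted)
  })
}

#' Simulate a two-condition negative-binomial count matrix
#'
#' Counts are drawn negative-binomially with per-condition means
#' `mu * 2^(+logfc/2)` (treatment) and `mu * 2^(-logfc/2)` (control) and
#' variance `mu + dispersion * mu^2`; `dispersion = 0` degenerates to
#' Poisson. Replicate structure defaults to 4 + 4, the standard small
#' larval feeding-assay design. A gene's truth label is `true_logfc != 0`.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per condition (default 4).
#' @param baseline_mean Baseline mean count per gene (scalar or length
#'   `n_genes`).
#' @param dispersion Negative-binomial dispersion (>= 0).
#' @param true_logfc True log2 fold change per gene (scalar or length
#'   `n_genes`).
#' @param seed Integer seed.
#' @return A list with `counts` (tibble `gene_id` + sample columns),
#'   `conditions` (tibble `sample_id`, `condition`), and `truth` (tibble
#'   `gene_id`, `true_logfc`, `is_de`).
#' @export
simulate_counts <- function(n_genes = 2000, n_reps = 4, baseline_mean = 100,
                            dispersion = 0.2, true_logfc = 0, seed = 1L) {
  if (any(baseline_mean <= 0)) abort("`baseline_mean` must be > 0")
  if (dispersion < 0) abort("`dispersion` must be >= 0")
  mu <- rep_len(baseline_mean, n_genes)
  lfc <- rep_len(true_logfc, n_genes)
  withr::with_seed(seed, {
    mu_trt <- mu * 2^(lfc / 2)
    mu_ctl <- mu * 2^(-lfc / 2)
    draw <- function(mu_vec) {
      if (dispersion == 0) rpois(n_genes, mu_vec)
      else rnbinom(n_genes, mu = mu_vec, size = 1 / dispersion)
    }
    counts <- tibble(gene_id = sprintf("G%05d", seq_len(n_genes)))
    for (r in seq_len(n_reps)) counts[[sprintf("trt_%d", r)]] <- draw(mu_trt)
    for (r in seq_len(n_reps)) counts[[sprintf("ctl_%d", r)]] <- draw(mu_ctl)
    conditions <- tibble(
      sample_id = c(sprintf("trt_%d", seq_len(n_reps)),
                    sprintf("ctl_%d", seq_len(n_reps))),
      condition = rep(c("treatment", "control"), each = n_reps)
    )
    truth <- tibble(gene_id = counts$gene_id, true_logfc = lfc,
                    is_de = lfc != 0)
    list(counts = counts, conditions = conditions, truth = truth)
  })
}
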