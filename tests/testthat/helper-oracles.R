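# Independent oracles kept deliberately naive: full-matrix dynamic
# programming for the aligner, nested loops over raw membership triples for
# the orthology classification, and closed-form combinatorics for the exact
# test. These are written against the definitions, not against the package
# implementations they check.

# Full-matrix Gotoh score (no traceback): gap run of length L scores
# gap_open + (L - 1) * gap_extend.
sw_oracle_score <- function(q, s, match, mismatch, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open, E[i + 1, j] + gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open, F[i, j + 1] + gap_extend)
      sub <- if (qc[i] == sc[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive two-sided 2x2 exact-test p from first principles: probability of
# a table with fixed margins via binomial coefficients, two-sided tail as the
# total probability of tables no more probable than the observed one.
oracle_exact_p <- function(a, n_trt, n_ctl, k) {
  lo <- max(0, k - n_ctl)
  hi <- min(k, n_trt)
  xs <- lo:hi
  probs <- choose(n_trt, xs) * choose(n_ctl, k - xs) / choose(n_trt + n_ctl, k)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Naive per-gene classification by nested loops over the raw triples.
naive_classify <- function(memberships, sets, min_per_set,
                           arth_hits = NULL, self_hits = NULL,
                           evalue_thr = 1e-5, genes = NULL) {
  if (is.null(genes)) {
    genes <- unique(memberships[, c("gene_id", "species_id")])
  }
  out <- character(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    sp <- genes$species_id[g]
    og_rows <- memberships[memberships$gene_id == gid, , drop = FALSE]
    category <- NULL
    if (nrow(og_rows) > 0) {
      og <- og_rows$og_id[1]
      fam <- memberships[memberships$og_id == og, , drop = FALSE]
      n_counting <- 0
      for (set in sets) {
        n_sp <- 0
        for (s in set) {
          if (any(fam$species_id == s)) n_sp <- n_sp + 1
        }
        if (n_sp >= min_per_set) n_counting <- n_counting + 1
      }
      if (n_counting == 3) {
        n_own <- sum(fam$species_id == sp)
        category <- if (n_own == 1) "universal_single" else "universal_multi"
      } else if (n_counting == 2) {
        category <- "two_set"
      } else if (n_counting == 1) {
        category <- "set_restricted_ortholog"
      }
    }
    if (is.null(category)) {
      has_arth <- FALSE
      if (!is.null(arth_hits) && nrow(arth_hits) > 0) {
        for (h in seq_len(nrow(arth_hits))) {
          if (arth_hits$query_id[h] == gid &&
              arth_hits$subject_id[h] != gid &&
              arth_hits$evalue[h] < evalue_thr) { has_arth <- TRUE; break }
        }
      }
      has_self <- FALSE
      if (!has_arth && !is.null(self_hits) && nrow(self_hits) > 0) {
        for (h in seq_len(nrow(self_hits))) {
          if (self_hits$query_id[h] == gid &&
              self_hits$subject_id[h] != gid &&
              self_hits$evalue[h] < evalue_thr) { has_self <- TRUE; break }
        }
      }
      category <- if (has_arth) "arthropod_homolog"
      else if (has_self) "self_homolog"
      else "unique"
    }
    out[g] <- category
  }
  data.frame(gene_id = genes$gene_id, species_id = genes$species_id,
             category = out, stringsAsFactors = FALSE)
}

# Naive per-species copy-number split over three-set OGs.
naive_copy_split <- function(memberships, sets, min_per_set, universe) {
  res <- data.frame(species_id = universe, single_copy = 0L, multi_copy = 0L)
  for (og in unique(memberships$og_id)) {
    fam <- memberships[memberships$og_id == og, , drop = FALSE]
    n_counting <- 0
    for (set in sets) {
      n_sp <- length(unique(fam$species_id[fam$species_id %in% set]))
      if (n_sp >= min_per_set) n_counting <- n_counting + 1
    }
    if (n_counting != 3) next
    for (sp in unique(fam$species_id)) {
      n_own <- sum(fam$species_id == sp)
      i <- which(res$species_id == sp)
      if (n_own == 1) res$single_copy[i] <- res$single_copy[i] + 1L
      else res$multi_copy[i] <- res$multi_copy[i] + n_own
    }
  }
  res
}

# Random OG table fixture: <= 8 species split into three non-empty sets,
# <= 50 OGs, random memberships, some OG-less genes, random fallback hits
# (a mix of significant/insignificant and trivial self hits).
random_table_fixture <- function() {
  pick <- function(v) v[sample.int(length(v), 1)]   # safe for length-1 v
  n_sp <- sample(4:8, 1)
  species <- sprintf("SP%02d", seq_len(n_sp))
  cut1 <- pick(seq_len(n_sp - 2))
  cut2 <- pick(seq(cut1 + 1, n_sp - 1))
  sets <- list(a = species[seq_len(cut1)],
               b = species[seq(cut1 + 1, cut2)],
               c = species[seq(cut2 + 1, n_sp)])
  n_og <- sample(5:50, 1)
  rows <- list()
  gene_counter <- 0
  for (og in seq_len(n_og)) {
    members <- species[runif(n_sp) < runif(1)]
    if (length(members) == 0) members <- sample(species, 1)
    for (sp in members) {
      n_copies <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
      for (k in seq_len(n_copies)) {
        gene_counter <- gene_counter + 1
        rows[[length(rows) + 1]] <- data.frame(
          og_id = sprintf("OG%03d", og), species_id = sp,
          gene_id = sprintf("g%05d", gene_counter))
      }
    }
  }
  memberships <- do.call(rbind, rows)
  n_orph <- sample(5:20, 1)
  orphan_genes <- data.frame(
    gene_id = sprintf("orph%03d", seq_len(n_orph)),
    species_id = sample(species, n_orph, replace = TRUE))
  genes <- rbind(unique(memberships[, c("gene_id", "species_id")]),
                 orphan_genes)
  mk_hits <- function(queries, subjects, db) {
    n <- length(queries)
    if (n == 0) return(NULL)
    data.frame(query_id = queries, subject_id = subjects,
               pct_identity = 90, aln_length = 100L, mismatches = 10L,
               gap_openings = 0L, q_start = 1L, q_end = 100L, s_start = 1L,
               s_end = 100L,
               evalue = 10^runif(n, -12, -2),   # straddles the 1e-5 gate
               bit_score = 50, subject_db = db,
               stringsAsFactors = FALSE)
  }
  pool <- genes$gene_id
  n_arth <- sample(0:30, 1)
  arth <- mk_hits(sample(pool, n_arth, replace = TRUE),
                  sprintf("EXT%03d", seq_len(n_arth)), "arthropod")
  n_self <- sample(0:30, 1)
  self_q <- sample(pool, n_self, replace = TRUE)
  # a third of self hits are trivial self-matches, which must never count
  self_s <- ifelse(runif(n_self) < 0.3, self_q,
                   sample(pool, n_self, replace = TRUE))
  self <- mk_hits(self_q, self_s, "self")
  list(
    table = ortho_table(memberships, species_universe = species),
    partition = species_partition(sets),
    policy = partition_policy(min(2L, min(lengths(sets)))),
    arth = arth, self = self, genes = genes
  )
}

# Hand-built tabular hit row for screen fixtures.
mk_hit <- function(scaffold, qs, qe, e, subject = "b1", db = "bacterial",
                   bit = 50, ident = 90, gaps = 0L) {
  tibble::tibble(query_id = scaffold, subject_id = subject,
                 pct_identity = ident, aln_length = qe - qs + 1L,
                 mismatches = 5L, gap_openings = gaps,
                 q_start = as.integer(qs), q_end = as.integer(qe),
                 s_start = 1L, s_end = qe - qs + 1L, evalue = e,
                 bit_score = bit, subject_db = db)
}
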