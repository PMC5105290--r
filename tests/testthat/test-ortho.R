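make_table <- function(...) {
  rows <- list(...)
  memberships <- do.call(rbind, lapply(rows, function(r) {
    data.frame(og_id = r[1], species_id = r[2], gene_id = r[3])
  }))
  ortho_table(memberships,
              species_universe = sprintf("SP%d", 1:6))
}

six_sp_partition <- function() {
  species_partition(list(a = c("SP1", "SP2"), b = c("SP3", "SP4"),
                         c = c("SP5", "SP6")))
}

test_that("og_span counts sets by the min-species rule", {
  part <- six_sp_partition()
  pol <- partition_policy(2)
  expect_equal(og_span(c("SP1", "SP2", "SP3", "SP4", "SP5", "SP6"), part, pol),
               "three_set")
  # one set below threshold does not count
  expect_equal(og_span(c("SP1", "SP2", "SP3"), part, pol), "one_set")
  expect_equal(og_span(c("SP1", "SP2", "SP3", "SP4"), part, pol), "two_set")
  expect_equal(og_span("SP1", part, pol), "unshared")
  # repeats of one species are still one species
  expect_equal(og_span(c("SP1", "SP1", "SP1"), part, pol), "unshared")
  expect_error(og_span(character(), part, pol), "empty")
})

test_that("raising the species threshold never adds three-set OGs", {
  withr::local_seed(31)
  for (rep in seq_len(25)) {
    fx <- random_table_fixture()
    max_thr <- min(lengths(fx$partition$sets))
    n3 <- sapply(seq_len(max_thr), function(thr) {
      spans <- phytophagr:::og_spans(fx$table, fx$partition,
                                     partition_policy(thr))
      sum(spans$span == "three_set")
    })
    expect_true(all(diff(n3) <= 0))
  }
})

test_that("per-gene categories follow the three-set and fallback rules", {
  part <- six_sp_partition()
  tab <- make_table(
    c("OG1", "SP1", "u1"), c("OG1", "SP2", "u2"), c("OG1", "SP3", "u3"),
    c("OG1", "SP4", "u4"), c("OG1", "SP5", "u5"), c("OG1", "SP6", "u6"),
    c("OG1", "SP6", "u6b"),                      # SP6 has two copies in OG1
    c("OG2", "SP1", "t1"), c("OG2", "SP2", "t2"),
    c("OG2", "SP3", "t3"), c("OG2", "SP4", "t4"),
    c("OG3", "SP5", "r1"), c("OG3", "SP6", "r2"),
    c("OG4", "SP1", "x1")                        # unshared: falls through
  )
  mk <- function(q, s, e, db) tibble::tibble(
    query_id = q, subject_id = s, pct_identity = 90, aln_length = 100L,
    mismatches = 10L, gap_openings = 0L, q_start = 1L, q_end = 100L,
    s_start = 1L, s_end = 100L, evalue = e, bit_score = 50, subject_db = db)
  genes <- rbind(unique(tab$memberships[c("gene_id", "species_id")]),
                 data.frame(gene_id = c("a1", "s1", "q1", "w1"),
                            species_id = c("SP1", "SP2", "SP3", "SP4")))
  arth <- mk("a1", "OTHERG", 1e-8, "arthropod")
  self <- rbind(mk("s1", "s1_paralog", 1e-20, "self"),
                mk("q1", "q1", 1e-30, "self"),      # trivial self-match only
                mk("w1", "w1_paralog", 1e-4, "self")) # not significant
  cls <- classify_genes(tab, part, partition_policy(2), arth, self,
                        genes = genes)
  got <- setNames(as.character(cls$category), cls$gene_id)
  expect_equal(unname(got[c("u1", "u5")]), rep("universal_single", 2))
  expect_equal(unname(got[c("u6", "u6b")]), rep("universal_multi", 2))
  expect_equal(unname(got[c("t1", "t4")]), rep("two_set", 2))
  expect_equal(unname(got[c("r1", "r2")]), rep("set_restricted_ortholog", 2))
  expect_equal(unname(got["a1"]), "arthropod_homolog")
  expect_equal(unname(got["s1"]), "self_homolog")
  # a gene whose only self hit is to itself has no self homology
  expect_equal(unname(got["q1"]), "unique")
  expect_equal(unname(got["w1"]), "unique")
  # gene in an unshared OG uses the fallbacks too
  expect_equal(unname(got["x1"]), "unique")
})

test_that("every gene gets exactly one category and totals conserve", {
  withr::local_seed(97)
  for (rep in seq_len(30)) {
    fx <- random_table_fixture()
    cls <- classify_genes(fx$table, fx$partition, fx$policy, fx$arth,
                          fx$self, genes = fx$genes)
    expect_equal(nrow(cls), nrow(fx$genes))
    expect_false(any(is.na(cls$category)))
    summ <- summarize_partition(cls, fx$table, fx$partition, fx$policy)
    per_sp_genes <- table(factor(fx$genes$species_id,
                                 levels = summ$species$species_id))
    expect_equal(summ$species$total, as.integer(per_sp_genes))
    expect_equal(sum(summ$og$n_ogs),
                 length(unique(fx$table$memberships$og_id)))
  }
})

test_that("summarize_partition exposes widespread and universal-core views", {
  part <- six_sp_partition()
  tab <- make_table(
    c("OG1", "SP1", "g1"), c("OG1", "SP2", "g2"), c("OG1", "SP3", "g3"),
    c("OG1", "SP4", "g4"), c("OG1", "SP5", "g5"), c("OG1", "SP6", "g6"),
    # OG2 is three-set but not universal-core (SP2 absent)
    c("OG2", "SP1", "h1"), c("OG2", "SP3", "h3"), c("OG2", "SP4", "h4"),
    c("OG2", "SP5", "h5"), c("OG2", "SP6", "h6")
  )
  pol <- partition_policy(1)
  cls <- classify_genes(tab, part, pol)
  summ <- summarize_partition(cls, tab, part, pol)
  sp1 <- summ$superclass[summ$superclass$species_id == "SP1", ]
  expect_equal(sp1$widespread, 2L)       # g1 and h1
  expect_equal(sp1$universal_core, 1L)   # only OG1 spans all six species
  sp2 <- summ$superclass[summ$superclass$species_id == "SP2", ]
  expect_equal(sp2$widespread, 1L)
  expect_error(summarize_partition(cls[-1, ], tab, part, pol), "cover")
})

test_that("copy-number split tallies genes over shared OGs", {
  part <- six_sp_partition()
  pol <- partition_policy(1)
  tab <- make_table(
    c("OG1", "SP1", "a1"), c("OG1", "SP3", "a3"), c("OG1", "SP5", "a5"),
    c("OG2", "SP1", "b1"), c("OG2", "SP1", "b2"), c("OG2", "SP1", "b3"),
    c("OG2", "SP3", "b4"), c("OG2", "SP5", "b5")
  )
  split <- copy_number_split(tab, part, pol)
  sp1 <- split[split$species_id == "SP1", ]
  expect_equal(sp1$single_copy, 1L)   # one gene in OG1
  expect_equal(sp1$multi_copy, 3L)    # three genes in OG2
  expect_equal(split$multi_copy[split$species_id == "SP2"], 0L)

  withr::local_seed(55)
  for (rep in seq_len(20)) {
    fx <- random_table_fixture()
    got <- copy_number_split(fx$table, fx$partition, fx$policy)
    want <- naive_copy_split(fx$table$memberships, fx$partition$sets,
                             fx$policy$min_species_per_set,
                             fx$table$species_universe)
    expect_equal(got$single_copy, want$single_copy)
    expect_equal(got$multi_copy, want$multi_copy)
  }
})
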