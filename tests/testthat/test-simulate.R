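test_that("simulators are pure functions of their seed", {
  a <- simulate_gene_families(40, seed = 9)
  b <- simulate_gene_families(40, seed = 9)
  expect_identical(a$table$memberships, b$table$memberships)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    a$table$memberships,
    simulate_gene_families(40, seed = 10)$table$memberships))

  h1 <- simulate_hgt_genome(host_length = 20000, n_insertions = 2,
                            insertion_length = 300, n_decoys = 1,
                            decoy_length = 300, seed = 4)
  h2 <- simulate_hgt_genome(host_length = 20000, n_insertions = 2,
                            insertion_length = 300, n_decoys = 1,
                            decoy_length = 300, seed = 4)
  expect_identical(h1$genome$seq, h2$genome$seq)
  expect_identical(h1$truth, h2$truth)

  d1 <- simulate_domain_annotations(c("A", "B"), seed = 2)
  d2 <- simulate_domain_annotations(c("A", "B"), seed = 2)
  expect_identical(d1$annotations, d2$annotations)

  c1 <- simulate_counts(50, seed = 3)
  c2 <- simulate_counts(50, seed = 3)
  expect_identical(c1$counts, c2$counts)
})

test_that("without duplication or loss every family is universal single-copy", {
  sim <- simulate_gene_families(60, dup_rate = 0, loss_rate = 0, seed = 2)
  expect_equal(nrow(sim$table$memberships),
               60 * length(sim$table$species_universe))
  expect_true(all(sim$truth$category == "universal_single"))
  per_og <- dplyr::count(sim$table$memberships, og_id)
  expect_true(all(per_og$n == 15))
})

test_that("heavy loss produces lineage-restricted families whose truth matches presence", {
  sim <- simulate_gene_families(400, dup_rate = 0.3, loss_rate = 1.2,
                                seed = 33)
  expect_gt(length(unique(sim$truth$category)), 3)
  # spot-check truth against direct presence inspection for every family
  lookup <- phytophagr:::species_to_set(default_species_partition())
  fam <- split(sim$table$memberships, sim$table$memberships$og_id)
  for (og in names(fam)) {
    sp <- unique(fam[[og]]$species_id)
    n_counting <- sum(sapply(split(lookup$species_id, lookup$set_label),
                             function(set) sum(sp %in% set) >= 2))
    truth_cat <- unique(as.character(
      sim$truth$category[sim$truth$og_id == og]))
    if (n_counting == 3) {
      expect_true(all(truth_cat %in% c("universal_single",
                                       "universal_multi")))
    } else if (n_counting == 2) {
      expect_equal(truth_cat, "two_set")
    } else if (n_counting == 1) {
      expect_equal(truth_cat, "set_restricted_ortholog")
    } else {
      expect_true(all(truth_cat %in% c("arthropod_homolog", "self_homolog",
                                       "unique")))
    }
  }
})

test_that("planted insertions carry exact construction-time truth", {
  sim <- simulate_hgt_genome(host_length = 40000, n_insertions = 3,
                             insertion_length = 400, divergence = 0,
                             n_decoys = 1, decoy_length = 300, seed = 12)
  # at zero divergence the planted copy is the source and identity is 100
  expect_true(all(sim$truth$true_identity == 100))
  for (i in seq_len(3)) {
    planted <- substr(sim$genome$seq, sim$truth$start[i] + 1,
                      sim$truth$end[i])
    expect_equal(planted,
                 sim$bacterial_db$seq[sim$bacterial_db$id ==
                                        sim$truth$source_id[i]])
  }
  # junction evidence covers both boundaries in all libraries
  junc <- dplyr::count(sim$junctions, library_id)
  expect_equal(nrow(junc), 3L)          # default n_libraries = 3
  expect_true(all(junc$n == 2 * 3))     # two boundaries per insertion
  expect_setequal(
    sim$junctions$position,
    c(sim$truth$start, sim$truth$end))
})

test_that("realized insertion identity tracks the divergence in expectation", {
  sim <- simulate_hgt_genome(host_length = 3e5, n_insertions = 12,
                             insertion_length = 1000, divergence = 0.05,
                             n_decoys = 1, decoy_length = 300, seed = 21)
  expect_lt(abs(mean(sim$truth$true_identity) - 95), 1.5)
  expect_true(all(sim$truth$indel_events == 0))

  simi <- simulate_hgt_genome(host_length = 3e5, n_insertions = 12,
                              insertion_length = 1000, divergence = 0.3,
                              indel_rate = 0.02, n_decoys = 1,
                              decoy_length = 300, seed = 22)
  expect_lt(mean(simi$truth$true_identity), 75)
  expect_true(all(simi$truth$indel_events >= 1))
})

test_that("zero-dispersion counts behave like Poisson draws", {
  sim <- simulate_counts(n_genes = 10000, n_reps = 2, baseline_mean = 50,
                         dispersion = 0, true_logfc = 0, seed = 5)
  x <- sim$counts$trt_1
  expect_lt(abs(mean(x) - 50), 1)
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)   # variance ~ mean

  simnb <- simulate_counts(n_genes = 10000, n_reps = 2, baseline_mean = 50,
                           dispersion = 0.3, true_logfc = 0, seed = 5)
  y <- simnb$counts$trt_1
  expect_lt(abs(var(y) - (50 + 0.3 * 50^2)) / (50 + 0.3 * 50^2), 0.1)

  # the per-condition means split the fold change symmetrically
  simfc <- simulate_counts(n_genes = 20000, n_reps = 1, baseline_mean = 100,
                           dispersion = 0, true_logfc = 2, seed = 6)
  expect_lt(abs(mean(simfc$counts$trt_1) - 200), 2)
  expect_lt(abs(mean(simfc$counts$ctl_1) - 50), 1)
  expect_true(all(simfc$truth$is_de))
})
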