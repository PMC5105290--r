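species6 <- sprintf("SP%d", 1:6)

ann_rows <- function(species, domain, n, prefix = species) {
  tibble::tibble(gene_id = sprintf("%s_%s_%d", prefix, domain, seq_len(n)),
                 species_id = species, domain_acc = domain,
                 domain_name = paste("dom", domain))
}

test_that("count matrix counts genes once per domain with a complete grid", {
  ann <- dplyr::bind_rows(ann_rows("SP1", "D1", 3), ann_rows("SP2", "D1", 1),
                          ann_rows("SP1", "D2", 2))
  mat <- build_count_matrix(ann, species6)
  wide <- count_matrix_wide(mat)
  expect_equal(wide$SP1[wide$domain_acc == "D1"], 3L)
  expect_equal(wide$SP3[wide$domain_acc == "D1"], 0L)
  expect_equal(nrow(mat), 2 * 6)

  # duplicate (gene, domain) annotation rows count once
  dup <- dplyr::bind_rows(ann_rows("SP1", "D1", 1), ann_rows("SP1", "D1", 1))
  expect_equal(sum(build_count_matrix(dup, species6)$n_genes), 1L)

  empty <- build_count_matrix(ann[0, ], species6)
  expect_equal(nrow(empty), 0L)

  bad <- ann_rows("SPX", "D1", 1)
  expect_error(build_count_matrix(bad, species6), "not in the species list")
})

test_that("expansion flagging is strict at the max-count threshold", {
  ann <- dplyr::bind_rows(
    ann_rows("SP1", "Dsix", 6), ann_rows("SP2", "Dsix", 1),
    ann_rows("SP1", "Dfive", 5), ann_rows("SP3", "Dfive", 2),
    ann_rows("SP4", "Dzero", 1))
  mat <- build_count_matrix(ann, species6)
  flags <- flag_expansions(mat)   # default threshold: strictly more than 5
  expect_equal(flags$domain_acc, "Dsix")
  expect_equal(flags$max_count, 6L)
  expect_equal(flags$max_species, "SP1")

  # ties list all arg-max species
  tie <- dplyr::bind_rows(ann_rows("SP1", "Dt", 7), ann_rows("SP5", "Dt", 7))
  expect_equal(flag_expansions(build_count_matrix(tie, species6))$max_species,
               "SP1,SP5")
})

test_that("expansion flags are invariant under species reordering", {
  withr::local_seed(8)
  ann <- dplyr::bind_rows(ann_rows("SP1", "Da", 8), ann_rows("SP3", "Db", 2),
                          ann_rows("SP6", "Dc", 9), ann_rows("SP2", "Dc", 4))
  f1 <- flag_expansions(build_count_matrix(ann, species6))
  f2 <- flag_expansions(build_count_matrix(ann, rev(species6)))
  expect_equal(f1, f2)
})

test_that("orthology status bins partition each species' domain count", {
  tab <- ortho_table(data.frame(
    og_id = c("OG1", "OG1", "OG2", "OG2", "OG2"),
    species_id = c("SP1", "SP2", "SP1", "SP1", "SP2"),
    gene_id = c("a1", "a2", "b1", "b2", "b3")),
    species_universe = species6)
  ann <- tibble::tibble(
    gene_id = c("a1", "b1", "b2", "loner", "a2"),
    species_id = c("SP1", "SP1", "SP1", "SP1", "SP2"),
    domain_acc = "D1", domain_name = "dom")
  part <- orthology_status_partition("D1", ann, tab, species6)
  sp1 <- part[part$species_id == "SP1", ]
  expect_equal(sp1$single_copy, 1L)    # a1 alone in OG1 for SP1
  expect_equal(sp1$multi_copy, 2L)     # b1, b2 share OG2
  expect_equal(sp1$homology_only, 1L)  # loner has no OG
  # bins sum to the count-matrix cell for every species
  mat <- build_count_matrix(ann, species6)
  wide <- count_matrix_wide(mat)
  for (sp in species6) {
    row <- part[part$species_id == sp, ]
    expect_equal(row$single_copy + row$multi_copy + row$homology_only,
                 wide[[sp]][wide$domain_acc == "D1"])
  }
})

test_that("enrichment over the non-focal mean handles degenerate cases", {
  ann <- dplyr::bind_rows(ann_rows("SP1", "D1", 10),
                          purrr::map(c("SP2", "SP3", "SP4", "SP5", "SP6"),
                                     ~ ann_rows(.x, "D1", 2)))
  mat <- build_count_matrix(ann, species6)
  enr <- enrichment_vs_mean(mat, "D1", "SP1")
  expect_equal(enr$ratio, 5)
  expect_false(enr$degenerate)

  enr0 <- enrichment_vs_mean(mat, "D1", "SP2")
  expect_equal(enr0$focal_count, 2L)
  expect_equal(enr0$ratio, 2 / mean(c(10, 2, 2, 2, 2)))

  only_focal <- build_count_matrix(ann_rows("SP1", "D9", 3), species6)
  enr_inf <- enrichment_vs_mean(only_focal, "D9", "SP1")
  expect_true(is.infinite(enr_inf$ratio))
  expect_true(enr_inf$degenerate)

  empty <- build_count_matrix(ann_rows("SP2", "D8", 1), species6)
  enr_nan <- enrichment_vs_mean(empty, "D7", "SP1")
  expect_true(is.nan(enr_nan$ratio))

  # accession groups are summed before the ratio
  grp <- dplyr::bind_rows(ann_rows("SP1", "Dg1", 4), ann_rows("SP1", "Dg2", 6),
                          ann_rows("SP2", "Dg1", 1), ann_rows("SP2", "Dg2", 1),
                          ann_rows("SP3", "Dg1", 1), ann_rows("SP3", "Dg2", 1),
                          ann_rows("SP4", "Dg1", 1), ann_rows("SP4", "Dg2", 1),
                          ann_rows("SP5", "Dg1", 1), ann_rows("SP5", "Dg2", 1),
                          ann_rows("SP6", "Dg1", 1), ann_rows("SP6", "Dg2", 1))
  gmat <- build_count_matrix(grp, species6)
  expect_equal(enrichment_vs_mean(gmat, c("Dg1", "Dg2"), "SP1")$ratio, 5)
})

test_that("planted expansions are recovered exactly from simulated data", {
  planted <- tibble::tibble(domain_acc = c("IPR900001", "IPR900002"),
                            species_id = c("SP1", "SP4"),
                            n_genes = c(8L, 7L))
  sim <- simulate_domain_annotations(species6, n_domains = 15,
                                     planted = planted, background_max = 2,
                                     seed = 19)
  mat <- build_count_matrix(sim$annotations, species6)
  flags <- flag_expansions(mat)
  expect_setequal(flags$domain_acc, planted$domain_acc)
  expect_equal(flags$max_species[flags$domain_acc == "IPR900001"], "SP1")
  expect_equal(flags$max_count[flags$domain_acc == "IPR900002"], 7L)

  # nothing flagged without planting at background_max = 2
  sim0 <- simulate_domain_annotations(species6, n_domains = 15,
                                      background_max = 2, seed = 19)
  expect_equal(nrow(flag_expansions(build_count_matrix(sim0$annotations,
                                                       species6))), 0L)
})
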