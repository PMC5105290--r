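test_that("significant bacterial hits merge into regions by overlap", {
  hits <- dplyr::bind_rows(
    mk_hit("s1", 101, 500, 1e-20, "b1"),
    mk_hit("s1", 401, 900, 1e-10, "b2"),
    mk_hit("s1", 2001, 2500, 1e-8, "b3"),
    mk_hit("s2", 10, 50, 1e-4, "b4"))   # sub-threshold: dropped
  reg <- find_bacterial_regions(hits)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start, c(100L, 2000L))
  expect_equal(reg$end, c(900L, 2500L))
  expect_equal(reg$bact_subject_id[1], "b1")   # best hit carries the region
  expect_equal(reg$n_hits, c(2L, 1L))

  expect_equal(nrow(find_bacterial_regions(mk_hit("s1", 1, 100, 1e-4))), 0L)

  # adjacent but non-overlapping stays split unless a gap is allowed
  adj <- dplyr::bind_rows(mk_hit("s1", 1, 100, 1e-8),
                          mk_hit("s1", 151, 250, 1e-8))
  expect_equal(nrow(find_bacterial_regions(adj)), 2L)
  expect_equal(nrow(find_bacterial_regions(adj, gap = 60)), 1L)
})

test_that("conserved-gene exclusion compares E-values strictly", {
  reg <- find_bacterial_regions(mk_hit("s1", 101, 600, 1e-12))
  animal <- function(e) mk_hit("s1", 200, 400, e, "anim1", "animal")
  expect_equal(screen_region(reg, animal(1e-6))$status, "retained")
  expect_equal(screen_region(reg, animal(1e-20))$status, "excluded_conserved")
  expect_equal(screen_region(reg, NULL)$status, "retained")
  expect_equal(screen_region(reg, animal(1e-12))$status, "retained") # tie
  # a non-overlapping animal hit is no evidence
  far <- mk_hit("s1", 5000, 5400, 1e-30, "anim2", "animal")
  expect_equal(screen_region(reg, far)$status, "retained")
})

test_that("age classification follows the identity and indel tiers", {
  pol <- age_policy()   # recent >= 90, degrading <= 80 with >= 1 indel
  expect_equal(classify_age(95.0, 0, pol), "recent")
  expect_equal(classify_age(70.5, 3, pol), "degrading")
  expect_equal(classify_age(85.0, 0, pol), "intermediate")
  expect_equal(classify_age(75.0, 0, pol), "intermediate") # low id, no indel
  expect_equal(classify_age(90.0, 5, pol), "recent")       # boundary
  expect_error(age_policy(recent_min_identity = 80,
                          degrading_max_identity = 85))
})

test_that("junction confirmation needs both boundaries in enough libraries", {
  cand <- tibble::tibble(scaffold = "s1", start = 1000L, end = 3000L)
  ev <- function(pos, libs) tibble::tibble(
    scaffold = "s1", position = as.integer(pos), library_id = libs,
    supporting_pairs = 5L)
  both <- dplyr::bind_rows(ev(1010, c("L1", "L2", "L3")),
                           ev(2995, c("L1", "L2", "L3")))
  got <- confirm_junctions(cand, both)
  expect_equal(got$junction_libraries, 3L)
  expect_true(got$junction_confirmed)

  left_only <- ev(1010, c("L1", "L2", "L3"))
  got <- confirm_junctions(cand, left_only)
  expect_equal(got$junction_libraries, 3L)
  expect_false(got$junction_confirmed)

  got <- confirm_junctions(cand, both[0, ])
  expect_equal(got$junction_libraries, 0L)
  expect_false(got$junction_confirmed)

  # evidence outside the window does not support
  far <- dplyr::bind_rows(ev(1100, c("L1", "L2")), ev(2900, c("L1", "L2")))
  expect_false(confirm_junctions(cand, far, window = 50)$junction_confirmed)
  expect_true(confirm_junctions(cand, far, window = 100)$junction_confirmed)
})

test_that("flanking genes are the nearest non-overlapping neighbours", {
  cand <- tibble::tibble(scaffold = "s1", start = 500L, end = 1500L)
  genes <- tibble::tibble(
    gene_id = c("gLeftFar", "gLeft", "gOverlap", "gRight", "gRightFar"),
    scaffold = "s1",
    start = c(0L, 300L, 1400L, 2000L, 5000L),
    end = c(100L, 450L, 1600L, 2100L, 5100L),
    strand = "+", species = "AGLAB")
  got <- flanking_genes(cand, genes)
  expect_equal(got$left_gene_id, "gLeft")
  expect_equal(got$right_gene_id, "gRight")

  start_cand <- tibble::tibble(scaffold = "s1", start = 0L, end = 50L)
  got <- flanking_genes(start_cand, genes)
  expect_true(is.na(got$left_gene_id))

  # a gene touching the boundary exactly still flanks
  touch <- tibble::tibble(
    gene_id = "gTouch", scaffold = "s1", start = 1500L, end = 1700L,
    strand = "+", species = "AGLAB")
  expect_equal(flanking_genes(cand, touch)$right_gene_id, "gTouch")
})

test_that("the composed screen retains true insertions and drops decoys", {
  sim <- simulate_hgt_genome(host_length = 50000, n_insertions = 4,
                             insertion_length = 600, divergence = 0.05,
                             n_decoys = 2, decoy_length = 500, seed = 71)
  bact <- align_windows(sim$genome, sim$windows, sim$bacterial_db,
                        "bacterial")
  anim <- align_windows(sim$genome, sim$windows, sim$animal_db, "animal")
  cand <- screen_hgt(bact, anim, junctions = sim$junctions)
  ret <- dplyr::filter(cand, status == "retained")
  # every planted insertion is recovered by an overlapping retained region
  hits_per_ins <- sapply(seq_len(nrow(sim$truth)), function(i) {
    any(ret$start < sim$truth$end[i] & ret$end > sim$truth$start[i])
  })
  expect_true(all(hits_per_ins))
  # no decoy region survives the animal comparison
  dec_hit <- sapply(seq_len(nrow(sim$decoys)), function(i) {
    any(ret$start < sim$decoys$end[i] & ret$end > sim$decoys$start[i])
  })
  expect_false(any(dec_hit))
  expect_true(all(ret$junction_confirmed))
  g <- glance(cand)
  expect_equal(g$n_retained, 4L)
  expect_equal(g$n_excluded_conserved, 2L)
})
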