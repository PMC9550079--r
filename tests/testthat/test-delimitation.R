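test_that("barcode-gap partition splits a clean two-cluster dataset", {
  dm <- toy_two_cluster_dm(3, 3, a = 0.01, b = 0.10, seed = 1)
  p <- abgd_partition(dm, P = 0.02)
  expect_equal(n_groups(p), 2L)
  truth <- toy_two_cluster_truth(3, 3)
  expect_equal(length(unique(p$assignment[truth == "A"])), 1L)
  expect_equal(length(unique(p$assignment[truth == "B"])), 1L)
})

test_that("barcode-gap degenerate inputs give one group", {
  ids <- c("x", "y", "z")
  zero <- structure(list(ids = ids,
                         d = matrix(0, 3, 3, dimnames = list(ids, ids)),
                         overlap = matrix(500L, 3, 3, dimnames = list(ids, ids)),
                         min_overlap = 100L), class = "pdist")
  expect_equal(n_groups(abgd_partition(zero, 0.01)), 1L)
  one <- structure(list(ids = "x",
                                        d = matrix(0, 1, 1, dimnames = list("x", "x")),
                                        overlap = matrix(500L, 1, 1, dimnames = list("x", "x")),
                                        min_overlap = 100L), class = "pdist")
  expect_equal(n_groups(abgd_partition(one, 0.01)), 1L)
})

test_that("barcode-gap partition refuses undefined pairs", {
  dm <- toy_two_cluster_dm(3, 3)
  dm$d[2, 5] <- dm$d[5, 2] <- NA
  expect_error(abgd_partition(dm, 0.02), "undefined")
})

test_that("clean-gap contract holds across the prior window", {
  ## threshold-sweep oracle: every threshold inside (a, b) yields the same
  ## two components as the gap method for any prior below b
  dm <- toy_two_cluster_dm(4, 5, a = 0.015, b = 0.09, seed = 7)
  truth <- toy_two_cluster_truth(4, 5)
  for (tau in c(0.02, 0.05, 0.088)) {
    comp <- union_find_components(dm$d, tau)
    expect_equal(length(unique(comp)), 2L)
  }
  for (P in c(0.015, 0.03, 0.06, 0.089)) {
    p <- abgd_partition(dm, P)
    expect_equal(n_groups(p), 2L)
    expect_equal(length(unique(p$assignment[truth == "A"])), 1L)
  }
})

test_that("prior scan reports per-prior counts with a plateau at the truth", {
  sim <- generate_barcodes(synthetic_config(n_species = 4,
                                            samples_per_species = 5, seed = 5))
  dm <- p_distance_matrix(sim$sequences)
  cal <- calibration_report(sim$sequences, sim$truth)
  sc <- abgd_scan(dm)
  expect_equal(nrow(sc), 20L)
  ## priors inside the clean-gap window recover the truth exactly
  inwin <- sc$prior >= cal$max_intra & sc$prior < cal$min_inter
  expect_gte(sum(inwin), 1L)
  expect_true(all(sc$n_groups[inwin] == 4L))
  ## priors below the intraspecific ceiling oversplit, never undersplit
  expect_true(all(sc$n_groups[sc$prior < cal$max_intra] >= 4L))
  ## single specimen: every prior yields one group
  one <- p_distance_matrix(sim$sequences[1], min_overlap = 10)
  expect_true(all(abgd_scan(one)$n_groups == 1L))
})

test_that("single linkage chains below the threshold and isolates above", {
  ids <- c("a", "b", "c")
  d <- matrix(c(0, 0.01, 0.03, 0.01, 0, 0.01, 0.03, 0.01, 0), 3, 3,
              dimnames = list(ids, ids))
  dm <- structure(list(ids = ids, d = d,
                       overlap = matrix(500L, 3, 3, dimnames = list(ids, ids)),
                       min_overlap = 100L), class = "pdist")
  expect_equal(n_groups(single_linkage_partition(dm, 0.022)), 1L)
  expect_equal(n_groups(single_linkage_partition(dm, 0.005)), 3L)
})

test_that("single linkage equals the union-find oracle on random matrices", {
  for (s in 1:10) {
    set.seed(s)
    n <- 15
    ids <- sprintf("r%02d", 1:n)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.08)
    d <- d + t(d)
    dm <- structure(list(ids = ids, d = d,
                         overlap = matrix(500L, n, n, dimnames = list(ids, ids)),
                         min_overlap = 100L), class = "pdist")
    p <- single_linkage_partition(dm, 0.022)
    oracle <- union_find_components(d, 0.022)
    ## identical groupings up to relabeling
    expect_equal(length(unique(p$assignment)), length(unique(oracle)))
    expect_true(all(tapply(oracle, p$assignment[names(oracle)],
                           function(g) length(unique(g))) == 1L))
  }
})

test_that("best-match fallback applies overlap, similarity and tie rules", {
  base <- strrep("ACGT", 100)                       # 400 sites
  mut <- function(s, k) {                           # k mismatches
    ch <- strsplit(s, "")[[1]]
    ch[seq_len(k)] <- ifelse(ch[seq_len(k)] == "A", "C", "A")
    paste0(ch, collapse = "")
  }
  aln <- make_seqs(q = base, r1 = mut(base, 2), r2 = mut(base, 30),
                   r3 = mut(base, 2))
  dm <- p_distance_matrix(aln, min_overlap = 10)
  part <- partition(c(r1 = "g1", r2 = "g2", r3 = "g3"), "bin")
  ## two equally good matches in different groups: unassigned tie
  res <- assign_group_by_best_match("q", dm, part)
  expect_identical(res$reason, "tie")
  ## unique best match within 99%
  part2 <- partition(c(r1 = "g1", r2 = "g2"), "bin")
  dm2 <- subset_pdist(dm, c("q", "r1", "r2"))
  res2 <- assign_group_by_best_match("q", dm2, part2)
  expect_identical(res2$group, "g1")
  ## similarity floor
  part3 <- partition(c(r2 = "g2"), "bin")
  res3 <- assign_group_by_best_match("q", subset_pdist(dm, c("q", "r2")), part3)
  expect_identical(res3$reason, "below_similarity")
  ## overlap floor
  res4 <- assign_group_by_best_match("q", dm2, part2, min_overlap = 500)
  expect_identical(res4$reason, "no_defined_pair")
})

test_that("representative selection samples, collapses and is seeded", {
  sim <- generate_barcodes(synthetic_config(n_species = 3,
                                            samples_per_species = c(1, 2, 5),
                                            seed = 21))
  ## make two of the five in species 3 identical haplotypes
  ids3 <- names(sim$truth$assignment)[sim$truth$assignment == "SP03"]
  sim$sequences[ids3[2]] <- sim$sequences[ids3[1]]
  dm <- p_distance_matrix(sim$sequences)
  reps <- select_representatives(sim$sequences, dm, k = 3, seed = 99)
  sampled <- attr(reps, "sampled")
  ## the quota applies per oversplit group, which may subdivide species
  over <- abgd_partition(dm, 1e-4)
  bygroup <- table(over$assignment[sampled])
  expect_lte(max(bygroup), 3L)               # never more than k per group
  expect_setequal(unique(over$assignment[sampled]),
                  unique(over$assignment))   # every group represented
  expect_false(any(duplicated(reps)))        # haplotypes collapsed
  reps2 <- select_representatives(sim$sequences, dm, k = 3, seed = 99)
  expect_identical(reps, reps2)
  reps3 <- select_representatives(sim$sequences, dm, k = 3, seed = 100)
  expect_identical(sort(unique(sim$truth$assignment[attr(reps3, "sampled")])),
                   c("SP01", "SP02", "SP03"))
})

test_that("partitions cover their scope with disjoint non-empty groups", {
  sim <- generate_barcodes(synthetic_config(seed = 31))
  dm <- p_distance_matrix(sim$sequences)
  for (p in list(abgd_partition(dm, 0.02), single_linkage_partition(dm))) {
    expect_setequal(partition_scope(p), names(sim$sequences))
    expect_true(all(table(p$assignment) >= 1L))
  }
})
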