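test_that("subset shares match the brute-force oracle and conserve mass", {
  counts <- rbind(c(10, 0, 5, 1), c(15, 0, 0, 3), # subset A
                  c(0, 8, 5, 0),                  # subset B
                  c(0, 2, 10, 0), c(0, 0, 0, 0))  # subset C
  labs <- c("A", "A", "B", "C", "C")
  colnames(counts) <- paste0("g", 1:4)
  a <- toy_atlas(counts, genes = paste0("g", 1:4), cell_type = labs)
  sh <- subset_shares(a, min_cells = 1)
  expect_equal(sh, oracle_shares(counts, labs)[rownames(sh), colnames(sh)])
  detected <- colSums(counts) > 0
  expect_lt(max(abs(rowSums(sh)[detected] - 1)), 1e-12)
  # gene in exactly one subset
  expect_equal(unname(sh["g2", ]), c(0, 0.8, 0.2))
  # 25/75 split
  counts2 <- rbind(c(25), c(75))
  a2 <- toy_atlas(counts2, genes = "g", cell_type = c("A", "B"))
  expect_equal(unname(subset_shares(a2, min_cells = 1)["g", ]), c(0.25, 0.75))
})

test_that("complex weights are geometric means with absorbing zeros", {
  sh <- matrix(c(0.25, 1.0, 0, 0.5, 0.3, 0.3), 3, 2,
               dimnames = list(c("l1", "l2", "l3"), c("A", "B")))
  expect_equal(complex_weight(sh, "l1", "A"), 0.25)          # m = 1 identity
  expect_equal(complex_weight(sh, c("l1", "l2"), "A"), 0.5)  # gm(0.25, 1)
  expect_equal(complex_weight(sh, c("l2", "l3"), "A"), 0)    # zero absorbs
  expect_error(complex_weight(sh, "nope", "A"), "unresolvable")
})

test_that("pair scores and strengths equal the brute-force triple loop", {
  for (seed in c(1, 2, 3)) {
    counts <- withr::with_seed(seed, matrix(rpois(12 * 20, 2), 12, 20))
    labs <- rep(c("A", "B", "C", "D"), each = 3)
    a <- toy_atlas(counts, genes = sprintf("g%02d", 1:20), cell_type = labs)
    sh <- subset_shares(a, min_cells = 1)
    catal <- random_catalog(sprintf("g%02d", 1:20), 10, seed = seed + 100)
    for (k in c(1, 3, 10, 99)) {
      got <- interaction_strength(sh, catal, k = k)
      expect_equal(got$strength, oracle_strength(sh, catal, k),
                   tolerance = 1e-12)
    }
    # monotone in k, and k = Inf equals the plain sum over pairs
    s1 <- interaction_strength(sh, catal, k = 1)$strength
    s5 <- interaction_strength(sh, catal, k = 5)$strength
    sall <- interaction_strength(sh, catal, k = 1e6)$strength
    expect_true(all(s5 - s1 >= -1e-15))
    expect_true(all(sall - s5 >= -1e-15))
    # ledger reproduces the matrix
    got10 <- interaction_strength(sh, catal, k = 5)
    led <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(got10$ledger, in_top_k),
                      source, target),
      s = sum(score), .groups = "drop")
    for (r in seq_len(nrow(led)))
      expect_equal(got10$strength[led$source[r], led$target[r]], led$s[r])
    # scores live in [0, 1]
    expect_true(all(got10$ledger$score >= 0 & got10$ledger$score <= 1))
  }
})

test_that("cell order permutations leave interaction output unchanged", {
  counts <- withr::with_seed(7, matrix(rpois(15 * 10, 3), 15, 10))
  labs <- rep(c("A", "B", "C"), each = 5)
  a <- toy_atlas(counts, genes = paste0("g", 1:10), cell_type = labs)
  perm <- withr::with_seed(8, sample(15))
  ap <- atlas_subset(a, cells = perm)
  catal <- random_catalog(paste0("g", 1:10), 6, seed = 9)
  expect_identical(interaction_strength(subset_shares(a, min_cells = 1), catal)$strength,
                   interaction_strength(subset_shares(ap, min_cells = 1), catal)$strength)
})

test_that("rank_partners orders deterministically with documented z-scores", {
  m <- matrix(c(3, 2, 1, 1, 1, 1, 0, 5, 2), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  x <- structure(list(strength = m, ledger = tibble::tibble(), k = 10,
                      excluded = character(0)), class = "eoe_interaction")
  rp <- rank_partners(x, "A", top_n = 3)
  expect_equal(rp$partner, c("A", "B", "C"))
  expect_equal(rp$z, c(1, 0, -1))  # sample-sd convention on {3, 2, 1}
  # all-equal strengths: zeros, lexicographic order
  rpB <- rank_partners(x, "B", top_n = 3)
  expect_equal(rpB$partner, c("A", "B", "C"))
  expect_equal(rpB$z, c(0, 0, 0))
  expect_true(all(rpB$degenerate_z))
  # single partner degenerate
  rp1 <- rank_partners(x, "C", top_n = 1)
  expect_equal(rp1$z, 0)
  expect_true(rp1$degenerate_z)
})

test_that("planted axes dominate rankings, per condition", {
  f <- default_fixture()
  a <- f$filtered
  catal <- lr_catalog(
    c("axis_th2_fib", "axis_mast_endo"),
    list("G0201", "G0204"),
    list(c("G0202", "G0203"), "G0205"))
  sh <- subset_shares(a)
  ist <- interaction_strength(sh, catal, k = 10)
  # the planted th2 -> fibroblast axis is that cell type's top partner
  expect_equal(rank_partners(ist, "th2", 1)$partner, "fibroblast")
  expect_equal(rank_partners(ist, "mast", 1)$partner, "endothelial")
  # identical data relabeled into two conditions gives identical matrices
  a2 <- a
  a2$samples$condition <- rep(c("x", "y"), length.out = nrow(a2$samples))
  byc <- per_condition_interactions(a2, catal, k = 10)
  expect_equal(sort(names(byc)), c("x", "y"))
  full <- per_condition_interactions(a, catal, k = 10)
  expect_true(all(c("active", "healthy", "remission") %in% names(full)))
})

test_that("the shipped demo catalog parses with multi-subunit complexes", {
  path <- system.file("extdata", "lr_demo_catalog.csv", package = "eoatlas")
  catal <- read_lr_catalog(path)
  expect_equal(nrow(catal), 30)
  expect_true(any(lengths(catal$receptor) > 1))
  itg <- catal$receptor[[which(catal$pair_id == "MADCAM1_ITGA4B7")]]
  expect_equal(itg, c("ITGA4", "ITGB7"))
})
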