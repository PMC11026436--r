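make_comp <- function(counts, samples) {
  cells <- purrr::imap_dfr(asplit(counts, 1), function(row, s) {
    tibble::tibble(sample_id = s,
                   cell_type = factor(rep(colnames(counts), row),
                                      levels = colnames(counts)))
  })
  cells$barcode <- paste0("c", seq_len(nrow(cells)))
  composition_table(cells, samples)
}

test_that("clr_transform matches hand evaluation and its invariants", {
  m <- matrix(c(10, 20, 40), 1, dimnames = list("s1", c("a", "b", "c")))
  out <- clr_transform(m)
  gm <- prod(c(10, 20, 40))^(1 / 3)
  expect_equal(as.vector(out), log(c(10, 20, 40) / gm))
  # row sums are zero for arbitrary inputs, zeros imputed
  set.seed(1)
  y <- matrix(rpois(60, 3), 6, 10)
  expect_lt(max(abs(rowSums(clr_transform(y)))), 1e-9)
  # scale invariance (no zeros)
  y1 <- y + 1
  expect_equal(clr_transform(y1), clr_transform(y1 * 7))
  # uniform row maps to zero
  expect_equal(as.vector(clr_transform(matrix(5, 1, 4))), rep(0, 4))
  expect_error(clr_transform(matrix(0, 1, 3)), "all-zero")
})

test_that("composition_pca separates groups along PC1 with the causal loading", {
  # two sample groups differing only in cell type "a"
  counts <- rbind(matrix(rep(c(60, 20, 20), 4), 4, byrow = TRUE),
                  matrix(rep(c(20, 40, 40), 4), 4, byrow = TRUE))
  counts <- counts + matrix(rpois(24, 2), 8, 3)
  colnames(counts) <- c("a", "b", "c")
  rownames(counts) <- paste0("s", 1:8)
  pc <- composition_pca(clr_transform(counts))
  expect_true(all(sign(pc$scores$PC1[1:4]) != sign(pc$scores$PC1[5:8])))
  loads <- abs(pc$loadings$PC1)
  expect_equal(pc$loadings$cell_type[which.max(loads)], "a")
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)
  # identical samples give zero scores
  same <- matrix(5, 3, 4) + 0
  pc0 <- composition_pca(clr_transform(same))
  expect_lt(max(abs(pc0$scores$PC1)), 1e-12)
})

test_that("quantile normalization equalizes the per-type distributions", {
  set.seed(2)
  m <- matrix(rexp(50, c(1, 5, 10, 20, 40)), 10, 5, byrow = TRUE)
  qn <- quantile_normalize(m)
  sorted <- apply(qn, 2, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1])
  # ranks preserved within each column
  for (j in 1:5) expect_equal(rank(qn[, j]), rank(m[, j]))
})

test_that("nb_abundance drops degenerate covariates and excludes empty types", {
  des <- mini_design(6, 6)
  des$steroid <- FALSE  # constant -> must be dropped with a warning
  counts <- matrix(rpois(12 * 4, 40), 12, 4,
                   dimnames = list(des$sample_id, paste0("t", 1:4)))
  counts[, 4] <- 0L
  comp <- make_comp(counts, des)
  expect_warning(expect_warning(res <- nb_abundance(comp),
                                "steroid"), "all-zero")
  expect_false("t4" %in% res$cell_type)
  expect_true(all(c("estimate", "p.value", "fdr", "theta") %in% names(res)))
  # BH FDR is the standard step-up transform of the p-values
  one <- dplyr::filter(res, contrast == "active_vs_healthy")
  expect_equal(one$fdr, p.adjust(one$p.value, "BH"))
})

test_that("permanova is seed-reproducible, calibrated-ish and detects separation", {
  des <- mini_design(6, 6)
  set.seed(3)
  counts <- matrix(rpois(12 * 5, 50), 12, 5,
                   dimnames = list(des$sample_id, paste0("t", 1:5)))
  comp <- make_comp(counts, des)
  r1 <- permanova_composition(comp, terms = "condition", n_perm = 499, seed = 9L)
  r2 <- permanova_composition(comp, terms = "condition", n_perm = 499, seed = 9L)
  expect_equal(r1$p.value, r2$p.value)
  # strongly separated centroids reach the attainable minimum p; at 10 + 10
  # samples the chance of a partition-preserving permutation is negligible
  des2 <- mini_design(10, 10)
  counts2 <- matrix(rpois(20 * 5, 50), 20, 5,
                    dimnames = list(des2$sample_id, paste0("t", 1:5)))
  counts2[des2$condition == "active", 1] <-
    counts2[des2$condition == "active", 1] + 500L
  compsep <- make_comp(counts2, des2)
  rs <- permanova_composition(compsep, terms = "condition", n_perm = 499, seed = 1L)
  expect_equal(rs$p.value, 1 / 500)
  # single-level term dropped with warning
  expect_warning(permanova_composition(comp, terms = c("condition", "diet"),
                                       n_perm = 99, seed = 1L), "diet")
})

test_that("activity correlation reproduces the closed-form t-test", {
  des <- mini_design(7, 7)
  act <- seq_len(14) * 3
  des$eos_per_hpf <- act
  counts <- cbind(act, matrix(rpois(14 * 3, 30), 14, 3))
  colnames(counts) <- paste0("t", 1:4)
  rownames(counts) <- des$sample_id
  comp <- make_comp(counts, des)
  res <- activity_correlation(comp, "eos_per_hpf")
  # type t1 equals the activity -> perfect monotone association
  expect_equal(res$rho[res$cell_type == "t1"], 1)
  expect_lt(res$p.value[res$cell_type == "t1"], 1e-10)
  # closed form at rho = 0.72, n = 14
  rho <- 0.72; n <- 14
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  expect_equal(tt, 3.594015, tolerance = 1e-5)
  expect_equal(2 * pt(-tt, n - 2), 0.003686, tolerance = 1e-4)
  # constant activity is an error
  des0 <- des; des0$eos_per_hpf <- 5
  expect_error(activity_correlation(make_comp(counts, des0), "eos_per_hpf"),
               "constant")
})

test_that("proportion correlation clusters merge duplicates first", {
  des <- mini_design(5, 5)
  set.seed(4)
  base <- matrix(rpois(10 * 3, 40), 10, 3)
  counts <- cbind(base, base[, 1])  # t4 duplicates t1
  colnames(counts) <- paste0("t", 1:4)
  rownames(counts) <- des$sample_id
  pcl <- proportion_correlation_clusters(make_comp(counts, des))
  expect_equal(unname(diag(pcl$correlation)), rep(1, 4))
  expect_equal(pcl$correlation["t1", "t4"], 1)
  expect_lt(pcl$hclust$height[1], 1e-10)
  first_pair <- sort(pcl$hclust$labels[-pcl$hclust$merge[1, ]])
  expect_equal(first_pair, c("t1", "t4"))
  # a two-part closure is perfectly anti-correlated
  two <- matrix(c(10, 30, 50, 70, 90, 90, 70, 50, 30, 10), 5, 2,
                dimnames = list(des$sample_id[1:5], c("x", "y")))
  des5 <- des[1:5, ]
  pcl2 <- proportion_correlation_clusters(make_comp(two, des5))
  expect_equal(pcl2$correlation["x", "y"], -1)
})

test_that("Fisher screen matches exact hypergeometric tails", {
  res <- condition_proportion_fisher(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$p.value, 1)
  res2 <- condition_proportion_fisher(matrix(c(5, 0, 0, 5), 2))
  expect_equal(res2$p.value, 2 / choose(10, 5), tolerance = 1e-12)
  res3 <- condition_proportion_fisher(matrix(c(0, 3, 0, 4), 2, byrow = TRUE))
  expect_true(res3$degenerate)
  expect_equal(res3$p.value, 1)
  many <- condition_proportion_fisher(list(a = matrix(c(5, 0, 0, 5), 2),
                                           b = matrix(c(10, 10, 10, 10), 2)))
  expect_equal(many$fdr, p.adjust(many$p.value, "BH"))
})

test_that("lasso recovers an identity signal and prunes collinear copies", {
  set.seed(6)
  n <- 30
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- X[, 3]
  fit <- lasso_fraction_predictor(y, X)
  expect_true("f3" %in% fit$coef$feature)
  expect_lt(mean((fit$predictions$observed - fit$predictions$loocv_predicted)^2),
            0.05 * stats::var(y))
  expect_gt(fit$r, 0.95)
  # collinear duplicate: at the first knot where either enters, only one does
  X2 <- cbind(X, f3copy = X[, 3])
  cv <- glmnet::cv.glmnet(X2, y, nfolds = n, grouped = FALSE)
  beta <- as.matrix(cv$glmnet.fit$beta[c("f3", "f3copy"), ])
  first <- which(colSums(beta != 0) > 0)[1]
  expect_equal(sum(beta[, first] != 0), 1)
  expect_error(lasso_fraction_predictor(rep(0, n), X), "zero")
  # broom-style accessors
  expect_s3_class(generics::tidy(fit), "tbl_df")
  expect_equal(generics::glance(fit)$n, n)
})
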