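#' Covariate-adjusted differential expression by logistic regression
#'
#' For one cell type, tests each gene for differential expression between
#' two condition groups with a likelihood-ratio test: group membership is
#' modeled by logistic regression on the gene's log-normalized expression
#' plus nuisance covariates (log2 number of detected genes per cell,
#' steroid treatment, region, 10x chemistry), and compared against the
#' covariate-only null. Log2 fold changes are computed from group means of
#' `expm1(lognorm)` with a small pseudo-count. Both Bonferroni- and
#' BH-adjusted p-values are reported; the significance convention is
#' adjusted p < 0.001 and fold change > 1.5.
#'
#' @param atlas an [eoe_atlas()] with `cell_type` labels and condition
#'   metadata in the sample table.
#' @param cell_type cell type to test within.
#' @param group_a,group_b condition labels; fold changes are A over B.
#' @param covariates per-cell or per-sample nuisance terms; `log2_detected`
#'   is computed per cell, others are looked up in the sample table and
#'   dropped (with a warning) when constant.
#' @param min_cells minimum cells required in each group.
#' @param min_expressing_frac genes are tested only if expressed (count > 0)
#'   in at least this fraction of cells in either group.
#' @param pseudocount added to `expm1` group means before the log2 ratio.
#' @return tibble of class-stable columns: `gene`, `log2_fc`, `p.value`
#'   (LRT), `p_bonferroni`, `p_bh`, `frac_a`, `frac_b`, `flag`
#'   (""/"ridge"/"separation"), `significant`.
#' @export
de_logistic <- function(atlas, cell_type, group_a, group_b,
                        covariates = c("steroid", "region", "chemistry"),
                        min_cells = 20, min_expressing_frac = 0.10,
                        pseudocount = 1e-9) {
  stopifnot(inherits(atlas, "eoe_atlas"))
  cond <- atlas$samples$condition[match(atlas$cells$sample_id,
                                        atlas$samples$sample_id)]
  in_type <- atlas$cells$cell_type == cell_type
  ia <- which(in_type & cond == group_a)
  ib <- which(in_type & cond == group_b)
  if (length(ia) < min_cells || length(ib) < min_cells)
    stop("fewer than ", min_cells, " cells in a group (",
         length(ia), " vs ", length(ib), ")", call. = FALSE)
  idx <- c(ia, ib)
  y <- rep(c(1L, 0L), c(length(ia), length(ib)))
  sub <- atlas_subset(atlas, cells = idx)
  ln <- lognorm(sub)
  detected <- Matrix::rowSums(sub$counts > 0)
  covdf <- data.frame(log2_detected = log2(pmax(detected, 1)))
  samp_cov <- sub$samples[match(sub$cells$sample_id, sub$samples$sample_id), ,
                          drop = FALSE]
  for (cv in covariates) {
    if (!cv %in% names(samp_cov)) {
      warning("covariate `", cv, "` absent; dropped", call. = FALSE); next
    }
    v <- samp_cov[[cv]]
    if (length(unique(v)) < 2) {
      warning("covariate `", cv, "` constant; dropped", call. = FALSE); next
    }
    covdf[[cv]] <- v
  }
  frac_a <- Matrix::colMeans(sub$counts[seq_along(ia), , drop = FALSE] > 0)
  frac_b <- Matrix::colMeans(sub$counts[-seq_along(ia), , drop = FALSE] > 0)
  test_genes <- which(pmax(frac_a, frac_b) >= min_expressing_frac)
  X0 <- stats::model.matrix(~ ., covdf)
  ctrl <- list(maxit = 50)
  fit0 <- suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial(),
                                          control = ctrl))
  dev0 <- fit0$deviance
  res <- purrr::map_dfr(test_genes, function(g) {
    expr <- ln[, g]
    X1 <- cbind(X0, expr = as.vector(expr))
    flag <- ""
    fit1 <- suppressWarnings(stats::glm.fit(X1, y, family = stats::binomial(),
                                            control = ctrl))
    dev1 <- fit1$deviance
    bexpr <- fit1$coefficients[["expr"]]
    if (!fit1$converged || !is.finite(bexpr) || abs(bexpr) > 15) {
      # (quasi-)separation on the gene term: small-ridge refit stabilizes
      # both deviances so the LRT stays comparable
      flag <- if (!fit1$converged) "ridge" else "separation"
      dev1 <- ridge_logistic(X1, y, lambda = 1e-3)$deviance
      dev0 <- ridge_logistic(X0, y, lambda = 1e-3)$deviance
    }
    pval <- stats::pchisq(max(dev0 - dev1, 0), df = 1, lower.tail = FALSE)
    mean_a <- mean(expm1(expr[seq_along(ia)]))
    mean_b <- mean(expm1(expr[-seq_along(ia)]))
    tibble::tibble(gene = atlas$genes[g],
                   log2_fc = log2((mean_a + pseudocount) / (mean_b + pseudocount)),
                   p.value = pval, frac_a = frac_a[g], frac_b = frac_b[g],
                   flag = flag)
  })
  if (nrow(res) == 0) return(res)
  res$p_bonferroni <- pmin(res$p.value * nrow(res), 1)
  res$p_bh <- stats::p.adjust(res$p.value, "BH")
  res$significant <- res$p_bonferroni < 0.001 & abs(res$log2_fc) > log2(1.5)
  attr(res, "groups") <- c(a = group_a, b = group_b)
  attr(res, "cell_type") <- cell_type
  dplyr::arrange(res, .data$p.value)
}

# Newton-iterated logistic regression with an L2 penalty on all but the
# intercept; used only to stabilize (quasi-)separated fits for the LRT.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 50) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(lambda, p); pen[1, 1] <- 0
  pen_dev <- function(b) {
    mu <- pmin(pmax(stats::plogis(drop(X %*% b)), 1e-12), 1 - 1e-12)
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)) + drop(t(b) %*% pen %*% b)
  }
  dev_old <- pen_dev(beta)
  for (i in seq_len(maxit)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    gr <- crossprod(X, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step)) break
    # backtracking keeps the penalized deviance monotone
    sc <- 1
    repeat {
      cand <- beta + sc * drop(step)
      if (pen_dev(cand) <= dev_old + 1e-10 || sc < 1e-4) break
      sc <- sc / 2
    }
    beta <- beta + sc * drop(step)
    dev_new <- pen_dev(beta)
    if (abs(dev_old - dev_new) < 1e-10) { dev_old <- dev_new; break }
    dev_old <- dev_new
  }
  mu <- stats::plogis(drop(X %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  list(coefficients = beta,
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Ambient-RNA majority-downregulation filter
#'
#' Differential expression driven by ambient RNA shows up as apparent
#' upregulation that is not reproduced within individual samples: a gene
#' called up in the focal condition overall, yet down relative to the
#' comparison group in most individual focal samples, is likely ambient
#' contamination. For every upregulated gene this filter compares, in each
#' of the M focal-condition samples, the mean log-normalized expression in
#' that sample's cells of the focal cell type against the pooled
#' comparison-group cells of the same type; if strictly more than M/2
#' samples show a negative difference the gene is flagged `ambient_filtered`.
#'
#' @param de a [de_logistic()] table (its `groups`/`cell_type` attributes
#'   locate the comparison).
#' @param atlas the atlas the table was computed from.
#' @param cell_type,focal_group,comparison_group override the attributes if
#'   needed; `focal_group` defaults to group A (the upregulated side).
#' @return the `de` tibble with columns `n_focal_samples`, `n_down_samples`
#'   and logical `ambient_filtered` added (FALSE for genes not upregulated).
#' @export
ambient_filter <- function(de, atlas, cell_type = NULL, focal_group = NULL,
                           comparison_group = NULL) {
  gr <- attr(de, "groups")
  if (is.null(cell_type)) cell_type <- attr(de, "cell_type")
  if (is.null(focal_group)) focal_group <- gr[["a"]]
  if (is.null(comparison_group)) comparison_group <- gr[["b"]]
  cond <- atlas$samples$condition[match(atlas$cells$sample_id,
                                        atlas$samples$sample_id)]
  in_type <- atlas$cells$cell_type == cell_type
  focal_samples <- atlas$samples$sample_id[atlas$samples$condition == focal_group]
  comp_idx <- which(in_type & cond == comparison_group)
  if (!length(comp_idx)) stop("no comparison-group cells of type ", cell_type,
                              call. = FALSE)
  sub_all <- atlas_subset(atlas, cells = which(in_type & cond %in%
                                                 c(focal_group, comparison_group)))
  ln <- lognorm(sub_all)
  is_comp <- sub_all$samples$condition[match(sub_all$cells$sample_id,
                                             sub_all$samples$sample_id)] == comparison_group
  gidx <- match(de$gene, sub_all$genes)
  base_mean <- Matrix::colMeans(ln[is_comp, gidx, drop = FALSE])
  keep_samples <- character(0)
  sample_means <- list()
  for (s in focal_samples) {
    rows <- which(sub_all$cells$sample_id == s)
    if (!length(rows)) {
      warning("focal sample ", s, " has no ", cell_type,
              " cells; excluded from M", call. = FALSE)
      next
    }
    keep_samples <- c(keep_samples, s)
    sample_means[[s]] <- Matrix::colMeans(ln[rows, gidx, drop = FALSE])
  }
  M <- length(keep_samples)
  if (M == 0) stop("no focal samples with cells of type ", cell_type, call. = FALSE)
  down <- vapply(seq_len(nrow(de)), function(i) {
    sum(vapply(keep_samples, function(s)
      sample_means[[s]][i] - base_mean[i] < 0, logical(1)))
  }, integer(1))
  de$n_focal_samples <- M
  de$n_down_samples <- down
  de$ambient_filtered <- de$log2_fc > 0 & down > M / 2
  de
}

#' Log-fold-change concordance between two comparisons
#'
#' Matches genes significant in either of two differential-expression
#' tables and reports the Pearson correlation and regression slope of their
#' log2 fold changes, plus the overlap fraction (genes significant in both,
#' with the same sign, out of those significant in the first).
#'
#' @param de_ab,de_cd tables from [de_logistic()].
#' @param significant_only compare only genes significant in either table
#'   (default) or all shared tested genes.
#' @return tibble with one row: `n_shared`, `r`, `slope`, `p.value` (slope
#'   t-test), `overlap_frac`.
#' @export
lfc_concordance <- function(de_ab, de_cd, significant_only = TRUE) {
  merged <- dplyr::inner_join(
    dplyr::select(de_ab, "gene", lfc_ab = "log2_fc", sig_ab = "significant"),
    dplyr::select(de_cd, "gene", lfc_cd = "log2_fc", sig_cd = "significant"),
    by = "gene")
  if (significant_only) merged <- dplyr::filter(merged, .data$sig_ab | .data$sig_cd)
  if (nrow(merged) < 3) {
    warning("fewer than 3 shared genes; concordance undefined", call. = FALSE)
    return(tibble::tibble(n_shared = nrow(merged), r = NA_real_,
                          slope = NA_real_, p.value = NA_real_,
                          overlap_frac = NA_real_))
  }
  sl <- summary(stats::lm(lfc_cd ~ lfc_ab, data = merged))$coefficients
  both <- merged$sig_ab & merged$sig_cd &
    sign(merged$lfc_ab) == sign(merged$lfc_cd)
  tibble::tibble(
    n_shared = nrow(merged),
    r = stats::cor(merged$lfc_ab, merged$lfc_cd),
    slope = sl["lfc_ab", 1], p.value = sl["lfc_ab", 4],
    overlap_frac = if (any(merged$sig_ab)) sum(both) / sum(merged$sig_ab) else NA_real_)
}
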