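#' Build a sample-by-cell-type composition table
#'
#' Tabulates annotated cells into a samples x cell-types count matrix and
#' carries the per-sample covariates along; this is the substrate of every
#' abundance statistic in the package.
#'
#' @param atlas an [eoe_atlas()] whose cells carry `cell_type` labels, or a
#'   tibble of cells with `sample_id` and `cell_type` columns.
#' @param samples per-sample covariate tibble; taken from the atlas when
#'   omitted.
#' @return object of class `eoe_composition`: list with `counts` (integer
#'   matrix, samples x cell types) and `samples` (covariate tibble aligned to
#'   the rows).
#' @export
composition_table <- function(atlas, samples = NULL) {
  if (inherits(atlas, "eoe_atlas")) {
    cells <- atlas$cells
    if (is.null(samples)) samples <- atlas$samples
  } else {
    cells <- tibble::as_tibble(atlas)
  }
  if (is.null(samples)) stop("`samples` covariate table required", call. = FALSE)
  if (!"cell_type" %in% names(cells))
    stop("cells carry no `cell_type` labels", call. = FALSE)
  samples <- tibble::as_tibble(samples)
  tab <- table(factor(cells$sample_id, levels = samples$sample_id),
               cells$cell_type)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  structure(list(counts = counts, samples = samples),
            class = "eoe_composition")
}

#' @export
print.eoe_composition <- function(x, ...) {
  cat("<eoe_composition> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " cell types, ", sum(x$counts), " cells\n", sep = "")
  invisible(x)
}

#' Per-sample cell-type proportions
#' @param comp an `eoe_composition`.
#' @return samples x cell-types matrix of proportions (rows sum to 1).
#' @export
composition_proportions <- function(comp) {
  sweep(comp$counts, 1, rowSums(comp$counts), "/")
}

# drop covariates that are constant (or single-level) across samples
usable_covariates <- function(samples, covariates, context) {
  keep <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(samples)) {
      warning(context, ": covariate `", cv, "` absent from sample table; dropped",
              call. = FALSE)
    } else if (length(unique(samples[[cv]])) < 2) {
      warning(context, ": covariate `", cv, "` is constant across samples; dropped",
              call. = FALSE)
    } else keep <- c(keep, cv)
  }
  keep
}

condition_factor <- function(x, reference = "healthy") {
  lev <- unique(as.character(x))
  stats::relevel(factor(x, levels = c(reference, sort(setdiff(lev, reference)))),
                 ref = reference)
}

#' Negative-binomial differential cell-type abundance
#'
#' Models each cell type's per-sample cell count with a negative-binomial
#' regression, `log mu = X beta + log N_s`, where `N_s` is the total number
#' of analyzed cells in the sample (offset) and the design contains disease
#' condition plus technical/clinical covariates. Significance of the
#' condition contrasts is assessed by Wald tests on the regression
#' coefficients with Benjamini-Hochberg FDR across cell types. The
#' dispersion is estimated per cell type by maximum likelihood; cell types
#' where the NB fit fails fall back to Poisson and are flagged.
#'
#' @param comp an `eoe_composition`.
#' @param covariates sample-table columns entered as predictors besides
#'   `condition`; constant columns are dropped with a warning.
#' @param reference reference condition level (default `"healthy"`).
#' @return tibble with one row per cell type and condition contrast:
#'   `cell_type`, `contrast`, `estimate` (natural-log fold change), `se`,
#'   `statistic` (Wald z), `p.value`, `fdr` (BH across cell types within the
#'   contrast), `theta`, `model` ("nb" or "poisson" fallback).
#' @export
nb_abundance <- function(comp,
                         covariates = c("chemistry", "steroid", "region"),
                         reference = "healthy") {
  stopifnot(inherits(comp, "eoe_composition"))
  samples <- comp$samples
  if (!"condition" %in% names(samples))
    stop("sample table needs a `condition` column", call. = FALSE)
  cond <- condition_factor(samples$condition, reference)
  if (length(levels(cond)) < 2 || min(table(cond)) < 2)
    stop("need >= 2 condition levels with >= 2 samples each", call. = FALSE)
  covariates <- usable_covariates(samples, covariates, "nb_abundance")
  N <- rowSums(comp$counts)
  keep_types <- colSums(comp$counts) > 0
  if (any(!keep_types))
    warning("excluding all-zero cell types: ",
            paste(colnames(comp$counts)[!keep_types], collapse = ", "),
            call. = FALSE)
  df0 <- data.frame(condition = cond, samples[covariates], logN = log(N))
  form <- stats::reformulate(c("condition", covariates, "offset(logN)"),
                             response = "y")
  res <- purrr::map_dfr(colnames(comp$counts)[keep_types], function(ct) {
    df <- df0
    df$y <- comp$counts[, ct]
    fit <- NULL
    model <- "nb"
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(form, data = df,
                                    control = stats::glm.control(maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !is.finite(fit$theta)) {
      model <- "poisson"
      fit <- suppressWarnings(stats::glm(form, data = df, family = stats::poisson()))
    }
    sm <- summary(fit)$coefficients
    rows <- grep("^condition", rownames(sm), value = TRUE)
    tibble::tibble(
      cell_type = ct,
      contrast = paste0(sub("^condition", "", rows), "_vs_", reference),
      estimate = sm[rows, 1], se = sm[rows, 2], statistic = sm[rows, 3],
      p.value = 2 * stats::pnorm(-abs(sm[rows, 3])),
      theta = if (model == "nb") fit$theta else Inf,
      model = model
    )
  })
  res |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(fdr = stats::p.adjust(.data$p.value, "BH")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contrast, .data$p.value)
}

#' Centered log-ratio transform of a composition table
#'
#' Replaces zero counts by `zero_replace` (half-count multiplicative
#' replacement by default), closes each row to proportions and applies the
#' CLR: `ln p_c - mean_c ln p_c`. Output rows sum to zero.
#'
#' @param comp an `eoe_composition` or a nonnegative samples x parts matrix.
#' @param zero_replace pseudo-count substituted for zeros before closure.
#' @return samples x cell-types real matrix.
#' @export
clr_transform <- function(comp, zero_replace = 0.5) {
  y <- if (inherits(comp, "eoe_composition")) comp$counts else as.matrix(comp)
  if (any(y < 0)) stop("negative counts", call. = FALSE)
  if (any(rowSums(y) == 0)) stop("sample with all-zero counts", call. = FALSE)
  y[y == 0] <- zero_replace
  p <- sweep(y, 1, rowSums(y), "/")
  lg <- log(p)
  sweep(lg, 1, rowMeans(lg), "-")
}

#' PCA of CLR-transformed composition
#'
#' Centered (unscaled) principal component analysis of the CLR matrix, the
#' standard ordination for compositional shifts. The sign of each component
#' is fixed so that its largest-magnitude loading is positive.
#'
#' @param clr matrix from [clr_transform()] (or any samples x features
#'   matrix).
#' @param rank number of components to keep (default all available).
#' @return object of class `eoe_pca`: `scores` tibble (sample, PC columns),
#'   `loadings` tibble, `var_explained` numeric vector.
#' @export
composition_pca <- function(clr, rank = NULL) {
  if (nrow(clr) < 2) stop("need >= 2 samples", call. = FALSE)
  if (is.null(rownames(clr)))
    rownames(clr) <- paste0("s", seq_len(nrow(clr)))
  if (is.null(colnames(clr)))
    colnames(clr) <- paste0("v", seq_len(ncol(clr)))
  pc <- stats::prcomp(clr, center = TRUE, scale. = FALSE)
  r <- min(if (is.null(rank)) ncol(pc$x) else rank, ncol(pc$x))
  flip <- vapply(seq_len(r), function(j) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 1)
  scores <- sweep(pc$x[, seq_len(r), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(r), drop = FALSE], 2, flip, "*")
  ve <- pc$sdev^2 / max(sum(pc$sdev^2), .Machine$double.eps)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(clr)),
                              tibble::as_tibble(scores)),
    loadings = dplyr::bind_cols(tibble::tibble(cell_type = colnames(clr)),
                                tibble::as_tibble(loadings)),
    var_explained = ve[seq_len(r)]
  ), class = "eoe_pca")
}

#' @export
print.eoe_pca <- function(x, ...) {
  cat("<eoe_pca> ", nrow(x$scores), " samples, ",
      length(x$var_explained), " components (PC1 ",
      sprintf("%.1f%%", 100 * x$var_explained[1]), ")\n", sep = "")
  invisible(x)
}

#' Quantile normalization across samples
#'
#' Each column's values are replaced by the mean order statistics pooled
#' over all columns, preserving ranks (average for ties); after the
#' transform every column has the same sorted value vector.
#'
#' @param mat samples x variables numeric matrix.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    # average reference values for tied ranks (non-integer average ranks)
    stats::approx(seq_along(ref), ref, xout = rk, rule = 2)$y
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Rank regression of quantile-normalized proportions
#'
#' Nonparametric companion to [nb_abundance()]: cell-type proportions are
#' quantile-normalized across samples to a common reference distribution
#' (so rare, high-variance types are comparable to abundant ones), then each
#' cell type's normalized values are regressed on condition and covariates
#' by OLS with two-tailed t-tests on the coefficients and BH FDR across
#' cell types.
#'
#' @inheritParams nb_abundance
#' @return tibble: `cell_type`, `contrast`, `estimate`, `se`, `statistic`
#'   (t), `p.value`, `fdr`.
#' @export
quantile_rank_regression <- function(comp,
                                     covariates = c("chemistry", "steroid",
                                                    "region"),
                                     reference = "healthy") {
  stopifnot(inherits(comp, "eoe_composition"))
  samples <- comp$samples
  cond <- condition_factor(samples$condition, reference)
  covariates <- usable_covariates(samples, covariates, "quantile_rank_regression")
  qn <- quantile_normalize(composition_proportions(comp))
  df0 <- data.frame(condition = cond, samples[covariates])
  form <- stats::reformulate(c("condition", covariates), response = "y")
  res <- purrr::map_dfr(colnames(qn), function(ct) {
    df <- df0
    df$y <- qn[, ct]
    sm <- summary(stats::lm(form, data = df))$coefficients
    rows <- grep("^condition", rownames(sm), value = TRUE)
    tibble::tibble(
      cell_type = ct,
      contrast = paste0(sub("^condition", "", rows), "_vs_", reference),
      estimate = sm[rows, 1], se = sm[rows, 2], statistic = sm[rows, 3],
      p.value = sm[rows, 4])
  })
  res |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(fdr = stats::p.adjust(.data$p.value, "BH")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contrast, .data$p.value)
}

#' PERMANOVA on cellular composition
#'
#' Permutational multivariate ANOVA of the quantile-normalized composition
#' profiles under Euclidean distance, partitioning sequential sums of
#' squares across the model terms; the p-value for each term is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param comp an `eoe_composition`.
#' @param terms sample-table columns to partition variance over, in order;
#'   single-level terms are dropped with a warning.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed making the permutations reproducible.
#' @return tibble: `term`, `df`, `sum_of_squares`, `r_squared`, `statistic`
#'   (pseudo-F), `p.value`.
#' @export
permanova_composition <- function(comp, terms = c("condition", "steroid", "diet"),
                                  n_perm = 1e4, seed = 1L) {
  stopifnot(inherits(comp, "eoe_composition"), n_perm >= 99)
  samples <- comp$samples
  terms <- usable_covariates(samples, terms, "permanova_composition")
  if (!length(terms)) stop("no usable terms", call. = FALSE)
  qn <- quantile_normalize(composition_proportions(comp))
  d <- stats::dist(qn)
  df <- as.data.frame(samples[terms])
  form <- stats::reformulate(terms, response = "d")
  env <- list2env(list(d = d))
  res <- withr_seed(as.integer(seed), {
    vegan::adonis2(stats::as.formula(form, env = env), data = df,
                   permutations = n_perm, by = "terms")
  })
  tb <- tibble::tibble(
    term = rownames(res), df = res$Df, sum_of_squares = res$SumOfSqs,
    r_squared = res$R2, statistic = res$F, p.value = res$`Pr(>F)`)
  dplyr::filter(tb, !.data$term %in% c("Residual", "Total"))
}

#' Correlation of cell-type abundance with disease activity
#'
#' Spearman rank correlation between a per-sample clinical activity measure
#' (eosinophils per high-power field, EREFS, ...) and each cell type's
#' abundance, with t-based two-tailed p-values
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` df) and BH FDR across cell
#' types.
#'
#' @param comp an `eoe_composition`.
#' @param activity name of the sample-table column holding the activity
#'   measure, or a numeric vector aligned to samples.
#' @param use correlate raw cell counts (`"counts"`, default) or per-sample
#'   proportions (`"proportions"`).
#' @param fdr_cutoff reported set threshold (default 0.1).
#' @return tibble: `cell_type`, `rho`, `statistic`, `p.value`, `fdr`,
#'   `reported` (fdr < cutoff).
#' @export
activity_correlation <- function(comp, activity = "eos_per_hpf",
                                 use = c("counts", "proportions"),
                                 fdr_cutoff = 0.1) {
  stopifnot(inherits(comp, "eoe_composition"))
  use <- match.arg(use)
  act <- if (is.character(activity) && length(activity) == 1)
    comp$samples[[activity]] else activity
  if (is.null(act)) stop("activity column not found", call. = FALSE)
  ok <- !is.na(act)
  if (sum(ok) < 4) stop("need >= 4 samples with activity values", call. = FALSE)
  if (stats::sd(act[ok]) == 0)
    stop("activity is constant; correlation undefined", call. = FALSE)
  mat <- if (use == "counts") comp$counts else composition_proportions(comp)
  mat <- mat[ok, , drop = FALSE]
  act <- act[ok]
  n <- length(act)
  res <- purrr::map_dfr(colnames(mat), function(ct) {
    rho <- suppressWarnings(stats::cor(mat[, ct], act, method = "spearman"))
    if (is.na(rho)) return(tibble::tibble(cell_type = ct, rho = NA_real_,
                                          statistic = NA_real_, p.value = NA_real_))
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    tibble::tibble(cell_type = ct, rho = rho, statistic = tt,
                   p.value = 2 * stats::pt(-abs(tt), df = n - 2))
  })
  res$fdr <- stats::p.adjust(res$p.value, "BH")
  res$reported <- !is.na(res$fdr) & res$fdr < fdr_cutoff
  dplyr::arrange(res, .data$p.value)
}

#' Cell-type proportion co-variation clusters
#'
#' Pearson correlation across samples between the proportions of every pair
#' of cell types, hierarchically clustered with the Mcquitty (WPGMA) linkage
#' on distance `1 - r`. Cell types with zero variance across samples are
#' excluded with a warning.
#'
#' @param comp an `eoe_composition`.
#' @return object of class `eoe_propclust`: `correlation` matrix, `hclust`
#'   tree, `excluded` character vector.
#' @export
proportion_correlation_clusters <- function(comp) {
  stopifnot(inherits(comp, "eoe_composition"))
  if (nrow(comp$counts) < 3) stop("need >= 3 samples", call. = FALSE)
  props <- composition_proportions(comp)
  sds <- apply(props, 2, stats::sd)
  excluded <- colnames(props)[sds == 0]
  if (length(excluded))
    warning("excluding zero-variance cell types: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  props <- props[, sds > 0, drop = FALSE]
  r <- stats::cor(props)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "mcquitty")
  structure(list(correlation = r, hclust = hc, excluded = excluded),
            class = "eoe_propclust")
}

#' @export
print.eoe_propclust <- function(x, ...) {
  cat("<eoe_propclust> ", ncol(x$correlation), " cell types clustered (WPGMA on 1 - r)\n",
      sep = "")
  invisible(x)
}

#' Fisher's exact tests of subset membership by condition
#'
#' Two-tailed Fisher's exact test on 2x2 contingency tables of cell-subset
#' membership versus condition; when several subsets are tested at once the
#' p-values are BH-adjusted. A table with an empty margin is degenerate:
#' its p-value is 1 by convention and the row is flagged.
#'
#' @param tables a single 2x2 matrix, or a named list of 2x2 matrices
#'   (one per subset).
#' @return tibble: `subset`, `odds_ratio`, `p.value`, `fdr`, `degenerate`.
#' @export
condition_proportion_fisher <- function(tables) {
  if (is.matrix(tables)) tables <- list(subset = tables)
  if (is.null(names(tables))) names(tables) <- paste0("subset", seq_along(tables))
  res <- purrr::imap_dfr(tables, function(tab, nm) {
    tab <- as.matrix(tab)
    stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(tibble::tibble(subset = nm, odds_ratio = NA_real_, p.value = 1,
                            degenerate = TRUE))
    }
    ft <- stats::fisher.test(tab)
    tibble::tibble(subset = nm, odds_ratio = unname(ft$estimate),
                   p.value = ft$p.value, degenerate = FALSE)
  })
  res$fdr <- stats::p.adjust(res$p.value, "BH")
  res[, c("subset", "odds_ratio", "p.value", "fdr", "degenerate")]
}

#' Lasso selection of composition features predicting a cell fraction
#'
#' L1-penalized linear regression of a per-sample target fraction (for
#' example IL13RA2+ fibroblasts out of all fibroblasts) on per-sample
#' cell-type composition features. The penalty is chosen by leave-one-out
#' cross-validation over a log-spaced grid; the model is then refit on all
#' samples at the selected penalty, and the leave-one-out predictions are
#' compared with the observed values by a linear regression whose slope
#' t-test p-value summarizes predictive association.
#'
#' @param target numeric per-sample response (length = rows of `features`).
#' @param features samples x features numeric matrix (standardized
#'   internally by the fit).
#' @param nlambda length of the penalty grid.
#' @return object of class `eoe_lasso` with elements `lambda`, `coef`
#'   (tibble of nonzero coefficients), `predictions` tibble
#'   (`observed`, `loocv_predicted`), `slope`, `slope_p`, `r`; methods
#'   [generics::tidy()], [generics::glance()], [ggplot2::autoplot()].
#' @export
lasso_fraction_predictor <- function(target, features, nlambda = 100) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(target) != n) stop("target/feature length mismatch", call. = FALSE)
  if (n < 5) stop("need >= 5 samples", call. = FALSE)
  if (all(target == 0)) stop("target is identically zero", call. = FALSE)
  cv <- glmnet::cv.glmnet(features, target, nfolds = n, grouped = FALSE,
                          keep = TRUE, standardize = TRUE, nlambda = nlambda)
  ilam <- which.min(cv$cvm)
  preds <- cv$fit.preval[, ilam]
  cf <- stats::coef(cv, s = cv$lambda[ilam])
  nz <- which(cf[-1] != 0)
  coefs <- tibble::tibble(feature = rownames(cf)[-1][nz],
                          estimate = cf[-1][nz])
  slope <- slope_p <- r <- NA_real_
  if (stats::sd(preds) > 0) {
    sl <- summary(stats::lm(target ~ preds))$coefficients
    slope <- sl["preds", 1]; slope_p <- sl["preds", 4]
    r <- stats::cor(target, preds)
  }
  structure(list(
    lambda = cv$lambda[ilam], cv = cv, coef = coefs,
    predictions = tibble::tibble(observed = target, loocv_predicted = preds),
    slope = slope, slope_p = slope_p, r = r, n = n
  ), class = "eoe_lasso")
}

#' @export
print.eoe_lasso <- function(x, ...) {
  cat("<eoe_lasso> lambda* = ", signif(x$lambda, 3), ", ",
      nrow(x$coef), " features selected, LOOCV r = ", signif(x$r, 3), "\n", sep = "")
  invisible(x)
}
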