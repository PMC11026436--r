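#' Gene signature score with binned control genes
#'
#' Per-cell signature score in the binned-control style: all genes are
#' ranked by their dataset-average log-normalized expression and split into
#' `n_bins` expression bins; for every signature gene, `n_ctrl` control
#' genes are drawn from its bin; the score of a cell is the mean
#' log-normalized expression of the signature genes minus the mean of the
#' control genes. A signature that behaves like its expression-matched
#' controls therefore scores around zero.
#'
#' @param atlas an [eoe_atlas()].
#' @param signature character vector of gene names (duplicates removed);
#'   genes absent from the matrix are dropped, and an all-absent signature
#'   is an error.
#' @param n_bins number of expression bins (default 25).
#' @param n_ctrl control genes sampled per signature gene (default 100,
#'   with replacement when a bin is smaller).
#' @param seed integer seed for the control draw.
#' @return named numeric vector of per-cell scores.
#' @export
score_signature <- function(atlas, signature, n_bins = 25, n_ctrl = 100,
                            seed = 1L) {
  stopifnot(inherits(atlas, "eoe_atlas"))
  signature <- unique(signature)
  present <- intersect(signature, atlas$genes)
  if (!length(present))
    stop("signature entirely absent from the matrix", call. = FALSE)
  if (ncol(atlas$counts) < n_bins)
    stop("fewer genes than bins", call. = FALSE)
  ln <- lognorm(atlas)
  avg <- Matrix::colMeans(ln)
  bins <- ggplot2::cut_number(rank(avg, ties.method = "first"), n = n_bins,
                              labels = FALSE)
  sig_idx <- match(present, atlas$genes)
  ctrl_idx <- withr_seed(seed, {
    unlist(lapply(sig_idx, function(g) {
      pool <- which(bins == bins[g])
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  sig_mean <- Matrix::rowMeans(ln[, sig_idx, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(ln[, ctrl_idx, drop = FALSE])
  stats::setNames(as.vector(sig_mean - ctrl_mean), atlas$cells$barcode)
}

#' Non-negative matrix factorization gene programs
#'
#' Decomposes the log-normalized expression of a cell family (e.g. all
#' macrophages) into `rank` additive gene programs by NMF with
#' multiplicative Frobenius updates from a seeded random start. Cells are
#' scored by their program coefficients, and each program is summarized by
#' its top-loading genes.
#'
#' @param atlas an [eoe_atlas()] (typically subset to one cell family).
#' @param rank number of programs (>= 1, at most `min(dim)`).
#' @param n_iter multiplicative update iterations.
#' @param seed integer seed for the random initialization.
#' @return object of class `eoe_nmf`: `gene_loadings` (genes x rank),
#'   `cell_scores` (cells x rank), `error_trace` (Frobenius reconstruction
#'   error per iteration, nonincreasing), `rank`.
#' @export
nmf_programs <- function(atlas, rank = 6, n_iter = 200, seed = 1L) {
  stopifnot(inherits(atlas, "eoe_atlas"))
  V <- t(as.matrix(lognorm(atlas)))  # genes x cells, nonnegative
  if (rank > min(dim(V))) stop("rank exceeds matrix dimensions", call. = FALSE)
  if (rank < 1) stop("rank must be >= 1", call. = FALSE)
  eps <- 1e-10
  set <- withr_seed(seed, list(
    W = matrix(stats::runif(nrow(V) * rank, 0.1, 1), ncol = rank),
    H = matrix(stats::runif(rank * ncol(V), 0.1, 1), nrow = rank)))
  W <- set$W; H <- set$H
  err <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    err[it] <- norm(V - W %*% H, "F")
  }
  dimnames(W) <- list(rownames(V), paste0("program", seq_len(rank)))
  dimnames(H) <- list(colnames(W), colnames(V))
  structure(list(gene_loadings = W, cell_scores = t(H),
                 error_trace = err, rank = rank), class = "eoe_nmf")
}

#' @export
print.eoe_nmf <- function(x, ...) {
  cat("<eoe_nmf> ", nrow(x$gene_loadings), " genes x ", nrow(x$cell_scores),
      " cells, rank ", x$rank, ", final error ",
      signif(utils::tail(x$error_trace, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Top genes of each NMF program
#' @param x an `eoe_nmf`.
#' @param n genes per program.
#' @return tibble: `program`, `gene`, `loading`, `rank`.
#' @export
program_top_genes <- function(x, n = 10) {
  purrr::map_dfr(colnames(x$gene_loadings), function(p) {
    v <- x$gene_loadings[, p]
    ord <- order(v, decreasing = TRUE)[seq_len(min(n, length(v)))]
    tibble::tibble(program = p, gene = names(v)[ord], loading = v[ord],
                   rank = seq_along(ord))
  })
}

#' Expressed-fraction screen for candidate genes
#'
#' For each candidate gene and each cell subset, the fraction of the
#' subset's cells with nonzero counts; a gene passes in a subset when that
#' fraction is at least `threshold` (default 25%).
#'
#' @param atlas an [eoe_atlas()] with `cell_type` labels.
#' @param genes candidate gene names.
#' @param threshold minimum expressing-cell fraction (inclusive).
#' @return tibble: `gene`, `cell_type`, `frac_expressing`, `pass`.
#' @export
expressed_gene_screen <- function(atlas, genes, threshold = 0.25) {
  stopifnot(inherits(atlas, "eoe_atlas"))
  labels <- atlas$cells$cell_type
  if (is.null(labels)) stop("cells carry no `cell_type` labels", call. = FALSE)
  gi <- match(genes, atlas$genes)
  if (anyNA(gi))
    stop("unknown gene(s): ", paste(genes[is.na(gi)], collapse = ", "),
         call. = FALSE)
  purrr::map_dfr(sort(unique(labels)), function(ct) {
    rows <- which(labels == ct)
    frac <- Matrix::colMeans(atlas$counts[rows, gi, drop = FALSE] > 0)
    tibble::tibble(gene = genes, cell_type = ct,
                   frac_expressing = as.vector(frac),
                   pass = as.vector(frac) >= threshold)
  })
}

#' Risk-gene modules from subset pseudo-bulk profiles
#'
#' Builds the mean-variant pseudo-bulk profile of each candidate gene across
#' cell subsets, square-root transforms it (variance stabilization for
#' count means) and clusters genes by Ward.D2 agglomeration on Euclidean
#' distances between profiles; modules come from cutting the tree.
#'
#' @param atlas an [eoe_atlas()] with `cell_type` labels.
#' @param genes candidate genes (>= 3 after screening, or an error).
#' @param k number of modules to cut; `NULL` cuts at half the maximum merge
#'   height.
#' @param subsets optional subset whitelist (default all labeled subsets).
#' @return object of class `eoe_modules`: `profiles` (genes x subsets sqrt
#'   mean pseudo-bulk), `hclust`, `modules` tibble (`gene`, `module`).
#' @export
risk_modules <- function(atlas, genes, k = NULL, subsets = NULL) {
  stopifnot(inherits(atlas, "eoe_atlas"))
  labels <- atlas$cells$cell_type
  if (is.null(subsets)) subsets <- sort(unique(labels))
  genes <- sort(unique(genes))
  if (length(genes) < 3) stop("need >= 3 genes", call. = FALSE)
  prof <- vapply(subsets, function(ct)
    pseudobulk_mean(atlas, cells = which(labels == ct))[genes],
    numeric(length(genes)))
  prof <- sqrt(matrix(prof, nrow = length(genes),
                      dimnames = list(genes, subsets)))
  if (any(stats::dist(prof) == 0))
    warning("genes with identical profiles present (distance 0); merged first",
            call. = FALSE)
  hc <- stats::hclust(stats::dist(prof), method = "ward.D2")
  kk <- if (is.null(k)) max(sum(hc$height > max(hc$height) / 2) + 1, 1) else k
  mods <- stats::cutree(hc, k = min(kk, length(genes)))
  structure(list(profiles = prof, hclust = hc,
                 modules = tibble::tibble(gene = names(mods),
                                          module = unname(mods))),
            class = "eoe_modules")
}

#' @export
print.eoe_modules <- function(x, ...) {
  cat("<eoe_modules> ", nrow(x$profiles), " genes, ",
      length(unique(x$modules$module)), " modules (Ward.D2 on sqrt pseudo-bulk)\n",
      sep = "")
  invisible(x)
}

#' Spearman correlation of two per-sample summaries
#'
#' Rank correlation (average ties) between paired per-sample statistics,
#' e.g. a cell subset's per-sample proportion against the per-sample mean
#' signature score of that subset, with the t-based two-tailed p-value.
#'
#' @param a,b paired numeric vectors (n >= 4 after NA removal).
#' @return tibble: `rho`, `statistic`, `p.value`, `n`.
#' @export
signature_correlation <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 4) stop("need >= 4 paired samples", call. = FALSE)
  rho <- stats::cor(a, b, method = "spearman")
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  tibble::tibble(rho = rho, statistic = tt,
                 p.value = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}
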