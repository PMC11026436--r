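#' Learn a supervised latent space from a labeled reference
#'
#' Maps the labeled reference to a low-dimensional latent space by
#' neighborhood component analysis (NCA): a linear projection of
#' standardized log-normalized expression optimized so that stochastic
#' nearest-neighbor classification of the labels succeeds. The projection is
#' initialized from PCA and refined by L-BFGS on the softmax-NCA objective;
#' with `nca_iter = 0` the model degenerates to the PCA projection. The
#' preprocessing recipe (gene set, per-gene reference mean/sd) is frozen
#' into the model and re-applied unchanged to queries, so no query
#' statistics leak into the mapping.
#'
#' @param reference an [eoe_atlas()] whose cells carry `cell_type` labels.
#' @param dim latent dimensionality (default 50, capped at the number of
#'   genes used).
#' @param n_hvg number of highly variable genes retained (by lognorm
#'   variance); `NULL` keeps all genes.
#' @param nca_iter maximum NCA optimizer iterations (default 30).
#' @param max_cells training cells subsampled per fit for tractability.
#' @param seed integer seed (subsampling and optimizer are deterministic
#'   given it).
#' @return object of class `eoe_latent`: `projection` (genes x dim),
#'   `genes`, `center`, `scale`, `latent` (training embedding), `labels`,
#'   `converged`.
#' @export
fit_latent <- function(reference, dim = 50, n_hvg = 2000, nca_iter = 30,
                       max_cells = 2000, seed = 1L) {
  stopifnot(inherits(reference, "eoe_atlas"))
  labels <- reference$cells$cell_type
  if (is.null(labels) || length(unique(labels)) < 2)
    stop("reference needs >= 2 cell-type labels", call. = FALSE)
  ln <- lognorm(reference)
  vars <- col_vars_sparse(ln)
  keep <- if (is.null(n_hvg) || n_hvg >= ncol(ln)) seq_len(ncol(ln)) else
    sort(order(vars, decreasing = TRUE)[seq_len(n_hvg)])
  genes <- reference$genes[keep]
  if (dim > length(genes))
    stop("latent dim (", dim, ") exceeds number of genes used (",
         length(genes), ")", call. = FALSE)
  X <- as.matrix(ln[, keep, drop = FALSE])
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- scale(X, center = ctr, scale = scl)
  idx <- seq_len(nrow(Xs))
  if (nrow(Xs) > max_cells) {
    idx <- withr_seed(seed, sample(idx, max_cells))
  }
  Xt <- Xs[idx, , drop = FALSE]
  yt <- labels[idx]
  pc <- stats::prcomp(Xt, center = FALSE, scale. = FALSE, rank. = dim)
  A0 <- pc$rotation  # genes x dim
  converged <- TRUE
  A <- A0
  if (nca_iter > 0) {
    opt <- withr_seed(seed, stats::optim(
      par = as.vector(A0), fn = nca_objective, gr = nca_gradient,
      X = Xt, y = yt, d = dim, method = "L-BFGS-B",
      control = list(maxit = nca_iter)))
    A <- matrix(opt$par, ncol = dim)
    converged <- opt$convergence == 0
  }
  dimnames(A) <- list(genes, paste0("L", seq_len(dim)))
  structure(list(projection = A, genes = genes, center = ctr, scale = scl,
                 latent = Xs %*% A, labels = labels, converged = converged,
                 dim = dim), class = "eoe_latent")
}

col_vars_sparse <- function(m) {
  mu <- Matrix::colMeans(m)
  Matrix::colMeans(m^2) - mu^2
}

# negative NCA objective: -sum_i p(correct neighbor of i)
nca_softmax <- function(par, X, y, d) {
  A <- matrix(par, ncol = d)
  Z <- X %*% A
  n <- nrow(Z)
  sq <- rowSums(Z^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
  D <- pmax(D, 0)
  E <- exp(-(D - apply(D + diag(Inf, n), 1, min)))  # row-shifted for stability
  diag(E) <- 0
  P <- E / pmax(rowSums(E), .Machine$double.eps)
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  list(P = P, same = same, Z = Z)
}

nca_objective <- function(par, X, y, d) {
  s <- nca_softmax(par, X, y, d)
  -sum(s$P[s$same])
}

nca_gradient <- function(par, X, y, d) {
  s <- nca_softmax(par, X, y, d)
  P <- s$P; same <- s$same; Z <- s$Z
  p_i <- rowSums(P * same)
  # d f / dA = 2 S A with S = sum_ik W_ik (x_i - x_k)(x_i - x_k)',
  # W_ik = p_ik (p_i - [k in class of i]); expand S A via
  # X' diag(rs) Z - X' W Z - X' W' Z + X' diag(cs) Z
  W <- P * p_i - P * same
  rs <- rowSums(W); cs <- colSums(W)
  SA <- t(X) %*% (rs * Z) - t(X) %*% (W %*% Z) -
    t(X) %*% (t(W) %*% Z) + t(X) %*% (cs * Z)
  # objective is -f, so its gradient is -2 S A
  -2 * as.vector(SA)
}

#' @export
print.eoe_latent <- function(x, ...) {
  cat("<eoe_latent> ", length(x$genes), " genes -> ", x$dim,
      " dims, ", length(unique(x$labels)), " reference labels\n", sep = "")
  invisible(x)
}

#' Project new cells into a fitted latent space
#'
#' Applies the frozen preprocessing recipe (gene intersection, reference
#' standardization) and the linear NCA projection to query cells.
#'
#' @param model an `eoe_latent` from [fit_latent()].
#' @param query an [eoe_atlas()].
#' @param min_overlap minimum fraction of model genes the query must share.
#' @return cells x dim latent matrix.
#' @export
project_latent <- function(model, query, min_overlap = 0.5) {
  stopifnot(inherits(model, "eoe_latent"), inherits(query, "eoe_atlas"))
  shared <- intersect(model$genes, query$genes)
  if (length(shared) < min_overlap * length(model$genes)) {
    miss <- setdiff(model$genes, query$genes)
    stop("query shares only ", length(shared), "/", length(model$genes),
         " model genes (missing e.g. ",
         paste(utils::head(miss, 5), collapse = ", "), ")", call. = FALSE)
  }
  ln <- lognorm(query)
  gi <- match(model$genes, query$genes)
  X <- matrix(0, nrow(ln), length(model$genes))
  present <- !is.na(gi)
  X[, present] <- as.matrix(ln[, gi[present], drop = FALSE])
  # absent genes imputed at the reference mean (z = 0 after standardization)
  X[, !present] <- matrix(model$center[!present], nrow(X), sum(!present),
                          byrow = TRUE)
  Xs <- scale(X, center = model$center, scale = model$scale)
  Xs %*% model$projection
}

#' k-nearest-neighbor label transfer in the latent space
#'
#' Classifies query cells by Euclidean k-nearest neighbors among the
#' reference cells in the NCA latent space: majority label, ties broken by
#' the largest summed inverse distance, with the vote fraction reported as
#' a confidence.
#'
#' @param model an `eoe_latent`.
#' @param query an [eoe_atlas()].
#' @param k neighbors (default 11).
#' @param min_overlap passed to [project_latent()].
#' @return tibble: `barcode`, `label`, `vote_frac`.
#' @export
classify_knn <- function(model, query, k = 11, min_overlap = 0.5) {
  Zq <- project_latent(model, query, min_overlap)
  Zr <- model$latent
  labs <- model$labels
  k <- min(k, nrow(Zr))
  sq_r <- rowSums(Zr^2)
  out <- vector("list", nrow(Zq))
  block <- 500L
  for (start in seq(1, nrow(Zq), by = block)) {
    rows <- start:min(start + block - 1, nrow(Zq))
    D <- outer(rowSums(Zq[rows, , drop = FALSE]^2), sq_r, "+") -
      2 * Zq[rows, , drop = FALSE] %*% t(Zr)
    D <- pmax(D, 0)
    for (r in seq_along(rows)) {
      nn <- order(D[r, ])[seq_len(k)]
      votes <- table(labs[nn])
      top <- names(votes)[votes == max(votes)]
      if (length(top) > 1) {
        invd <- vapply(top, function(lb)
          sum(1 / pmax(sqrt(D[r, nn[labs[nn] == lb]]), 1e-12)), 1)
        top <- names(which.max(invd))
      }
      out[[rows[r]]] <- tibble::tibble(label = top,
                                       vote_frac = max(votes) / k)
    }
  }
  dplyr::bind_cols(tibble::tibble(barcode = query$cells$barcode),
                   dplyr::bind_rows(out))
}
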