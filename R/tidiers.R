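#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy / glance methods for fitted eoatlas objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated component,
#' `glance()` a one-row model summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return a tibble.
#' @name eoatlas-tidiers
NULL

#' @rdname eoatlas-tidiers
#' @export
tidy.eoe_lasso <- function(x, ...) x$coef

#' @rdname eoatlas-tidiers
#' @export
glance.eoe_lasso <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_selected = nrow(x$coef),
                 slope = x$slope, slope_p = x$slope_p, r = x$r, n = x$n)
}

#' @rdname eoatlas-tidiers
#' @export
tidy.eoe_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"cell_type", names_to = "component",
                      values_to = "loading")
}

#' @rdname eoatlas-tidiers
#' @export
glance.eoe_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$var_explained)),
                 var_explained = x$var_explained)
}

#' @rdname eoatlas-tidiers
#' @export
tidy.eoe_interaction <- function(x, ...) {
  dplyr::filter(x$ledger, .data$in_top_k)
}

#' @rdname eoatlas-tidiers
#' @export
glance.eoe_interaction <- function(x, ...) {
  tibble::tibble(n_subsets = nrow(x$strength), k = x$k,
                 n_pairs = length(unique(x$ledger$pair_id)),
                 n_excluded = length(x$excluded),
                 max_strength = max(x$strength))
}

#' @rdname eoatlas-tidiers
#' @export
tidy.eoe_nmf <- function(x, ...) program_top_genes(x)

#' @rdname eoatlas-tidiers
#' @export
glance.eoe_nmf <- function(x, ...) {
  tibble::tibble(rank = x$rank, n_iter = length(x$error_trace),
                 final_error = utils::tail(x$error_trace, 1))
}

#' @rdname eoatlas-tidiers
#' @export
tidy.eoe_modules <- function(x, ...) x$modules

#' @rdname eoatlas-tidiers
#' @export
tidy.eoe_propclust <- function(x, ...) {
  r <- x$correlation
  idx <- which(upper.tri(r), arr.ind = TRUE)
  tibble::tibble(type_a = rownames(r)[idx[, 1]], type_b = colnames(r)[idx[, 2]],
                 r = r[idx])
}

#' @rdname eoatlas-tidiers
#' @export
glance.eoe_latent <- function(x, ...) {
  tibble::tibble(dim = x$dim, n_genes = length(x$genes),
                 n_cells = nrow(x$latent),
                 n_labels = length(unique(x$labels)), converged = x$converged)
}
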