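#' Read a ligand-receptor catalog
#'
#' Catalog CSV with columns `pair_id`, `ligand_subunits`, `receptor_subunits`;
#' multi-subunit complexes (e.g. integrin heterodimers) list their subunits
#' separated by `|`. A small demo catalog ships with the package
#' (`system.file("extdata", "lr_demo_catalog.csv", package = "eoatlas")`).
#'
#' @param path CSV file path.
#' @return tibble of class `lr_catalog`: `pair_id`, `ligand` (list column of
#'   character vectors), `receptor` (list column).
#' @export
read_lr_catalog <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("pair_id", "ligand_subunits", "receptor_subunits")
  if (!all(need %in% names(df)))
    stop("catalog must have columns ", paste(need, collapse = ", "), call. = FALSE)
  out <- tibble::tibble(
    pair_id = df$pair_id,
    ligand = strsplit(df$ligand_subunits, "|", fixed = TRUE),
    receptor = strsplit(df$receptor_subunits, "|", fixed = TRUE))
  if (any(lengths(out$ligand) == 0) || any(lengths(out$receptor) == 0))
    stop("every pair needs at least one subunit on each side", call. = FALSE)
  class(out) <- c("lr_catalog", class(out))
  out
}

#' @rdname read_lr_catalog
#' @param pair_id,ligand,receptor construct a catalog in code: id vector,
#'   list of ligand subunit sets, list of receptor subunit sets.
#' @export
lr_catalog <- function(pair_id, ligand, receptor) {
  out <- tibble::tibble(pair_id = pair_id,
                        ligand = lapply(ligand, as.character),
                        receptor = lapply(receptor, as.character))
  if (any(lengths(out$ligand) == 0) || any(lengths(out$receptor) == 0))
    stop("every pair needs at least one subunit on each side", call. = FALSE)
  class(out) <- c("lr_catalog", class(out))
  out
}

#' Per-gene UMI share across cell subsets
#'
#' For every gene, the share of its total detected UMIs contributed by each
#' cell subset: `s[g, subset] = UMIs of g in subset / UMIs of g overall`.
#' Rows of detected genes sum to 1; undetected genes are all-zero. Subsets
#' smaller than `min_cells` are dropped before the shares are computed, so
#' tiny subsets do not produce noisy shares.
#'
#' @param atlas an [eoe_atlas()] with `cell_type` labels (or supply
#'   `labels`).
#' @param labels optional per-cell subset labels overriding `cell_type`.
#' @param min_cells subsets with fewer cells are excluded (default 10).
#' @return genes x subsets dense matrix of shares.
#' @export
subset_shares <- function(atlas, labels = NULL, min_cells = 10) {
  stopifnot(inherits(atlas, "eoe_atlas"))
  if (is.null(labels)) labels <- atlas$cells$cell_type
  if (is.null(labels) || anyNA(labels))
    stop("every cell must carry a subset label", call. = FALSE)
  keep_lab <- names(which(table(labels) >= min_cells))
  keep <- labels %in% keep_lab
  m <- atlas$counts[keep, , drop = FALSE]
  lab <- factor(labels[keep], levels = sort(keep_lab))
  # subset x gene sums, then transpose to genes x subsets
  agg <- t(as.matrix(Matrix::t(m) %*% Matrix::sparse.model.matrix(~ 0 + lab)))
  sums <- colSums(agg)
  shares <- t(agg) / ifelse(sums > 0, sums, 1)
  shares[sums == 0, ] <- 0
  dimnames(shares) <- list(atlas$genes, levels(lab))
  shares
}

#' Geometric-mean complex weight
#'
#' Weight of a (possibly multi-subunit) complex in one subset: the geometric
#' mean of the subunit genes' UMI shares there. Any subunit with zero share
#' makes the weight zero.
#'
#' @param shares matrix from [subset_shares()].
#' @param subunits character vector of subunit gene names.
#' @param subset subset (column) name.
#' @return scalar weight in `[0, 1]`.
#' @export
complex_weight <- function(shares, subunits, subset) {
  missing <- setdiff(subunits, rownames(shares))
  if (length(missing))
    stop("unresolvable subunit(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  vals <- shares[subunits, subset]
  if (any(vals == 0)) return(0)
  exp(mean(log(vals)))
}

#' Directed ligand-receptor pair scores between two subsets
#'
#' Score of a pair for ordered subsets (i = ligand side, j = receptor side):
#' the product of the ligand complex weight in i and the receptor complex
#' weight in j. Pairs with subunits absent from the matrix are excluded and
#' logged in the `excluded` attribute.
#'
#' @param shares matrix from [subset_shares()].
#' @param catalog an [lr_catalog()].
#' @param i,j subset names (ligand side, receptor side).
#' @return tibble: `pair_id`, `ligand_weight`, `receptor_weight`, `score`.
#' @export
pair_scores <- function(shares, catalog, i, j) {
  genes <- rownames(shares)
  resolvable <- purrr::map_lgl(seq_len(nrow(catalog)), function(p)
    all(c(catalog$ligand[[p]], catalog$receptor[[p]]) %in% genes))
  excluded <- catalog$pair_id[!resolvable]
  cat2 <- catalog[resolvable, ]
  out <- purrr::map_dfr(seq_len(nrow(cat2)), function(p) {
    lw <- complex_weight(shares, cat2$ligand[[p]], i)
    rw <- complex_weight(shares, cat2$receptor[[p]], j)
    tibble::tibble(pair_id = cat2$pair_id[p], ligand_weight = lw,
                   receptor_weight = rw, score = lw * rw)
  })
  attr(out, "excluded") <- excluded
  out
}

#' Top-k ligand-receptor interaction strength between subsets
#'
#' For every ordered pair of cell subsets (ligand side, receptor side) the
#' interaction strength is the sum of the k largest ligand-receptor pair
#' scores; truncating at k damps the contribution of the long tail of
#' background pairs. The per-pair score ledger is retained so any strength
#' entry can be reproduced by summing its top-k ledger rows.
#'
#' @param shares matrix from [subset_shares()].
#' @param catalog an [lr_catalog()].
#' @param k number of top pair scores summed (default 10).
#' @param symmetrize also report `strength[i,j] + strength[j,i]`.
#' @return object of class `eoe_interaction`: `strength` (directed subsets x
#'   subsets matrix), `symmetric` (or NULL), `ledger` tibble (`source`,
#'   `target`, `pair_id`, `score`, `rank`, `in_top_k`), `k`.
#' @export
interaction_strength <- function(shares, catalog, k = 10, symmetrize = FALSE) {
  stopifnot(k >= 1)
  subsets <- colnames(shares)
  genes <- rownames(shares)
  resolvable <- purrr::map_lgl(seq_len(nrow(catalog)), function(p)
    all(c(catalog$ligand[[p]], catalog$receptor[[p]]) %in% genes))
  cat2 <- catalog[resolvable, ]
  # precompute complex weights per subset: pairs x subsets, ligand & receptor
  lw <- matrix(0, nrow(cat2), length(subsets),
               dimnames = list(cat2$pair_id, subsets))
  rw <- lw
  for (p in seq_len(nrow(cat2))) for (s in subsets) {
    lw[p, s] <- complex_weight(shares, cat2$ligand[[p]], s)
    rw[p, s] <- complex_weight(shares, cat2$receptor[[p]], s)
  }
  strength <- matrix(0, length(subsets), length(subsets),
                     dimnames = list(subsets, subsets))
  ledger <- vector("list", length(subsets)^2)
  li <- 0
  for (i in subsets) for (j in subsets) {
    sc <- lw[, i] * rw[, j]
    ord <- order(sc, decreasing = TRUE)
    topn <- min(k, length(sc))
    strength[i, j] <- sum(sc[ord][seq_len(topn)])
    li <- li + 1
    ledger[[li]] <- tibble::tibble(
      source = i, target = j, pair_id = cat2$pair_id[ord], score = sc[ord],
      rank = seq_along(ord), in_top_k = seq_along(ord) <= topn)
  }
  structure(list(
    strength = strength,
    symmetric = if (symmetrize) strength + t(strength) else NULL,
    ledger = dplyr::bind_rows(ledger), k = k,
    excluded = catalog$pair_id[!resolvable]
  ), class = "eoe_interaction")
}

#' @export
print.eoe_interaction <- function(x, ...) {
  cat("<eoe_interaction> ", nrow(x$strength), " subsets, k = ", x$k,
      ", max strength ", signif(max(x$strength), 3), "\n", sep = "")
  invisible(x)
}

#' Rank the interaction partners of each cell type
#'
#' Orders, for every cell subset, its partners by directed interaction
#' strength (ties broken lexicographically by partner name) and reports the
#' top `top_n` with row z-scores of the strengths (sample standard
#' deviation; a single partner gets z = 0 and is flagged degenerate).
#'
#' @param x an `eoe_interaction` from [interaction_strength()].
#' @param cell_type optional single subset; default all.
#' @param top_n partners to report per subset.
#' @param direction rank partners as receivers of this subset's ligands
#'   (`"outgoing"`, rows) or senders to it (`"incoming"`, columns).
#' @return tibble: `cell_type`, `partner`, `strength`, `rank`, `z`,
#'   `degenerate_z`.
#' @export
rank_partners <- function(x, cell_type = NULL, top_n = 3,
                          direction = c("outgoing", "incoming")) {
  stopifnot(inherits(x, "eoe_interaction"))
  direction <- match.arg(direction)
  m <- if (direction == "outgoing") x$strength else t(x$strength)
  types <- if (is.null(cell_type)) rownames(m) else cell_type
  purrr::map_dfr(types, function(ct) {
    v <- m[ct, ]
    ord <- order(-v, names(v))
    sel <- ord[seq_len(min(top_n, length(v)))]
    sdv <- stats::sd(v[sel])
    degenerate <- length(sel) < 2 || !is.finite(sdv) || sdv == 0
    z <- if (degenerate) rep(0, length(sel)) else (v[sel] - mean(v[sel])) / sdv
    tibble::tibble(cell_type = ct, partner = names(v)[sel],
                   strength = unname(v[sel]), rank = seq_along(sel),
                   z = unname(z), degenerate_z = degenerate)
  })
}

#' Interaction strengths computed per condition
#'
#' Recomputes the UMI shares and top-k strengths within each condition's
#' cells separately, as when contrasting healthy, remission and active
#' biopsies.
#'
#' @inheritParams interaction_strength
#' @param atlas an [eoe_atlas()] with `cell_type` labels and a `condition`
#'   column in the sample table.
#' @param min_cells subset size floor passed to [subset_shares()].
#' @return named list of `eoe_interaction`, one per condition.
#' @export
per_condition_interactions <- function(atlas, catalog, k = 10, min_cells = 10) {
  stopifnot(inherits(atlas, "eoe_atlas"))
  conds <- unique(atlas$samples$condition)
  cond_by_cell <- atlas$samples$condition[match(atlas$cells$sample_id,
                                                atlas$samples$sample_id)]
  out <- lapply(stats::setNames(conds, conds), function(cd) {
    sub <- atlas_subset(atlas, cells = which(cond_by_cell == cd))
    sh <- subset_shares(sub, min_cells = min_cells)
    if (ncol(sh) == 0) return(NULL)
    interaction_strength(sh, catalog, k = k)
  })
  out[!vapply(out, is.null, logical(1))]
}
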