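#' QC thresholds for droplet scRNA-seq
#'
#' Cells are retained when their total UMI count is strictly above
#' `min_umis` and their mitochondrial UMI share is strictly below the
#' chemistry-specific ceiling: 25% for v2 chemistry, 40% for v3 chemistries,
#' which systematically carry a higher mitochondrial load.
#'
#' @param min_umis exclusive lower bound on total UMIs per cell.
#' @param max_mito_v2 exclusive mitochondrial-fraction ceiling for `v2`.
#' @param max_mito_v3 ceiling for `v3` and `v3-dual`.
#' @param mito_pattern regex identifying mitochondrial genes by name.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umis = 500, max_mito_v2 = 0.25,
                          max_mito_v3 = 0.40, mito_pattern = "^MT-") {
  stopifnot(max_mito_v2 > 0, max_mito_v2 <= 1, max_mito_v3 > 0, max_mito_v3 <= 1)
  structure(list(min_umis = min_umis, max_mito_v2 = max_mito_v2,
                 max_mito_v3 = max_mito_v3, mito_pattern = mito_pattern),
            class = "qc_thresholds")
}

mito_ceiling <- function(chemistry, thresholds) {
  out <- rep(NA_real_, length(chemistry))
  out[chemistry == "v2"] <- thresholds$max_mito_v2
  out[chemistry %in% c("v3", "v3-dual")] <- thresholds$max_mito_v3
  if (anyNA(out)) {
    stop("unknown chemistry label: ",
         paste(unique(chemistry[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Filter cells on UMI depth and mitochondrial load
#'
#' @param atlas an [eoe_atlas()]; each cell's sample must have a known
#'   chemistry (`v2`, `v3` or `v3-dual`).
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `eoe_atlas`; the per-sample retention log (cells in,
#'   cells kept, removal reasons) is attached as attribute `"retention"` and
#'   readable via [qc_retention()].
#' @export
filter_cells <- function(atlas, thresholds = qc_thresholds()) {
  stopifnot(inherits(atlas, "eoe_atlas"), inherits(thresholds, "qc_thresholds"))
  if (nrow(atlas$counts) == 0) {
    out <- atlas
    attr(out, "retention") <- tibble::tibble(
      sample_id = character(), n_in = integer(), n_kept = integer(),
      n_low_umi = integer(), n_high_mito = integer())
    return(out)
  }
  totals <- cell_totals(atlas)
  mito_idx <- grepl(thresholds$mito_pattern, atlas$genes)
  mito <- if (any(mito_idx))
    Matrix::rowSums(atlas$counts[, mito_idx, drop = FALSE]) else rep(0, length(totals))
  mito_frac <- ifelse(totals > 0, mito / totals, 0)
  ceilings <- mito_ceiling(cell_chemistry(atlas), thresholds)
  keep_umi <- totals > thresholds$min_umis
  keep_mito <- mito_frac < ceilings
  keep <- keep_umi & keep_mito
  log <- tibble::tibble(sample_id = atlas$cells$sample_id,
                        keep = keep, low_umi = !keep_umi, high_mito = !keep_mito) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_in = dplyr::n(), n_kept = sum(.data$keep),
                     n_low_umi = sum(.data$low_umi),
                     n_high_mito = sum(.data$high_mito), .groups = "drop")
  out <- atlas_subset(atlas, cells = which(keep))
  attr(out, "retention") <- log
  out
}

#' @rdname filter_cells
#' @param x an atlas returned by `filter_cells()`.
#' @export
qc_retention <- function(x) attr(x, "retention")

#' Per-cell log-normalized expression (log TP10K)
#'
#' Scales each cell to 10,000 total UMIs and applies `log1p`:
#' `ln(1 + 1e4 * count / cell_total)`. Sparsity is preserved.
#'
#' @param atlas an [eoe_atlas()] with no zero-total cells (run
#'   [filter_cells()] first).
#' @return sparse cells x genes matrix of normalized values.
#' @export
lognorm <- function(atlas) {
  stopifnot(inherits(atlas, "eoe_atlas"))
  if (nrow(atlas$counts) == 0) stop("no cells to normalize", call. = FALSE)
  totals <- cell_totals(atlas)
  if (any(totals == 0))
    stop("cells with zero total UMIs present; QC-filter before normalizing",
         call. = FALSE)
  m <- Matrix::Diagonal(x = 1e4 / totals) %*% atlas$counts
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(atlas$counts)
  methods::as(m, "CsparseMatrix")
}

#' Pseudo-bulk profiles
#'
#' `pseudobulk_sum()` aggregates a cell set by summing raw UMI vectors and
#' normalizing the sum to log TP10K: `ln(1 + 1e4 * sum_g / sum_total)`; all
#' entries are nonnegative. `pseudobulk_mean()` instead returns the per-gene
#' mean of raw counts across the cells (the variant used for risk-gene
#' module detection); set `normalized = TRUE` to average per-cell log TP10K
#' values instead of raw counts.
#'
#' @param atlas an [eoe_atlas()].
#' @param cells index (logical, integer or barcode character) of the cell
#'   set to aggregate; default all cells.
#' @param normalized for `pseudobulk_mean()`, average per-cell log TP10K
#'   rather than raw counts.
#' @return named per-gene numeric vector.
#' @export
pseudobulk_sum <- function(atlas, cells = NULL) {
  m <- resolve_cells(atlas, cells)
  if (nrow(m) == 0) stop("empty cell set", call. = FALSE)
  tot <- sum(m)
  if (tot == 0) stop("cell set has zero total UMIs", call. = FALSE)
  v <- log1p(1e4 * Matrix::colSums(m) / tot)
  stats::setNames(as.vector(v), atlas$genes)
}

#' @rdname pseudobulk_sum
#' @export
pseudobulk_mean <- function(atlas, cells = NULL, normalized = FALSE) {
  if (normalized) {
    ln <- lognorm(atlas)
    idx <- resolve_cell_index(atlas, cells)
    if (length(idx) == 0) stop("empty cell set", call. = FALSE)
    v <- Matrix::colMeans(ln[idx, , drop = FALSE])
  } else {
    m <- resolve_cells(atlas, cells)
    if (nrow(m) == 0) stop("empty cell set", call. = FALSE)
    v <- Matrix::colMeans(m)
  }
  stats::setNames(as.vector(v), atlas$genes)
}

resolve_cell_index <- function(atlas, cells) {
  if (is.null(cells)) return(seq_len(nrow(atlas$counts)))
  if (is.character(cells)) return(match(cells, atlas$cells$barcode))
  if (is.logical(cells)) return(which(cells))
  cells
}

resolve_cells <- function(atlas, cells) {
  atlas$counts[resolve_cell_index(atlas, cells), , drop = FALSE]
}
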