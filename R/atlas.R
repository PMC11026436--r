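#' Cell-by-gene atlas container
#'
#' Light container tying together a sparse UMI count matrix (cells x genes),
#' the gene identifiers, a per-cell metadata tibble and a per-sample metadata
#' tibble. All analysis functions in the package accept this object.
#'
#' @param counts sparse non-negative integer matrix, cells in rows, genes in
#'   columns (a [Matrix::dgCMatrix] or anything coercible).
#' @param genes character vector of gene identifiers, one per column.
#' @param cells tibble with one row per cell; must contain `barcode` and
#'   `sample_id`, optionally `cell_type` (absent before annotation).
#' @param samples tibble with one row per sample; must contain `sample_id`
#'   and `chemistry`, typically also `donor`, `condition`, `region`,
#'   `steroid`, `diet`, `eos_per_hpf`, `erefs`.
#'
#' @return an object of class `eoe_atlas`.
#' @export
eoe_atlas <- function(counts, genes, cells, samples) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  cells <- tibble::as_tibble(cells)
  samples <- tibble::as_tibble(samples)
  if (ncol(counts) != length(genes)) {
    stop("`genes` length (", length(genes), ") does not match count matrix columns (",
         ncol(counts), ")", call. = FALSE)
  }
  if (nrow(counts) != nrow(cells)) {
    stop("`cells` rows (", nrow(cells), ") do not match count matrix rows (",
         nrow(counts), ")", call. = FALSE)
  }
  if (any(counts@x < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (!all(c("barcode", "sample_id") %in% names(cells))) {
    stop("`cells` must contain columns `barcode` and `sample_id`", call. = FALSE)
  }
  if (!"sample_id" %in% names(samples)) {
    stop("`samples` must contain a `sample_id` column", call. = FALSE)
  }
  missing_samp <- setdiff(unique(cells$sample_id), samples$sample_id)
  if (length(missing_samp)) {
    stop("cells reference samples absent from `samples`: ",
         paste(utils::head(missing_samp, 5), collapse = ", "), call. = FALSE)
  }
  rownames(counts) <- cells$barcode
  colnames(counts) <- genes
  structure(
    list(counts = counts, genes = as.character(genes), cells = cells, samples = samples),
    class = "eoe_atlas"
  )
}

#' @export
print.eoe_atlas <- function(x, ...) {
  cat("<eoe_atlas> ", nrow(x$counts), " cells x ", ncol(x$counts), " genes, ",
      nrow(x$samples), " samples", sep = "")
  if ("cell_type" %in% names(x$cells)) {
    cat(", ", length(unique(x$cells$cell_type)), " cell types", sep = "")
  }
  cat("\n")
  if ("condition" %in% names(x$samples)) {
    tab <- table(x$samples$condition)
    cat("  conditions: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.eoe_atlas <- function(x) dim(x$counts)

#' Subset an atlas by cells and/or genes
#'
#' @param x an `eoe_atlas`.
#' @param cells logical, integer or character (barcode) index of cells to keep.
#' @param genes logical, integer or character index of genes to keep.
#' @return the subsetted `eoe_atlas`; samples with no remaining cells are kept
#'   in the sample table (they carry covariates other analyses may need).
#' @export
atlas_subset <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "eoe_atlas"))
  ci <- if (is.null(cells)) seq_len(nrow(x$counts)) else cells
  gi <- if (is.null(genes)) seq_len(ncol(x$counts)) else genes
  if (is.character(ci)) ci <- match(ci, x$cells$barcode)
  if (is.character(gi)) gi <- match(gi, x$genes)
  eoe_atlas(x$counts[ci, gi, drop = FALSE], x$genes[gi], x$cells[ci, , drop = FALSE],
            x$samples)
}

# per-cell total UMIs
cell_totals <- function(x) Matrix::rowSums(x$counts)

#' Per-cell chemistry lookup
#' @param x an `eoe_atlas`.
#' @return character vector, chemistry of each cell's sample.
#' @keywords internal
cell_chemistry <- function(x) {
  x$samples$chemistry[match(x$cells$sample_id, x$samples$sample_id)]
}
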