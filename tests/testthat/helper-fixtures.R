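# shared fixtures, built once per test run
.fixtures <- new.env()

default_fixture <- function() {
  if (is.null(.fixtures$res)) {
    .fixtures$res <- generate_atlas(atlas_config(seed = 101L))
    .fixtures$filtered <- filter_cells(.fixtures$res$atlas)
  }
  .fixtures
}

# minimal two/three-condition biopsy design for fast simulations
mini_design <- function(n_active = 5, n_healthy = 5, n_remission = 0,
                        chemistries = c("v2", "v3", "v3-dual")) {
  cond <- rep(c("active", "healthy", "remission"),
              c(n_active, n_healthy, n_remission))
  n <- length(cond)
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    donor = sprintf("D%02d", seq_len(n)),
    condition = cond,
    region = rep(c("distal", "proximal"), length.out = n),
    chemistry = rep(chemistries, length.out = n),
    steroid = rep(c(FALSE, TRUE), length.out = n) & cond != "healthy",
    diet = FALSE,
    eos_per_hpf = ifelse(cond == "active", 50L, 1L),
    erefs = ifelse(cond == "active", 5L, 0L))
}

no_effects <- function() list()
no_de <- function() tibble::tibble(gene = character(), cell_type = character(),
                                   condition = character(), lfc = numeric())

# a tiny atlas built directly from a dense matrix (single v3 sample)
toy_atlas <- function(counts, genes = NULL, cell_type = NULL) {
  n <- nrow(counts)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(counts)))
  cells <- tibble::tibble(barcode = paste0("c", seq_len(n)), sample_id = "S1")
  if (!is.null(cell_type)) cells$cell_type <- cell_type
  samples <- tibble::tibble(sample_id = "S1", donor = "D1",
                            condition = "healthy", region = "distal",
                            chemistry = "v3", steroid = FALSE, diet = FALSE,
                            eos_per_hpf = 0L, erefs = 0L)
  eoe_atlas(Matrix::Matrix(counts, sparse = TRUE), genes, cells, samples)
}

# ---- independent brute-force oracles -------------------------------------

# per-gene subset share by direct looping over cells
oracle_shares <- function(counts, labels) {
  counts <- as.matrix(counts)
  subsets <- sort(unique(labels))
  out <- matrix(0, ncol(counts), length(subsets),
                dimnames = list(colnames(counts), subsets))
  for (g in seq_len(ncol(counts))) {
    tot <- sum(counts[, g])
    if (tot == 0) next
    for (s in subsets) out[g, s] <- sum(counts[labels == s, g]) / tot
  }
  out
}

# directed top-k strengths by a direct triple loop (pairs x subset pairs)
oracle_strength <- function(shares, catalog, k) {
  subsets <- colnames(shares)
  gm <- function(genes, s) {
    v <- shares[genes, s]
    if (any(v == 0)) 0 else prod(v)^(1 / length(v))
  }
  strength <- matrix(0, length(subsets), length(subsets),
                     dimnames = list(subsets, subsets))
  for (i in subsets) for (j in subsets) {
    sc <- numeric(nrow(catalog))
    for (p in seq_len(nrow(catalog))) {
      sc[p] <- gm(catalog$ligand[[p]], i) * gm(catalog$receptor[[p]], j)
    }
    strength[i, j] <- sum(sort(sc, decreasing = TRUE)[seq_len(min(k, length(sc)))])
  }
  strength
}

# random gene-level catalog over synthetic gene names
random_catalog <- function(genes, n_pairs, seed, max_subunits = 2) {
  withr::with_seed(seed, {
    lig <- lapply(seq_len(n_pairs), function(i)
      sample(genes, sample(max_subunits, 1)))
    rec <- lapply(seq_len(n_pairs), function(i)
      sample(genes, sample(max_subunits, 1)))
    lr_catalog(sprintf("P%03d", seq_len(n_pairs)), lig, rec)
  })
}
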