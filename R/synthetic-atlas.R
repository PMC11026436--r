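#' Default multi-donor biopsy design
#'
#' Sample (biopsy) table emulating a three-condition esophageal biopsy cohort:
#' 22 donors contributing one or two regions each for 37 biopsies total
#' (14 active, 11 remission, 12 healthy), three 10x chemistry batches
#' (7 donors v2, 9 donors v3, 6 donors v3-dual), steroid/diet flags and
#' clinical activity scores (eosinophils per high-power field, EREFS) that
#' track condition.
#'
#' @param seed integer seed controlling the clinical-score draws.
#' @return tibble with columns `sample_id`, `donor`, `condition`, `region`,
#'   `chemistry`, `steroid`, `diet`, `eos_per_hpf`, `erefs`.
#' @export
default_design <- function(seed = 1L) {
  conditions <- c(rep("active", 8), rep("remission", 7), rep("healthy", 7))
  # donors with paired distal+proximal biopsies: 6/8 active, 4/7 remission,
  # 5/7 healthy -> 14 + 11 + 12 = 37 biopsies
  paired <- c(rep(c(TRUE, FALSE), c(6, 2)), rep(c(TRUE, FALSE), c(4, 3)),
              rep(c(TRUE, FALSE), c(5, 2)))
  # 7 donors v2, 9 v3, 6 v3-dual, interleaved across the condition blocks so
  # chemistry and condition are correlated but not confounded
  chem_pool <- rep(c("v2", "v3", "v3-dual"), c(7, 9, 6))
  chemistry <- character(length(conditions))
  chemistry[c(seq(1, 22, 3), seq(2, 22, 3), seq(3, 22, 3))] <- chem_pool
  donors <- sprintf("D%02d", seq_along(conditions))
  withr_seed(seed, {
    rows <- purrr::pmap_dfr(
      list(donors, conditions, paired, chemistry),
      function(d, cond, p, chem) {
        regions <- if (p) c("distal", "proximal") else sample(c("distal", "mixed"), 1)
        tibble::tibble(donor = d, condition = cond, region = regions, chemistry = chem)
      }
    )
    rows$steroid <- rows$donor %in% sample(donors[conditions != "healthy"], 6)
    rows$diet <- rows$donor %in% sample(donors[conditions != "healthy"], 5)
    rows$eos_per_hpf <- dplyr::case_when(
      rows$condition == "active" ~ stats::rpois(nrow(rows), 60),
      rows$condition == "remission" ~ stats::rpois(nrow(rows), 4),
      TRUE ~ stats::rpois(nrow(rows), 0.2)
    )
    rows$erefs <- dplyr::case_when(
      rows$condition == "active" ~ stats::rpois(nrow(rows), 5),
      rows$condition == "remission" ~ stats::rpois(nrow(rows), 2),
      TRUE ~ 0L
    )
  })
  rows$sample_id <- paste0(rows$donor, "_", substr(rows$region, 1, 4))
  dplyr::select(rows, "sample_id", "donor", "condition", "region", "chemistry",
                "steroid", "diet", "eos_per_hpf", "erefs")
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# derived stream seed: deterministic, stays in 32-bit signed range
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

#' Configuration for the synthetic atlas generator
#'
#' Collects every knob of the generative model: the biopsy design, the
#' cell-type palette and its Dirichlet base composition, condition-dependent
#' composition log-fold enrichments, cell-type/condition-specific differential
#' expression, ambient contamination, chemistry-dependent mitochondrial load,
#' and planted ligand-receptor axes. The defaults emulate a type-2
#' inflammation atlas: granulocytes (eosinophils, mast cells), Th2 cells and
#' IL13RA2+ fibroblasts enriched in active disease, apical epithelium
#' depleted, with a Th2 -> fibroblast ligand-receptor axis planted.
#'
#' @param n_genes number of non-mitochondrial genes.
#' @param cell_types character vector of cell-type names.
#' @param cells_per_sample cells per biopsy: a single count, a length-2
#'   range sampled uniformly per biopsy, or a vector named by `sample_id`
#'   (biopsy yields vary strongly in practice).
#' @param design sample table as produced by [default_design()].
#' @param composition_base Dirichlet concentration per cell type (named).
#' @param composition_effects named list `condition -> named numeric` of
#'   natural-log fold enrichments applied multiplicatively to the base
#'   concentrations.
#' @param de_effects tibble with columns `gene`, `cell_type`, `condition`,
#'   `lfc` (log2 fold change applied to that gene's rate in that cell type
#'   under that condition).
#' @param ambient_fraction fraction of each cell's UMIs drawn from the pooled
#'   ambient profile, in `[0, 1)`.
#' @param markers_per_type number of high-expression marker genes per type.
#' @param mito_gene_count number of mitochondrial (`MT-` prefixed) genes.
#' @param mito_fraction_by_chemistry named mean mitochondrial UMI share per
#'   chemistry.
#' @param lr_plants list of planted ligand-receptor axes; each element a list
#'   with `ligand`, `receptor` (character gene vectors), `source`, `target`
#'   (cell types) and `intensity` (rate multiplier in source/target).
#' @param composition_overrides optional tibble (`sample_id`, `cell_type`,
#'   `log_enrichment`) spiking or depleting single samples on top of the
#'   condition effects (e.g. one biopsy with a massive eosinophil load).
#' @param library_size_log_mean,library_size_log_sd log-normal library size.
#' @param seed master seed; per-sample streams are derived deterministically.
#' @return a list of class `atlas_config`.
#' @export
atlas_config <- function(n_genes = 300,
                         cell_types = c("eosinophil", "mast", "th2", "cd8_t",
                                        "plasma_b", "mac_plac8", "mac_folr2",
                                        "dc", "fibroblast", "fibroblast_il13ra2",
                                        "endothelial", "apical"),
                         cells_per_sample = 300,
                         design = default_design(seed),
                         composition_base = NULL,
                         composition_effects = default_composition_effects(),
                         de_effects = default_de_effects(),
                         ambient_fraction = 0.05,
                         markers_per_type = 10,
                         mito_gene_count = 10,
                         mito_fraction_by_chemistry = c(v2 = 0.08, v3 = 0.16,
                                                        "v3-dual" = 0.16),
                         lr_plants = default_lr_plants(),
                         composition_overrides = NULL,
                         library_size_log_mean = log(2000),
                         library_size_log_sd = 0.35,
                         seed = 1L) {
  if (is.null(composition_base)) {
    composition_base <- stats::setNames(
      rep(c(1.5, 2.5, 4, 8), length.out = length(cell_types)), cell_types)
  }
  cfg <- list(
    n_genes = as.integer(n_genes), cell_types = cell_types,
    cells_per_sample = cells_per_sample, design = tibble::as_tibble(design),
    composition_base = composition_base,
    composition_effects = composition_effects,
    de_effects = tibble::as_tibble(de_effects),
    ambient_fraction = ambient_fraction, markers_per_type = markers_per_type,
    mito_gene_count = as.integer(mito_gene_count),
    mito_fraction_by_chemistry = mito_fraction_by_chemistry,
    lr_plants = lr_plants,
    composition_overrides = if (is.null(composition_overrides))
      tibble::tibble(sample_id = character(), cell_type = character(),
                     log_enrichment = numeric())
    else tibble::as_tibble(composition_overrides),
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    seed = as.integer(seed)
  )
  validate_atlas_config(cfg)
  structure(cfg, class = "atlas_config")
}

validate_atlas_config <- function(cfg) {
  gene_names <- synthetic_gene_names(cfg)
  if (cfg$ambient_fraction < 0 || cfg$ambient_fraction >= 1)
    stop("`ambient_fraction` must be in [0, 1)", call. = FALSE)
  if (any(cfg$mito_fraction_by_chemistry < 0 | cfg$mito_fraction_by_chemistry >= 1))
    stop("mitochondrial fractions must be in [0, 1)", call. = FALSE)
  if (cfg$n_genes < 1 || cfg$mito_gene_count < 0)
    stop("gene counts must be positive", call. = FALSE)
  if (cfg$markers_per_type * length(cfg$cell_types) > cfg$n_genes)
    stop("markers_per_type * n_cell_types exceeds n_genes", call. = FALSE)
  if (is.null(names(cfg$composition_base)) ||
      !setequal(names(cfg$composition_base), cfg$cell_types))
    stop("`composition_base` must be named by the cell types", call. = FALSE)
  if (any(cfg$composition_base <= 0))
    stop("Dirichlet concentrations must be positive", call. = FALSE)
  bad_chem <- setdiff(unique(cfg$design$chemistry),
                      names(cfg$mito_fraction_by_chemistry))
  if (length(bad_chem))
    stop("no mitochondrial fraction configured for chemistry: ",
         paste(bad_chem, collapse = ", "), call. = FALSE)
  for (cond in names(cfg$composition_effects)) {
    bad <- setdiff(names(cfg$composition_effects[[cond]]), cfg$cell_types)
    if (length(bad))
      stop("composition effect references unknown cell type: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(cfg$de_effects)) {
    bad <- setdiff(cfg$de_effects$gene, gene_names)
    if (length(bad))
      stop("de_effects references unknown gene: ", paste(bad, collapse = ", "),
           call. = FALSE)
    bad <- setdiff(cfg$de_effects$cell_type, cfg$cell_types)
    if (length(bad))
      stop("de_effects references unknown cell type: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(cfg$composition_overrides)) {
    bad <- setdiff(cfg$composition_overrides$sample_id, cfg$design$sample_id)
    if (length(bad))
      stop("composition_overrides references unknown sample: ",
           paste(bad, collapse = ", "), call. = FALSE)
    bad <- setdiff(cfg$composition_overrides$cell_type, cfg$cell_types)
    if (length(bad))
      stop("composition_overrides references unknown cell type: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  for (pl in cfg$lr_plants) {
    bad <- setdiff(c(pl$ligand, pl$receptor), gene_names)
    if (length(bad))
      stop("lr_plants references unknown gene: ", paste(bad, collapse = ", "),
           call. = FALSE)
    bad <- setdiff(c(pl$source, pl$target), cfg$cell_types)
    if (length(bad))
      stop("lr_plants references unknown cell type: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Synthetic gene name palette for a configuration
#' @param cfg an `atlas_config` (or a list with `mito_gene_count`, `n_genes`).
#' @return character vector: `MT-1...` mitochondrial genes then `G0001...`.
#' @export
synthetic_gene_names <- function(cfg) {
  c(if (cfg$mito_gene_count > 0) paste0("MT-", seq_len(cfg$mito_gene_count)),
    sprintf("G%04d", seq_len(cfg$n_genes)))
}

#' @rdname atlas_config
#' @export
default_composition_effects <- function() {
  list(
    active = c(eosinophil = log(8), mast = log(3), th2 = log(2),
               fibroblast_il13ra2 = log(4), mac_plac8 = log(2),
               plasma_b = log(2), apical = -log(2), mac_folr2 = -log(1.5)),
    remission = c(eosinophil = log(1.5), mast = log(1.3))
  )
}

#' @rdname atlas_config
#' @export
default_de_effects <- function() {
  # genes chosen outside the per-type marker blocks (first
  # markers_per_type * n_types non-mito genes) so planted effects act on
  # broadly expressed genes
  tibble::tribble(
    ~gene,   ~cell_type,   ~condition, ~lfc,
    "G0151", "fibroblast", "active",    log2(3),
    "G0152", "fibroblast", "active",    log2(3),
    "G0153", "mac_plac8",  "active",    log2(4),
    "G0154", "apical",     "active",   -log2(2),
    "G0155", "fibroblast", "remission", log2(2)
  )
}

#' @rdname atlas_config
#' @export
default_lr_plants <- function() {
  list(
    list(ligand = "G0201", receptor = c("G0202", "G0203"),
         source = "th2", target = "fibroblast", intensity = 40),
    list(ligand = "G0204", receptor = "G0205",
         source = "mast", target = "endothelial", intensity = 40)
  )
}

# per-type expected gene rate matrix (genes x types), non-mito part
build_type_profiles <- function(cfg, gene_names) {
  n_types <- length(cfg$cell_types)
  is_mito <- startsWith(gene_names, "MT-")
  n_all <- length(gene_names)
  # shared baseline with heavy right tail, plus type-specific markers
  base <- stats::rgamma(n_all, shape = 0.4, rate = 1) + 0.02
  prof <- matrix(rep(base, n_types), ncol = n_types,
                 dimnames = list(gene_names, cfg$cell_types))
  nonmito_idx <- which(!is_mito)
  marker_pool <- nonmito_idx
  for (t in seq_len(n_types)) {
    mk <- marker_pool[seq_len(cfg$markers_per_type) + (t - 1) * cfg$markers_per_type]
    prof[mk, t] <- prof[mk, t] + stats::rgamma(length(mk), shape = 8, rate = 0.5)
    # markers are depleted elsewhere so types are well separated
    prof[mk, -t] <- prof[mk, -t] * 0.05
  }
  for (pl in cfg$lr_plants) {
    prof[pl$ligand, pl$source] <- pl$intensity
    prof[pl$ligand, setdiff(cfg$cell_types, pl$source)] <- 0.02
    prof[pl$receptor, pl$target] <- pl$intensity
    prof[pl$receptor, setdiff(cfg$cell_types, pl$target)] <- 0.02
  }
  prof
}

#' Generate true per-sample compositions and per-type cell counts
#'
#' The composition half of the generative model, exposed on its own because
#' abundance statistics only need cell counts per type, not gene counts:
#' for each biopsy the composition is drawn from a Dirichlet whose
#' concentration is the base vector times `exp(effects[condition])`, and
#' cells are allocated multinomially.
#'
#' @param cfg an [atlas_config()].
#' @return list with `composition` (samples x types true probabilities),
#'   `cell_counts` (samples x types integer matrix) and `design`.
#' @export
generate_composition <- function(cfg) {
  validate_atlas_config(cfg)
  design <- cfg$design
  n_types <- length(cfg$cell_types)
  comp <- matrix(0, nrow(design), n_types,
                 dimnames = list(design$sample_id, cfg$cell_types))
  counts <- comp
  for (s in seq_len(nrow(design))) {
    withr_seed(derive_seed(cfg$seed, s), {
      alpha <- cfg$composition_base
      eff <- cfg$composition_effects[[design$condition[s]]]
      if (!is.null(eff)) alpha[names(eff)] <- alpha[names(eff)] * exp(eff)
      ov <- cfg$composition_overrides
      ov <- ov[ov$sample_id == design$sample_id[s], , drop = FALSE]
      if (nrow(ov)) alpha[ov$cell_type] <- alpha[ov$cell_type] * exp(ov$log_enrichment)
      p <- stats::rgamma(n_types, shape = alpha, rate = 1)
      p <- p / sum(p)
      cps <- cfg$cells_per_sample
      n_cells <- if (!is.null(names(cps))) {
        if (!design$sample_id[s] %in% names(cps))
          stop("cells_per_sample names do not cover sample ",
               design$sample_id[s], call. = FALSE)
        cps[[design$sample_id[s]]]
      } else if (length(cps) == 2) {
        sample(cps[1]:cps[2], 1)
      } else cps
      comp[s, ] <- p
      counts[s, ] <- as.vector(stats::rmultinom(1, n_cells, p))
    })
  }
  list(composition = comp, cell_counts = counts, design = design)
}

#' Generate a synthetic single-cell atlas with known ground truth
#'
#' Draws a full cell-by-gene UMI matrix under the generative model described
#' in [atlas_config()]: Dirichlet-multinomial composition per biopsy,
#' log-normal library sizes, multinomial gene counts over cell-type mean
#' profiles modified by planted differential expression, UMI-level ambient
#' contamination, chemistry-dependent mitochondrial load and planted
#' ligand-receptor axes. Fully reproducible from the config seed.
#'
#' @param cfg an [atlas_config()].
#' @return list with `atlas` (an [eoe_atlas()]) and `truth` (class
#'   `eoe_truth`: true compositions, planted effect registry, ambient
#'   profile and fraction).
#' @export
generate_atlas <- function(cfg) {
  validate_atlas_config(cfg)
  gene_names <- synthetic_gene_names(cfg)
  is_mito <- startsWith(gene_names, "MT-")
  prof <- withr_seed(derive_seed(cfg$seed, 0L), build_type_profiles(cfg, gene_names))

  compo <- generate_composition(cfg)
  design <- cfg$design

  # normalized non-mito / mito halves of each type profile
  nm <- prof; nm[is_mito, ] <- 0
  nm <- sweep(nm, 2, colSums(nm), "/")
  mito_prof <- rep(0, length(gene_names))
  if (any(is_mito)) {
    mw <- withr_seed(derive_seed(cfg$seed, 1L),
                     stats::rgamma(sum(is_mito), shape = 2, rate = 1) + 0.1)
    mito_prof[is_mito] <- mw / sum(mw)
  }

  # per-sample ambient soup: the sample's own composition-weighted mixture of
  # type profiles plus its chemistry's mitochondrial load
  ambient_by_sample <- t(vapply(seq_len(nrow(design)), function(s) {
    chem_m <- cfg$mito_fraction_by_chemistry[[design$chemistry[s]]]
    amb <- as.vector(nm %*% compo$composition[s, ]) * (1 - chem_m) +
      mito_prof * chem_m
    amb / sum(amb)
  }, numeric(length(gene_names))))
  dimnames(ambient_by_sample) <- list(design$sample_id, gene_names)
  ambient <- colMeans(ambient_by_sample)

  ii <- vector("list", nrow(design)); jj <- ii; xx <- ii
  cells <- vector("list", nrow(design))
  de <- cfg$de_effects
  for (s in seq_len(nrow(design))) {
    n_by_type <- compo$cell_counts[s, ]
    chem_m <- cfg$mito_fraction_by_chemistry[[design$chemistry[s]]]
    cond <- design$condition[s]
    withr_seed(derive_seed(cfg$seed, 1000L + s), {
      si <- 0L
      n_tot <- sum(n_by_type)
      acc_i <- vector("list", n_tot); acc_j <- acc_i; acc_x <- acc_i
      types_vec <- character(n_tot)
      for (t in seq_along(cfg$cell_types)) {
        nct <- n_by_type[t]
        if (nct == 0) next
        rate <- nm[, t]
        if (nrow(de)) {
          hits <- de[de$cell_type == cfg$cell_types[t] & de$condition == cond, ]
          if (nrow(hits)) {
            gi <- match(hits$gene, gene_names)
            rate[gi] <- rate[gi] * 2^hits$lfc
            rate <- rate / sum(rate)
          }
        }
        p_cell <- rate * (1 - chem_m) + mito_prof * chem_m
        p_final <- (1 - cfg$ambient_fraction) * p_cell +
          cfg$ambient_fraction * ambient_by_sample[s, ]
        libs <- pmax(1, round(stats::rlnorm(nct, cfg$library_size_log_mean,
                                            cfg$library_size_log_sd)))
        for (cidx in seq_len(nct)) {
          cnt <- stats::rmultinom(1, libs[cidx], p_final)[, 1]
          nz <- which(cnt > 0)
          acc_i[[si + cidx]] <- rep.int(si + cidx, length(nz))
          acc_j[[si + cidx]] <- nz
          acc_x[[si + cidx]] <- cnt[nz]
        }
        types_vec[si + seq_len(nct)] <- cfg$cell_types[t]
        si <- si + nct
      }
      ii[[s]] <- unlist(acc_i); jj[[s]] <- unlist(acc_j); xx[[s]] <- unlist(acc_x)
      cells[[s]] <- tibble::tibble(
        barcode = sprintf("%s-%05d", design$sample_id[s], seq_len(n_tot)),
        sample_id = design$sample_id[s], cell_type = types_vec)
    })
  }
  offs <- cumsum(c(0L, vapply(cells, nrow, 1L)))[seq_len(nrow(design))]
  counts <- Matrix::sparseMatrix(
    i = unlist(purrr::map2(ii, offs, ~ .x + .y)), j = unlist(jj),
    x = unlist(xx), dims = c(sum(vapply(cells, nrow, 1L)), length(gene_names))
  )
  cells <- dplyr::bind_rows(cells)
  atlas <- eoe_atlas(counts, gene_names, cells, design)
  truth <- structure(list(
    composition = compo$composition,
    cell_counts = compo$cell_counts,
    composition_effects = cfg$composition_effects,
    de_effects = cfg$de_effects,
    lr_plants = cfg$lr_plants,
    ambient_fraction = cfg$ambient_fraction,
    ambient_profile = stats::setNames(ambient, gene_names),
    ambient_by_sample = ambient_by_sample,
    mito_fraction_by_chemistry = cfg$mito_fraction_by_chemistry,
    seed = cfg$seed
  ), class = "eoe_truth")
  list(atlas = atlas, truth = truth)
}

#' Write / read an atlas directory
#'
#' Serializes the atlas in the conventional exchange layout: `matrix.mtx`
#' (Matrix Market integer counts, genes x cells), `genes.tsv`,
#' `barcodes.tsv`, `cells.csv`, `samples.csv`, and `truth.json` when a truth
#' registry is supplied. `read_atlas()` inverts it bit-exactly.
#'
#' @param atlas an [eoe_atlas()].
#' @param dir directory to write into (created if needed).
#' @param truth optional `eoe_truth` registry.
#' @return `write_atlas()` the directory invisibly; `read_atlas()` a list
#'   with `atlas` and `truth` (NULL when absent).
#' @export
write_atlas <- function(atlas, dir, truth = NULL) {
  stopifnot(inherits(atlas, "eoe_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::t(atlas$counts)  # genes x cells on disk
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(atlas$genes, file.path(dir, "genes.tsv"))
  writeLines(atlas$cells$barcode, file.path(dir, "barcodes.tsv"))
  utils::write.csv(atlas$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(atlas$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth_to_list(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = I(17), null = "null")
  }
  invisible(dir)
}

truth_to_list <- function(truth) {
  list(
    composition = list(sample_id = rownames(truth$composition),
                       cell_type = colnames(truth$composition),
                       values = apply(truth$composition, 1, identity, simplify = FALSE)),
    cell_counts = apply(truth$cell_counts, 1, identity, simplify = FALSE),
    composition_effects = lapply(truth$composition_effects, as.list),
    de_effects = truth$de_effects,
    lr_plants = truth$lr_plants,
    ambient_fraction = truth$ambient_fraction,
    ambient_profile = as.list(truth$ambient_profile),
    ambient_by_sample = apply(truth$ambient_by_sample, 1, identity,
                              simplify = FALSE),
    mito_fraction_by_chemistry = as.list(truth$mito_fraction_by_chemistry),
    seed = truth$seed
  )
}

truth_from_list <- function(x) {
  sample_ids <- unlist(x$composition$sample_id)
  types <- unlist(x$composition$cell_type)
  comp <- do.call(rbind, lapply(x$composition$values, unlist))
  dimnames(comp) <- list(sample_ids, types)
  cc <- do.call(rbind, lapply(x$cell_counts, unlist))
  dimnames(cc) <- list(sample_ids, types)
  structure(list(
    composition = comp, cell_counts = cc,
    composition_effects = lapply(x$composition_effects, unlist),
    de_effects = if (length(x$de_effects))
      dplyr::bind_rows(lapply(x$de_effects, tibble::as_tibble))
    else tibble::tibble(gene = character(), cell_type = character(),
                        condition = character(), lfc = numeric()),
    lr_plants = lapply(x$lr_plants, function(p)
      list(ligand = unlist(p$ligand), receptor = unlist(p$receptor),
           source = p$source, target = p$target, intensity = p$intensity)),
    ambient_fraction = x$ambient_fraction,
    ambient_profile = unlist(x$ambient_profile),
    ambient_by_sample = {
      abs_mat <- do.call(rbind, lapply(x$ambient_by_sample, unlist))
      dimnames(abs_mat) <- list(sample_ids, names(unlist(x$ambient_profile)))
      abs_mat
    },
    mito_fraction_by_chemistry = unlist(x$mito_fraction_by_chemistry),
    seed = x$seed
  ), class = "eoe_truth")
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "cells.csv", "samples.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f)))
      stop("atlas directory is missing ", f, call. = FALSE)
  }
  mtx_file <- file.path(dir, "matrix.mtx")
  m <- tryCatch(Matrix::readMM(mtx_file),
                error = function(e) stop("failed to parse ", mtx_file, ": ",
                                         conditionMessage(e), call. = FALSE))
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(genes))
    stop("matrix.mtx declares ", nrow(m), " genes but genes.tsv has ",
         length(genes), " lines", call. = FALSE)
  if (ncol(m) != length(barcodes))
    stop("matrix.mtx declares ", ncol(m), " cells but barcodes.tsv has ",
         length(barcodes), " lines", call. = FALSE)
  cells <- tibble::as_tibble(utils::read.csv(file.path(dir, "cells.csv"),
                                             colClasses = "character"))
  samples <- tibble::as_tibble(utils::read.csv(file.path(dir, "samples.csv")))
  if (nrow(cells) && !identical(cells$barcode, barcodes))
    stop("barcodes.tsv and cells.csv disagree on cell barcodes", call. = FALSE)
  atlas <- eoe_atlas(Matrix::t(m), genes, cells, samples)
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    truth <- truth_from_list(jsonlite::read_json(tf, simplifyVector = FALSE))
  }
  list(atlas = atlas, truth = truth)
}
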