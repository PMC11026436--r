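test_that("generation is deterministic and counts respect library sizes", {
  cfg <- atlas_config(n_genes = 80, cells_per_sample = 60,
                      design = mini_design(3, 3), markers_per_type = 5,
                      de_effects = no_de(), lr_plants = list(), seed = 11L)
  r1 <- generate_atlas(cfg)
  r2 <- generate_atlas(cfg)
  expect_identical(r1$atlas$counts, r2$atlas$counts)
  expect_identical(r1$truth$composition, r2$truth$composition)
  expect_identical(r1$atlas$cells, r2$atlas$cells)
  # every cell's counts sum to its drawn library size (>= 1 by construction)
  expect_true(all(Matrix::rowSums(r1$atlas$counts) >= 1))
  # per-sample true compositions are probability vectors
  expect_equal(unname(rowSums(r1$truth$composition)),
               rep(1, nrow(r1$truth$composition)))
  # realized per-type counts match the truth registry
  comp <- composition_table(r1$atlas)
  expect_equal(comp$counts[rownames(r1$truth$cell_counts),
                           colnames(r1$truth$cell_counts)],
               r1$truth$cell_counts)
})

test_that("planted composition enrichment shows up at the expected magnitude", {
  # Dirichlet-multinomial oracle: expected proportion ratio for a 2-fold
  # concentration bump of one rare type, estimated by direct simulation
  base <- stats::setNames(c(1, rep(6, 7)), paste0("t", 1:8))
  eff <- log(2)
  sim_ratio <- local({
    set.seed(99)
    reps <- 1e4
    act <- replicate(reps, {
      a <- base; a[1] <- a[1] * exp(eff)
      g <- stats::rgamma(8, a); g[1] / sum(g)
    })
    hea <- replicate(reps, {
      g <- stats::rgamma(8, base); g[1] / sum(g)
    })
    mean(act) / mean(hea)
  })
  cfg <- atlas_config(
    n_genes = 60, cell_types = names(base), cells_per_sample = 400,
    design = mini_design(20, 20), composition_base = base,
    composition_effects = list(active = c(t1 = eff)),
    de_effects = no_de(), lr_plants = list(), markers_per_type = 4,
    seed = 5L)
  comp <- generate_composition(cfg)
  props <- comp$cell_counts / rowSums(comp$cell_counts)
  cond <- comp$design$condition
  emp_ratio <- mean(props[cond == "active", "t1"]) /
    mean(props[cond == "healthy", "t1"])
  # within sampling error at n = 20 + 20 samples of a skewed proportion
  expect_gt(emp_ratio, sim_ratio * 0.6)
  expect_lt(emp_ratio, sim_ratio * 1.6)
})

test_that("ambient share of a type-exclusive gene matches the planted fraction", {
  # gene G0030 exclusive to source type: its counts in OTHER types can come
  # only from ambient, so their expected share is ambient_fraction * soup
  base <- stats::setNames(rep(1, 4), c("src", "a", "b", "c"))
  cfg <- atlas_config(
    n_genes = 50, cell_types = names(base), cells_per_sample = 500,
    design = mini_design(2, 2), composition_base = base,
    composition_effects = no_effects(), de_effects = no_de(),
    lr_plants = list(list(ligand = "G0030", receptor = "G0030",
                          source = "src", target = "src", intensity = 50)),
    ambient_fraction = 0.10, markers_per_type = 3, seed = 21L)
  r <- generate_atlas(cfg)
  a <- r$atlas
  other <- which(a$cells$cell_type != "src")
  g <- match("G0030", a$genes)
  obs_frac <- sum(a$counts[other, g]) / sum(a$counts[other, ])
  exp_frac <- cfg$ambient_fraction *
    stats::weighted.mean(r$truth$ambient_by_sample[a$cells$sample_id[other], g],
                         rep(1, length(other)))
  expect_gt(obs_frac, exp_frac * 0.7)
  expect_lt(obs_frac, exp_frac * 1.3)
})

test_that("chemistry controls the mitochondrial load", {
  f <- default_fixture()
  a <- f$res$atlas
  mito <- Matrix::rowSums(a$counts[, startsWith(a$genes, "MT-")]) /
    Matrix::rowSums(a$counts)
  chem <- a$samples$chemistry[match(a$cells$sample_id, a$samples$sample_id)]
  m_v2 <- mean(mito[chem == "v2"])
  m_v3 <- mean(mito[chem != "v2"])
  expect_lt(abs(m_v2 - 0.08), 0.03)
  expect_lt(abs(m_v3 - 0.16), 0.04)
  expect_gt(m_v3, m_v2)
})

test_that("atlas round-trips bit-exactly through the directory layout", {
  cfg <- atlas_config(n_genes = 40, cells_per_sample = 25,
                      design = mini_design(2, 2), markers_per_type = 3,
                      de_effects = no_de(), lr_plants = list(), seed = 31L)
  r <- generate_atlas(cfg)
  d <- withr::local_tempdir()
  write_atlas(r$atlas, d, r$truth)
  rt <- read_atlas(d)
  expect_identical(as.matrix(rt$atlas$counts), as.matrix(r$atlas$counts))
  expect_identical(rt$atlas$genes, r$atlas$genes)
  expect_equal(rt$atlas$cells$barcode, r$atlas$cells$barcode)
  expect_identical(rt$truth$composition, r$truth$composition)
  expect_identical(rt$truth$ambient_profile, r$truth$ambient_profile)
  expect_identical(rt$truth$ambient_by_sample, r$truth$ambient_by_sample)
  expect_equal(rt$truth$de_effects, r$truth$de_effects)
  expect_identical(rt$truth$seed, r$truth$seed)
})

test_that("malformed atlas directories produce parse errors naming the file", {
  cfg <- atlas_config(n_genes = 30, cells_per_sample = 20,
                      design = mini_design(1, 1), markers_per_type = 2,
                      de_effects = no_de(), lr_plants = list(), seed = 41L)
  r <- generate_atlas(cfg)
  d <- withr::local_tempdir()
  write_atlas(r$atlas, d)
  # corrupt the MTX header dimensions
  lines <- readLines(file.path(d, "matrix.mtx"))
  hdr <- strsplit(lines[2], " ")[[1]]
  lines[2] <- paste(as.integer(hdr[1]) + 5, hdr[2], hdr[3])
  writeLines(lines, file.path(d, "matrix.mtx"))
  expect_error(read_atlas(d), "genes")
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "oops"),
             file.path(d, "matrix.mtx"))
  expect_error(read_atlas(d), "matrix.mtx")
})

test_that("an empty atlas is representable and round-trips", {
  genes <- c("MT-1", "g1", "g2")
  a <- eoe_atlas(Matrix::Matrix(0, 0, 3, sparse = TRUE), genes,
                 tibble::tibble(barcode = character(),
                                sample_id = character(),
                                cell_type = character()),
                 mini_design(1, 1))
  d <- withr::local_tempdir()
  write_atlas(a, d)
  rt <- read_atlas(d)
  expect_equal(dim(rt$atlas), c(0L, 3L))
  expect_identical(rt$atlas$genes, genes)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(atlas_config(ambient_fraction = 1), "ambient")
  expect_error(atlas_config(de_effects = tibble::tibble(
    gene = "NOPE", cell_type = "mast", condition = "active", lfc = 1)), "NOPE")
  expect_error(atlas_config(composition_effects = list(active = c(alien = 1))),
               "alien")
  expect_error(atlas_config(n_genes = 50), "markers_per_type")
  expect_error(atlas_config(composition_overrides = tibble::tibble(
    sample_id = "nope", cell_type = "mast", log_enrichment = 1)), "nope")
})
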