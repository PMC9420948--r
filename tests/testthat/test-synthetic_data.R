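test_that("plant_cnv_effect multiplies the mean and rejects bad domains", {
  expect_equal(plant_cnv_effect(10, 1.5), 15)
  expect_equal(plant_cnv_effect(10, 1.0), 10)
  expect_equal(plant_cnv_effect(4, 0.5), 2)
  expect_error(plant_cnv_effect(10, 0), class = "scnodule_domain_error")
  expect_error(plant_cnv_effect(-1, 2), class = "scnodule_domain_error")
})

test_that("identical config and seed reproduce the cohort byte-for-byte", {
  a <- small_sim(seed = 42)
  b <- small_sim(seed = 42)
  expect_identical(a$cohort$counts, b$cohort$counts)
  expect_identical(a$cohort$cells, b$cohort$cells)
  expect_identical(a$truth, b$truth)
  c <- small_sim(seed = 43)
  expect_false(identical(a$cohort$counts, c$cohort$counts))
})

test_that("realized malignant fractions match the configured fractions", {
  cfg <- sim_config(
    n_genes = 400, n_chromosomes = 4,
    n_samples = c(normal = 0, pGGN = 1, SN = 1),
    cell_counts = list(pGGN = c(epithelial = 600, T_cell = 100),
                       SN = c(epithelial = 600, T_cell = 100)),
    malignant_fraction = c(pGGN = 0.2, SN = 0.6),
    cnv_segments = "none", seed = 7)
  truth <- generate_cohort(cfg)$truth$cells
  frac <- function(st) {
    epi <- truth[truth$stage == st & truth$cell_type == "epithelial", ]
    mean(epi$is_malignant)
  }
  expect_lt(abs(frac("pGGN") - 0.2), 4 * sqrt(0.2 * 0.8 / 600))
  expect_lt(abs(frac("SN") - 0.6), 4 * sqrt(0.6 * 0.4 / 600))
  expect_true(all(!truth$is_malignant[truth$cell_type != "epithelial"]))
  expect_true(all(!truth$is_malignant[truth$stage == "normal"]))
})

test_that("planted low-gene artifacts are exactly the sub-threshold cells", {
  sim <- small_sim(seed = 9, artifact_counts = c(low_gene = 5, high_mito = 0,
                                                 doublet = 0))
  detected <- Matrix::colSums(sim$cohort$counts > 0)
  low <- sim$cohort$cells$barcode[detected < 200]
  planted <- sim$truth$cells$barcode[sim$truth$cells$artifact_kind %in%
                                       "low_gene"]
  expect_length(planted, 5)
  expect_setequal(low, planted)
})

test_that("inconsistent configurations raise errors naming the field", {
  expect_error(sim_config(n_genes = 100, n_chromosomes = 2,
                          genes_per_chromosome = c(30, 30)),
               "genes_per_chromosome", class = "scnodule_config_error")
  expect_error(sim_config(malignant_fraction = c(pGGN = 1.2, SN = 0.5)),
               "malignant_fraction", class = "scnodule_config_error")
  expect_error(
    sim_config(n_genes = 200, n_chromosomes = 2,
               n_samples = c(normal = 0, pGGN = 1, SN = 0),
               cell_counts = list(pGGN = c(epithelial = 10)),
               cnv_segments = list(pGGN1 = data.frame(
                 chromosome = c("chr1", "chr1"),
                 start_gene_index = c(1, 40),
                 end_gene_index = c(50, 60),
                 copy_ratio = c(1.5, 0.5)))),
    "overlapping", class = "scnodule_config_error")
  expect_error(sim_config(artifact_counts = c(low_gene = 0, high_mito = 0,
                                              doublet = 1)),
               "doublet", class = "scnodule_config_error")
})

test_that("copy-neutral segments leave segment genes at baseline", {
  # with copy_ratio 1 the malignant designation must carry no expression
  # signal: rank-test p-values on segment-gene expression are uniform
  seeds <- 1:200
  pvals <- vapply(seeds, function(s) {
    cfg <- sim_config(
      n_genes = 120, n_chromosomes = 2,
      n_samples = c(normal = 0, pGGN = 1, SN = 0),
      cell_counts = list(pGGN = c(epithelial = 40)),
      malignant_fraction = c(pGGN = 0.5, SN = 0),
      cnv_segments = list(pGGN1 = data.frame(
        chromosome = "chr1", start_gene_index = 1, end_gene_index = 40,
        copy_ratio = 1.0)),
      markers_per_type = 0, mito_gene_count = 5, seed = s)
    sim <- generate_cohort(cfg)
    seg <- Matrix::colMeans(sim$cohort$counts[1:40, ])
    mal <- sim$truth$cells$is_malignant
    if (sum(mal) < 3 || sum(!mal) < 3) return(NA_real_)
    suppressWarnings(stats::wilcox.test(seg[mal], seg[!mal])$p.value)
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 150)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))  # discrete ties
  expect_gt(ks$p.value, 0.001)
})
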