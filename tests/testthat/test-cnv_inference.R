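test_that("genomic gene ordering is stable with documented tie-breaks", {
  genes <- tibble::tibble(gene_id = c("a", "b", "c"),
                          chromosome = "chr1",
                          start = c(0, 100, 200))
  expect_equal(order_genes_genomically(genes), 1:3)

  genes2 <- tibble::tibble(gene_id = c("a", "b"), chromosome = "chr1",
                           start = c(500, 100))
  expect_equal(order_genes_genomically(genes2), c(2L, 1L))

  # tie on (chromosome, start): gene id lexicographic
  genes3 <- tibble::tibble(gene_id = c("zz", "aa"), chromosome = "chr1",
                           start = c(100, 100))
  expect_equal(order_genes_genomically(genes3), c(2L, 1L))

  # chromosomes keep their input order, not alphabetical
  genes4 <- tibble::tibble(gene_id = c("a", "b", "c"),
                           chromosome = c("chr2", "chr2", "chr10"),
                           start = c(0, 10, 0))
  expect_equal(order_genes_genomically(genes4), c(1L, 2L, 3L))

  genes5 <- tibble::tibble(gene_id = c("a", "b"), chromosome = c("chr1", NA),
                           start = c(0, 10))
  expect_error(order_genes_genomically(genes5), "b",
               class = "scnodule_annotation_error")
})

test_that("reference-mean gene filter applies the cutoff inclusively", {
  counts <- rbind(c(0, 0, 1), c(0, 0, 0), c(5, 5, 5))
  expect_equal(filter_genes_by_reference_mean(counts, 1:3, 0.1), c(1L, 3L))
  expect_equal(filter_genes_by_reference_mean(counts, 1:3, 0), 1:3)
  expect_error(filter_genes_by_reference_mean(counts, integer(0)),
               class = "scnodule_config_error")
})

test_that("reference centering subtracts the reference mean and clamps", {
  norm <- cbind(ref1 = c(1, 2, 3), ref2 = c(3, 2, 1), obs = c(2, 2, 9))
  cen <- center_on_reference(norm, 1:2, clamp = 3)
  expect_equal(unname(cen[, "obs"]), c(0, 0, 3))  # 9 - 2 = 7, clipped to 3
  # a cell identical to the reference mean profile is all-zero
  expect_equal(unname(cen[, "ref1"]), c(-1, 0, 1))
  one <- center_on_reference(norm[, 1, drop = FALSE], 1, clamp = 3)
  expect_true(all(one == 0))                      # self-centering
})

test_that("sliding-window smoothing matches the hand-computed example", {
  centered <- matrix(c(0, 0, 3, 0, 0), ncol = 1)
  sm <- smooth_sliding_window(centered, rep("chr1", 5), window = 3,
                              recenter = FALSE)
  expect_equal(as.vector(sm), c(0, 1, 1, 1, 0))
  expect_true(all(smooth_sliding_window(matrix(0, 6, 3), rep("chr1", 6),
                                        window = 3) == 0))
  expect_error(smooth_sliding_window(centered, rep("chr1", 5), window = 4),
               class = "scnodule_config_error")
  expect_warning(smooth_sliding_window(centered, rep("chr1", 5),
                                       window = 7, recenter = FALSE),
                 "smallest chromosome")
})

test_that("smoothing equals the naive double-loop oracle across chromosomes", {
  set.seed(11)
  for (rep in 1:5) {
    centered <- matrix(rnorm(30 * 10), 30, 10)
    chrom <- rep(c("chr1", "chr2"), c(17, 13))
    for (w in c(3, 5, 7)) {
      expect_lt(max(abs(
        smooth_sliding_window(centered, chrom, w) -
          oracle_smooth(centered, chrom, w))), 1e-10)
    }
  }
})

test_that("adding a constant to a cell leaves its re-centered profile fixed", {
  set.seed(12)
  centered <- matrix(rnorm(40 * 4), 40, 4)
  chrom <- rep(c("chr1", "chr2"), each = 20)
  base <- smooth_sliding_window(centered, chrom, 5)
  shifted <- centered
  shifted[, 2] <- shifted[, 2] + 1.7
  expect_equal(smooth_sliding_window(shifted, chrom, 5), base)
})

test_that("a planted gain lifts smoothed values in malignant cells", {
  cfg <- sim_config(
    n_genes = 600, n_chromosomes = 2,
    n_samples = c(normal = 0, pGGN = 1, SN = 0),
    cell_counts = list(pGGN = c(epithelial = 200, T_cell = 60,
                                myeloid = 60)),
    malignant_fraction = c(pGGN = 0.5, SN = 0),
    cnv_segments = list(pGGN1 = data.frame(
      chromosome = "chr1", start_gene_index = 50, end_gene_index = 169,
      copy_ratio = 1.5)),
    seed = 21)
  sim <- generate_cohort(cfg)
  cnv <- infer_cnv(sim$cohort, "pGGN1", cnv_params(window = 51))
  seg_gene_ids <- sim$cohort$genes$gene_id[50:169]
  in_seg <- cnv$windows$gene_id %in% seg_gene_ids
  per_cell <- rowMeans(cnv$values[, in_seg, drop = FALSE])
  mal <- sim$truth$cells$is_malignant[match(cnv$cells$barcode,
                                            sim$truth$cells$barcode)]
  expect_gte(sum(mal), 50)
  expect_gte(sum(!mal), 50)
  p <- stats::wilcox.test(per_cell[mal], per_cell[!mal],
                          alternative = "greater")$p.value
  expect_lt(p, 0.01)
  # CNVMatrix contract: values bounded by the clamp, windows chromosome-pure
  expect_true(all(abs(cnv$values) <= cnv$params$clamp))
  first_chr <- cnv$windows$chromosome[match(cnv$windows$first_gene,
                                            cnv$windows$gene_id)]
  expect_equal(first_chr, cnv$windows$chromosome)
})
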