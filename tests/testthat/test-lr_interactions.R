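lr_fixture <- function() {
  # 3 genes x 8 cells, two types of 4 cells each, hand-set values
  norm <- rbind(lig = c(2, 2, 2, 2, 0, 0, 0, 0),
                rec = c(0, 0, 0, 0, 4, 4, 4, 4),
                off = rep(0, 8))
  colnames(norm) <- paste0("c", 1:8)
  labels <- rep(c("sender", "receiver"), each = 4)
  list(norm = norm, labels = labels)
}

test_that("the interaction mean averages the two cluster means", {
  f <- lr_fixture()
  r <- interaction_mean(f$norm, "lig", "rec", 1:4, 5:8)
  expect_equal(r$value, 3)
  expect_false(r$inactive)

  # unexpressed ligand: value still reported, flagged inactive
  r0 <- interaction_mean(f$norm, "off", "rec", 1:4, 5:8)
  expect_equal(r0$value, 2)
  expect_true(r0$inactive)

  # degenerate symmetry: same gene, same cells
  rs <- interaction_mean(f$norm, "lig", "lig", 1:4, 1:4)
  expect_equal(rs$value, 2)

  expect_error(interaction_mean(f$norm, "nope", "rec", 1:4, 5:8),
               class = "scnodule_config_error")
})

test_that("the expression-fraction filter counts expressing cells", {
  norm <- matrix(0, 1, 100, dimnames = list("g", NULL))
  norm[1, 1:12] <- 1
  expect_true(expression_fraction_filter(norm, "g", 1:100, 0.10))
  expect_false(expression_fraction_filter(norm, "g", 13:100, 0.10))
  expect_true(expression_fraction_filter(norm, "g", 13:100, 0))
})

test_that("permutation p-values live on the add-one grid and are seeded", {
  f <- lr_fixture()
  p <- permutation_pvalue(f$norm, "lig", "rec", f$labels, "sender",
                          "receiver", lr_params(n_permutations = 200,
                                                seed = 5))
  expect_true(abs(p * 201 - round(p * 201)) < 1e-12)
  p2 <- permutation_pvalue(f$norm, "lig", "rec", f$labels, "sender",
                           "receiver", lr_params(n_permutations = 200,
                                                 seed = 5))
  expect_identical(p, p2)

  # all-zero expression: every permuted mean ties the observed 0
  pz <- permutation_pvalue(f$norm, "off", "off", f$labels, "sender",
                           "receiver", lr_params(n_permutations = 100))
  expect_equal(pz, 1)

  expect_error(
    permutation_pvalue(f$norm, "lig", "rec", f$labels, "absent", "receiver"),
    class = "scnodule_domain_error")
})

test_that("the engine matches an independent brute-force shuffler", {
  set.seed(17)
  norm <- matrix(round(rexp(4 * 50), 2), 4, 50,
                 dimnames = list(c("l1", "r1", "l2", "r2"), paste0("c", 1:50)))
  labels <- sample(rep(c("A", "B", "C"), c(20, 18, 12)))
  cells <- tibble::tibble(barcode = paste0("c", 1:50), cell_type = labels,
                          stage = "pGGN")
  pairs <- tibble::tibble(pair_id = c("p1", "p2"),
                          ligand = c("l1", "l2"), receptor = c("r1", "r2"))
  res <- score_interactions(norm, cells, pairs,
                            lr_params(n_permutations = 300, seed = 9))
  for (row in c(1, 5, 10, 17)) {
    p_oracle <- oracle_perm_p(norm, res$ligand[row], res$receptor[row],
                              labels, res$sender[row], res$receiver[row],
                              n_perm = 300, seed = 9)
    expect_equal(res$p_value[row], p_oracle)
  }
})

test_that("stage-specific edges land in the network difference report", {
  it <- tibble::tibble(
    stage = c("pGGN", "SN", "SN"),
    pair_id = c("p1", "p1", "p2"),
    ligand = "l", receptor = "r",
    sender = c("A", "A", "B"), receiver = "B",
    interaction_mean = 1, p_value = c(0.01, 0.20, 0.01),
    inactive = FALSE,
    significant = c(TRUE, FALSE, TRUE))
  class(it) <- c("interaction_table", class(it))
  net <- build_interaction_network(it)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$difference$pair_id, c("p1", "p2"))
  expect_equal(net$difference$specific_to[net$difference$pair_id == "p1"],
               "pGGN")

  empty <- build_interaction_network(it[it$p_value > 0.5, ])
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$difference), 0)
})

test_that("a pair planted in SN is detected in SN and not in pGGN", {
  hits_sn <- 0
  hits_pggn <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(
      n_genes = 400, n_chromosomes = 2,
      n_samples = c(normal = 0, pGGN = 1, SN = 1),
      cell_counts = list(pGGN = c(T_cell = 80, myeloid = 80),
                         SN = c(T_cell = 80, myeloid = 80)),
      malignant_fraction = c(pGGN = 0, SN = 0),
      cnv_segments = "none", markers_per_type = 0,
      lr_pairs_planted = data.frame(
        ligand_gene = "g00011", receptor_gene = "g00022",
        sender_type = "T_cell", receiver_type = "myeloid", stage = "SN"),
      lr_boost = 6, seed = 100 + s)
    sim <- generate_cohort(cfg)
    norm <- normalize_log(sim$cohort)
    pairs <- tibble::tibble(pair_id = "planted", ligand = "g00011",
                            receptor = "g00022")
    res <- score_interactions(norm, sim$cohort$cells, pairs,
                              lr_params(n_permutations = 200, seed = s))
    sig <- res[res$sender == "T_cell" & res$receiver == "myeloid", ]
    hits_sn <- hits_sn + sig$significant[sig$stage == "SN"]
    hits_pggn <- hits_pggn + sig$significant[sig$stage == "pGGN"]
  }
  expect_gte(hits_sn, 9)
  expect_lte(hits_pggn, 2)
})
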