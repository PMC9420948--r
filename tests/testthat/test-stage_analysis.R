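test_that("marker scoring assigns the expressing type and breaks ties", {
  norm <- rbind(gX1 = c(5, 0), gX2 = c(4, 0), gY1 = c(0, 5), gY2 = c(0, 4))
  colnames(norm) <- c("c1", "c2")
  res <- score_cell_types(norm, list(X = c("gX1", "gX2"),
                                     Y = c("gY1", "gY2")))
  expect_equal(res$assignment$cell_type, c("X", "Y"))

  # identical marker sets: identical scores, lexicographic winner
  res2 <- score_cell_types(norm, list(zeta = c("gX1", "gX2"),
                                      alpha = c("gX1", "gX2")))
  expect_equal(res2$scores[, "alpha"], res2$scores[, "zeta"])
  expect_true(all(res2$assignment$cell_type == "alpha"))

  expect_error(score_cell_types(norm, list(X = c("gX1", "missing"))),
               "missing", class = "scnodule_config_error")
})

test_that("marker scoring recovers planted types on a simulated cohort", {
  sim <- small_sim(seed = 31, marker_boost = 4)
  q <- apply_qc_filters(sim$cohort)
  norm <- normalize_log(q$kept)
  marker_sets <- split(sim$truth$genes$gene_id[!is.na(sim$truth$genes$marker_of)],
                       sim$truth$genes$marker_of[!is.na(sim$truth$genes$marker_of)])
  res <- score_cell_types(norm, marker_sets)
  acc <- mean(res$assignment$cell_type == q$kept$cells$cell_type)
  expect_gte(acc, 0.95)
})

test_that("stage composition proportions are normalized per stage", {
  cells <- tibble::tibble(
    stage = rep(c("normal", "pGGN"), c(10, 100)),
    cell_type = c(rep("epithelial", 10), rep("epithelial", 30),
                  rep("T_cell", 70)))
  expect_warning(comp <- composition_by_stage(cells), "SN")
  expect_equal(comp$proportion[comp$stage == "normal"], 1.0)
  expect_equal(sort(comp$proportion[comp$stage == "pGGN"]), c(0.3, 0.7))
  sums <- tapply(comp$proportion, comp$stage, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})

test_that("the rank-sum engine agrees with stats::wilcox.test", {
  set.seed(41)
  m <- matrix(rpois(100 * 50, 2), 100, 50)
  in_a <- rep(c(TRUE, FALSE), c(25, 25))
  p <- scnodule:::rank_sum_rows(m, in_a)
  p_ref <- apply(m, 1, function(x) suppressWarnings(
    stats::wilcox.test(x[in_a], x[!in_a], exact = FALSE)$p.value))
  expect_equal(p, p_ref, tolerance = 1e-12)

  # exact path: small groups, continuous data
  m2 <- matrix(rnorm(40 * 16), 40, 16)
  in_a2 <- rep(c(TRUE, FALSE), each = 8)
  p2 <- scnodule:::rank_sum_rows(m2, in_a2)
  p2_ref <- apply(m2, 1, function(x)
    stats::wilcox.test(x[in_a2], x[!in_a2], exact = TRUE)$p.value)
  expect_equal(p2, p2_ref, tolerance = 1e-12)
})

test_that("DEG calling: identity contrast is empty, labels swap cleanly", {
  sim <- small_sim(seed = 32)
  norm <- normalize_log(sim$cohort)
  epi <- which(sim$cohort$cells$cell_type == "epithelial")
  a <- epi[sim$cohort$cells$stage[epi] == "pGGN"]
  b <- epi[sim$cohort$cells$stage[epi] == "normal"]

  expect_equal(nrow(wilcoxon_deg(norm, a, a)), 0)

  ab <- wilcoxon_deg(norm, a, b, filter = FALSE)
  ba <- wilcoxon_deg(norm, b, a, filter = FALSE)
  expect_equal(ab$logFC, -ba$logFC)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$passes, ba$passes)
  swapped <- ifelse(ab$direction == "up", "down", "up")
  expect_equal(swapped[abs(ab$logFC) > 0], ba$direction[abs(ab$logFC) > 0])

  expect_equal(ab$p_adjusted, stats::p.adjust(ab$p_value, "BH"))
  expect_true(all(ab$p_adjusted >= ab$p_value))
  expect_error(wilcoxon_deg(norm, a[1:2], b), class = "scnodule_domain_error")
})

test_that("the logFC convention is ln of mean de-logged expression", {
  norm <- rbind(g1 = c(log(3), log(5), log(4), log(2), log(2), log(2)))
  colnames(norm) <- paste0("c", 1:6)
  tab <- wilcoxon_deg(rbind(norm, norm, norm), 1:3, 4:6, filter = FALSE)
  expect_equal(tab$logFC[1],
               log(mean(c(2, 4, 3)) + 1) - log(mean(c(1, 1, 1)) + 1))
})

test_that("stage-dependent DEGs need the same direction in both contrasts", {
  t1 <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       cell_type = "epithelial",
                       direction = c("up", "up", "down"))
  t2 <- tibble::tibble(gene_id = c("g1", "g2", "g4"),
                       cell_type = "epithelial",
                       direction = c("up", "down", "down"))
  out <- stage_dependent_degs(t1, t2)
  expect_equal(out$gene_id, "g1")
  expect_equal(out$direction, "up")
})

test_that("a planted monotone gene is recovered as stage-dependent up", {
  set.seed(43)
  n_genes <- 300
  mk_stage <- function(mult, n = 60) {
    mu <- rep(2, n_genes)
    mu[1] <- 2 * mult
    matrix(rnbinom(n_genes * n, mu = mu, size = 10), n_genes)
  }
  counts <- cbind(mk_stage(1), mk_stage(2), mk_stage(4))
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  norm <- normalize_log(counts)
  stage <- rep(c("normal", "pGGN", "SN"), each = 60)
  d1 <- wilcoxon_deg(norm, which(stage == "pGGN"), which(stage == "normal"),
                     contrast = "pGGN_vs_normal", cell_type = "epithelial")
  d2 <- wilcoxon_deg(norm, which(stage == "SN"), which(stage == "pGGN"),
                     contrast = "SN_vs_pGGN", cell_type = "epithelial")
  out <- stage_dependent_degs(d1, d2)
  expect_true("g001" %in% out$gene_id[out$direction == "up"])
})
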