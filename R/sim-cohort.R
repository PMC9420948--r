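#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a gene x cell UMI count matrix under the model described in
#' [sim_config()] and returns it together with a truth table recording, for
#' every cell, its type, stage, sample, malignant status and artifact status,
#' and for every gene, its marker/mito/CNV-segment membership. The truth
#' table is what downstream QC, CNV, malignancy, differential-expression and
#' ligand-receptor modules are benchmarked against.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `cohort` — a [cohort()] (counts + gene + cell annotations);
#'   * `truth` — a list of tibbles `cells`, `genes`, `segments`, `lr_pairs`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 300, n_chromosomes = 3,
#'                   n_samples = c(normal = 1, pGGN = 1, SN = 1),
#'                   cell_counts = list(
#'                     normal = c(epithelial = 20, T_cell = 20),
#'                     pGGN = c(epithelial = 20, T_cell = 20),
#'                     SN = c(epithelial = 20, T_cell = 20)),
#'                   cnv_segments = "none", seed = 7)
#' sim <- generate_cohort(cfg)
#' sim$cohort
generate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)

  genes <- build_gene_table(cfg)
  segs <- segment_table(cfg, genes)

  # relative baseline means; mito genes pinned to the target fraction
  base <- rlnorm(cfg$n_genes, cfg$baseline_mean_log_mu,
                 cfg$baseline_mean_log_sigma)
  mito <- genes$is_mito
  if (any(mito)) {
    base[mito] <- base[mito] / sum(base[mito]) *
      cfg$mito_frac_target / (1 - cfg$mito_frac_target) * sum(base[!mito])
  }
  base_mu <- base / sum(base) * cfg$library_size_mean

  all_types <- unique(unlist(lapply(cfg$cell_counts, names)))
  marker_rows <- assign_markers(cfg, genes, segs, all_types)

  cells <- build_cell_table(cfg)
  cells$is_malignant <- FALSE
  for (st in .tumor_stages) {
    frac <- cfg$malignant_fraction[[st]]
    if (is.null(frac) || is.na(frac)) frac <- 0
    idx <- which(cells$stage == st & cells$cell_type == "epithelial")
    if (length(idx)) {
      cells$is_malignant[idx] <- rbinom(length(idx), 1L, frac) == 1L
    }
  }

  blocks <- list()
  samples <- unlist(sample_names(cfg), use.names = FALSE)
  for (sm in samples) {
    rows <- which(cells$sample == sm)
    if (!length(rows)) next
    blocks[[sm]] <- draw_sample_block(cfg, base_mu, marker_rows, segs,
                                      cells[rows, , drop = FALSE])
  }

  art <- draw_artifacts(cfg, base_mu, marker_rows, segs, genes)
  counts <- do.call(cbind, c(unname(blocks), list(art$counts)))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  cells_all <- bind_rows(cells, art$cells)

  coh <- cohort(counts,
                genes[, c("gene_id", "gene_name", "chromosome", "start",
                          "is_mito")],
                cells_all[, c("barcode", "sample", "stage", "cell_type")])

  truth <- list(
    cells = as_tibble(cells_all[, c("barcode", "sample", "stage", "cell_type",
                                    "is_malignant", "is_artifact",
                                    "artifact_kind")]),
    genes = tibble(gene_id = genes$gene_id,
                   chromosome = genes$chromosome,
                   marker_of = marker_label(marker_rows, cfg$n_genes),
                   in_cnv_segment = seq_len(cfg$n_genes) %in%
                     unlist(lapply(segs, function(s)
                       unlist(Map(seq, s$start_global, s$end_global)))),
                   is_mito = genes$is_mito),
    segments = if (length(segs)) {
      bind_rows(lapply(names(segs), function(sm)
        mutate(segs[[sm]], sample = sm, .before = 1)))
    } else {
      tibble(sample = character(), chromosome = character(),
             start_gene_index = integer(), end_gene_index = integer(),
             copy_ratio = double(), start_global = integer(),
             end_global = integer())
    },
    lr_pairs = cfg$lr_pairs_planted %||%
      tibble(ligand_gene = character(), receptor_gene = character(),
             sender_type = character(), receiver_type = character(),
             stage = character()))

  list(cohort = coh, truth = truth, config = cfg)
}

build_gene_table <- function(cfg) {
  gpc <- cfg$genes_per_chromosome
  chrom <- rep(paste0("chr", seq_len(cfg$n_chromosomes)), gpc)
  within <- unlist(lapply(gpc, seq_len))
  ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  is_mito <- rep(FALSE, cfg$n_genes)
  if (cfg$mito_gene_count > 0) {
    is_mito[seq(cfg$n_genes - cfg$mito_gene_count + 1L, cfg$n_genes)] <- TRUE
  }
  tibble(gene_id = ids, gene_name = ids, chromosome = chrom,
         start = (within - 1L) * 10000L, is_mito = is_mito)
}

# segments with global gene indices attached
segment_table <- function(cfg, genes) {
  offs <- cumsum(c(0L, cfg$genes_per_chromosome))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  lapply(cfg$cnv_segments, function(seg) {
    seg <- as_tibble(seg)
    ci <- match(seg$chromosome, chroms)
    mutate(seg,
           start_global = offs[ci] + .data$start_gene_index,
           end_global = offs[ci] + .data$end_gene_index)
  })
}

assign_markers <- function(cfg, genes, segs, types) {
  in_seg <- seq_len(cfg$n_genes) %in%
    unlist(lapply(segs, function(s)
      unlist(Map(seq, s$start_global, s$end_global))))
  pool <- which(!genes$is_mito & !in_seg)
  need <- cfg$markers_per_type * length(types)
  if (length(pool) < need) {
    config_error("markers_per_type",
                 sprintf("needs %d marker genes but only %d eligible", need,
                         length(pool)))
  }
  picked <- sample(pool, need)
  split(picked, rep(types, each = cfg$markers_per_type))
}

marker_label <- function(marker_rows, n_genes) {
  lab <- rep(NA_character_, n_genes)
  for (t in names(marker_rows)) lab[marker_rows[[t]]] <- t
  lab
}

build_cell_table <- function(cfg) {
  sams <- sample_names(cfg)
  out <- list()
  for (st in .stages) {
    sm <- sams[[st]]
    counts <- cfg$cell_counts[[st]]
    if (is.null(counts)) next
    counts <- vapply(counts, as.integer, integer(1))
    for (j in seq_along(sm)) {
      # split each type's stage count as evenly as possible across samples
      per <- vapply(counts, function(k) {
        k %/% length(sm) + as.integer(j <= k %% length(sm))
      }, integer(1))
      if (sum(per) == 0) next
      out[[sm[j]]] <- tibble(sample = sm[j], stage = st,
                             cell_type = rep(names(per), per))
    }
  }
  cells <- bind_rows(out)
  cells <- cells |>
    group_by(.data$sample) |>
    mutate(barcode = sprintf("%s_c%05d", .data$sample, dplyr::row_number())) |>
    ungroup()
  cells$is_artifact <- FALSE
  cells$artifact_kind <- NA_character_
  cells[, c("barcode", "sample", "stage", "cell_type", "is_artifact",
            "artifact_kind")]
}

# expected-count matrix for a block of cells from one sample, then NB draw
draw_sample_block <- function(cfg, base_mu, marker_rows, segs, cells) {
  mu <- expected_means(cfg, base_mu, marker_rows, segs, cells)
  matrix(rnbinom(length(mu), size = cfg$nb_dispersion, mu = mu),
         nrow = nrow(mu))
}

expected_means <- function(cfg, base_mu, marker_rows, segs, cells,
                           lib_boost = 1) {
  n <- nrow(cells)
  libf <- rlnorm(n, -cfg$library_size_sigma^2 / 2, cfg$library_size_sigma) *
    lib_boost
  mu <- outer(base_mu, libf)
  for (t in intersect(names(marker_rows), unique(cells$cell_type))) {
    cols <- which(cells$cell_type == t)
    mu[marker_rows[[t]], cols] <- mu[marker_rows[[t]], cols] *
      cfg$marker_boost
  }
  sm <- cells$sample[1]
  seg <- segs[[sm]]
  mal <- which(cells$is_malignant)
  if (!is.null(seg) && length(mal)) {
    for (i in seq_len(nrow(seg))) {
      rows <- seq(seg$start_global[i], seg$end_global[i])
      mu[rows, mal] <- plant_cnv_effect(mu[rows, mal], seg$copy_ratio[i])
    }
  }
  lr <- cfg$lr_pairs_planted
  if (!is.null(lr) && nrow(lr)) {
    gid <- sprintf("g%05d", seq_len(cfg$n_genes))
    st <- cells$stage[1]
    for (i in seq_len(nrow(lr))) {
      if (lr$stage[i] != st) next
      lig <- match(lr$ligand_gene[i], gid)
      rec <- match(lr$receptor_gene[i], gid)
      if (is.na(lig) || is.na(rec)) {
        config_error("lr_pairs_planted", "gene id not in simulated genes")
      }
      snd <- which(cells$cell_type == lr$sender_type[i])
      rcv <- which(cells$cell_type == lr$receiver_type[i])
      if (length(snd)) mu[lig, snd] <- mu[lig, snd] * cfg$lr_boost
      if (length(rcv)) mu[rec, rcv] <- mu[rec, rcv] * cfg$lr_boost
    }
  }
  mu
}

draw_artifacts <- function(cfg, base_mu, marker_rows, segs, genes) {
  ac <- cfg$artifact_counts
  kinds <- rep(c("low_gene", "high_mito", "doublet"),
               c(ac[["low_gene"]], ac[["high_mito"]], ac[["doublet"]]))
  samples <- unlist(sample_names(cfg), use.names = FALSE)
  stage_of <- sub("[0-9]+$", "", samples)
  keep <- vapply(stage_of, function(st)
    sum(cfg$cell_counts[[st]] %||% 0) > 0, logical(1))
  samples <- samples[keep]
  stage_of <- stage_of[keep]
  if (!length(kinds)) {
    return(list(counts = matrix(0L, cfg$n_genes, 0),
                cells = tibble(barcode = character(), sample = character(),
                               stage = character(), cell_type = character(),
                               is_artifact = logical(),
                               artifact_kind = character())))
  }
  cols <- matrix(0L, cfg$n_genes, length(kinds))
  meta <- vector("list", length(kinds))
  for (i in seq_along(kinds)) {
    sm <- samples[((i - 1L) %% length(samples)) + 1L]
    st <- stage_of[((i - 1L) %% length(samples)) + 1L]
    types <- names(cfg$cell_counts[[st]])[cfg$cell_counts[[st]] > 0]
    ty <- types[sample.int(length(types), 1)]
    one <- function(type, boost = 1, mito_target = NULL, pool = NULL) {
      mu <- expected_means(cfg, base_mu, marker_rows, segs,
                           tibble(sample = sm, stage = st, cell_type = type,
                                  is_malignant = FALSE),
                           lib_boost = boost)[, 1]
      if (!is.null(mito_target)) {
        m <- genes$is_mito
        mu[m] <- mu[m] / sum(mu[m]) *
          mito_target / (1 - mito_target) * sum(mu[!m])
      }
      if (!is.null(pool)) mu[-pool] <- 0
      rnbinom(length(mu), size = cfg$nb_dispersion, mu = mu)
    }
    x <- switch(kinds[i],
      low_gene = one(ty, pool = sample.int(cfg$n_genes, cfg$low_gene_pool)),
      high_mito = {
        for (try in 1:100) {
          x <- one(ty, mito_target = cfg$high_mito_frac)
          if (sum(x[genes$is_mito]) > 0.10 * sum(x)) break
        }
        x
      },
      doublet = {
        boost <- cfg$doublet_boost
        ok <- FALSE
        for (try in 1:20) {
          ty2 <- types[sample.int(length(types), 1)]
          x <- one(ty, boost = boost) + one(ty2, boost = boost)
          if (sum(x > 0) > cfg$doublet_min_genes) {
            ok <- TRUE
            break
          }
          boost <- boost * 1.5
        }
        if (!ok) {
          abort("could not draw a doublet exceeding the detected-gene bound",
                class = "scnodule_config_error")
        }
        x
      })
    cols[, i] <- x
    meta[[i]] <- tibble(barcode = sprintf("%s_art_%s%03d", sm, kinds[i], i),
                        sample = sm, stage = st, cell_type = ty,
                        is_artifact = TRUE, artifact_kind = kinds[i])
  }
  list(counts = cols, cells = bind_rows(meta))
}
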