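# small dense dataset built by hand for the threshold tests
make_tiny_ds <- function() {
  genes <- c(sprintf("g%02d", 1:8), "mt-x", "mt-y")
  expr <- matrix(5L, 4, 10, dimnames = list(paste0("c", 1:4), genes))
  expr[, 9:10] <- 0L
  expr[2, ] <- c(rep(0L, 7), 3L, 0L, 0L)         # 1 detected gene
  expr[3, 9:10] <- 40L                            # high mito
  guide_umi <- matrix(0L, 4, 3,
                      dimnames = list(paste0("c", 1:4), c("G1", "G2", "G3")))
  guide_umi[1, 1] <- 10L
  guide_umi[2, 1] <- 10L
  guide_umi[3, 1] <- 10L
  guide_umi[4, 1:2] <- c(10L, 7L)
  cell_dataset(expr, guide_umi)
}

test_that("guide detection thresholds and statuses", {
  ds <- make_tiny_ds()
  aq <- assign_guides(ds, min_umi = 3)
  expect_equal(aq$assigned_guide[1], "G1")
  expect_equal(aq$guide_status[4], "fail_multi")
  expect_equal(aq$n_guides, c(1L, 1L, 1L, 2L))
  # UMIs below threshold do not count
  ds$guide_umi[1, 2] <- 2L
  expect_equal(assign_guides(ds, min_umi = 3)$n_guides[1], 1L)
  s <- assignment_summary(aq)
  expect_equal(s$n_single, 3L)
  expect_equal(s$singlet_percent, 75)
})

test_that("cell QC applies gene, mito and guide criteria in order", {
  ds <- make_tiny_ds()
  f <- qc_cells(ds, min_genes = 5, max_genes = 4500, max_mito = 0.10)
  qc <- f$qc
  expect_equal(qc$status, c("pass", "fail_genes", "fail_mito", "fail_multi"))
  expect_equal(qc$genes_detected[2], 1L)
  expect_gt(qc$mito_fraction[3], 0.10)
  expect_equal(rownames(f$expr), "c1")
  expect_equal(unname(f$cell_guide["c1"]), "G1")
  expect_error(qc_cells(ds, min_genes = 100), "no cells pass")
})

test_that("simulated QC failure labels are recovered exactly", {
  for (seed in c(101, 102)) {
    cfg <- small_sc_cfg(seed)
    sl <- simulate_library(cfg)
    sc <- simulate_sc(cfg, sl)
    f <- qc_cells(sc$dataset)
    expect_identical(f$qc$status, sc$ledger$expected_status)
  }
})

test_that("planted multiplet rate is recovered", {
  cfg <- small_sc_cfg(103)
  sl <- simulate_library(cfg)
  sc <- simulate_sc(cfg, sl)
  aq <- assign_guides(sc$dataset)
  captured <- sc$ledger$captured
  rate <- sum(aq$n_guides[captured] >= 2) / sum(captured)
  ci <- stats::binom.test(sum(sc$ledger$multiplet), nrow(sc$ledger),
                          0.08)$conf.int
  expect_gt(rate, ci[1] - 0.02)
  expect_lt(rate, ci[2] + 0.02)
})

test_that("log normalization matches a two-line reference and is scale-free", {
  genes <- sprintf("g%02d", 1:30)
  counts <- withr::with_seed(9, matrix(rpois(600, 4), 20, 30,
    dimnames = list(sprintf("c%02d", 1:20), genes)))
  counts[1, ] <- 0L; counts[1, 5] <- 10L
  gu <- matrix(10L, 20, 1, dimnames = list(rownames(counts), "G1"))
  ds <- cell_dataset(counts, gu)
  X <- normalize_log(ds)
  # cell 1: a single expressed gene takes the whole scale factor
  expect_equal(X[1, 5], log(1 + 1e4))
  expect_equal(sum(X[1, -5]), 0)
  # independent reference implementation
  ref <- log1p(sweep(counts, 1, rowSums(counts), "/") * 1e4)
  expect_equal(X, ref, tolerance = 1e-12)
  # doubling a cell's counts leaves its normalized vector unchanged
  counts2 <- counts; counts2[2, ] <- 2L * counts2[2, ]
  X2 <- normalize_log(cell_dataset(counts2, gu))
  expect_equal(X2[2, ], X[2, ])
})

test_that("pseudotime orients archetypes at 0 and 1 and flags degeneracy", {
  genes <- c(sprintf("s%02d", 1:10), "dm", "lm")
  gm <- data.frame(gene = genes, mito = FALSE,
                   signature = c(rep(TRUE, 10), FALSE, FALSE),
                   leukemia_marker = c(rep(FALSE, 11), TRUE),
                   diff_marker = c(rep(FALSE, 10), TRUE, FALSE))
  leuk_profile <- c(rep(c(40L, 2L), 5), 1L, 40L)
  diff_profile <- c(rep(c(2L, 40L), 5), 40L, 1L)
  expr <- rbind(matrix(rep(leuk_profile, 6), 6, byrow = TRUE),
                matrix(rep(diff_profile, 6), 6, byrow = TRUE))
  # tiny jitter so within-archetype variance is nonzero
  expr <- expr + withr::with_seed(2, matrix(rpois(144, 1), 12))
  dimnames(expr) <- list(sprintf("c%02d", 1:12), genes)
  gu <- matrix(10L, 12, 1, dimnames = list(rownames(expr), "G1"))
  ds <- cell_dataset(expr, gu, gm)
  ds$cell_guide <- stats::setNames(rep("G1", 12), rownames(expr))
  pt <- signature_pseudotime(ds)
  expect_true(all(pt$tau >= 0 & pt$tau <= 1))
  expect_lt(max(pt$tau[1:6]), 0.2)   # leukemia archetype near 0
  expect_gt(min(pt$tau[7:12]), 0.8)  # differentiated archetype near 1

  const <- expr; const[] <- 5L
  dsc <- cell_dataset(const, gu, gm)
  dsc$cell_guide <- ds$cell_guide
  expect_error(signature_pseudotime(dsc), "degenerate|zero variance")
})

test_that("pseudotime recovers the latent differentiation axis", {
  rho <- vapply(c(104, 105, 106), function(seed) {
    cfg <- small_sc_cfg(seed)
    sl <- simulate_library(cfg)
    sc <- simulate_sc(cfg, sl)
    f <- qc_cells(sc$dataset)
    pt <- signature_pseudotime(f)
    d <- sc$ledger$d[match(names(pt$tau), sc$ledger$cell)]
    stats::cor(pt$tau, d, method = "spearman")
  }, numeric(1))
  expect_true(all(rho >= 0.8))
})

test_that("per-guide pseudotime medians are null outside planted windows", {
  # no effect: guides in a non-essential region behave like neg controls
  hits <- vapply(1:20, function(seed) {
    cfg <- small_sc_cfg(300 + seed, sc = list(n_cells = 1200L, n_filler = 300L,
                                              effect_size = 0))
    sl <- simulate_library(cfg)
    sc <- simulate_sc(cfg, sl)
    f <- qc_cells(sc$dataset)
    pt <- signature_pseudotime(f)
    med <- pt$per_guide_median
    cat_of <- sl$library$guides$category[
      match(names(med), sl$library$guides$guide_id)]
    neutral <- guides_in_span(sl$library, residue_span(290, 400))$guide_id
    p <- stats::wilcox.test(med[names(med) %in% neutral],
                            med[cat_of == "neg_control"],
                            exact = FALSE)$p.value
    p <= 0.01
  }, logical(1))
  expect_lte(sum(hits), 1)
})

test_that("smoothed pseudotime track rises inside the planted window", {
  cfg <- small_sc_cfg(107)
  sl <- simulate_library(cfg)
  sc <- simulate_sc(cfg, sl)
  f <- qc_cells(sc$dataset)
  pt <- signature_pseudotime(f)
  tr <- pseudotime_residue_track(pt, sl$library)
  expect_equal(nrow(tr), 400)
  inside <- mean(tr$score[60:160])
  outside <- mean(tr$score[c(1:40, 300:400)])
  expect_gt(inside, outside + 0.2)

  # flat medians give a flat track
  flat <- pt
  flat$per_guide_median[] <- 0.5
  trf <- pseudotime_residue_track(flat, sl$library)
  expect_equal(trf$score, rep(0.5, 400))

  # agrees with the brute-force Nadaraya-Watson oracle
  med <- pt$per_guide_median
  med <- med[names(med) %in% sl$library$guides$guide_id[
    sl$library$guides$category == "tiling"]]
  x <- sl$library$guides$cds_cut_nt[
    match(names(med), sl$library$guides$guide_id)]
  oracle <- brute_force_smooth(x, unname(med), attr(tr, "bandwidth_nt"),
                               sl$library$cds_length_nt, 400)
  expect_equal(tr$score, oracle, tolerance = 1e-10)
})

test_that("pseudobulk profiles match per-gene brute-force smoothing", {
  cfg <- small_sc_cfg(108)
  sl <- simulate_library(cfg)
  sc <- simulate_sc(cfg, sl)
  f <- qc_cells(sc$dataset)
  pm <- pseudobulk_profiles(f, sl$library)
  expect_equal(nrow(pm), 400)
  expect_equal(ncol(pm), 100)

  # independent recomputation of one gene column
  X <- normalize_log(f)
  g <- "Sig007"
  guide <- f$cell_guide
  tab <- table(guide)
  keep <- intersect(names(tab)[tab >= 3],
                    sl$library$guides$guide_id[
                      sl$library$guides$category == "tiling"])
  means <- vapply(keep, function(gg) mean(X[names(guide)[guide == gg], g]),
                  numeric(1))
  x <- sl$library$guides$cds_cut_nt[match(keep, sl$library$guides$guide_id)]
  oracle <- brute_force_smooth(x, unname(means), attr(pm, "bandwidth_nt"),
                               sl$library$cds_length_nt, 400)
  expect_equal(unname(pm[, g]), oracle, tolerance = 1e-10)
})

test_that("position correlation is a clamped symmetric Pearson matrix", {
  pm <- structure(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1)),
                  class = c("pseudobulk_matrix", "matrix"))
  r <- position_correlation(pm)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_equal(diag(r), rep(1, 3))
  expect_equal(r, t(r))
  expect_true(all(r >= -1 & r <= 1))
  # zero-variance rows give missing correlations, diagonal stays 1
  pm2 <- structure(rbind(c(1, 2, 3, 4), c(2, 2, 2, 2)),
                   class = c("pseudobulk_matrix", "matrix"))
  r2 <- position_correlation(pm2)
  expect_true(is.na(r2[1, 2]))
  expect_equal(diag(r2), c(1, 1))
  expect_error(position_correlation(pm[, 1, drop = FALSE]), ">= 2")
})

test_that("residue PC1 recovers rank-1 structure and fixed orientation", {
  u <- c(0.1, 0.5, 1.2, -0.4, 0.9)
  v <- c(2, -1, 0.5)
  pm <- structure(outer(u, v), class = c("pseudobulk_matrix", "matrix"))
  pc <- residue_pc1(pm)
  uc <- u - mean(u)
  # proportional to the centered left factor
  expect_equal(abs(cor(pc$score, uc)), 1, tolerance = 1e-10)
  # orientation rule: flipping every gene column leaves oriented PC1 fixed
  ref <- residue_track(uc, source = "pseudotime")
  pc_a <- residue_pc1(pm, orient = ref)
  pm_f <- structure(-unclass(pm), class = class(pm))
  pc_b <- residue_pc1(pm_f, orient = ref)
  expect_equal(pc_a$score, pc_b$score, tolerance = 1e-10)
  expect_gt(cor(pc_a$score, ref$score), 0)
})

test_that("planted essential region separates from neutral residues on PC1", {
  cfg <- small_sc_cfg(109)
  sl <- simulate_library(cfg)
  sc <- simulate_sc(cfg, sl)
  f <- qc_cells(sc$dataset)
  pt <- signature_pseudotime(f)
  tr <- pseudotime_residue_track(pt, sl$library)
  pm <- pseudobulk_profiles(f, sl$library)
  pc <- residue_pc1(pm, orient = tr)
  ess <- pc$score[60:160]
  neu <- pc$score[300:400]
  pooled_sd <- sqrt((stats::var(ess) + stats::var(neu)) / 2)
  expect_gt((mean(ess) - mean(neu)) / pooled_sd, 2)
})

test_that("group differential expression is calibrated on planted shifts", {
  de_genes <- sprintf("Fil%03d", 1:30)
  n_true_called <- 0; n_true <- 0; n_false <- 0; n_null <- 0
  for (seed in 1:10) {
    cfg <- small_sc_cfg(
      500 + seed,
      sc = list(de_windows = list(
        list(start = 60, end = 160, genes = de_genes, log_shift = 1))))
    sl <- simulate_library(cfg)
    sc <- simulate_sc(cfg, sl)
    f <- qc_cells(sc$dataset)
    de_a <- group_de(f, sl$library, residue_span(60, 160))
    is_true <- de_a$gene %in% de_genes
    n_true_called <- n_true_called + sum(de_a$differential[is_true])
    n_true <- n_true + sum(is_true)
    null_genes <- grepl("^Fil", de_a$gene) & !is_true
    n_false <- n_false + sum(de_a$differential[null_genes])
    n_null <- n_null + sum(null_genes)
  }
  expect_gte(n_true_called / n_true, 27 / 30)
  expect_lte(n_false / n_null, 0.05)

  # two regions planted with the same heterogeneous effect vector give
  # strongly correlated effect estimates
  shifts <- seq(-1, 1.5, length.out = 30)
  effects_a <- NULL; effects_b <- NULL
  for (seed in 521:523) {
    cfg <- small_sc_cfg(
      seed,
      sc = list(de_windows = list(
        list(start = 60, end = 160, genes = de_genes, log_shift = shifts),
        list(start = 220, end = 270, genes = de_genes, log_shift = shifts))))
    sl <- simulate_library(cfg)
    sc <- simulate_sc(cfg, sl)
    f <- qc_cells(sc$dataset)
    de_a <- group_de(f, sl$library, residue_span(60, 160))
    de_b <- group_de(f, sl$library, residue_span(220, 270))
    effects_a <- c(effects_a, de_a$effect[de_a$gene %in% de_genes])
    effects_b <- c(effects_b, de_b$effect[de_b$gene %in% de_genes])
  }
  expect_gte(stats::cor(effects_a, effects_b), 0.9)

  # identical groups: zero effects, no calls
  cfg <- small_sc_cfg(550)
  sl <- simulate_library(cfg)
  sc <- simulate_sc(cfg, sl)
  f <- qc_cells(sc$dataset)
  neg_ids <- sl$library$guides$guide_id[
    sl$library$guides$category == "neg_control"]
  de0 <- group_de(f, sl$library, residue_span(290, 400), reference = neg_ids)
  expect_lte(sum(de0$differential), 2)
  expect_error(group_de(f, sl$library, residue_span(1, 2)), "undersized")
})

test_that("QC pass set is invariant to cell order", {
  cfg <- small_sc_cfg(110)
  sl <- simulate_library(cfg)
  sc <- simulate_sc(cfg, sl)
  ds <- sc$dataset
  perm <- withr::with_seed(1, sample(nrow(ds$expr)))
  ds2 <- cell_dataset(ds$expr[perm, ], ds$guide_umi[perm, ], ds$gene_meta)
  f1 <- qc_cells(ds)
  f2 <- qc_cells(ds2)
  expect_setequal(rownames(f1$expr), rownames(f2$expr))
})

test_that("cell datasets round-trip through MTX and TSV inputs", {
  cfg <- small_sc_cfg(111, sc = list(n_cells = 60L, n_filler = 20L,
                                     n_signature = 10L))
  sl <- simulate_library(cfg)
  sc <- simulate_sc(cfg, sl)
  ds <- sc$dataset
  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(t(ds$expr), sparse = TRUE),
                  file.path(dir, "expr.mtx"))
  writeLines(colnames(ds$expr), file.path(dir, "genes.tsv"))
  writeLines(rownames(ds$expr), file.path(dir, "barcodes.tsv"))
  utils::write.table(as.data.frame(as.matrix(ds$guide_umi)),
                     file.path(dir, "guides.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(ds$gene_meta, file.path(dir, "gene_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_cell_dataset(file.path(dir, "expr.mtx"),
                            file.path(dir, "guides.tsv"),
                            file.path(dir, "genes.tsv"),
                            file.path(dir, "barcodes.tsv"),
                            file.path(dir, "gene_meta.tsv"))
  expect_equal(as.matrix(back$expr), as.matrix(ds$expr))
  expect_equal(back$gene_meta, ds$gene_meta)
})
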