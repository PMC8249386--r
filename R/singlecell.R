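#' Single-cell dataset with direct guide capture
#'
#' Bundles a cell x gene UMI count matrix, a cell x guide capture-count
#' matrix and per-gene metadata flags. Cells are rows in both matrices and
#' must agree; identifiers must be unique.
#'
#' @param expr cell x gene counts (base matrix or `Matrix` sparse matrix),
#'   rownames = cell barcodes, colnames = gene names.
#' @param guide_umi cell x guide capture counts, same rownames as `expr`,
#'   colnames = guide ids.
#' @param gene_meta data.frame with column `gene` and logical columns
#'   `mito`, `signature` (<= 100 genes), `leukemia_marker`, `diff_marker`;
#'   if omitted, `mito` defaults to genes matching `^mt-` (case-insensitive)
#'   and the other flags to `FALSE`.
#' @param cell_guide optional named character vector cell -> guide id
#'   (normally filled in by [qc_cells()]).
#' @return An object of class `cell_dataset`.
#' @export
cell_dataset <- function(expr, guide_umi, gene_meta = NULL, cell_guide = NULL) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("'expr' needs cell rownames and gene colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate cell identifiers")
  if (anyDuplicated(colnames(expr))) stop("duplicate gene identifiers")
  if (!identical(rownames(expr), rownames(guide_umi)))
    stop("'expr' and 'guide_umi' must share identical cell rownames")
  if (is.null(colnames(guide_umi))) stop("'guide_umi' needs guide colnames")
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene = colnames(expr),
                            mito = grepl("^mt-", colnames(expr), ignore.case = TRUE),
                            signature = FALSE, leukemia_marker = FALSE,
                            diff_marker = FALSE, stringsAsFactors = FALSE)
  }
  for (fl in c("mito", "signature", "leukemia_marker", "diff_marker"))
    if (!fl %in% names(gene_meta)) gene_meta[[fl]] <- FALSE
  if (!setequal(gene_meta$gene, colnames(expr)))
    stop("gene_meta genes do not match expr columns")
  gene_meta <- gene_meta[match(colnames(expr), gene_meta$gene), , drop = FALSE]
  rownames(gene_meta) <- NULL
  if (sum(gene_meta$signature) > 100)
    stop("signature gene set exceeds 100 genes")
  structure(list(expr = expr, guide_umi = guide_umi, gene_meta = gene_meta,
                 cell_guide = cell_guide, qc = NULL),
            class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("cell_dataset: %d cells x %d genes, %d guides captured%s\n",
              nrow(x$expr), ncol(x$expr), ncol(x$guide_umi),
              if (!is.null(x$cell_guide)) " (QC applied)" else ""))
  invisible(x)
}

#' Assign captured guides to cells
#'
#' A guide is detected in a cell when its capture UMI count reaches
#' `min_umi` (an ambient-RNA guard). Cells with exactly one detected guide
#' are assignable; zero detected guides gives status `fail_none`, two or
#' more `fail_multi` (doublets or multiply infected cells).
#'
#' @param ds a [cell_dataset()].
#' @param min_umi detection threshold (default 3).
#' @return data.frame with columns `cell`, `n_guides`, `assigned_guide`
#'   (NA unless exactly one) and `guide_status`.
#' @export
assign_guides <- function(ds, min_umi = 3) {
  stopifnot(inherits(ds, "cell_dataset"))
  det <- as.matrix(ds$guide_umi >= min_umi)
  n <- rowSums(det)
  assigned <- rep(NA_character_, nrow(det))
  one <- which(n == 1L)
  if (length(one) > 0)
    assigned[one] <- colnames(det)[max.col(det[one, , drop = FALSE])]
  status <- ifelse(n == 0L, "fail_none", ifelse(n >= 2L, "fail_multi", "pass"))
  data.frame(cell = rownames(ds$expr), n_guides = as.integer(n),
             assigned_guide = assigned, guide_status = status,
             stringsAsFactors = FALSE)
}

#' Summarize guide assignment rates
#'
#' @param aq an [assign_guides()] table.
#' @return list with total cells, counts of cells with a single / two /
#'   more-than-two detected guides, none, and `singlet_percent`.
#' @export
assignment_summary <- function(aq) {
  n_total <- nrow(aq)
  list(n_total = n_total,
       n_single = sum(aq$n_guides == 1L),
       n_two = sum(aq$n_guides == 2L),
       n_more = sum(aq$n_guides > 2L),
       n_none = sum(aq$n_guides == 0L),
       singlet_percent = singlet_rate(sum(aq$n_guides == 1L), n_total))
}

#' Single-guide assignment rate in percent
#'
#' @param n_single cells with exactly one detected guide.
#' @param n_total total cells.
#' @return `100 * n_single / n_total`.
#' @export
singlet_rate <- function(n_single, n_total) {
  stopifnot(n_total > 0, n_single >= 0, n_single <= n_total)
  100 * n_single / n_total
}

#' Quality-control filter for single cells
#'
#' A cell passes when its number of detected genes (counts > 0) lies in
#' `[min_genes, max_genes]`, its mitochondrial read fraction is at most
#' `max_mito`, and exactly one guide is detected. Failure statuses are
#' assigned with precedence `fail_genes` > `fail_mito` > `fail_multi` /
#' `fail_none`.
#'
#' @param ds a [cell_dataset()].
#' @param min_genes,max_genes detected-gene bounds (defaults 200 and 4500).
#' @param max_mito maximum mitochondrial fraction (default 0.10).
#' @param min_umi guide detection threshold, see [assign_guides()].
#' @return The filtered [cell_dataset()] containing only passing cells,
#'   with `cell_guide` filled in and the full per-cell QC table (all input
#'   cells) in `$qc`.
#' @export
qc_cells <- function(ds, min_genes = 200, max_genes = 4500, max_mito = 0.10,
                     min_umi = 3) {
  stopifnot(inherits(ds, "cell_dataset"))
  expr <- ds$expr
  tot <- Matrix::rowSums(expr)
  genes_detected <- Matrix::rowSums(expr > 0)
  mito <- ds$gene_meta$mito
  mito_fraction <- if (any(mito))
    Matrix::rowSums(expr[, mito, drop = FALSE]) / pmax(tot, 1) else
    rep(0, nrow(expr))
  ag <- assign_guides(ds, min_umi)
  status <- ifelse(genes_detected < min_genes | genes_detected > max_genes,
                   "fail_genes",
            ifelse(mito_fraction > max_mito, "fail_mito", ag$guide_status))
  qc <- data.frame(cell = rownames(expr),
                   genes_detected = as.integer(genes_detected),
                   mito_fraction = as.numeric(mito_fraction),
                   n_guides = ag$n_guides,
                   assigned_guide = ag$assigned_guide,
                   status = status, stringsAsFactors = FALSE)
  pass <- status == "pass"
  if (!any(pass)) {
    tally <- table(status)
    stop("no cells pass QC (",
         paste(sprintf("%s: %d", names(tally), tally), collapse = ", "), ")")
  }
  out <- ds
  out$expr <- expr[pass, , drop = FALSE]
  out$guide_umi <- ds$guide_umi[pass, , drop = FALSE]
  out$cell_guide <- stats::setNames(qc$assigned_guide[pass], qc$cell[pass])
  out$qc <- qc
  out
}

#' Library-size normalization with log transform
#'
#' Scales each cell's counts to a fixed total (default 10,000), then
#' applies `log(1 + x)` (natural log). Doubling all counts of a cell leaves
#' its normalized vector unchanged.
#'
#' @param ds a [cell_dataset()] (normally after [qc_cells()]).
#' @param scale_factor target per-cell total.
#' @return Dense cell x gene matrix of normalized values.
#' @export
normalize_log <- function(ds, scale_factor = 1e4) {
  stopifnot(inherits(ds, "cell_dataset"))
  tot <- Matrix::rowSums(ds$expr)
  if (any(tot == 0))
    stop("zero-count cell(s) present; these should have failed QC: ",
         paste(utils::head(rownames(ds$expr)[tot == 0], 3), collapse = ", "))
  log1p(as.matrix(ds$expr) / tot * scale_factor)
}

#' Signature-gene pseudotime
#'
#' A deterministic trajectory score: the first principal component of the
#' cell-centered, log-normalized signature-gene submatrix, min-max scaled to
#' `[0, 1]` and sign-oriented so that pseudotime correlates positively with
#' the mean expression of differentiation markers (and hence negatively
#' with leukemia markers). Per-guide medians are reported for guides with
#' at least `min_cells` assigned cells. An externally computed per-cell
#' pseudotime can be supplied via `tau` to bypass the internal PCA.
#'
#' @param ds a QC-filtered [cell_dataset()] with `cell_guide` set.
#' @param min_cells minimum cells per guide for a median (default 3).
#' @param tau optional externally computed pseudotime, named by cell.
#' @return An object of class `pseudotime_table`: list with `tau` (named,
#'   in `[0,1]`) and `per_guide_median`.
#' @export
signature_pseudotime <- function(ds, min_cells = 3, tau = NULL) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$cell_guide))
    stop("run qc_cells() first (cell_guide is unset)")
  X <- normalize_log(ds)
  if (is.null(tau)) {
    sig <- ds$gene_meta$signature
    if (sum(sig) < 2) stop("need >= 2 signature genes")
    if (nrow(X) < 10) stop("need >= 10 passing cells")
    S <- scale(X[, sig, drop = FALSE], center = TRUE, scale = FALSE)
    sv <- La.svd(S, nu = 1, nv = 0)
    if (sv$d[1] <= .Machine$double.eps * max(dim(S)))
      stop("degenerate signature matrix: zero variance")
    pc1 <- sv$u[, 1] * sv$d[1]
    rng <- range(pc1)
    if (diff(rng) == 0) stop("degenerate signature matrix: constant PC1")
    tau <- (pc1 - rng[1]) / diff(rng)
    names(tau) <- rownames(X)
    dm <- ds$gene_meta$diff_marker
    lm <- ds$gene_meta$leukemia_marker
    orient <- NA_real_
    if (any(dm)) orient <- stats::cor(tau, rowMeans(X[, dm, drop = FALSE]))
    if (is.na(orient) && any(lm))
      orient <- -stats::cor(tau, rowMeans(X[, lm, drop = FALSE]))
    if (!is.na(orient) && orient < 0) tau <- 1 - tau
  } else {
    tau <- tau[rownames(X)]
    if (anyNA(tau)) stop("external 'tau' must cover every passing cell")
  }
  med <- tapply(tau, ds$cell_guide[names(tau)], stats::median)
  n_per <- table(ds$cell_guide[names(tau)])
  med <- med[names(n_per)[n_per >= min_cells]]
  structure(list(tau = tau,
                 per_guide_median = stats::setNames(as.numeric(med), names(med)),
                 min_cells = min_cells),
            class = "pseudotime_table")
}

#' Smoothed per-residue pseudotime track
#'
#' Treats per-guide pseudotime medians as a [score_track()] and reuses
#' [kernel_smooth()]; guides lacking enough cells are simply absent,
#' enlarging the effective gaps.
#'
#' @param pt a [signature_pseudotime()] result.
#' @param lib a [guide_library()].
#' @param bandwidth_nt see [kernel_smooth()].
#' @return A [residue_track()] with source `"pseudotime"`.
#' @export
pseudotime_residue_track <- function(pt, lib, bandwidth_nt = NULL) {
  stopifnot(inherits(pt, "pseudotime_table"))
  med <- pt$per_guide_median
  med <- med[names(med) %in% lib$guides$guide_id[lib$guides$category == "tiling"]]
  if (length(med) < 2) stop("need per-guide medians for >= 2 tiling guides")
  kernel_smooth(score_track(med), lib, bandwidth_nt, source = "pseudotime")
}

#' Per-residue transcriptomic profiles (pseudobulk, smoothed)
#'
#' For each signature gene, computes the per-guide mean of log-normalized
#' expression over that guide's cells and smooths it along the gene body
#' ([kernel_smooth()]), giving one residue-length column per gene.
#'
#' @param ds a QC-filtered [cell_dataset()].
#' @param lib a [guide_library()].
#' @param min_cells minimum cells per guide (default 3).
#' @param bandwidth_nt see [kernel_smooth()].
#' @return Matrix residues x signature genes of class `pseudobulk_matrix`
#'   with attribute `bandwidth_nt`.
#' @export
pseudobulk_profiles <- function(ds, lib, min_cells = 3, bandwidth_nt = NULL) {
  stopifnot(inherits(ds, "cell_dataset"), inherits(lib, "guide_library"))
  if (is.null(ds$cell_guide)) stop("run qc_cells() first")
  sig <- ds$gene_meta$signature
  if (sum(sig) < 2) stop("need >= 2 signature genes")
  X <- normalize_log(ds)[, sig, drop = FALSE]
  guide <- ds$cell_guide[rownames(X)]
  n_per <- table(guide)
  tiling_ids <- lib$guides$guide_id[lib$guides$category == "tiling"]
  keep_guides <- intersect(names(n_per)[n_per >= min_cells], tiling_ids)
  if (length(keep_guides) < 2)
    stop("need >= 2 tiling guides with >= ", min_cells, " cells")
  in_keep <- guide %in% keep_guides
  M <- rowsum(X[in_keep, , drop = FALSE], guide[in_keep])
  M <- M / as.vector(table(guide[in_keep])[rownames(M)])
  x <- lib$guides$cds_cut_nt[match(rownames(M), lib$guides$guide_id)]
  h <- bandwidth_nt %||% default_bandwidth(lib)
  sm <- nw_smooth(seq_len(lib$cds_length_nt), x, M, h)
  L <- lib$protein_length_aa
  k <- 3 * seq_len(L)
  P <- (sm$fit[k - 2, , drop = FALSE] + sm$fit[k - 1, , drop = FALSE] +
        sm$fit[k, , drop = FALSE]) / 3
  dimnames(P) <- list(NULL, colnames(X))
  structure(P, bandwidth_nt = sm$bandwidth, class = c("pseudobulk_matrix", "matrix"))
}

#' Position-ordered Pearson correlation matrix
#'
#' Pearson correlation between the residue rows of a pseudobulk profile
#' matrix: entry (i, j) is the correlation of residues i and j across the
#' signature genes. The diagonal is set to 1; zero-variance rows give
#' missing values; off-diagonal values are clamped to `[-1, 1]`.
#'
#' @param pm a [pseudobulk_profiles()] matrix.
#' @return residues x residues matrix of class `correlation_matrix`.
#' @export
position_correlation <- function(pm) {
  if (ncol(pm) < 2) stop("need >= 2 signature gene columns")
  r <- suppressWarnings(stats::cor(t(unclass(pm))))
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  structure(r, class = c("correlation_matrix", "matrix"))
}

#' First principal component of the residue profiles
#'
#' PC1 score per residue of the gene-centered pseudobulk profile matrix,
#' summarizing the dominant transcriptomic axis along the protein. The sign
#' is oriented so that PC1 correlates positively with a supplied reference
#' track (typically the smoothed pseudotime track).
#'
#' @param pm a [pseudobulk_profiles()] matrix.
#' @param orient optional [residue_track()] fixing the sign.
#' @return A [residue_track()] with source `"pc1"`.
#' @export
residue_pc1 <- function(pm, orient = NULL) {
  X <- scale(unclass(pm), center = TRUE, scale = FALSE)
  sv <- La.svd(X, nu = 1, nv = 0)
  if (sv$d[1] <= .Machine$double.eps * max(dim(X)))
    stop("degenerate profile matrix")
  pc1 <- sv$u[, 1] * sv$d[1]
  if (!is.null(orient)) {
    stopifnot(inherits(orient, "residue_track"), nrow(orient) == length(pc1))
    cc <- stats::cor(pc1, orient$score, use = "complete.obs")
    if (!is.na(cc) && cc < 0) pc1 <- -pc1
  }
  residue_track(pc1, bandwidth_nt = attr(pm, "bandwidth_nt"), source = "pc1")
}

#' Differential expression between a targeted region and reference cells
#'
#' Compares cells whose assigned guide cuts inside `region` against
#' reference cells (by default, cells carrying negative-control guides).
#' Per gene: mean difference of log-normalized expression (region minus
#' reference), two-sample Wilcoxon rank-sum p-value, and Benjamini-Hochberg
#' FDR; genes at FDR < `fdr` are flagged differential.
#'
#' @param ds a QC-filtered [cell_dataset()].
#' @param lib a [guide_library()].
#' @param region a [residue_span()].
#' @param reference `"neg_control"` or a character vector of guide ids.
#' @param min_cells_group minimum cells per group (default 10).
#' @param fdr call threshold (default 0.05).
#' @return data.frame with columns `gene`, `effect`, `p_value`, `fdr`,
#'   `differential`.
#' @export
group_de <- function(ds, lib, region, reference = "neg_control",
                     min_cells_group = 10, fdr = 0.05) {
  stopifnot(inherits(ds, "cell_dataset"), inherits(lib, "guide_library"),
            inherits(region, "residue_span"))
  if (is.null(ds$cell_guide)) stop("run qc_cells() first")
  region_ids <- guides_in_span(lib, region)$guide_id
  ref_ids <- if (identical(reference, "neg_control"))
    lib$guides$guide_id[lib$guides$category == "neg_control"] else reference
  guide <- ds$cell_guide
  a <- names(guide)[guide %in% region_ids]
  b <- names(guide)[guide %in% ref_ids]
  if (length(a) < min_cells_group || length(b) < min_cells_group)
    stop("undersized group: region ", length(a), " cells, reference ",
         length(b), " cells (need >= ", min_cells_group, ")")
  X <- normalize_log(ds)
  Xa <- X[a, , drop = FALSE]; Xb <- X[b, , drop = FALSE]
  effect <- colMeans(Xa) - colMeans(Xb)
  p <- vapply(seq_len(ncol(X)), function(j) {
    if (all(Xa[, j] == Xa[1, j]) && all(Xb[, j] == Xa[1, j])) return(1)
    suppressWarnings(stats::wilcox.test(Xa[, j], Xb[, j], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = colnames(X), effect = as.numeric(effect), p_value = p,
             fdr = q, differential = q < fdr, stringsAsFactors = FALSE)
}

#' Read a cell dataset from standard on-disk formats
#'
#' @param expr_path expression matrix: MatrixMarket `.mtx` (with `genes_path`
#'   and `barcodes_path` giving one identifier per line) or a dense TSV with
#'   cell rownames and gene colnames.
#' @param guide_path cell x guide capture counts as TSV (cell rownames).
#' @param genes_path,barcodes_path identifier files for MTX input; the MTX
#'   is expected gene x cell (as emitted by droplet pipelines) and is
#'   transposed to cell x gene.
#' @param gene_meta_path optional TSV with columns `gene` and logical flag
#'   columns (see [cell_dataset()]).
#' @return A [cell_dataset()].
#' @export
read_cell_dataset <- function(expr_path, guide_path, genes_path = NULL,
                              barcodes_path = NULL, gene_meta_path = NULL) {
  if (grepl("\\.mtx(\\.gz)?$", expr_path)) {
    if (is.null(genes_path) || is.null(barcodes_path))
      stop("MTX input needs genes_path and barcodes_path")
    m <- Matrix::readMM(expr_path)
    genes <- readLines(genes_path)
    cells <- readLines(barcodes_path)
    dimnames(m) <- list(genes, cells)
    expr <- Matrix::t(m)
  } else {
    expr <- as.matrix(utils::read.delim(expr_path, row.names = 1,
                                        check.names = FALSE))
  }
  guide_umi <- as.matrix(utils::read.delim(guide_path, row.names = 1,
                                           check.names = FALSE))
  guide_umi <- guide_umi[rownames(expr), , drop = FALSE]
  gene_meta <- NULL
  if (!is.null(gene_meta_path)) {
    gene_meta <- utils::read.delim(gene_meta_path, stringsAsFactors = FALSE)
    for (fl in setdiff(names(gene_meta), "gene"))
      gene_meta[[fl]] <- as.logical(gene_meta[[fl]])
  }
  cell_dataset(expr, guide_umi, gene_meta)
}
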