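#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives all three generators
#' ([simulate_library()], [simulate_screen()], [simulate_sc()]). The
#' defaults emulate a high-density tiling screen of a 1537-aa
#' methyltransferase in a murine leukemia model: 602 tiling guides over the
#' CDS (stop codon included), spiked-in negative controls (fluorophore /
#' luciferase / safe-harbor targeting) and positive controls targeting an
#' essential replication gene, essential windows at the catalytic core
#' (127-332), a drug-interacting regulatory element pair (460-555 depleted
#' under drug, 558-662 enriched under drug) and a cofactor-binding motif
#' (863-900), and a single-cell stage in which guides hitting
#' loss-of-function windows push cells along a leukemia-to-differentiation
#' axis.
#'
#' @param seed integer seed; all randomness derives from it (no hidden
#'   entropy).
#' @param protein_length_aa protein length (default 1537).
#' @param include_stop count the stop codon in the CDS length?
#' @param n_guides,n_neg,n_pos tiling and control guide numbers (defaults
#'   602, 25, 11; odd control counts keep control medians on actual
#'   guides).
#' @param jitter tiling cut positions are a uniform grid jittered by
#'   `U(-jitter, jitter)` grid spacings (default 0.45; 0 gives exact
#'   arithmetic spacing).
#' @param essential_windows list of windows, each
#'   `list(start, end, fitness, drug_fitness)`; `fitness` is the per-day
#'   log2 frequency effect for guides cutting inside (<= 0 for depletion),
#'   `drug_fitness` an additional per-day effect under the drug arm.
#' @param pos_control_fitness per-day fitness of positive-control guides
#'   (default -0.25).
#' @param screen list: `reads_per_sample` (default 602000, i.e. 1000x
#'   coverage), `days` (default c(0, 3, 6, 9, 12)), `abundance_sdlog`
#'   (lognormal plasmid-pool spread, 0.5), `decoy_frac` (off-library reads
#'   in FASTQ emission, 0.05), `dropout_frac` (guides planted at near-zero
#'   day-0 abundance, 0).
#' @param sc list: `n_cells` (4943), `n_signature` (100), `n_filler`
#'   (480), `n_mito` (15), `multiplet_rate` (0.08), `capture_fail_rate`
#'   (0.02), `lowgene_rate` (0.03), `himito_rate` (0.04), `effect_size`
#'   (0.8, scales the differentiation shift of loss-of-function guides),
#'   `marker_slope` (2.5), `signature_slope` (2), `libsize_meanlog`
#'   (log(5000)), `libsize_sdlog` (0.25), `dispersion` (negative-binomial
#'   dispersion, 0.1), `guide_umi_mu` (20), `de_windows` (optional list of
#'   `list(start, end, genes, log_shift)` planting direct expression shifts
#'   for cells whose guide cuts inside the window; `log_shift` may be a
#'   scalar or a per-gene vector), `de_base` (base abundance weight of
#'   planted differential genes, 0.1, kept modest so the planted shift does
#'   not perturb the depth normalization of unshifted genes).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       protein_length_aa = 1537L,
                       include_stop = TRUE,
                       n_guides = 602L,
                       n_neg = 25L,
                       n_pos = 11L,
                       jitter = 0.45,
                       essential_windows = list(
                         list(start = 127, end = 332, fitness = -0.25, drug_fitness = 0),
                         list(start = 460, end = 555, fitness = -0.15, drug_fitness = -0.10),
                         list(start = 558, end = 662, fitness = 0, drug_fitness = 0.10),
                         list(start = 863, end = 900, fitness = -0.25, drug_fitness = 0)),
                       pos_control_fitness = -0.25,
                       screen = list(),
                       sc = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  screen_def <- list(reads_per_sample = 602000L, days = c(0, 3, 6, 9, 12),
                     abundance_sdlog = 0.5, decoy_frac = 0.05,
                     dropout_frac = 0)
  sc_def <- list(n_cells = 4943L, n_signature = 100L, n_filler = 480L,
                 n_mito = 15L, multiplet_rate = 0.08,
                 capture_fail_rate = 0.02, lowgene_rate = 0.03,
                 himito_rate = 0.04, effect_size = 0.8, marker_slope = 2.5,
                 signature_slope = 2, libsize_meanlog = log(5000),
                 libsize_sdlog = 0.25, dispersion = 0.1, guide_umi_mu = 20,
                 de_windows = NULL, de_base = 0.1)
  screen <- utils::modifyList(screen_def, screen)
  sc <- utils::modifyList(sc_def, sc, keep.null = TRUE)
  L <- as.integer(protein_length_aa)
  for (w in essential_windows)
    if (w$start < 1 || w$end > L || w$start > w$end)
      stop("essential window outside protein: ", w$start, "-", w$end)
  stopifnot(n_guides >= 2, n_neg >= 0, n_pos >= 0, jitter >= 0,
            screen$reads_per_sample > 0, sc$multiplet_rate >= 0,
            sc$multiplet_rate < 1, sc$dispersion > 0)
  structure(list(seed = seed, protein_length_aa = L,
                 include_stop = isTRUE(include_stop),
                 n_guides = as.integer(n_guides), n_neg = as.integer(n_neg),
                 n_pos = as.integer(n_pos), jitter = jitter,
                 essential_windows = essential_windows,
                 pos_control_fitness = pos_control_fitness,
                 screen = screen, sc = sc),
            class = "sim_config")
}

cds_length_of <- function(cfg)
  3L * (cfg$protein_length_aa + as.integer(cfg$include_stop))

random_spacers <- function(n) {
  sp <- character(0)
  while (length(sp) < n) {
    extra <- vapply(seq_len(n - length(sp) + 8L), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
      character(1))
    sp <- unique(c(sp, extra))
  }
  sp[seq_len(n)]
}

window_of_residue <- function(res, windows) {
  for (k in seq_along(windows))
    if (res >= windows[[k]]$start && res <= windows[[k]]$end) return(k)
  NA_integer_
}

#' Simulate a tiling sgRNA library with a ground-truth ledger
#'
#' Tiling cut positions are drawn on a jittered uniform grid over the CDS;
#' negative and positive control guides are appended. The ledger records
#' each guide's cut residue, essential-window membership and per-day
#' fitness (log2 frequency effect) under control and drug conditions.
#'
#' @param cfg a [sim_config()].
#' @return list with `library` (a [guide_library()]) and `ledger`
#'   (data.frame `guide_id`, `category`, `cds_cut_nt`, `residue`, `window`,
#'   `fitness`, `drug_fitness`).
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  cds <- cds_length_of(cfg)
  n <- cfg$n_guides
  if (n > cds) stop("infeasible density: more guides than CDS nucleotides")
  spacing <- cds / n
  centers <- (seq_len(n) - 0.5) * spacing
  cuts <- round(centers + stats::runif(n, -cfg$jitter, cfg$jitter) * spacing)
  cuts <- pmin(pmax(cuts, 1L), cds)
  neg_genes <- c("Luc", "Ren", "GFP", "RFP", "Rosa26")
  ids <- c(sprintf("sgTile_%04d", seq_len(n)),
           if (cfg$n_neg > 0)
             sprintf("sgNeg_%s_%d", neg_genes[(seq_len(cfg$n_neg) - 1) %% 5 + 1],
                     (seq_len(cfg$n_neg) - 1) %/% 5 + 1),
           if (cfg$n_pos > 0) sprintf("sgPos_mRpa3_%d", seq_len(cfg$n_pos)))
  category <- c(rep("tiling", n), rep("neg_control", cfg$n_neg),
                rep("pos_control", cfg$n_pos))
  guides <- data.frame(guide_id = ids,
                       spacer = random_spacers(length(ids)),
                       category = category,
                       cds_cut_nt = c(as.integer(cuts),
                                      rep(NA_integer_, cfg$n_neg + cfg$n_pos)),
                       strand = sample(c("+", "-"), length(ids), replace = TRUE),
                       stringsAsFactors = FALSE)
  lib <- guide_library(guides, cds, cfg$protein_length_aa)
  residue <- ifelse(category == "tiling", ceiling(guides$cds_cut_nt / 3), NA)
  win <- vapply(residue, function(r)
    if (is.na(r)) NA_integer_ else window_of_residue(r, cfg$essential_windows),
    integer(1))
  fitness <- numeric(length(ids))
  drug_fitness <- numeric(length(ids))
  tw <- !is.na(win)
  fitness[tw] <- vapply(win[tw], function(k) cfg$essential_windows[[k]]$fitness,
                        numeric(1))
  drug_fitness[tw] <- vapply(win[tw], function(k)
    cfg$essential_windows[[k]]$drug_fitness %||% 0, numeric(1))
  fitness[category == "pos_control"] <- cfg$pos_control_fitness
  ledger <- data.frame(guide_id = ids, category = category,
                       cds_cut_nt = guides$cds_cut_nt,
                       residue = as.integer(residue), window = win,
                       fitness = fitness, drug_fitness = drug_fitness,
                       stringsAsFactors = FALSE)
  list(library = lib, ledger = ledger)
}

#' Simulate survival-screen count matrices with known fitness
#'
#' Day-0 counts are multinomial over lognormal plasmid-pool abundances;
#' the expected frequency of guide g at day t is proportional to
#' `f0(g) * 2^(fitness(g) * t)` (plus `drug_fitness` under the drug arm).
#' The ledger stores the exact expected CRISPR score per guide, day and
#' condition, including the renormalization shift.
#'
#' @param cfg a [sim_config()].
#' @param sim_lib a [simulate_library()] result.
#' @param conditions subset of `c("control", "drug")`.
#' @return list with `counts` (guide x sample integer matrix, samples named
#'   `<condition>_d<day>`), `abundance` (day-0 pool proportions) and
#'   `ledger` (per guide, condition and late day: true fitness and exact
#'   expected CS).
#' @export
simulate_screen <- function(cfg, sim_lib, conditions = "control") {
  stopifnot(inherits(cfg, "sim_config"))
  conditions <- match.arg(conditions, c("control", "drug"), several.ok = TRUE)
  lib <- sim_lib$library
  led <- sim_lib$ledger
  set.seed(cfg$seed + 1L)
  n <- nrow(lib$guides)
  abund <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$screen$abundance_sdlog)
  dropout <- rep(FALSE, n)
  if (cfg$screen$dropout_frac > 0) {
    k <- max(1L, round(cfg$screen$dropout_frac * n))
    dropout[sample.int(n, k)] <- TRUE
    abund[dropout] <- abund[dropout] * 1e-4
  }
  p0 <- abund / sum(abund)
  days <- cfg$screen$days
  reads <- cfg$screen$reads_per_sample
  counts <- NULL
  ledger_rows <- list()
  for (cond in conditions) {
    f <- led$fitness + if (cond == "drug") led$drug_fitness else 0
    for (t in days) {
      w <- p0 * 2^(f * t)
      pt <- w / sum(w)
      col <- stats::rmultinom(1, reads, pt)[, 1]
      counts <- cbind(counts, col)
      colnames(counts)[ncol(counts)] <- sprintf("%s_d%g", cond, t)
      if (t > 0) {
        # expected CS = log10(f_t/f_0); the log10(sum) term is the
        # library-wide renormalization shift
        exp_cs <- f * t * log10(2) - log10(sum(p0 * 2^(f * t)))
        ledger_rows[[length(ledger_rows) + 1L]] <-
          data.frame(guide_id = led$guide_id, condition = cond, day = t,
                     fitness = f, expected_cs = exp_cs,
                     stringsAsFactors = FALSE)
      }
    }
  }
  rownames(counts) <- led$guide_id
  list(counts = counts, abundance = p0,
       dropout = led$guide_id[dropout],
       ledger = do.call(rbind, ledger_rows))
}

SCREEN_READ_PREFIX <- "CTTGTGGAAAGGACGAAACACCG"
SCREEN_READ_SUFFIX <- "GTTTTAGAGCTAGGCCAACATG"

#' Emit screen FASTQ files reproducing a simulated count matrix
#'
#' Each guide contributes exactly its count-matrix reads, wrapped in the
#' vector backbone (`...CACCG<spacer>GTTT...`); decoy reads (half with a
#' random off-library spacer in the backbone, half plain random sequence)
#' are appended at `decoy_frac` of the matched reads. Counting the emitted
#' FASTQ with [count_screen()] therefore reproduces the count matrix
#' exactly.
#'
#' @param sim a [simulate_screen()] result.
#' @param lib the matching [guide_library()].
#' @param dir output directory (created if needed).
#' @param samples subset of count-matrix columns (default: all).
#' @param decoy_frac decoy read fraction (default from nowhere: 0.05).
#' @param seed seed for decoys and read shuffling.
#' @return Named character vector of FASTQ paths, with a `decoys` attribute
#'   giving the per-sample decoy counts.
#' @export
write_screen_fastq <- function(sim, lib, dir, samples = NULL,
                               decoy_frac = 0.05, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- sim$counts
  samples <- samples %||% colnames(counts)
  set.seed(seed)
  spacer_set <- lib$guides$spacer
  paths <- character(0)
  decoys <- integer(0)
  for (s in samples) {
    col <- counts[, s]
    reads <- paste0(SCREEN_READ_PREFIX,
                    rep(lib$guides$spacer, times = col),
                    SCREEN_READ_SUFFIX)
    n_dec <- round(decoy_frac * sum(col))
    if (n_dec > 0) {
      n_back <- n_dec %/% 2
      dec_sp <- random_spacers(n_back + 8L)
      dec_sp <- setdiff(dec_sp, spacer_set)[seq_len(n_back)]
      backboned <- paste0(SCREEN_READ_PREFIX, dec_sp, SCREEN_READ_SUFFIX)
      plain <- vapply(seq_len(n_dec - n_back), function(i)
        paste(sample(c("A", "C", "T"), 60, replace = TRUE), collapse = ""),
        character(1))
      reads <- c(reads, backboned, plain)
    }
    reads <- sample(reads)
    path <- file.path(dir, paste0(s, ".fastq"))
    qual <- strrep("I", nchar(reads))
    writeLines(paste0("@read", seq_along(reads), "\n", reads, "\n+\n", qual),
               path)
    paths[s] <- path
    decoys[s] <- n_dec
  }
  structure(paths, decoys = decoys)
}

#' Simulate a direct-capture single-cell dataset with a ground-truth ledger
#'
#' Each cell receives one guide (multiplets at `multiplet_rate` receive two
#' or three; capture failures at `capture_fail_rate` receive none in the
#' capture matrix). A latent differentiation state `d` in (0, 1) is drawn
#' Beta(2, 6) for baseline cells and shifted high (Beta with shape
#' displaced by `effect_size`) for cells whose guide cuts inside a
#' loss-of-function (fitness < 0) window, emulating differentiation upon
#' target inactivation. Leukemia markers decrease and differentiation
#' markers increase monotonically in `d`; half the signature genes go up
#' and half down. Counts are negative binomial; mitochondrial fraction and
#' low-complexity (few detected genes) failures are planted at set rates
#' with wide margins so the QC ledger is exact.
#'
#' @param cfg a [sim_config()].
#' @param sim_lib a [simulate_library()] result.
#' @return list with `dataset` (a [cell_dataset()]) and `ledger`
#'   (per cell: true guides, multiplet/captured flags, latent `d`, planted
#'   failure labels and the expected QC status).
#' @export
simulate_sc <- function(cfg, sim_lib) {
  stopifnot(inherits(cfg, "sim_config"))
  lib <- sim_lib$library
  led <- sim_lib$ledger
  sc <- cfg$sc
  set.seed(cfg$seed + 2L)

  n_cells <- sc$n_cells
  guide_ids <- lib$guides$guide_id
  n_guides <- length(guide_ids)

  primary <- sample(guide_ids, n_cells, replace = TRUE)
  multiplet <- stats::runif(n_cells) < sc$multiplet_rate
  extra <- ifelse(multiplet, 1L + (stats::runif(n_cells) < 0.25), 0L)
  captured <- stats::runif(n_cells) >= sc$capture_fail_rate
  lowgene <- stats::runif(n_cells) < sc$lowgene_rate
  himito <- !lowgene & stats::runif(n_cells) < sc$himito_rate

  # loss-of-function windows drive differentiation
  lof <- led$fitness < 0 & led$category == "tiling"
  wg <- as.numeric(lof[match(primary, led$guide_id)])
  eff <- sc$effect_size
  d <- stats::rbeta(n_cells, 2 + 6 * eff * wg, 6 - 4 * eff * wg)

  genes <- c(sprintf("Sig%03d", seq_len(sc$n_signature)),
             "Meis1", "Hoxa9", "Myc", "Cd11b", "Gr1", "Ltf",
             sprintf("mt-Nd%02d", seq_len(sc$n_mito)),
             sprintf("Fil%03d", seq_len(sc$n_filler)))
  n_genes <- length(genes)
  is_sig <- grepl("^Sig", genes)
  is_leuk <- genes %in% c("Meis1", "Hoxa9", "Myc")
  is_diff <- genes %in% c("Cd11b", "Gr1", "Ltf")
  is_mito <- grepl("^mt-", genes)

  base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.5)
  base[is_leuk | is_diff] <- 3
  slope <- numeric(n_genes)
  slope[is_leuk] <- -sc$marker_slope
  slope[is_diff] <- sc$marker_slope
  sig_idx <- which(is_sig)
  slope[sig_idx] <- rep_len(c(sc$signature_slope, -sc$signature_slope),
                            length(sig_idx))

  # optional direct expression shifts for cells hitting given windows;
  # planted differential genes sit at modest base abundance (de_base) so
  # the shifted group's total mRNA, and with it the depth normalization of
  # unshifted genes, is essentially unperturbed
  shift <- matrix(0, n_cells, n_genes)
  if (!is.null(sc$de_windows)) {
    res_of <- led$residue[match(primary, led$guide_id)]
    for (w in sc$de_windows) {
      in_w <- !is.na(res_of) & res_of >= w$start & res_of <= w$end
      gi <- match(w$genes, genes)
      if (anyNA(gi)) stop("de_windows names unknown gene(s)")
      base[gi] <- sc$de_base
      ls <- rep(w$log_shift, length.out = length(gi))
      shift[in_w, gi] <- sweep(shift[in_w, gi, drop = FALSE], 2, ls, "+")
    }
  }

  libsize <- stats::rlnorm(n_cells, sc$libsize_meanlog, sc$libsize_sdlog)
  mf <- pmin(stats::rbeta(n_cells, 12, 360), 0.07)
  mf[himito] <- stats::runif(sum(himito), 0.18, 0.30)

  # per-cell gene weights: base * exp(slope * (d - 0.5) + planted shift),
  # mito genes get exactly the mito fraction, the rest shares (1 - mf)
  W <- exp(outer(d - 0.5, slope)) * rep(base, each = n_cells) * exp(shift)
  W[, is_mito] <- 0
  W <- W / rowSums(W) * (1 - mf)
  Wm <- matrix(rep(base[is_mito], each = n_cells), n_cells)
  W[, is_mito] <- Wm / rowSums(Wm) * mf
  mu <- W * libsize
  size <- 1 / sc$dispersion
  expr <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu, size = size),
                 n_cells, n_genes,
                 dimnames = list(sprintf("cell_%05d", seq_len(n_cells)), genes))

  # planted low-complexity cells keep exactly 120 random genes
  for (i in which(lowgene)) {
    keep <- sample.int(n_genes, 120)
    drop <- setdiff(seq_len(n_genes), keep)
    expr[i, drop] <- 0L
  }

  # guide capture: real guides get UMI >= 5, ambient guides 1-2 (below the
  # default detection threshold)
  guide_umi <- matrix(0L, n_cells, n_guides,
                      dimnames = list(rownames(expr), guide_ids))
  cell_guides <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    gs <- primary[i]
    if (extra[i] > 0)
      gs <- c(gs, sample(setdiff(guide_ids, gs), extra[i]))
    cell_guides[[i]] <- gs
    if (captured[i])
      guide_umi[i, gs] <- 5L + stats::rnbinom(length(gs), mu = sc$guide_umi_mu,
                                              size = 5)
    n_amb <- stats::rpois(1, 0.8)
    if (n_amb > 0) {
      amb <- sample(setdiff(guide_ids, gs), min(n_amb, n_guides - length(gs)))
      guide_umi[i, amb] <- sample(1:2, length(amb), replace = TRUE)
    }
  }

  expected_status <- ifelse(lowgene, "fail_genes",
                     ifelse(himito, "fail_mito",
                     ifelse(!captured, "fail_none",
                     ifelse(extra > 0, "fail_multi", "pass"))))

  gene_meta <- data.frame(gene = genes, mito = is_mito, signature = is_sig,
                          leukemia_marker = is_leuk, diff_marker = is_diff,
                          stringsAsFactors = FALSE)
  ds <- cell_dataset(expr, guide_umi, gene_meta)
  ledger <- data.frame(cell = rownames(expr), primary_guide = primary,
                       guides = vapply(cell_guides, paste, "", collapse = ","),
                       n_guides_true = 1L + extra, multiplet = multiplet,
                       captured = captured, d = d, lowgene = lowgene,
                       himito = himito, in_lof_window = wg == 1,
                       expected_status = expected_status,
                       stringsAsFactors = FALSE)
  list(dataset = ds, ledger = ledger)
}
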