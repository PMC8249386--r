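#' Per-guide score track
#'
#' A named set of per-guide scores (CRISPR scores, normalized CRISPR
#' scores, per-guide pseudotime medians, ...). Guides excluded upstream are
#' simply absent, never zero.
#'
#' @param values named numeric vector (names are guide ids).
#' @param condition,timepoint free-text labels carried along.
#' @return data.frame of class `score_track` with columns `guide_id`,
#'   `score` and attributes `condition`, `timepoint`.
#' @export
score_track <- function(values, condition = NA_character_,
                        timepoint = NA_character_) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  out <- data.frame(guide_id = names(values), score = as.numeric(values),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, condition = condition, timepoint = timepoint,
            class = c("score_track", "data.frame"))
}

#' Per-residue score track
#'
#' @param score numeric vector, one value per residue 1..protein length;
#'   `NA` marks residues with no value (e.g. unmapped after an ortholog
#'   transfer).
#' @param bandwidth_nt smoothing bandwidth in nucleotides (NA if the track
#'   was not produced by smoothing).
#' @param source provenance label, e.g. `"survival"`, `"pseudotime"` or
#'   `"expression:<gene>"`.
#' @return data.frame of class `residue_track` with columns `residue`,
#'   `score` and attributes `bandwidth_nt`, `source`.
#' @export
residue_track <- function(score, bandwidth_nt = NA_real_, source = "survival") {
  out <- data.frame(residue = seq_along(score), score = as.numeric(score))
  structure(out, bandwidth_nt = bandwidth_nt, source = source,
            class = c("residue_track", "data.frame"))
}

#' @export
plot.residue_track <- function(x, ...) {
  graphics::plot(x$residue, x$score, type = "l", xlab = "residue",
                 ylab = attr(x, "source") %||% "score", ...)
  invisible(x)
}

#' CRISPR score: pseudocounted log10 frequency fold change
#'
#' The CRISPR score of a guide is the log10 fold change of its library
#' frequency between an early (reference) and a late sample,
#' \deqn{CS(g) = \log_{10}\frac{(c_{late}+pc)/(T_{late}+pc\,N)}
#'                            {(c_{early}+pc)/(T_{early}+pc\,N)}}
#' with pseudocount `pc` applied to counts and totals (`N` = library size).
#' Guides excluded by the representation filter are absent from the track.
#'
#' @param ft a [to_frequencies()] result.
#' @param early,late sample ids present in the table.
#' @param pseudocount pseudocount (default 0.5); `0` gives the plain
#'   frequency ratio.
#' @param condition label stored on the returned track.
#' @return A [score_track()] over the non-excluded guides.
#' @export
crispr_score <- function(ft, early, late, pseudocount = 0.5,
                         condition = NA_character_) {
  stopifnot(inherits(ft, "frequency_table"))
  for (s in c(early, late))
    if (!s %in% colnames(ft$counts)) stop("sample '", s, "' not in table")
  keep <- setdiff(rownames(ft$counts), ft$excluded)
  pc <- pseudocount
  N <- ft$library_size
  fe <- (ft$counts[keep, early] + pc) / (ft$totals[[early]] + pc * N)
  fl <- (ft$counts[keep, late] + pc) / (ft$totals[[late]] + pc * N)
  score_track(stats::setNames(log10(fl / fe), keep),
              condition = condition, timepoint = late)
}

#' Control-anchored normalized CRISPR score (NCS)
#'
#' Affinely rescales a CRISPR score track so that the median score of the
#' negative-control guides is exactly 0.00 and the median of the
#' positive-control (essential-gene) guides exactly -1.00:
#' `NCS = (CS - med_neg) / (med_neg - med_pos)`. Rank order of guides is
#' preserved. Medians over an even number of controls are the mean of the
#' two central values.
#'
#' @param track a [score_track()] of CRISPR scores.
#' @param lib a [guide_library()] declaring the control categories.
#' @return A [score_track()] of normalized scores.
#' @export
normalize_ncs <- function(track, lib) {
  stopifnot(inherits(track, "score_track"), inherits(lib, "guide_library"))
  cat_of <- lib$guides$category[match(track$guide_id, lib$guides$guide_id)]
  if (anyNA(cat_of)) stop("track contains guides absent from the library")
  neg <- track$score[cat_of == "neg_control"]
  pos <- track$score[cat_of == "pos_control"]
  if (length(neg) == 0 || length(pos) == 0)
    stop("need at least one scored neg_control and one pos_control guide")
  med_neg <- stats::median(neg)
  med_pos <- stats::median(pos)
  if (med_neg == med_pos) stop("degenerate controls: identical medians")
  ncs <- (track$score - med_neg) / (med_neg - med_pos)
  score_track(stats::setNames(ncs, track$guide_id),
              condition = attr(track, "condition"),
              timepoint = attr(track, "timepoint"))
}

#' Default smoothing bandwidth: maximum inter-guide gap
#'
#' The bandwidth for gene-body smoothing is the maximum gap length between
#' consecutive distinct tiling cut positions, so that locally sparse
#' regions are still covered by the kernel.
#'
#' @param lib a [guide_library()].
#' @return Bandwidth in nucleotides (positive double).
#' @export
default_bandwidth <- function(lib) {
  stopifnot(inherits(lib, "guide_library"))
  x <- sort(unique(lib$guides$cds_cut_nt[lib$guides$category == "tiling"]))
  if (length(x) < 2) stop("need >= 2 distinct tiling cut positions")
  max(diff(x))
}

# Nadaraya-Watson regression with a Gaussian kernel at evaluation points p.
# V: one row per guide, one column per signal; returns length(p) x ncol(V).
# Widens h (doubling, with a warning) if the kernel underflows to zero total
# weight at any p.
nw_smooth <- function(p, x, V, h) {
  if (is.null(dim(V))) V <- matrix(V, ncol = 1)
  stopifnot(length(x) == nrow(V), h > 0)
  repeat {
    W <- exp(-outer(p, x, "-")^2 / (2 * h^2))
    sw <- rowSums(W)
    if (all(sw > 0)) break
    h <- 2 * h
    warning("kernel weights underflowed; bandwidth widened to ", h, " nt")
  }
  list(fit = (W %*% V) / sw, bandwidth = h)
}

#' Gaussian-kernel gene-body smoothing with codon averaging
#'
#' Interpolates a per-guide score track along the CDS by Gaussian kernel
#' (Nadaraya-Watson) smoothing evaluated at every nucleotide, then averages
#' each trinucleotide codon to obtain one value per peptide position:
#' \deqn{S(p) = \sum_g w_g v_g / \sum_g w_g,\quad
#'       w_g = e^{-(p-x_g)^2/(2h^2)}}
#' with \eqn{x_g} the guide's cut nucleotide and \eqn{h} the bandwidth
#' (default: [default_bandwidth()], the maximum inter-guide gap). Gaussian
#' tails are kept (no truncation window). Control guides and guides absent
#' from the track enlarge the effective gaps but do not contribute.
#'
#' @param track a [score_track()]; only tiling guides are used.
#' @param lib a [guide_library()].
#' @param bandwidth_nt bandwidth in nucleotides; default
#'   [default_bandwidth()].
#' @param source provenance label for the result.
#' @return A [residue_track()] of length `protein_length_aa`.
#' @export
kernel_smooth <- function(track, lib, bandwidth_nt = NULL, source = "survival") {
  stopifnot(inherits(track, "score_track"), inherits(lib, "guide_library"))
  g <- lib$guides
  i <- match(track$guide_id, g$guide_id)
  if (anyNA(i)) stop("track contains guides absent from the library")
  til <- g$category[i] == "tiling"
  x <- g$cds_cut_nt[i][til]
  v <- track$score[til]
  ok <- is.finite(v)
  x <- x[ok]; v <- v[ok]
  if (length(v) < 2) stop("need >= 2 scored tiling guides to smooth")
  h <- bandwidth_nt %||% default_bandwidth(lib)
  sm <- nw_smooth(seq_len(lib$cds_length_nt), x, v, h)
  S <- sm$fit[, 1]
  L <- lib$protein_length_aa
  k <- 3 * seq_len(L)
  residue_track((S[k - 2] + S[k - 1] + S[k]) / 3,
                bandwidth_nt = sm$bandwidth, source = source)
}

#' Survival-screen scan pipeline
#'
#' Composition of [to_frequencies()], [crispr_score()] (replicate pairs
#' averaged on the CS scale), optional [normalize_ncs()] and
#' [kernel_smooth()].
#'
#' @param counts guide x sample count matrix (e.g. from [count_screen()] or
#'   [simulate_screen()]).
#' @param lib a [guide_library()].
#' @param early,late sample ids; vectors of equal length are treated as
#'   replicate pairs and averaged at the CS stage.
#' @param normalize apply control anchoring ([normalize_ncs()])?
#' @param bandwidth_nt smoothing bandwidth; default [default_bandwidth()].
#' @param pseudocount see [crispr_score()].
#' @param min_frac_of_expected see [to_frequencies()].
#' @param condition label carried onto the tracks.
#' @return list with `scores` (per-guide [score_track()], CS or NCS) and
#'   `smoothed` (per-residue [residue_track()]).
#' @export
scan_pipeline <- function(counts, lib, early, late, normalize = FALSE,
                          bandwidth_nt = NULL, pseudocount = 0.5,
                          min_frac_of_expected = 0.05,
                          condition = NA_character_) {
  stopifnot(length(early) == length(late), length(early) >= 1)
  ft <- to_frequencies(counts, lib, min_frac_of_expected,
                       reference = early[1])
  tracks <- mapply(function(e, l)
    crispr_score(ft, e, l, pseudocount, condition)$score,
    early, late, SIMPLIFY = FALSE)
  cs <- rowMeans(do.call(cbind, tracks))
  keep <- setdiff(rownames(ft$counts), ft$excluded)
  track <- score_track(stats::setNames(cs, keep), condition = condition,
                       timepoint = paste(late, collapse = "+"))
  if (normalize) track <- normalize_ncs(track, lib)
  smoothed <- kernel_smooth(track, lib, bandwidth_nt,
                            source = if (normalize) "survival_ncs" else "survival")
  list(scores = track, smoothed = smoothed)
}

#' Write a score or residue track as TSV
#'
#' @param track a [score_track()] or [residue_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(condition = attr(track, "condition"),
            timepoint = attr(track, "timepoint"),
            bandwidth_nt = attr(track, "bandwidth_nt"),
            source = attr(track, "source"))
  meta <- meta[!is.na(meta)]
  if (length(meta) > 0)
    writeLines(sprintf("# %s=%s", names(meta), meta), con)
  utils::write.table(as.data.frame(track), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
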