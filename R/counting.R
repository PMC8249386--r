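#' Extract 20-nt spacers from amplicon reads
#'
#' Scans each read for the vector backbone layout `CACCG<spacer 20 nt>GTTT`
#' and returns the 20-mer between the first `CACCG` whose downstream window
#' completes the layout and the `GTTT` exactly 20 nt after it. Reads without
#' such an arrangement yield `NA` (a normal outcome, not an error).
#'
#' @param reads character vector of A/C/G/T/N read sequences.
#' @return character vector of spacers (`NA` where no backbone match).
#' @export
extract_spacer <- function(reads) {
  reads <- toupper(as.character(reads))
  m <- regexpr("CACCG[ACGTN]{20}GTTT", reads, perl = TRUE)
  out <- rep(NA_character_, length(reads))
  hit <- !is.na(m) & m > 0L
  out[hit] <- substr(reads[hit], m[hit] + 5L, m[hit] + 24L)
  out
}

#' Count guides in a FASTQ sample by exact spacer match
#'
#' Extracts spacers with [extract_spacer()] and counts reads whose spacer
#' perfectly matches a library spacer (exact dictionary lookup, no
#' mismatches). Reads with an extractable spacer absent from the library are
#' discarded and tallied separately.
#'
#' @param reads a FASTQ path (plain or gzip) or a character vector of read
#'   sequences.
#' @param lib a [guide_library()].
#' @param sample_id label for the sample.
#' @return Named integer vector of per-guide counts (all library guides,
#'   zeros included) with attributes `sample_id` and `stats` (a list with
#'   `reads_seen`, `with_backbone`, `matched`, `discarded`).
#' @export
count_guides <- function(reads, lib, sample_id = "sample") {
  stopifnot(inherits(lib, "guide_library"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    seqs <- tryCatch(
      as.character(Biostrings::readDNAStringSet(reads, format = "fastq")),
      error = function(e) character(0))
  } else {
    seqs <- as.character(reads)
  }
  n_guides <- nrow(lib$guides)
  counts <- integer(n_guides)
  names(counts) <- lib$guides$guide_id
  if (length(seqs) == 0L) {
    warning("no reads for sample '", sample_id, "': zero counts returned")
    sp <- character(0)
    idx <- integer(0)
  } else {
    sp <- extract_spacer(seqs)
    idx <- match(sp, lib$guides$spacer)
    counts <- counts + tabulate(idx, nbins = n_guides)
  }
  stats <- list(reads_seen = length(seqs),
                with_backbone = sum(!is.na(sp)),
                matched = sum(!is.na(idx)),
                discarded = sum(!is.na(sp)) - sum(!is.na(idx)))
  structure(counts, sample_id = sample_id, stats = stats)
}

#' Count several FASTQ samples into a guide x sample matrix
#'
#' @param files named character vector of FASTQ paths (names are sample
#'   ids).
#' @param lib a [guide_library()].
#' @param log_path optional path; per-sample read-accounting stats are
#'   written there as JSON.
#' @return Integer matrix guides x samples with a `stats` attribute (named
#'   list of per-sample accounting).
#' @export
count_screen <- function(files, lib, log_path = NULL) {
  stopifnot(length(files) > 0)
  if (is.null(names(files)) || any(names(files) == ""))
    stop("'files' must be a named vector (names = sample ids)")
  cols <- lapply(names(files), function(s) count_guides(files[[s]], lib, s))
  m <- do.call(cbind, lapply(cols, as.integer))
  dimnames(m) <- list(lib$guides$guide_id, names(files))
  stats <- lapply(cols, attr, "stats")
  names(stats) <- names(files)
  if (!is.null(log_path))
    jsonlite::write_json(stats, log_path, auto_unbox = TRUE, pretty = TRUE)
  structure(m, stats = stats)
}

#' Per-sample guide frequencies with low-representation filtering
#'
#' Frequencies are read counts divided by the per-sample total matched to
#' the library. Guides whose frequency in the reference (early) sample falls
#' below `min_frac_of_expected` times the expected uniform frequency
#' `1/n_guides` are excluded from downstream analysis in every sample, so
#' fold changes are never computed on unreliable baselines. Frequencies over
#' the retained guides are renormalized to sum to one per sample.
#'
#' @param counts integer matrix guides x samples (rownames are guide ids),
#'   or a single [count_guides()] column.
#' @param lib a [guide_library()].
#' @param min_frac_of_expected exclusion threshold as a fraction of the
#'   expected uniform frequency (default 0.05).
#' @param reference sample id used to decide exclusion (default: first
#'   column).
#' @return An object of class `frequency_table`: list with `freq`
#'   (renormalized frequencies over retained guides), `counts`, `totals`,
#'   `excluded` (guide ids), `reference` and `library_size`.
#' @export
to_frequencies <- function(counts, lib, min_frac_of_expected = 0.05,
                           reference = NULL) {
  stopifnot(inherits(lib, "guide_library"))
  if (is.null(dim(counts))) {
    sid <- attr(counts, "sample_id") %||% "sample"
    counts <- matrix(as.integer(counts), ncol = 1,
                     dimnames = list(names(counts), sid))
  }
  if (is.null(rownames(counts)))
    stop("'counts' must have guide ids as rownames")
  if (!identical(sort(rownames(counts)), sort(lib$guides$guide_id)))
    stop("count matrix rows do not match the library guide ids")
  counts <- counts[lib$guides$guide_id, , drop = FALSE]
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero matched reads: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  reference <- reference %||% colnames(counts)[1]
  if (!reference %in% colnames(counts))
    stop("reference sample '", reference, "' not in count matrix")
  raw <- sweep(counts, 2, totals, "/")
  expected <- 1 / nrow(counts)
  excluded <- rownames(counts)[raw[, reference] < min_frac_of_expected * expected]
  keep <- setdiff(rownames(counts), excluded)
  if (length(keep) < 2)
    stop("fewer than two guides survive the representation filter")
  freq <- raw[keep, , drop = FALSE]
  freq <- sweep(freq, 2, colSums(freq), "/")
  structure(list(freq = freq, counts = counts, totals = totals,
                 excluded = excluded, reference = reference,
                 library_size = nrow(counts)),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("frequency_table: %d guides x %d samples, %d excluded (<%s of expected in '%s')\n",
              x$library_size, ncol(x$freq), length(x$excluded), "threshold", x$reference))
  invisible(x)
}
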