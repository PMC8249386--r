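#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

GUIDE_CATEGORIES <- c("tiling", "neg_control", "pos_control")

#' Tiling sgRNA library
#'
#' Container for a CRISPR gene-tiling sgRNA library targeting a single
#' coding sequence (CDS): one row per guide with its 20-nt spacer, category
#' (`tiling`, `neg_control`, `pos_control`) and, for tiling guides, the
#' predicted Cas9 cut position within the CDS as a 1-based nucleotide index
#' on the coding strand (SpCas9 blunt cut, 3 nt 5' of the PAM).
#'
#' Coordinates are 1-based and spans inclusive throughout. By default
#' `cds_length_nt` counts the stop codon, i.e. equals
#' `3 * (protein_length_aa + 1)`; the stop-less convention
#' `3 * protein_length_aa` is also accepted and recorded implicitly by the
#' stored length.
#'
#' @param guides data.frame with columns `guide_id`, `spacer`, `category`,
#'   `cds_cut_nt` (NA for control guides) and optionally `strand`.
#' @param cds_length_nt CDS length in nucleotides.
#' @param protein_length_aa protein length in residues.
#' @return An object of class `guide_library`: a list with elements
#'   `guides` (validated data.frame, input row order preserved),
#'   `cds_length_nt` and `protein_length_aa`.
#' @examples
#' g <- data.frame(guide_id = c("g1", "g2", "n1"),
#'                 spacer = c(strrep("ACGT", 5), strrep("GGCA", 5), strrep("TTAC", 5)),
#'                 category = c("tiling", "tiling", "neg_control"),
#'                 cds_cut_nt = c(10, 40, NA))
#' lib <- guide_library(g, cds_length_nt = 60, protein_length_aa = 19)
#' @export
guide_library <- function(guides, cds_length_nt, protein_length_aa) {
  stopifnot(is.data.frame(guides))
  required <- c("guide_id", "spacer", "category")
  miss <- setdiff(required, names(guides))
  if (length(miss) > 0)
    stop("library table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"cds_cut_nt" %in% names(guides)) guides$cds_cut_nt <- NA_integer_
  if (!"strand" %in% names(guides)) guides$strand <- "+"
  guides <- guides[, c("guide_id", "spacer", "category", "cds_cut_nt", "strand")]
  guides$guide_id <- as.character(guides$guide_id)
  guides$spacer <- toupper(as.character(guides$spacer))
  guides$category <- as.character(guides$category)
  guides$cds_cut_nt <- suppressWarnings(as.integer(guides$cds_cut_nt))
  guides$strand <- as.character(guides$strand)
  rownames(guides) <- NULL

  dup <- unique(guides$guide_id[duplicated(guides$guide_id)])
  if (length(dup) > 0)
    stop("duplicate guide_id: ", paste(dup, collapse = ", "))
  bad_cat <- setdiff(unique(guides$category), GUIDE_CATEGORIES)
  if (length(bad_cat) > 0)
    stop("unknown guide category: ", paste(bad_cat, collapse = ", "))
  bad_sp <- which(nchar(guides$spacer) != 20L | grepl("[^ACGT]", guides$spacer))
  if (length(bad_sp) > 0)
    stop("row ", bad_sp[1], " (guide_id ", guides$guide_id[bad_sp[1]],
         "): spacer must be exactly 20 nt of A/C/G/T")
  bad_strand <- which(!guides$strand %in% c("+", "-"))
  if (length(bad_strand) > 0)
    stop("row ", bad_strand[1], ": strand must be '+' or '-'")

  cds_length_nt <- as.integer(cds_length_nt)
  protein_length_aa <- as.integer(protein_length_aa)
  if (length(cds_length_nt) != 1L || is.na(cds_length_nt) || cds_length_nt <= 0L)
    stop("cds_length_nt must be a positive integer")
  if (length(protein_length_aa) != 1L || is.na(protein_length_aa) || protein_length_aa <= 0L)
    stop("protein_length_aa must be a positive integer")
  if (!cds_length_nt %in% (3L * c(protein_length_aa, protein_length_aa + 1L)))
    stop("cds_length_nt must equal 3*protein_length_aa or 3*(protein_length_aa+1)")

  tiling <- guides$category == "tiling"
  no_cut <- tiling & is.na(guides$cds_cut_nt)
  if (any(no_cut))
    stop("tiling guide without cds_cut_nt: ",
         paste(guides$guide_id[no_cut], collapse = ", "))
  ctrl_cut <- !tiling & !is.na(guides$cds_cut_nt)
  if (any(ctrl_cut))
    stop("control guide must not carry cds_cut_nt: ",
         paste(guides$guide_id[ctrl_cut], collapse = ", "))
  oob <- tiling & (guides$cds_cut_nt < 1L | guides$cds_cut_nt > cds_length_nt)
  if (any(oob))
    stop("cds_cut_nt outside 1..cds_length_nt for guide: ",
         paste(guides$guide_id[oob], collapse = ", "))

  structure(list(guides = guides,
                 cds_length_nt = cds_length_nt,
                 protein_length_aa = protein_length_aa),
            class = "guide_library")
}

#' @export
print.guide_library <- function(x, ...) {
  tab <- table(factor(x$guides$category, levels = GUIDE_CATEGORIES))
  cat(sprintf("guide_library: %d guides (%d tiling, %d neg_control, %d pos_control)\n",
              nrow(x$guides), tab[["tiling"]], tab[["neg_control"]], tab[["pos_control"]]))
  cat(sprintf("  CDS %d nt, protein %d aa, tiling density %.1f bp/sgRNA\n",
              x$cds_length_nt, x$protein_length_aa, tiling_density(x)))
  invisible(x)
}

#' Read a tiling library from a tab-delimited file
#'
#' The file is tab-delimited with a header naming at least `guide_id`,
#' `spacer` and `category`; tiling rows must carry `cds_cut_nt`. Lines
#' starting with `#` are ignored, except that the CDS geometry may be stored
#' in comment lines of the form `# cds_length_nt=4614` and
#' `# protein_length_aa=1537` (as written by [write_library()]). Explicit
#' arguments override the comments.
#'
#' @param path path to the TSV file.
#' @param cds_length_nt,protein_length_aa CDS geometry; required unless
#'   present as header comments.
#' @return A [guide_library()].
#' @export
parse_library <- function(path, cds_length_nt = NULL, protein_length_aa = NULL) {
  lines <- readLines(path, warn = FALSE)
  comments <- grep("^#", lines, value = TRUE)
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), comments, value = TRUE)
    if (length(hit) == 0) return(NULL)
    as.integer(sub(".*=\\s*", "", hit[1]))
  }
  cds_length_nt <- cds_length_nt %||% grab("cds_length_nt")
  protein_length_aa <- protein_length_aa %||% grab("protein_length_aa")
  if (is.null(cds_length_nt) || is.null(protein_length_aa))
    stop("cds_length_nt and protein_length_aa must be given as arguments ",
         "or as '# key=value' header comments")
  guides <- utils::read.delim(text = lines, comment.char = "#",
                              stringsAsFactors = FALSE)
  guide_library(guides, cds_length_nt, protein_length_aa)
}

#' Write a tiling library to a tab-delimited file
#'
#' Writes the guide table with `# cds_length_nt=` / `# protein_length_aa=`
#' header comments so that [parse_library()] round-trips losslessly.
#'
#' @param lib a [guide_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "guide_library"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cds_length_nt=%d", lib$cds_length_nt),
               sprintf("# protein_length_aa=%d", lib$protein_length_aa)), con)
  utils::write.table(lib$guides, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Residue (codon) index of a guide's cut site
#'
#' Partitions the CDS into consecutive trinucleotide codons and returns the
#' 1-based residue index containing each tiling guide's cut nucleotide,
#' `ceiling(cds_cut_nt / 3)`; independent of strand.
#'
#' @param lib a [guide_library()].
#' @param guide_id optional character vector restricting (and ordering) the
#'   result; requesting a control guide is an error (it has no position on
#'   the target CDS).
#' @return Named integer vector of residue indices (names are guide ids).
#' @export
cut_codon <- function(lib, guide_id = NULL) {
  stopifnot(inherits(lib, "guide_library"))
  g <- lib$guides
  if (is.null(guide_id)) {
    g <- g[g$category == "tiling", , drop = FALSE]
  } else {
    i <- match(guide_id, g$guide_id)
    if (anyNA(i)) stop("unknown guide_id: ", paste(guide_id[is.na(i)], collapse = ", "))
    g <- g[i, , drop = FALSE]
    ctrl <- g$category != "tiling"
    if (any(ctrl))
      stop("no genomic target: ", paste(g$guide_id[ctrl], collapse = ", "),
           " is a control guide")
  }
  structure(as.integer(ceiling(g$cds_cut_nt / 3)), names = g$guide_id)
}

#' Inclusive residue span
#'
#' @param start_aa,end_aa 1-based inclusive residue indices,
#'   `1 <= start_aa <= end_aa`.
#' @return An object of class `residue_span`.
#' @export
residue_span <- function(start_aa, end_aa) {
  start_aa <- as.integer(start_aa); end_aa <- as.integer(end_aa)
  stopifnot(length(start_aa) == 1L, length(end_aa) == 1L,
            !is.na(start_aa), !is.na(end_aa))
  if (start_aa < 1L || start_aa > end_aa)
    stop("invalid span: need 1 <= start_aa <= end_aa")
  structure(list(start_aa = start_aa, end_aa = end_aa), class = "residue_span")
}

#' @export
print.residue_span <- function(x, ...) {
  cat(sprintf("residue_span %d-%d (%d aa)\n", x$start_aa, x$end_aa, span_length(x)))
  invisible(x)
}

#' Number of residues in a span
#'
#' @param span a [residue_span()].
#' @return `end_aa - start_aa + 1`.
#' @export
span_length <- function(span) {
  stopifnot(inherits(span, "residue_span"))
  span$end_aa - span$start_aa + 1L
}

#' Tiling guides cutting within a residue span
#'
#' @param lib a [guide_library()].
#' @param span a [residue_span()] within the protein.
#' @return data.frame of tiling guides whose cut codon lies in the span,
#'   ordered by `cds_cut_nt` ascending (possibly zero rows).
#' @export
guides_in_span <- function(lib, span) {
  stopifnot(inherits(lib, "guide_library"), inherits(span, "residue_span"))
  if (span$end_aa > lib$protein_length_aa)
    stop("span extends beyond protein length ", lib$protein_length_aa)
  g <- lib$guides[lib$guides$category == "tiling", , drop = FALSE]
  res <- ceiling(g$cds_cut_nt / 3)
  g <- g[res >= span$start_aa & res <= span$end_aa, , drop = FALSE]
  g <- g[order(g$cds_cut_nt), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Average tiling density in bp per sgRNA
#'
#' CDS length divided by the number of tiling guides.
#'
#' @param lib a [guide_library()].
#' @return bp per guide (double).
#' @export
tiling_density <- function(lib) {
  stopifnot(inherits(lib, "guide_library"))
  n <- sum(lib$guides$category == "tiling")
  if (n == 0) stop("library has no tiling guides")
  lib$cds_length_nt / n
}
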