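#' Global pairwise protein alignment as a residue mapping
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5) between two protein sequences; aligned non-gap column
#' pairs become (source residue, target residue) mapping pairs. The pairs
#' are colinear: strictly increasing in both coordinates.
#'
#' @param src_seq,tgt_seq protein sequences as character strings,
#'   `AAString`, or single-record `AAStringSet` (e.g. from
#'   `Biostrings::readAAStringSet`).
#' @return An object of class `residue_mapping`: list with `pairs`
#'   (data.frame `src`, `tgt`), `identity_fraction` (identical residues /
#'   aligned pairs), `score`, `src_length`, `tgt_length`.
#' @export
align_pair <- function(src_seq, tgt_seq) {
  as_aa <- function(s) {
    if (methods::is(s, "XStringSet")) s <- s[[1]]
    toupper(as.character(s))
  }
  src <- as_aa(src_seq); tgt <- as_aa(tgt_seq)
  if (nchar(src) == 0 || nchar(tgt) == 0) stop("empty sequence")
  blosum62 <- get_blosum62()
  aln <- Biostrings::pairwiseAlignment(src, tgt, type = "global",
                                       substitutionMatrix = blosum62,
                                       gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- cumsum(pa != "-")
  j <- cumsum(sa != "-")
  both <- pa != "-" & sa != "-"
  pairs <- data.frame(src = i[both], tgt = j[both])
  idf <- if (nrow(pairs) > 0) mean(pa[both] == sa[both]) else 0
  structure(list(pairs = pairs, identity_fraction = idf,
                 score = Biostrings::score(aln),
                 src_length = nchar(src), tgt_length = nchar(tgt)),
            class = "residue_mapping")
}

# BLOSUM62 from Biostrings' bundled data, loaded lazily.
get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("residue_mapping: %d aligned pairs (%d aa -> %d aa), identity %.1f%%\n",
              nrow(x$pairs), x$src_length, x$tgt_length,
              100 * x$identity_fraction))
  invisible(x)
}

#' Transfer a per-residue track across orthologs
#'
#' Each target residue receives the score of its mapped source residue;
#' unmapped target residues are missing (`NA`).
#'
#' @param track a [residue_track()] in source numbering.
#' @param map a [align_pair()] mapping.
#' @return A [residue_track()] of length `map$tgt_length`.
#' @export
transfer_track <- function(track, map) {
  stopifnot(inherits(track, "residue_track"), inherits(map, "residue_mapping"))
  if (nrow(track) < max(c(0L, map$pairs$src)))
    stop("track is shorter than the mapped source residues")
  out <- rep(NA_real_, map$tgt_length)
  out[map$pairs$tgt] <- track$score[map$pairs$src]
  residue_track(out, bandwidth_nt = attr(track, "bandwidth_nt"),
                source = attr(track, "source"))
}

#' Paint a residue track onto a PDB structure
#'
#' Writes (i) a residue-attribute file in the UCSF Chimera dialect
#' (`attribute:`, `match mode: 1-to-1`, `recipient: residues` header, then
#' one `TAB /<chain>:<resnum> TAB <value>` line per annotated residue) and
#' (ii) a copy of the PDB whose temperature-factor column (columns 61-66 of
#' ATOM/HETATM records) holds the track score linearly rescaled to
#' `[0, 100]`; residues without a score get 0.00. Structure residue numbers
#' are taken from the coordinate file as-is (author numbering). Insertion
#' codes are rejected.
#'
#' @param track a [residue_track()] indexed by the structure's author
#'   residue numbers.
#' @param pdb_path input PDB file.
#' @param chain chain identifier to annotate.
#' @param attribute_name name recorded in the attribute file.
#' @param attr_path,out_pdb_path output paths (defaults: alongside the
#'   input, suffixed `.defattr` / `_painted.pdb`).
#' @return An object of class `structure_attribution`: list with
#'   `assignments` (data.frame `chain`, `resno`, `score`, `bfactor`),
#'   `attribute_name`, `unannotated` (residue numbers in the chain lacking
#'   a score) and the two output paths.
#' @export
write_attributes <- function(track, pdb_path, chain, attribute_name = "score",
                             attr_path = NULL, out_pdb_path = NULL) {
  stopifnot(inherits(track, "residue_track"))
  pdb <- bio3d::read.pdb(pdb_path)
  chains <- sort(unique(pdb$atom$chain))
  if (!chain %in% chains)
    stop("chain '", chain, "' not in structure (available: ",
         paste(chains, collapse = ", "), ")")
  ins <- pdb$atom$insert
  if (any(!is.na(ins) & ins != ""))
    stop("PDB contains insertion codes; not supported")
  resno <- sort(unique(pdb$atom$resno[pdb$atom$chain == chain]))

  score <- stats::setNames(track$score, track$residue)
  annotated <- resno[resno %in% track$residue & is.finite(score[as.character(resno)])]
  unannotated <- setdiff(resno, annotated)
  s <- score[as.character(annotated)]
  if (length(s) > 0) {
    rng <- range(s)
    b <- if (diff(rng) == 0) rep(50, length(s)) else (s - rng[1]) / diff(rng) * 100
  } else {
    b <- numeric(0)
  }
  bmap <- stats::setNames(b, annotated)

  attr_path <- attr_path %||% paste0(sub("\\.pdb$", "", pdb_path), ".defattr")
  out_pdb_path <- out_pdb_path %||% paste0(sub("\\.pdb$", "", pdb_path), "_painted.pdb")

  con <- file(attr_path, "w")
  writeLines(c(paste0("attribute: ", attribute_name),
               "match mode: 1-to-1",
               "recipient: residues",
               sprintf("\t/%s:%d\t%.6g", chain, annotated, s)), con)
  close(con)

  lines <- readLines(pdb_path, warn = FALSE)
  rec <- substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")
  if (any(rec)) {
    ch <- substr(lines[rec], 22, 22)
    rn <- suppressWarnings(as.integer(substr(lines[rec], 23, 26)))
    newb <- rep(0, sum(rec))
    hit <- ch == chain & rn %in% annotated
    newb[hit] <- bmap[as.character(rn[hit])]
    body <- lines[rec]
    # pad short records so columns 61-66 exist
    body <- formatC(body, width = 66, flag = "-")
    substr(body, 61, 66) <- sprintf("%6.2f", newb)
    lines[rec] <- sub("\\s+$", "", body)
  }
  writeLines(lines, out_pdb_path)

  structure(list(assignments = data.frame(chain = chain, resno = annotated,
                                          score = as.numeric(s),
                                          bfactor = as.numeric(b)),
                 attribute_name = attribute_name,
                 unannotated = unannotated,
                 attr_path = attr_path, pdb_path = out_pdb_path),
            class = "structure_attribution")
}

#' Re-read a residue attribute file
#'
#' Parses the Chimera-dialect attribute format written by
#' [write_attributes()].
#'
#' @param path attribute file path.
#' @return list with `attribute_name` and `assignments` (data.frame
#'   `chain`, `resno`, `value`).
#' @export
read_attributes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name <- sub("^attribute:\\s*", "", grep("^attribute:", lines, value = TRUE)[1])
  rows <- grep("^\t", lines, value = TRUE)
  m <- regmatches(rows, regexec("^\t/([^:]+):(-?[0-9]+)\t(.+)$", rows))
  ok <- lengths(m) == 4
  list(attribute_name = name,
       assignments = data.frame(
         chain = vapply(m[ok], `[`, "", 2),
         resno = as.integer(vapply(m[ok], `[`, "", 3)),
         value = as.numeric(vapply(m[ok], `[`, "", 4)),
         stringsAsFactors = FALSE))
}
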