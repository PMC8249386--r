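# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# deterministic distinct 20-mers
toy_spacers <- function(n) {
  withr::with_seed(424242, {
    sp <- character(0)
    while (length(sp) < n)
      sp <- unique(c(sp, replicate(n + 4, paste(
        sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""))))
    sp[seq_len(n)]
  })
}

# uniform toy library: one guide per codon, cut at the codon's first
# nucleotide, plus optional controls
toy_library <- function(n_codons = 50, n_neg = 0, n_pos = 0,
                        include_stop = FALSE) {
  n <- n_codons + n_neg + n_pos
  spacers <- toy_spacers(n)
  guides <- data.frame(
    guide_id = c(sprintf("t%03d", seq_len(n_codons)),
                 if (n_neg > 0) sprintf("neg%02d", seq_len(n_neg)),
                 if (n_pos > 0) sprintf("pos%02d", seq_len(n_pos))),
    spacer = spacers,
    category = c(rep("tiling", n_codons), rep("neg_control", n_neg),
                 rep("pos_control", n_pos)),
    cds_cut_nt = c(3L * seq_len(n_codons) - 2L, rep(NA, n_neg + n_pos)),
    stringsAsFactors = FALSE)
  guide_library(guides, 3L * (n_codons + include_stop), n_codons)
}

# independent brute-force smoother: double loop over nucleotides and
# guides, then codon averaging (the oracle for kernel_smooth)
brute_force_smooth <- function(x, v, h, cds_len, n_res) {
  S <- numeric(cds_len)
  for (p in seq_len(cds_len)) {
    w <- exp(-(p - x)^2 / (2 * h^2))
    S[p] <- sum(w * v) / sum(w)
  }
  vapply(seq_len(n_res), function(r) mean(S[(3 * r - 2):(3 * r)]), numeric(1))
}

# small single-cell study conditions used where tests loop over seeds:
# fewer cells and filler genes than the full-size defaults, same rates
small_sc_cfg <- function(seed, sc = list(), ...) {
  sim_config(seed = seed,
             protein_length_aa = 400L,
             n_guides = 160L, n_neg = 15L, n_pos = 7L,
             essential_windows = list(
               list(start = 60, end = 160, fitness = -0.25, drug_fitness = 0),
               list(start = 220, end = 270, fitness = -0.15, drug_fitness = 0)),
             sc = utils::modifyList(list(n_cells = 1200L, n_filler = 300L), sc,
                                    keep.null = TRUE),
             ...)
}

# Jaccard index of two residue index sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
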