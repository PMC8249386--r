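---
title: "Methods: scoring and smoothing CRISPR gene-tiling screens"
author: "tilescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and smoothing CRISPR gene-tiling screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilescan)
```

# The problem

A gene-tiling CRISPR screen saturates the coding exons of a single gene
with sgRNAs — one guide every few base pairs — so that the phenotypic
consequence of damaging each small stretch of protein can be read out
position by position. Two readouts are supported:

* **survival screens**: guide frequencies in a pooled culture are compared
  between an early and a late time point by amplicon sequencing; guides
  hitting essential protein regions deplete;
* **single-cell screens**: each guide carries a capture sequence so a
  droplet platform reads the guide identity alongside the cell's
  transcriptome, and the transcriptional state of cells carrying each
  guide is summarized per targeted position.

Both readouts end in the same object: a smoothed per-residue track along
the protein, which can be compared between conditions, correlated across
positions, or painted onto a 3-D structure.

# Survival screen model

## Counting

Amplicon reads are scanned for the vector backbone layout
`CACCG<spacer, 20 nt>GTTT`; the first position at which the complete
layout matches yields the spacer. Spacers are matched against the library
by exact dictionary lookup — no mismatch tolerance — which reproduces a
perfect-match alignment policy without an external aligner. Reads whose
spacer is absent from the library are tallied and discarded.

## Frequencies and exclusion

Per sample, a guide's frequency is its count divided by the total counts
matched to the library. Guides whose frequency in the *reference* (early)
sample falls below 5% of the expected uniform frequency `1/n_guides` are
excluded from every sample: a guide that failed to establish itself at
baseline cannot support a fold change. The expected frequency is taken as
uniform because no plasmid-pool reference is assumed; a reference column
can be designated instead.

## CRISPR score and control anchoring

The CRISPR score is the log10 fold change of a guide's frequency between
early and late samples, stabilized by a pseudocount (default 0.5, applied
to counts and, scaled by library size, to totals):

$$CS(g) = \log_{10}\frac{(c_{late}+pc)/(T_{late}+pc\,N)}
                        {(c_{early}+pc)/(T_{early}+pc\,N)}$$

Replicates are averaged on the CS scale. To compare arms run under
different conditions, scores are anchored to the spiked-in controls:

$$NCS(g) = \frac{CS(g) - \mathrm{med}_{neg}}
                {\mathrm{med}_{neg} - \mathrm{med}_{pos}}$$

so the median over negative controls (non-targeting: fluorophores,
luciferases, safe harbor) is exactly 0.00 and over positive controls
(guides against an essential replication gene) exactly −1.00. The map is
affine; with positive controls scoring below negative controls (the
operating condition of any functioning screen) guide rank order is
preserved. Each condition arm is normalized against its own controls by
default; a shared normalization can be arranged by passing a combined
count matrix.

## Gene-body smoothing

Individual guides are noisy (variable cutting efficiency, in-frame
repair, off-target effects), so the per-position signal is the
kernel-weighted average of nearby guides. At every CDS nucleotide $p$:

$$S(p) = \frac{\sum_g w_g\,v_g}{\sum_g w_g},\qquad
  w_g = \exp\!\left(-\frac{(p-x_g)^2}{2h^2}\right)$$

with $x_g$ the guide's cut nucleotide (SpCas9 blunt cut, 3 nt 5′ of the
PAM, on the coding strand). The bandwidth $h$ defaults to the **maximum
gap** between consecutive distinct cut positions, so that even the most
sparsely covered region is reached by the kernel; Gaussian tails are kept
(no truncation). The per-residue value is the mean of $S$ over the
residue's three codon nucleotides. Smoothing weights are convex, so the
smoothed track is bounded by the input score range and commutes with
affine transformations of the scores.

Numerical notes: medians over an even number of controls are the mean of
the two central values; if the kernel underflows everywhere at some
position (impossible at the default bandwidth) the bandwidth is doubled
with a warning; guides excluded upstream are simply absent, enlarging the
effective gaps rather than contributing zeros.

# Single-cell stage

## Guide assignment and QC

A guide is *detected* in a cell when its capture UMI count reaches
`min_umi = 3`; requiring more than one molecule guards against ambient
guide RNA. Cells pass QC when they detect between 200 and 4500 genes,
carry at most 10% mitochondrial reads, and detect exactly one guide
(doublets and multiply infected cells are excluded). Failure labels are
assigned with gene-count checks first, then mitochondrial fraction, then
guide multiplicity.

## Pseudotime

Counts are depth-normalized to 10,000 per cell and log(1+x) transformed.
Pseudotime is deliberately simple and seedless: the first principal
component of the centered signature-gene submatrix (the 100 genes most
affected by pharmacological inhibition of the target, supplied as a gene
list), min–max scaled to [0, 1] and oriented so that it correlates
positively with myeloid differentiation markers (and hence negatively
with leukemia markers). A graph-based trajectory tool can be substituted
by passing an externally computed per-cell pseudotime; the downstream
summarization is unchanged. Per-guide medians are reported for guides
with at least `min_cells = 3` assigned cells — with ~7 cells per guide,
smaller guides must be droppable without failure.

## Position-level transcriptomics

For each signature gene, per-guide mean log-normalized expression is
smoothed along the gene body exactly as the survival scores are, giving a
residues × genes profile matrix. From it:

* **position correlation**: Pearson correlation between residue rows —
  positions whose perturbation produces similar transcriptomes correlate,
  revealing functionally coupled regions;
* **residue PC1**: the first principal component of the gene-centered
  profiles, a one-dimensional transcriptomic coordinate per residue,
  sign-oriented against the pseudotime track;
* **group differential expression**: cells whose guide cuts inside a
  region versus negative-control cells, per gene: mean log-normalized
  difference, Wilcoxon rank-sum p-value and Benjamini–Hochberg FDR
  (distribution-free, the standard choice for single-cell two-group
  comparisons).

Correlation is computed at residue level (after smoothing) by default —
the natural coordinate for a protein-position map; per-guide profiles are
accessible before smoothing for users who prefer the unsmoothed variant.

# Structure annotation

Tracks computed on one ortholog are transferred to another by global
pairwise alignment (Needleman–Wunsch, BLOSUM62, gap opening 10, gap
extension 0.5 — fixed, reproducible parameters); aligned non-gap columns
define a colinear residue mapping. Annotated structures are written two
ways: a residue-attribute text file (for "render by attribute"-style
coloring) and a copy of the PDB with the temperature-factor column
replaced by the track rescaled to [0, 100] (0.00 for residues without a
score; a constant track maps to 50). Only columns 61–66 of ATOM/HETATM
records are touched, and author residue numbering is used as-is.
Insertion codes are rejected rather than silently misassigned.

# Growth-competition arithmetic

Relative proliferation is the odds ratio of the FP⁺ fraction between time
t and the day-3 baseline; live-cell counts cancel algebraically and the
implementation verifies the printed four-factor form against the reduced
odds form to 1e−12. The resistance index divides a construct's RP under
drug by the control construct's at the same dose (×100%), by default at
day 9, with replicates averaged before the ratio.

# What the generators emulate

Every stage is testable against seeded synthetic data with a ground-truth
ledger. Defaults describe the full-size study conditions: a 1537-aa
target tiled by 602 guides (7.7 bp/guide, stop codon counted), 25
negative and 11 positive controls (odd counts keep control medians on
actual guides), screens at 1000× coverage over days 0–12, essential
windows at the catalytic core (127–332), a drug-sensitizing element
(460–555), a drug-resistance element (558–662, positive fitness only
under drug) and a cofactor-binding motif (863–900), each with per-day
log2 frequency effects; and a single-cell dataset of 4943 cells with an
8% multiplet rate, ~2% capture failures, planted QC failures, and a
latent differentiation state d ~ Beta(2, 6) shifted high for cells whose
guide hits a loss-of-function window (fitness < 0). Markers respond
monotonically to d (leukemia markers down, differentiation markers up),
half the signature genes rise and half fall, and counts are negative
binomial (dispersion 0.1) for realistic overdispersion.

Planted QC failures are constructed with wide margins (low-complexity
cells keep exactly 120 genes; contaminated cells draw 18–30% mitochondrial
fraction against a ≤7% baseline) so that the expected QC label is exact
and filter decisions can be compared label-for-label. Planted
differential-expression genes are simulated at modest abundance
(`de_base = 0.1`) so that a +1 log shift on 30 genes leaves the per-cell
depth normalization essentially unperturbed; with highly expressed
planted genes the compositional shift would bias every unshifted gene
downward under depth normalization — a genuine limitation of
normalization-based differential expression worth remembering with real
data too.

The generators do **not** emulate: droplet barcode chemistry or UMI
collision, sequencing error beyond off-library decoy reads, guide
position-dependent cutting efficiency, in-frame repair outcomes,
off-target cutting, cell-cycle structure, or batch effects. Passing
recovery tests therefore demonstrates the correctness and calibration of
the computations, not robustness to every artifact of real droplet data.

# Problem sizes and test design

Unit and property tests run on toy libraries (50–150 codons) where
brute-force oracles (double-loop Nadaraya–Watson, codon-table lookup,
exhaustive max-gap scan) are exact; recovery suites use a 400-aa / 160-
guide / 1200-cell configuration across 20–50 seeds, and single full-size
(1537 aa / 602 guides / 4943 cells) runs verify the headline quantities.
These sizes were chosen so the whole suite runs in well under a minute
per module while keeping ≥ 6 guides in every planted window, the regime
in which window recovery is expected to work.

# Known limitations

* The pseudotime is a linear one-component summary; branching or cyclic
  trajectories would need an external tool (whose output can be passed
  in).
* Depth normalization couples planted (or real) expression shifts across
  genes; effect sizes near the compositional footprint should be
  interpreted cautiously.
* Exact-match counting discards reads with sequencing errors inside the
  spacer; at typical amplicon error rates this loses a few percent of
  reads uniformly and does not bias fold changes.
* NCS anchoring assumes functioning controls; degenerate control medians
  are a hard error rather than a silent fallback.
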