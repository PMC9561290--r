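---
title: "utrtile: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{utrtile: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrtile)
```

## The problem and the assay

Many neuronal transcripts are transported into neurites by *cis*-acting
RNA elements ("zipcodes"), usually in the 3' UTR. A dense-tiling MPRA
locates such elements by cloning thousands of overlapping UTR fragments
into a reporter transcript, expressing the library in neuronal cells,
mechanically fractionating the cells into soma and neurite compartments,
and sequencing the reporter inserts from both. Fragments that carry a
localization element become neurite-enriched; because neighboring
fragments overlap almost entirely, enrichment varies smoothly along the
UTR and active regions appear as contiguous runs of enriched fragments.

`utrtile` implements the complete computational side of this design:
pool design, quantification, enrichment statistics, window calling, and
sequence characterization — plus a synthetic-data module so every stage
can be exercised and validated without any real sequencing data.

## Pool design

For each gene, the 3' UTR intervals of all isoforms with well-defined 3'
ends (no `cds_end_NF`/`mRNA_end_NF` annotation tags) are merged into a
single **meta-UTR** spanning their genomic union. Genes are excluded when
the meta-UTR exceeds 10 kb or when the polyA site is not within 200 nt of
a supplied list of conserved polyA sites (the liftOver that produces this
list is an external step; the designer consumes its output as a BED).
Every exclusion is recorded in a per-run audit table — genes are never
silently dropped.

Tiling uses 260-nt oligos at a 4-nt step over the sequence
`flank + UTR + flank` with 260-nt genomic flanks, so the UTR ends are
covered at full depth. Coordinates are 0-based and end-exclusive; oligo
offsets are reported relative to UTR position 0 (negative offsets lie in
the upstream flank). With these defaults every interior UTR nucleotide is
contained in exactly `260 / 4 = 65` oligos, an identity the test suite
asserts by brute-force membership counting. When the design length minus
the oligo length is not a step multiple, a final oligo is anchored flush
with the 3' end; it may sit closer than one step to its neighbor, and all
downstream code accepts that geometry.

## Synthetic data: the stated world

The generator produces the inputs the downstream stages assume, with full
truth records:

* **UTRs** — lengths uniform in 500–5000 nt; background composition
  uniform (50% A+G). Planted localization elements are rewritten base by
  base to a target A+G fraction of 0.8, reflecting the A/G-rich character
  of the elements this assay class recovers. Sequence is random rather
  than drawn from a real chromosome so no genome download is ever
  required; any template FASTA can be substituted where realism matters.
* **Counts** — baseline oligo abundances are log-normal (sdlog 0.5,
  the paper-scale "most oligos roughly equally abundant" regime; the
  abundance law is configurable because the original simulation states
  only "random abundance"). An oligo receives an element's `log2_effect`
  in neurite samples when it overlaps at least half of the element.
  Counts are negative binomial with dispersion 0.05 (typical for targeted
  amplicon replicates; dispersion 0 gives Poisson), library sizes uniform
  in a configurable range, four replicates per compartment by default.
* **Reads** — the source oligo of each pair is drawn by abundance. The
  forward read is the first 97 nt of the insert; the reverse read is the
  reverse complement of the last 91 nt prefixed by a random 8-nt UMI
  (mimicking post-trimming reads of the targeted sequencing protocol).
  Per-base deletions (rate 1e-4) are applied first, with the read
  extended from the template so it always has full declared length, then
  per-base substitutions (rate 0.002, uniform among the other three
  bases). The order deletions-then-mutations is fixed for
  reproducibility; the protocol description does not state one. All
  randomness flows from a single seed through a documented LCG splitter
  (`derive_seed()`), and UMIs are uniform random — collisions are
  modeled, not avoided, as in the real protocol.

What the generator does **not** emulate: position-dependent sequencer
quality, PCR jackpotting beyond UMI reuse, chimeras, synthesis indel
hotspots, and fragment-level GC bias. A green recovery test therefore
establishes that the statistics are implemented correctly and calibrated
under NB noise — not that they are robust to every artifact of real
libraries.

## Quantification

Adapter trimming removes the expected 5' adapters (up to 10% mismatches)
and drops/counts pairs without them. The UMI is the first 8 nt of the
reverse read after adapter removal, matching the protocol in which the
RT primer places the UMI immediately downstream of the adapter.

Read assignment exploits the end-anchored geometry: the forward read
aligns to an oligo's 5' end and the reverse read to its 3' end, so even
2-nt-step neighbors are distinguishable by the pair. The builtin assigner
nominates candidates by exact 16-mers at fixed template offsets and
scores them with a banded (half-width 4), start-anchored edit distance on
both mates; the best-scoring oligo wins and score ties are left
unassigned (conservative; tie handling is not specified by the original
pipeline). The `effort` setting mirrors the seed-extension effort knob of
end-to-end aligners: `"default"` probes one seed per mate, `"high"`
probes every non-overlapping seed and rescans the whole pool when seeding
fails. High effort is what achieves 100% correct assignment on 2-nt-step
libraries in the acceptance run; default effort loses the ~0.1% of pairs
whose two probed seeds both carry errors, reproducing the qualitative
default < high ordering. SAM remains the interchange format
(`read_sam_assignments()`), so any external end-to-end aligner run with
proper-paired, no-discordant settings can be swapped in.

UMI deduplication is exact-match counting of distinct 8-mers per oligo
per sample — deliberately no Hamming-1 clustering, for fidelity to the
described counting script; clustering belongs to a different error model
and is out of scope. Uniqueness is evaluated per oligo (not per mapping
position), as the counting script describes.

## Enrichment statistics

Normalization is median-of-ratios (size factor = median across all-nonzero
oligos of count / row geometric mean), falling back to total-count scaling
with a warning when no all-nonzero row exists.

The differential test is a documented negative-binomial Wald test rather
than a call into an external DE engine: per-oligo method-of-moments
dispersions are shrunk (6 prior degrees of freedom, log-space) toward a
parametric trend `alpha(mu) = a0 + a1/mu`, group means come from
normalized counts, and the variance of the log ratio follows the NB delta
method `Var(log mu_hat) = (1/n^2) sum_j 1/(s_j mu) + alpha/n`. Oligos
with fewer than 20 pooled raw counts in either compartment are not tested
(`fdr = NA`); the 20-count floor is applied to pooled per-compartment
counts (a per-replicate reading is stricter and can be emulated by
raising `min_count`). P-values are BH-adjusted over tested rows;
`log2fc > 0` means neurite-enriched. The acceptance surface of this test
is simulation-based — type-I error and effect recovery — not numerical
identity with any particular DE package, and `read_de_table()` accepts
any externally produced table. A 0.5 pseudocount appears only in the
descriptive fold change of rows with a zero group mean, never in the
test.

Cross-dataset gene selection Z-normalizes enrichment within each dataset
using the population (n-denominator) standard deviation — chosen so that
a three-value dataset {2, 0, -2} maps to {1.22, 0, -1.22} — then ranks
genes by NA-aware median Z across datasets, classifying genes with median
Z >= 2 (inclusive) as localized. `qpcr_fold_enrichment()` is the small
delta-delta-Ct utility for reporter validation:
`fold = 2^-[(Ct_rep - Ct_ctrl)_neurite - (Ct_rep - Ct_ctrl)_soma]`.

## Window calling

Significant oligos (`fdr < 0.01` and positive fold change by default; the
figure-level 0.05 is a flag, and `direction = "soma"` reuses the
machinery) are segmented by the x/y/x+2y rule: traverse 5'→3', open a
window at the first enriched oligo, extend while enriched; at the first
non-enriched oligo set `x`, let `y` be the distance to the next enriched
oligo; if all oligos in `[x+y, x+2y)` are enriched, extend the window
through `x+2y-1` and continue (the rule then re-applies iteratively with
a fresh `x`/`y` — "the process was continued" is read as iteration);
otherwise close the window at its last enriched member. Three choices the
rule's prose leaves open are fixed and documented here: `x` and `y` are
measured in oligo-index units (equivalent to nucleotides under uniform
steps, and unambiguous at the anchored final oligo); a bridge that would
run past the end of the tiling is not attempted; and gap oligos inside a
successful bridge are retained as window members.

The implementation is verified against an independent run-length
formulation of the same rule (a gap bridges exactly when the following
enriched run is at least as long) on 10,000 random significance vectors.

Each window reports its **union** interval `[first_offset, last_offset +
260)`, its **intersection** `[last_offset, first_offset + 260)` (the
sequence common to all members; empty when member starts span more than
one oligo length — the identity `length = 260 - (last_offset -
first_offset)` is asserted on every called window), and its **peak
oligo**: the significant member with maximal log2 fold change, ties
broken by proximity to the union midpoint, then 5'-most.

Positional QC follows the same logic as the assay's internal controls:
`neighbor_similarity_test()` compares adjacent-oligo enrichment
differences against within-gene position shuffles (Wilcoxon rank-sum),
and `smooth_profile()` provides the 8-oligo sliding mean/sd used for
profile plots (even `k` uses the window `i-3 ... i+4`, shrunk at edges).

## Sequence features

Composition and A/G statistics treat U as T and exclude ambiguous bases
from denominators. `max_ag_window()` scans all 100-nt windows at step 1
by sliding sum (ties to the 5'-most start; shorter sequences are scored
whole and flagged) and is checked against an O(n·w) brute force. The
0.75 A/G threshold is inclusive. Kmer enrichment (default k = 6, not
stated by the source analysis and therefore configurable) uses
pseudocounted log2 frequency ratios — antisymmetric under fg/bg swap —
with two-sided binomial tests BH-corrected across all 4^k kmers, counted
on the RNA sense strand only. Structure metrics fold 80-nt windows slid
5 nt with an external `RNAfold` when requested (median window MFE
summarizes the oligo; the backend's quadruplex mode sets the flag);
without the backend the energies are `NA` and the quadruplex flag falls
back to a regex (four runs of >= 3 G with 1–7-nt loops). A missing
backend under `backend = "external"` is an error, never a silent
fallback.

## Numerical and engineering choices

* Seeds: every stochastic function takes a `seed`; sub-streams derive
  via a minimal-standard LCG and stay below 2^31.
* The banded edit distance caps at `max_dist` (20) per mate with early
  abandonment; reads beyond the cap are unassigned rather than
  force-assigned.
* PCR handle sequences default to 20-nt placeholders — the real handles
  are a synthesis-order property, not part of the analysis.
* Control oligos in "whole" placement mode pad with random sequence
  seeded from the control's name, so pools are reproducible byte for
  byte.
* The `~8100-member` scale of the original pool may or may not count
  controls; the manifest keeps controls in a `ctrl:` namespace so either
  accounting is recoverable.

## Known limitations

* The NB Wald test is calibrated for >= 2 replicates per compartment and
  moderate dispersion; single-replicate designs are rejected rather than
  given fragile p-values.
* The builtin assigner assumes end-anchored reads (post-trim MPRA
  geometry); it is not a general-purpose aligner.
* Conservation scoring (phastCons) and polyA-site liftOver are consumed
  as precomputed inputs, never computed.
* G-quadruplex regex matching is a coarse stand-in for thermodynamic
  prediction and is only used when no folding backend is available.
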