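---
title: "Site-wise conservation and selection profiling of protein-coding barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-wise conservation and selection profiling of protein-coding barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiscan)
```

## Scope and model

`coiscan` treats an aligned protein-coding marker — canonically the
658-bp COI barcode, which translates to 219 amino acid columns in
frame — as a column-wise sample of evolutionary outcomes. Each amino
acid column is summarised by its residue frequency vector and Shannon
entropy in nats, H = −Σ pᵢ ln pᵢ, and classified with this precedence:

1. **conserved** — exactly one residue state observed;
2. **non-variable within group** — several residues, all inside one of
   the five biochemical groups (nonpolar aliphatic G,A,V,L,M,I; polar
   uncharged S,T,C,P,N,Q; aromatic F,Y,W; positively charged K,R,H;
   negatively charged D,E). The group override applies at *any*
   entropy, because chemically conservative variation is treated as
   functionally silent;
3. **non-variable** — entropy below 0.5 nats;
4. **variable** — binned into (0.5,0.7], (0.7,0.9], (0.9,1.1] and
   >1.1.

The bin edges are implemented as half-open-left intervals. Printed
descriptions of such bins ("0.5–0.7, 0.71–0.9, …") are ambiguous about
boundary membership; half-open intervals make the partition exact and
total. Entropy uses the natural logarithm, the convention of the
alignment editors this profiling mirrors; the base is a parameter.

Gaps (`-`) and unknowns (`X`) are excluded from frequencies, entropies
and consensus calculations by default, so a column that is gapped in a
few lineages but otherwise invariant still counts as conserved —
deletions are analysed as their own signal, not as a 21st residue
state. A `gap_policy = "as_state"` option exists for sensitivity
analysis.

**Consensus conservation** relaxes strict conservation to "modal
residue frequency ≥ t" (default t = 0.995). This matters for unequal
sampling depths: with ten times more sequences in one taxon, a single
deviant sequence destroys strict conservation, while the 99.5%
criterion is nearly depth-invariant.

**Deletions** are maximal internal runs of gap columns per translated
sequence. Terminal gap runs are treated as missing data (partial
sequences) rather than deletions, because the analysis targets
full-length barcodes in which internal gaps are the biological signal;
`terminal_policy = "count"` reverses this.

## Structure context

Columns are mapped to residues of a reference crystal structure by a
constant offset (column c ↔ residue c + offset), with distances
computed as minimum heavy-atom Euclidean distances to any ligand atom
(heme groups, Cu, Zn, Mg by default). A site is *proximal* when its
distance is strictly below 5 Å — atomic interaction distance. Two
choices deserve comment:

* **Heavy-atom minimum over backbone and side chain.** The alternative
  (side-chain only, or Cβ) undercounts glycine and proline contacts;
  the minimum over all heavy atoms is the most conservative notion of
  "can physically interact".
* **Distances on the experimental reference structure**, not per-taxon
  homology models. Building and scoring homology models is outside the
  package's scope; proximity flags are therefore statements about the
  reference frame of the bovine enzyme, and sites whose proximal
  status depends on lineage-specific conformational change will not be
  captured.

The shipped default segment table divides the 219 barcode columns into
six transmembrane helices (159 columns) and five connecting loops (60
columns, with Loop 4–5 spanning 10 residues); the first helix enters
the region already truncated and the last is cut short, because the
primer sites sit inside helices. Published boundaries exist only as a
drawing, so the defaults were constructed once to satisfy every stated
numeric constraint and are deliberately user-editable (`coi_segments()`
returns an ordinary tibble; any non-overlapping interval table works).
The default column→residue offset of +17 for the bovine reference
chain follows from the truncation statements: if the first helix lacks
its first six residues and spans residues 12–40 of the chain, column 1
sits at residue 18.

## Statistical machinery

**G-test of independence with Williams correction.** The
log-likelihood-ratio statistic G = 2 Σ O ln(O/E) is divided by
q = 1 + (N Σ 1/Rᵢ − 1)(N Σ 1/Cⱼ − 1) / (6 N (r−1)(c−1)) before the
chi-square tail is taken. The correction is the package default
because the corrected statistic — not the raw one — reproduces
published G values computed from the same count layouts to printed
precision (the raw statistic differs in the third significant digit).
Zero margins raise an error suggesting category collapse rather than
silently dropping rows.

**Wilcoxon rank-sum.** Midranks for ties; the reported W is defined as
the Mann–Whitney U of the *first* sample (so W_x + W_y = n_x·n_y). The
default p-value is the normal approximation with tie and continuity
corrections, appropriate at the ~219-codon sample sizes the package
compares; an exact distribution is used automatically for two untied
samples of ≤ 10.

**dN/dS.** The package uses Nei–Gojobori (1986) counting: per-codon
synonymous/nonsynonymous site fractions (changes to stop codons count
as nonsynonymous, so sites sum to 3 per codon), observed differences
averaged over all minimal substitution paths with stop-traversing
paths excluded (falling back to the unrestricted average when every
path is blocked), and Jukes–Cantor correction d = −(3/4) ln(1 − 4p/3),
undefined at p ≥ 3/4. Counts are accumulated per codon column over
sequence pairs, capped at 500 randomly sampled pairs per alignment
(seed-controlled) to keep large datasets tractable. A counting
estimator was chosen over ML codon models deliberately: the
inferential claim it supports — strong purifying selection, site
medians far below 1 — is robust to the estimator, and counting is
transparent enough to verify against path enumeration in the test
suite. Absolute site estimates are *not* comparable to ML codon-model
output, and single-codon comparisons can leave dS undefined (a lone
synonymous difference gives pS > 3/4 by construction).

**Substitution matrix.** Directional mutation-spectrum summaries need
polarity, which pairwise data do not provide. The package polarises
each column against its majority base as the simplest defensible
ancestral proxy: every minority base contributes one majority→minority
event, tied columns are skipped, and the 4×4 count matrix is rescaled
so its off-diagonal sum is exactly 100. This is an empirical count
matrix, not a rate-matrix ML estimate; it is directional (needed for
the C→T vs T→C asymmetry question) at the price of mis-polarising
columns where the ancestral base is in the minority.

## The synthetic-data generator

The simulator exists so that every pipeline stage can be tested
against known truth. It emulates the statistical structure of real
mitochondrial barcode datasets:

* AT-biased equilibrium composition (default A 0.30, C 0.22, G 0.16,
  T 0.32 — 62% AT, matching the >60% AT typical of animal mtDNA);
* transition excess (κ = 4) plus a further ×2 multiplier (α) on the
  two oxidative-damage transitions C→T and G→A;
* codon sites assigned to three constraint classes (defaults: 30%
  invariant, 30% group-constrained, 40% free), implemented by
  rejection sampling: proposals that create stops are always rejected,
  invariant sites reject everything, group-constrained sites reject
  amino acid changes leaving the root residue's biochemical group, and
  free sites accept nonsynonymous changes with probability
  `accept_nonsyn` (default 0.1, i.e. strong purifying selection);
* trees are Yule (pure-birth) with the tip count requested; a
  parasite clade of approximately the requested size can be labelled,
  and deletion events (geometric residue lengths, positions biased
  towards loop columns, applied as frame-preserving 3k-nucleotide gap
  runs) are drawn only on parasite terminal branches.

Rejection sampling was chosen over explicit codon rate matrices
because it gives direct, auditable control over exactly the site
classes the classifier must recover, and the acceptance filter *is*
the selective constraint, making the event log interpretable. Every
accepted substitution and every deletion is logged, and replaying the
log from the root must reproduce each leaf exactly — this
event-sourcing identity is asserted in the tests.

What the generator does **not** emulate: alignment error (sequences
are simulated aligned), frameshift indels, heterogeneous rates among
lineages, coalescent/demographic structure, sequencing error beyond
what the quality filter would remove, and the real taxon-sampling
imbalance of public barcode repositories. Recovery results on
synthetic data therefore demonstrate correctness of the machinery
under the stated generative assumptions, not robustness to misaligned
or contaminated real data.

## Numerical and degenerate-input choices

* Ambiguity fractions for the quality filter are computed over non-gap
  positions with a strict `<` comparison (1% means 6 N's pass and 7
  fail on a 658-nt record); "full length" means exact ungapped length
  match when a length is configured.
* Frame auto-detection minimises internal stop codons summed over
  records, breaking ties toward the lowest offset; translation fails
  only when more than half the records have no stop-free frame.
* All-gap columns yield NA entropy/class with a warning instead of an
  error, so a single fully deleted region does not abort a profile.
* Haplotype collapsing keeps the first-seen record as representative,
  making output order-stable and reruns byte-identical.
* All randomness (tree, root sequence, proposals, pair subsampling,
  deletion placement) flows through explicit integer seeds; the
  deletion stage derives its stream from `seed + 1` so that toggling
  deletions does not perturb the substitution history.

## Problem sizes

The test suite exercises the recovery properties at the sizes the
package treats as its reference conditions: 50 taxa × 200 codons for
the purifying-vs-neutral dN/dS separation (10 seeds per regime, pair
cap 500), 90 taxa (30 parasitic) × 150 codons × 50 replicates for the
parasite–deletion association recovery, and 20 taxa × 200 codons for
substitution-matrix checks. Oracle-equivalence tests run a few hundred
random small instances per statistic against independent brute-force
implementations.

## Known limitations

* Proximity flags refer to the reference structure only (see above).
* Majority-base polarity mis-assigns direction at columns where the
  ancestral state is in the minority; the substitution matrix is a
  descriptive spectrum, not an evolutionary rate estimate.
* NG86 ignores transition/transversion bias in its site counting, so
  under a κ > 1 mutation process neutral sequence yields site dN/dS
  somewhat below 1; regime comparisons remain valid because the bias
  is shared, but absolute medians should be read with this in mind.
* The G-test does not correct for phylogenetic non-independence;
  lineage-correlated traits (parasitism, deletions) inflate type I
  error, and results should be read as descriptive association, not
  as a phylogenetically controlled test.
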