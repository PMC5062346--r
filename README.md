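# coiscan

Site-wise conservation, structure context and selection profiling of
protein-coding DNA barcodes.

## The problem

The 658-bp COI barcode is sequenced millions of times over for species
identification, but it also encodes the enzymatically active core of
cytochrome c oxidase (COX). That makes the barcode a window onto
functional constraint: some amino acid columns never vary across the
animal kingdom, others vary only within one biochemical group, and a few
variable or deleted sites sit within atomic interaction distance (< 5 Å)
of the heme, Cu, Zn and Mg ligands where changes can plausibly affect
electron transfer. `coiscan` is for molecular ecologists and
evolutionary biologists who want to turn an aligned barcode dataset into
that kind of per-site functional readout, with the statistics to back
the patterns.

## What it computes

For an aligned, translated marker the package profiles every amino acid
column by Shannon entropy

H(x) = −Σᵢ pᵢ ln pᵢ,

classifying each site as *conserved* (one residue state), *non-variable
within a biochemical group* (all residues in one of the five standard
groups — nonpolar aliphatic, polar uncharged, aromatic, positively or
negatively charged — regardless of entropy), *non-variable* (H < 0.5
nats) or *variable*, binned by entropy. Sites are annotated with
transmembrane helix/loop segments and, given a reference PDB structure,
with minimum heavy-atom ligand distances. Internal deletions are
detected as maximal gap runs per sequence.

Inference uses the Williams-corrected G-test of independence
(G = G_raw/q with q = 1 + (N ΣRᵢ⁻¹ − 1)(N ΣCⱼ⁻¹ − 1)/(6N·df)) for
loop/helix enrichment and parasite–deletion association, a
tie-corrected Wilcoxon rank-sum test for comparing selection between
taxa, Nei–Gojobori (1986) counting estimates of codon-wise dN/dS with
Jukes–Cantor correction, and an empirical directional substitution
matrix normalised so its twelve off-diagonal rates sum to 100. A seeded
codon-alignment simulator with per-site selective constraints provides
ground truth for every stage.

## Worked example

Simulate a barcode-like dataset with a parasite clade carrying extra
deletions, profile it, and test the associations:

```r
library(coiscan)

cfg <- run_config(out_dir = "demo", seed = 101,
                  sim = sim_params(n_taxa = 30, n_codons = 120,
                                   n_parasite = 8, deletion_rate = 0.8,
                                   seed = 101))
bundle <- run_simulate(cfg)
cfg$fasta    <- bundle$paths[["fasta"]]
cfg$metadata <- bundle$paths[["metadata"]]
cfg$frame    <- 0L

res <- run_profile(cfg)
#> Filter funnel: input=30 -> quality_filtered=30 -> haplotypes=27
glance(res$profile)
#> # A tibble: 1 × 7
#>   n_sites n_conserved n_nonvariable n_within_group n_variable ...
#> 1     120          86             9             23          2
```

Of the 120 simulated codon sites, 86 come out strictly conserved, 23
vary only within one biochemical group and 2 are variable — the
signature of the purifying constraints the simulator imposes. The
statistics stage cross-tabulates parasitic lifestyle against observed
deletions and tests it:

```r
st <- run_stats(cfg, res)
st$parasite_deletion$table
#>               deletion no_deletion
#>   parasite           4           4
#>   free_living        0          19
st$parasite_deletion$statistic   # Williams-corrected G = 9.95
st$parasite_deletion$p           # p = 0.0016
```

Deletions occur in 4 of 8 parasite haplotypes and in none of the 19
free-living ones; the G-test rejects independence. On published count
layouts the same machinery reproduces printed statistics: the 2×2 table
of 23 conserved sites against the 159 helix / 60 loop columns gives

```r
tidy(g_test(matrix(c(16, 143, 7, 53), 2, byrow = TRUE)))
#>   statistic    df p.value correction method
#> 1     0.114     1   0.736  williams   G-test of independence
```

Per-codon selection and mutation-spectrum summaries come from the same
objects: `st$dnds_median$value` is 0 here (no codon accumulates enough
nonsynonymous change under purifying acceptance 0.1), and
`substitution_count_matrix(res$alignment)` returns the normalised rate
matrix, with C→T (30.5) and G→A (14.3) dominating their reverse
directions (2.2 and 1.6) as configured through the damage-bias
multiplier. `autoplot()` methods draw the entropy landscape, the
dN/dS profile and the substitution matrix.

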