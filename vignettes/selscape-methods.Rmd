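---
title: "Methods: dual-timescale selection scans and IDR analysis with selscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-timescale selection scans and IDR analysis with selscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selscape)
```

selscape asks two questions about a set of genes — in the motivating use
case, genes whose products silence transposable elements (the piRNA
pathway, the HUSH and NuRD complexes, and related factors):

1. **Recent, population-level selection.** Do the genes carry signatures of
   recent positive selection in human populations, visible as depressed
   windowed site-frequency-spectrum statistics concurrently across many
   populations?
2. **Long-term, protein-level selection.** Are the codon-level positively
   selected sites accumulated over primate evolution concentrated in
   intrinsically disordered regions (IDRs), and how variable are IDR
   sequence and ensemble features across orthologs?

Both layers are built around tabular data (tibbles in, tibbles out) so the
stages compose with ordinary dplyr pipelines, and both are backed by
generators that plant known truth, so every stage can be validated by
recovery rather than by eyeballing.

## The population layer

### Windowed statistics

For a genomic window with `n` sampled haplotypes and derived-allele counts
$x_i$ at its $S$ segregating sites (ancestral states known, i.e. the
unfolded spectrum), the package computes:

* nucleotide diversity $\pi = \sum_i 2 x_i (n - x_i) / (n(n-1))$, the mean
  pairwise Hamming distance (summed per window; per-bp variants divide by
  the window length);
* Watterson's $\theta_W = S / a_1$, $a_1 = \sum_{i=1}^{n-1} 1/i$;
* Fay & Wu's $\theta_H = \sum_i 2 x_i^2 / (n(n-1))$, which up-weights
  high-frequency derived alleles;
* Tajima's $D = (\pi - \theta_W) / \sqrt{e_1 S + e_2 S(S-1)}$ with the
  standard sample-size constants;
* unnormalized Fay & Wu's $H = \pi - \theta_H$.

Two conventions matter downstream. First, windows with $S = 0$ (and any
window where the variance term of $D$ vanishes, which includes every
sample of fewer than four haplotypes) yield *missing* values, never zero:
a zero would rank as unremarkable, while an empty window is simply
uninformative and is excluded from ranking. Second, $H$ is used in its
unnormalized form; the scan consumes only within-population ranks, which
any monotone per-population normalization leaves unchanged at a fixed
sample size.

`windows_from_vcf()` reads a VCF with an `AA` (ancestral allele) INFO tag
into overlapping windows. Sites are polarized case-insensitively against
`AA`; a site whose `AA` equals ALT has its count flipped to `n - c`.
Multi-allelic sites, sites without a usable `AA`, sites whose `AA` matches
neither allele, and sites monomorphic after polarization are dropped and
tallied in a log attached to the result, so filter effects are auditable.
Window tiling is deterministic: 0-based half-open windows start at every
multiple of the step; emission stops with the first window reaching the
chromosome end, which is truncated there rather than dropped.

### The scan

Within each population and statistic, windows are ranked ascending (rank 1
= lowest = most extreme for the low tail of $D$ and $H$), with ties
assigned the minimum of the tied range — the conservative choice, since it
moves tied windows *toward* the extreme tail. Each gene receives the
minimum rank over all windows overlapping it by at least one bp; a gene is
tagged *extreme* when that rank falls within the lowest 5% of ranked
windows (inclusive boundary, `ceiling(q * n_ranked)`). A gene is a
**concurrent hit** when it is extreme for *every* scanned statistic
(default: both $D$ and $H$) in at least 10 populations. Because tagging is
rank-based within each population, demographic differences between
populations (which shift whole distributions) do not by themselves create
hits.

Whether the 5% tail should be taken over windows or over genes' minimum
ranks is genuinely ambiguous; the package implements the window-level tail
as the default and exposes the gene-level alternative via
`scan_config(tail_unit = "genes")` rather than deciding silently. Note
that a gene's minimum over several windows makes the per-gene tag rate
exceed the nominal 5% when windows overlap heavily; calibration
experiments therefore use non-overlapping windows (one per gene region).

The diversity comparison (`pi_background_comparison()`) assigns each gene
the *median* per-bp $\pi$ over its overlapping windows (median chosen for
robustness; the window-to-gene aggregation is otherwise unconstrained) and
compares candidates against `B = 1000` equal-size random background
subsets with a two-sided Wilcoxon rank-sum test. No single-number
aggregation of the iterations is imposed: the result object keeps the full
p-value vector (via `tidy()`), and `glance()` reports the median p, the
fraction of iterations in which the candidate median was lower, and one
pooled test of candidates against the entire background.

### The coalescent generator and its sweep model

`simulate_neutral_window()` draws a Kingman coalescent (pairwise
coalescence rate $k(k-1)/2$ among $k$ lineages) and places infinite-sites
mutations on branches at rate $\theta/2$ per unit branch length; each
mutation gets a distinct uniform physical coordinate. The simulated window
is the unit of complete linkage: there is no recombination within it and
free recombination between windows. The defaults (`theta = 2` on 2-kb
blocks, i.e. $\theta = 0.001$/bp, `n_haplotypes = 30`) emulate human-like
diversity with roughly 15 diploid individuals per population, and the
50-kb *analysis* windows of the scan then aggregate ~25 independent
genealogical blocks (`retile_windows()` or the VCF round trip). This
separation matters statistically: a 50-kb window that were a single
genealogy would give the neutral $H$ distribution so heavy a left tail
(one deep basal branch can mimic a sweep) that no rank scan could separate
sweeps from neutral noise, whereas real 50-kb human windows contain many
quasi-independent genealogies.

The sweep model is a star-merger distortion, not a forward simulation: at
backward time `sweep_age`, each surviving lineage joins a single star
ancestor with probability `sweep_strength`. One uniformly chosen lineage
**always escapes** the merger. The escape lineage plays the role of the
recombinant/ancestral haplotypes present in any real sample: it keeps the
merged lineage segregating, so mutations accumulating on the merged
lineage before the final coalescence appear as *high-frequency derived*
alleles. Without it, a full-strength sweep would collapse to a pure star
genealogy whose variants are all singletons — strongly negative $D$ but
slightly *positive* $H$, the opposite of the signature the sweep model
exists to produce. With it, strength-1, age-0.05 sweeps give mean
$D \approx -2.3$ and mean $H \approx -38$ per 50-kb analysis window at the
default diversity, against neutral means of ~0.

Not emulated, deliberately: migration and shared demography (shared sweeps
are induced by reusing `sweep_windows` across otherwise independent
populations), recombination *within* a block, growth/bottlenecks, genotype
likelihoods and genotyping error, and any uncertainty in ancestral-state
assignment (the simulator is fully polarized by construction; real-data
users must bring their own polarization and quality filters). Passing
recovery tests on these simulations therefore demonstrates the scan logic,
not robustness to demographic confounding or mispolarization.

## The protein layer

### Consensus site calling

Per-site selection calls from five methods are consumed as a normalized
table (`method`, `alignment_column`, `score`, `direction`). The consensus
rule is literal about each method's published cutoff style: BEB and FUBAR
pass at posterior $\ge 0.90$ (inclusive), MEME and FEL at $p < 0.1$
(strict), and a column is a consensus positive-selection target when at
least two of the four methods pass. BEB and FUBAR are counted as distinct
voters — both are site-posterior methods, but the rule is implemented as
stated rather than collapsing them. SLAC identifies negatively selected
sites (direction `"negative"`, $p \le 0.1$ inclusive; the cutoff is not
fixed by convention anywhere, so it defaults to the FEL value and is
configurable). Overlap between the positive and negative sets is reported
as a warning, not an error. `map_column_to_reference()` provides the
gap-skipping bijection from alignment columns to reference residue
numbers.

### IDR construction and features

Ortholog-consensus IDRs are built by a per-column species vote: at each
alignment column, the fraction of species *with a residue there* whose
residue is called disordered is computed; columns with fraction $\ge 0.5$
(inclusive) are consensus-disordered, and maximal runs of
consensus-disordered reference residues of length $\ge 30$ become IDR
intervals. "The same orthologous region predicted in at least half the
species" is thus operationalized column-wise, since region identity across
species is otherwise undefined; all-gap species drop out of the vote
automatically.

Sequence descriptors per IDR and ortholog (ortholog subsequences are the
MSA projection of the reference interval, gaps removed):

* FCR $= (n^+ + n^-)/N$ and NCPR $= (n^+ - n^-)/N$, with K, R positive
  and D, E negative by default. Histidine is excluded from the charged set
  by default (its charge is pH-dependent); `include_histidine = TRUE`
  restores it.
* SHD, sequence hydropathy decoration,
  $\mathrm{SHD} = \frac{1}{N}\sum_{i<j} (\lambda_i + \lambda_j)(j-i)^{-\beta}$
  with $\beta = 1$ and $\lambda$ a hydropathy scale normalized to
  $[0, 1]$. The descriptor is cited in the literature by name with more
  than one parameterization in circulation; this functional form is the
  distance-decayed pairwise one, shipped with the Kyte–Doolittle scale
  rescaled to the unit interval. Any fixed positive scale preserves the
  reversal symmetry and the group-comparison semantics used downstream,
  which is what the analyses consume.

Ensemble features — conformational entropy per residue ($S_{conf}/N$) and
the Flory scaling exponent ($\nu$) — are *inputs, never computed*: they
come from an external predictor in real use, so the package only joins
them (per IDR, or per IDR and ortholog) and summarizes them. The
synthetic generator produces them as noisy monotone functions of each
segment's SHD, purely so the group-comparison machinery is exercisable;
nothing about those synthetic values is physically meaningful.

Across-ortholog variability uses the sample (n−1) standard deviation, one
value per IDR and feature.

### Statistics

* **Enrichment**: exact binomial test with the in-IDR site count as
  successes, all consensus sites as trials, and the summed IDR length over
  the summed analyzed length as the success probability. One-sided
  ("greater") by default, since the hypothesis is enrichment; two-sided is
  available. In the pipeline the analyzed length is the full reference
  protein length; with trimmed alignments users should pass the retained
  length instead.
* **Group comparisons** (selected vs non-selected IDRs, where selected
  means containing at least one consensus positive site): two-sided
  Wilcoxon rank-sum with tie correction, exact for tie-free groups of at
  most 20, normal approximation otherwise.
* **Constraint correlations**: Kendall's tau-b between the per-IDR
  fraction of negatively selected sites (count over IDR residue length,
  closed interval) and each ensemble feature; exact p for 8 or fewer
  tie-free pairs.
* **Cross-annotation check**: Pearson correlation between per-protein
  disorder fractions from two sources; degenerate (zero-variance) input
  returns a missing correlation with a warning.

### The proteome generator

`simulate_ortholog_proteins()` plants: disorder-biased segments (residue
composition skewed toward disorder-promoting residues inside segments;
per-residue disorder calls at 0.95 inside vs 0.05 outside by default);
true positively selected sites via per-residue Bernoulli draws whose
probability is $\rho$-fold higher inside segments (so at $\rho = 5$ and
IDR fraction 0.4 the expected in-IDR share is $2/2.6 = 10/13$); uniform
negative sites; per-method call tables with configurable
sensitivity/specificity and scores always on the correct side of each
method's threshold; and ortholog MSAs with substitutions, deletions and
occasional reference-gap insertion columns. Per-protein IDR fractions
vary deterministically around the target (±0.1 by default, averaging the
target exactly) so per-protein disorder fractions are not degenerate.
It does not emulate: correlated evolution between sites, alignment error,
rate variation across lineages, or realistic indel length distributions.

## Numerical and design choices, in one place

* Rank ties: minimum of the tied block. Tail boundary: inclusive ceiling.
* $S = 0$ (or zero-variance) windows: missing statistics, excluded from
  ranking, written as `NA` in TSVs.
* Final window truncated at the chromosome end; short windows emitted.
* Multi-allelic and unpolarizable VCF sites skipped with logged counts;
  `AA` comparison case-insensitive.
* Sweep model: independent Bernoulli star-merger with one forced escape
  lineage (rationale above).
* Consensus boundaries: posteriors inclusive, p-values strict; SLAC
  inclusive at 0.1 (configurable).
* Negative-site fraction denominator: IDR residue length, not alignment
  columns.
* Binomial enrichment: one-sided "greater" by default.
* One global seed derives every per-window, per-population and per-stage
  stream, so runs are byte-reproducible end to end (report JSON included;
  no timestamps are written).

## Problem sizes used by the test suite

The packaged experiments are sized to be decisive yet quick: neutral
calibration uses 4,000 windows at $n = 25$, $\theta = 5$ (the mean of $H$
has Monte-Carlo SE ≈ 0.056 there); sweep recovery uses 500 gene regions ×
12 populations at the default human-like diversity with 5 planted sweeps;
enrichment calibration uses 1,000 single-proteome replicates with
per-replicate IDR geometry and ~300 sites at low per-residue density
(where the exact binomial's discreteness is negligible), and power uses
300 replicates at the study conditions (ρ = 5, ~100 sites, fraction 0.4);
consensus recovery uses 50 proteins with ~500 planted sites. The default
end-to-end pipeline simulates 12 populations × 3 Mb and a 20-protein
proteome, and runs in about a minute.

## Known limitations

* The scan's neutral calibration assumes exchangeable windows; real
  genomes have mutation- and recombination-rate heterogeneity that widens
  rank tails locally.
* The concurrence rule treats populations as independent; shared ancestry
  makes "10 of 54 populations" less than 10 independent confirmations,
  and the same caveat applies to the simulated populations.
* Unnormalized $H$ is adequate for rank-based use but not comparable
  across sample sizes.
* The binomial enrichment test models site placement with replacement; at
  realistic site densities (well under a few percent of residues) the
  distinction from without-replacement placement is negligible, but it is
  visible in dense synthetic settings.
* IDR calling depends entirely on the upstream disorder predictions
  supplied as input; the package consensus-calls but does not predict.
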