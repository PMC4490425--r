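---
title: "Codon usage, codon context and positional bias: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage, codon context and positional bias: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

This vignette is the package's account of what it computes, the assumptions
behind each statistic, and the choices made where more than one reasonable
definition exists. The companion README shows a worked example; the test
suite holds the quantitative evidence for every claim made here.

## ORF validation and filtering

An analysable coding sequence begins with ATG, ends with TAA/TAG/TGA, has
length a positive multiple of 3, and contains neither an in-frame internal
stop nor a character outside A/C/G/T. `filter_orfs()` additionally drops
sequences of 300 bp or less (the threshold is strict: a 300-bp ORF is
excluded, a 303-bp one kept, counting start and stop codons in the length),
and — when a table of homolog reference lengths is supplied, standing in
for a BLAST top-hit length — sequences whose length falls outside
0.95–1.05 of the reference, bounds inclusive. Each rejection carries
exactly one reason: the first failing rule in a fixed order
(frame, start, stop, internal stop, alphabet, length, homolog ratio), which
makes filter reports deterministic and the partition property
(kept + rejected = input) trivial to audit. Internal stops are checked in
frame 0 only; an out-of-frame stop trinucleotide is not an error. All
internal computation uses the DNA alphabet; user-facing tables render
codons with U because that is how the field prints them.

## Codon usage statistics

`count_codons()` counts every in-frame codon, including the start ATG and
the stop codon by default: corpus-level accounting (totals, per-mille
frequencies, GC partition) covers the whole ORF. RSCU and SCUO, by
contrast, are statements about synonymous *choice*, so they exclude the
non-degenerate Met and Trp; the stop codons form their own 3-member family
with its own RSCU. Per-mille frequencies are over all 64 codons, while
"fold of the mean" comparisons use the 61 sense codons — with uniform usage
every sense codon would sit at 1000/61 ≈ 16.4 per-mille.

SCUO uses base-2 logarithms. Its source definition fixes no base, and the
ratio `(log S − H)/log S` is base-invariant anyway; base 2 keeps the
intermediate entropies in bits. Families absent from a gene or corpus are
omitted from the weighted sum (the 0·log 0 := 0 convention applied at the
family level).

High-frequency codons are those with RSCU > 1.5 *or* a within-family share
above 60%; the two rules are deliberately redundant for highly degenerate
families but not for 2-fold ones (a 2-fold codon at share 0.74 has RSCU
1.48 — caught by the share rule only). Abundant/rare sets are the top and
bottom 15 sense codons by frequency; stop codons are excluded, and
frequency ties at a set boundary resolve to the lexicographically smaller
codon so the sets are reproducible.

## Codon pairs and the Audic–Claverie test

Pairs are counted at junction distances 0–5 (number of intervening codons)
over the *interior* codons of each gene — the start and stop codons are
excluded, and no pair spans two genes. The expected frequency of a pair is
the product of the interior single-codon frequencies; expected counts for
testing are analytic (`N · exp_freq`) rather than drawn from a shuffle
realization, which keeps calls deterministic. The shuffling null models are
used where they are irreplaceable: type-I-error verification (SC) and the
positional KLD baseline (SSC).

The count test is the Audic–Claverie posterior tail. The posterior
`p(y|x)` is exactly a negative binomial with size `x+1` and success
probability `N1/(N1+N2)`, so tails are evaluated through `pnbinom()` —
exact and overflow-safe at any count; the test suite cross-checks this
against direct log-space summation. The p-value is two-sided (twice the
smaller tail, capped at 1) because both preferred and avoided items are of
interest; reported p-values are floored at 1e-10. A call requires both
`p < 0.01` and `|log2(obs/exp)| ≥ 1.5` — the cutoff is on the log2 scale
(2^1.5 ≈ 2.8-fold), not a 1.5-fold change. The 0.5-count continuity
correction enters the ratio only when either count is zero; the p-value
always uses the raw integers.

RSCPU applies to neighboring pairs only. The four pairs of two
single-codon families (MetMet, MetTrp, TrpMet, TrpTrp) carry no synonymous
choice and are excluded from the RSCPU universe (3721 → 3717), but remain
in the 61 × 61 bias table. Amino-acid-pair families never observed are
absent from the result rather than reported as 0/0.

## Positional bias

Bins are 10 codons each: five bins after the start codon (bin_1 … bin_5,
codons 2–51) and five before the stop (bin_−5 … bin_−1). Only genes with at
least 102 codons including start and stop enter positional analysis — that
is the shortest length at which the 5′ and 3′ bins are disjoint, and
near-threshold genes are otherwise ambiguous to bin.

`KLD(k)` sums `p ln(p/q)` over amino-acid families present in bin *k*,
with `q` the corpus-wide within-family usage (start/stop positions
excluded from `q`, matching the bins' own universe). Codons unobserved in
a bin contribute 0; a codon observed in a bin but absent from the corpus
background is impossible when `q` comes from the same corpus, and the
function treats it as an error rather than returning infinity. Because a
finite bin has positive expected KLD even under no positional structure,
the reported profile carries an SSC null baseline: the SSC shuffle permutes
codons among all corpus positions encoding the same amino acid, which
preserves every protein sequence and the corpus codon counts (hence `q`)
exactly, isolating positional signal. The default is 100 replicates with a
caller-supplied seed; `kld_corrected` is raw minus null mean, and the null
sd calibrates detection (the self-consistency tests use a ±3 sd band).

Post-AUG bias compares the codon following the start (or following
internal, non-start ATGs whose successor is not the stop) against interior
frequencies with the same test and thresholds as pair calling, and
aggregates obs/exp over the 12 positional-nucleotide masks (base × codon
position, e.g. Gnn/nGn/nnG).

Context logos use 18-nt windows: 9 flank nucleotides, the anchor codon
(positions 10–12, dropped from the output), and 6 nucleotides beyond.
Information content follows the WebLogo convention
`R = 2 − (H + e_n)` with the 4-state small-sample correction
`e_n = 3/(2 ln 2 · n)`; since the correction can push R marginally below
zero at small `n`, R is clamped at 0 so letter heights stay well-formed.
Note the geometry: for the start anchor the six "following" nucleotides are
CDS positions 4–9, so a Kozak +4 G is a property of codon 2, not of any
flank; flank-profile injection demonstrates motif detection at −3
(upstream) and, for the stop anchor, at the first downstream position.

## Composition and GC3 strata

Mono-, di- and tri-nucleotide frequencies come from overlapping windows
that never span sequence boundaries. The odds ratios are applied to the
coding strand only — these are mRNA coding sequences, so no
reverse-complement symmetrization is appropriate. The ρ_CWG denominator
term `f_CNG` is implemented exactly as the composite formula specifies.
Zero denominators (e.g. a corpus with no CNG trinucleotide) yield a
flagged `NA`, not a crash, since they arise naturally on toy inputs.

GC3 terciles sort genes by GC3 with ties broken by id and split them into
near-equal thirds; when the count is not divisible by 3 the middle stratum
takes the first extra gene (646 genes → 215/216/215) and the low stratum
the second. Group contrasts of ρ_CG/ρ_CWG carry percentile bootstrap 95%
intervals from gene-level resampling (default 1000 replicates, seeded) —
the group-difference claim needs an uncertainty statement and the
gene-level bootstrap is the assumption-lightest one available here. The
SCUO–GC3 relation is summarised by a least-squares polynomial (default
degree 2, capturing the characteristic U shape); the fitted minimum is
closed-form for a convex quadratic and a grid minimum over the observed
GC3 range otherwise.

## Cross-species comparison

Species profiles collect ORF/codon totals, the GC partition, the
59-dimensional RSCU vector in a fixed codon order, and the codon-context
adjusted-residual matrix. For clustering, each codon column is first
standardized to zero mean and unit variance across species — "adjusted
RSCU" — so that high-degeneracy families (whose RSCU ranges are wider) do
not dominate the distance; constant columns are set to 0. Species distance
is Euclidean by default, with rank-order (Spearman) correlation distance
available as an alternative; linkage is average in both cases, and
`hclust`'s input-order tie-breaking makes results deterministic. PCA is
centered and unscaled, with each component's sign fixed so its
largest-magnitude loading is positive; the same conventions apply to the
per-gene RSCU matrix if one is supplied. Context trees use
1 − Pearson correlation of the flattened residual matrices (0 identical,
2 anti-correlated) with average linkage. Trees serialize to newick with
whitespace in names replaced by underscores. These are similarity
dendrograms, not phylogenies: no substitution model, no bootstrap support.

## The synthetic-corpus generator

The generator emulates the statistical structure the analyses assume:
interior amino acids i.i.d. (uniform over the 20 by default), codons drawn
from per-family weight vectors, optional first-order pair coupling
(a multiplicative reweighting of the next codon's family vector given the
previous codon), optional per-bin multiplicative overrides of the family
weights, stop codons from a 3-vector, and flank nucleotides from
per-position profiles (9 upstream, 6 downstream by default). Gene lengths
are uniform or clamped-lognormal in codons, including start and stop.
Defaults are neutral: uniform weights, no coupling, no overrides — the
null corpus. Everything is reproducible from the spec's seed.

Two consequences of this design are worth knowing when reading test
results. First, pair coupling acts *within* the family of the second
codon, so the attainable pair enrichment is `w/(1 + (w−1)q)` for weight
`w` and baseline share `q` — a 2-fold family cannot exceed 2-fold
enrichment no matter the weight; detection tests therefore inject into
high-degeneracy families. Second, a positional override shifts the
corpus-wide background `q` a little (the injected bin is part of the
corpus), so mid-gene bins are only approximately null; injection scenarios
use long genes so the injected bin is a small fraction of the corpus.

What the generator does **not** emulate: expression levels, amino-acid
composition biases of real proteomes, length–bias correlations,
within-gene GC gradients, or any mutational process. Passing
parameter-recovery tests therefore shows the estimators are correct and
calibrated under the stated model, not that real transcriptomes satisfy
that model.

The shuffling null models are exact permutations: SSC permutes codons
within amino-acid classes corpus-wide (proteins and codon counts
preserved); SC permutes all interior codons (lengths and codon counts
preserved, proteins not). Interior-only SC cannot introduce internal
stops, because interior codons of validated ORFs are sense codons.

## Problem sizes, determinism, and limits

The test suite and the acceptance script size their simulations to make
the stochastic bands comfortable rather than marginal: RSCU recovery to
±0.05 uses ~4×10⁵ codons (at 10⁵ the sampling noise of a 6-fold family
alone approaches the band), null calibration uses 20 seeds of ~10⁵ codons
each, and KLD/logo detection scenarios use 300–400 genes. All stochastic
functions take explicit seeds; rerunning any pipeline with the same
configuration and seed reproduces every output byte-for-byte.

Known limitations: no CAI/ENC/tRNA-adaptation indices (different
questions), no mRNA secondary-structure energetics, no GO annotation (the
GC3 strata that would feed one are produced), and the comparative module
consumes user-supplied FASTA rather than fetching genomes. The
Audic–Claverie test compares a count against an analytically expected
count as if both were measured libraries; this is conservative under the
null (the test assumes more variance than the one-sample situation has),
which is the safe direction for calling bias.
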