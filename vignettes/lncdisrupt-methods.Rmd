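---
title: "Methods: scoring structure-disruptive variants in disease-locus lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring structure-disruptive variants in disease-locus lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most disease-associated variants from genome-wide association studies fall
outside protein-coding sequence, and many land inside long non-coding RNAs
(lncRNAs) that overlap or flank disease candidate genes. A single-nucleotide
change in a lncRNA can reshape its secondary structure and thereby its
function. `lncdisrupt` implements the full chain of analysis for this
question: classify lncRNAs against candidate genes by strand and position,
map nominally significant variants into them, score each exonic variant for
secondary-structure disruption with an empirical p-value, and rank the
significant variants by combined regulatory, cis-eQTL, recent-selection and
structural evidence. A synthetic-data module generates fixtures with known
ground truth for every stage, so each claim the pipeline makes is testable.

## Locus classification

Intervals are 0-based half-open internally (BED convention); variant
positions are 1-based on disk (VCF convention) and converted on read.

A lncRNA relates to a candidate gene by one of five regimes: same-strand
overlap of at least one nucleotide (*sense intersecting*), full containment
of the lncRNA span in the gene span on the same strand (*sense 100%
overlapping*, a subset of the former), opposite-strand overlap (*antisense
intersecting*), or — for disjoint pairs — *flanking* within 5 kb of a gene
boundary, sense or antisense by strand match. The flank rule is inclusive
at exactly 5,000 bp, matching the windowing semantics of the standard
interval tools. Containment is judged on gene spans, not exon unions,
because gene-level coordinates are the usual intersection substrate; an
exon-union mode is available via `use_exon_union`.

Each lncRNA also receives exactly one positional category, with precedence
sense exonic > sense non-exonic > antisense > intergenic (within flank) >
unassociated. Precedence resolves lncRNAs that touch several genes: a
lncRNA exonic to one gene and antisense to another is sense exonic. The
implementation uses GenomicRanges interval trees; the test suite holds it
to 100% agreement with a brute-force all-pairs scan re-stating the
definitions directly.

## Variant mapping

Variants are kept when their association p-value for the chosen disease is
strictly below alpha (default 0.01; the strictness is deliberate and
configurable). Mapping assigns a variant to every lncRNA whose half-open
span contains it. Intronic assignments are flagged and retained — structure
scoring later requires an exonic position, and dropped records should be
visible, not silent. Exonic offsets are spliced-transcript coordinates,
strand-aware: on the minus strand the offset counts from the 3' genomic
end, i.e. the transcript 5' end. Folding always operates on the spliced
transcript in sense orientation, and minus-strand genomic alleles are
complemented before substitution; this is the natural choice because the
molecule that folds is the transcript, not the genome.

## The folding engine

Base-pair probabilities come from a McCaskill-style inside–outside
partition function over a deliberately simple energy model: every
canonical or wobble pair (AU, UA, GC, CG, GU, UG) contributes the same
Boltzmann factor `pair_weight`, hairpin loops keep at least `min_loop = 3`
unpaired bases, and there are no stacking, dangle or loop-type terms. The
recursion conditions on the pairing partner of a segment's last base, so
every structure is counted exactly once, and the outside pass yields exact
pair probabilities in O(n^3). Partition-function values are rescaled per
nucleotide to keep doubles in range, with the scale retried automatically
on overflow or underflow.

This model was chosen because it is *exactly checkable*: the suite
verifies the engine against Boltzmann-weighted exhaustive enumeration of
all structures for sequences up to 25 nt, to 1e-9. A full thermodynamic
engine can be substituted behind the same contract; interfaces and
invariants do not change, only the numbers.

The default `pair_weight = exp(3.5)` corresponds to about −2.2 kcal/mol
per pair at 37 °C, inside the range of real helix stacking energies.
Weaker settings make ensembles so soft that a genuine stem break is
statistically indistinguishable from any substitution that merely adds one
competing pair; the default gives planted stem-breaking variants a clear
signal while remaining physically plausible.

One caveat the model forces: a sequence and its reverse complement give
mirror-image pair matrices only on wobble-free alphabets. G·U maps to C·A
under reverse complementation, and C·A cannot pair, so the mirror symmetry
is tested (and holds exactly) on {G,C}-only and {A,U}-only sequences, and
cannot hold in general for any model that admits wobble pairs.

## Disruption scoring

For an exonic variant, a window of ±200 nt around the position is cut from
the spliced transcript (clipped, never discarded, at transcript ends).
Wild-type and mutant windows — differing at exactly the variant position —
are folded, and the local region of maximal change is found: over all
regions `[i, j]` containing the variant with length at least
`min_region = 50`,

    d(i, j) = sqrt( sum_{i<=u<v<=j} (P_wt[u,v] − P_mut[u,v])^2 ) / (j − i + 1)

is maximized; ties break to the smallest `i`, then smallest `j`. The
minimum region length and the length normalization make the maximization
well-defined (an unnormalized sum is monotone in region size; a fully free
region length degenerates to single entries). `min_region` is clamped to
the window length for short transcripts. The scan uses two-dimensional
prefix sums, so each mutant costs O(n^2) after the O(n^3) fold.

The empirical p-value resamples the background directly: `n_background`
random single-nucleotide substitutions (position uniform over the window,
alternate allele uniform over the three non-reference bases) are scored
against the wild type, and

    p = (1 + #{background d >= d_obs}) / (n_background + 1).

The add-one smoothing keeps p strictly positive and makes the null
distribution uniform on a discrete grid, which the suite verifies with a
Kolmogorov–Smirnov test over 500 null replicates. A variant is called
significant at p ≤ 0.2; that permissive threshold mirrors the screening
character of the analysis — it feeds a ranking, not a final call.

## Evidence and ranking

Annotation never filters: variants missing from the regulatory, iHS or
eQTL tables keep explicit unknowns. cis-eQTL records survive only within
±1 Mb of the target gene's transcription start site (inclusive). Recent
positive selection is `|iHS| >= 2.5`, inclusive. LD is computed as the
squared Pearson correlation of genotype dosages (composite LD) — phase is
not modeled, which is a documented divergence from haplotype-based r².

Significant variants are ranked lexicographically: regulatory score
ascending with unknown last, then presence of at least one cis-eQTL, then
selection, then disruption p-value, with a positional tie-break
(chromosome, position, id) making the order total and reproducible. The
evidence types are weighed hierarchically in this listed order rather than
by a composite score, because any weighting would be arbitrary while a
lexicographic order is transparent and stable. The regulatory score
vocabulary is an ordered configuration vector, not hard-coded.

## Composition and expression statistics

GC content excludes ambiguity codes from numerator and denominator.
Welch's t statistic, the chi-square goodness-of-fit test against
background class proportions, and Spearman correlation (average ranks for
ties) are implemented from their formulas and held to 1e-9 agreement with
the standard reference implementations in the suite — the references serve
as oracles, not as the implementation, so the check is meaningful.
Enrichment residuals default to adjusted standardized residuals
`(O − E) / sqrt(E (1 − p))`, the form whose null distribution is standard
normal; plain Pearson residuals sit behind a flag. Repeat–lncRNA overlap
is strand-agnostic (genomic repeats do not know transcript strand), and a
repeat overlapping several lncRNAs counts once toward class percentages.

Expression filtering keeps genes with FPKM strictly above 1 in every
tissue; "not detected" means at or below the threshold everywhere. The
log10 transform used for display cannot change rank correlations, so
host-gene/lncRNA Spearman values are identical on either scale — computed
once, on ranks.

## The synthetic-data module

The generators produce the study conditions the rest of the package is
exercised under; their defaults are fixed, not tuning knobs: 200 candidate
genes and 500 lncRNAs mixed 30/20/20/30 over the four categories, 2,000
variants with 10% nominally significant, 14 expression tissues, a planted
host–lncRNA rank correlation of 0.8, LD targets {0, 0.5, 1}, and a 10 bp
planted stem.

*Locus fixtures* are truth-by-construction: genes (three 300 bp exons, 800
bp introns) are laid out with inter-gene gaps of three flank lengths, and
each lncRNA is placed to satisfy exactly its planted category definition —
overlapping a same-strand exon, contained in a same-strand intron,
opposite-strand inside a gene, or disjoint within the flank. Classifier
tests are therefore exact, not statistical.

*Structure fixtures* plant a conformational switch. A perfect stem–loop
(mixed, aperiodic G/C arms; 4 nt A loop) sits in a poly-A background,
followed immediately by a decoy arm that can re-pair the 3' stem arm in a
shifted register capped at stem−1 pairs by the minimum-loop rule. The
perfect stem is thus the unique pairing maximum of the wild type; the
mid-stem G→A removes that one-pair margin and splits the ensemble across
both registers, rearranging probabilities over the whole element. This
design is a consequence of the energy model: with equal pair energies and
free bulges, breaking one pair of an isolated hairpin changes roughly one
matrix entry — the same magnitude as any background substitution that
offers the stem a single competing partner — so an isolated hairpin cannot
yield a detectable planted variant at all, whereas a switch concentrates
many entries of change on the planted position. Arms are redrawn (runs
≤ 2, low self-similarity under shifts 1–4, and a deterministic fold check
that the planted break moves the element's ensemble) so every seed plants
a construction that actually encodes the intended truth; no empirical
p-values enter this check. The element sits ~120 nt into the transcript so
the ±200 nt window dilutes in-element background substitutions. The
neutral variant is an A→C in the poly-A tail whose window excludes all
paired elements; A and C pair with nothing there, so its distance is
exactly zero by construction.

*Evidence fixtures* draw iHS scores with a configurable extreme fraction,
scatter regulatory scores and cis-eQTL hits over nearby genes, and
simulate dosage pairs from two-locus haplotype frequencies at allele
frequency 0.5 with `D = sqrt(r²)/4`, which reproduces each LD target and
degenerates to identical dosage vectors at r² = 1.

*Expression fixtures* plant pairs sharing a latent tissue effect with
Pearson correlation `2 sin(pi * rho / 6)` on the log scale, the bivariate
normal value whose Spearman correlation is `rho`; monotone transforms to
the FPKM scale leave ranks unchanged.

What the fixtures deliberately do not emulate: real genome geometry and
gene density, thermodynamically realistic RNA ensembles, LD decay along
chromosomes, or the zero-inflated tails of real FPKM data. Passing tests
show the machinery is correct under its stated model, not that the simple
energy model reproduces the predictions a full thermodynamic engine would
make on real transcripts.

## Problem sizes and numerical choices

The test suite verifies the folding engine on 100 random sequences up to
25 nt against exhaustive enumeration; calibrates null p-values with 500
replicates of 199 background draws on 60 nt windows; measures planted
power over 100 seeded fixtures at 59 background draws; and runs the
end-to-end pipeline on the default 200-gene/500-lncRNA/2,000-variant
bundle twice, requiring byte-identical outputs. The pipeline default of
200 background draws per variant balances p-value resolution (~0.005)
against folding cost. A single global seed fans out to per-stage seeds by
stable string hashing, so adding a stage never perturbs another stage's
draws.

## Limitations

The reference energy model ignores stacking, loop penalties and dangles;
absolute disruption distances are not comparable to thermodynamic tools,
only the pipeline semantics are. Composite LD understates haplotype r²
when phase matters. The ranking is hierarchical by construction; users
wanting a weighted score should consume the annotated table and impose
their own. Pseudoknots, RNA–RNA interactions and isoform-level
classification are out of scope.
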