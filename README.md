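# lncdisrupt

Prioritizing structure-disruptive GWAS variants in long non-coding RNAs.

Most disease-associated variants from genome-wide association studies lie
outside protein-coding sequence; many fall inside long non-coding RNAs
(lncRNAs) that overlap or flank disease candidate genes, where a single
nucleotide change can reshape the RNA's secondary structure. `lncdisrupt`
is an R package for analysts who want to take a set of candidate genes, a
lncRNA annotation and a GWAS variant table and produce a ranked list of
variants with structural and regulatory evidence. It implements:

- **Strand-aware locus classification** — lncRNAs vs candidate genes under
  the overlap regimes *sense intersecting* (≥ 1 nt same-strand overlap),
  *sense 100% overlapping* (span containment), *antisense intersecting*,
  and *flanking* within an inclusive 5 kb window; plus the exclusive
  four-category taxonomy sense exonic / sense non-exonic / antisense /
  intergenic.
- **Variant mapping** — nominal filtering at p < 0.01 (strict), assignment
  to lncRNA spans with spliced, strand-aware transcript offsets.
- **Structure-disruption scoring** — wild-type and mutant base-pair
  probability matrices from a McCaskill-style partition function
  (inside–outside, O(n³); every canonical/GU pair carries equal energy,
  minimum hairpin loop 3) over a ±200 nt window; the local region `[i, j]`
  containing the variant (length ≥ 50) maximizing

      d(i,j) = sqrt( Σ_{i≤u<v≤j} (P_wt[u,v] − P_mut[u,v])² ) / (j − i + 1)

  and an empirical p-value `p = (1 + #{background d ≥ d_obs}) / (n + 1)`
  from n random single-nucleotide background substitutions; significance
  at p ≤ 0.2.
- **Evidence ranking** — regulatory score (ordered categories, unknown
  last), cis-eQTLs within ±1 Mb of the TSS, recent positive selection at
  |iHS| ≥ 2.5, composite LD r² from genotype dosages; lexicographic,
  fully reproducible ranking.
- **Composition and expression statistics** — GC content, Welch's t,
  repeat-class composition with chi-square enrichment and adjusted
  standardized residuals, FPKM > 1 expression filtering and host-gene
  Spearman correlations.
- **Synthetic fixtures with known truth** for every stage, so each claim
  is testable: planted categories recovered exactly, planted
  stem-breaking variants detected, planted LD and expression correlations
  recovered.

## Worked example

Score a planted stem-breaking variant against its matched neutral control:

```r
library(lncdisrupt)

fx <- generate_structure_fixture(sim_config(seed = 2))
am <- map_variants(list(fx$disruptive, fx$neutral), list(fx$lnc))

score_variant(fx$lnc, am[am$variant_id == "rs_disruptive", ],
              fx$disruptive, list(n_background = 199, seed = 2))
#> <disruption_result> rs_disruptive in LNC_HAIRPIN: d = 0.02649 over [112, 161], p = 0.02 *

score_variant(fx$lnc, am[am$variant_id == "rs_neutral", ],
              fx$neutral, list(n_background = 199, seed = 2))
#> <disruption_result> rs_neutral in LNC_HAIRPIN: d = 0 over [0, 200], p = 1
```

The mid-stem G→A rearranges base-pair probabilities over a 50 nt region
(`d = 0.026`) and beats 199 random background substitutions in all but a
few draws (`p = 0.02`, significant at the 0.2 screening threshold); the
control in an unpaired poly-A stretch changes nothing (`d = 0`, `p = 1`).

The full pipeline on the default synthetic bundle (200 genes, 500 lncRNAs,
2,000 variants, two disease labels):

```r
bundle <- generate_fixture_bundle(sim_config(seed = 7))
run_pipeline(pipeline_config(bundle = bundle, seed = 7))
#> <pipeline_result>
#>   lncRNA-gene association records: 500
#>   disease n_nominal n_mapped n_mapped_exonic n_scored n_significant n_ranked
#> 1     IBD       190       11              11       10             3        3
#> 2     T1D       198       13              13       11             2        2
```

Counts contract across stage boundaries (ranked ≤ significant ≤ scored ≤
mapped ≤ nominal); variants that cannot be scored (intronic, reference
mismatch) are listed in a per-disease skipped table, never dropped
silently. With `outdir =` set, every table is written as TSV together
with a manifest (configuration hash, seed, package version), and re-runs
with the same seed are byte-identical.

A command-line wrapper lives at `inst/scripts/run-pipeline.R`.

## Documentation

The methods vignette (`vignettes/lncdisrupt-methods.Rmd`) describes the
energy model and its single parameter, the disruption score and its
region search, the empirical p-value calibration, the classification
precedence rules, the ranking comparator, and exactly what the synthetic
fixtures do and do not emulate about real data.
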