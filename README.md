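# deltaDS

Quantifying how coding single nucleotide variants (SNVs) change the
predicted intrinsic disorder tendency of proteins.

Many functionally important proteins contain intrinsically disordered
regions, and missense mutations that flip a region between structure and
disorder tendencies are enriched among disease-associated variants. For a
biallelic exonic SNV that causes a single amino-acid polymorphism (SAP),
`deltaDS` scores both allelic protein sequences with a per-residue
disorder predictor (scores in [0, 1]; > 0.5 = predicted disorder) and
computes, at the substituted residue,

```
ΔDS = DS_min − DS_maj
```

where `DS_min` and `DS_maj` are the disorder scores under the minor and
major allele. A positive ΔDS means the minor allele pushes the region
towards disorder; a negative ΔDS towards structure. Around this statistic
the package provides the full analysis pipeline:

- **Variant → protein mapping** (`mapVariants`): exact multi-frame
  translation of CDS sequences, with ambiguity and reference-mismatch
  reporting, consequence classification (synonymous / missense /
  nonsense) and missense filtering.
- **Substitution-space enumeration** (`enumerateSingleBaseChanges`): of
  the 380 ordered amino-acid substitutions, only 150 are reachable by a
  single base change within a codon; the multimap of realising codon
  changes is exported.
- **Pluggable disorder prediction** (`builtinPredictor`,
  `externalPredictor`, `readScores`): a deterministic window-averaged
  propensity model (TOP-IDP scale, sigmoid calibration) or per-residue
  score files from any external predictor.
- **Context dependence** (`isoformShiftDistribution`,
  `crossProteinShiftDistribution`, `substitutionClassTable`): how much
  ΔDS for the same substitution shifts across isoforms of a gene versus
  across unrelated proteins, plus per-substitution mean ± STD tables.
- **MAF stratification** (`computeMaf`, `partitionCounts`,
  `compareMafGroups`): minor-allele frequencies from genotype dosages
  (with major/minor swap propagation), partition at the |ΔDS| ≥ 0.04
  threshold, and a two-sided Wilcoxon rank-sum comparison of the +ΔDS and
  −ΔDS groups — the purifying-selection signal.
- **Trait validation** (`intersectTrait`, `destabilizationProfile`):
  intersection of high-|ΔDS| SNVs with trait answer sheets (lists of
  simulated causal SNVs) and sign × region cross-tabulation.
- **Synthetic cohorts** (`cohortConfig`, `generateCohort`,
  `simulateCohort`): seeded GAW17-like cohorts — genes, isoforms,
  variants, Hardy–Weinberg genotypes, answer sheets — with full ground
  truth and a tunable MAF–ΔDS coupling, so every stage is testable
  without external data.

## Worked example

Generate a seeded synthetic cohort (1,000 SNVs, 200 individuals, 60
genes) and run the full pipeline:

```r
library(deltaDS)

cfg <- cohortConfig(n_genes = 60, mean_cds_length = 150,
                    n_individuals = 200, n_snvs = 1000,
                    n_causal_per_trait = c(8, 10, 9), seed = 1)
co  <- generateCohort(cfg)
out <- runPipeline(co)
```

The partition of the 1,000 SNVs (420 synonymous, 560 missense, 20
nonsense by construction) splits the missense set into 297 with +ΔDS and
263 with −ΔDS, of which 76 and 64 lie beyond the 0.04 magnitude
threshold (25% of the missense data). The MAF comparison of the two
beyond-threshold groups shows the planted purifying-selection coupling:

```
MAF comparison (beyond |dDS| >= 0.04): +dDS n=76 mean MAF=0.0543;
  -dDS n=64 mean MAF=0.0267; Wilcoxon p=0.0499 *
```

The strongest substitution classes run in the expected physicochemical
direction — large hydrophobics mutating to hydrophilics gain disorder,
the reverse gains structure:

```r
substitutionClassTable(out$results, topK = 3)
#>   substitution n mean_delta_ds std_delta_ds      substitution n mean_delta_ds
#>   W>S          6    0.078      0.034            K>I          2   -0.096
#>   L>P          2    0.070      0.051            P>L          3   -0.088
#>   M>K          5    0.068      0.023            G>W          2   -0.083
```

Context dependence: pairing the same SNV across isoforms of its gene
gives a mean |ΔDS shift| of 0.00085 (226 pairs), while pairing the same
substitution across unrelated proteins gives 0.0156 (1,320 pairs) — the
isoform contexts barely move ΔDS, unrelated contexts move it an order of
magnitude more. Finally, `out$traits$summary` checks the trait answer
sheets: e.g. for trait Q2, 10 causal genes contain 32 SNVs with
|ΔDS| ≥ 0.04, 7 of which are themselves in the answer sheet of 10
planted causal SNVs.

## Documentation

The methods vignette (`vignettes/deltaDS-methods.Rmd`) describes the
model, the builtin predictor and its calibration, the synthetic-cohort
generator's assumptions, and known limitations.
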