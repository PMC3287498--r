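---
title: "deltaDS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deltaDS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltaDS)
```

# The model

A biallelic exonic SNV that changes an amino acid (a single amino-acid
polymorphism, SAP) can shift the local balance between structure and
intrinsic disorder of the protein region it sits in. Per-residue disorder
predictors assign each residue a score in $[0, 1]$, with scores above 0.5
read as predicted disorder and at or below 0.5 as predicted structure.
`deltaDS` quantifies the allelic shift as

$$\Delta DS = DS_{min} - DS_{maj},$$

the difference between the disorder scores of the sequence carrying the
minor allele and the sequence carrying the major allele, evaluated at the
substituted residue. A positive $\Delta DS$ means the minor allele is the
more disorder-promoting one. Both allelic sequences are re-predicted in
full rather than patching one profile, because per-residue predictors are
context-sensitive: the same substitution scores differently in different
sequence neighbourhoods, and that context dependence is itself one of the
quantities the package measures.

Synonymous variants cannot change the score of the encoded residue and
nonsense variants truncate the protein, so both are excluded from the
$\Delta DS$ analysis (their counts are retained by `filterSaps` and
`partitionCounts`).

# Variant-to-protein mapping

`mapVariantToProtein` translates the supplied CDS in frames 1–3 of the
forward strand (frames 4–6 of the reverse complement on request) and
looks for the protein as an exact, contiguous match inside each frame's
translation; contiguity guarantees that matched residues appear in the
same sequential order in both sequences. All overlapping matches are
collected; the variant maps only when exactly one consistent
(frame, offset) assignment covers its codon. Everything else is reported,
never guessed: `ref_mismatch` when the declared reference base disagrees
with the CDS, `no_match` when no frame translates to the protein,
`ambiguous` when repeated segments allow more than one placement (these
are logged rather than resolved, since no order check can break a true
repeat), and `outside_protein` when the codon falls outside the matched
region (e.g. in the stop codon). Coordinates are 1-based throughout:
`cds_position` within the CDS, `protein_position` within the protein,
`position_in_codon` in 1–3. Ambiguous IUPAC bases are rejected — the
variant model is biallelic SNVs only; indels, multi-allelic sites and
splice variants are out of scope.

Isoforms are handled by mapping the same variant against every protein
recorded for its gene. An isoform lacking the variant's segment simply
reports `no_match`/`outside_protein` for that member and is dropped from
the pairwise comparison, with the drop visible in the mapping table.

# The builtin disorder predictor

Trained per-residue predictors are ensembles of fitted models and cannot
be reproduced from a paper description; `deltaDS` therefore treats the
predictor as a pluggable component. The **builtin** model is a
transparent two-step stand-in with the same interface and score
semantics:

1. each residue receives the TOP-IDP disorder propensity (Campen et al.
   2008), a published 20-value scale on which P, E, K, S are
   disorder-promoting and W, F, Y, I order-promoting;
2. propensities are averaged over a centred window of `windowLength`
   residues (default 21, a common window size for disorder smoothing),
   truncated — not padded — at the sequence ends so a single-residue
   sequence is still well-defined; the window mean $\bar p$ is mapped
   through the monotone sigmoid
   $score = 1/(1 + e^{-k(\bar p - p_0)})$.

The calibration is fixed at $p_0 = 0.05$ (near the scale's interior
midpoint, so mixed sequences sit near 0.5) and $k = 8$, chosen once so
that (a) homopolymers of the extreme residues land clearly on either side
of 0.5, and (b) a single substitution inside a mid-range context can move
the score by a few hundredths — the regime in which the 0.04 partition
threshold is meaningful. Ties at exactly 0.5 are classed *structured*, so
"disordered" strictly requires a score above 0.5.

Two numerical properties are guaranteed by construction and enforced by
tests: **monotonicity** (raising any residue's propensity never lowers
any score) and **locality** — a substitution at position $i$ perturbs
scores only within $(windowLength-1)/2$ residues of $i$, bit-for-bit.
Window sums are computed independently per position rather than by
running cumulative sums precisely so that the locality is exact in
floating point, not merely approximate.

The builtin model makes no claim to the accuracy of trained predictors:
it has no length-dependent ensembling and no learned sequence features.
Real predictor output plugs in through `externalPredictor` /
`readScores` (per-residue TSV; for variant scoring the file must also
carry the alternate-allele profiles keyed `<protein_id>|<variant_id>`),
and every downstream stage is indifferent to which predictor produced
the scores. Scores travel at full precision internally and in the score
TSVs (17 significant digits, so write–read round trips are exact);
report-style outputs round to 2 decimals for display only.

# Context-dependence summaries

`isoformShiftDistribution` pairs the $\Delta DS$ values of the same SNV
mapped into different isoforms of its gene; `crossProteinShiftDistribution`
pairs the same amino-acid substitution across distinct proteins. For a
group of $m$ values, all $m(m-1)/2$ unordered pairs contribute one
absolute shift and one sign-flip indicator; groups of size one are
skipped and counted. The "peak" of a shift distribution is
operationalised as the modal histogram bin at a default bin width of
0.001 over $|shift|$, with mean and median reported alongside so that no
claim rests on the binning. Sign flips are assessed only between two
nonzero values; pairs involving an exact zero are tallied separately —
zero has no sign, and counting such pairs as flips would inflate the
rate. `substitutionClassTable` groups $\Delta DS$ by amino-acid
substitution (or by realising codon change) and reports n, mean and
sample STD (STD undefined for singletons), with top-$k$ selections
sorted descending for positive means and ascending for negative ones.

# MAF stratification

`computeMaf` counts the rarer allele over $2N$ chromosomes; missing
genotypes leave both numerator and denominator. When the declared
alternate allele turns out to be the more frequent one, the major/minor
roles are swapped and the swap propagates to the SAP — the minor allele
defines $DS_{min}$, so the measured $\Delta DS$ of a swapped variant is
the negation of its reference-orientation value. An exact 50/50 tie
keeps the declared reference as major, for determinism.

The partition threshold defaults to $|\Delta DS| \ge 0.04$ with an
*inclusive* comparison; a strict mode is available and the mode used is
recorded in all outputs, since the two differ only for values exactly at
the threshold. The group comparison (`compareMafGroups`) contrasts the
MAF distributions of the $+\Delta DS$ and $-\Delta DS$ groups, either
beyond or within the threshold (both modes are implemented because
either contrast is scientifically meaningful; *beyond* is the default).
The default test is the two-sided Wilcoxon rank-sum test (normal
approximation), chosen because rare-variant MAF spectra are heavily
right-skewed and mean-based tests are fragile there; a Welch t-test is
available as a sensitivity check.

# The synthetic cohort generator

`generateCohort` emulates the *structure* of an exome-resequencing
cohort of the GAW17 type: coding genes with isoform records, a mixed
synonymous/missense/nonsense variant set, per-individual genotypes with
a rare-variant-heavy MAF spectrum, and trait answer sheets of causal
SNVs. The defaults mirror that structure at full scale — 697
individuals, 24,487 SNVs in 3,205 genes, consequence mix 0.42/0.56/0.02
— while tests and examples run smaller configurations of the same model.
Specifically:

- **Sequences.** Protein lengths are gamma-distributed around
  `mean_cds_length` (minimum 30 codons). Residues are drawn from a
  per-gene mixture of the order-promoting and disorder-promoting halves
  of the propensity scale, with the per-gene weight drawn from
  Beta$(2b, 2(1-b))$ ($b$ = `composition_bias`, default 0.5) so that
  genes span ordered, disordered and mixed contexts. CDSs are
  back-translated with uniformly random synonymous codons plus a random
  stop.
- **Variants.** SNVs are placed by rejection sampling (gene chosen
  proportional to length, uniform codon, position and alternate base)
  until the consequence quotas — largest-remainder rounding of the mix —
  are met exactly; duplicates are rejected.
- **Ground truth.** The true $\Delta DS$ of every missense SNV is
  computed with the same predictor the pipeline will use, which is what
  makes exact end-to-end recovery a testable invariant.
- **MAF and genotypes.** The neutral spectrum is Beta(0.5, 8) — a
  rare-variant-heavy shape resembling exome resequencing spectra — with
  draws above 0.5 resampled so every value is a valid MAF. Missense SNVs
  with $\Delta DS \le -0.04$ have their MAF multiplied by
  `coupling_effect` (default 0.5). This one-sided coupling is a
  deliberate design choice: it is the minimal structure that produces a
  group-level MAF difference between the $+\Delta DS$ and $-\Delta DS$
  beyond-threshold populations (the purifying-selection signal the MAF
  comparison is built to detect) while leaving the sub-threshold
  contrast null. A sign-symmetric coupling would depress both groups
  equally and make the contrast undetectable by construction. It is a
  stand-in for selection, not a population-genetics model. Genotypes are
  Binomial(2, MAF) per individual — Hardy–Weinberg, no linkage
  disequilibrium, no population structure, no missingness.
- **Isoforms.** A fraction `isoform_rate` of genes receives one isoform
  derived by a terminal-segment deletion (length 1 + Poisson, at least
  15 residues retained). Terminal deletions keep the shared sequence
  identical to the canonical, so isoform-level $\Delta DS$ shifts are
  nonzero only for SNVs within a window of the cut — exactly the
  "nearly identical contexts" regime the isoform comparison is meant to
  probe.
- **Answer sheets.** Causal SNVs are sampled per trait among missense
  variants with weight $(|\Delta DS| + 0.01)^{w}$ (default $w = 2$),
  representing traits whose causal variants are enriched for
  disorder-disrupting changes. Traits are represented *only* as answer
  sheets; no phenotype values are simulated, because no pipeline stage
  consumes them — validation is overlap against the answer key, as with
  the GAW17 convention.
- **Reproducibility.** One global seed feeds a fixed hierarchy of
  derived per-stage stream seeds (genes, variants, MAF, genotypes,
  isoforms, traits), so identical configurations give byte-identical
  cohort files and individual stages can be reasoned about
  independently.

What passing tests on these cohorts show — and what they do not: they
verify the pipeline's mechanics (mapping, scoring, swap propagation,
grouping, testing, intersection) exactly, and the statistical machinery's
calibration and power under a known coupling. They do not show that the
builtin predictor approximates any trained predictor on real proteins,
nor that real MAF spectra follow a scaled-Beta selection model.

# Problem sizes and numerical choices in the test suite

The end-to-end recovery check runs a 1,000-SNV, 200-individual,
60-gene cohort; the context-ordering check a 400-SNV cohort with
isoforms on every gene; the calibration study 5,000 null replicates at
200 SNVs per group and the power study 200 replicates at 2,000 per
group — sizes chosen to estimate the type-I rate to about $\pm 0.003$
and the power to a few percent while keeping the suite quick on one
core. Grouped means are cross-checked against a flat one-pass oracle at
$10^{-12}$; the $\Delta DS$ identity is enforced at $10^{-9}$ in the
results container's validity method; antisymmetry under allele swap and
predictor locality are asserted bit-exactly.

# Known limitations

- The builtin predictor is a propensity-smoothing model: adequate for
  exercising and validating the pipeline, not a substitute for a trained
  predictor when scoring real variants — use the external-score adapter
  for that.
- Mapping requires exact translated matches; sequence pairs with
  mismatches (polymorphisms between the CDS source and the protein
  database, RNA editing) report `no_match` rather than aligning around
  the difference.
- The generator omits linkage disequilibrium, kinship, sequencing error
  and genotype missingness; MAF–selection coupling is a group-level
  scaling, not a forward population model.
- Stop-gain and stop-loss variants are excluded from scoring by design;
  their consequence counts are preserved.
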