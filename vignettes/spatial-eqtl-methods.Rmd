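---
title: "Methods: spatial eQTL mapping, haplotype dosage models and constraint summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial eQTL mapping, haplotype dosage models and constraint summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speqtl)
```

This vignette is the package's account of its science: the models and
procedures each stage implements, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical conventions, and the known limitations. Every number shown here
is computed by the code in this document or by the package's test suite;
nothing is quoted from elsewhere.

## 1. Fragment-level spatial evidence

Fragment-resolution Hi-C reports chromatin contacts between restriction
fragments, so the spatial side of the analysis reconstructs the fragment
universe by *digital digestion*: the genome is scanned (case-insensitively;
ambiguity codes never match) for the enzyme's recognition motif, and a cut
is placed at `motif start + cut_offset`. The offset encodes the enzyme's
cut chemistry — MboI cuts before its GATC site (offset 0), HindIII cuts
after the first base of AAGCTT (offset 1). Fragments are the intervals
between consecutive cuts plus the chromosome ends, so they partition each
chromosome exactly; the tiling is asserted property-style in the tests.

```{r}
digest(c(demo = "AAGATCAAGATCAA"), "MboI")
```

Published contact dumps differ in their coordinate dialects, so contact
rows given as interval pairs are resolved to fragments by preferring an
exact boundary match and otherwise taking the fragment containing the
interval midpoint — robust to off-by-one conventions without silently
shifting well-formed data. Rows that cannot be resolved are counted and
skipped; if more than half of a file fails, the run stops, because that
pattern indicates a wrong fragment index rather than a few bad rows.

A SNP–gene pair is *spatial* when some contact links the SNP's fragment to
a **distal** fragment overlapping the gene. Three conventions matter:

* *Overlap* means any overlap of at least 1 bp between the distal fragment
  and the gene's annotated interval, strand-agnostic, with no binning or
  padding around fragments. A stricter full-containment mode
  (`containment = "full"`) is available.
* *Distal* excludes the SNP's own fragment: a gene overlapping the SNP
  fragment itself is not spatial evidence, whatever self-contacts exist.
* Contacts are unordered pairs; both orientations of every row are
  considered, and the pairing is symmetric under swapping the two sides
  (a tested invariant).

Whether a contact in *any* Hi-C library suffices, or only tissue-matched
libraries should gate tissue-specific eQTL calls, is genuinely open: the
contact libraries and the expression panels come from separate,
non-homogeneous sources. The package uses any-library gating and retains
per-source provenance on every pair, so a stricter tissue-matched analysis
can be layered on the output rather than baked into the primitive.

## 2. The eQTL model

Each candidate pair is tested per tissue by ordinary least squares of
expression on allele dosage (0/1/2 alternate alleles). Expression is first
rank-inverse-normal transformed per gene per tissue
(`qnorm((rank - 0.5)/n)`), the standard practice in large expression
atlases: it makes the slope a *normalized effect size* (NES) comparable
across genes and robust to outliers. The transform can be disabled
(`normalize = FALSE`), in which case the slope is in raw expression units.

```{r}
test_association(c(0, 1, 2, 0, 1, 2), c(1.0, 2.0, 2.9, 1.1, 2.1, 3.0))
```

Degenerate inputs — monomorphic dosage, constant expression, fewer than
three complete pairs — yield an `untestable` status rather than an error,
so a scan over thousands of pairs does not die on one bad column.
Missing entries are dropped pairwise.

Multiple testing is controlled by Benjamini–Hochberg across **all**
testable SNP × gene × tissue combinations of one invocation; significance
is called on the adjusted p (default FDR 0.05). The family is a
convention, not a theorem — the package documents it and keeps it to one
invocation so the user controls the family by controlling the call.
Untestable records are excluded from the family but still emitted, flagged.

Connections are classified by the minimum base-pair gap between the
variant position and the gene interval: `cis` below 1 Mb on the same
chromosome, `trans_intra` at or above 1 Mb, `trans_inter` across
chromosomes. The boundary at exactly 1 Mb goes to trans (the cis
definition is strictly `< 1 Mb`). Distance is measured to the nearest gene
edge, not the TSS, matching the "between SNP and gene" phrasing of the
underlying method; both choices are flagged in the code where a TSS-based
variant would plug in.

### Genome-wide scan mode

The scan asks the converse question: which variants anywhere in the genome
regulate one target gene? It tests every variant with MAF ≥ 5% against the
target's normalized expression per tissue and retains raw `p < 1e-6` — a
fixed exome-wide threshold rather than FDR, because the scan is a
screening step with a single prespecified response. Hits are grouped into
loci by single-linkage clustering within 1 Mb per chromosome and tissue,
and hit variants are then fed back through the confirmation engine against
*all* genes to enumerate co-regulated genes. The vectorized closed-form
OLS used here is cross-checked against the scalar path (and `stats::lm`)
in the tests.

## 3. Haplotype dosage analysis

Distinct phased haplotypes over the locus's variant sites are clustered on
Euclidean distance with Ward's minimum-variance criterion in its
squared-dissimilarity form (`stats::hclust`, method `"ward.D2"`; the
unsquared `"ward.D"` variant sits behind a flag). The tree is cut at
k = 2, and the cluster with the higher mean alternate-allele load at the
designated tag sites is labelled **A**. Distinct haplotypes are clustered
unweighted — the dendrogram describes haplotype structure, not cohort
frequencies — with a count-weighted mode behind a flag. Haplotypes are
sorted by identifier before clustering, which makes the output invariant
to input order (a tested property; `hclust` itself breaks merge ties by
input position).

Individuals carry two haplotypes, hence a cluster-A allele dosage of 0, 1
or 2 (groups 3, 2, 1). Carriers of known function-altering coding
mutations are removed before association — their strong primary effect
would otherwise confound the modifier-haplotype signal — using a default
exclusion list that can be overridden.

The additive model regresses a phenotype on dosage: the heterozygote
expectation sits midway between the homozygotes, and the slope is the
effect per cluster-A allele in phenotype units (years, for onset and
diagnosis age). The report carries the Pearson correlation and its
two-sided p, the slope and standard error, per-group means and the
group 1 − group 3 difference. Relabelling A and B negates r and the slope
exactly (tested). Multiple phenotypes are tested separately without
multiplicity correction, mirroring how such cohort analyses are reported;
a BH option exists downstream since all p-values are returned.

## 4. Constraint summaries

Genes reached by significant eQTLs are grouped by connection class and
summarized against the unconnected background: the proportion with
pLI ≥ 0.9 and the median pLI. The threshold comparator is `≥` by default
(`strict = TRUE` gives `>`); the even-length median is the midpoint of the
central pair (`stats::median`). These are descriptive summaries — no
enrichment test is attached, because gene lists produced by overlapping
fragment and contact structure violate the independence assumptions of the
usual tests; the honest output is the proportions and medians themselves.

## 5. The synthetic-data generator

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes, so all downstream stages are
testable offline. Its defaults *are* the package's standard study
conditions:

| parameter | default | why |
|---|---|---|
| genome | 3 chromosomes × 200 kb | full pipeline in well under 2 minutes |
| enzyme | MboI | 4-bp cutter: ~256 bp fragments in uniform sequence |
| genes | 20 non-overlapping, 1 target | enough for cis and trans partners |
| variants | 150, MAF ∈ [0.05, 0.5] | a third concentrated at the target locus |
| planted links | 10 contact-supported eQTLs, 1 in 4 trans | trans links are much rarer than cis in contact maps |
| effect size | 1.0 expression sd / allele | resolvable at n = 200 with room to spare |
| expression | 5 tissues × 200 samples, noise sd 1 | typical mid-size tissue panel |
| cohort | 229 individuals, 3 tag + 12 extra sites | the scale of a single-centre sequencing cohort |
| cluster-A frequency | 0.286 | Hardy–Weinberg dosage groups of realistic size |
| onset delay | +2.85 y / allele, noise sd 8.5 y | a ~5.7 y homozygote spread against wide onset dispersion |
| diagnosis lag | Uniform(1, 3) y after onset | makes the two phenotypes highly collinear |
| carriers | 9.2% flagged | ~21 exclusions from 229 |
| pLI | bimodal Beta mixture, intolerant-component probability graded 0.05 / 0.20 / 0.50 / 0.85 by class | reproduces the distance-graded constraint pattern |

Reproducibility: every generator draws from its own stream seeded at
`cfg$seed` plus a fixed offset (genome +101, variants +102, contacts +103,
expression +104, cohort +105, pLI +106, planted-pair selection +107), and
restores the caller's RNG state afterwards. Identical configurations give
byte-identical serialized bundles (tested), and the draw order within each
generator is fixed by the code path, not by input order.

What the generator deliberately does **not** emulate: linkage
disequilibrium beyond the two-cluster haplotype design (genotypes are
independent across variants, so the scan sees no LD shadows around planted
regulators); population stratification; read-level noise; distance decay
in contact frequency (decoy contacts are uniform over fragment pairs); and
covariate structure in expression (the regression hook for a covariate
matrix exists but the generator plants none). Passing tests therefore
demonstrate correctness of the statistical machinery and the planted-signal
recovery, not robustness to LD, stratification or batch effects in real
cohorts.

## 6. Numerical and design choices

* **Coordinates.** 0-based half-open internally everywhere; variant input
  is 1-based (VCF convention) and converted exactly once at parse time. A
  variant exactly on a cut position belongs to the fragment starting there
  (half-open rule) — a deterministic tie-break.
* **Cut-offset convention.** The digestion literature rarely states its
  cut convention; any consistent choice shifts fragment boundaries by at
  most the motif length. The registry makes the offset explicit per enzyme
  and `register_enzyme()` accepts others.
* **Closed-form OLS.** The engine uses the textbook closed form (scalar
  and vectorized) rather than `lm` for speed at scan scale; `lm` and
  `cor.test` serve as oracles in the test suite, never as the
  implementation path being tested.
* **p-value edge cases.** A zero-residual fit returns p = 0 for a nonzero
  slope and p = 1 for a zero slope; negative rounding residue in the
  vectorized sum of squares is clamped at zero.
* **Locus clustering.** Single-linkage within 1 Mb per chromosome — the
  simplest rule that merges a hit cluster into one locus and never merges
  across chromosomes.
* **Scan problem sizes.** The test suite and acceptance script run the
  scan at 60–150 variants × 200 samples and the calibration properties at
  500 tests × 50 seeds — sizes chosen so the full suite completes in
  about a minute on one core while keeping every statistical check
  adequately powered.
* **Known limitations.** No double digests or hg19↔hg38 liftover; no
  contact-significance modelling (presence of a contact is the evidence,
  as in the underlying method); no PEER-style covariate estimation; the
  haplotype stage starts from phased haplotypes and does not phase.

## 7. What the acceptance script recomputes

`scripts/acceptance.R --seed S --out f.json` regenerates the default study
at seed S, runs the installed package end to end and writes the headline
quantities: spatial-pair and significant-record counts, the planted-eQTL
recovery rate, cis/trans record counts, pooled scan loci and hit SNPs,
distinct haplotypes, carrier exclusions, dosage-group sizes, Pearson r and
per-allele slope for onset age, the group 1 − group 3 diagnosis-age
difference, the heterozygote intermediate, and per-class pLI medians and
intolerant proportions. All values are computed at run time from the
generated data; none are stored.
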