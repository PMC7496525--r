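# speqtl

Spatial eQTL mapping from restriction-fragment chromatin contacts, with
haplotype dosage modelling and loss-of-function-constraint summaries.

## The problem

An expression quantitative trait locus (eQTL) is a variant whose genotype
is statistically associated with a gene's expression. A *spatial* eQTL is
additionally supported by physical evidence: a Hi-C chromatin contact
between the restriction fragment carrying the SNP and a fragment
overlapping the gene. Combining the two lines of evidence lets a
regulatory-genomics analysis connect non-coding variants in a disease
locus to the genes they plausibly control — nearby (*cis*, < 1 Mb) or far
away on the same or another chromosome (*trans*) — and then ask whether
those connections matter clinically.

`speqtl` implements that analysis as a reusable R pipeline:

1. **Fragment index** — digital digestion of a genome with a named
   restriction enzyme (MboI `^GATC`, HindIII `A^AGCTT`, extensible
   registry) into fragments that tile each chromosome exactly, plus
   binary-search assignment of variants to fragments.
2. **Spatial pairs** — resolution of fragment–fragment contact tables
   (with cell-line/tissue source labels) and emission of SNP–gene pairs
   whenever a contact links the SNP's fragment to a *distal* fragment
   overlapping a gene. No binning or padding; fragment intervals are used
   verbatim.
3. **eQTL engine** — per-tissue ordinary least squares of rank-normalized
   expression on allele dosage (0/1/2). The slope is the normalized effect
   size (NES, per alternate allele); Benjamini–Hochberg correction is
   applied across all tests of a run and significance is called on the
   *adjusted* p (FDR < 0.05). Connections are classified cis /
   trans-intrachromosomal / trans-interchromosomal at the 1 Mb boundary.
   A genome-wide scan mode tests every common variant (MAF ≥ 5%) against a
   target gene at a fixed exome-wide threshold (P < 1e-6), groups hits
   into 1 Mb loci, and feeds hit variants back through the engine to find
   co-regulated genes.
4. **Haplotype analysis** — Ward clustering (Euclidean distance,
   dissimilarities squared before updating) of phased locus haplotypes
   into clusters A (alternate-allele-rich at tag sites) and B; exclusion
   of coding-mutation carriers; assignment of individuals to dosage groups
   (2/1/0 cluster-A alleles = groups 1/2/3); and additive-model regression
   of phenotypes on dosage, reporting Pearson r, the per-allele slope and
   per-group means.
5. **Constraint enrichment** — per connection class, the proportion of
   connected genes with pLI ≥ 0.9 and the median pLI, against the
   unconnected background.
6. **Synthetic data** — a deterministic generator for every input the
   pipeline consumes (genome, genes, variants, contacts with planted
   SNP–gene links, Hardy–Weinberg genotypes, per-tissue expression with
   planted additive effects, a two-cluster haplotype cohort with a planted
   per-allele onset delay, a bimodal pLI table), so the whole pipeline
   runs and is tested offline.

## Worked example

```r
library(speqtl)

cfg    <- synthetic_config(seed = 1)          # default toy study
bundle <- simulate_bundle(cfg, dir = "demo_inputs")

pc <- pipeline_config(input_dir = "demo_inputs", out_dir = "demo_out",
                      tag_sites = bundle$cohort$tag_sites)

locus <- run_locus_analysis(pc)
locus$connection_counts
#>         class n_records n_pairs
#> 1         cis        40       8
#> 2 trans_intra         0       0
#> 3 trans_inter        10       2
```

Fifty of the tested SNP–gene–tissue records are significant at FDR 0.05;
cis connections outnumber trans, as expected of fragment-level contact
maps. Each record carries its effect size and class:

```r
head(subset(locus$records, significant), 4)
#>        rsid gene_id     tissue       nes   p_adjusted connection_class
#> 31 rs000030     G19      blood 0.8123104 2.892723e-20              cis
#> 32 rs000030     G19 cerebellum 0.7300114 6.282182e-16              cis
#> 33 rs000030     G19     cortex 0.8315608 2.064085e-21              cis
#> 34 rs000030     G19      liver 0.6272661 9.243435e-12              cis
```

The cohort stage clusters haplotypes, drops coding-mutation carriers
(24 of 229 here), and tests the additive dosage model:

```r
cohort <- run_cohort_analysis(pc)
cohort$group_summary
#>   group dosage   n mean_onset_age mean_diagnosis_age
#> 1     1      2  12       67.41354           69.41070
#> 2     2      1  82       63.07692           65.02257
#> 3     3      0 111       60.30744           62.24925
r <- cohort$regressions$onset_age
sprintf("onset: r = %.2f (p = %.2g), %+.2f years per cluster-A allele",
        r$pearson_r, r$p_value, r$slope)
#> "onset: r = 0.22 (p = 0.0017), +3.14 years per cluster-A allele"
```

The generator planted +2.85 years of onset delay per cluster-A allele; the
recovered slope (+3.14, SE ≈ 0.99) and the ordered group means show the
heterozygotes sitting between the homozygote groups, the signature of an
additive effect. Finally, constraint by connection distance:

```r
run_pli_summary(pc, records = locus$records)
#>         class n_genes n_missing_pli proportion_intolerant median_pli
#> 1  background      13             0                   0.0 0.05133755
#> 2         cis       5             0                   0.2 0.17699246
#> 3 trans_intra       0             0                    NA         NA
#> 4 trans_inter       2             0                   1.0 0.96814009
```

Genes reached over longer distances carry more loss-of-function-intolerant
mass — the planted gradient, recovered.

A thin CLI over the same functions is installed at
`inst/cli/speqtl.R` (`Rscript speqtl.R simulate|digest|pairs|eqtl|scan|cohort|pli|all ...`).

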