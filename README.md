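# florin

Integrative multi-omic analysis of a late-flowering phenotype in a
woody fruit species: a case/control genome scan for candidate loci,
differential expression of mRNAs / lncRNAs / miRNAs between normal
(NF) and late (LF) flowering buds, and inference of competing
endogenous RNA (ceRNA) triplets that tie the two together. The package
is aimed at plant genomicists who want each stage of such an analysis
— normally scattered across a dozen external tools — as tested,
deterministic R functions over standard formats (GFF3, FASTA, VCF,
TSV), plus a synthetic-data generator that makes the whole pipeline
verifiable end to end.

## What it computes

**Differential expression.** FPKM ($10^9 c_{is}/(L_i N_s)$) and TPM
normalisation; a pooled exact conditional test per feature with
Benjamini–Hochberg correction; class-specific calling at
$|\log_2 \text{ratio}| \ge 1$ with $q \le 0.001$ (mRNA/lncRNA) or
$q \le 0.1$ (miRNA).

**miRNA response elements (MREs).** Plant-style position-weighted
complementarity scoring (mismatch 1, G:U wobble 0.5, penalties doubled
over miRNA positions 2–13, cutoff 4.0).

**lncRNA targets.** *cis* by a strand-aware genomic window (10 kb
upstream / 20 kb downstream of the mRNA) and *trans* by an additive
antisense duplex-energy surrogate (G:C −3, A:T −2, G:U −1; cutoff −30),
each additionally requiring Spearman and Pearson correlations ≥ 0.6.

**ceRNA triplets.** For an (mRNA, lncRNA) pair with $K$ and $n$
targeting miRNAs out of a universe of $N$ and $k$ shared, the
hypergeometric upper tail

$$p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} \Big/ \binom{N}{n}$$

selects pairs sharing more miRNAs than chance; triplets additionally
require all members differentially expressed with the mRNA and lncRNA
opposing the shared miRNA.

**GWAS candidates.** Genotype QC (missing rate < 0.2, MAF > 0.05),
Cochran–Armitage trend test per SNP, Bonferroni threshold
$-\log_{10}(\alpha/m)$, ±10 kb candidate regions with gene overlap,
best-dichotomy genotype–phenotype concordance, and promoter G-box
(`TACGTG`) disruption annotation for candidate SNPs.

## Worked example

Simulate a dataset with one planted ceRNA triplet (coupling 0.9,
planted DE on all three members, planted MREs, a background MRE
universe of 24 miRNAs) and one causal promoter SNP (penetrance 0.95),
then recover both:

```r
library(florin)

design <- simulation_design(
  seed = 11, n_mrna = 12, n_lncrna = 10, n_mirna = 24,
  n_reps_per_condition = 4,
  planted_de = data.frame(feature_id = c("mRNA_001", "lncRNA_001", "miR_01"),
                          log2_effect = c(-2.5, -2.5, 2.5)),
  planted_triplets = data.frame(mrna_id = "mRNA_001", lncrna_id = "lncRNA_001",
                                mirna_id = "miR_01", coupling = 0.9))
plan <- rbind(
  data.frame(transcript_id = c("mRNA_001", "lncRNA_001"),
             mirna_id = "miR_01", score = c(0, 1)),
  data.frame(transcript_id = rep(sprintf("mRNA_%03d", 2:12), length.out = 23),
             mirna_id = sprintf("miR_%02d", 2:24), score = 0))
sim <- simulate_dataset(design, mre_plan = plan)

res <- run_triplet_analysis(sim)
res$triplets[, c("mrna_id", "lncrna_id", "mirna_id", "k_shared", "N",
                 "p_shared", "mrna_dir", "mirna_dir")]
#>    mrna_id  lncrna_id mirna_id k_shared  N   p_shared mrna_dir mirna_dir
#> 1 mRNA_001 lncRNA_001   miR_01        1 24 0.04166667     down        up
```

The planted triplet is the only one emitted: the pair shares its one
miRNA out of a 24-miRNA universe (p = 1/24), and the direction
constraint holds (mRNA and lncRNA down in LF, miRNA up).

```r
gw <- run_gwas_analysis(sim$genotypes, sim$phenotypes, sim$annotation)
round(gw$threshold, 3)
#> [1] 4.591
gw$assoc[gw$top, c("chrom", "pos", "neg_log10_p")]
#>      chrom     pos neg_log10_p
#> 1985  chr1 2893182    14.86
gw$regions[, c("chrom", "start", "end")]
#>   chrom   start     end
#> 1  chr1 2883182 2903182
sim$genotype_truth$causal_pos
#> [1] 2893182
```

The causal SNP tops the scan (−log10 p = 14.86 against a Bonferroni
cutoff of 4.59), its genotypes agree with the NF/LF classes for 98.5%
of accessions, and the ±10 kb candidate region contains it. Finally,
the SNP disrupts the planted promoter G-box:

```r
hits <- motif_scan(sim$promoter[[1]], seq_id = "promoter")
snp_motif_disruption(list(pos = sim$genotype_truth$promoter_snp_pos,
                          ref = sim$genotype_truth$ref,
                          alt = sim$genotype_truth$alt),
                     hits, sim$promoter[[1]])
#>     seq_id start  end strand  motif disrupted
#> 1 promoter  1000 1005      + TACGTG      TRUE
```

See `vignettes/integrative-late-flowering-analysis.Rmd` for the models,
their assumptions and the design decisions.

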