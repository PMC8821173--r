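#' Analysis thresholds
#'
#' Bundles every tunable cutoff the pipeline uses in one place, with the
#' study defaults: genes (mRNA/lncRNA) are called differentially expressed
#' at |log2 ratio| >= 1 and BH-adjusted p <= 0.001, miRNAs at adjusted
#' p <= 0.1; lncRNA-mRNA pairs require Spearman rho >= 0.6 and Pearson
#' r >= 0.6; the cis window extends 10 kb upstream and 20 kb downstream of
#' the mRNA; trans pairs need duplex energy below -30 (surrogate units);
#' MRE calls accept penalty scores up to 4; genotype QC keeps SNPs with
#' missing rate < 0.2 and MAF > 0.05 (both strict); candidate regions pad
#' significant SNPs by +/- 10 kb; the family-wise level is 0.05.
#'
#' @param de_lfc_min minimum |log2 ratio| for differential expression.
#' @param de_q_gene BH-adjusted p cutoff for mRNA/lncRNA.
#' @param de_q_mirna BH-adjusted p cutoff for miRNA.
#' @param cor_min minimum for both Spearman and Pearson correlations.
#' @param cis_up,cis_down cis window pads (nt) upstream/downstream of the
#'   mRNA, strand-aware.
#' @param energy_max trans relationship requires duplex energy strictly
#'   below this (negative) value.
#' @param mre_cutoff maximum MRE penalty score retained.
#' @param alpha family-wise significance level for the Bonferroni cutoff.
#' @param maf_min QC keeps SNPs with MAF strictly above this.
#' @param miss_max QC keeps SNPs with missing rate strictly below this.
#' @param region_pad half-width (nt) of candidate regions around
#'   significant SNPs.
#' @return a list of class `"florin_thresholds"`.
#' @export
default_thresholds <- function(de_lfc_min = 1.0,
                               de_q_gene = 0.001,
                               de_q_mirna = 0.1,
                               cor_min = 0.6,
                               cis_up = 10000L,
                               cis_down = 20000L,
                               energy_max = -30,
                               mre_cutoff = 4.0,
                               alpha = 0.05,
                               maf_min = 0.05,
                               miss_max = 0.2,
                               region_pad = 10000L) {
  th <- list(de_lfc_min = de_lfc_min, de_q_gene = de_q_gene,
             de_q_mirna = de_q_mirna, cor_min = cor_min,
             cis_up = as.integer(cis_up), cis_down = as.integer(cis_down),
             energy_max = energy_max, mre_cutoff = mre_cutoff,
             alpha = alpha, maf_min = maf_min, miss_max = miss_max,
             region_pad = as.integer(region_pad))
  stopifnot(th$de_lfc_min > 0, th$de_q_gene > 0, th$de_q_mirna > 0,
            th$cor_min > 0, th$cis_up > 0, th$cis_down > 0,
            th$energy_max < 0, th$mre_cutoff >= 0,
            th$alpha > 0, th$alpha < 1, th$maf_min > 0, th$miss_max > 0,
            th$region_pad >= 0)
  class(th) <- "florin_thresholds"
  th
}
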