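#' End-to-end ceRNA triplet analysis on a simulated or assembled dataset
#'
#' Splits the count matrix by feature class, runs the class-specific
#' differential-expression calls (NF reference vs LF), predicts MREs on
#' all transcripts, and assembles direction-constrained triplets with the
#' shared-MRE hypergeometric test.
#'
#' @param sim a [simulate_dataset()] result, or any list with the same
#'   components (`annotation`, `mirnas`, `transcripts`,
#'   `expression$counts`).
#' @param thresholds a [default_thresholds()] list.
#' @param p_cutoff shared-MRE significance cutoff.
#' @return list with `de` (per-class full DE tables), `de_filtered`,
#'   `mres`, `triplets`.
#' @export
run_triplet_analysis <- function(sim, thresholds = default_thresholds(),
                                 p_cutoff = 0.05) {
  counts <- sim$expression$counts
  cond <- em_conditions(counts)
  ids <- list(mrna = sim$annotation$id[sim$annotation$biotype == "mRNA"],
              lncrna = sim$annotation$id[sim$annotation$biotype == "lncRNA"],
              mirna = names(sim$mirnas))
  class_of <- c(mrna = "gene", lncrna = "gene", mirna = "miRNA")
  de <- lapply(names(ids), function(cl) {
    em <- expression_matrix(unclass(counts)[ids[[cl]], , drop = FALSE],
                            unit = "count", conditions = cond)
    de_analysis(em, "NF", "LF", feature_class = class_of[[cl]],
                thresholds = thresholds)
  })
  names(de) <- names(ids)
  de_filtered <- list(
    mrna = filter_de(de$mrna, "gene", thresholds),
    lncrna = filter_de(de$lncrna, "gene", thresholds),
    mirna = filter_de(de$mirna, "miRNA", thresholds))
  mres <- find_targets(sim$mirnas, sim$transcripts,
                       cutoff = thresholds$mre_cutoff)
  triplets <- select_triplets(de_filtered$mrna, de_filtered$lncrna,
                              de_filtered$mirna, mres,
                              p_cutoff = p_cutoff)
  list(de = de, de_filtered = de_filtered, mres = mres,
       triplets = triplets)
}

#' End-to-end GWAS candidate analysis
#'
#' Runs genotype QC, the trend-test association scan with Bonferroni
#' thresholding, candidate-region extraction with gene overlap, and (for
#' the top SNP) genotype-phenotype concordance.
#'
#' @param genotypes a [genotype_calls()] object.
#' @param phenotypes named character vector of classes.
#' @param annotation optional `gene_annotation` for region gene overlap.
#' @param thresholds a [default_thresholds()] list.
#' @return list with `assoc` (per-SNP results), `threshold`, `regions`,
#'   `top` (row index of the smallest p) and `top_concordance`.
#' @export
run_gwas_analysis <- function(genotypes, phenotypes, annotation = NULL,
                              thresholds = default_thresholds()) {
  qc <- qc_filter(genotypes, thresholds)
  assoc <- association_scan(qc, phenotypes, alpha = thresholds$alpha)
  regions <- candidate_regions(assoc, annotation,
                               pad = thresholds$region_pad)
  top <- if (any(assoc$testable)) which.min(assoc$p_value) else NA_integer_
  top_conc <- if (!is.na(top)) {
    concordance(qc$codes[top, ], phenotypes[colnames(qc$codes)])
  } else NA_real_
  list(assoc = assoc, threshold = attr(assoc, "threshold"),
       regions = regions, genotypes_qc = qc, top = top,
       top_concordance = top_conc)
}
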