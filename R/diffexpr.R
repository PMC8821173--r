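#' FPKM normalisation
#'
#' Fragments per kilobase per million mapped fragments:
#' \eqn{FPKM_{is} = 10^9 \, c_{is} / (L_i \, N_s)} with \eqn{c_{is}} the
#' count, \eqn{L_i} the feature length in nt and \eqn{N_s} the per-sample
#' library size (column sum). A zero library size yields an all-zero
#' column with a warning.
#'
#' @param counts an [expression_matrix()] with unit `"count"`.
#' @param lengths named numeric vector of feature lengths (nt) covering
#'   every feature in `counts`.
#' @return an [expression_matrix()] with unit `"FPKM"`.
#' @export
compute_fpkm <- function(counts, lengths) {
  stopifnot(inherits(counts, "expression_matrix"),
            em_unit(counts) == "count")
  len <- check_lengths(lengths, rownames(counts))
  libsize <- colSums(counts)
  zero <- libsize == 0
  if (any(zero)) {
    warning("sample(s) with zero library size: ",
            paste(colnames(counts)[zero], collapse = ", "))
    libsize[zero] <- 1  # column is all zero anyway
  }
  fpkm <- unclass(counts) * 1e9 / (len %o% libsize)
  expression_matrix(fpkm, unit = "FPKM", conditions = em_conditions(counts))
}

#' TPM normalisation
#'
#' Transcripts per kilobase million: per-sample length-normalised rates
#' \eqn{r_{is} = c_{is}/L_i} rescaled so each non-empty sample column sums
#' to \eqn{10^6}. An all-zero sample stays all zero, with a warning.
#'
#' @inheritParams compute_fpkm
#' @return an [expression_matrix()] with unit `"TPM"`.
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(inherits(counts, "expression_matrix"),
            em_unit(counts) == "count")
  len <- check_lengths(lengths, rownames(counts))
  rate <- unclass(counts) / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero sample(s): ", paste(colnames(counts)[zero],
                                          collapse = ", "))
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  expression_matrix(tpm, unit = "TPM", conditions = em_conditions(counts))
}

check_lengths <- function(lengths, features) {
  miss <- setdiff(features, names(lengths))
  if (length(miss)) {
    stop("missing length for feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  len <- as.numeric(lengths[features])
  if (any(len <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  len
}

#' Two-condition differential-expression test on pooled counts
#'
#' Counts are pooled within each condition (replicates summed). The
#' reported effect is `log2_ratio = log2((pool_b' + pc) / (pool_a' + pc))`
#' where the pools are first scaled to the mean pooled library size
#' (library-size scaling) and `pc` is a pseudocount guarding against
#' zeros. The p-value comes from the exact two-sided conditional test on
#' the 2x2 table (feature pooled count vs rest of library, condition a vs
#' b), two-sidedness by the minimum-likelihood rule (all tables with
#' probability <= that of the observed table are summed).
#'
#' @param counts an [expression_matrix()] with unit `"count"`.
#' @param group_a,group_b condition labels; the ratio is b over a (by
#'   convention a = NF reference, b = LF).
#' @param pseudocount added to the scaled pools for the ratio only, not
#'   the test.
#' @return data frame with columns `feature_id`, `log2_ratio`, `p_value`.
#' @export
de_test <- function(counts, group_a = "NF", group_b = "LF",
                    pseudocount = 1) {
  stopifnot(inherits(counts, "expression_matrix"),
            em_unit(counts) == "count")
  cond <- em_conditions(counts)
  if (!group_a %in% cond) stop("no samples with condition '", group_a, "'",
                               call. = FALSE)
  if (!group_b %in% cond) stop("no samples with condition '", group_b, "'",
                               call. = FALSE)
  m <- unclass(counts)
  pool_a <- rowSums(m[, cond == group_a, drop = FALSE])
  pool_b <- rowSums(m[, cond == group_b, drop = FALSE])
  la <- sum(pool_a)
  lb <- sum(pool_b)
  lbar <- (la + lb) / 2
  sa <- if (la > 0) pool_a * lbar / la else pool_a
  sb <- if (lb > 0) pool_b * lbar / lb else pool_b
  lfc <- log2((sb + pseudocount) / (sa + pseudocount))
  p <- vapply(seq_along(pool_a), function(i) {
    tab <- matrix(c(pool_a[i], la - pool_a[i],
                    pool_b[i], lb - pool_b[i]), nrow = 2)
    if (sum(tab[1, ]) == 0 || la == 0 || lb == 0) return(1)
    stats::fisher.test(round(tab), conf.int = FALSE)$p.value
  }, numeric(1))
  data.frame(feature_id = rownames(m), log2_ratio = lfc,
             p_value = pmin(p, 1), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1 and mapped back to input order.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return vector of adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Full differential-expression call for one feature class
#'
#' Runs [de_test()], adjusts with [bh_adjust()], and labels the direction
#' of each feature that passes the class-specific thresholds (`up` =
#' higher in `group_b`; `ns` otherwise).
#'
#' @inheritParams de_test
#' @param feature_class `"gene"` (mRNA/lncRNA; q cutoff 0.001) or
#'   `"miRNA"` (q cutoff 0.1).
#' @param thresholds a [default_thresholds()] list.
#' @return data frame with columns `feature_id`, `log2_ratio`, `p_value`,
#'   `q_value`, `direction`.
#' @export
de_analysis <- function(counts, group_a = "NF", group_b = "LF",
                        feature_class = c("gene", "miRNA"),
                        thresholds = default_thresholds(),
                        pseudocount = 1) {
  feature_class <- match.arg(feature_class)
  res <- de_test(counts, group_a, group_b, pseudocount)
  res$q_value <- bh_adjust(res$p_value)
  q_max <- if (feature_class == "gene") thresholds$de_q_gene else
    thresholds$de_q_mirna
  pass <- abs(res$log2_ratio) >= thresholds$de_lfc_min & res$q_value <= q_max
  res$direction <- ifelse(!pass, "ns",
                          ifelse(res$log2_ratio > 0, "up", "down"))
  res
}

#' Filter differential-expression results at the study thresholds
#'
#' Keeps features with |log2 ratio| >= 1 and BH-adjusted p below the
#' class-specific cutoff (<= 0.001 for genes, <= 0.1 for miRNAs), both
#' comparisons inclusive. Direction is set from the sign of the ratio.
#'
#' @param results data frame from [de_analysis()] (columns `log2_ratio`
#'   and `q_value` required).
#' @param feature_class `"gene"` or `"miRNA"`.
#' @param thresholds a [default_thresholds()] list.
#' @return the retained rows, `direction` populated with `up`/`down`.
#' @export
filter_de <- function(results, feature_class = c("gene", "miRNA"),
                      thresholds = default_thresholds()) {
  feature_class <- match.arg(feature_class)
  stopifnot(all(c("log2_ratio", "q_value") %in% names(results)))
  q_max <- if (feature_class == "gene") thresholds$de_q_gene else
    thresholds$de_q_mirna
  keep <- abs(results$log2_ratio) >= thresholds$de_lfc_min &
    results$q_value <= q_max
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2_ratio > 0, "up", "down")
  rownames(out) <- NULL
  out
}
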