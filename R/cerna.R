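#' Upper-tail hypergeometric test for shared miRNAs
#'
#' Probability of observing at least `k` shared miRNAs between the target
#' sets of an mRNA and a lncRNA under random draws from a universe of `N`
#' miRNAs: `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, where `K`
#' miRNAs target the mRNA and `n` the lncRNA. `k = 0` gives exactly 1.
#'
#' @param N universe size: distinct miRNAs with at least one predicted
#'   MRE anywhere in the dataset.
#' @param K number of miRNAs targeting the mRNA.
#' @param n number of miRNAs targeting the lncRNA.
#' @param k number of shared miRNAs.
#' @return the upper-tail p-value in (0, 1].
#' @export
hypergeom_shared <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) assert_scalar_number(v, "arg")
  if (K > N || n > N) stop("K and n must not exceed N", call. = FALSE)
  if (k < 0 || k > min(K, n)) stop("k must lie in [0, min(K, n)]",
                                   call. = FALSE)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Assemble ceRNA triplets from shared, direction-opposed MREs
#'
#' Emits (mRNA, lncRNA, miRNA) triplets satisfying the three selection
#' criteria: (1) all three members pass their differential-expression
#' filters; (2) the miRNA has a predicted MRE on both the mRNA and the
#' lncRNA (the shared-MRE reading of [same_mre()]); (3) the mRNA and
#' lncRNA change in the same direction, opposite to the miRNA. In
#' addition the full miRNA target sets of the pair must share
#' significantly more miRNAs than chance under [hypergeom_shared()]
#' (`p <= p_cutoff`). Pairwise expression correlations are reported for
#' audit when expression matrices are supplied, but are not thresholded
#' here.
#'
#' @param de_mrna,de_lncrna,de_mirna filtered DE tables ([filter_de()]
#'   output; columns `feature_id`, `direction`).
#' @param mres MRE table from [find_targets()].
#' @param expr_mrna,expr_lncrna,expr_mirna optional [expression_matrix()]
#'   objects (shared sample columns) for the audit correlations.
#' @param p_cutoff shared-MRE significance cutoff (default 0.05; no
#'   multiplicity correction across pairs unless `adjust = TRUE`).
#' @param adjust apply BH across tested pairs before the cutoff.
#' @param focus optional character vector restricting the mRNAs
#'   considered (e.g. a pathway gene list).
#' @return data frame with one row per triplet: ids, the hypergeometric
#'   test fields (`N`, `K`, `n_lnc`, `k_shared`, `p_shared`), the three
#'   DE directions and the three audit correlations (`NA` when
#'   expression was not supplied).
#' @export
select_triplets <- function(de_mrna, de_lncrna, de_mirna, mres,
                            expr_mrna = NULL, expr_lncrna = NULL,
                            expr_mirna = NULL, p_cutoff = 0.05,
                            adjust = FALSE, focus = NULL) {
  empty <- data.frame(mrna_id = character(), lncrna_id = character(),
                      mirna_id = character(), N = integer(), K = integer(),
                      n_lnc = integer(), k_shared = integer(),
                      p_shared = numeric(), mrna_dir = character(),
                      lncrna_dir = character(), mirna_dir = character(),
                      mrna_mirna_cor = numeric(),
                      lncrna_mirna_cor = numeric(),
                      mrna_lncrna_cor = numeric(), stringsAsFactors = FALSE)
  if (!nrow(de_mrna) || !nrow(de_lncrna) || !nrow(de_mirna) || !nrow(mres)) {
    return(empty)
  }
  # universe: distinct miRNAs with >= 1 predicted MRE in the dataset
  N <- length(unique(mres$mirna_id))
  targets_of <- split(mres$mirna_id, mres$transcript_id)
  targets_of <- lapply(targets_of, unique)
  mrna_ids <- de_mrna$feature_id
  if (!is.null(focus)) mrna_ids <- intersect(mrna_ids, focus)
  mrna_ids <- intersect(mrna_ids, names(targets_of))
  lnc_ids <- intersect(de_lncrna$feature_id, names(targets_of))
  if (!length(mrna_ids) || !length(lnc_ids)) return(empty)
  dir_of <- function(de) stats::setNames(de$direction, de$feature_id)
  dm <- dir_of(de_mrna); dl <- dir_of(de_lncrna); di <- dir_of(de_mirna)
  de_mirna_ids <- de_mirna$feature_id

  rows <- list()
  for (mid in mrna_ids) {
    tm <- targets_of[[mid]]
    for (lid in lnc_ids) {
      tl <- targets_of[[lid]]
      shared <- intersect(tm, tl)
      p <- hypergeom_shared(N, length(tm), length(tl), length(shared))
      shared_de <- intersect(shared, de_mirna_ids)
      for (qid in shared_de) {
        ok_dir <- dm[[mid]] == dl[[lid]] && dm[[mid]] != di[[qid]]
        if (!ok_dir) next
        rows[[length(rows) + 1L]] <- data.frame(
          mrna_id = mid, lncrna_id = lid, mirna_id = qid, N = N,
          K = length(tm), n_lnc = length(tl), k_shared = length(shared),
          p_shared = p, mrna_dir = dm[[mid]], lncrna_dir = dl[[lid]],
          mirna_dir = di[[qid]],
          mrna_mirna_cor = audit_cor(expr_mrna, mid, expr_mirna, qid),
          lncrna_mirna_cor = audit_cor(expr_lncrna, lid, expr_mirna, qid),
          mrna_lncrna_cor = audit_cor(expr_mrna, mid, expr_lncrna, lid),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (adjust) {
    # one test per distinct (mRNA, lncRNA) pair; BH across pairs
    pair_key <- paste(out$mrna_id, out$lncrna_id, sep = "\r")
    upair <- !duplicated(pair_key)
    q <- bh_adjust(out$p_shared[upair])
    out$p_shared <- q[match(pair_key, pair_key[upair])]
  }
  out <- out[out$p_shared <= p_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

audit_cor <- function(em_a, id_a, em_b, id_b) {
  if (is.null(em_a) || is.null(em_b)) return(NA_real_)
  if (!id_a %in% rownames(em_a) || !id_b %in% rownames(em_b)) {
    return(NA_real_)
  }
  unname(correlation_pair(unclass(em_a)[id_a, ],
                          unclass(em_b)[id_b, ])["pearson"])
}

#' Build the regulatory network from triplets and lncRNA-mRNA pairs
#'
#' Per triplet: directed edges miRNA->mRNA and miRNA->lncRNA. Per
#' classified lncRNA-mRNA pair whose two endpoints are both network
#' nodes: an edge tagged by its cis/trans relation. Duplicate edges are
#' collapsed.
#'
#' @param triplets [select_triplets()] output.
#' @param lnc_pairs optional [classify_pairs()] output (rows with
#'   relation `none` are ignored).
#' @return data frame of network edges (`source`, `target`, `kind`).
#' @export
build_network <- function(triplets, lnc_pairs = NULL) {
  edges <- data.frame(source = character(), target = character(),
                      kind = character(), stringsAsFactors = FALSE)
  if (nrow(triplets)) {
    edges <- rbind(
      data.frame(source = triplets$mirna_id, target = triplets$mrna_id,
                 kind = "miRNA->mRNA", stringsAsFactors = FALSE),
      data.frame(source = triplets$mirna_id, target = triplets$lncrna_id,
                 kind = "miRNA->lncRNA", stringsAsFactors = FALSE))
  }
  if (!is.null(lnc_pairs) && nrow(lnc_pairs)) {
    nodes <- unique(c(triplets$mrna_id, triplets$lncrna_id,
                      triplets$mirna_id))
    lp <- lnc_pairs[lnc_pairs$relation %in% c("cis", "trans") &
                      lnc_pairs$lncrna_id %in% nodes &
                      lnc_pairs$mrna_id %in% nodes, , drop = FALSE]
    if (nrow(lp)) {
      edges <- rbind(edges, data.frame(
        source = lp$lncrna_id, target = lp$mrna_id,
        kind = sprintf("lncRNA-mRNA(%s)", lp$relation),
        stringsAsFactors = FALSE))
    }
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  validate_edges(edges)
}
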