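#' Candidate cis lncRNA-mRNA pairs by genomic window
#'
#' A lncRNA is a cis candidate of an mRNA if their loci lie on the same
#' chromosome and the lncRNA interval intersects (boundary-touching
#' counts) the strand-aware window around the mRNA: 10 kb past the 5' end
#' and 20 kb past the 3' end of the gene (pads swap genomic sides on the
#' minus strand).
#'
#' @param annotation a `gene_annotation` data frame with both biotypes.
#' @param thresholds a [default_thresholds()] list (`cis_up`, `cis_down`).
#' @return data frame with columns `lncrna_id`, `mrna_id`, one row per
#'   candidate pair.
#' @export
cis_candidates <- function(annotation, thresholds = default_thresholds()) {
  annotation <- validate_annotation(annotation)
  mrna <- annotation[annotation$biotype == "mRNA", , drop = FALSE]
  lnc <- annotation[annotation$biotype == "lncRNA", , drop = FALSE]
  empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(mrna) || !nrow(lnc)) return(empty)
  plus <- mrna$strand == "+"
  win_start <- ifelse(plus, mrna$start - thresholds$cis_up,
                      mrna$start - thresholds$cis_down)
  win_end <- ifelse(plus, mrna$end + thresholds$cis_down,
                    mrna$end + thresholds$cis_up)
  win <- GenomicRanges::GRanges(
    mrna$chrom, IRanges::IRanges(pmax(win_start, 1), win_end))
  lgr <- GenomicRanges::GRanges(lnc$chrom,
                                IRanges::IRanges(lnc$start, lnc$end))
  ov <- GenomicRanges::findOverlaps(lgr, win)
  if (!length(ov)) return(empty)
  pairs <- unique(data.frame(
    lncrna_id = lnc$id[S4Vectors::queryHits(ov)],
    mrna_id = mrna$id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  pairs
}

#' Spearman and Pearson correlation of two expression profiles
#'
#' Midranks are used for ties in the Spearman statistic. A zero-variance
#' vector yields `NA` correlations, which downstream filters treat as a
#' failure.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return named numeric vector `c(spearman = ..., pearson = ...)`.
#' @export
correlation_pair <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(spearman = NA_real_, pearson = NA_real_))
  }
  c(spearman = stats::cor(x, y, method = "spearman"),
    pearson = stats::cor(x, y, method = "pearson"))
}

# Per-pair duplex energies [base a, base b]: G:C -3, A:T -2, G:U(T) -1,
# non-pairing 0.
pair_energy_matrix <- function() {
  e <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  e["G", "C"] <- -3; e["C", "G"] <- -3
  e["A", "T"] <- -2; e["T", "A"] <- -2
  e["G", "T"] <- -1; e["T", "G"] <- -1
  e
}

#' Surrogate duplex binding energy
#'
#' Additive energy of the single best contiguous, fully paired antisense
#' duplex between two transcripts: over all alignments of `a` against the
#' reversed `b` and all contiguous spans in which every opposed position
#' pairs (Watson-Crick or G:U), the energy is the sum of per-pair values
#' G:C -3, A:T -2, G:U -1. If no position pairs anywhere the energy is 0.
#' More negative = stronger predicted binding; the trans-relationship
#' cutoff (-30 by default) applies to these surrogate units.
#'
#' @param a,b DNA sequences (character scalars).
#' @return scalar energy (<= 0).
#' @export
duplex_energy <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty",
                                     call. = FALSE)
  ea <- encode_dna(a)
  eb <- rev(encode_dna(b))  # antisense orientation
  if (anyNA(ea) || anyNA(eb)) stop("sequences must be over A/C/G/T",
                                   call. = FALSE)
  EM <- pair_energy_matrix()
  na <- length(ea); nb <- length(eb)
  best <- 0
  # a[i] pairs b[j - t] as i advances, i.e. eb index increases with i:
  # scan every diagonal of constant offset q = (eb index) - (a index)
  for (q in (1L - na):(nb - 1L)) {
    ai <- max(1L, 1L - q):min(na, nb - q)
    bi <- ai + q
    e <- EM[cbind(ea[ai], eb[bi])]
    # all per-pair energies are negative, so the best sub-span of a
    # maximal pairing run is the whole run
    r <- rle(e < 0)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cs <- c(0, cumsum(e))
    run_sums <- cs[ends[r$values] + 1L] - cs[starts[r$values]]
    best <- min(best, run_sums)
  }
  best
}

#' Classify lncRNA-mRNA pairs as cis, trans or none
#'
#' A pair is `cis` when the genomic window condition of
#' [cis_candidates()] holds and both correlations (Spearman and Pearson,
#' computed across the shared samples) are >= `cor_min`; otherwise
#' `trans` when [duplex_energy()] is strictly below `energy_max` and both
#' correlations pass; otherwise `none`. Duplex energies are only
#' evaluated for non-cis pairs whose correlations pass (the reported
#' `energy` is `NA` elsewhere). Annotated features without an expression
#' profile or sequence are skipped with a message.
#'
#' @param annotation a `gene_annotation` data frame.
#' @param expr_lnc,expr_mrna [expression_matrix()] objects sharing the
#'   same sample columns.
#' @param sequences named character vector of transcript sequences (needed
#'   for the trans rule).
#' @param thresholds a [default_thresholds()] list.
#' @return data frame with columns `lncrna_id`, `mrna_id`, `relation`,
#'   `spearman`, `pearson`, `energy`.
#' @export
classify_pairs <- function(annotation, expr_lnc, expr_mrna, sequences,
                           thresholds = default_thresholds()) {
  annotation <- validate_annotation(annotation)
  stopifnot(identical(colnames(expr_lnc), colnames(expr_mrna)))
  if (ncol(expr_lnc) < 6) {
    warning("only ", ncol(expr_lnc),
            " samples: correlation estimates are noisy below n = 6")
  }
  lnc_ids <- annotation$id[annotation$biotype == "lncRNA"]
  mrna_ids <- annotation$id[annotation$biotype == "mRNA"]
  drop_l <- setdiff(lnc_ids, rownames(expr_lnc))
  drop_m <- setdiff(mrna_ids, rownames(expr_mrna))
  if (length(drop_l) || length(drop_m)) {
    message(length(drop_l) + length(drop_m),
            " annotated feature(s) without expression skipped")
  }
  lnc_ids <- intersect(lnc_ids, rownames(expr_lnc))
  mrna_ids <- intersect(mrna_ids, rownames(expr_mrna))
  if (!length(lnc_ids) || !length(mrna_ids)) {
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      relation = character(), spearman = numeric(),
                      pearson = numeric(), energy = numeric(),
                      stringsAsFactors = FALSE))
  }
  lmat <- t(unclass(expr_lnc)[lnc_ids, , drop = FALSE])
  mmat <- t(unclass(expr_mrna)[mrna_ids, , drop = FALSE])
  sp <- stats::cor(lmat, mmat, method = "spearman")
  pe <- stats::cor(lmat, mmat, method = "pearson")
  cis <- cis_candidates(annotation, thresholds)
  cis_key <- paste(cis$lncrna_id, cis$mrna_id, sep = "\r")
  grid <- expand.grid(lncrna_id = lnc_ids, mrna_id = mrna_ids,
                      stringsAsFactors = FALSE)
  grid$spearman <- sp[cbind(grid$lncrna_id, grid$mrna_id)]
  grid$pearson <- pe[cbind(grid$lncrna_id, grid$mrna_id)]
  cor_ok <- !is.na(grid$spearman) & !is.na(grid$pearson) &
    grid$spearman >= thresholds$cor_min & grid$pearson >= thresholds$cor_min
  in_cis <- paste(grid$lncrna_id, grid$mrna_id, sep = "\r") %in% cis_key
  grid$relation <- "none"
  grid$relation[in_cis & cor_ok] <- "cis"
  grid$energy <- NA_real_
  maybe_trans <- which(!in_cis & cor_ok)
  for (i in maybe_trans) {
    if (!grid$lncrna_id[i] %in% names(sequences) ||
        !grid$mrna_id[i] %in% names(sequences)) {
      message("pair ", grid$lncrna_id[i], "/", grid$mrna_id[i],
              " skipped: sequence unavailable")
      next
    }
    grid$energy[i] <- duplex_energy(sequences[[grid$lncrna_id[i]]],
                                    sequences[[grid$mrna_id[i]]])
    if (grid$energy[i] < thresholds$energy_max) grid$relation[i] <- "trans"
  }
  grid[, c("lncrna_id", "mrna_id", "relation", "spearman", "pearson",
           "energy")]
}
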