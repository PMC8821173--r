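#' Genotype quality control
#'
#' Keeps biallelic SNPs with missing rate strictly below `miss_max` and
#' minor allele frequency strictly above `maf_min` (MAF computed on
#' non-missing calls). The numbers removed by each filter are reported
#' via a message.
#'
#' @param genotypes a [genotype_calls()] object.
#' @param thresholds a [default_thresholds()] list.
#' @return the filtered [genotype_calls()] object.
#' @export
qc_filter <- function(genotypes, thresholds = default_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_calls"))
  codes <- genotypes$codes
  n_acc <- ncol(codes)
  miss_rate <- rowMeans(is.na(codes))
  n_obs <- n_acc - rowSums(is.na(codes))
  alt_freq <- rowSums(codes, na.rm = TRUE) / (2 * pmax(n_obs, 1))
  maf <- pmin(alt_freq, 1 - alt_freq)
  keep_miss <- miss_rate < thresholds$miss_max
  keep_maf <- maf > thresholds$maf_min
  keep <- keep_miss & keep_maf & n_obs > 0
  message(sum(!keep_miss), " SNP(s) removed by missing-rate filter, ",
          sum(keep_miss & !keep_maf), " by MAF filter")
  genotype_calls(genotypes$snps[keep, , drop = FALSE],
                 codes[keep, , drop = FALSE])
}

# Core Cochran-Armitage computation shared by trend_test and
# association_scan; operates on sufficient statistics.
ca_chisq <- function(N, R, S1, S2, T1) {
  # scores 0/1/2: S1 = sum of genotypes, S2 = sum of squared genotypes,
  # T1 = sum of genotypes among cases, R cases of N.
  pbar <- R / N
  den <- pbar * (1 - pbar) * (S2 - S1^2 / N)
  num <- (T1 - pbar * S1)^2
  chi <- ifelse(den > 0, num / den, NA_real_)
  chi
}

#' Cochran-Armitage trend test for one SNP
#'
#' One-degree-of-freedom chi-square test for a dose-dependent association
#' between alt-allele count (scores 0/1/2) and a two-class phenotype,
#' on the 2x3 class-by-genotype table after dropping missing calls. A
#' genotype that is constant across accessions (or a class with fewer
#' than 2 genotyped accessions) is flagged untestable and excluded from
#' thresholding.
#'
#' @param codes integer vector of genotype codes (0/1/2, `NA` missing).
#' @param classes character/factor vector of phenotype classes, parallel
#'   to `codes`.
#' @param case_class the class treated as cases (default `"LF"`).
#' @return list with `statistic`, `p_value`, `neg_log10_p`, `testable`.
#' @export
trend_test <- function(codes, classes, case_class = "LF") {
  ok <- !is.na(codes)
  g <- codes[ok]
  case <- classes[ok] == case_class
  if (sum(case) < 2L || sum(!case) < 2L) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                neg_log10_p = NA_real_, testable = FALSE))
  }
  if (length(unique(g)) < 2L) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                neg_log10_p = NA_real_, testable = FALSE))
  }
  chi <- ca_chisq(N = length(g), R = sum(case), S1 = sum(g),
                  S2 = sum(g^2), T1 = sum(g[case]))
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  list(statistic = chi, p_value = p, neg_log10_p = -log10(p),
       testable = TRUE)
}

#' Bonferroni threshold on the -log10 scale
#'
#' `-log10(alpha / m)` for family-wise level `alpha` over `m` tests. The
#' unrounded value is returned and should be applied as-is; display at
#' two decimals is a reporting convention.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of tests (>= 1).
#' @return the threshold on the -log10 p scale.
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_scalar_number(alpha, "alpha")
  assert_scalar_number(m, "m")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  -log10(alpha / m)
}

#' Genome-wide case/control association scan
#'
#' Vectorised Cochran-Armitage trend test over all SNPs, with the
#' Bonferroni threshold `-log10(alpha / m)` computed over the `m`
#' testable SNPs. Untestable SNPs (constant genotype) carry `NA`
#' p-values and are never significant.
#'
#' @param genotypes a [genotype_calls()] object (post-QC).
#' @param phenotypes named character vector mapping accession ids to
#'   classes (`NF`/`LF`).
#' @param case_class the class treated as cases.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @return data frame with one row per SNP: `chrom`, `pos`, `statistic`,
#'   `p_value`, `neg_log10_p`, `testable`, `significant`; the threshold
#'   is attached as attribute `"threshold"`.
#' @export
association_scan <- function(genotypes, phenotypes, case_class = "LF",
                             alpha = default_thresholds()$alpha) {
  stopifnot(inherits(genotypes, "genotype_calls"))
  acc <- colnames(genotypes$codes)
  phenotypes <- validate_phenotypes(phenotypes, accessions = acc)
  codes <- genotypes$codes
  case <- phenotypes[acc] == case_class
  obs <- !is.na(codes)
  G <- codes; G[!obs] <- 0L
  N <- rowSums(obs)
  R <- rowSums(obs[, case, drop = FALSE])
  S1 <- rowSums(G)
  S2 <- rowSums(G^2)
  T1 <- rowSums(G[, case, drop = FALSE])
  chi <- ca_chisq(N, R, S1, S2, T1)
  testable <- !is.na(chi) & R >= 2 & (N - R) >= 2
  chi[!testable] <- NA_real_
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  m <- sum(testable)
  thr <- if (m >= 1) bonferroni_threshold(alpha, m) else Inf
  nlp <- -log10(p)
  res <- data.frame(chrom = genotypes$snps$chrom, pos = genotypes$snps$pos,
                    statistic = chi, p_value = p, neg_log10_p = nlp,
                    testable = testable,
                    significant = !is.na(nlp) & nlp >= thr,
                    stringsAsFactors = FALSE)
  attr(res, "threshold") <- thr
  attr(res, "n_tests") <- m
  res
}

#' Candidate regions around significant SNPs
#'
#' Pads each significant SNP by `pad` nt on both sides (clipped at
#' coordinate 1), merges overlapping or touching same-chromosome regions,
#' and attaches overlapping genes by interval intersection.
#'
#' @param assoc association results ([association_scan()] output or any
#'   data frame with `chrom`, `pos`, `significant`).
#' @param annotation optional `gene_annotation` data frame for gene
#'   overlap.
#' @param pad half-width of the region in nt.
#' @return data frame with columns `chrom`, `start`, `end`,
#'   `member_snps` (list column of SNP positions) and `genes` (list
#'   column of overlapping gene ids).
#' @export
candidate_regions <- function(assoc, annotation = NULL,
                              pad = default_thresholds()$region_pad) {
  stopifnot(pad >= 0)
  sig <- assoc[assoc$significant %in% TRUE, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!nrow(sig)) {
    empty$member_snps <- list()
    empty$genes <- list()
    return(empty)
  }
  gr <- GenomicRanges::GRanges(
    sig$chrom, IRanges::IRanges(pmax(sig$pos - pad, 1), sig$pos + pad))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  snp_gr <- GenomicRanges::GRanges(sig$chrom,
                                   IRanges::IRanges(sig$pos, sig$pos))
  ov <- GenomicRanges::findOverlaps(snp_gr, merged)
  members <- split(sig$pos[S4Vectors::queryHits(ov)],
                   S4Vectors::subjectHits(ov))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged), stringsAsFactors = FALSE)
  out$member_snps <- lapply(seq_len(nrow(out)), function(i) {
    sort(unique(members[[as.character(i)]]))
  })
  out$genes <- vector("list", nrow(out))
  if (!is.null(annotation) && nrow(annotation)) {
    agr <- GenomicRanges::GRanges(
      annotation$chrom, IRanges::IRanges(annotation$start, annotation$end))
    gov <- GenomicRanges::findOverlaps(agr, merged)
    gl <- split(annotation$id[S4Vectors::queryHits(gov)],
                S4Vectors::subjectHits(gov))
    for (i in seq_len(nrow(out))) {
      ids <- gl[[as.character(i)]]
      out$genes[[i]] <- if (is.null(ids)) character() else sort(unique(ids))
    }
  } else {
    out$genes <- replicate(nrow(out), character(), simplify = FALSE)
  }
  out
}

#' Genotype-phenotype concordance for one SNP
#'
#' Best-dichotomy concordance: each of the three groupings of genotype
#' codes ({0} vs {1,2}, {0,1} vs {2}, {0,2} vs {1}) is tried with both
#' class assignments, and the maximum fraction of (non-missing)
#' accessions whose side matches their phenotype class is returned. A
#' constant genotype degenerates to the majority-class fraction.
#'
#' @inheritParams trend_test
#' @return fraction in \[0, 1\].
#' @export
concordance <- function(codes, classes, case_class = "LF") {
  ok <- !is.na(codes)
  if (!any(ok)) stop("all genotype calls missing", call. = FALSE)
  g <- codes[ok]
  case <- classes[ok] == case_class
  splits <- list(g >= 1, g >= 2, g == 1)  # {0}|{1,2}, {0,1}|{2}, {0,2}|{1}
  best <- 0
  for (side in splits) {
    best <- max(best, mean(side == case), mean(side != case))
  }
  best
}

#' Scan a sequence for motif occurrences on both strands
#'
#' Exact occurrences of each motif on the forward strand and of its
#' reverse complement (reported with strand `-`), with 1-based inclusive
#' coordinates on the given sequence.
#'
#' @param seq a DNA sequence (character scalar).
#' @param motifs character vector of motifs over A/C/G/T; the default is
#'   the G-box core `TACGTG`.
#' @param seq_id id recorded in the output.
#' @return data frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `motif`.
#' @export
motif_scan <- function(seq, motifs = "TACGTG", seq_id = "seq") {
  subject <- Biostrings::DNAString(seq)
  rows <- list()
  for (motif in motifs) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") motif else revcomp(motif)
      hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject)
      if (length(hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seq_id, start = Biostrings::start(hits),
          end = Biostrings::end(hits), strand = strand, motif = motif,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does a SNP disrupt a motif occurrence?
#'
#' For every motif hit containing the SNP position, the alt allele is
#' substituted into the sequence and the hit window re-tested for
#' membership in the motif set, strand-aware (a minus-strand hit is
#' compared through its reverse complement). The hit is disrupted iff
#' the substituted window matches no motif in the set.
#'
#' @param snp list or one-row data frame with `pos`, `ref`, `alt`
#'   (position on `seq`, 1-based).
#' @param hits [motif_scan()] output for `seq`.
#' @param seq the sequence the hits were found on.
#' @param motifs the motif set used for the re-test (defaults to the
#'   motifs present in `hits`).
#' @return `hits` restricted to windows containing the SNP, with an
#'   added logical column `disrupted`.
#' @export
snp_motif_disruption <- function(snp, hits, seq,
                                 motifs = unique(hits$motif)) {
  pos <- as.integer(snp$pos)
  if (substr(seq, pos, pos) != snp$ref) {
    stop(sprintf("ref allele '%s' does not match sequence base '%s' at %d",
                 snp$ref, substr(seq, pos, pos), pos), call. = FALSE)
  }
  containing <- hits[hits$start <= pos & hits$end >= pos, , drop = FALSE]
  if (!nrow(containing)) {
    containing$disrupted <- logical()
    return(containing)
  }
  mut <- seq
  substr(mut, pos, pos) <- snp$alt
  containing$disrupted <- vapply(seq_len(nrow(containing)), function(i) {
    win <- substr(mut, containing$start[i], containing$end[i])
    if (containing$strand[i] == "-") win <- revcomp(win)
    !win %in% motifs
  }, logical(1))
  rownames(containing) <- NULL
  containing
}
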