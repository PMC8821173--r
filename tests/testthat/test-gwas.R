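toy_genotypes <- function(codes) {
  n <- ncol(codes)
  colnames(codes) <- sprintf("a%02d", seq_len(n))
  genotype_calls(
    data.frame(chrom = "chr1", pos = seq_len(nrow(codes)) * 1000L,
               ref = "A", alt = "G", stringsAsFactors = FALSE), codes)
}

test_that("QC applies strict missing-rate and MAF filters", {
  codes <- rbind(
    rep(0L, 10),                    # monomorphic, MAF 0 -> out
    c(1L, rep(0L, 9)),              # MAF 0.05 exactly -> out (strict >)
    c(1L, 1L, rep(0L, 8)),          # MAF 0.10 -> in
    c(rep(NA_integer_, 2), rep(1L, 8)),  # missing rate 0.2 exactly -> out
    c(NA_integer_, rep(1L, 8), 0L)) # missing 0.1, MAF 0.05... check below
  # row 5: 8 hets + 1 hom-ref among 9 calls -> alt freq 8/18, MAF 8/18 -> in
  gc <- toy_genotypes(codes)
  kept <- suppressMessages(qc_filter(gc))
  expect_equal(kept$snps$pos, c(3000L, 5000L))
  # hand-computed MAFs on a small random matrix
  withr::with_seed(31, {
    m <- matrix(sample(c(0L, 1L, 2L, NA), 50, TRUE,
                       prob = c(.4, .3, .2, .1)), 5, 10)
    gc2 <- toy_genotypes(m)
    kept2 <- suppressMessages(qc_filter(gc2))
    expect_kept <- vapply(1:5, function(i) {
      g <- m[i, ]
      miss <- mean(is.na(g))
      af <- sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
      maf <- min(af, 1 - af)
      miss < 0.2 && maf > 0.05
    }, logical(1))
    expect_equal(nrow(kept2$codes), sum(expect_kept))
  })
})

test_that("trend test matches the closed form and prop.trend.test", {
  # cases (0,0,10) vs controls (10,0,0) across genotypes 0/1/2
  codes <- c(rep(2L, 10), rep(0L, 10))
  classes <- rep(c("LF", "NF"), each = 10)
  got <- trend_test(codes, classes)
  # closed form: N=20, R=10, S1=20, S2=40, T1=20
  pbar <- 0.5
  chi_hand <- (20 - pbar * 20)^2 / (pbar * (1 - pbar) * (40 - 20^2 / 20))
  expect_equal(got$statistic, chi_hand)
  expect_equal(got$statistic, 20)  # perfect separation, scores 0/2
  # cross-check against the stock implementation on random tables
  withr::with_seed(32, {
    for (rep in 1:20) {
      g <- sample(0:2, 40, TRUE)
      cl <- sample(c("NF", "LF"), 40, TRUE, prob = c(0.6, 0.4))
      if (length(unique(g)) < 2 || min(table(cl)) < 2) next
      ours <- trend_test(g, cl)
      x <- tapply(cl == "LF", g, sum)
      n <- table(g)
      ref <- suppressWarnings(
        prop.trend.test(x, n, score = as.numeric(names(n))))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("balanced identical class rows give statistic 0 and constant genotypes are untestable", {
  codes <- rep(c(0L, 1L, 2L), times = 4)
  classes <- rep(c("LF", "NF"), each = 6)
  got <- trend_test(codes, classes)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  flat <- trend_test(rep(1L, 12), classes)
  expect_false(flat$testable)
  expect_true(is.na(flat$p_value))
})

test_that("the vectorised scan reproduces per-SNP trend tests", {
  withr::with_seed(33, {
    codes <- matrix(sample(c(0:2, NA), 300, TRUE, prob = c(.4, .3, .2, .1)),
                    30, 10)
    gc <- toy_genotypes(codes)
    pheno <- setNames(rep(c("NF", "LF"), 5), colnames(gc$codes))
    scan <- association_scan(gc, pheno)
    for (i in seq_len(nrow(codes))) {
      single <- trend_test(codes[i, ], pheno[colnames(gc$codes)])
      expect_equal(scan$p_value[i], single$p_value, tolerance = 1e-12)
    }
  })
})

test_that("Bonferroni threshold is monotone and matches closed forms", {
  expect_equal(bonferroni_threshold(0.05, 1), -log10(0.05))
  expect_equal(bonferroni_threshold(0.01, 100), 4)
  expect_lt(bonferroni_threshold(0.05, 100),
            bonferroni_threshold(0.05, 1000))
  expect_gt(bonferroni_threshold(0.01, 100),
            bonferroni_threshold(0.05, 100))
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("candidate regions pad, clip, merge and attach genes", {
  assoc <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      pos = c(50000L, 55000L, 200000L, 3000L),
                      significant = c(TRUE, TRUE, TRUE, TRUE))
  ann <- gene_annotation(
    id = c("g_in", "g_out"), chrom = c("chr1", "chr1"),
    start = c(45000, 150000), end = c(46000, 151000),
    strand = "+", biotype = "mRNA")
  regions <- candidate_regions(assoc, ann, pad = 10000L)
  expect_equal(nrow(regions), 3L)
  chr1 <- regions[regions$chrom == "chr1", ]
  # SNPs 5 kb apart merge into one region spanning both pads
  expect_equal(chr1$start[1], 40000L)
  expect_equal(chr1$end[1], 65000L)
  expect_equal(chr1$member_snps[[1]], c(50000L, 55000L))
  expect_equal(chr1$genes[[1]], "g_in")
  expect_equal(chr1$genes[[2]], character())
  # clipping at coordinate 1
  chr2 <- regions[regions$chrom == "chr2", ]
  expect_equal(chr2$start, 1L)
  # disjoint and sorted
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
  }
  expect_equal(nrow(candidate_regions(assoc[0, ], ann)), 0L)
})

test_that("concordance is the best over all dichotomies and assignments", {
  # perfect separation
  codes <- c(rep(2L, 5), rep(0L, 5))
  classes <- rep(c("LF", "NF"), each = 5)
  expect_equal(concordance(codes, classes), 1)
  # constant genotype degenerates to the majority-class fraction
  expect_equal(concordance(rep(1L, 10), rep(c("LF", "NF"), c(3, 7))), 0.7)
  # brute force over the 6 dichotomy-assignment combinations
  withr::with_seed(34, {
    for (rep in 1:10) {
      g <- sample(0:2, 66, TRUE)
      cl <- sample(rep(c("LF", "NF"), c(23, 43)))
      sides <- list(g >= 1, g >= 2, g == 1)
      best <- max(vapply(sides, function(s) {
        max(mean(s == (cl == "LF")), mean(s != (cl == "LF")))
      }, numeric(1)))
      expect_equal(concordance(g, cl), best)
    }
  })
})

test_that("motif scanning finds both strands and equals brute force", {
  seqv <- paste0(strrep("A", 10), "TACGTG", strrep("A", 10))
  hits <- motif_scan(seqv)
  expect_equal(hits$start, 11L)
  expect_equal(hits$end, 16L)
  expect_equal(hits$strand, "+")
  # reverse complement of TACGTG = CACGTA -> minus-strand hit
  seqm <- paste0(strrep("A", 5), "CACGTA", strrep("A", 5))
  hm <- motif_scan(seqm)
  expect_equal(hm$strand, "-")
  expect_equal(hm$start, 6L)
  expect_equal(nrow(motif_scan(strrep("A", 50))), 0L)
  withr::with_seed(35, {
    s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
    got <- motif_scan(s, motifs = c("TACGTG", "CACGTG"))
    bf <- motif_bruteforce(s, motifs = c("TACGTG", "CACGTG"))
    key <- function(d) sort(paste(d$start, d$end, d$strand, d$motif))
    expect_equal(key(got), key(bf))
  })
})

test_that("SNP substitution detects motif disruption strand-aware", {
  seqv <- paste0(strrep("A", 10), "TACGTG", strrep("T", 10))
  hits <- motif_scan(seqv)
  # third nucleotide of the G-box is the C at position 13
  dis <- snp_motif_disruption(list(pos = 13, ref = "C", alt = "T"),
                              hits, seqv)
  expect_equal(nrow(dis), 1L)
  expect_true(dis$disrupted)
  # SNP outside all hits -> no records
  none <- snp_motif_disruption(list(pos = 2, ref = "A", alt = "G"),
                               hits, seqv)
  expect_equal(nrow(none), 0L)
  # motif set {TACGTG, CACGTG}: T->C at position 1 still matches the set
  dis2 <- snp_motif_disruption(list(pos = 11, ref = "T", alt = "C"),
                               hits, seqv, motifs = c("TACGTG", "CACGTG"))
  expect_false(dis2$disrupted)
  # ref mismatch errors
  expect_error(snp_motif_disruption(list(pos = 13, ref = "G", alt = "T"),
                                    hits, seqv), "does not match")
  # minus-strand hit: disruption assessed through the reverse complement
  seqm <- paste0(strrep("A", 5), "CACGTA", strrep("G", 5))
  hm <- motif_scan(seqm)
  # position 8 is the C pairing the motif's 4th base G; change breaks it
  dm <- snp_motif_disruption(list(pos = 8, ref = "C", alt = "A"), hm, seqm)
  expect_true(dm$disrupted)
})
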