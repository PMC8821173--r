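# Independent oracles used across the suite. Each re-derives the quantity
# from first principles, by enumeration or brute force, without touching
# the package's implementation path.

# Step-up FDR adjustment straight from the definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Upper-tail shared-miRNA probability by enumerating every n-subset of the
# universe and counting overlaps with the first K elements.
hyper_upper_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Exact rational-arithmetic tail probability through python's fractions
# module (same container image); returns a double.
hyper_upper_fraction <- function(N, K, n, k) {
  script <- paste(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "N,K,n,k = (int(x) for x in sys.argv[1:5])",
    "num = sum(comb(K,i)*comb(N-K,n-i) for i in range(k, min(K,n)+1))",
    "print(float(Fraction(num, comb(N,n))))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), N, K, n, k),
                 stdout = TRUE)
  as.numeric(out)
}

# Best fully paired contiguous antisense duplex by brute force over all
# offsets and spans.
duplex_bruteforce <- function(a, b) {
  pe <- function(x, y) {
    if ((x == "G" && y == "C") || (x == "C" && y == "G")) return(-3)
    if ((x == "A" && y == "T") || (x == "T" && y == "A")) return(-2)
    if ((x == "G" && y == "T") || (x == "T" && y == "G")) return(-1)
    0
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- 0
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      # start pairing a[i] with b[j], extending a forward / b backward
      tot <- 0
      t <- 0
      while (i + t <= length(av) && j - t >= 1) {
        e <- pe(av[i + t], bv[j - t])
        if (e == 0) break
        tot <- tot + e
        best <- min(best, tot)
        t <- t + 1
      }
    }
  }
  best
}

# All-pairs interval check of the strand-aware cis window.
cis_bruteforce <- function(ann, th = florin::default_thresholds()) {
  mrna <- ann[ann$biotype == "mRNA", ]
  lnc <- ann[ann$biotype == "lncRNA", ]
  rows <- list()
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(mrna))) {
      if (lnc$chrom[i] != mrna$chrom[j]) next
      if (mrna$strand[j] == "+") {
        ws <- mrna$start[j] - th$cis_up
        we <- mrna$end[j] + th$cis_down
      } else {
        ws <- mrna$start[j] - th$cis_down
        we <- mrna$end[j] + th$cis_up
      }
      ws <- max(ws, 1)
      if (lnc$start[i] <= we && lnc$end[i] >= ws) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncrna_id = lnc$id[i], mrna_id = mrna$id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Sliding exact comparison on both strands.
motif_bruteforce <- function(seq, motifs) {
  rc <- function(s) rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", s))))
  rows <- list()
  for (motif in motifs) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") motif else rc(motif)
      L <- nchar(pat)
      for (s in seq_len(nchar(seq) - L + 1)) {
        if (substr(seq, s, s + L - 1) == pat) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = s, end = s + L - 1, strand = strand, motif = motif,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), motif = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Double loop over every window of every transcript, scored by
# score_site(), then the stated collapse rule applied naively.
find_targets_bruteforce <- function(mirnas, transcripts, cutoff) {
  rows <- list()
  for (tid in names(transcripts)) {
    for (mid in names(mirnas)) {
      m <- nchar(mirnas[[mid]])
      L <- nchar(transcripts[[tid]])
      if (L < m) next
      hits <- data.frame(start = integer(), score = numeric())
      for (o in seq_len(L - m + 1)) {
        sc <- florin::score_site(mirnas[[mid]],
                                 substr(transcripts[[tid]], o,
                                        o + m - 1))$score
        if (sc <= cutoff) hits <- rbind(hits,
                                        data.frame(start = o, score = sc))
      }
      if (!nrow(hits)) next
      kept <- hits[0, ]
      for (i in order(hits$score, hits$start)) {
        if (!nrow(kept) ||
            all(hits$start[i] + m - 1 < kept$start |
                  hits$start[i] > kept$start + m - 1)) {
          kept <- rbind(kept, hits[i, ])
        }
      }
      kept <- kept[order(kept$start), ]
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mid, transcript_id = tid, start = kept$start,
        end = kept$start + m - 1, score = kept$score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shared study-condition scenario for planted-triplet recovery: one coupled
# triplet with opposed planted DE, plus a background MRE universe giving
# the shared-MRE test a non-degenerate null (one MRE per non-triplet
# miRNA).
triplet_scenario <- function(seed, coupling = 0.9, n_mirna = 24,
                             n_reps = 4) {
  design <- florin::simulation_design(
    seed = seed, n_mrna = 12, n_lncrna = 10, n_mirna = n_mirna,
    n_reps_per_condition = n_reps,
    planted_de = data.frame(
      feature_id = c("mRNA_001", "lncRNA_001", "miR_01"),
      log2_effect = c(-2.5, -2.5, 2.5), stringsAsFactors = FALSE),
    planted_triplets = data.frame(
      mrna_id = "mRNA_001", lncrna_id = "lncRNA_001", mirna_id = "miR_01",
      coupling = coupling, stringsAsFactors = FALSE))
  others <- sprintf("miR_%02d", 2:n_mirna)
  plan <- rbind(
    data.frame(transcript_id = c("mRNA_001", "lncRNA_001"),
               mirna_id = "miR_01", score = c(0, 1),
               stringsAsFactors = FALSE),
    data.frame(transcript_id = rep(sprintf("mRNA_%03d", 2:12),
                                   length.out = length(others)),
               mirna_id = others, score = 0, stringsAsFactors = FALSE))
  florin::simulate_dataset(design, mre_plan = plan)
}
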