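# Pairing penalties indexed [mirna base, target base] with A=1 C=2 G=3 T=4.
# Watson-Crick 0; G:U wobble 0.5 (G~T in DNA letters, either orientation);
# anything else 1.
pair_penalty_matrix <- function() {
  p <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  p["A", "T"] <- 0; p["T", "A"] <- 0
  p["G", "C"] <- 0; p["C", "G"] <- 0
  p["G", "T"] <- 0.5; p["T", "G"] <- 0.5
  p
}

# Position weights: penalties over miRNA positions 2-13 (the seed-extended
# 5' region critical for plant targeting) count double.
position_weights <- function(m) {
  w <- rep(1, m)
  if (m >= 2) w[2:min(13L, m)] <- 2
  w
}

#' Score one candidate miRNA binding window
#'
#' Position-weighted complementarity penalty in the classic plant
#' target-prediction style. The window is read 5'->3' on the transcript
#' and compared against the reverse-oriented miRNA, so miRNA position 1
#' (its 5' end) pairs with the window's 3' end. Per miRNA position:
#' Watson-Crick pair 0, G:U wobble 0.5, mismatch 1; penalties at miRNA
#' positions 2-13 are doubled. The score is the weighted sum; 0 means a
#' perfect duplex.
#'
#' @param mirna miRNA sequence (DNA alphabet, 5'->3').
#' @param window transcript window of the same length, 5'->3'.
#' @return list with `score` (penalty, >= 0) and `alignment` (character
#'   vector over miRNA positions 1..m with values `"match"`, `"GU"`,
#'   `"mismatch"`).
#' @export
score_site <- function(mirna, window) {
  if (nchar(mirna) != nchar(window)) {
    stop("miRNA and window must have equal length", call. = FALSE)
  }
  mi <- encode_dna(mirna)
  wi <- rev(encode_dna(window))  # wi[i] faces miRNA position i
  if (anyNA(mi) || anyNA(wi)) stop("sequences must be over A/C/G/T",
                                   call. = FALSE)
  pen <- pair_penalty_matrix()[cbind(mi, wi)]
  w <- position_weights(length(mi))
  aln <- c("match", "GU", "mismatch")[match(pen, c(0, 0.5, 1))]
  list(score = sum(pen * w), alignment = aln)
}

#' Predict miRNA response elements (MREs) on transcripts
#'
#' Slides every miRNA over every transcript, scores all windows with
#' [score_site()], and reports sites with penalty `<= cutoff` (1-based
#' inclusive coordinates on the transcript). Overlapping qualifying
#' windows of the same miRNA on the same transcript are collapsed to the
#' lowest-scoring one, ties broken leftmost.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum penalty score retained (default
#'   `default_thresholds()$mre_cutoff`).
#' @return data frame with columns `mirna_id`, `transcript_id`, `start`,
#'   `end`, `score`, `alignment` (compact string, `|` match, `o` G:U,
#'   `x` mismatch, over miRNA positions 1..m).
#' @export
find_targets <- function(mirnas, transcripts,
                         cutoff = default_thresholds()$mre_cutoff) {
  stopifnot(cutoff >= 0)
  pm <- pair_penalty_matrix()
  out <- list()
  for (tid in names(transcripts)) {
    s <- encode_dna(transcripts[[tid]])
    L <- length(s)
    for (mid in names(mirnas)) {
      mi <- encode_dna(mirnas[[mid]])
      m <- length(mi)
      if (L < m) next
      n_win <- L - m + 1L
      w <- position_weights(m)
      total <- numeric(n_win)
      for (i in seq_len(m)) {
        # miRNA position i pairs with window offset o at s[o + m - i]
        total <- total + w[i] * pm[mi[i], s[(m - i + 1L):(L - i + 1L)]]
      }
      hit <- which(total <= cutoff)
      if (!length(hit)) next
      df <- data.frame(mirna_id = mid, transcript_id = tid,
                       start = hit, end = hit + m - 1L,
                       score = total[hit], stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- collapse_overlaps(df)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      alignment = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$alignment <- vapply(seq_len(nrow(res)), function(i) {
    aln <- score_site(mirnas[[res$mirna_id[i]]],
                      substr(transcripts[[res$transcript_id[i]]],
                             res$start[i], res$end[i]))$alignment
    paste(c("|", "o", "x")[match(aln, c("match", "GU", "mismatch"))],
          collapse = "")
  }, character(1))
  res
}

# Greedy collapse of overlapping qualifying windows for one
# miRNA/transcript: keep lowest score, ties leftmost.
collapse_overlaps <- function(df) {
  ord <- order(df$score, df$start)
  kept <- df[0, ]
  for (i in ord) {
    if (!nrow(kept) ||
        all(df$start[i] > kept$end | df$end[i] < kept$start)) {
      kept <- rbind(kept, df[i, ])
    }
  }
  kept[order(kept$start), , drop = FALSE]
}

#' Do two MRE sites represent the same miRNA response element?
#'
#' Sites on two different molecules cannot be coordinate-identical, so
#' "same MRE" is interpreted as: both sites are elements of the same
#' miRNA. With `strict = TRUE` the pairing patterns must also be
#' identical (sequence-identical site reading).
#'
#' @param a,b single rows from [find_targets()] output (or lists with
#'   `mirna_id` and, for `strict`, `alignment`).
#' @param strict also require identical alignment patterns.
#' @return logical scalar.
#' @export
same_mre <- function(a, b, strict = FALSE) {
  same <- identical(as.character(a$mirna_id), as.character(b$mirna_id))
  if (strict) {
    same <- same && identical(as.character(a$alignment),
                              as.character(b$alignment))
  }
  same
}
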