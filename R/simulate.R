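#' Simulation design
#'
#' Defines every parameter of the synthetic dataset the generators below
#' emit. The defaults mirror the study design the pipeline targets: a
#' two-condition (NF vs LF) expression experiment with 2 biological
#' replicates per condition, and a 66-accession association panel split
#' 43 NF / 23 LF. Outputs are fully determined by `seed`.
#'
#' @param seed integer seed controlling all randomness.
#' @param n_mrna,n_lncrna,n_mirna feature counts.
#' @param chrom_len chromosome length (nt) for feature placement.
#' @param cis_fraction fraction of lncRNAs placed inside the cis window
#'   of at least one mRNA; the rest are placed outside all windows.
#' @param n_reps_per_condition biological replicates per condition.
#' @param nb_mean_log_range `(low, high)` range of baseline log2 means
#'   for the negative-binomial counts.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param planted_de data frame with columns `feature_id`, `log2_effect`
#'   (signed; positive = up in LF), or `NULL`.
#' @param planted_triplets data frame with columns `mrna_id`,
#'   `lncrna_id`, `mirna_id`, `coupling` in (0, 1], or `NULL`.
#' @param n_accessions panel size.
#' @param n_cases number of LF accessions.
#' @param n_snps number of biallelic SNPs.
#' @param maf_range `(low, high)` allele-frequency range for non-causal
#'   SNPs; must lie in (0, 0.5].
#' @param missing_rate i.i.d. missingness rate (never applied to the
#'   causal SNP).
#' @param causal_index index of the causal SNP among `1..n_snps`.
#' @param penetrance probability in (0.5, 1] that the causal genotype
#'   matches the phenotype class.
#' @param mirna_len length of simulated miRNAs (nt).
#' @param promoter_len length of the emitted promoter sequence (nt).
#' @return a validated list of class `"simulation_design"`.
#' @export
simulation_design <- function(seed = 1L,
                              n_mrna = 30L, n_lncrna = 20L, n_mirna = 8L,
                              chrom_len = 6e6,
                              cis_fraction = 0.5,
                              n_reps_per_condition = 2L,
                              nb_mean_log_range = c(5, 9),
                              nb_dispersion = 0.05,
                              planted_de = NULL,
                              planted_triplets = NULL,
                              n_accessions = 66L, n_cases = 23L,
                              n_snps = 2000L,
                              maf_range = c(0.05, 0.5),
                              missing_rate = 0.05,
                              causal_index = NULL,
                              penetrance = 0.95,
                              mirna_len = 21L,
                              promoter_len = 2000L) {
  d <- list(seed = as.integer(seed), n_mrna = as.integer(n_mrna),
            n_lncrna = as.integer(n_lncrna), n_mirna = as.integer(n_mirna),
            chrom_len = chrom_len, cis_fraction = cis_fraction,
            n_reps_per_condition = as.integer(n_reps_per_condition),
            nb_mean_log_range = nb_mean_log_range,
            nb_dispersion = nb_dispersion, planted_de = planted_de,
            planted_triplets = planted_triplets,
            n_accessions = as.integer(n_accessions),
            n_cases = as.integer(n_cases), n_snps = as.integer(n_snps),
            maf_range = maf_range, missing_rate = missing_rate,
            causal_index = if (is.null(causal_index)) {
              max(1L, as.integer(n_snps) %/% 2L)
            } else as.integer(causal_index),
            penetrance = penetrance, mirna_len = as.integer(mirna_len),
            promoter_len = as.integer(promoter_len))
  stopifnot(d$cis_fraction >= 0, d$cis_fraction <= 1,
            d$n_reps_per_condition >= 1,
            d$nb_dispersion > 0,
            d$n_cases < d$n_accessions,
            d$missing_rate >= 0, d$missing_rate < 1,
            d$penetrance > 0.5, d$penetrance <= 1,
            d$causal_index >= 1, d$causal_index <= max(d$n_snps, 1))
  if (d$maf_range[1] <= 0 || d$maf_range[2] > 0.5 ||
      d$maf_range[1] > d$maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  class(d) <- "simulation_design"
  d
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a genomic annotation with controlled cis structure
#'
#' Places `n_mrna` mRNA loci on one chromosome in well-separated slots,
#' then places exactly `round(cis_fraction * n_lncrna)` lncRNAs inside
#' the strand-aware cis window (10 kb upstream / 20 kb downstream) of at
#' least one mRNA and the remainder in a region beyond every window. The
#' construction is verified against [cis_candidates()] before returning;
#' strands are assigned uniformly.
#'
#' @param design a [simulation_design()].
#' @param thresholds a [default_thresholds()] list (window pads).
#' @return a `gene_annotation` data frame; the planted cis lncRNA ids
#'   are attached as attribute `"cis_lncrnas"`.
#' @export
simulate_annotation <- function(design,
                                thresholds = default_thresholds()) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, {
    n_m <- design$n_mrna; n_l <- design$n_lncrna
    if (n_m == 0 && n_l == 0) {
      return(gene_annotation(character(), character(), integer(),
                             integer(), character(), character()))
    }
    slot <- 80000L
    far_gap <- 50000L
    need <- n_m * slot + far_gap + n_l * 3000L + 30000L
    if (design$chrom_len < need) {
      stop("chrom_len too small to place all features without overlap",
           call. = FALSE)
    }
    n_cis <- round(design$cis_fraction * n_l)
    if (n_cis > 0 && n_m == 0) {
      stop("cannot place cis lncRNAs without any mRNA", call. = FALSE)
    }
    mrna_len <- sample(1000:3000, max(n_m, 1), replace = TRUE)
    mrna_start <- 20000L + (seq_len(n_m) - 1L) * slot
    mrna <- if (n_m > 0) {
      data.frame(id = sprintf("mRNA_%03d", seq_len(n_m)), chrom = "chr1",
                 start = mrna_start, end = mrna_start + mrna_len[seq_len(n_m)] - 1L,
                 strand = sample(c("+", "-"), n_m, replace = TRUE),
                 biotype = "mRNA", stringsAsFactors = FALSE)
    } else NULL
    lnc_len <- sample(300:1000, max(n_l, 1), replace = TRUE)
    lnc_rows <- list()
    if (n_l > 0) {
      for (j in seq_len(n_l)) {
        if (j <= n_cis) {
          # start point within [gene start - 9 kb, gene end]: that point
          # lies inside the host's window on either strand orientation
          host <- ((j - 1L) %% n_m) + 1L
          s <- sample(max(1L, mrna$start[host] - 9000L):mrna$end[host], 1L)
        } else {
          # far region beyond every mRNA window
          s <- 20000L + n_m * slot + far_gap + (j - n_cis - 1L) * 3000L
        }
        lnc_rows[[j]] <- data.frame(
          id = sprintf("lncRNA_%03d", j), chrom = "chr1",
          start = s, end = s + lnc_len[j] - 1L,
          strand = sample(c("+", "-"), 1L), biotype = "lncRNA",
          stringsAsFactors = FALSE)
      }
    }
    ann <- validate_annotation(rbind(mrna, do.call(rbind, lnc_rows)))
    # verify the planted layout against the window oracle
    cc <- cis_candidates(ann, thresholds)
    in_cis <- sort(unique(cc$lncrna_id))
    planted <- if (n_cis > 0) sprintf("lncRNA_%03d", seq_len(n_cis)) else
      character()
    if (!identical(in_cis, sort(planted))) {
      stop("internal error: planted cis layout failed verification",
           call. = FALSE)
    }
    attr(ann, "cis_lncrnas") <- planted
    ann
  })
}

#' Simulate miRNA sequences
#'
#' Uniform random sequences; each is guaranteed at least one G or T in
#' its tail (positions 14..m) so that half-unit MRE penalties remain
#' plantable through G:U wobbles.
#'
#' @param design a [simulation_design()].
#' @return named character vector of miRNA sequences.
#' @export
simulate_mirnas <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed + 1L, {
    m <- design$mirna_len
    seqs <- vapply(seq_len(design$n_mirna), function(i) {
      repeat {
        s <- random_dna(m)
        tail_bases <- strsplit(substr(s, 14, m), "")[[1]]
        if (any(tail_bases %in% c("G", "T"))) return(s)
      }
    }, character(1))
    stats::setNames(seqs, sprintf("miR_%02d", seq_len(design$n_mirna)))
  })
}

# Build a window that scores exactly `score` against `mirna` under
# score_site(). Starts from the perfect reverse complement and introduces
# mismatches/wobbles; penalties are achievable in 0.5 steps.
make_scored_window <- function(mirna, score) {
  m <- nchar(mirna)
  mi <- strsplit(mirna, "")[[1]]
  win <- strsplit(revcomp(mirna), "")[[1]]  # window index j = m - i + 1
  half <- round(score * 2)
  if (abs(score * 2 - half) > 1e-9 || score < 0) {
    stop("penalty must be a nonnegative multiple of 0.5", call. = FALSE)
  }
  nonseed <- setdiff(seq_len(m), 2:min(13, m))  # weight-1 miRNA positions
  nonseed <- rev(nonseed)                       # prefer the 3' tail
  used <- logical(m)
  mismatch_base <- function(b) {
    # neither Watson-Crick complement nor wobble partner
    switch(b, A = "C", C = "A", G = "A", T = "C")
  }
  wobble_base <- function(b) switch(b, G = "T", T = "G", NA_character_)
  if (half %% 2 == 1) {  # need one half-unit: a wobble at a weight-1 position
    cand <- nonseed[mi[nonseed] %in% c("G", "T") & !used[nonseed]]
    if (!length(cand)) {
      stop("half-unit penalty not plantable: no G/T at a weight-1 position",
           call. = FALSE)
    }
    i <- cand[1]
    win[m - i + 1L] <- wobble_base(mi[i])
    used[i] <- TRUE
    half <- half - 1L
  }
  # remaining half-units are even: weight-1 mismatches (2 half-units each),
  # then seed mismatches (4) if the tail runs out
  while (half > 0) {
    cand <- nonseed[!used[nonseed]]
    if (length(cand) && half >= 2) {
      i <- cand[1]
      win[m - i + 1L] <- mismatch_base(mi[i])
      used[i] <- TRUE
      half <- half - 2L
    } else {
      seed <- setdiff(2:min(13, m), which(used))
      if (half >= 4 && length(seed)) {
        i <- seed[length(seed)]
        win[m - i + 1L] <- mismatch_base(mi[i])
        used[i] <- TRUE
        half <- half - 4L
      } else if (half == 2 && length(seed[mi[seed] %in% c("G", "T")])) {
        i <- seed[mi[seed] %in% c("G", "T")][1]
        win[m - i + 1L] <- wobble_base(mi[i])
        used[i] <- TRUE
        half <- half - 2L
      } else {
        stop("requested penalty not plantable for this miRNA", call. = FALSE)
      }
    }
  }
  paste(win, collapse = "")
}

#' Simulate transcript sequences with planted MREs
#'
#' Background sequence is i.i.d. uniform over A/C/G/T with lengths taken
#' from the annotation. Each row of `mre_plan` plants one binding window
#' whose [score_site()] penalty at the planted offset equals the planned
#' score exactly (verified before returning); planted windows on the same
#' transcript do not overlap.
#'
#' @param annotation a `gene_annotation` data frame (one transcript per
#'   feature, sequence length = locus length).
#' @param mirnas named character vector from [simulate_mirnas()].
#' @param mre_plan data frame with columns `transcript_id`, `mirna_id`,
#'   `score` (multiples of 0.5), or `NULL` for no planted sites.
#' @param design a [simulation_design()].
#' @return named character vector of transcript sequences; planted site
#'   coordinates are attached as attribute `"planted_sites"` (data frame
#'   `transcript_id`, `mirna_id`, `start`, `end`, `score`).
#' @export
simulate_transcripts <- function(annotation, mirnas, mre_plan = NULL,
                                 design) {
  stopifnot(inherits(design, "simulation_design"))
  annotation <- validate_annotation(annotation)
  with_seed(design$seed + 2L, {
    lens <- stats::setNames(annotation$end - annotation$start + 1L,
                            annotation$id)
    seqs <- vapply(lens, random_dna, character(1))
    planted <- data.frame(transcript_id = character(),
                          mirna_id = character(), start = integer(),
                          end = integer(), score = numeric(),
                          stringsAsFactors = FALSE)
    if (!is.null(mre_plan) && nrow(mre_plan)) {
      occupied <- lapply(seqs, function(x) integer())
      for (r in seq_len(nrow(mre_plan))) {
        tid <- mre_plan$transcript_id[r]
        mid <- mre_plan$mirna_id[r]
        if (!tid %in% names(seqs)) stop("unknown transcript in MRE plan: ",
                                        tid, call. = FALSE)
        if (!mid %in% names(mirnas)) stop("unknown miRNA in MRE plan: ",
                                          mid, call. = FALSE)
        win <- make_scored_window(mirnas[[mid]], mre_plan$score[r])
        m <- nchar(win)
        L <- nchar(seqs[[tid]])
        if (L < m) stop("transcript too short for planted site",
                        call. = FALSE)
        free <- setdiff(seq_len(L - m + 1L),
                        unlist(lapply(occupied[[tid]], function(s) {
                          (s - m + 1L):(s + m - 1L)
                        })))
        free <- free[free >= 1]
        if (!length(free)) stop("no room left for planted site on ", tid,
                                call. = FALSE)
        at <- sample(free, 1L)
        substr(seqs[[tid]], at, at + m - 1L) <- win
        occupied[[tid]] <- c(occupied[[tid]], at)
        got <- score_site(mirnas[[mid]],
                          substr(seqs[[tid]], at, at + m - 1L))$score
        if (!isTRUE(all.equal(got, mre_plan$score[r]))) {
          stop("internal error: planted site rescored to ", got,
               call. = FALSE)
        }
        planted <- rbind(planted, data.frame(
          transcript_id = tid, mirna_id = mid, start = at,
          end = at + m - 1L, score = mre_plan$score[r],
          stringsAsFactors = FALSE))
      }
    }
    attr(seqs, "planted_sites") <- planted
    seqs
  })
}

#' Simulate negative-binomial expression counts with planted structure
#'
#' Baseline log2 means are uniform over `nb_mean_log_range`; counts are
#' negative-binomial with dispersion `nb_dispersion`. Planted DE features
#' shift the LF condition mean by `2^log2_effect`. Each planted triplet
#' shares one per-sample latent activity variable `z ~ N(0, 1)`: the
#' miRNA mean is multiplied by `2^(0.5 * coupling * z)` and the coupled
#' mRNA and lncRNA means by the reciprocal, so the mRNA and lncRNA
#' co-vary positively and each varies negatively with the miRNA,
#' monotonically in the coupling strength. The 0.5 log2-unit scale keeps
#' the shared fluctuation comparable to biological replicate noise
#' rather than to condition effects.
#'
#' @param features data frame with columns `feature_id`, `length`.
#' @param design a [simulation_design()].
#' @return list with `counts` (an [expression_matrix()], unit `count`,
#'   samples `NF_1.., LF_1..`) and `truth` (planted effects and
#'   latent-factor draws).
#' @export
simulate_expression <- function(features, design) {
  stopifnot(inherits(design, "simulation_design"),
            all(c("feature_id", "length") %in% names(features)))
  planted_de <- design$planted_de
  trips <- design$planted_triplets
  ref_ids <- c(planted_de$feature_id, trips$mrna_id, trips$lncrna_id,
               trips$mirna_id)
  missing_ref <- setdiff(ref_ids, features$feature_id)
  if (length(missing_ref)) {
    stop("planted effect references unknown feature(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  with_seed(design$seed + 3L, {
    nf <- nrow(features)
    reps <- design$n_reps_per_condition
    samples <- c(sprintf("NF_%d", seq_len(reps)),
                 sprintf("LF_%d", seq_len(reps)))
    cond <- stats::setNames(rep(c("NF", "LF"), each = reps), samples)
    base_mu <- 2^stats::runif(nf, design$nb_mean_log_range[1],
                              design$nb_mean_log_range[2])
    mu <- matrix(base_mu, nf, length(samples),
                 dimnames = list(features$feature_id, samples))
    if (!is.null(planted_de) && nrow(planted_de)) {
      idx <- match(planted_de$feature_id, features$feature_id)
      mu[idx, cond == "LF"] <- mu[idx, cond == "LF"] *
        2^planted_de$log2_effect
    }
    z <- NULL
    if (!is.null(trips) && nrow(trips)) {
      z <- matrix(stats::rnorm(nrow(trips) * length(samples)),
                  nrow(trips), length(samples))
      for (t in seq_len(nrow(trips))) {
        # latent miRNA activity: 0.5 log2-units per unit coupling, so the
        # shared factor induces clear correlation structure without
        # swamping planted condition effects
        f <- 2^(0.5 * trips$coupling[t] * z[t, ])
        mu[trips$mirna_id[t], ] <- mu[trips$mirna_id[t], ] * f
        mu[trips$mrna_id[t], ] <- mu[trips$mrna_id[t], ] / f
        mu[trips$lncrna_id[t], ] <- mu[trips$lncrna_id[t], ] / f
      }
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / design$nb_dispersion),
                     nf, length(samples),
                     dimnames = dimnames(mu))
    list(counts = expression_matrix(counts, unit = "count",
                                    conditions = cond),
         truth = list(planted_de = planted_de, planted_triplets = trips,
                      baseline_mu = stats::setNames(base_mu,
                                                    features$feature_id),
                      latent = z))
  })
}

#' Simulate a case/control genotype panel with one causal promoter SNP
#'
#' Phenotype classes are fixed at `n_cases` LF among `n_accessions`
#' accessions. Non-causal SNPs draw an alt-allele frequency uniformly
#' from `maf_range` and genotypes binomially, independent of phenotype
#' (exactly null). The causal SNP genotype matches the phenotype class
#' (LF -> 2, NF -> 0) with probability `penetrance`, otherwise it is
#' drawn from the background model. Missingness is i.i.d. at
#' `missing_rate` except never on the causal SNP. The causal SNP is
#' placed at the third nucleotide of a G-box core (`TACGTG`) planted in
#' the emitted promoter sequence, so the alt allele disrupts the motif.
#'
#' @param design a [simulation_design()].
#' @return list with `genotypes` ([genotype_calls()]), `phenotypes`
#'   (named vector), `promoter` (named character vector of length 1) and
#'   `truth` (causal index/position, promoter coordinates, alleles,
#'   allele frequencies).
#' @export
simulate_genotypes <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed + 4L, {
    n_acc <- design$n_accessions
    n_snp <- design$n_snps
    acc <- sprintf("acc_%02d", seq_len(n_acc))
    classes <- stats::setNames(
      sample(rep(c("LF", "NF"), c(design$n_cases, n_acc - design$n_cases))),
      acc)
    pos <- sort(sample.int(design$chrom_len, n_snp))
    freqs <- stats::runif(n_snp, design$maf_range[1], design$maf_range[2])
    codes <- matrix(stats::rbinom(n_snp * n_acc, 2L, rep(freqs, n_acc)),
                    n_snp, n_acc, dimnames = list(NULL, acc))
    ci <- design$causal_index
    is_case <- classes[acc] == "LF"
    concordant <- stats::runif(n_acc) <= design$penetrance
    causal <- ifelse(concordant, ifelse(is_case, 2L, 0L),
                     stats::rbinom(n_acc, 2L, freqs[ci]))
    codes[ci, ] <- causal
    miss <- matrix(stats::runif(n_snp * n_acc) < design$missing_rate,
                   n_snp, n_acc)
    miss[ci, ] <- FALSE
    codes[miss] <- NA_integer_
    # promoter carrying the G-box; the causal SNP sits on its third base
    gbox <- "TACGTG"
    repeat {
      prom <- random_dna(design$promoter_len)
      box_at <- max(1L, design$promoter_len %/% 2L)
      substr(prom, box_at, box_at + 5L) <- gbox
      if (nrow(motif_scan(prom, gbox, seq_id = "promoter")) == 1L) break
    }
    prom_pos <- box_at + 2L  # third nucleotide of TACGTG
    ref_allele <- substr(prom, prom_pos, prom_pos)  # "C"
    alt_allele <- sample(setdiff(DNA_BASES, ref_allele), 1L)
    ref <- sample(DNA_BASES, n_snp, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1), USE.NAMES = FALSE)
    ref[ci] <- ref_allele
    alt[ci] <- alt_allele
    snps <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
    list(genotypes = genotype_calls(snps, codes),
         phenotypes = classes,
         promoter = stats::setNames(prom, "promoter"),
         truth = list(causal_index = ci, causal_pos = pos[ci],
                      promoter_snp_pos = prom_pos, ref = ref_allele,
                      alt = alt_allele, allele_freqs = freqs,
                      gbox_start = box_at))
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running every generator with consistent inputs:
#' annotation, miRNAs, transcripts (with any planted MREs), expression
#' counts (with planted DE and triplet coupling) and the genotype panel.
#'
#' @param design a [simulation_design()].
#' @param mre_plan optional plan forwarded to [simulate_transcripts()].
#' @param thresholds forwarded to [simulate_annotation()].
#' @return list with components `design`, `annotation`, `mirnas`,
#'   `transcripts`, `expression` (counts + truth), `genotypes`,
#'   `phenotypes`, `promoter`, `genotype_truth`.
#' @export
simulate_dataset <- function(design, mre_plan = NULL,
                             thresholds = default_thresholds()) {
  ann <- simulate_annotation(design, thresholds)
  mirnas <- simulate_mirnas(design)
  tx <- simulate_transcripts(ann, mirnas, mre_plan, design)
  features <- data.frame(
    feature_id = c(ann$id, names(mirnas)),
    length = c(ann$end - ann$start + 1L, nchar(mirnas)),
    stringsAsFactors = FALSE)
  expr <- simulate_expression(features, design)
  geno <- simulate_genotypes(design)
  list(design = design, annotation = ann, mirnas = mirnas,
       transcripts = tx, expression = expr,
       genotypes = geno$genotypes, phenotypes = geno$phenotypes,
       promoter = geno$promoter, genotype_truth = geno$truth)
}

#' Write a simulated dataset to a directory of standard-format files
#'
#' Emits `annotation.gff3`, `transcripts.fasta`, `mirnas.fasta`,
#' `promoter.fasta`, `expr_mrna.tsv`, `expr_lncrna.tsv`,
#' `expr_mirna.tsv`, `genotypes.vcf`, `phenotypes.tsv` and `truth.json`.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gff3(sim$annotation, p("annotation.gff3"))
  write_fasta(sim$transcripts, p("transcripts.fasta"))
  write_fasta(sim$mirnas, p("mirnas.fasta"))
  write_fasta(sim$promoter, p("promoter.fasta"))
  counts <- sim$expression$counts
  split_ids <- split(sim$annotation$id, sim$annotation$biotype)
  subset_em <- function(ids) {
    expression_matrix(unclass(counts)[ids, , drop = FALSE], unit = "count",
                      conditions = em_conditions(counts))
  }
  write_expression_table(subset_em(split_ids$mRNA), p("expr_mrna.tsv"))
  write_expression_table(subset_em(split_ids$lncRNA), p("expr_lncrna.tsv"))
  write_expression_table(subset_em(names(sim$mirnas)), p("expr_mirna.tsv"))
  write_vcf_minimal(sim$genotypes, p("genotypes.vcf"))
  utils::write.table(
    data.frame(accession = names(sim$phenotypes),
               class = unname(sim$phenotypes)),
    p("phenotypes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    note = paste("synthetic data: negative-binomial counts with a shared",
                 "latent-activity factor per planted triplet; these noise",
                 "models are stand-ins chosen by this package, not",
                 "estimated from real data"),
    planted_de = sim$expression$truth$planted_de,
    planted_triplets = sim$expression$truth$planted_triplets,
    planted_mres = attr(sim$transcripts, "planted_sites"),
    genotype_truth = sim$genotype_truth[
      c("causal_index", "causal_pos", "promoter_snp_pos", "ref", "alt")])
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
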