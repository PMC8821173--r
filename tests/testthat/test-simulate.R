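test_that("generators are deterministic under the seed and vary across seeds", {
  d <- simulation_design(seed = 101, n_mrna = 6, n_lncrna = 6, n_mirna = 4,
                         n_snps = 50)
  s1 <- simulate_dataset(d)
  s2 <- simulate_dataset(d)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(unclass(s1$expression$counts),
                   unclass(s2$expression$counts))
  expect_identical(s1$genotypes, s2$genotypes)
  d3 <- simulation_design(seed = 102, n_mrna = 6, n_lncrna = 6,
                          n_mirna = 4, n_snps = 50)
  s3 <- simulate_dataset(d3)
  expect_false(identical(unclass(s1$expression$counts),
                         unclass(s3$expression$counts)))
})

test_that("annotation places the requested fraction of lncRNAs in cis windows", {
  d <- simulation_design(seed = 103, n_mrna = 8, n_lncrna = 10,
                         cis_fraction = 0.5)
  ann <- simulate_annotation(d)
  cc <- cis_candidates(ann)
  expect_equal(length(unique(cc$lncrna_id)), 5L)
  expect_setequal(unique(cc$lncrna_id), attr(ann, "cis_lncrnas"))
  # zero features -> empty annotation
  d0 <- simulation_design(seed = 1, n_mrna = 0, n_lncrna = 0, n_snps = 10,
                          cis_fraction = 0)
  expect_equal(nrow(simulate_annotation(d0)), 0L)
  # infeasible placement errors
  expect_error(simulate_annotation(
    simulation_design(seed = 1, n_mrna = 50, n_lncrna = 10,
                      chrom_len = 1e5)), "chrom_len")
})

test_that("planted MREs rescore exactly as planned and are recovered", {
  d <- simulation_design(seed = 104, n_mrna = 4, n_lncrna = 2, n_mirna = 3)
  ann <- simulate_annotation(d)
  mir <- simulate_mirnas(d)
  plan <- data.frame(
    transcript_id = c("mRNA_001", "mRNA_002", "lncRNA_001"),
    mirna_id = c("miR_01", "miR_02", "miR_01"),
    score = c(0, 2.5, 4), stringsAsFactors = FALSE)
  tx <- simulate_transcripts(ann, mir, plan, d)
  planted <- attr(tx, "planted_sites")
  expect_equal(nrow(planted), 3L)
  for (i in seq_len(nrow(planted))) {
    win <- substr(tx[[planted$transcript_id[i]]], planted$start[i],
                  planted$end[i])
    expect_equal(score_site(mir[[planted$mirna_id[i]]], win)$score,
                 plan$score[i])
  }
  hits <- find_targets(mir, tx, cutoff = 4)
  for (i in seq_len(nrow(planted))) {
    match_row <- hits[hits$mirna_id == planted$mirna_id[i] &
                        hits$transcript_id == planted$transcript_id[i] &
                        hits$start == planted$start[i], ]
    expect_equal(nrow(match_row), 1L)
    expect_equal(match_row$score, plan$score[i])
  }
  expect_error(simulate_transcripts(ann, mir, data.frame(
    transcript_id = "mRNA_001", mirna_id = "miR_01", score = 0.3), d),
    "multiple of 0.5")
})

test_that("null expression yields a small false-positive fraction at the gene filter", {
  fp <- vapply(1:8, function(s) {
    d <- simulation_design(seed = 200 + s, n_mrna = 40, n_lncrna = 0,
                           n_mirna = 0, cis_fraction = 0)
    ann <- simulate_annotation(d)
    feats <- data.frame(feature_id = ann$id,
                        length = ann$end - ann$start + 1L)
    ex <- simulate_expression(feats, d)
    de <- de_analysis(ex$counts, "NF", "LF", "gene")
    mean(de$direction != "ns")
  }, numeric(1))
  expect_lt(mean(fp), 0.02)
})

test_that("a strong planted effect is detected by the gene filter", {
  hit <- vapply(1:10, function(s) {
    d <- simulation_design(
      seed = 300 + s, n_mrna = 30, n_lncrna = 0, n_mirna = 0,
      cis_fraction = 0, n_reps_per_condition = 4,
      planted_de = data.frame(feature_id = "mRNA_001", log2_effect = 3))
    ann <- simulate_annotation(d)
    feats <- data.frame(feature_id = ann$id,
                        length = ann$end - ann$start + 1L)
    ex <- simulate_expression(feats, d)
    de <- filter_de(de_analysis(ex$counts, "NF", "LF", "gene"), "gene")
    "mRNA_001" %in% de$feature_id
  }, logical(1))
  expect_gte(sum(hit), 9L)
})

test_that("planted triplets induce the stated correlation signs", {
  d <- simulation_design(
    seed = 105, n_mrna = 6, n_lncrna = 4, n_mirna = 3,
    n_reps_per_condition = 10,
    planted_triplets = data.frame(mrna_id = "mRNA_001",
                                  lncrna_id = "lncRNA_001",
                                  mirna_id = "miR_01", coupling = 0.9))
  ann <- simulate_annotation(d)
  feats <- data.frame(
    feature_id = c(ann$id, sprintf("miR_%02d", 1:3)),
    length = c(ann$end - ann$start + 1L, rep(21L, 3)))
  ex <- simulate_expression(feats, d)
  m <- log1p(unclass(ex$counts))
  expect_gt(cor(m["mRNA_001", ], m["lncRNA_001", ]), 0.5)
  expect_lt(cor(m["mRNA_001", ], m["miR_01", ]), -0.5)
  expect_lt(cor(m["lncRNA_001", ], m["miR_01", ]), -0.5)
})

test_that("genotype panel honours the design: classes, MAF, missingness, causal SNP", {
  d <- simulation_design(seed = 106, n_snps = 400, penetrance = 1,
                         missing_rate = 0.05)
  g <- simulate_genotypes(d)
  expect_equal(sum(g$phenotypes == "LF"), 23L)
  expect_equal(sum(g$phenotypes == "NF"), 43L)
  ci <- g$truth$causal_index
  # causal SNP: never missing; perfect penetrance separates classes
  expect_false(anyNA(g$genotypes$codes[ci, ]))
  expect_equal(concordance(g$genotypes$codes[ci, ],
                           g$phenotypes[colnames(g$genotypes$codes)]), 1)
  # causal SNP attains the minimum p in a full scan
  scan <- association_scan(g$genotypes, g$phenotypes)
  expect_equal(which.min(scan$p_value), ci)
  # empirical MAF of non-causal SNPs within the design range +/- sampling
  # error at n = 66 (binomial sd ~ sqrt(0.5^2/132) ~ 0.045; allow 4 sd)
  codes <- g$genotypes$codes[-ci, ]
  af <- rowSums(codes, na.rm = TRUE) /
    (2 * rowSums(!is.na(codes)))
  maf <- pmin(af, 1 - af)
  expect_true(all(maf <= 0.5))
  expect_true(all(maf >= 0.05 - 4 * 0.045))
  # overall missingness near the design rate
  expect_equal(mean(is.na(codes)), 0.05, tolerance = 0.2)
  # invalid MAF range errors
  expect_error(simulation_design(seed = 1, maf_range = c(0.1, 0.7)),
               "maf_range")
  # causal SNP sits on the third base of the planted promoter G-box
  hits <- motif_scan(g$promoter[[1]], seq_id = "promoter")
  expect_equal(nrow(hits), 1L)
  expect_equal(g$truth$promoter_snp_pos, hits$start + 2L)
  dis <- snp_motif_disruption(
    list(pos = g$truth$promoter_snp_pos, ref = g$truth$ref,
         alt = g$truth$alt), hits, g$promoter[[1]])
  expect_true(dis$disrupted)
})

test_that("simulation files round-trip through the standard-format writers", {
  d <- simulation_design(seed = 107, n_mrna = 4, n_lncrna = 3, n_mirna = 2,
                         n_snps = 20)
  sim <- simulate_dataset(d)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  ann <- read_gff3(file.path(dir, "annotation.gff3"))
  expect_equal(as.data.frame(ann)[order(ann$id), ],
               as.data.frame(sim$annotation)[order(sim$annotation$id), ],
               ignore_attr = TRUE)
  tx <- read_fasta(file.path(dir, "transcripts.fasta"))
  expect_equal(sort(names(tx)), sort(sim$annotation$id))
  geno <- suppressMessages(read_vcf_minimal(file.path(dir, "genotypes.vcf")))
  expect_equal(geno$codes, sim$genotypes$codes)
  em <- read_expression_table(
    file.path(dir, "expr_mirna.tsv"), unit = "count",
    conditions = attr(sim$expression$counts, "conditions"))
  expect_equal(unclass(em)[, ],
               unclass(sim$expression$counts)[names(sim$mirnas), ])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$genotype_truth$causal_index,
               sim$genotype_truth$causal_index)
})
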