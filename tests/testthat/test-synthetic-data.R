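test_that("the generators are deterministic under a fixed seed", {
  cfg <- tiny_config()
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$models, b$models)
  expect_identical(a$truth, b$truth)
  fa <- simulate_fraction_counts(a$models, a$truth, cfg)
  fb <- simulate_fraction_counts(b$models, b$truth, cfg)
  expect_identical(fa, fb)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  pa <- simulate_expression_panel(seed = 3)
  pb <- simulate_expression_panel(seed = 3)
  expect_identical(pa, pb)
  # and FASTA/GTF serializations are byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(a$sequences, f1); write_fasta(b$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("n_genes = 0 gives empty outputs and empty truth", {
  cfg <- sim_config(n_genes = 0, seed = 1)
  sim <- simulate_genome(cfg)
  expect_equal(length(sim$sequences), 0L)
  expect_equal(nrow(sim$models), 0L)
  expect_equal(nrow(sim$truth$genes), 0L)
  fr <- simulate_fraction_counts(sim$models, sim$truth, cfg)
  expect_equal(nrow(fr$counts), 0L)
  expect_equal(nrow(fr$junctions), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = -1), "n_genes")
  expect_error(sim_config(gc_content = 1.2), "fractions")
  expect_error(sim_config(exon_len = c(400, 100)), "range")
  expect_error(sim_config(seq_depth = -5), "rates and depths")
  expect_error(sim_config(psi_weak = c(0.2, 1.4)), "psi")
})

test_that("realized exonic U1 counts match the configured Poisson rate", {
  # 100 genes x 2 kb exonic at 2 motifs/kb: expect 400 +/- 3 Poisson SD
  cfg <- sim_config(n_genes = 100, seed = 13, lncrna_fraction = 0,
                    exons_per_gene = c(4, 4), exon_len = c(500, 500),
                    planted_u1_rate_exonic = c(coding = 2, lncRNA = 2))
  sim <- simulate_genome(cfg)
  expect_equal(sum(sim$truth$genes$exonic_length), 200000L)
  total <- sum(sim$truth$genes$u1_exonic)
  expect_lt(abs(total - 400), 3 * sqrt(400))
})

test_that("zero sequencing depth gives all-zero count tables", {
  cfg <- tiny_config(seq_depth = 0, junction_depth = 0, fulllength_depth = 0)
  sim <- simulate_genome(cfg)
  fr <- simulate_fraction_counts(sim$models, sim$truth, cfg)
  expect_true(all(fr$counts$reads_nuc == 0 & fr$counts$reads_cyt == 0))
  expect_true(all(fr$junctions$junction_reads == 0))
  expect_equal(nrow(fr$fulllength), 0L)
})

test_that("a null export model gives equal cytoplasmic shares across genes", {
  cfg <- sim_config(n_genes = 60, seed = 17, seq_depth = 500,
                    export_model_coefficients = c(intercept = 0,
                                                  beta_u1_exonic = 0,
                                                  beta_isor = 0))
  sim <- simulate_genome(cfg)
  expect_true(all(sim$truth$genes$p_cyt == 0.5))
  fr <- simulate_fraction_counts(sim$models, sim$truth, cfg)
  share <- fr$counts$reads_cyt / (fr$counts$reads_nuc + fr$counts$reads_cyt)
  # binomial sampling noise only: no gene deviates beyond ~4 SD
  expect_true(all(abs(share - 0.5) < 4 * sqrt(0.25 / 500) + 0.02))
})

test_that("the export model is recoverable from realized N/C ratios", {
  cfg <- sim_config(n_genes = 100, seed = 23, seq_depth = 400)
  sim <- simulate_genome(cfg)
  fr <- simulate_fraction_counts(sim$models, sim$truth, cfg)
  nc <- nc_ratio(data.frame(
    gene_id = fr$counts$gene_id,
    fpkm_nuc = compute_fpkm(fr$counts$reads_nuc, fr$counts$exonic_length,
                            sum(fr$counts$reads_nuc)),
    fpkm_cyt = compute_fpkm(fr$counts$reads_cyt, fr$counts$exonic_length,
                            sum(fr$counts$reads_cyt))
  ))
  tg <- sim$truth$genes[match(nc$gene_id, sim$truth$genes$gene_id), ]
  # beta_u1_exonic < 0: exonic U1 density retains transcripts in the nucleus
  expect_gt(cor(tg$u1_exonic_density, nc$nc_ratio, method = "spearman",
                use = "complete.obs"), 0.5)
  # regression on true features recovers both coefficient signs
  fit <- lm(nc$nc_ratio ~ tg$u1_exonic_density + tg$isor_true)
  expect_gt(coef(fit)[2], 0)   # N/C rises with exonic U1 density
  expect_lt(coef(fit)[3], 0)   # N/C falls with splicing
})

test_that("multi-mutation reads are exactly the ones recorded in truth", {
  cfg <- tiny_config(assay_depth = 500, multi_mutation_fraction = 0.1)
  sim <- simulate_genome(cfg)
  eff <- data.frame(mutation_id = "m1",
                    gene_id = sim$truth$genes$gene_id[1],
                    position = 5L, ref = "A", alt = "G",
                    odds_multiplier = 1, psi_delta = 0, intron_id = NA)
  assay <- simulate_mutation_assay(sim$models, eff, sim$truth, cfg)
  rc <- assay$read_calls
  multi <- rc$read_id[lengths(gregexpr(",", rc$mutations)) > 0 &
                      grepl(",", rc$mutations)]
  expect_setequal(multi, assay$truth$multi_mutation_reads$read_id)
  ct <- count_alleles(rc)
  expect_equal(attr(ct, "n_discarded"), length(multi))
  # position outside the gene errors
  bad <- eff; bad$position <- 10^6
  expect_error(simulate_mutation_assay(sim$models, bad, sim$truth, cfg),
               "outside")
})

test_that("expression panels have the configured block correlation structure", {
  pan <- simulate_expression_panel(n_ind_a = 50, n_ind_b = 50,
                                   blocks = list(list(n_genes = 8, r = 0.9,
                                                      shared = TRUE)),
                                   n_noise = 30, seed = 31)
  blk <- pan$truth$gene_a[pan$truth$block == 1]
  ca <- cor(t(pan$panel_a[blk, ]))
  expect_gt(mean(ca[upper.tri(ca)]), 0.7)
  noise <- pan$truth$gene_a[pan$truth$block == 0][1:10]
  cn <- cor(t(pan$panel_a[c(blk[1], noise), ]))[1, -1]
  expect_lt(max(abs(cn)), 0.5)
})
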