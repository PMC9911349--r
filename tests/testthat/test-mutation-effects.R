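test_that("multi-mutation reads are discarded; others increment one cell", {
  rc <- data.frame(
    read_id = c("m1_r1", "m1_r2", "m1_r3", "m1_r4", "m2_r1"),
    fraction = c("nuc", "cyt", "nuc", "nuc", "cyt"),
    mutations = c("m1", "m1,m2", "", "m1", ""),
    stringsAsFactors = FALSE)
  ct <- count_alleles(rc)
  expect_equal(attr(ct, "n_discarded"), 1L)
  m1 <- ct[ct$mutation_id == "m1", ]
  expect_equal(m1$n_mut_nuc, 2L)   # r1, r4
  expect_equal(m1$n_ref_nuc, 1L)   # r3 (reference read on m1's amplicon)
  expect_equal(m1$n_mut_cyt, 0L)
  m2 <- ct[ct$mutation_id == "m2", ]
  expect_equal(m2$n_ref_cyt, 1L)
  # conservation: retained reads = total cells
  expect_equal(sum(as.matrix(ct[, -1])), nrow(rc) - 1L)
})

test_that("Fisher p matches the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p, 1)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$odds_ratio, 1)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3)$p, 34 / 70)
  # zero margin: untestable
  z <- fisher_exact_2x2(0, 0, 5, 5)
  expect_equal(z$p, 1)
  expect_true(is.na(z$odds_ratio))
  # against stats::fisher.test for all tables with N <= 16
  for (N in 2:16) for (a in 0:N) for (b in 0:(N - a))
    for (cc in 0:(N - a - b)) {
      d <- N - a - b - cc
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
      mine <- fisher_exact_2x2(a, b, cc, d)$p
      ref <- stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value
      expect_equal(mine, ref, tolerance = 1e-9)
    }
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  # independent step-up re-implementation as oracle
  step_up <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    q <- rep(NA_real_, m)
    running <- 1
    for (i in seq_along(o)) {
      rank_i <- m - i + 1
      running <- min(running, p[o[i]] * m / rank_i)
      q[o[i]] <- running
    }
    q
  }
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("export-shift calls follow the nuclear-odds direction", {
  counts <- data.frame(mutation_id = "m", n_mut_nuc = 100L, n_ref_nuc = 100L,
                       n_mut_cyt = 400L, n_ref_cyt = 100L)
  res <- test_export_shift(counts)
  expect_equal(res$export_call, "increased_export")
  expect_lt(res$odds_ratio, 1)
  expect_lt(res$q_bh, 0.05)
  # flipping the fraction labels flips every call
  flipped <- data.frame(mutation_id = "m", n_mut_nuc = 400L, n_ref_nuc = 100L,
                        n_mut_cyt = 100L, n_ref_cyt = 100L)
  expect_equal(test_export_shift(flipped)$export_call, "decreased_export")
  # zero mutant reads: untestable, no call
  zero <- data.frame(mutation_id = "m", n_mut_nuc = 0L, n_ref_nuc = 100L,
                     n_mut_cyt = 0L, n_ref_cyt = 100L)
  rz <- test_export_shift(zero)
  expect_false(rz$testable)
  expect_equal(rz$export_call, "none")
})

test_that("export-shift type-I error is controlled under the null", {
  set.seed(14)
  n <- 500
  p_nuc <- runif(n, 0.2, 0.8)
  counts <- data.frame(
    mutation_id = sprintf("m%03d", 1:n),
    n_mut_nuc = rbinom(n, 1000, p_nuc), n_ref_nuc = rbinom(n, 1000, p_nuc))
  counts$n_mut_cyt <- 1000L - counts$n_mut_nuc
  counts$n_ref_cyt <- 1000L - counts$n_ref_nuc
  res <- test_export_shift(counts)
  rate <- mean(res$export_call != "none")
  # BH controls FDR at 0.05; under the global null the family-wise rate of
  # any call is <= alpha, so the per-test rate is far below it
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("an injected 4x export odds shift is detected with high power", {
  cfg <- sim_config(n_genes = 4, seed = 19, assay_depth = 2000,
                    multi_mutation_fraction = 0.05)
  sim <- simulate_genome(cfg)
  gid <- sim$truth$genes$gene_id[1]
  hits <- vapply(1:40, function(rep) {
    cfg_r <- sim_config(n_genes = 4, seed = 1000 + rep, assay_depth = 2000)
    eff <- data.frame(mutation_id = "m1", gene_id = gid, position = 5L,
                      ref = "A", alt = "G", odds_multiplier = 4,
                      psi_delta = 0, intron_id = NA)
    assay <- simulate_mutation_assay(sim$models, eff, sim$truth, cfg_r)
    res <- test_export_shift(count_alleles(assay$read_calls))
    res$export_call == "decreased_export"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("splice-shift calls require both significance and the 5% PSI rule", {
  ev <- data.frame(mutation_id = rep(c("sig", "small"), each = 2),
                   allele = rep(c("ref", "mut"), 2),
                   junction_reads = c(900L, 800L, 900L, 880L),
                   retention_reads = c(100L, 200L, 100L, 120L))
  res <- test_splice_shift(ev)
  sig <- res[res$mutation_id == "sig", ]
  expect_equal(sig$delta_psi, -0.1)
  expect_equal(sig$splice_call, "weaker")
  small <- res[res$mutation_id == "small", ]
  expect_equal(small$splice_call, "none")  # |delta| = 0.02 <= 0.05
  # identical counts: p = 1, no call
  same <- data.frame(mutation_id = "x", allele = c("ref", "mut"),
                     junction_reads = c(500L, 500L),
                     retention_reads = c(100L, 100L))
  rs <- test_splice_shift(same)
  expect_equal(rs$p_raw_splice, 1)
  expect_equal(rs$splice_call, "none")
})

test_that("the top-50% U1 filter is rank-based and deterministic", {
  eff <- data.frame(mutation_id = sprintf("m%02d", 1:10),
                    du1_score = c(-3, 0.5, 2, -0.1, 1.5, -2.5, 0.2, 4, -1, 0.8))
  kept <- filter_u1_effects(eff)
  expect_equal(nrow(kept), 5L)
  expect_setequal(kept$mutation_id, c("m08", "m01", "m06", "m03", "m05"))
  # invariant to score scaling
  eff2 <- eff; eff2$du1_score <- eff$du1_score * 100
  expect_equal(filter_u1_effects(eff2)$mutation_id, kept$mutation_id)
  # all-tied scores: deterministic tie-break by mutation id
  eff3 <- eff; eff3$du1_score <- 1
  expect_equal(filter_u1_effects(eff3)$mutation_id, sprintf("m%02d", 1:5))
})

test_that("concordance couples splice direction with export direction", {
  eff <- data.frame(
    splice_call = c("stronger", "stronger", "weaker", "weaker", "none"),
    export_call = c("increased_export", "decreased_export",
                    "decreased_export", "decreased_export",
                    "increased_export"))
  cs <- concordance_summary(eff)
  expect_equal(cs$n_eligible, 4L)
  expect_equal(cs$n_concordant, 3L)
  expect_equal(cs$percent, 75.0)
  all_conc <- data.frame(splice_call = c("stronger", "weaker"),
                         export_call = c("increased_export",
                                         "decreased_export"))
  expect_equal(concordance_summary(all_conc)$percent, 100.0)
})

test_that("splicing-coupled injections yield concordant calls at depth", {
  cfg <- sim_config(n_genes = 10, seed = 29, assay_depth = 4000,
                    junction_depth = 800)
  sim <- simulate_genome(cfg)
  ti <- sim$truth$introns
  picks <- ti[!duplicated(ti$gene_id), ][1:6, ]
  # stronger splicing is injected together with increased export
  # (odds multiplier < 1), matching the generative coupling
  eff <- data.frame(mutation_id = sprintf("m%02d", 1:6),
                    gene_id = picks$gene_id, position = 5L,
                    ref = "A", alt = "G",
                    odds_multiplier = rep(c(0.25, 4), 3),
                    psi_delta = 0,
                    intron_id = picks$intron_id)
  # orient psi_delta away from the boundary so the shift is realizable
  eff$psi_delta <- ifelse(eff$odds_multiplier < 1,
                          pmin(0.3, 0.95 - picks$splice_fraction),
                          -pmin(0.3, picks$splice_fraction - 0.05))
  assay <- simulate_mutation_assay(sim$models, eff, sim$truth, cfg)
  res <- merge(test_export_shift(count_alleles(assay$read_calls)),
               test_splice_shift(assay$junction_evidence),
               by = "mutation_id")
  cs <- concordance_summary(res)
  expect_gte(cs$n_eligible, 4L)
  expect_gte(cs$percent, 90)
})
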