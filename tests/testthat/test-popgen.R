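test_that("equal-rate site counting matches codon enumeration", {
  # TTT: of the nine single-nucleotide changes only TTT->TTC is synonymous
  s <- count_ng_sites("TTT")
  expect_equal(s$nonsyn_sites, 8 / 3)
  expect_equal(s$syn_sites, 1 / 3)
  # independent enumeration oracle over random CDS
  set.seed(3)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (rep in 1:5) {
    cds <- paste0(sample(sense, 20, replace = TRUE), collapse = "")
    got <- count_ng_sites(cds)
    ns <- 0; ss <- 0
    for (ci in seq(1, nchar(cds), 3)) {
      codon <- substring(cds, ci, ci + 2)
      for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                         substr(codon, pos, pos))) {
        mut <- codon; substr(mut, pos, pos) <- b
        if (code[[mut]] == code[[codon]] && code[[mut]] != "*")
          ss <- ss + 1 / 3 else ns <- ns + 1 / 3
      }
    }
    expect_equal(got$nonsyn_sites, ns)
    expect_equal(got$syn_sites, ss)
    expect_equal(got$nonsyn_sites + got$syn_sites, nchar(cds))
  }
  expect_error(count_ng_sites("TTTA"), "divisible")
  expect_error(count_ng_sites("TAATTT"), "stop")
})

test_that("pN/pS behaves at its boundary cases and centres near 1 when neutral", {
  cds <- "ATGGCTAGCGATCGATTTAAAGGG"
  # GCT->GCA and AGC->AGT are synonymous third-position changes
  syn <- data.frame(position = c(5L, 8L), alt = c("A", "T"))
  r <- pnps(cds, syn)
  expect_equal(r$n_nonsyn_poly, 0L)
  expect_equal(r$pnps, 0)
  # no variants at all: undefined, flagged, never a silent 0/0
  r0 <- pnps(cds, data.frame(position = integer(0), alt = character(0)))
  expect_false(r0$defined)
  expect_true(is.na(r0$pnps))
  # out-of-frame positions are skipped and tallied
  rs <- pnps(cds, data.frame(position = c(5L, 999L), alt = c("A", "G")))
  expect_equal(rs$n_skipped, 1L)
  # neutral simulation: variants uniform over positions, random alts
  set.seed(11)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  vals <- vapply(1:200, function(i) {
    cds_i <- paste0(sample(sense, 30, replace = TRUE), collapse = "")
    pos <- sample(0:(nchar(cds_i) - 1), 25)
    ref <- substring(cds_i, pos + 1, pos + 1)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  "")
    pnps(cds_i, data.frame(position = pos, alt = alt))$pnps
  }, numeric(1))
  expect_lt(abs(median(vals, na.rm = TRUE) - 1), 0.15)
})

test_that("DAF spectra are proper distributions with binomial-scale bootstrap SDs", {
  sp <- daf_spectrum(c(0.05, 0.06, 0.07), n_bins = 10)
  expect_equal(sp$proportions[1], 1)
  expect_equal(sum(sp$proportions), 1)
  set.seed(21)
  freqs <- runif(500, 0.001, 0.999)
  sp2 <- daf_spectrum(freqs, n_bins = 5, n_boot = 1000, seed = 2)
  expect_equal(sum(sp2$proportions), 1, tolerance = 1e-12)
  expected_sd <- sqrt(sp2$proportions * (1 - sp2$proportions) / 500)
  expect_true(all(abs(sp2$boot_sd - expected_sd) / expected_sd < 0.2))
  expect_error(daf_spectrum(numeric(0)), "no sites")
  expect_error(daf_spectrum(c(0.5, 1)), "in \\(0, 1\\)")
  # pooled spectrum equals the site-count-weighted mixture of class spectra
  f1 <- runif(300, 0.001, 0.999); f2 <- runif(100, 0.001, 0.999)
  s1 <- daf_spectrum(f1, n_bins = 8, n_boot = 10)
  s2 <- daf_spectrum(f2, n_bins = 8, n_boot = 10)
  pooled <- daf_spectrum(c(f1, f2), n_bins = 8, n_boot = 10)
  expect_equal(pooled$proportions,
               (300 * s1$proportions + 100 * s2$proportions) / 400)
})

test_that("g1 skewness matches the moment oracle", {
  expect_equal(skewness_g1(c(1, 2, 3)), 0)
  expect_gt(skewness_g1(c(1, 1, 1, 10)), 0)
  expect_error(skewness_g1(c(1, 2)), "at least 3")
  expect_error(skewness_g1(c(2, 2, 2)), "zero variance")
  skip_if_not_installed("e1071")
  set.seed(31)
  for (i in 1:100) {
    x <- rnorm(sample(5:50, 1))
    expect_equal(skewness_g1(x), e1071::skewness(x, type = 1),
                 tolerance = 1e-12)
  }
})

test_that("the Monte-Carlo skew test is calibrated and powered", {
  cfg <- sim_config(n_genes = 0, seed = 1, n_chromosomes_population = 100,
                    selection_classes = list(
                      synonymous = list(model = "neutral", n = 300),
                      focal = list(model = "constrained", shape = 2.5,
                                   n = 150)))
  pop <- simulate_population(cfg)
  neutral <- pop$derived_freq[pop$site_class == "synonymous"]
  focal <- pop$derived_freq[pop$site_class == "focal"]
  mt <- mc_skew_test(focal, neutral, n_boot = 5000, seed = 5)
  expect_lt(mt$p, 0.01)   # planted excess of rare derived alleles
  expect_gt(mt$p, 0)
  # p is always in (0, 1] by add-one smoothing
  mt2 <- mc_skew_test(neutral, neutral, n_boot = 200, seed = 6)
  expect_lte(mt2$p, 1)
  expect_gt(mt2$p, 0)
  # determinism
  expect_identical(mc_skew_test(focal, neutral, n_boot = 500, seed = 9),
                   mc_skew_test(focal, neutral, n_boot = 500, seed = 9))
})

test_that("segregating sites are classified by strand-resolved context", {
  m <- fit_maxent(consensus_sites(300), constraint_order = 2)
  flank <- "ACGA"
  sites <- data.frame(
    site_id = c("disrupt", "out", "badctx"),
    ref_context = c(paste0(flank, "CAGGT", "AAGT", flank),
                    paste0(strrep("A", 8), "C", strrep("A", 8)),
                    paste0(strrep("N", 8), "C", strrep("N", 8))),
    derived_allele = c("C", "G", "G"),
    lineage = "A", stringsAsFactors = FALSE)
  cl <- classify_segregating_sites(sites, m, channel = "splice")
  expect_equal(cl$effect_call[1], "weaken")
  expect_true(cl$in_window[1])
  expect_true(cl$in_window[2])          # scored, whatever the sign
  expect_false(cl$in_window[3])         # ambiguous context skipped
  expect_equal(cl$effect_call[3], "neutral")
})

test_that("lineage summaries report per-direction percentages, NA when empty", {
  cl <- data.frame(
    lineage = c(rep("human", 11), rep("macaque", 3)),
    channel = "splice",
    effect_call = c(rep("strengthen", 7), rep("weaken", 4),
                    rep("neutral", 3)))
  s <- summarize_lineage_effects(cl)
  hu <- s[s$lineage == "human", ]
  expect_equal(hu$percent_strengthen, 63.6)   # 7 of 11
  ma <- s[s$lineage == "macaque", ]
  expect_equal(ma$n_total, 0L)
  expect_true(is.na(ma$percent_strengthen))
})
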