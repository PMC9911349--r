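test_that("one-hot encoding is a bijection with zero columns for N", {
  m <- encode_onehot("ACGT")
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(unname(colSums(m)), rep(1, 4))
  expect_equal(unname(m), diag(4))
  expect_equal(unname(encode_onehot("N")), matrix(0, 1, 4))
  s <- "GATTACAGGTAAGTCC"
  expect_equal(decode_onehot(encode_onehot(s)), s)
})

test_that("extreme-N/C labeling takes the stated tails deterministically", {
  set.seed(2)
  n <- 200
  seqs <- setNames(vapply(1:n, function(i)
    paste0(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""),
    ""), sprintf("g%03d", 1:n))
  nc <- data.frame(gene_id = names(seqs), nc_ratio = rnorm(n),
                   passed_filter = TRUE)
  lab <- label_extremes(nc, seqs)
  expect_equal(sum(lab$label == "nuclear"), 10L)
  expect_equal(sum(lab$label == "cytosolic"), 10L)
  expect_equal(length(intersect(lab$gene_id[lab$label == "nuclear"],
                                lab$gene_id[lab$label == "cytosolic"])), 0L)
  # all-tied ratios: deterministic tie-break by gene id, still 2 x floor(0.05 n)
  nc$nc_ratio <- 1
  lab2 <- label_extremes(nc, seqs)
  expect_equal(nrow(lab2), 20L)
  expect_identical(lab2, label_extremes(nc, seqs))
  # over-length sequences are ineligible
  seqs[["g001"]] <- strrep("A", 6000)
  expect_false("g001" %in% label_extremes(nc, seqs)$gene_id)
})

test_that("the 8:1:1 split is stratified, deterministic, and near-exact", {
  lab <- data.frame(id = 1:100,
                    label = rep(c("nuclear", "cytosolic"), each = 50))
  sp <- split_dataset(lab, seed = 4)
  expect_equal(as.integer(table(sp$split)[c("train", "valid", "test")]),
               c(80L, 10L, 10L))
  tab <- table(sp$label, sp$split)
  expect_true(all(abs(tab["nuclear", ] - tab["cytosolic", ]) <= 1))
  expect_identical(sp, split_dataset(lab, seed = 4))
  expect_false(identical(sp$split, split_dataset(lab, seed = 5)$split))
})

test_that("rank-based AUC matches its definition and the pairwise oracle", {
  expect_equal(evaluate_auc(c(1, 2, 3, 4), c("c", "c", "n", "n"),
                            positive = "n"), 1)
  expect_equal(evaluate_auc(rep(1, 10), rep(c("c", "n"), 5), positive = "n"),
               0.5)
  set.seed(6)
  scores <- sample(100, 60, replace = TRUE)  # with ties
  labels <- sample(c("n", "c"), 60, replace = TRUE)
  pos <- which(labels == "n"); neg <- which(labels == "c")
  oracle <- mean(outer(scores[pos], scores[neg],
                       function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(evaluate_auc(scores, labels, positive = "n"), oracle)
  # invariant under strictly monotone transforms
  expect_equal(evaluate_auc(exp(scores / 20), labels, positive = "n"), oracle)
})

test_that("training memorizes two separable constant sequences", {
  train <- data.frame(
    sequence = rep(c(strrep("ACGTT", 20), strrep("TTGCA", 20)), each = 25),
    label = rep(c("nuclear", "cytosolic"), each = 25))
  valid <- train[c(1:5, 26:30), ]
  m <- train_cnn(cnn_spec(seed = 2, epochs = 15, pool_width = 8), train, valid)
  p <- predict(m, train$sequence)
  acc <- mean((p > 0.5) == (train$label == "nuclear"))
  expect_equal(acc, 1)
  expect_error(train_cnn(cnn_spec(), train[train$label == "nuclear", ], valid),
               "single class")
})

test_that("training is seed-deterministic", {
  ds <- simulate_localization_dataset(n = 120, len_range = c(300L, 600L),
                                      seed = 8)
  ds <- split_dataset(ds, seed = 8)
  sp <- cnn_spec(seed = 8, epochs = 5)
  m1 <- train_cnn(sp, ds[ds$split == "train", ], ds[ds$split == "valid", ])
  m2 <- train_cnn(sp, ds[ds$split == "train", ], ds[ds$split == "valid", ])
  expect_identical(m1$W, m2$W)
  te <- ds[ds$split == "test", ]
  expect_identical(evaluate_auc(predict(m1, te$sequence), te$label),
                   evaluate_auc(predict(m2, te$sequence), te$label))
})

test_that("motif extraction recovers a filter planted as the motif matcher", {
  pwm <- matrix(0.1 / 3, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("G", "G", "T", "A", "A", "G", "T")
  for (k in 1:7) pwm[cons[k], k] <- 0.9
  # hand-built model: filter 1's weights are the log-PWM at offsets 1..7
  # of the 11-nt window, filter 2 is inert
  W <- matrix(rep(log(0.1 / 3), 44), 44, 2)
  for (k in 1:7) for (bidx in 1:4)
    W[k * 4 + bidx, 1] <- log(pwm[bidx, k])
  W[, 2] <- 0
  model <- structure(list(
    spec = cnn_spec(n_filters = 2, seed = 1),
    W = W, b = c(30, 0), v = c(1, 0), cc = 0), class = "cnn_model")
  set.seed(9)
  seqs <- vapply(1:30, function(i) {
    s <- paste0(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
    substr(s, 50, 56) <- "GGTAAGT"
    s
  }, "")
  mot <- extract_motifs(model, seqs, top_k = 5, activation_quantile = 0.9)
  expect_lte(length(mot), 2L)
  best <- mot[[1]]
  expect_equal(best$filter_id, 1L)
  expect_gt(pfm_correlation(best$pfm, pwm), 0.8)
  expect_equal(unname(colSums(best$pfm)),
               rep(best$n_contributing_windows, 11))
})

test_that("shuffled labels give chance-level AUC", {
  ds <- simulate_localization_dataset(n = 160, len_range = c(300L, 700L),
                                      seed = 10)
  aucs <- vapply(1:3, function(s) {
    set.seed(100 + s)
    ds$label <- sample(ds$label)
    dsp <- split_dataset(ds, seed = s)
    m <- train_cnn(cnn_spec(seed = s, epochs = 6),
                   dsp[dsp$split == "train", ], dsp[dsp$split == "valid", ])
    te <- dsp[dsp$split == "test", ]
    evaluate_auc(predict(m, te$sequence), te$label)
  }, numeric(1))
  expect_true(all(aucs >= 0.25 & aucs <= 0.75))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})
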