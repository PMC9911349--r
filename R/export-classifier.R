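#' One-hot encode a nucleotide sequence
#'
#' @param sequence ACGTN string.
#' @return an nchar x 4 binary matrix (columns A, C, G, T); `N` rows are
#'   all-zero.
#' @export
encode_onehot <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(ch, BASES)
  m <- matrix(0, length(ch), 4L, dimnames = list(NULL, BASES))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence string
#' @param m matrix from [encode_onehot()].
#' @return character string ("N" for all-zero rows).
#' @export
decode_onehot <- function(m) {
  paste0(apply(m, 1, function(r) {
    i <- which(r == 1)
    if (length(i) == 1L) BASES[i] else "N"
  }), collapse = "")
}

#' Label transcripts at the extremes of the N/C distribution
#'
#' The classifier's training labels: transcripts in the highest `fraction`
#' of the N/C ratio distribution are "nuclear", the lowest `fraction`
#' "cytosolic" (default 5% each). Only filter-passing genes with sequence
#' length below `max_len` are eligible; boundary ties break by gene id so
#' labeling is deterministic.
#'
#' @param nc_table data.frame with gene_id, nc_ratio, passed_filter.
#' @param sequences named character vector of transcript sequences.
#' @param fraction per-class tail fraction.
#' @param max_len sequence length cap (exclusive).
#' @return data.frame (gene_id, sequence, label).
#' @export
label_extremes <- function(nc_table, sequences, fraction = 0.05,
                           max_len = 5000L) {
  el <- nc_table[nc_table$passed_filter & nc_table$gene_id %in% names(sequences), ,
                 drop = FALSE]
  el$sequence <- unname(sequences[el$gene_id])
  el <- el[nchar(el$sequence) < max_len, , drop = FALSE]
  k <- floor(fraction * nrow(el))
  if (k == 0L) return(data.frame(gene_id = character(0),
                                 sequence = character(0),
                                 label = character(0)))
  up <- el[order(-el$nc_ratio, el$gene_id), ][seq_len(k), ]
  pool <- el[!el$gene_id %in% up$gene_id, , drop = FALSE]
  dn <- pool[order(pool$nc_ratio, pool$gene_id), ][seq_len(min(k, nrow(pool))), ]
  out <- rbind(
    data.frame(gene_id = up$gene_id, sequence = up$sequence,
               label = "nuclear", stringsAsFactors = FALSE),
    data.frame(gene_id = dn$gene_id, sequence = dn$sequence,
               label = "cytosolic", stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Stratified train/validation/test split
#'
#' @param labeled data.frame with a `label` column.
#' @param ratios train/valid/test proportions (default 8:1:1).
#' @param seed integer seed; same seed gives the identical assignment.
#' @return input with a `split` column (train/valid/test), class-stratified
#'   with each split within one sequence of the exact proportion per class.
#' @export
split_dataset <- function(labeled, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  ratios <- ratios / sum(ratios)
  set.seed(seed)
  labeled$split <- NA_character_
  for (idx in split(seq_len(nrow(labeled)), labeled$label)) {
    n <- length(idx)
    n_valid <- floor(ratios[2] * n)
    n_test <- floor(ratios[3] * n)
    perm <- sample(idx)
    labeled$split[perm[seq_len(n_valid)]] <- "valid"
    labeled$split[perm[n_valid + seq_len(n_test)]] <- "test"
    labeled$split[perm[-(seq_len(n_valid + n_test))]] <- "train"
  }
  labeled
}

#' Classifier specification
#'
#' Architecture: one convolutional layer of `n_filters` filters of width
#' `filter_width` (11 nt, the first-layer receptive field through which the
#' network reads the sequence in 11-bp windows) with ReLU, a pooling layer
#' (local max over tiled regions, averaged -- sensitive to motif counts,
#' not just presence), and one fully connected sigmoid output unit. Trained with Adam on binary cross-entropy and early
#' stopping on validation loss.
#'
#' @param filter_width first-layer filter width, nt.
#' @param n_filters number of first-layer filters.
#' @param pooling "avgmax" (local max pooling over `pool_width`-window
#'   regions, region values ReLU'd and averaged; motif-count sensitive) or
#'   "max" (global best match).
#' @param pool_width region width (in windows) for avgmax pooling.
#' @param lr Adam learning rate.
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param positive_class label mapped to output 1.
#' @param seed integer seed; training is fully seed-deterministic.
#' @return a `cnn_spec` list.
#' @export
cnn_spec <- function(filter_width = 11L, n_filters = 16L,
                     pooling = "avgmax", pool_width = 24L,
                     lr = 0.02, epochs = 40L, batch_size = 32L,
                     patience = 5L, positive_class = "nuclear", seed = 1L) {
  stopifnot(pooling %in% c("avgmax", "max"), filter_width >= 1, n_filters >= 1,
            pool_width >= 1)
  structure(list(filter_width = as.integer(filter_width),
                 n_filters = as.integer(n_filters), pooling = pooling,
                 pool_width = as.integer(pool_width),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 positive_class = positive_class, seed = as.integer(seed)),
            class = c("cnn_spec", "list"))
}

encode_set <- function(sequences) lapply(sequences, encode_onehot)

cnn_forward_set <- function(X_list, W, b, v, cc, pooling, pool_width) {
  t(vapply(X_list, function(X) {
    fw <- conv_pool_forward(X, W, b, pooling, pool_width)
    h <- fw$pooled
    c(stats::plogis(sum(v * h) + cc), h)
  }, numeric(1L + length(b))))
}

#' Train the nuclear-export sequence classifier
#'
#' @param spec a [cnn_spec()].
#' @param train,valid data.frames with `sequence` and `label` columns;
#'   both classes must be present in the training set.
#' @return a `cnn_model` with weights, the spec and a per-epoch training
#'   history.
#' @export
train_cnn <- function(spec, train, valid) {
  if (nrow(train) == 0L || nrow(valid) == 0L)
    stop("train_cnn: empty training or validation set")
  if (length(unique(train$label)) < 2L)
    stop("train_cnn: training set contains a single class")
  set.seed(spec$seed)
  nW <- spec$filter_width * 4L
  Ff <- spec$n_filters
  W <- matrix(stats::rnorm(nW * Ff, sd = 0.1), nW, Ff)
  b <- rep(0, Ff)
  v <- stats::rnorm(Ff, sd = 0.1)
  cc <- 0

  Xtr <- encode_set(train$sequence)
  ytr <- as.numeric(train$label == spec$positive_class)
  Xva <- encode_set(valid$sequence)
  yva <- as.numeric(valid$label == spec$positive_class)

  # Adam state
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
  mW <- W * 0; vW <- W * 0; mb <- b * 0; vb <- b * 0
  mv <- v * 0; vv <- v * 0; mc <- 0; vc <- 0

  bce <- function(p, y) -mean(y * log(pmax(p, 1e-12)) +
                              (1 - y) * log(pmax(1 - p, 1e-12)))
  best <- list(loss = Inf, W = W, b = b, v = v, cc = cc, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        valid_loss = numeric(0))
  stall <- 0L
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample(length(Xtr))
    for (batch in split(ord, ceiling(seq_along(ord) / spec$batch_size))) {
      gW <- W * 0; gb <- b * 0; gv <- v * 0; gc_ <- 0
      for (i in batch) {
        fw <- conv_pool_forward(Xtr[[i]], W, b, spec$pooling, spec$pool_width)
        h <- fw$pooled
        p <- stats::plogis(sum(v * h) + cc)
        g <- (p - ytr[i]) / length(batch)
        gv <- gv + g * h
        gc_ <- gc_ + g
        dh <- g * v
        if (any(dh != 0)) {
          bw <- conv_pool_backward(Xtr[[i]], W, b, dh, spec$pooling,
                                   spec$pool_width)
          gW <- gW + bw$gW
          gb <- gb + bw$gb
        }
      }
      tstep <- tstep + 1
      corr <- sqrt(1 - beta2^tstep) / (1 - beta1^tstep)
      mW <- beta1 * mW + (1 - beta1) * gW; vW <- beta2 * vW + (1 - beta2) * gW^2
      W <- W - spec$lr * corr * mW / (sqrt(vW) + eps)
      mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
      b <- b - spec$lr * corr * mb / (sqrt(vb) + eps)
      mv <- beta1 * mv + (1 - beta1) * gv; vv <- beta2 * vv + (1 - beta2) * gv^2
      v <- v - spec$lr * corr * mv / (sqrt(vv) + eps)
      mc <- beta1 * mc + (1 - beta1) * gc_; vc <- beta2 * vc + (1 - beta2) * gc_^2
      cc <- cc - spec$lr * corr * mc / (sqrt(vc) + eps)
    }
    ptr <- cnn_forward_set(Xtr, W, b, v, cc, spec$pooling, spec$pool_width)[, 1]
    pva <- cnn_forward_set(Xva, W, b, v, cc, spec$pooling, spec$pool_width)[, 1]
    tl <- bce(ptr, ytr); vl <- bce(pva, yva)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                         valid_loss = vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, W = W, b = b, v = v, cc = cc, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= spec$patience) break
    }
  }
  structure(list(spec = spec, W = best$W, b = best$b, v = best$v,
                 cc = best$cc, best_epoch = best$epoch,
                 valid_loss = best$loss, history = history),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "cnn_model: %d filters x %d nt, %s pooling; best epoch %d (valid loss %.4f)\n",
    x$spec$n_filters, x$spec$filter_width, x$spec$pooling,
    x$best_epoch, x$valid_loss))
  invisible(x)
}

#' Predicted probability of the positive (nuclear) class
#' @param object a `cnn_model`.
#' @param sequences character vector of sequences.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.cnn_model <- function(object, sequences, ...) {
  X <- encode_set(sequences)
  cnn_forward_set(X, object$W, object$b, object$v, object$cc,
                  object$spec$pooling, object$spec$pool_width)[, 1]
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive scores above a random negative (ties counted half).
#'
#' @param scores numeric predictions.
#' @param labels class labels.
#' @param positive label counted as positive.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(scores, labels, positive = "nuclear") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("evaluate_auc: need both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Extract motifs from first-layer activations
#'
#' For each first-layer filter, collects the windows whose activation
#' reaches at least `activation_quantile` of that filter's maximum
#' activation over the sequence set, builds a position-frequency matrix
#' from them, and ranks filters by their mean top-window activation.
#'
#' @param model a trained `cnn_model`.
#' @param sequences character vector of sequences to scan.
#' @param top_k number of filters to return (all if larger than the filter
#'   count).
#' @param activation_quantile fraction of the per-filter maximum required
#'   for a window to contribute.
#' @return list of motifs, each with filter_id, rank, activation_score,
#'   pfm (4 x width counts; columns sum to n_contributing_windows),
#'   n_contributing_windows.
#' @export
extract_motifs <- function(model, sequences, top_k = 5L,
                           activation_quantile = 0.5) {
  if (length(sequences) == 0L) stop("extract_motifs: no sequences")
  X <- encode_set(sequences)
  Ff <- model$spec$n_filters
  w <- model$spec$filter_width
  # pass 1: per-filter maximum activation
  fmax <- rep(-Inf, Ff)
  acts <- lapply(X, function(x) conv_activations(x, model$W, model$b))
  for (A in acts) if (nrow(A) > 0) fmax <- pmax(fmax, apply(A, 2, max))
  thr <- activation_quantile * fmax
  # pass 2: collect contributing windows
  pfm <- lapply(seq_len(Ff), function(f) matrix(0, 4, w,
                                                dimnames = list(BASES, NULL)))
  nwin <- rep(0L, Ff)
  act_sum <- rep(0, Ff)
  for (i in seq_along(X)) {
    A <- acts[[i]]
    if (nrow(A) == 0) next
    for (f in seq_len(Ff)) {
      sel <- which(A[, f] >= thr[f] & A[, f] > 0)
      for (t in sel) {
        pfm[[f]] <- pfm[[f]] + t(X[[i]][t:(t + w - 1L), , drop = FALSE])
        nwin[f] <- nwin[f] + 1L
        act_sum[f] <- act_sum[f] + A[t, f]
      }
    }
  }
  score <- ifelse(nwin > 0, act_sum / nwin, -Inf)
  ord <- order(-score)
  keep <- ord[seq_len(min(top_k, Ff))]
  lapply(seq_along(keep), function(r) {
    f <- keep[r]
    list(filter_id = f, rank = r, activation_score = score[f],
         pfm = pfm[[f]], n_contributing_windows = nwin[f])
  })
}

#' Best-alignment correlation between a PFM and a reference PWM
#'
#' Column-normalizes the PFM and slides the (possibly narrower) reference
#' PWM across it, returning the maximal Pearson correlation over offsets.
#'
#' @param pfm 4 x w count or probability matrix.
#' @param ref_pwm 4 x w2 probability matrix, w2 <= w.
#' @return maximal Pearson correlation.
#' @export
pfm_correlation <- function(pfm, ref_pwm) {
  cs <- colSums(pfm)
  cs[cs == 0] <- 1
  p <- sweep(pfm, 2, cs, "/")
  w <- ncol(p); w2 <- ncol(ref_pwm)
  if (w2 > w) stop("pfm_correlation: reference wider than PFM")
  best <- -1
  for (off in 0:(w - w2)) {
    sub <- p[, off + seq_len(w2), drop = FALSE]
    best <- max(best, stats::cor(as.vector(sub), as.vector(ref_pwm)))
  }
  best
}
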