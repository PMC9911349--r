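#' Simulate a labeled nuclear/cytosolic sequence classification task
#'
#' Generates mature transcript sequences whose subcellular label is driven
#' by planted exonic U1 motifs, the sequence-visible component of the
#' export log-odds (splice strength acts through motif retention: poorly
#' spliced, nucleus-bound transcripts retain U1-bearing sequence, fully
#' spliced cytosolic transcripts do not). Nuclear sequences carry
#' Poisson(`rate_nuc` per kb) planted copies of [u1_consensus()] (at least
#' `min_nuc`), cytosolic sequences Poisson(`rate_cyt` per kb) copies, which
#' makes the classes near-separable: the attribute `bayes_error` reports
#' the exact error of the optimal count-based classifier under the
#' generative model.
#'
#' @param n total sequences (half per class).
#' @param len_range nt length range, uniform.
#' @param rate_nuc,rate_cyt planted motifs per kb per class.
#' @param min_nuc minimum planted motifs in a nuclear sequence.
#' @param gc_content background GC.
#' @param u1_mutation_rate per-base mutation of the planted consensus.
#' @param seed integer seed.
#' @return data.frame (seq_id, sequence, label in nuclear/cytosolic,
#'   n_planted) with attributes `planted_pwm` (4 x 7 probability matrix of
#'   the planting distribution) and `bayes_error`.
#' @export
simulate_localization_dataset <- function(n = 2000L,
                                          len_range = c(500L, 2000L),
                                          rate_nuc = 6, rate_cyt = 0.15,
                                          min_nuc = 2L,
                                          gc_content = 0.45,
                                          u1_mutation_rate = 0.1,
                                          seed = 1L) {
  set.seed(seed)
  n_nuc <- n %/% 2L
  labels <- c(rep("nuclear", n_nuc), rep("cytosolic", n - n_nuc))
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  seqs <- character(n); planted <- integer(n)
  for (i in seq_len(n)) {
    s <- random_seq(lens[i], gc_content)
    rate <- if (labels[i] == "nuclear") rate_nuc else rate_cyt
    n_target <- stats::rpois(1, rate * lens[i] / 1000)
    if (labels[i] == "nuclear") n_target <- max(n_target, min_nuc)
    placed <- integer(0)
    attempts <- 0L
    usable <- lens[i] - 7L
    while (length(placed) < n_target && attempts < 50L * max(n_target, 1L)) {
      attempts <- attempts + 1L
      pos <- sample.int(usable + 1L, 1)
      if (!any(abs(pos - placed) < 7L)) {
        substr(s, pos, pos + 6L) <- mutate_consensus(u1_consensus(),
                                                     u1_mutation_rate)
        placed <- c(placed, pos)
      }
    }
    seqs[i] <- s
    planted[i] <- length(placed)
  }
  out <- data.frame(seq_id = sprintf("seq%04d", seq_len(n)),
                    sequence = seqs, label = labels, n_planted = planted,
                    stringsAsFactors = FALSE)
  # exact Bayes error of the optimal count-based rule, averaged over lengths
  lens_grid <- seq(len_range[1], len_range[2])
  kmax <- 50L
  be <- mean(vapply(lens_grid, function(L) {
    lam_n <- rate_nuc * L / 1000; lam_c <- rate_cyt * L / 1000
    k <- 0:kmax
    p_n <- stats::dpois(k, lam_n)
    p_n[k < min_nuc] <- 0; p_n[k == min_nuc] <- stats::ppois(min_nuc, lam_n)
    p_c <- stats::dpois(k, lam_c)
    sum(pmin(p_n, p_c)) / 2
  }, numeric(1)))
  # empirical PWM of the planting distribution
  cons <- seq_to_digits(u1_consensus())
  pwm <- matrix(u1_mutation_rate / 3, 4, 7, dimnames = list(BASES, NULL))
  for (k in seq_len(7)) pwm[cons[k] + 1L, k] <- 1 - u1_mutation_rate
  attr(out, "planted_pwm") <- pwm
  attr(out, "bayes_error") <- be
  out
}
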