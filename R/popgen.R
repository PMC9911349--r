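#' Nonsynonymous and synonymous site counts of a CDS
#'
#' Equal-rate (Nei-Gojobori-style) site counting: for each codon, each of
#' the nine possible single-nucleotide changes is classified against the
#' standard genetic code; a codon position contributes
#' (nonsynonymous changes)/3 nonsynonymous sites and (synonymous)/3
#' synonymous sites, so every position contributes exactly one site in
#' total. Changes that create a stop codon count as nonsynonymous.
#'
#' @param coding_sequence in-frame CDS (length divisible by 3, no internal
#'   stop codons).
#' @return list(nonsyn_sites, syn_sites), possibly fractional.
#' @export
count_ng_sites <- function(coding_sequence) {
  coding_sequence <- toupper(coding_sequence)
  L <- nchar(coding_sequence)
  if (L %% 3 != 0) stop("count_ng_sites: length not divisible by 3")
  code <- Biostrings::GENETIC_CODE
  codons <- substring(coding_sequence, seq(1, L, 3), seq(3, L, 3))
  aas <- code[codons]
  if (anyNA(aas)) stop("count_ng_sites: non-ACGT codon")
  internal <- aas[-length(aas)] == "*"
  if (any(internal))
    stop("count_ng_sites: internal stop codon at codon ", which(internal)[1])
  ns <- 0; ss <- 0
  for (cd in codons) {
    ch <- strsplit(cd, "")[[1]]
    aa0 <- code[[cd]]
    for (pos in 1:3) for (b in setdiff(BASES, ch[pos])) {
      mut <- ch; mut[pos] <- b
      aa1 <- code[[paste0(mut, collapse = "")]]
      if (aa1 == aa0 && aa1 != "*") ss <- ss + 1 / 3 else ns <- ns + 1 / 3
    }
  }
  list(nonsyn_sites = ns, syn_sites = ss)
}

#' pN/pS from polymorphism counts and site counts
#'
#' `pnps = (n_nonsyn / nonsyn_sites) / (n_syn / syn_sites)`. Variants
#' outside aligned codon positions are skipped and tallied. With no
#' synonymous polymorphism the ratio is undefined (NA with a flag), never
#' a silent 0/0.
#'
#' @param cds in-frame coding (or pseudo-coding) sequence; for non-coding
#'   orthologues, the frame projected from the homologous protein through
#'   a codon-level alignment.
#' @param variants data.frame with `position` (0-based within `cds`) and
#'   `alt` columns.
#' @return list(n_nonsyn_poly, n_syn_poly, nonsyn_sites, syn_sites, pnps,
#'   defined, n_skipped).
#' @export
pnps <- function(cds, variants) {
  cds <- toupper(cds)
  L <- nchar(cds)
  sites <- count_ng_sites(cds)
  code <- Biostrings::GENETIC_CODE
  n_non <- 0L; n_syn <- 0L; skipped <- 0L
  for (i in seq_len(nrow(variants))) {
    pos <- variants$position[i]
    if (is.na(pos) || pos < 0 || pos >= L) { skipped <- skipped + 1L; next }
    cstart <- (pos %/% 3) * 3 + 1
    codon <- substring(cds, cstart, cstart + 2)
    mut <- codon
    substr(mut, pos %% 3 + 1, pos %% 3 + 1) <- variants$alt[i]
    if (is.na(code[mut])) { skipped <- skipped + 1L; next }
    if (code[[mut]] == code[[codon]] && code[[mut]] != "*")
      n_syn <- n_syn + 1L
    else n_non <- n_non + 1L
  }
  defined <- n_syn > 0
  list(n_nonsyn_poly = n_non, n_syn_poly = n_syn,
       nonsyn_sites = sites$nonsyn_sites, syn_sites = sites$syn_sites,
       pnps = if (defined)
         (n_non / sites$nonsyn_sites) / (n_syn / sites$syn_sites)
       else NA_real_,
       defined = defined, n_skipped = skipped)
}

#' Derived-allele-frequency spectrum with bootstrap errors
#'
#' Bins derived-allele frequencies into `n_bins` equal-width bins on (0, 1)
#' and estimates the standard deviation of each bin proportion by
#' resampling sites with replacement (1,000 replicates by default).
#'
#' @param freqs derived-allele frequencies in (0, 1).
#' @param n_bins number of equal-width bins.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return list(breaks, proportions, boot_sd, n_sites).
#' @export
daf_spectrum <- function(freqs, n_bins = 10L, n_boot = 1000L, seed = 1L) {
  if (length(freqs) == 0L) stop("daf_spectrum: no sites")
  if (any(freqs <= 0 | freqs >= 1)) stop("daf_spectrum: freqs must lie in (0, 1)")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(freqs, breaks, rightmost.closed = TRUE)
  prop <- tabulate(bin, nbins = n_bins) / length(freqs)
  set.seed(seed)
  n <- length(freqs)
  boot <- matrix(0, n_boot, n_bins)
  for (r in seq_len(n_boot)) {
    rb <- bin[sample.int(n, n, replace = TRUE)]
    boot[r, ] <- tabulate(rb, nbins = n_bins) / n
  }
  list(breaks = breaks, proportions = prop,
       boot_sd = apply(boot, 2, stats::sd), n_sites = n)
}

#' Sample skewness (g1)
#'
#' Third standardized central moment, `g1 = m3 / m2^(3/2)` with biased
#' central moments (denominator n).
#'
#' @param values numeric vector, length >= 3, non-zero variance.
#' @return g1.
#' @export
skewness_g1 <- function(values) {
  n <- length(values)
  if (n < 3L) stop("skewness_g1: need at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("skewness_g1: zero variance")
  mean((values - m)^3) / m2^1.5
}

# vectorized g1 over the rows of a matrix (internal, for the Monte Carlo)
row_skewness <- function(M) {
  mu <- rowMeans(M)
  D <- M - mu
  m2 <- rowMeans(D^2)
  rowMeans(D^3) / m2^1.5
}

#' Monte-Carlo test for a left-skewed frequency spectrum
#'
#' Tests whether the focal sites' derived-allele frequencies are more
#' left-skewed (excess of rare derived alleles) than a neutral background.
#' The null distribution is the skewness of `length(focal)` sites resampled
#' with replacement from the neutral frequencies, repeated `n_boot` times
#' (10,000 by default). A left-leaning spectrum (mass piled on low
#' frequencies) makes the skewness of the frequency values more positive,
#' so the one-sided p-value is
#' `(1 + #{null skewness >= observed}) / (n_boot + 1)`, always in (0, 1].
#'
#' @param focal_freqs,neutral_freqs derived-allele frequencies.
#' @param n_boot Monte-Carlo replicates.
#' @param seed integer seed.
#' @param alternative "left" (default; excess of rare derived alleles) or
#'   "two.sided".
#' @return list(observed_skewness, p, n_focal, n_boot).
#' @export
mc_skew_test <- function(focal_freqs, neutral_freqs, n_boot = 10000L,
                         seed = 1L, alternative = c("left", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(focal_freqs) < 3L || length(neutral_freqs) < 3L)
    stop("mc_skew_test: need at least 3 sites in each set")
  obs <- skewness_g1(focal_freqs)
  set.seed(seed)
  nf <- length(focal_freqs)
  M <- matrix(sample(neutral_freqs, n_boot * nf, replace = TRUE), n_boot, nf)
  null <- row_skewness(M)
  null <- null[is.finite(null)]
  p_left <- (1 + sum(null >= obs)) / (length(null) + 1)
  p <- if (alternative == "left") p_left
       else min(1, 2 * min(p_left, (1 + sum(null <= obs)) / (length(null) + 1)))
  list(observed_skewness = obs, p = p, n_focal = nf, n_boot = n_boot)
}

#' Classify segregating sites by their motif-score effect
#'
#' For each site, computes the variant delta-score in its sequence context
#' with [variant_delta_score()] and calls the site strengthen / weaken /
#' neutral by the sign. Sites whose context is unavailable or contains
#' ambiguous bases are flagged out-of-window and called neutral.
#'
#' @param sites data.frame with `ref_context` (length 2*width - 1, variant
#'   centred, transcribed strand) and `derived_allele` columns plus any
#'   identifier columns (carried through).
#' @param motif_model a `maxent_model`.
#' @param channel label for the score channel ("U1" or "splice").
#' @return input with delta, effect_call, channel, in_window columns added.
#' @export
classify_segregating_sites <- function(sites, motif_model, channel = "U1") {
  n <- nrow(sites)
  delta <- rep(NA_real_, n); call <- rep("neutral", n)
  in_window <- rep(FALSE, n)
  w <- motif_model$width
  for (i in seq_len(n)) {
    ctx <- sites$ref_context[i]
    if (is.na(ctx) || nchar(ctx) != 2 * w - 1 ||
        grepl("[^ACGTacgt]", ctx) ||
        !sites$derived_allele[i] %in% BASES) next
    vd <- variant_delta_score(motif_model, toupper(ctx),
                              sites$derived_allele[i])
    delta[i] <- vd$delta
    call[i] <- vd$call
    in_window[i] <- TRUE
  }
  sites$delta <- delta
  sites$effect_call <- call
  sites$channel <- channel
  sites$in_window <- in_window
  sites
}

#' Per-lineage summary of segregating-site effects
#'
#' Counts strengthen/weaken calls per (lineage, channel) cell and reports
#' the percentage of strengthening sites among non-neutral sites, rounded
#' to one decimal. Neutral sites are excluded from denominators; empty
#' cells report NA, never 0%.
#'
#' @param classified data.frame with lineage, channel, effect_call columns.
#' @return data.frame (lineage, channel, n_strengthen, n_weaken, n_total,
#'   percent_strengthen).
#' @export
summarize_lineage_effects <- function(classified) {
  cls <- classified[classified$effect_call %in% c("strengthen", "weaken"), ,
                    drop = FALSE]
  combos <- unique(classified[, c("lineage", "channel"), drop = FALSE])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- cls$lineage == combos$lineage[i] & cls$channel == combos$channel[i]
    ns <- sum(cls$effect_call[sel] == "strengthen")
    nw <- sum(cls$effect_call[sel] == "weaken")
    data.frame(lineage = combos$lineage[i], channel = combos$channel[i],
               n_strengthen = ns, n_weaken = nw, n_total = ns + nw,
               percent_strengthen = if (ns + nw > 0)
                 round(100 * ns / (ns + nw), 1) else NA_real_,
               percent_weaken = if (ns + nw > 0)
                 round(100 * nw / (ns + nw), 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
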