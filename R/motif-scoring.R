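BASES <- c("A", "C", "G", "T")

# sequence string -> integer digits 0..3 (NA for ambiguous bases)
seq_to_digits <- function(s) {
  m <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES) - 1L
  m
}

# enumeration of the full site space: 4^width x width matrix of digits,
# most significant position first (row r encodes site index r)
site_space_digits <- function(width) {
  n <- 4L^width
  D <- matrix(0L, n, width)
  for (k in seq_len(width)) {
    block <- 4L^(width - k)
    D[, k] <- (seq_len(n) - 1L) %/% block %% 4L
  }
  D
}

digits_to_index <- function(d) {
  # d: matrix (n x width) of digits; returns 1-based site indices
  w <- ncol(d)
  idx <- rep(0, nrow(d))
  for (k in seq_len(w)) idx <- idx + d[, k] * 4^(w - k)
  idx + 1
}

#' Canonical U1 recognition 7-mer
#'
#' The 5'-splice-site-like consensus recognized by the U1 snRNP. Used as
#' the default planted motif by the synthetic-data generator.
#' @return "GGTAAGT"
#' @export
u1_consensus <- function() "GGTAAGT"

#' Fit a maximum-entropy site model
#'
#' Fits the maximum-entropy distribution over fixed-width sites subject to
#' positional marginal constraints estimated from training sites. With
#' `constraint_order = 1` the solution is the product of positional
#' marginals (closed form). With `constraint_order = 2` all pairwise
#' positional marginals are imposed and the distribution is obtained by
#' iterative proportional fitting on the full 4^width table, run until the
#' maximum marginal deviation is below `tol` or `max_sweeps` sweeps.
#'
#' Scores are log2-odds against a 0-order background; the `strong_threshold`
#' is the exact `strong_quantile` quantile of the score distribution under
#' the background (computed by weighted enumeration of the site space, no
#' sampling involved).
#'
#' @param training_sites character vector of equal-length ACGT strings.
#' @param constraint_order 1 or 2.
#' @param pseudocount added per cell when estimating marginals (default 0.5;
#'   use 0 for exact closed-form checks).
#' @param background length-4 nucleotide distribution (A,C,G,T), default
#'   uniform.
#' @param strong_quantile background quantile defining a "strong" site.
#' @param tol IPF convergence tolerance on marginal deviation.
#' @param max_sweeps IPF sweep cap.
#' @return an object of class `maxent_model`.
#' @export
fit_maxent <- function(training_sites, constraint_order = 2,
                       pseudocount = 0.5,
                       background = rep(0.25, 4),
                       strong_quantile = 0.95,
                       tol = 1e-4, max_sweeps = 500L) {
  if (length(training_sites) == 0L) stop("fit_maxent: empty training set")
  width <- nchar(training_sites[1])
  if (!all(nchar(training_sites) == width))
    stop("fit_maxent: training sites of unequal width")
  if (!constraint_order %in% c(1, 2)) stop("fit_maxent: constraint_order must be 1 or 2")
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  dm <- t(vapply(training_sites, seq_to_digits, integer(width), USE.NAMES = FALSE))
  if (anyNA(dm)) stop("fit_maxent: non-ACGT symbol in training sites")
  D <- site_space_digits(width)
  n_space <- nrow(D)

  # positional marginals (with pseudocount)
  marg1 <- vapply(seq_len(width), function(k) {
    cnt <- tabulate(dm[, k] + 1L, nbins = 4L) + pseudocount
    cnt / sum(cnt)
  }, numeric(4))  # 4 x width

  if (constraint_order == 1) {
    logp <- rep(0, n_space)
    for (k in seq_len(width)) logp <- logp + log(marg1[D[, k] + 1L, k])
    p <- exp(logp)
    n_sweeps <- 0L
    max_dev <- 0
  } else {
    pairs <- utils::combn(width, 2)
    targets <- vector("list", ncol(pairs))
    gidx <- vector("list", ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      cnt <- tabulate(dm[, i1] * 4L + dm[, i2] + 1L, nbins = 16L) + pseudocount
      targets[[j]] <- cnt / sum(cnt)
      gidx[[j]] <- D[, i1] * 4L + D[, i2] + 1L
    }
    p <- rep(1 / n_space, n_space)
    n_sweeps <- 0L
    repeat {
      n_sweeps <- n_sweeps + 1L
      for (j in seq_along(targets)) {
        m <- as.vector(rowsum(p, gidx[[j]]))
        p <- p * (targets[[j]] / m)[gidx[[j]]]
      }
      p <- p / sum(p)
      max_dev <- 0
      for (j in seq_along(targets)) {
        m <- as.vector(rowsum(p, gidx[[j]]))
        max_dev <- max(max_dev, max(abs(m - targets[[j]])))
      }
      if (max_dev < tol || n_sweeps >= max_sweeps) break
    }
  }
  p <- p / sum(p)

  # background probability of every site and log2-odds scores
  logb <- rep(0, n_space)
  for (k in seq_len(width)) logb <- logb + log(background[D[, k] + 1L])
  pb <- exp(logb)
  scores <- log2(p) - log2(pb)  # -Inf allowed when p == 0 (pseudocount 0)

  # exact background quantile of the score distribution
  ord <- order(scores)
  cum <- cumsum(pb[ord])
  strong_threshold <- scores[ord][which(cum >= strong_quantile)[1]]

  structure(list(
    width = width, constraint_order = constraint_order,
    pseudocount = pseudocount, background = background,
    marg1 = marg1, prob = p, score_table = scores,
    strong_quantile = strong_quantile, strong_threshold = strong_threshold,
    ipf_sweeps = n_sweeps, ipf_max_dev = max_dev
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: width %d, order %d, strong threshold %.3f (q=%.2f)\n",
    x$width, x$constraint_order, x$strong_threshold, x$strong_quantile))
  invisible(x)
}

#' Marginal distribution of a fitted model over chosen positions
#'
#' @param model a `maxent_model`.
#' @param positions integer vector of 1 or 2 positions.
#' @return probability vector (length 4 or 16, second position fastest).
#' @export
model_marginal <- function(model, positions) {
  D <- site_space_digits(model$width)
  if (length(positions) == 1L) {
    g <- D[, positions] + 1L
    nb <- 4L
  } else if (length(positions) == 2L) {
    g <- D[, positions[1]] * 4L + D[, positions[2]] + 1L
    nb <- 16L
  } else stop("model_marginal: 1 or 2 positions")
  as.vector(rowsum(model$prob, factor(g, levels = seq_len(nb))))
}

#' Log2-odds score of a site
#' @param model a `maxent_model`.
#' @param site ACGT string of the model's width (vectorized).
#' @return log2(P_model / P_background); `-Inf` for sites the model assigns
#'   zero probability (possible only with pseudocount 0).
#' @export
score_site <- function(model, site) {
  vapply(site, function(s) {
    d <- seq_to_digits(s)
    if (length(d) != model$width) stop("score_site: site width mismatch")
    if (anyNA(d)) stop("score_site: non-ACGT symbol")
    model$score_table[digits_to_index(matrix(d, 1))]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan a sequence with a site model
#'
#' Scores every window of the model's width along a sequence (the spliced
#' or genic sequence of the gene, already on the transcribed strand).
#' Windows containing ambiguous bases are skipped and tallied. The optional
#' region mask annotates each hit as exonic or intronic by the label of the
#' window's first position.
#'
#' @param model a `maxent_model`.
#' @param sequence ACGTN string.
#' @param region_mask optional character vector, one label per position
#'   (e.g. "exonic"/"intronic").
#' @return data.frame (position 0-based window start, site, score, region,
#'   strong) with attribute `n_skipped` (ambiguous windows).
#' @export
scan_sequence <- function(model, sequence, region_mask = NULL) {
  w <- model$width
  L <- nchar(sequence)
  empty <- data.frame(position = integer(), site = character(),
                      score = numeric(), region = character(),
                      strong = logical())
  if (L < w) { attr(empty, "n_skipped") <- 0L; return(empty) }
  d <- seq_to_digits(sequence)
  n_win <- L - w + 1L
  idx <- rep(0, n_win)
  bad <- rep(FALSE, n_win)
  for (k in seq_len(w)) {
    dk <- d[k:(k + n_win - 1L)]
    bad <- bad | is.na(dk)
    idx <- idx + ifelse(is.na(dk), 0, dk) * 4^(w - k)
  }
  keep <- which(!bad)
  if (!is.null(region_mask)) {
    stopifnot(length(region_mask) == L)
    region <- region_mask[keep]
  } else region <- rep(NA_character_, length(keep))
  sc <- model$score_table[idx[keep] + 1]
  out <- data.frame(
    position = keep - 1L,
    site = substring(sequence, keep, keep + w - 1L),
    score = sc,
    region = region,
    strong = sc >= model$strong_threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Motif-site density per kilobase
#'
#' @param hits a hit table from [scan_sequence()] (optionally pre-filtered
#'   by region).
#' @param region_length length of the scanned region in nt (> 0).
#' @param strong_only count only hits at or above the strong threshold
#'   (the convention for genome-wide gene sets); `FALSE` counts all hits
#'   (used for small gene sets where power is limiting).
#' @return sites per kb.
#' @export
u1_density <- function(hits, region_length, strong_only = TRUE) {
  if (region_length <= 0) stop("u1_density: region_length must be > 0")
  n <- if (strong_only) sum(hits$strong) else nrow(hits)
  n / (region_length / 1000)
}

#' Delta-score of a single-nucleotide change
#'
#' @param model a `maxent_model`.
#' @param ref_context,alt_context ACGT strings of the model's width
#'   differing at exactly one position (or identical).
#' @return list(delta, call) with call in strengthen/weaken/neutral.
#' @export
delta_score <- function(model, ref_context, alt_context) {
  if (nchar(ref_context) != model$width || nchar(alt_context) != model$width)
    stop("delta_score: context width mismatch")
  ndiff <- sum(strsplit(ref_context, "")[[1]] != strsplit(alt_context, "")[[1]])
  if (ndiff > 1L) stop("delta_score: contexts differ at more than one position")
  d <- score_site(model, alt_context) - score_site(model, ref_context)
  call <- if (d > 0) "strengthen" else if (d < 0) "weaken" else "neutral"
  list(delta = unname(d), call = call)
}

#' Delta-score of a variant inside its sequence context
#'
#' Considers every scoring window overlapping the variant and uses the
#' window with the maximal score over either allele for both alleles (the
#' standard convention for site-disruption scoring).
#'
#' @param model a `maxent_model`.
#' @param ref_context ACGT string of length `2*width - 1` with the variant
#'   position at its centre, on the transcribed strand.
#' @param alt_base single alternate base.
#' @return list(delta, call, window_offset) where window_offset is the
#'   0-based offset of the chosen window within `ref_context`.
#' @export
variant_delta_score <- function(model, ref_context, alt_base) {
  w <- model$width
  if (nchar(ref_context) != 2 * w - 1)
    stop("variant_delta_score: context must have length 2*width - 1")
  alt_context <- ref_context
  substr(alt_context, w, w) <- alt_base
  best <- -Inf; best_off <- 0L; best_delta <- 0
  for (off in 0:(w - 1L)) {
    rwin <- substring(ref_context, off + 1L, off + w)
    awin <- substring(alt_context, off + 1L, off + w)
    sr <- score_site(model, rwin)
    sa <- score_site(model, awin)
    if (max(sr, sa) > best) {
      best <- max(sr, sa)
      best_off <- off
      best_delta <- sa - sr
    }
  }
  call <- if (best_delta > 0) "strengthen" else if (best_delta < 0) "weaken" else "neutral"
  list(delta = unname(best_delta), call = call, window_offset = best_off)
}

#' Position weight matrix from aligned sites
#'
#' @param sites equal-length ACGT strings.
#' @param pseudocount per-cell pseudocount.
#' @return 4 x width probability matrix with rownames A,C,G,T.
#' @export
pwm_from_sites <- function(sites, pseudocount = 0.5) {
  width <- nchar(sites[1])
  dm <- t(vapply(sites, seq_to_digits, integer(width), USE.NAMES = FALSE))
  if (anyNA(dm)) stop("pwm_from_sites: non-ACGT symbol")
  m <- vapply(seq_len(width), function(k) {
    cnt <- tabulate(dm[, k] + 1L, nbins = 4L) + pseudocount
    cnt / sum(cnt)
  }, numeric(4))
  rownames(m) <- BASES
  m
}

#' Serialize / load a maxent model as JSON
#'
#' The model is stored factorized (training marginals, order, background,
#' options); the full distribution is refit deterministically on load.
#' @param model a `maxent_model`.
#' @param path JSON path.
#' @return `path` invisibly / the reloaded model.
#' @export
write_motif_model <- function(model, path) {
  jsonlite::write_json(list(
    width = model$width, constraint_order = model$constraint_order,
    pseudocount = model$pseudocount, background = model$background,
    strong_quantile = model$strong_quantile,
    training_marginals = model$marg1
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
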