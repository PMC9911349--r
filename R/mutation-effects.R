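#' Tabulate allele-resolved fraction counts from read calls
#'
#' Reads carrying two or more mutations are discarded entirely (their
#' compound effects cannot be attributed to one site); every other read
#' increments exactly one cell: the mutant cell of its single mutation, or
#' the reference cell of every mutation whose amplicon it covers. Read
#' calls here are per-amplicon, so a reference read (empty mutation list)
#' is assigned to the mutations given in `covers` (or, when `covers` is
#' absent, reference reads are matched to mutations by their read-id
#' prefix up to `"_r"`).
#'
#' @param read_calls data.frame (read_id, fraction in nuc/cyt, mutations:
#'   comma-separated mutation ids, "" for reference reads; optional covers
#'   column naming the mutation whose amplicon the read belongs to).
#' @param mutation_ids mutations to tabulate (default: all observed).
#' @return data.frame (mutation_id, n_mut_nuc, n_ref_nuc, n_mut_cyt,
#'   n_ref_cyt) with attribute `n_discarded` (multi-mutation reads).
#' @export
count_alleles <- function(read_calls, mutation_ids = NULL) {
  stopifnot(all(c("read_id", "fraction", "mutations") %in% names(read_calls)))
  muts <- strsplit(read_calls$mutations, ",", fixed = TRUE)
  muts[!nzchar(read_calls$mutations)] <- list(character(0))
  nmut <- lengths(muts)
  discard <- nmut >= 2L
  covers <- if ("covers" %in% names(read_calls)) read_calls$covers
            else sub("_r[0-9]+$", "", read_calls$read_id)
  observed <- unique(c(unlist(muts[nmut == 1L]), covers))
  if (is.null(mutation_ids)) mutation_ids <- sort(observed)
  tab <- matrix(0L, length(mutation_ids), 4L,
                dimnames = list(mutation_ids,
                                c("n_mut_nuc", "n_ref_nuc",
                                  "n_mut_cyt", "n_ref_cyt")))
  for (i in which(!discard)) {
    nuc <- read_calls$fraction[i] == "nuc"
    if (nmut[i] == 1L) {
      m <- muts[[i]][1]
      if (m %in% mutation_ids)
        tab[m, if (nuc) "n_mut_nuc" else "n_mut_cyt"] <-
          tab[m, if (nuc) "n_mut_nuc" else "n_mut_cyt"] + 1L
    } else {
      m <- covers[i]
      if (m %in% mutation_ids)
        tab[m, if (nuc) "n_ref_nuc" else "n_ref_cyt"] <-
          tab[m, if (nuc) "n_ref_nuc" else "n_ref_cyt"] + 1L
    }
  }
  out <- data.frame(mutation_id = rownames(tab), tab,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_discarded") <- sum(discard)
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summing, over the hypergeometric distribution
#' fixed at the table margins, the probabilities of all tables no more
#' likely than the observed one. The odds ratio is the sample odds ratio
#' `(a*d)/(b*c)`. A zero margin makes the table uninformative: p = 1 and
#' the odds ratio is flagged undefined (NA).
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   rows = (mut, ref) and columns = (nuc, cyt): a = mut/nuc, b = mut/cyt,
#'   c = ref/nuc, d = ref/cyt.
#' @return list(odds_ratio, p).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
    stop("fisher_exact_2x2: cells must be non-negative integers")
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # column 1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0)
    return(list(odds_ratio = NA_real_, p = 1))
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = min(p, 1))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate correction (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("bh_adjust: p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-mutation test of nuclear-export shift
#'
#' For each mutation, Fisher's exact test on the (allele x fraction) table;
#' BH correction is pooled across all testable mutations in the assay. The
#' odds ratio is the nuclear odds of the mutant allele over the reference
#' allele: OR > 1 means the mutant is nuclear-retained
#' (call `decreased_export` at q < alpha), OR < 1 means it is
#' cytoplasm-enriched (`increased_export`). Mutations with a zero margin
#' (e.g. no mutant reads at all) are untestable: excluded from the BH
#' family and flagged.
#'
#' @param counts an [count_alleles()]-layout data.frame.
#' @param alpha BH-corrected significance threshold.
#' @return data.frame (mutation_id, odds_ratio, p_raw, q_bh, export_call,
#'   testable).
#' @export
test_export_shift <- function(counts, alpha = 0.05) {
  n <- nrow(counts)
  or <- rep(NA_real_, n); p <- rep(NA_real_, n)
  testable <- rep(FALSE, n)
  for (i in seq_len(n)) {
    a <- counts$n_mut_nuc[i]; b <- counts$n_mut_cyt[i]
    cc <- counts$n_ref_nuc[i]; d <- counts$n_ref_cyt[i]
    if ((a + b) > 0 && (cc + d) > 0 && (a + cc) > 0 && (b + d) > 0) {
      ft <- fisher_exact_2x2(a, b, cc, d)
      or[i] <- ft$odds_ratio; p[i] <- ft$p
      testable[i] <- TRUE
    }
  }
  q <- rep(NA_real_, n)
  q[testable] <- bh_adjust(p[testable])
  call <- rep("none", n)
  sig <- testable & !is.na(q) & q < alpha
  call[sig & or < 1] <- "increased_export"
  call[sig & or > 1] <- "decreased_export"
  data.frame(mutation_id = counts$mutation_id, odds_ratio = or,
             p_raw = p, q_bh = q, export_call = call, testable = testable,
             stringsAsFactors = FALSE)
}

#' Per-mutation test of splicing shift
#'
#' Fisher's exact test on (junction/retention x ref/mut) per mutation with
#' BH correction; a splice call additionally requires the PSI difference to
#' exceed `min_delta` (the "greater than 5%" rule).
#'
#' @param junction_evidence data.frame (mutation_id, allele ref/mut,
#'   junction_reads, retention_reads).
#' @param alpha BH-corrected significance threshold.
#' @param min_delta minimal |psi_mut - psi_ref| for a call.
#' @return data.frame (mutation_id, psi_ref, psi_mut, delta_psi,
#'   p_raw_splice, q_bh_splice, splice_call in
#'   stronger/weaker/none).
#' @export
test_splice_shift <- function(junction_evidence, alpha = 0.05,
                              min_delta = 0.05) {
  ids <- unique(junction_evidence$mutation_id)
  rows <- lapply(ids, function(id) {
    ev <- junction_evidence[junction_evidence$mutation_id == id, ]
    r <- ev[ev$allele == "ref", ]; m <- ev[ev$allele == "mut", ]
    if (nrow(r) != 1L || nrow(m) != 1L)
      stop("test_splice_shift: need one ref and one mut row per mutation")
    psi_r <- compute_psi(r$junction_reads, r$retention_reads)$psi
    psi_m <- compute_psi(m$junction_reads, m$retention_reads)$psi
    ft <- fisher_exact_2x2(r$junction_reads, r$retention_reads,
                           m$junction_reads, m$retention_reads)
    data.frame(mutation_id = id, psi_ref = psi_r, psi_mut = psi_m,
               delta_psi = psi_m - psi_r, p_raw_splice = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh_splice <- bh_adjust(out$p_raw_splice)
  call <- rep("none", nrow(out))
  sig <- !is.na(out$q_bh_splice) & out$q_bh_splice < alpha &
    !is.na(out$delta_psi) & abs(out$delta_psi) > min_delta
  call[sig & out$delta_psi > 0] <- "stronger"
  call[sig & out$delta_psi < 0] <- "weaker"
  out$splice_call <- call
  rownames(out) <- NULL
  out
}

#' Keep mutations with the most dramatic U1 score changes
#'
#' Ranks mutations by |delta U1 score| and keeps the top `keep_fraction`
#' (default top 50%). Ties break by mutation id, so the kept set is
#' deterministic and invariant to monotone rescaling of the scores.
#'
#' @param effects data.frame with mutation_id and du1_score columns.
#' @param keep_fraction fraction to keep.
#' @return the kept subset, with a `du1_rank_kept` flag column added.
#' @export
filter_u1_effects <- function(effects, keep_fraction = 0.5) {
  k <- floor(keep_fraction * nrow(effects))
  ord <- order(-abs(effects$du1_score), effects$mutation_id)
  effects$du1_rank_kept <- FALSE
  effects$du1_rank_kept[ord[seq_len(k)]] <- TRUE
  effects[effects$du1_rank_kept, , drop = FALSE]
}

#' Concordance between splicing shifts and export shifts
#'
#' Among mutations with both a splice call and an export call, a mutation
#' is concordant when stronger splicing goes with increased export or
#' weaker splicing with decreased export -- the direction expected if
#' splicing drives nuclear export.
#'
#' @param effects data.frame with splice_call and export_call columns.
#' @return list(n_eligible, n_concordant, percent) with percent rounded to
#'   one decimal.
#' @export
concordance_summary <- function(effects) {
  el <- effects[effects$splice_call %in% c("stronger", "weaker") &
                effects$export_call %in% c("increased_export",
                                           "decreased_export"), ,
                drop = FALSE]
  conc <- (el$splice_call == "stronger" & el$export_call == "increased_export") |
          (el$splice_call == "weaker" & el$export_call == "decreased_export")
  list(n_eligible = nrow(el), n_concordant = sum(conc),
       percent = if (nrow(el) > 0) round(100 * sum(conc) / nrow(el), 1)
                 else NA_real_)
}
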