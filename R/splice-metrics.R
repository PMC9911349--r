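#' Per-intron per cent spliced in (PSI)
#'
#' PSI = junction / (junction + retention), where `junction_reads` span the
#' exon-exon junction and `retention_reads` support the unspliced intron at
#' the same boundary. Intron-body-only reads are not counted, which keeps
#' PSI a two-outcome proportion amenable to Fisher testing. Introns with no
#' evidence get `NA` and `covered = FALSE` rather than NaN.
#'
#' @param junction_reads,retention_reads non-negative counts (vectorized).
#' @return data.frame with `psi` and `covered` columns.
#' @export
compute_psi <- function(junction_reads, retention_reads) {
  if (any(junction_reads < 0) || any(retention_reads < 0))
    stop("compute_psi: negative counts")
  tot <- junction_reads + retention_reads
  covered <- tot > 0
  psi <- ifelse(covered, junction_reads / tot, NA_real_)
  data.frame(psi = psi, covered = covered)
}

#' Gene-level isoform spliced-out ratio (ISOR)
#'
#' ISOR measures how much sequence a gene's transcripts splice out relative
#' to their exonic length:
#' `ISOR = sum_i(intron_length_i * PSI_i) / exonic_length`.
#' Each intron contributes its length weighted by its observed spliced
#' fraction, so a fully spliced gene with 1 kb of intron and 2 kb of exon
#' scores 0.5, and intron-rich genes can legitimately exceed 1. Introns with
#' zero evidence are skipped (not imputed as unspliced); a gene with no
#' covered intron is flagged `covered = FALSE`.
#'
#' @param evidence data.frame with columns gene_id, intron_id,
#'   intron_length, junction_reads, retention_reads.
#' @param exonic_lengths named vector of exonic lengths per gene (e.g. from
#'   [exonic_length()]).
#' @return data.frame (gene_id, isor, exonic_length, n_introns_covered,
#'   covered).
#' @export
compute_isor <- function(evidence, exonic_lengths) {
  stopifnot(all(c("gene_id", "intron_length",
                  "junction_reads", "retention_reads") %in% names(evidence)))
  if (any(evidence$intron_length <= 0)) stop("compute_isor: intron_length must be > 0")
  ps <- compute_psi(evidence$junction_reads, evidence$retention_reads)
  parts <- lapply(split(seq_len(nrow(evidence)), evidence$gene_id), function(i) {
    cov <- ps$covered[i]
    gid <- evidence$gene_id[i[1]]
    el <- exonic_lengths[[gid]]
    if (is.null(el) || is.na(el)) stop("compute_isor: no exonic length for ", gid)
    data.frame(
      gene_id = gid,
      isor = if (any(cov))
        sum(evidence$intron_length[i][cov] * ps$psi[i][cov]) / el else NA_real_,
      exonic_length = el,
      n_introns_covered = sum(cov),
      covered = any(cov),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' ISOR from full-length transcript reads
#'
#' Independent estimator of ISOR from reads that report complete transcript
#' structure (the long-read analogue): for each read, the spliced-out length
#' is the summed length of the introns it does not retain; ISOR is the mean
#' over reads of spliced-out length / exonic length. Equals [compute_isor()]
#' exactly when per-intron retention is independent across reads and counts
#' are noise-free.
#'
#' @param transcript_reads data.frame with columns read_id, gene_id,
#'   retained_introns (comma-separated intron ids, "" when fully spliced).
#' @param intron_table introns of the gene models (from [introns()]).
#' @param exonic_lengths named vector of exonic lengths per gene.
#' @return data.frame (gene_id, isor, exonic_length, n_reads, covered).
#' @export
isor_from_fulllength <- function(transcript_reads, intron_table, exonic_lengths) {
  stopifnot(all(c("read_id", "gene_id", "retained_introns") %in% names(transcript_reads)))
  parts <- lapply(split(transcript_reads, transcript_reads$gene_id), function(rd) {
    gid <- rd$gene_id[1]
    itab <- intron_table[intron_table$gene_id == gid, , drop = FALSE]
    total_intron <- sum(itab$length)
    el <- exonic_lengths[[gid]]
    if (is.null(el) || is.na(el)) stop("isor_from_fulllength: no exonic length for ", gid)
    spliced_out <- vapply(rd$retained_introns, function(s) {
      if (is.na(s) || !nzchar(s)) return(total_intron)
      kept <- as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
      total_intron - sum(itab$length[match(kept, itab$intron_id)])
    }, numeric(1), USE.NAMES = FALSE)
    data.frame(gene_id = gid, isor = mean(spliced_out) / el,
               exonic_length = el, n_reads = nrow(rd), covered = nrow(rd) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
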