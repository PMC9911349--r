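#' FPKM from raw counts
#'
#' Fragments per kilobase of exon per million mapped reads:
#' `count / (exonic_length/1000 * mapped_reads/1e6)`. The library size is
#' the total mapped reads of that fraction's own library; nuclear and
#' cytoplasmic libraries are never pooled for normalization.
#'
#' @param read_count non-negative read count(s).
#' @param exonic_length exonic length in nt (> 0).
#' @param mapped_reads total mapped reads in the library (> 0).
#' @return FPKM value(s).
#' @export
compute_fpkm <- function(read_count, exonic_length, mapped_reads) {
  if (any(exonic_length <= 0)) stop("compute_fpkm: exonic_length must be > 0")
  if (any(mapped_reads <= 0)) stop("compute_fpkm: mapped_reads must be > 0")
  read_count / (exonic_length / 1000 * mapped_reads / 1e6)
}

#' Nuclear/cytoplasmic ratio per gene
#'
#' Genes with total expression `fpkm_nuc + fpkm_cyt < min_total` (default
#' 0.2 FPKM) are flagged as filtered and receive `NA`; otherwise
#' `nc_ratio = log2((fpkm_nuc + pseudocount) / (fpkm_cyt + pseudocount))`
#' with a pseudocount of 0.1 on each FPKM. Positive values indicate nuclear
#' retention, negative values active export.
#'
#' @param fraction_table data.frame with columns `gene_id`, `fpkm_nuc`,
#'   `fpkm_cyt`.
#' @param min_total expression filter on `fpkm_nuc + fpkm_cyt`.
#' @param pseudocount added to each FPKM before the log ratio.
#' @return input with `nc_ratio` and `passed_filter` columns added.
#' @export
nc_ratio <- function(fraction_table, min_total = 0.2, pseudocount = 0.1) {
  stopifnot(all(c("fpkm_nuc", "fpkm_cyt") %in% names(fraction_table)))
  if (any(fraction_table$fpkm_nuc < 0) || any(fraction_table$fpkm_cyt < 0))
    stop("nc_ratio: negative FPKM")
  tot <- fraction_table$fpkm_nuc + fraction_table$fpkm_cyt
  pass <- tot >= min_total
  r <- ifelse(pass,
              log2((fraction_table$fpkm_nuc + pseudocount) /
                   (fraction_table$fpkm_cyt + pseudocount)),
              NA_real_)
  fraction_table$nc_ratio <- r
  fraction_table$passed_filter <- pass
  fraction_table
}

#' Z-score normalization within groups
#'
#' Used for cross-dataset (e.g. cross-species) N/C ratio comparisons:
#' within each group values are centred and scaled to sample SD 1
#' (denominator n - 1). A zero-variance or size-1 group is an error,
#' never silently zeroed.
#'
#' @param values numeric vector (NAs allowed; passed through as NA).
#' @param grouping factor-like of the same length; one group by default.
#' @return numeric vector of z-scores.
#' @export
zscore_normalize <- function(values, grouping = rep(1L, length(values))) {
  stopifnot(length(values) == length(grouping))
  out <- rep(NA_real_, length(values))
  for (g in split(seq_along(values), grouping)) {
    v <- values[g]
    ok <- !is.na(v)
    if (sum(ok) < 2L) stop("zscore_normalize: group with fewer than 2 values")
    s <- stats::sd(v[ok])
    if (s == 0) stop("zscore_normalize: zero variance within a group")
    out[g] <- (v - mean(v[ok])) / s
  }
  out
}

#' Cytoplasmic-to-total expression ratio
#'
#' The proportion of a gene's transcripts located in the cytoplasm,
#' `fpkm_cyt / (fpkm_nuc + fpkm_cyt)`. The complementary single-gene export
#' measure to the N/C ratio: for a fixed total it is a strictly decreasing
#' function of the N/C ratio.
#'
#' @param fpkm_nuc,fpkm_cyt non-negative FPKM values (not both zero).
#' @return fraction in \[0, 1\].
#' @export
cyto_total_ratio <- function(fpkm_nuc, fpkm_cyt) {
  if (any(fpkm_nuc < 0) || any(fpkm_cyt < 0))
    stop("cyto_total_ratio: negative FPKM")
  tot <- fpkm_nuc + fpkm_cyt
  if (any(tot == 0)) stop("cyto_total_ratio: both fractions zero")
  fpkm_cyt / tot
}
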