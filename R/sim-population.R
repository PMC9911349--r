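#' Simulate polymorphic sites under neutral and constrained regimes
#'
#' Derived-allele counts i (out of `n_chromosomes_population` chromosomes)
#' are drawn with weight proportional to 1/i for the neutral model (the
#' standard neutral site-frequency spectrum) and 1/i^shape for constrained
#' classes (shape > 1 gives the excess of rare derived alleles expected
#' under purifying selection). The ancestral allele is recorded explicitly:
#' about half the sites are written with AA = REF and half with AA = ALT,
#' so that consumers must polarize.
#'
#' Uses `config$seed + 3`.
#'
#' @param config a [sim_config()]; classes come from
#'   `config$selection_classes` (each entry may set `n` and `lineage`).
#' @return data.frame in the [load_variants()] layout (chrom, position,
#'   ref, alt, derived_allele, derived_freq, lineage, site_class) plus a
#'   `derived_count` column; VCF-writable via [write_variants()].
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  n_chrom <- config$n_chromosomes_population
  rows <- list()
  pos0 <- 0L
  for (cl_name in names(config$selection_classes)) {
    cl <- config$selection_classes[[cl_name]]
    n_sites <- if (!is.null(cl$n)) cl$n else config$n_sites_per_class
    if (n_sites == 0) next
    shape <- if (identical(cl$model, "constrained")) {
      if (!is.null(cl$shape)) cl$shape else 2
    } else 1
    i_vals <- seq_len(n_chrom - 1L)
    w <- 1 / i_vals^shape
    derived_count <- sample(i_vals, n_sites, replace = TRUE, prob = w)
    ref <- sample(BASES, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
    aa_is_ref <- stats::runif(n_sites) < 0.5
    rows[[cl_name]] <- data.frame(
      chrom = "chr_pop",
      position = pos0 + seq_len(n_sites) * 10L,
      ref = ref, alt = alt,
      derived_allele = ifelse(aa_is_ref, alt, ref),
      derived_freq = derived_count / n_chrom,
      lineage = if (!is.null(cl$lineage)) cl$lineage else "A",
      site_class = cl_name,
      derived_count = derived_count,
      stringsAsFactors = FALSE
    )
    pos0 <- pos0 + n_sites * 10L + 1000L
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), position = integer(0),
               ref = character(0), alt = character(0),
               derived_allele = character(0), derived_freq = numeric(0),
               lineage = character(0), site_class = character(0),
               derived_count = integer(0))
  rownames(out) <- NULL
  out
}
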