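#' Simulate fractionation read counts, junction evidence and full-length reads
#'
#' Per gene, a Poisson(`seq_depth`) total read count is split between the
#' cytoplasmic and nuclear fractions binomially with the gene's true export
#' propensity. Per intron, Poisson(`junction_depth`) boundary reads are
#' split between junction-spanning and intron-retention reads with the true
#' spliced fraction. Full-length reads report, per transcript copy, which
#' introns it retains (each intron independently retained with probability
#' one minus its spliced fraction) -- the long-read oracle for ISOR.
#'
#' Uses `config$seed + 1` so that genome generation and count generation
#' are independently reproducible.
#'
#' @param models a [gene_models()] table from [simulate_genome()].
#' @param truth the truth record from [simulate_genome()].
#' @param config the same [sim_config()].
#' @return list(counts, junctions, fulllength):
#'   counts (gene_id, exonic_length, reads_nuc, reads_cyt),
#'   junctions (gene_id, intron_id, intron_length, junction_reads,
#'   retention_reads), fulllength (read_id, gene_id, retained_introns).
#' @export
simulate_fraction_counts <- function(models, truth, config) {
  if (config$seq_depth < 0 || config$junction_depth < 0 ||
      config$fulllength_depth < 0)
    stop("simulate_fraction_counts: depths must be >= 0")
  if (!all(truth$genes$gene_id %in% unique(models$gene_id)))
    stop("simulate_fraction_counts: truth does not match models")
  set.seed(config$seed + 1L)
  tg <- truth$genes
  ng <- nrow(tg)
  counts <- data.frame(gene_id = character(0), exonic_length = integer(0),
                       reads_nuc = integer(0), reads_cyt = integer(0))
  if (ng > 0) {
    total <- stats::rpois(ng, config$seq_depth)
    cyt <- stats::rbinom(ng, total, tg$p_cyt)
    counts <- data.frame(gene_id = tg$gene_id,
                         exonic_length = tg$exonic_length,
                         reads_nuc = total - cyt, reads_cyt = cyt,
                         stringsAsFactors = FALSE)
  }
  ti <- truth$introns
  ni <- nrow(ti)
  junctions <- data.frame(gene_id = character(0), intron_id = integer(0),
                          intron_length = integer(0),
                          junction_reads = integer(0),
                          retention_reads = integer(0))
  if (ni > 0) {
    tot <- stats::rpois(ni, config$junction_depth)
    junc <- stats::rbinom(ni, tot, ti$splice_fraction)
    junctions <- data.frame(gene_id = ti$gene_id, intron_id = ti$intron_id,
                            intron_length = ti$intron_length,
                            junction_reads = junc, retention_reads = tot - junc,
                            stringsAsFactors = FALSE)
  }
  fl_rows <- list()
  if (ng > 0 && config$fulllength_depth > 0) {
    nreads <- stats::rpois(ng, config$fulllength_depth)
    for (i in seq_len(ng)) {
      if (nreads[i] == 0) next
      gid <- tg$gene_id[i]
      it <- ti[ti$gene_id == gid, , drop = FALSE]
      retained <- vapply(seq_len(nreads[i]), function(r) {
        if (nrow(it) == 0) return("")
        keep <- stats::runif(nrow(it)) >= it$splice_fraction
        paste(it$intron_id[keep], collapse = ",")
      }, "")
      fl_rows[[i]] <- data.frame(
        read_id = sprintf("%s_fl%04d", gid, seq_len(nreads[i])),
        gene_id = gid, retained_introns = retained,
        stringsAsFactors = FALSE
      )
    }
  }
  fulllength <- if (length(fl_rows)) do.call(rbind, fl_rows) else
    data.frame(read_id = character(0), gene_id = character(0),
               retained_introns = character(0))
  rownames(fulllength) <- NULL
  list(counts = counts, junctions = junctions, fulllength = fulllength)
}
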