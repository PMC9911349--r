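#' Simulate an allele-resolved CRISPR fractionation read-out
#'
#' For each injected mutation, `assay_depth` reads overlapping the site are
#' generated; each read carries the mutant allele with probability 0.5 and
#' is assigned to the nuclear or cytoplasmic fraction according to its
#' allele's nuclear probability. The reference allele uses the gene's true
#' nuclear probability; the mutant allele multiplies the nuclear odds by
#' the injected `odds_multiplier` (> 1 retains in the nucleus, < 1 promotes
#' export). A configured fraction of mutant reads additionally carries a
#' second mutation, to exercise the multi-mutation discard rule; those read
#' ids are recorded in the truth table. Mutations mapped to an intron also
#' get per-allele junction evidence with the mutant PSI shifted by
#' `psi_delta`.
#'
#' Uses `config$seed + 2`.
#'
#' @param models a [gene_models()] table.
#' @param injected_effects data.frame with columns mutation_id, gene_id,
#'   position (0-based, within the gene's exonic span), ref, alt,
#'   odds_multiplier, psi_delta, intron_id (NA when not splice-linked).
#' @param truth the truth record from [simulate_genome()].
#' @param config the same [sim_config()].
#' @return list(read_calls, junction_evidence, truth):
#'   read_calls (read_id, fraction in nuc/cyt, mutations as comma list,
#'   "" for pure reference reads); junction_evidence (mutation_id, allele
#'   in ref/mut, junction_reads, retention_reads); truth (per-mutation
#'   injected effects plus multi-mutation read ids).
#' @export
simulate_mutation_assay <- function(models, injected_effects, truth, config) {
  req <- c("mutation_id", "gene_id", "position", "ref", "alt",
           "odds_multiplier", "psi_delta")
  stopifnot(all(req %in% names(injected_effects)))
  set.seed(config$seed + 2L)
  tg <- truth$genes
  ex_len <- exonic_length(models)
  read_rows <- list(); junc_rows <- list(); multi_rows <- list()
  for (i in seq_len(nrow(injected_effects))) {
    ef <- injected_effects[i, ]
    gi <- match(ef$gene_id, tg$gene_id)
    if (is.na(gi)) stop("simulate_mutation_assay: unknown gene ", ef$gene_id)
    if (ef$position < 0 || ef$position >= ex_len[[ef$gene_id]])
      stop("simulate_mutation_assay: position outside gene ", ef$gene_id)
    depth <- config$assay_depth
    if (depth == 0) next
    p_nuc_ref <- 1 - tg$p_cyt[gi]
    p_nuc_mut <- stats::plogis(stats::qlogis(p_nuc_ref) + log(ef$odds_multiplier))
    is_mut <- stats::runif(depth) < 0.5
    p_nuc <- ifelse(is_mut, p_nuc_mut, p_nuc_ref)
    frac <- ifelse(stats::runif(depth) < p_nuc, "nuc", "cyt")
    read_id <- sprintf("%s_r%05d", ef$mutation_id, seq_len(depth))
    muts <- ifelse(is_mut, ef$mutation_id, "")
    # a stated fraction of mutant reads carry a second mutation
    co <- is_mut & stats::runif(depth) < config$multi_mutation_fraction
    muts[co] <- paste0(ef$mutation_id, ",", ef$mutation_id, "_co")
    read_rows[[i]] <- data.frame(read_id = read_id, fraction = frac,
                                 mutations = muts, stringsAsFactors = FALSE)
    if (any(co)) multi_rows[[i]] <- data.frame(
      mutation_id = ef$mutation_id, read_id = read_id[co],
      stringsAsFactors = FALSE)
    # junction evidence per allele
    if (!is.null(ef$intron_id) && !is.na(ef$intron_id)) {
      ti <- truth$introns
      ii <- which(ti$gene_id == ef$gene_id & ti$intron_id == ef$intron_id)
      if (length(ii) != 1L)
        stop("simulate_mutation_assay: unknown intron for ", ef$mutation_id)
      psi_ref <- ti$splice_fraction[ii]
      psi_mut <- min(max(psi_ref + ef$psi_delta, 0), 1)
      tot <- stats::rpois(2, config$junction_depth * 5)
      junc <- stats::rbinom(2, tot, c(psi_ref, psi_mut))
      junc_rows[[i]] <- data.frame(
        mutation_id = ef$mutation_id, allele = c("ref", "mut"),
        junction_reads = junc, retention_reads = tot - junc,
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
  out <- list(
    read_calls = bind(read_rows, data.frame(read_id = character(0),
                                            fraction = character(0),
                                            mutations = character(0))),
    junction_evidence = bind(junc_rows, data.frame(
      mutation_id = character(0), allele = character(0),
      junction_reads = integer(0), retention_reads = integer(0))),
    truth = list(
      effects = injected_effects,
      multi_mutation_reads = bind(multi_rows, data.frame(
        mutation_id = character(0), read_id = character(0)))
    )
  )
  rownames(out$read_calls) <- rownames(out$junction_evidence) <- NULL
  out
}
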