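# Small shared fixtures, built in code at test time.

tiny_config <- function(...) {
  args <- list(n_genes = 12, seed = 42, seq_depth = 300,
               junction_depth = 150, fulllength_depth = 80)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# two-exon plus-strand toy gene on a 60-nt chromosome:
# exon1 = [10, 20), intron = [20, 30), exon2 = [30, 45)
toy_gene <- function(strand = "+") {
  list(
    models = gene_models(gene_id = c("g1", "g1"), chrom = "chrT",
                         strand = strand, start = c(10L, 30L),
                         end = c(20L, 45L)),
    genome = Biostrings::DNAStringSet(c(
      chrT = "AACCGGTTAAACGTACGTACTTTTGGGGCCATGCATGCATGCATGAAAAACCCCCGGGGG"))
  )
}

# consensus-biased 9-mer training set for maxent fits
consensus_sites <- function(n = 300, rate = 0.15, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    ch <- strsplit("CAGGTAAGT", "")[[1]]
    hit <- stats::runif(9) < rate
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste0(ch, collapse = "")
  }, "")
}

random_9mers <- function(n, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = ""), "")
}
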