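# uniform draw from an integer range; safe when the range is a single value
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq(as.integer(lo), as.integer(hi)), n, replace = TRUE)
}

# random background sequence with a given GC content
random_seq <- function(n, gc) {
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste0(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# mutate a consensus string per-base at the given rate
mutate_consensus <- function(consensus, rate) {
  ch <- strsplit(consensus, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1), "")
  paste0(ch, collapse = "")
}

# splice-donor 9-mer (3 exonic + 6 intronic positions). Strong donors are
# near-consensus CAG|GTAAGT; weak donors keep only the invariant GT
# dinucleotide and are otherwise random.
sample_donor <- function(strong, gc) {
  if (strong) {
    mutate_consensus("CAGGTAAGT", 0.05)
  } else {
    ex <- random_seq(3L, gc)
    tail <- random_seq(4L, gc)
    paste0(ex, "GT", tail)
  }
}

#' Simulate a genome of multi-exon genes with planted U1 motifs
#'
#' Builds each gene on its own chromosome (gene body plus flanks), in two
#' classes (coding-like / lncRNA-like) that differ in exonic vs intronic U1
#' planting rates and splice-donor strength. Donor 9-mers occupy the last 3
#' exonic and first 6 intronic positions of every exon-intron boundary; U1
#' 7-mers ([u1_consensus()] with per-base mutations) are planted at the
#' configured Poisson rates at non-overlapping positions away from the
#' donor regions. Each intron carries a true spliced fraction drawn from
#' the strong or weak PSI range according to its donor class, and each gene
#' a true export propensity from the logistic export model.
#'
#' @param config a [sim_config()].
#' @return list with `sequences` (named [Biostrings::DNAStringSet]),
#'   `models` (a [gene_models()] table) and `truth`
#'   (`$genes`, `$introns` data.frames recording planted counts, true
#'   splicing fractions, true ISOR and export propensity).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  truth_genes <- list(); truth_introns <- list()
  model_rows <- list(); seqs <- character(0)
  if (n > 0) {
    n_lnc <- round(n * config$lncrna_fraction)
    biotypes <- sample(c(rep("lncRNA", n_lnc), rep("coding", n - n_lnc)))
    coef <- config$export_model_coefficients
    for (i in seq_len(n)) {
      gid <- sprintf("gene%04d", i)
      bt <- biotypes[i]
      strand <- sample(c("+", "-"), 1)
      k <- sample_range(config$exons_per_gene[1], config$exons_per_gene[2], 1)
      exlens <- sample_range(config$exon_len[1], config$exon_len[2], k)
      inlens <- if (k > 1)
        sample_range(config$intron_len[1], config$intron_len[2], k - 1)
      else integer(0)
      donor_strong <- if (k > 1)
        stats::runif(k - 1) < config$splice_strength_mix[[bt]] else logical(0)
      psi_true <- ifelse(donor_strong,
                         stats::runif(max(k - 1, 0), config$psi_strong[1], config$psi_strong[2]),
                         stats::runif(max(k - 1, 0), config$psi_weak[1], config$psi_weak[2]))

      # build transcribed-strand pieces
      ex_seq <- vapply(exlens, random_seq, "", gc = config$gc_content)
      in_seq <- vapply(inlens, random_seq, "", gc = config$gc_content)
      # overwrite donor 9-mers at each boundary
      for (j in seq_len(k - 1)) {
        d <- sample_donor(donor_strong[j], config$gc_content)
        substr(ex_seq[j], exlens[j] - 2L, exlens[j]) <- substr(d, 1, 3)
        substr(in_seq[j], 1L, 6L) <- substr(d, 4, 9)
      }
      # plant U1 7-mers at non-overlapping positions (exons: keep the last
      # 3 nt for the donor; introns: keep the first 6 nt)
      plant <- function(s, rate, lo_pad, hi_pad) {
        len <- nchar(s)
        usable <- len - lo_pad - hi_pad - 7L
        n_target <- if (usable > 0) stats::rpois(1, rate * len / 1000) else 0L
        placed <- integer(0)
        attempts <- 0L
        while (length(placed) < n_target && attempts < 50L * max(n_target, 1L)) {
          attempts <- attempts + 1L
          pos <- sample.int(usable + 1L, 1) + lo_pad  # 1-based start
          if (!any(abs(pos - placed) < 7L)) {
            substr(s, pos, pos + 6L) <- mutate_consensus(u1_consensus(),
                                                         config$u1_mutation_rate)
            placed <- c(placed, pos)
          }
        }
        list(seq = s, n = length(placed))
      }
      u1_ex <- 0L; u1_in <- 0L
      for (j in seq_len(k)) {
        pl <- plant(ex_seq[j], config$planted_u1_rate_exonic[[bt]],
                    lo_pad = 0L, hi_pad = if (j < k) 3L else 0L)
        ex_seq[j] <- pl$seq; u1_ex <- u1_ex + pl$n
      }
      for (j in seq_len(max(k - 1, 0))) {
        pl <- plant(in_seq[j], config$planted_u1_rate_intronic[[bt]],
                    lo_pad = 6L, hi_pad = 0L)
        in_seq[j] <- pl$seq; u1_in <- u1_in + pl$n
      }

      # assemble gene on transcribed strand, then place in genomic space
      pieces <- character(2 * k - 1)
      pieces[seq(1, 2 * k - 1, by = 2)] <- ex_seq
      if (k > 1) pieces[seq(2, 2 * k - 2, by = 2)] <- in_seq
      gene_seq <- paste0(pieces, collapse = "")
      glen <- nchar(gene_seq)
      flank <- config$flank
      genomic <- if (strand == "+") gene_seq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_seq)))
      chrom_seq <- paste0(random_seq(flank, config$gc_content), genomic,
                          random_seq(flank, config$gc_content))
      chrom <- paste0("chr_", gid)
      seqs[chrom] <- chrom_seq

      # exon coordinates: transcribed-strand offsets -> genomic 0-based half-open
      tx_starts <- cumsum(c(0L, exlens[-k] + inlens))
      tx_ends <- tx_starts + exlens
      if (strand == "+") {
        gstart <- flank + tx_starts; gend <- flank + tx_ends
      } else {
        gstart <- flank + glen - tx_ends; gend <- flank + glen - tx_starts
      }
      model_rows[[i]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        start = gstart, end = gend, biotype = bt, species = "sim",
        stringsAsFactors = FALSE
      )

      exonic_len <- sum(exlens)
      isor_true <- if (k > 1) sum(inlens * psi_true) / exonic_len else 0
      u1_ex_density <- u1_ex / (exonic_len / 1000)
      p_cyt <- stats::plogis(coef[["intercept"]] +
                             coef[["beta_u1_exonic"]] * u1_ex_density +
                             coef[["beta_isor"]] * isor_true)
      truth_genes[[i]] <- data.frame(
        gene_id = gid, biotype = bt, strand = strand,
        n_exons = k, exonic_length = exonic_len,
        intronic_length = sum(inlens),
        u1_exonic = u1_ex, u1_intronic = u1_in,
        u1_genic = u1_ex + u1_in,
        u1_exonic_density = u1_ex_density,
        isor_true = isor_true, p_cyt = p_cyt,
        stringsAsFactors = FALSE
      )
      if (k > 1) truth_introns[[i]] <- data.frame(
        gene_id = gid, intron_id = seq_len(k - 1),
        intron_length = inlens, donor_strong = donor_strong,
        splice_fraction = psi_true, stringsAsFactors = FALSE
      )
    }
  }
  models <- if (length(model_rows)) {
    mr <- do.call(rbind, model_rows)
    gene_models(mr$gene_id, mr$chrom, mr$strand, mr$start, mr$end,
                mr$biotype, mr$species)
  } else gene_models(character(0), character(0), character(0), integer(0),
                     integer(0))
  truth <- list(
    genes = if (length(truth_genes)) do.call(rbind, truth_genes) else
      data.frame(gene_id = character(0)),
    introns = if (length(truth_introns)) do.call(rbind, truth_introns) else
      data.frame(gene_id = character(0), intron_id = integer(0),
                 intron_length = integer(0), donor_strong = logical(0),
                 splice_fraction = numeric(0))
  )
  rownames(truth$genes) <- rownames(truth$introns) <- NULL
  list(sequences = Biostrings::DNAStringSet(seqs), models = models, truth = truth)
}
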