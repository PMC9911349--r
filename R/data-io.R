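#' Construct a gene-model table
#'
#' Gene models are stored as a flat exon table in internal coordinates:
#' 0-based, half-open intervals. Conversions to/from 1-based inclusive GTF
#' coordinates happen only at the I/O boundary ([load_gene_models()],
#' [write_gene_models()]), so every downstream metric shares one convention.
#'
#' @param gene_id character vector, one entry per exon.
#' @param chrom chromosome name per exon.
#' @param strand `"+"` or `"-"` per exon (constant within a gene).
#' @param start,end 0-based half-open exon interval; `end > start`.
#' @param biotype `"coding"` or `"lncRNA"` per exon.
#' @param species species label (free text), recycled.
#' @return A `data.frame` of class `gene_models` with one row per exon,
#'   sorted by gene and start, with an `exon_rank` column in genomic order.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        biotype = "coding", species = "speciesA") {
  stopifnot(length(gene_id) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("gene_models: exon end must exceed start")
  if (!all(strand %in% c("+", "-"))) stop("gene_models: strand must be '+' or '-'")
  df <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    strand = as.character(strand),
    start = as.integer(start), end = as.integer(end),
    biotype = rep_len(as.character(biotype), length(gene_id)),
    species = rep_len(as.character(species), length(gene_id)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  # non-overlap check within genes
  for (g in split(seq_len(nrow(df)), df$gene_id)) {
    if (length(g) > 1L && any(df$start[g][-1] < df$end[g][-length(g)]))
      stop("gene_models: overlapping exons in gene ", df$gene_id[g[1]])
  }
  df$exon_rank <- stats::ave(seq_len(nrow(df)), df$gene_id, FUN = seq_along)
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Intron intervals of gene models
#'
#' @param models a `gene_models` table.
#' @return data.frame with one row per intron (gene_id, intron_id, chrom,
#'   strand, start, end, length) in internal 0-based half-open coordinates.
#'   Intron ids number introns 1..k in genomic order.
#' @export
introns <- function(models) {
  parts <- lapply(split(models, models$gene_id), function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(
      gene_id = ex$gene_id[1], intron_id = seq_len(nrow(ex) - 1L),
      chrom = ex$chrom[1], strand = ex$strand[1],
      start = ex$end[-nrow(ex)], end = ex$start[-1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), intron_id = integer(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer())
  }
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Exonic length per gene (union of exons)
#' @param models a `gene_models` table.
#' @return named integer vector of summed exon lengths.
#' @export
exonic_length <- function(models) {
  tapply(models$end - models$start, models$gene_id, sum)
}

#' Read gene models from GTF
#'
#' Parses exon features of a GTF 2.2 file (1-based inclusive coordinates)
#' into the internal 0-based half-open convention. Multi-transcript genes
#' are collapsed to the union of their exons: all gene-level statistics
#' (N/C ratio, ISOR, U1 density) are computed per locus, not per isoform.
#'
#' @param path GTF file path.
#' @return a `gene_models` table.
#' @export
load_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("load_gene_models: no exon features in ", path)
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("load_gene_models: exon with unknown strand")
  biotype <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else "coding"
  species <- if (!is.null(gr$species)) gr$species else "speciesA"
  df <- data.frame(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GTF 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    biotype = biotype, species = species,
    stringsAsFactors = FALSE
  )
  # collapse to union of exons per gene
  gr2 <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start + 1L, df$end),
                                strand = df$strand)
  # min.gapwidth = 0: merge overlapping exons across isoforms but keep
  # abutting exons distinct
  grl <- GenomicRanges::reduce(S4Vectors::split(gr2, df$gene_id),
                               min.gapwidth = 0L)
  ex <- unlist(grl)
  meta <- df[!duplicated(df$gene_id), c("gene_id", "biotype", "species")]
  idx <- match(names(ex), meta$gene_id)
  gene_models(
    gene_id = names(ex),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    biotype = meta$biotype[idx], species = meta$species[idx]
  )
}

#' Write gene models to GTF
#'
#' Emits one `exon` feature per exon plus a `transcript` feature per gene
#' (one collapsed transcript per locus), converting internal 0-based
#' half-open coordinates back to GTF 1-based inclusive.
#'
#' @param models a `gene_models` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  ex <- GenomicRanges::GRanges(
    models$chrom,
    IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand
  )
  ex$type <- "exon"
  ex$gene_id <- models$gene_id
  ex$transcript_id <- paste0(models$gene_id, ".t1")
  ex$gene_biotype <- models$biotype
  ex$species <- models$species
  spans <- do.call(rbind, lapply(split(models, models$gene_id), function(m) {
    data.frame(gene_id = m$gene_id[1], chrom = m$chrom[1], strand = m$strand[1],
               start = min(m$start), end = max(m$end),
               biotype = m$biotype[1], species = m$species[1])
  }))
  tx <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end),
    strand = spans$strand
  )
  tx$type <- "transcript"
  tx$gene_id <- spans$gene_id
  tx$transcript_id <- paste0(spans$gene_id, ".t1")
  tx$gene_biotype <- spans$biotype
  tx$species <- spans$species
  rtracklayer::export(c(tx, ex), path, format = "gtf")
  invisible(path)
}

#' Spliced (mature) transcript sequence of a gene
#'
#' Concatenates exon sequences 5' to 3'. For minus-strand genes the exon
#' sequences are taken in reverse genomic order and reverse-complemented,
#' so the result always reads in the direction of transcription.
#'
#' @param model a `gene_models` table restricted to one gene (or a table
#'   plus `gene_id=` to select one).
#' @param genome a named [Biostrings::DNAStringSet] (chromosome sequences).
#' @param gene_id optional gene to extract when `model` holds several.
#' @return a single character string (ACGT alphabet).
#' @export
get_spliced_sequence <- function(model, genome, gene_id = NULL) {
  if (!is.null(gene_id)) model <- model[model$gene_id == gene_id, , drop = FALSE]
  if (nrow(model) == 0L) stop("get_spliced_sequence: no exons for gene")
  if (length(unique(model$gene_id)) != 1L)
    stop("get_spliced_sequence: pass one gene (or set gene_id=)")
  chrom <- model$chrom[1]
  if (!chrom %in% names(genome)) stop("get_spliced_sequence: chrom not in genome: ", chrom)
  chrlen <- Biostrings::width(genome[chrom])
  if (any(model$end > chrlen)) stop("get_spliced_sequence: exon beyond chromosome end")
  model <- model[order(model$start), , drop = FALSE]
  pieces <- substring(as.character(genome[[chrom]]), model$start + 1L, model$end)
  seq <- paste0(pieces, collapse = "")
  if (model$strand[1] == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  seq
}

#' Genic (unspliced) sequence of a gene, 5' to 3'
#' @inheritParams get_spliced_sequence
#' @return a single character string spanning first exon start to last exon end.
#' @export
get_genic_sequence <- function(model, genome, gene_id = NULL) {
  if (!is.null(gene_id)) model <- model[model$gene_id == gene_id, , drop = FALSE]
  if (nrow(model) == 0L) stop("get_genic_sequence: no exons for gene")
  chrom <- model$chrom[1]
  seq <- substring(as.character(genome[[chrom]]), min(model$start) + 1L, max(model$end))
  if (model$strand[1] == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  seq
}

#' Read polymorphic sites from a VCF
#'
#' Expects VCF 4.x with `AA` (ancestral allele) and `AF` (alternate allele
#' frequency) INFO keys. Derived-allele frequency is `AF` when the ancestral
#' allele equals REF, and `1 - AF` when it equals ALT. Sites whose AA is
#' missing or matches neither allele cannot be polarized; they are excluded
#' from the returned table and counted in the `n_unpolarized` attribute.
#' Never imputed.
#'
#' @param path VCF file path.
#' @return data.frame (chrom, position 0-based, ref, alt, derived_allele,
#'   derived_freq, lineage, site_class) with attribute `n_unpolarized`.
#' @export
load_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(), position = integer(),
                      ref = character(), alt = character(),
                      derived_allele = character(), derived_freq = numeric(),
                      lineage = character(), site_class = character())
  if (nrow(fix) == 0L) { attr(empty, "n_unpolarized") <- 0L; return(empty) }
  aa <- toupper(vcfR::extract.info(v, "AA"))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  lineage <- vcfR::extract.info(v, "LIN")
  site_class <- vcfR::extract.info(v, "CLASS")
  ref <- toupper(fix$REF); alt <- toupper(fix$ALT)
  polarized <- !is.na(aa) & (aa == ref | aa == alt)
  out <- data.frame(
    chrom = fix$CHROM[polarized],
    position = as.integer(fix$POS[polarized]) - 1L,
    ref = ref[polarized], alt = alt[polarized],
    derived_allele = ifelse(aa[polarized] == ref[polarized],
                            alt[polarized], ref[polarized]),
    derived_freq = ifelse(aa[polarized] == ref[polarized],
                          af[polarized], 1 - af[polarized]),
    lineage = if (all(is.na(lineage))) NA_character_ else lineage[polarized],
    site_class = if (all(is.na(site_class))) NA_character_ else site_class[polarized],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_unpolarized") <- sum(!polarized)
  out
}

#' Write polymorphic sites to a VCF 4.2 file
#'
#' Serializes a site table (as produced by [simulate_population()]) with
#' `AA`, `AF`, `LIN` and `CLASS` INFO keys. `AF` is the alternate-allele
#' frequency, reconstructed from the derived allele and its frequency.
#'
#' @param sites data.frame with chrom, position (0-based), ref, alt,
#'   derived_allele, derived_freq, lineage, site_class.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(sites, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
    "##INFO=<ID=LIN,Number=1,Type=String,Description=\"Lineage\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Site class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- hdr
  if (nrow(sites) > 0L) {
    aa <- ifelse(sites$derived_allele == sites$alt, sites$ref, sites$alt)
    af <- ifelse(sites$derived_allele == sites$alt,
                 sites$derived_freq, 1 - sites$derived_freq)
    info <- sprintf("AA=%s;AF=%s;LIN=%s;CLASS=%s",
                    aa, formatC(af, digits = 6, format = "g"),
                    sites$lineage, sites$site_class)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                              sites$chrom, sites$position + 1L,
                              sites$ref, sites$alt, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences as FASTA (60-column wrap)
#' @param sequences named character vector or [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet
#' @param path FASTA file path.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)
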