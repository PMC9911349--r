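#' Run the synthetic end-to-end analysis pipeline
#'
#' Orchestrates the stages on a self-generated dataset: genome simulation,
#' fractionation counts, N/C ratios, ISOR, U1 scanning and densities,
#' optional classifier training with motif extraction, CRISPR mutation
#' effects, and population selection tests. Each stage writes a TSV into
#' `outdir`, and a JSON manifest records parameters, the seed, and an md5
#' per output so a rerun with the same config is verifiably identical.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created).
#' @param stages character subset of
#'   c("simulate", "localization", "splicing", "motifs", "classifier",
#'   "mutation_effects", "popgen"); stages later in the list depend on
#'   "simulate".
#' @param classifier_n sequences for the classifier stage (kept small by
#'   default; set higher for benchmark-scale runs).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "localization", "splicing",
                                    "motifs", "mutation_effects", "popgen"),
                         classifier_n = 200L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }
  if (!"simulate" %in% stages)
    stop("run_pipeline: the simulate stage is required")
  sim <- simulate_genome(config)
  write_fasta(sim$sequences, file.path(outdir, "genome.fa"))
  outputs[["genome.fa"]] <- unname(tools::md5sum(file.path(outdir, "genome.fa")))
  write_gene_models(sim$models, file.path(outdir, "models.gtf"))
  outputs[["models.gtf"]] <- unname(tools::md5sum(file.path(outdir, "models.gtf")))
  fr <- simulate_fraction_counts(sim$models, sim$truth, config)
  emit(fr$counts, "counts.tsv")
  emit(fr$junctions, "junctions.tsv")

  nc <- NULL
  if ("localization" %in% stages) {
    lib_n <- max(sum(fr$counts$reads_nuc), 1)
    lib_c <- max(sum(fr$counts$reads_cyt), 1)
    nc <- nc_ratio(data.frame(
      gene_id = fr$counts$gene_id,
      fpkm_nuc = compute_fpkm(fr$counts$reads_nuc, fr$counts$exonic_length, lib_n),
      fpkm_cyt = compute_fpkm(fr$counts$reads_cyt, fr$counts$exonic_length, lib_c)
    ))
    emit(nc, "nc_ratio.tsv")
  }
  if ("splicing" %in% stages) {
    iso <- compute_isor(fr$junctions, exonic_length(sim$models))
    emit(iso, "isor.tsv")
  }
  u1_model <- NULL
  if ("motifs" %in% stages || "classifier" %in% stages) {
    set.seed(config$seed + 10L)
    train_sites <- vapply(seq_len(500), function(i)
      paste0(mutate_consensus(u1_consensus(), config$u1_mutation_rate),
             random_seq(2L, config$gc_content)), "")
    u1_model <- fit_maxent(train_sites, constraint_order = 1, tol = 1e-4)
  }
  if ("motifs" %in% stages) {
    dens <- do.call(rbind, lapply(unique(sim$models$gene_id), function(g) {
      sp <- get_spliced_sequence(sim$models, sim$sequences, gene_id = g)
      hits <- scan_sequence(u1_model, sp)
      data.frame(gene_id = g,
                 u1_exonic_density = u1_density(hits, nchar(sp)),
                 stringsAsFactors = FALSE)
    }))
    emit(dens, "u1_density.tsv")
  }
  if ("classifier" %in% stages) {
    ds <- simulate_localization_dataset(n = classifier_n, seed = config$seed)
    ds <- split_dataset(ds, seed = config$seed)
    model <- train_cnn(cnn_spec(seed = config$seed),
                       ds[ds$split == "train", ], ds[ds$split == "valid", ])
    test <- ds[ds$split == "test", ]
    auc <- evaluate_auc(predict(model, test$sequence), test$label)
    emit(data.frame(metric = "test_auc", value = auc), "classifier_auc.tsv")
  }
  if ("mutation_effects" %in% stages && nrow(sim$truth$introns) > 0) {
    gi <- sim$truth$introns$gene_id[1]
    eff <- data.frame(mutation_id = c("m1", "m2"), gene_id = gi,
                      position = c(10L, 20L), ref = "A", alt = "G",
                      odds_multiplier = c(4, 1), psi_delta = c(-0.2, 0),
                      intron_id = sim$truth$introns$intron_id[1])
    assay <- simulate_mutation_assay(sim$models, eff, sim$truth, config)
    counts <- count_alleles(assay$read_calls)
    res <- merge(test_export_shift(counts),
                 test_splice_shift(assay$junction_evidence),
                 by = "mutation_id", all.x = TRUE)
    emit(res, "mutation_effects.tsv")
  }
  if ("popgen" %in% stages) {
    pop <- simulate_population(config)
    write_variants(pop, file.path(outdir, "population.vcf"))
    outputs[["population.vcf"]] <-
      unname(tools::md5sum(file.path(outdir, "population.vcf")))
    classes <- split(pop$derived_freq, pop$site_class)
    neutral <- classes[["synonymous"]]
    rows <- lapply(setdiff(names(classes), "synonymous"), function(cl) {
      mt <- mc_skew_test(classes[[cl]], neutral, n_boot = 2000L,
                         seed = config$seed)
      data.frame(site_class = cl, skewness = mt$observed_skewness,
                 p = mt$p, stringsAsFactors = FALSE)
    })
    if (length(rows)) emit(do.call(rbind, rows), "skew_tests.tsv")
  }
  manifest <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    stages = stages,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
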