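#' Simulate a two-species co-expression panel
#'
#' Generates FPKM matrices for two species with block co-expression
#' structure and a 1:1 orthology map. Genes in a block load on a shared
#' latent factor with within-block Pearson correlation approximately `r`;
#' shared blocks are correlated in both species, lineage-specific blocks
#' only in species A (their species-B orthologues are independent noise).
#' Default panel sizes follow a two-population brain study design: 134
#' individuals for species A and 35 for species B.
#'
#' Uses `seed` directly (defaults to `config$seed + 4` when a config is
#' given).
#'
#' @param n_ind_a,n_ind_b individuals per species.
#' @param blocks list of block specs `list(n_genes, r, shared)`.
#' @param n_noise unstructured background genes.
#' @param seed integer seed.
#' @param config optional [sim_config()]; only its seed is used.
#' @return list(panel_a, panel_b, orthology, truth): matrices are genes x
#'   individuals (FPKM >= 0), orthology maps gene_a to gene_b, truth
#'   records each gene's block and whether it is shared.
#' @export
simulate_expression_panel <- function(n_ind_a = 134L, n_ind_b = 35L,
                                      blocks = list(
                                        list(n_genes = 10L, r = 0.8, shared = TRUE),
                                        list(n_genes = 10L, r = 0.8, shared = FALSE)
                                      ),
                                      n_noise = 50L,
                                      seed = NULL, config = NULL) {
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed + 4L else 5L
  set.seed(seed)
  n_genes <- sum(vapply(blocks, function(b) as.integer(b$n_genes),
                        integer(1))) + as.integer(n_noise)
  gene_a <- sprintf("geneA%04d", seq_len(n_genes))
  gene_b <- sprintf("geneB%04d", seq_len(n_genes))
  make_panel <- function(n_ind, species_a) {
    m <- matrix(NA_real_, n_genes, n_ind)
    gi <- 0L
    block_id <- integer(n_genes); shared <- logical(n_genes)
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      correlated <- species_a || b$shared
      f <- stats::rnorm(n_ind)
      for (j in seq_len(b$n_genes)) {
        gi <- gi + 1L
        block_id[gi] <- bi; shared[gi] <- b$shared
        z <- if (correlated)
          sqrt(b$r) * f + sqrt(1 - b$r) * stats::rnorm(n_ind)
        else stats::rnorm(n_ind)
        m[gi, ] <- pmax(0, 5 + 2 * z)
      }
    }
    if (n_noise > 0) {
      idx <- gi + seq_len(n_noise)
      m[idx, ] <- pmax(0, 5 + 2 * matrix(stats::rnorm(n_noise * n_ind),
                                         n_noise, n_ind))
      block_id[idx] <- 0L; shared[idx] <- NA
    }
    list(m = m, block = block_id, shared = shared)
  }
  pa <- make_panel(n_ind_a, species_a = TRUE)
  pb <- make_panel(n_ind_b, species_a = FALSE)
  rownames(pa$m) <- gene_a; colnames(pa$m) <- sprintf("indA%03d", seq_len(n_ind_a))
  rownames(pb$m) <- gene_b; colnames(pb$m) <- sprintf("indB%03d", seq_len(n_ind_b))
  list(
    panel_a = pa$m, panel_b = pb$m,
    orthology = data.frame(gene_a = gene_a, gene_b = gene_b,
                           stringsAsFactors = FALSE),
    truth = data.frame(gene_a = gene_a, gene_b = gene_b,
                       block = pa$block, shared = pa$shared,
                       stringsAsFactors = FALSE)
  )
}
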