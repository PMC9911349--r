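#' Drop weakly expressed genes from an expression panel
#'
#' @param panel genes x individuals FPKM matrix.
#' @param min_fpkm genes with panel-mean FPKM below this are removed
#'   (default 0.2).
#' @return the row-subset matrix (with a warning when empty).
#' @export
filter_expressed <- function(panel, min_fpkm = 0.2) {
  if (nrow(panel) == 0L) { warning("filter_expressed: empty panel"); return(panel) }
  keep <- rowMeans(panel) >= min_fpkm
  out <- panel[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("filter_expressed: no genes pass the filter")
  out
}

#' Co-expression partner sets of focal genes
#'
#' For each focal gene, Pearson correlations against every other gene in
#' the panel, p-values from the exact t transform
#' `t = r * sqrt((n-2)/(1-r^2))`, and BH correction across that focal
#' gene's tests; partners are the genes at q < alpha. Constant-expression
#' genes have no defined correlation and are excluded (tallied per focal
#' gene).
#'
#' @param panel genes x individuals FPKM matrix (>= 3 individuals).
#' @param focal_genes character vector of row names.
#' @param alpha BH-corrected significance threshold.
#' @return named list (per focal gene) of data.frames (partner, r, p, q,
#'   significant) with attribute `n_excluded` per focal gene.
#' @export
partner_sets <- function(panel, focal_genes, alpha = 0.05) {
  n <- ncol(panel)
  if (n < 3L) stop("partner_sets: need at least 3 individuals")
  missing <- setdiff(focal_genes, rownames(panel))
  if (length(missing))
    stop("partner_sets: focal genes absent from panel: ",
         paste(missing, collapse = ", "))
  sds <- apply(panel, 1, stats::sd)
  out <- lapply(focal_genes, function(f) {
    others <- setdiff(rownames(panel), f)
    usable <- others[sds[others] > 0]
    if (sds[f] == 0) usable <- character(0)
    res <- data.frame(partner = character(0), r = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0))
    if (length(usable)) {
      r <- as.vector(stats::cor(panel[f, ], t(panel[usable, , drop = FALSE])))
      r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
      tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      p[abs(r) >= 1] <- 0
      q <- bh_adjust(p)
      res <- data.frame(partner = usable, r = r, p = p, q = q,
                        significant = q < alpha, stringsAsFactors = FALSE)
      rownames(res) <- NULL
    }
    attr(res, "n_excluded") <- length(others) - length(usable)
    res
  })
  names(out) <- focal_genes
  out
}

#' Cross-species conservation of a co-expression partner set
#'
#' For a focal gene's significant partners in species A, the fraction whose
#' orthologous gene pair is also significantly co-expressed in species B.
#' Partners without an orthologue are excluded from the denominator
#' (tallied); a focal gene without an orthologue or with no mappable
#' significant partners returns NA with a flag.
#'
#' @param partner_table one focal gene's data.frame from [partner_sets()]
#'   (species A).
#' @param focal_gene the focal gene id in species A.
#' @param panel_b species-B genes x individuals matrix.
#' @param orthology data.frame (gene_a, gene_b), 1:1.
#' @param alpha significance threshold in species B.
#' @return list(fraction, n_partners, n_mapped, n_conserved, defined).
#' @export
conservation_fraction <- function(partner_table, focal_gene, panel_b,
                                  orthology, alpha = 0.05) {
  partners <- partner_table$partner[partner_table$significant]
  map <- stats::setNames(orthology$gene_b, orthology$gene_a)
  focal_b <- unname(map[focal_gene])
  if (length(focal_b) != 1L || is.na(focal_b) ||
      !focal_b %in% rownames(panel_b))
    return(list(fraction = NA_real_, n_partners = length(partners),
                n_mapped = 0L, n_conserved = 0L, defined = FALSE))
  partners_b <- map[partners]
  mapped <- !is.na(partners_b) & partners_b %in% rownames(panel_b)
  if (!any(mapped))
    return(list(fraction = NA_real_, n_partners = length(partners),
                n_mapped = 0L, n_conserved = 0L, defined = FALSE))
  ps_b <- partner_sets(panel_b, focal_b, alpha = alpha)[[1]]
  sig_b <- ps_b$partner[ps_b$significant]
  conserved <- partners_b[mapped] %in% sig_b
  list(fraction = mean(conserved), n_partners = length(partners),
       n_mapped = sum(mapped), n_conserved = sum(conserved), defined = TRUE)
}

#' Rank-based comparison of two groups of conservation fractions
#'
#' Wilcoxon rank-sum (or signed-rank when `paired`) test wrapper.
#'
#' @param fractions_de_novo,fractions_background numeric vectors.
#' @param paired use the signed-rank test on pairs.
#' @param ... passed to [stats::wilcox.test()].
#' @return list(statistic, p).
#' @export
compare_groups <- function(fractions_de_novo, fractions_background,
                           paired = FALSE, ...) {
  wt <- suppressWarnings(
    stats::wilcox.test(fractions_de_novo, fractions_background,
                       paired = paired, exact = NULL, ...))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
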