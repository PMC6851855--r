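#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Probability-mass rule: with margins fixed, the two-tailed p-value is the
#' sum of hypergeometric probabilities of all tables whose probability does
#' not exceed the observed one (within a relative tolerance of 1e-7, the
#' convention shared by common implementations). A zero margin gives p = 1.
#'
#' @param tab 2x2 matrix (or 4-vector a, b, c, d filled by row) of
#'   non-negative integer counts.
#' @return the two-tailed p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2, byrow = !is.matrix(tab))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[2, 1]       # column-1 total ("successes")
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]       # row-1 total (draws)
  if (m == 0 || n == 0 || k == 0 || m + n == k) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' GO term enrichment of a gene set against a genome background
#'
#' For every GO term with at least one gene in the set, builds the 2x2 table
#' (in-set annotated / in-set not / rest-of-background annotated / rest not),
#' tests it with the two-tailed Fisher exact test, adjusts across terms with
#' Benjamini-Hochberg, and reports the fold change as the term's proportion
#' in the set over its proportion in the whole background.
#'
#' @param gene_set character vector of gene ids (subset of the background).
#' @param annotation data.frame with columns `gene` and `term` (one row per
#'   gene-term pair).
#' @param background character vector of background gene ids; defaults to
#'   all annotated genes.
#' @return data.frame sorted by adjusted p: `term`, `set_annotated`,
#'   `set_total`, `bg_annotated`, `bg_total`, `fold_change`, `p`, `p_adj`.
#' @export
enrich_terms <- function(gene_set, annotation,
                         background = unique(annotation$gene)) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background))
    stop("gene set must be a subset of the background")
  if (length(gene_set) == 0)
    return(data.frame(term = character(), set_annotated = integer(),
                      set_total = integer(), bg_annotated = integer(),
                      bg_total = integer(), fold_change = numeric(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  set_terms <- unique(ann$term[ann$gene %in% gene_set])
  n_set <- length(gene_set)
  n_bg <- length(background)
  rows <- lapply(set_terms, function(tm) {
    genes_tm <- unique(ann$gene[ann$term == tm])
    a <- sum(gene_set %in% genes_tm)
    b <- n_set - a
    c_tot <- length(genes_tm)                 # annotated in full background
    c_rest <- c_tot - a                       # annotated outside the set
    d_rest <- (n_bg - n_set) - c_rest
    data.frame(term = tm, set_annotated = a, set_total = n_set,
               bg_annotated = c_tot, bg_total = n_bg,
               fold_change = (a / n_set) / (c_tot / n_bg),
               p = fisher_exact_2x2(matrix(c(a, b, c_rest, d_rest), 2, 2,
                                           byrow = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p_adj, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
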