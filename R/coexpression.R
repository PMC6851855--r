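#' Quantile normalization followed by log2 transform
#'
#' Forces every sample column onto the same empirical distribution (the row
#' means of the column-sorted matrix; tied values share the mean of their
#' rank range), then applies `log2(x + 1)`.
#'
#' @param tpm genes x samples nonnegative matrix.
#' @param log2_offset pseudo-count added before the log (default 1).
#' @return normalized, log2-transformed matrix of the same shape.
#' @export
quantile_normalize_log2 <- function(tpm, log2_offset = 1) {
  stopifnot(is.matrix(tpm), ncol(tpm) >= 2)
  if (any(tpm < 0)) stop("TPM values must be nonnegative")
  zero_col <- apply(tpm, 2, function(x) all(x == 0))
  if (any(zero_col))
    stop("all-zero sample column(s): ",
         paste(colnames(tpm)[zero_col], collapse = ", "))
  qn <- limma::normalizeQuantiles(tpm, ties = TRUE)
  dimnames(qn) <- dimnames(tpm)
  log2(qn + log2_offset)
}

#' Select the most variable genes by standard deviation
#'
#' Ranks genes by their across-sample SD and keeps the top `k`. Genes listed
#' in `force_include` (e.g. the focal homoeologs) are added if they fall
#' outside the top `k`, with a message.
#'
#' @param mat genes x samples matrix (normalized).
#' @param k number of genes to keep.
#' @param force_include gene ids always retained.
#' @return character vector of selected gene ids.
#' @export
top_variable_genes <- function(mat, k, force_include = character()) {
  stopifnot(k <= nrow(mat))
  sds <- apply(mat, 1, stats::sd)
  sel <- names(sort(sds, decreasing = TRUE))[seq_len(k)]
  missing <- setdiff(force_include, sel)
  if (length(missing)) {
    message("force-including ", length(missing),
            " focal gene(s) outside the top ", k, " by SD")
    sel <- union(sel, missing)
  }
  sel
}

#' Pearson correlation between two expression profiles
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return the product-moment correlation.
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: PCC undefined")
  stats::cor(x, y)
}

#' Global co-expression network over the most variable genes
#'
#' Computes all pairwise PCCs among the top `k` most-variable genes and keeps
#' the extreme-correlation edges (PCC < `neg_cut` or PCC > `pos_cut`).
#' Constant genes are excluded with a message.
#'
#' @param mat normalized genes x samples matrix.
#' @param k number of most-variable genes to use.
#' @param neg_cut,pos_cut edge thresholds (defaults -0.90 / 0.98).
#' @param force_include gene ids passed to [top_variable_genes()].
#' @return data.frame of edges: `gene_i`, `gene_j`, `pcc`, `sign`, `layer`.
#' @export
build_global_network <- function(mat, k = min(10000L, nrow(mat)),
                                 neg_cut = -0.90, pos_cut = 0.98,
                                 force_include = character()) {
  sel <- top_variable_genes(mat, k, force_include)
  sub <- mat[sel, , drop = FALSE]
  const <- apply(sub, 1, stats::sd) == 0
  if (any(const)) {
    message("excluding ", sum(const), " constant gene(s) from PCC")
    sub <- sub[!const, , drop = FALSE]
  }
  cm <- stats::cor(t(sub))
  keep <- which((cm < neg_cut | cm > pos_cut) &
                upper.tri(cm), arr.ind = TRUE)
  if (nrow(keep) == 0)
    return(data.frame(gene_i = character(), gene_j = character(),
                      pcc = numeric(), sign = character(),
                      layer = character(), stringsAsFactors = FALSE))
  data.frame(gene_i = rownames(cm)[keep[, 1]],
             gene_j = colnames(cm)[keep[, 2]],
             pcc = cm[keep],
             sign = ifelse(cm[keep] > 0, "positive", "negative"),
             layer = "global", stringsAsFactors = FALSE)
}

#' Local co-expression network around the focal homoeolog triad
#'
#' For each focal gene, all other genes are ranked by their PCC with it; the
#' member set is the union over the three homoeologs of genes that are both
#' in the top `top_frac` of that ranking and exceed `abs_cut` in absolute
#' PCC. Edges connect each focal gene to its qualifying members. The ranking
#' uses signed PCC by default; set `rank_abs = TRUE` to rank on |PCC|.
#'
#' @param mat normalized genes x samples matrix.
#' @param focal character vector of focal gene ids present in `mat`.
#' @param top_frac top fraction of the per-focal PCC ranking (default 0.01).
#' @param abs_cut absolute-PCC threshold (default 0.60).
#' @param rank_abs rank by absolute instead of signed PCC.
#' @return list with `members` (gene ids) and `edges` (data.frame: gene_i =
#'   focal, gene_j = member, pcc, sign, layer = "local").
#' @export
build_local_network <- function(mat, focal, top_frac = 0.01,
                                abs_cut = 0.60, rank_abs = FALSE) {
  stopifnot(all(focal %in% rownames(mat)))
  others <- setdiff(rownames(mat), focal)
  members <- character(); edges <- list()
  for (f in focal) {
    if (stats::sd(mat[f, ]) == 0) {
      warning("focal gene ", f, " is constant; skipped")
      next
    }
    ok <- others[apply(mat[others, , drop = FALSE], 1, stats::sd) > 0]
    r <- as.vector(stats::cor(mat[f, ], t(mat[ok, , drop = FALSE])))
    names(r) <- ok
    score <- if (rank_abs) abs(r) else r
    cut <- stats::quantile(score, 1 - top_frac, names = FALSE, type = 7)
    hit <- ok[score >= cut & abs(r) > abs_cut]   # boundary ties all kept
    members <- union(members, hit)
    if (length(hit))
      edges[[f]] <- data.frame(gene_i = f, gene_j = hit, pcc = r[hit],
                               sign = ifelse(r[hit] > 0, "positive",
                                             "negative"),
                               layer = "local", stringsAsFactors = FALSE)
  }
  edges <- if (length(edges))
    do.call(rbind, c(edges, list(make.row.names = FALSE)))
  else data.frame(gene_i = character(), gene_j = character(),
                  pcc = numeric(), sign = character(), layer = character(),
                  stringsAsFactors = FALSE)
  list(members = members, edges = edges)
}

#' Export network nodes and edges as TSV
#'
#' @param edges edge data.frame (from the global or local builder).
#' @param focal focal gene ids, flagged in the node table.
#' @param node_path,edge_path output paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(edges, focal, node_path, edge_path) {
  nodes <- unique(c(edges$gene_i, edges$gene_j, focal))
  nd <- data.frame(gene = nodes, focal = nodes %in% focal,
                   stringsAsFactors = FALSE)
  write_tsv(nd, node_path)
  write_tsv(edges, edge_path)
  invisible(c(node_path, edge_path))
}
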