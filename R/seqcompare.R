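#' Kimura 2-parameter distance between two aligned DNA sequences
#'
#' Columns with a gap in either sequence are removed (complete deletion,
#' applied pairwise), then
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition and
#' `Q` the transversion proportion. Saturated pairs (a log argument <= 0)
#' return NA.
#'
#' @param seq1,seq2 aligned DNA sequences of equal length ('-' = gap).
#' @return the K2P distance, or NA when undefined.
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- toupper(strsplit(seq1, "", fixed = TRUE)[[1]])
  b <- toupper(strsplit(seq2, "", fixed = TRUE)[[1]])
  stopifnot(length(a) == length(b))
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  L <- length(a)
  if (L == 0) return(NA_real_)
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / L
  Q <- sum(diff & !transition) / L
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

#' Pairwise K2P distance matrix for an aligned sequence set
#'
#' @param seqs named character vector of aligned DNA sequences.
#' @return symmetric distance matrix with zero diagonal (NA for saturated
#'   pairs).
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2, length(unique(nchar(seqs))) == 1)
  ids <- if (is.null(names(seqs))) paste0("seq", seq_len(n)) else names(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- k2p_distance(seqs[i], seqs[j])
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via the standard implementation), with negative
#' branch lengths clamped to zero and their (negative) length transferred to
#' the sister edge so path lengths are preserved.
#'
#' @param d symmetric distance matrix with >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(nrow(d) >= 3)
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sisters <- which(tr$edge[, 1] == parent)
    sisters <- setdiff(sisters, e)
    if (length(sisters))
      tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] +
        tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}

#' Bootstrap support for a K2P neighbor-joining tree
#'
#' Gap-containing columns are removed alignment-wide, columns are resampled
#' with replacement `n_reps` times, the NJ tree is rebuilt per replicate, and
#' the frequency of each bipartition of the original tree is reported as a
#' percentage at its node.
#'
#' @param seqs named character vector of aligned DNA sequences.
#' @param n_reps number of bootstrap replicates (0 = no supports).
#' @param seed integer seed for the resampling.
#' @return list with `tree` (the original NJ tree) and `support` (integer
#'   percentages per internal node; NULL when `n_reps = 0`).
#' @export
bootstrap_support <- function(seqs, n_reps = 1000L, seed = 1L) {
  stopifnot(length(seqs) >= 3)
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(chars) <- names(seqs)
  keep <- colSums(chars == "-") == 0       # complete deletion, whole set
  chars <- chars[, keep, drop = FALSE]
  build <- function(m) {
    s <- apply(m, 1, paste, collapse = "")
    nj_tree(k2p_matrix(s))
  }
  tree <- build(chars)
  if (n_reps == 0) return(list(tree = tree, support = NULL))
  set.seed(seed)
  counts <- ape::boot.phylo(tree, chars, build, B = n_reps,
                            quiet = TRUE, trees = FALSE)
  list(tree = tree, support = round(100 * counts / n_reps))
}

#' Count amino-acid differences between two aligned protein sequences
#'
#' Columns containing a gap in either sequence are excluded; the percent is
#' the differing-column count over the compared columns, to one decimal.
#'
#' @param seq1,seq2 aligned protein sequences of equal length.
#' @return list with `count`, `compared` and `percent`.
#' @export
count_aa_differences <- function(seq1, seq2) {
  a <- toupper(strsplit(seq1, "", fixed = TRUE)[[1]])
  b <- toupper(strsplit(seq2, "", fixed = TRUE)[[1]])
  stopifnot(length(a) == length(b))
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no comparable columns")
  count <- sum(a != b)
  list(count = count, compared = length(a),
       percent = round(100 * count / length(a), 1))
}
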