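#' Per-site nucleotide diversity (unbiased heterozygosity)
#'
#' Average pairwise diversity per SNP site: `2 * p * (1 - p) * n / (n - 1)`
#' where `p` is the alternate-allele frequency and `n` the number of called
#' allele copies.
#'
#' @param alt_copies number of alternate-allele copies called at the site.
#' @param total_copies number of called allele copies (>= 2).
#' @return the per-site diversity.
#' @export
site_pi <- function(alt_copies, total_copies) {
  stopifnot(total_copies >= 2, alt_copies >= 0, alt_copies <= total_copies)
  p <- alt_copies / total_copies
  2 * p * (1 - p) * total_copies / (total_copies - 1)
}

#' Hudson-type per-site F_ST between two populations
#'
#' `F_ST = 1 - H_w / H_b` where `H_w` is the mean of the two unbiased
#' within-population heterozygosities and
#' `H_b = p1 (1 - p2) + p2 (1 - p1)`. Negative values are reported as
#' computed; sites fixed for the same allele in both populations (`H_b = 0`)
#' return NA and are excluded upstream.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param n1,n2 called allele copies in each population (>= 2); `Inf` gives
#'   the infinite-sample form.
#' @return list with `fst`, `hw`, `hb`.
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  corr <- function(n) if (is.infinite(n)) 1 else n / (n - 1)
  hw <- mean(c(2 * p1 * (1 - p1) * corr(n1), 2 * p2 * (1 - p2) * corr(n2)))
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  list(fst = if (hb == 0) NA_real_ else 1 - hw / hb, hw = hw, hb = hb)
}

site_stats <- function(geno, pop_rows) {
  # per-site alt copies and called copies per population (diploid dosage)
  lapply(pop_rows, function(rows) {
    sub <- geno[rows, , drop = FALSE]
    called <- colSums(!is.na(sub)) * 2
    alt <- colSums(sub, na.rm = TRUE)
    list(alt = alt, n = called, p = ifelse(called > 0, alt / called, NA))
  })
}

#' Sliding-window scan of nucleotide diversity and F_ST
#'
#' Windows of `window` bp advance by `step` bp along the chromosome. Per
#' window, pi for each population is the mean per-site diversity over its
#' SNPs, and F_ST between the two populations is the ratio-of-averages
#' Hudson estimator `1 - sum(H_w) / sum(H_b)` over sites with `H_b > 0`.
#' Windows without usable SNPs carry NA statistics.
#'
#' @param geno accessions x SNPs dosage matrix (0/1/2, NA missing).
#' @param positions 1-based bp positions per SNP column.
#' @param populations character vector (one label per accession) with
#'   exactly two levels; the first level sorted is population 1.
#' @param window,step window size and step in bp (defaults 2 Mb / 400 kb).
#' @param chrom_length chromosome length; defaults to the last SNP position.
#' @return data.frame: `start`, `end` (1-based, end-inclusive), `n_snps`,
#'   `pi_<pop>` per population, `fst`.
#' @export
window_scan <- function(geno, positions, populations,
                        window = 2e6, step = 4e5,
                        chrom_length = max(positions)) {
  stopifnot(ncol(geno) == length(positions),
            nrow(geno) == length(populations),
            !is.unsorted(positions))
  pops <- sort(unique(populations))
  stopifnot(length(pops) == 2)
  pop_rows <- lapply(pops, function(p) which(populations == p))
  st <- site_stats(geno, pop_rows)
  usable <- st[[1]]$n >= 2 & st[[2]]$n >= 2
  pi_site <- lapply(st, function(s)
    ifelse(s$n >= 2, 2 * s$p * (1 - s$p) * s$n / pmax(s$n - 1, 1), NA))
  hw_site <- (pi_site[[1]] + pi_site[[2]]) / 2
  hb_site <- st[[1]]$p * (1 - st[[2]]$p) + st[[2]]$p * (1 - st[[1]]$p)
  if (window > chrom_length) {
    warning("window larger than chromosome; using one truncated window")
    starts <- 1
  } else {
    starts <- seq(1, chrom_length - window + 1, by = step)
  }
  rows <- lapply(starts, function(s0) {
    e0 <- min(s0 + window - 1, chrom_length)
    in_win <- positions >= s0 & positions <= e0 & usable
    n <- sum(in_win)
    if (n == 0) {
      return(data.frame(start = s0, end = e0, n_snps = 0L,
                        pi1 = NA_real_, pi2 = NA_real_, fst = NA_real_))
    }
    hb_sum <- sum(hb_site[in_win])
    fst <- if (hb_sum > 0) 1 - sum(hw_site[in_win]) / hb_sum else NA_real_
    data.frame(start = s0, end = e0, n_snps = n,
               pi1 = mean(pi_site[[1]][in_win]),
               pi2 = mean(pi_site[[2]][in_win]), fst = fst)
  })
  out <- do.call(rbind, rows)
  names(out)[4:5] <- paste0("pi_", pops)
  out
}

#' Extract genic haplotypes and per-population frequency tables
#'
#' Accessions with any missing or heterozygous call across the region's SNPs
#' are excluded (effectively inbred material; heterozygous genic calls are
#' treated as unresolvable). Haplotypes are keyed by the genotype vector and
#' labeled H1, H2, ... by descending pooled frequency.
#'
#' @param geno accessions x SNPs dosage matrix.
#' @param positions bp positions per SNP column.
#' @param populations character vector per accession.
#' @param region `c(start, end)` bp interval (1-based, inclusive).
#' @return data.frame: `haplotype`, `population`, `count`, `frequency`, plus
#'   attribute `"keys"` mapping labels to genotype-vector keys.
#' @export
extract_haplotypes <- function(geno, positions, populations, region) {
  cols <- which(positions >= region[1] & positions <= region[2])
  if (!length(cols)) stop("region contains no SNPs")
  sub <- geno[, cols, drop = FALSE]
  ok <- apply(sub, 1, function(g) !anyNA(g) && all(g %in% c(0, 2)))
  if (!any(ok)) {
    warning("all accessions excluded (missing or heterozygous calls)")
    return(data.frame(haplotype = character(), population = character(),
                      count = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  }
  sub <- sub[ok, , drop = FALSE]
  pops <- populations[ok]
  key <- apply(sub, 1, paste, collapse = "")
  pooled <- sort(table(key), decreasing = TRUE)
  labels <- stats::setNames(paste0("H", seq_along(pooled)), names(pooled))
  rows <- list()
  for (pn in unique(pops)) {
    kt <- table(key[pops == pn])
    rows[[pn]] <- data.frame(haplotype = labels[names(kt)],
                             population = pn,
                             count = as.integer(kt),
                             frequency = as.integer(kt) / sum(kt),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$population, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "keys") <- labels
  out
}

#' Fisher test of a haplotype's carrier frequency between two populations
#'
#' Builds the 2x2 carrier / non-carrier x population table and applies the
#' two-tailed Fisher exact test.
#'
#' @param hap_table data.frame from [extract_haplotypes()] (or any table
#'   with columns `haplotype`, `population`, `count`).
#' @param haplotype haplotype label to test.
#' @param pop1,pop2 population labels.
#' @return list with `p`, and the 2x2 `table` used.
#' @export
compare_haplotype_freqs <- function(hap_table, haplotype, pop1, pop2) {
  get <- function(pop) {
    sub <- hap_table[hap_table$population == pop, , drop = FALSE]
    if (!nrow(sub)) stop("population ", pop, " absent from the table")
    carrier <- sum(sub$count[sub$haplotype == haplotype])
    c(carrier = carrier, other = sum(sub$count) - carrier)
  }
  c1 <- get(pop1); c2 <- get(pop2)
  tab <- matrix(c(c1["carrier"], c1["other"], c2["carrier"], c2["other"]),
                2, 2, byrow = TRUE,
                dimnames = list(c(pop1, pop2), c("carrier", "non_carrier")))
  if (sum(tab[, "carrier"]) == 0) return(list(p = 1, table = tab))
  list(p = fisher_exact_2x2(tab), table = tab)
}
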