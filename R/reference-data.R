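#' Grain trait group summaries for the TaGW7-edited families
#'
#' Published group-level summaries (number of plants, per-trait means and
#' standard errors) for the T3 progenies of the two edited wheat families:
#' the family segregating mutations only in the B-genome copy of TaGW7
#' (`family = "B_only"`) and the family segregating mutations in both the B
#' and D copies (`family = "B_and_D"`). Genotype codes use uppercase for
#' wild-type and lowercase for mutated alleles of the A, B and D homoeologs;
#' `AABBDD` is the segregated t-wild-type baseline. Traits: grain width and
#' length in mm, grain area in mm^2, thousand grain weight (tgw) in g.
#'
#' These summaries are the inputs for recomputing the percent-change cells
#' of the trait tables; per-plant raw data are not included.
#'
#' @return data.frame with columns `family`, `genotype`, `n`, and
#'   `<trait>_mean` / `<trait>_se` for the four traits.
#' @export
grain_trait_reference <- function() {
  rbind(
    data.frame(family = "B_only",
               genotype = c("AABBDD", "AABbDD", "AAbbDD"),
               n = c(9L, 21L, 13L),
               width_mean = c(3.62, 3.65, 3.70),
               width_se = c(0.033, 0.031, 0.023),
               length_mean = c(6.16, 6.19, 6.23),
               length_se = c(0.056, 0.030, 0.038),
               area_mean = c(16.09, 16.37, 16.64),
               area_se = c(0.27, 0.18, 0.17),
               tgw_mean = c(40.32, 41.23, 42.31),
               tgw_se = c(0.88, 0.76, 0.69),
               stringsAsFactors = FALSE),
    data.frame(family = "B_and_D",
               genotype = c("AABBDD", "AAbbDD", "AABBdd", "AAbbdd"),
               n = c(26L, 7L, 6L, 47L),
               width_mean = c(3.67, 3.74, 3.75, 3.76),
               width_se = c(0.017, 0.028, 0.032, 0.012),
               length_mean = c(6.27, 6.29, 6.14, 6.12),
               length_se = c(0.033, 0.066, 0.057, 0.020),
               area_mean = c(16.67, 16.92, 16.73, 16.66),
               area_se = c(0.14, 0.24, 0.25, 0.09),
               tgw_mean = c(42.72, 43.48, 43.96, 44.07),
               tgw_se = c(0.48, 1.03, 0.72, 0.35),
               stringsAsFactors = FALSE))
}

#' Percent-change cells recomputed from grouped trait means
#'
#' Recomputes, for every non-reference genotype of one family in
#' [grain_trait_reference()] (or any table with the same columns), the
#' percent change of each trait mean against the reference genotype's mean.
#'
#' @param summaries data.frame in the [grain_trait_reference()] layout.
#' @param family family id to use.
#' @param reference reference genotype code.
#' @return data.frame: `genotype`, `trait`, `pct_change` (2 decimals).
#' @export
reference_pct_changes <- function(summaries = grain_trait_reference(),
                                  family = "B_and_D",
                                  reference = "AABBDD") {
  sub <- summaries[summaries$family == family, , drop = FALSE]
  ref <- sub[sub$genotype == reference, , drop = FALSE]
  stopifnot(nrow(ref) == 1)
  traits <- c("width", "length", "area", "tgw")
  rows <- list()
  for (g in setdiff(sub$genotype, reference)) {
    grp <- sub[sub$genotype == g, , drop = FALSE]
    for (t in traits) {
      col <- paste0(t, "_mean")
      rows[[length(rows) + 1]] <- data.frame(
        genotype = g, trait = t,
        pct_change = pct_change(grp[[col]], ref[[col]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Haplotype counts of the TaGW7 homoeologs across wheat populations
#'
#' Published per-population haplotype accession counts for the genic regions
#' of the three TaGW7 homoeologs in hexaploid wheat cultivars and landraces
#' and in tetraploid domesticated and wild emmer. Frequencies are recomputed
#' from the counts by [haplotype_reference_freqs()].
#'
#' @return data.frame: `gene`, `population`, `haplotype`, `count`.
#' @export
haplotype_reference_counts <- function() {
  data.frame(
    gene = c(rep("GW7-A1", 4 + 4 + 1 + 3), rep("GW7-B1", 4 + 3 + 2 + 2),
             rep("GW7-D1", 2 + 2)),
    population = c(rep("cultivars", 4), rep("landraces", 4),
                   "domesticated_emmer", rep("wild_emmer", 3),
                   rep("cultivars", 4), rep("landraces", 3),
                   rep("domesticated_emmer", 2), rep("wild_emmer", 2),
                   rep("cultivars", 2), rep("landraces", 2)),
    haplotype = c("H1a", "H2a", "H3a", "H4a",
                  "H1a", "H2a", "H3a", "H5a",
                  "H1a", "H1a", "H5a", "H6a",
                  "H1b", "H2b", "H3b", "H4b",
                  "H1b", "H2b", "H3b",
                  "H1b", "H2b", "H1b", "H2b",
                  "H1d", "H2d", "H1d", "H2d"),
    count = c(306L, 39L, 17L, 1L,
              210L, 3L, 31L, 3L,
              28L, 6L, 14L, 11L,
              203L, 136L, 4L, 11L,
              163L, 61L, 6L,
              14L, 6L, 4L, 26L,
              341L, 3L, 242L, 2L),
    stringsAsFactors = FALSE)
}

#' Haplotype frequencies recomputed from accession counts
#'
#' @param counts data.frame in the [haplotype_reference_counts()] layout.
#' @return the same table with a `frequency` column (count over the
#'   gene-by-population total), to full precision.
#' @export
haplotype_reference_freqs <- function(counts = haplotype_reference_counts()) {
  totals <- stats::aggregate(count ~ gene + population, counts, sum)
  idx <- match(paste(counts$gene, counts$population),
               paste(totals$gene, totals$population))
  counts$frequency <- counts$count / totals$count[idx]
  counts
}
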