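#' Per-plant trait means from spike-level measurements
#'
#' Grain width, length, area and thousand grain weight are measured per
#' spike; the plant value is the unweighted mean over its spikes. A plant
#' with a missing value for one trait is excluded for that trait only.
#'
#' @param records data.frame with columns `plant_id`, `genotype`, `spike`
#'   and the traits `width`, `length`, `area`, `tgw`.
#' @return data.frame with one row per plant: `plant_id`, `genotype` and the
#'   per-trait means.
#' @export
plant_trait_means <- function(records) {
  traits <- c("width", "length", "area", "tgw")
  stopifnot(all(c("plant_id", "genotype", traits) %in% names(records)))
  ids <- unique(records$plant_id)
  out <- data.frame(plant_id = ids,
                    genotype = records$genotype[match(ids,
                                                      records$plant_id)],
                    stringsAsFactors = FALSE)
  for (t in traits)
    out[[t]] <- vapply(ids, function(p)
      mean(records[[t]][records$plant_id == p], na.rm = TRUE), 0)
  out
}

#' Percent change of a group mean against a reference mean
#'
#' @param mean_group,mean_ref group and reference means (unrounded).
#' @param digits decimals for printing (default 2, the usual table format).
#' @return percent change, rounded to `digits`.
#' @export
pct_change <- function(mean_group, mean_ref, digits = 2) {
  round(100 * (mean_group - mean_ref) / mean_ref, digits)
}

#' Pooled-variance two-tailed Student's t test
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t`, `df` (`n1 + n2 - 2`) and two-tailed `p`. When the
#'   pooled variance is zero: `p = 1` for equal means; `p = 0` (flagged with
#'   `degenerate = TRUE`) otherwise.
#' @export
students_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    eq <- mean(x) == mean(y)
    return(list(t = if (eq) 0 else Inf, df = length(x) + length(y) - 2,
                p = if (eq) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

stars_for_p <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.0001) "****"
  else if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else ""
}

#' Per-genotype trait summaries with percent change against a reference
#'
#' For each genotype group: n, per-trait mean and standard error
#' (SD / sqrt(n)), percent change of the mean against the reference
#' genotype's mean, the pooled-variance two-tailed t-test p-value against the
#' reference, and significance stars (`*` for 0.01 < p < 0.05 up to `****`
#' for p < 0.0001). Groups with fewer than 2 plants get summaries but no
#' test.
#'
#' @param plant_means data.frame from [plant_trait_means()].
#' @param reference reference genotype code (e.g. `"AABBDD"`).
#' @return data.frame, one row per genotype x trait: `genotype`, `n`,
#'   `trait`, `mean`, `se`, `pct_change`, `p_value`, `stars`.
#' @export
group_summary <- function(plant_means, reference = "AABBDD") {
  if (!reference %in% plant_means$genotype)
    stop("reference genotype absent from the data")
  traits <- c("width", "length", "area", "tgw")
  groups <- unique(plant_means$genotype)
  rows <- list()
  for (g in groups) {
    sub <- plant_means[plant_means$genotype == g, , drop = FALSE]
    ref <- plant_means[plant_means$genotype == reference, , drop = FALSE]
    for (t in traits) {
      m <- mean(sub[[t]]); n <- nrow(sub)
      se <- if (n > 1) stats::sd(sub[[t]]) / sqrt(n) else NA_real_
      pc <- pct_change(m, mean(ref[[t]]))
      p <- NA_real_
      if (g != reference && n >= 2 && nrow(ref) >= 2)
        p <- students_t_test(sub[[t]], ref[[t]])$p
      if (g == reference) pc <- 0
      rows[[length(rows) + 1]] <- data.frame(
        genotype = g, n = n, trait = t, mean = m, se = se,
        pct_change = pc, p_value = p, stars = stars_for_p(p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param values numeric response vector.
#' @param groups factor or character group labels (>= 2 groups, each with
#'   >= 2 observations).
#' @return list with `F`, `p` and `tukey` (data.frame: comparison, diff,
#'   lwr, upr, p_adj). When all observations are identical, `F` and `p` are
#'   NA.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  if (stats::var(values) == 0)
    return(list(F = NA_real_, p = NA_real_, tukey = NULL))
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Trait summaries by functional gene-copy count
#'
#' Groups plants by the number of non-mutated copies of the focal gene
#' (0-6), summarizes each trait per group, and reports the direction of the
#' dosage trend as the sign of the Spearman correlation between the group
#' means and the copy count.
#'
#' @param plant_means data.frame from [plant_trait_means()].
#' @param functional_copies integer vector aligned with `plant_means` rows.
#' @return list with `summary` (data.frame: copies, n, trait, mean, se) and
#'   `trend` (data.frame: trait, spearman_rho, direction).
#' @export
dosage_trend <- function(plant_means, functional_copies) {
  stopifnot(length(functional_copies) == nrow(plant_means))
  traits <- c("width", "length", "area", "tgw")
  keep <- !is.na(functional_copies)
  pm <- plant_means[keep, , drop = FALSE]
  fc <- functional_copies[keep]
  rows <- list(); trend <- list()
  for (t in traits) {
    agg_mean <- tapply(pm[[t]], fc, mean)
    agg_n <- tapply(pm[[t]], fc, length)
    agg_se <- tapply(pm[[t]], fc, stats::sd) / sqrt(agg_n)
    copies <- as.integer(names(agg_mean))
    rows[[t]] <- data.frame(copies = copies, n = as.integer(agg_n),
                            trait = t, mean = as.numeric(agg_mean),
                            se = as.numeric(agg_se),
                            stringsAsFactors = FALSE)
    rho <- if (length(copies) > 1)
      suppressWarnings(stats::cor(copies, as.numeric(agg_mean),
                                  method = "spearman"))
    else NA_real_
    trend[[t]] <- data.frame(
      trait = t, spearman_rho = rho,
      direction = if (is.na(rho) || rho == 0) "flat"
                  else if (rho > 0) "increasing" else "decreasing",
      stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       trend = do.call(rbind, c(trend, list(make.row.names = FALSE))))
}

#' Relative expression from qPCR Ct values (2^-ddCt)
#'
#' `dCt = Ct_target - Ct_reference` per sample; with a calibrator pair the
#' result is `2^-(dCt_sample - dCt_calibrator)`; without one, `2^-dCt` is
#' returned and labeled accordingly.
#'
#' @param ct_target,ct_reference Ct values of the target and the reference
#'   (housekeeping, e.g. actin) gene in the sample.
#' @param ct_target_cal,ct_reference_cal optional calibrator-sample Ct pair.
#' @return list with `relative_expression` and `method` ("ddCt" or "dCt").
#' @export
qpcr_relative_expression <- function(ct_target, ct_reference,
                                     ct_target_cal = NULL,
                                     ct_reference_cal = NULL) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference))
  dct <- ct_target - ct_reference
  if (is.null(ct_target_cal) || is.null(ct_reference_cal))
    return(list(relative_expression = 2^(-dct), method = "dCt"))
  stopifnot(is.finite(ct_target_cal), is.finite(ct_reference_cal))
  ddct <- dct - (ct_target_cal - ct_reference_cal)
  list(relative_expression = 2^(-ddct), method = "ddCt")
}
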