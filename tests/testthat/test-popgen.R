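test_that("per-site diversity uses the unbiased pairwise form", {
  expect_equal(site_pi(1, 2), 1)              # one ref, one alt copy
  expect_equal(site_pi(0, 10), 0)             # monomorphic
  expect_equal(site_pi(1, 4), 0.5)            # 3 differing pairs / 6 pairs
  expect_error(site_pi(3, 2))
})

test_that("Hudson F_ST matches closed forms and label-swap invariance", {
  expect_equal(hudson_fst(1, Inf, 0, Inf)$fst, 1)   # fixed different alleles
  expect_equal(hudson_fst(0.5, 1e6, 0.5, 1e6)$fst, 0, tolerance = 1e-5)
  expect_equal(hudson_fst(0.8, Inf, 0.2, Inf)$fst, (0.68 - 0.32) / 0.68)
  expect_true(is.na(hudson_fst(0, 10, 0, 10)$fst))  # both fixed, same allele
  # allele-label swap: p -> 1 - p leaves pi and F_ST unchanged
  set.seed(13)
  for (i in 1:20) {
    p1 <- runif(1); p2 <- runif(1); n1 <- sample(4:40, 1); n2 <- sample(4:40, 1)
    a <- hudson_fst(p1, n1, p2, n2)
    b <- hudson_fst(1 - p1, n1, 1 - p2, n2)
    expect_equal(a$fst, b$fst, tolerance = 1e-12)
    expect_equal(site_pi(round(p1 * n1), n1),
                 site_pi(n1 - round(p1 * n1), n1), tolerance = 1e-12)
  }
})

test_that("window statistics equal a per-site oracle recomputation", {
  set.seed(14)
  for (rep in 1:20) {
    n_acc <- 20; n_snp <- 60
    geno <- matrix(sample(c(0, 2, NA), n_acc * n_snp, replace = TRUE,
                          prob = c(0.5, 0.45, 0.05)), n_acc, n_snp)
    positions <- sort(sample.int(1e6, n_snp))
    pops <- rep(c("dom", "wild"), each = 10)
    ws <- window_scan(geno, positions, pops, window = 250000, step = 250000,
                      chrom_length = 1e6)
    w <- ws[2, ]  # second window
    cols <- which(positions >= w$start & positions <= w$end)
    hw_sum <- 0; hb_sum <- 0; pis <- c(dom = 0, wild = 0); cnt <- 0
    for (j in cols) {
      g1 <- geno[pops == "dom", j]; g2 <- geno[pops == "wild", j]
      n1 <- 2 * sum(!is.na(g1)); n2 <- 2 * sum(!is.na(g2))
      if (n1 < 2 || n2 < 2) next
      cnt <- cnt + 1
      p1 <- sum(g1, na.rm = TRUE) / n1; p2 <- sum(g2, na.rm = TRUE) / n2
      pi1 <- 2 * p1 * (1 - p1) * n1 / (n1 - 1)
      pi2 <- 2 * p2 * (1 - p2) * n2 / (n2 - 1)
      pis <- pis + c(pi1, pi2)
      hw_sum <- hw_sum + (pi1 + pi2) / 2
      hb_sum <- hb_sum + p1 * (1 - p2) + p2 * (1 - p1)
    }
    if (cnt == 0) next
    expect_equal(w$n_snps, cnt)
    expect_equal(w$pi_dom, pis[["dom"]] / cnt, tolerance = 1e-12)
    expect_equal(w$pi_wild, pis[["wild"]] / cnt, tolerance = 1e-12)
    expect_equal(w$fst, 1 - hw_sum / hb_sum, tolerance = 1e-12)
  }
})

test_that("null simulation shows flat F_ST; planted sweep is recovered", {
  cfg0 <- sim_config(seed = 15, sweep_strength = 0, n_snps = 2000,
                     missing_rate = 0)
  pg0 <- sim_popgen(cfg0)
  ws0 <- window_scan(pg0$geno, pg0$positions, pg0$pops$population,
                     chrom_length = cfg0$chrom_length)
  inside0 <- ws0$start >= cfg0$sweep_span[1] & ws0$end <= cfg0$sweep_span[2]
  # pi ratio ~ 1 and F_ST not elevated inside the (absent) sweep
  expect_equal(mean(ws0$pi_domesticated[inside0], na.rm = TRUE) /
                 mean(ws0$pi_domesticated[!inside0], na.rm = TRUE),
               1, tolerance = 0.15)
  expect_lt(mean(ws0$fst, na.rm = TRUE), 0.05)

  cfg1 <- sim_config(seed = 15, n_snps = 2000)
  pg1 <- sim_popgen(cfg1)
  ws1 <- window_scan(pg1$geno, pg1$positions, pg1$pops$population,
                     chrom_length = cfg1$chrom_length)
  top <- ws1[which.max(ws1$fst), ]
  expect_true(top$start <= cfg1$sweep_span[2] &&
              top$end >= cfg1$sweep_span[1])
  inside1 <- ws1$start >= cfg1$sweep_span[1] & ws1$end <= cfg1$sweep_span[2]
  expect_lt(mean(ws1$pi_domesticated[inside1], na.rm = TRUE),
            0.5 * mean(ws1$pi_domesticated[!inside1], na.rm = TRUE))
})

test_that("haplotype tables recover programmed frequencies and exclusions", {
  # two identical genotype vectors collapse into one haplotype
  geno <- rbind(c(0, 2, 0), c(0, 2, 0), c(2, 0, 2), c(0, NA, 0), c(0, 1, 0))
  pos <- c(10, 20, 30)
  pops <- rep("wild", 5)
  ht <- extract_haplotypes(geno, pos, pops, c(1, 40))
  expect_equal(sum(ht$count), 3)    # missing and heterozygous rows excluded
  expect_equal(ht$count[ht$haplotype == "H1"], 2)
  expect_equal(sum(ht$frequency), 1, tolerance = 1e-9)

  # programmed haplotypes recovered exactly at zero missing rate
  cfg <- sim_config(seed = 16, missing_rate = 0)
  pg <- sim_popgen(cfg)
  ht <- extract_haplotypes(pg$geno, pg$positions, pg$pops$population,
                           pg$gene_region)
  truth_tab <- table(pg$pops$population, pg$truth$hap_id)
  for (pn in rownames(truth_tab)) {
    sub <- ht[ht$population == pn, ]
    expect_equal(sum(sub$count), sum(truth_tab[pn, ]))
    expect_equal(sort(sub$count, decreasing = TRUE),
                 sort(as.integer(truth_tab[pn, truth_tab[pn, ] > 0]),
                      decreasing = TRUE))
    expect_equal(sum(sub$frequency), 1, tolerance = 1e-9)
  }
})

test_that("between-population haplotype Fisher tests behave as expected", {
  ht <- data.frame(haplotype = c("H1", "H2", "H1", "H2"),
                   population = c("wild", "wild", "dom", "dom"),
                   count = c(6, 25, 28, 0))
  r <- compare_haplotype_freqs(ht, "H1", "wild", "dom")
  expect_lt(r$p, 1e-4)
  expect_equal(unname(r$table["wild", ]), c(6, 25))
  # equal balanced counts: p = 1
  ht2 <- data.frame(haplotype = rep(c("H1", "H2"), 2),
                    population = rep(c("a", "b"), each = 2),
                    count = c(5, 5, 5, 5))
  expect_equal(compare_haplotype_freqs(ht2, "H1", "a", "b")$p, 1)
  # haplotype absent from both populations
  expect_equal(compare_haplotype_freqs(ht2, "H9", "a", "b")$p, 1)
})

test_that("VCF round-trips through the writer and reader unchanged", {
  cfg <- sim_config(seed = 17, n_snps = 300)
  pg <- sim_popgen(cfg)
  path <- tempfile(fileext = ".vcf")
  write_vcf(pg$geno, pg$positions, pg$chrom, path)
  back <- read_vcf_matrix(path)
  expect_equal(unname(back$geno), unname(pg$geno))
  expect_equal(back$positions, pg$positions)
  expect_equal(back$chrom, pg$chrom)
  expect_equal(rownames(back$geno), pg$pops$accession)
})
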