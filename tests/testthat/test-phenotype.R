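test_that("plant means average spikes; missing values drop the plant trait", {
  rec <- data.frame(plant_id = c("p1", "p1", "p1", "p2"),
                    genotype = "AABBDD", spike = c(1, 2, 3, 1),
                    width = c(3.6, 3.7, 3.8, 3.5),
                    length = c(6.1, 6.2, 6.3, 6.0),
                    area = c(16, 16, 16, 15),
                    tgw = c(40, NA, 42, 39))
  pm <- plant_trait_means(rec)
  expect_equal(pm$width[pm$plant_id == "p1"], 3.7)
  expect_equal(pm$width[pm$plant_id == "p2"], 3.5)      # single spike
  expect_equal(pm$tgw[pm$plant_id == "p1"], 41)         # NA spike excluded
})

test_that("pooled t-test matches the closed form and is calibrated under the null", {
  r <- students_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.2878641, tolerance = 1e-6)
  same <- students_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  flat <- students_t_test(c(2, 2), c(2, 2))
  expect_equal(flat$p, 1)
  deg <- students_t_test(c(2, 2), c(3, 3))
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  # null calibration: rejection rate ~ alpha
  set.seed(100)
  rej <- mean(replicate(1000, students_t_test(rnorm(10), rnorm(10))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("one-way ANOVA equals the brute-force sums-of-squares oracle", {
  set.seed(7)
  g <- rep(letters[1:4], times = c(5, 6, 7, 8))
  y <- rnorm(length(g), mean = rep(c(0, 0.5, 1, 0.2), times = c(5, 6, 7, 8)))
  res <- anova_tukey(y, g)
  # independent oracle: explicit between/within sums of squares
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((y - means[g])^2)
  f_oracle <- (ss_b / 3) / (ss_w / (length(y) - 4))
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  # two groups: F = t^2
  r2 <- anova_tukey(y[g %in% c("a", "b")], g[g %in% c("a", "b")])
  t2 <- students_t_test(y[g == "a"], y[g == "b"])$t^2
  expect_equal(r2$F, t2, tolerance = 1e-10)
  # identical observations: F undefined
  expect_true(is.na(anova_tukey(rep(1, 6), rep(c("a", "b"), 3))$F))
})

test_that("group summaries reproduce percent change and star conventions", {
  set.seed(8)
  pm <- data.frame(plant_id = sprintf("p%02d", 1:20),
                   genotype = rep(c("AABBDD", "AAbbDD"), each = 10),
                   width = c(rnorm(10, 3.62, 0.02), rnorm(10, 3.70, 0.02)),
                   length = rnorm(20, 6.2, 0.05),
                   area = rnorm(20, 16, 0.3),
                   tgw = rnorm(20, 41, 1))
  gs <- group_summary(pm, reference = "AABBDD")
  ref_w <- gs[gs$genotype == "AABBDD" & gs$trait == "width", ]
  mut_w <- gs[gs$genotype == "AAbbDD" & gs$trait == "width", ]
  expect_equal(ref_w$pct_change, 0)
  expect_equal(mut_w$pct_change,
               round(100 * (mut_w$mean - ref_w$mean) / ref_w$mean, 2))
  expect_equal(mut_w$se,
               sd(pm$width[pm$genotype == "AAbbDD"]) / sqrt(10))
  expect_equal(mut_w$p_value,
               students_t_test(pm$width[pm$genotype == "AAbbDD"],
                               pm$width[pm$genotype == "AABBDD"])$p)
  expect_error(group_summary(pm, reference = "XXYYZZ"), "reference")
  expect_equal(c(triadkit:::stars_for_p(0.03),
                 triadkit:::stars_for_p(0.00005),
                 triadkit:::stars_for_p(0.2)),
               c("*", "****", ""))
})

test_that("dosage grouping reports the programmed trend directions", {
  cfg <- sim_config(seed = 42, n_plants = 200)
  sim <- sim_phenotypes(cfg)
  pm <- plant_trait_means(sim$phenotypes)
  fc <- vapply(strsplit(pm$genotype, ""), function(ch)
    sum(ch %in% LETTERS), 0L)
  dt <- dosage_trend(pm, fc)
  # width and TGW rise with mutation dosage, i.e. fall with functional copies
  expect_equal(dt$trend$direction[dt$trend$trait == "width"], "decreasing")
  expect_equal(dt$trend$direction[dt$trend$trait == "tgw"], "decreasing")
  expect_equal(dt$trend$direction[dt$trend$trait == "length"], "increasing")
  # single genotype: one group, no trend
  one <- dosage_trend(pm[pm$genotype == "AAbbdd", , drop = FALSE],
                      rep(2L, sum(pm$genotype == "AAbbdd")))
  expect_equal(unique(one$summary$copies), 2L)
  expect_true(all(one$trend$direction == "flat"))
})

test_that("qPCR relative expression follows 2^-ddCt", {
  r <- qpcr_relative_expression(25, 20, 26, 20)
  expect_equal(r$relative_expression, 2)
  expect_equal(r$method, "ddCt")
  expect_equal(qpcr_relative_expression(25, 20, 25, 20)$relative_expression, 1)
  r3 <- qpcr_relative_expression(23, 20)
  expect_equal(r3$relative_expression, 2^-3)
  expect_equal(r3$method, "dCt")
})

test_that("noise-free single plants reproduce programmed effects exactly", {
  cfg <- sim_config(seed = 1, noise_sd = c(0, 0, 0, 0),
                    spike_sd = c(0, 0, 0, 0), n_spikes = 1)
  plants <- data.frame(plant_id = c("ref", "mutB"),
                       code = c("AABBDD", "AAbbDD"),
                       stringsAsFactors = FALSE)
  sim <- sim_phenotypes(cfg, plants)
  pm <- plant_trait_means(sim$phenotypes)
  w <- pm$width
  expect_equal(100 * (w[pm$plant_id == "mutB"] / w[pm$plant_id == "ref"] - 1),
               cfg$effect_sizes$B[["width"]], tolerance = 1e-9)
  tg <- pm$tgw
  expect_equal(100 * (tg[pm$plant_id == "mutB"] / tg[pm$plant_id == "ref"] - 1),
               cfg$effect_sizes$B[["tgw"]], tolerance = 1e-9)
})
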