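test_that("K2P distance matches closed forms and handles gaps/saturation", {
  s <- strrep("ACGT", 25)
  expect_equal(k2p_distance(s, s), 0)
  # 10% transitions (A->G), no transversions: -1/2 ln(0.8)
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(s1, s2), -0.5 * log(0.8), tolerance = 1e-9)
  # 10% transversions (A->C): -1/2 ln(0.9) - 1/4 ln(0.8)
  s3 <- paste0(strrep("C", 10), strrep("A", 90))
  expect_equal(k2p_distance(s1, s3), -0.5 * log(0.9) - 0.25 * log(0.8),
               tolerance = 1e-9)
  # gap columns removed pairwise before counting
  g1 <- paste0("--", strrep("A", 98))
  expect_equal(k2p_distance(g1, s1), 0)
  # saturation: log argument <= 0 is undefined
  expect_true(is.na(k2p_distance(strrep("A", 10), strrep("G", 10))))
  # monotone in P and in Q within the domain
  d_at <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  Ps <- seq(0, 0.3, by = 0.05)
  expect_true(all(diff(vapply(Ps, d_at, 0, Q = 0.1)) > 0))
  expect_true(all(diff(vapply(Ps, d_at, 0, P = 0.05)) > 0))
})

test_that("K2P matrix agrees with the reference implementation in ape", {
  set.seed(21)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("a", "c", "g", "t"), 300, replace = TRUE), collapse = ""),
    "")
  names(seqs) <- paste0("t", 1:5)
  ours <- k2p_matrix(toupper(seqs))
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(seqs, "")))
  rownames(bin) <- names(seqs)
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(ours), unname(ref[names(seqs), names(seqs)]),
               tolerance = 1e-9)
})

test_that("neighbor joining recovers additive trees, 3-taxon closed form", {
  # 3 taxa: branch lengths from the three-point formulas
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)
  # additive 4-taxon matrix: true quartet recovered
  # tree ((a:1,b:2):1,(c:1.5,d:0.5)) in distance form
  d4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 3
  d4["a", "c"] <- d4["c", "a"] <- 3.5
  d4["a", "d"] <- d4["d", "a"] <- 2.5
  d4["b", "c"] <- d4["c", "b"] <- 4.5
  d4["b", "d"] <- d4["d", "b"] <- 3.5
  d4["c", "d"] <- d4["d", "c"] <- 2
  tr4 <- nj_tree(d4)
  # the only internal split must separate {a,b} from {c,d}
  parts <- ape::prop.part(tr4)
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  expect_true(any(vapply(splits, function(s)
    identical(s, c("a", "b")) || identical(s, c("c", "d")), TRUE)))
  # ultrametric two-cherry matrix: cherries preserved
  du <- matrix(4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(du) <- 0
  du["a", "b"] <- du["b", "a"] <- 1
  du["c", "d"] <- du["d", "c"] <- 1
  tru <- nj_tree(du)
  pairs <- ape::prop.part(tru)
  labs <- attr(pairs, "labels")
  cherries <- lapply(pairs, function(p) sort(labs[p]))
  expect_true(any(vapply(cherries, identical, TRUE, c("a", "b"))) ||
              any(vapply(cherries, identical, TRUE, c("c", "d"))))
  expect_error(nj_tree(matrix(0, 2, 2)))
  # negative branch lengths are clamped with length moved to the sister
  set.seed(22)
  dd <- as.matrix(dist(matrix(rnorm(12), 6)))
  expect_true(all(nj_tree(dd)$edge.length >= 0))
})

test_that("NJ recovers the generating topology for random additive trees", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are reproducible percentages in [0, 100]", {
  set.seed(24)
  block <- function(base, k) paste(sample(c("A", "C", "G", "T"), k,
                                          replace = TRUE), collapse = "")
  core1 <- block(1, 300)
  mut <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(runif(length(ch)) < rate)
    ch[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
    paste(ch, collapse = "")
  }
  core2 <- mut(core1, 0.3)   # diverged but far from K2P saturation
  seqs <- c(a = mut(core1, 0.02), b = mut(core1, 0.02),
            c = mut(core2, 0.02), d = mut(core2, 0.02))
  bs <- bootstrap_support(seqs, n_reps = 200, seed = 7)
  sup <- bs$support[!is.na(bs$support)]
  expect_true(all(sup >= 0 & sup <= 100))
  # two clearly separated clades: saturated support
  expect_gte(max(sup), 95)
  # fixed seed: identical supports across runs
  bs2 <- bootstrap_support(seqs, n_reps = 200, seed = 7)
  expect_identical(bs$support, bs2$support)
  # zero replicates: tree only
  bs0 <- bootstrap_support(seqs, n_reps = 0)
  expect_null(bs0$support)
  expect_s3_class(bs0$tree, "phylo")
})

test_that("amino-acid difference counts exclude gap columns", {
  expect_equal(count_aa_differences("ACDEF", "ACDEF"),
               list(count = 0L, compared = 5L, percent = 0))
  r <- count_aa_differences("ACD", "ACE")
  expect_equal(r$count, 1L)
  expect_equal(r$percent, 33.3)
  g <- count_aa_differences("AC-EF", "ACDEG")
  expect_equal(g$compared, 4L)
  expect_equal(g$count, 1L)
  # 32 differences over 950 compared columns -> 3.4%
  a <- paste(rep("A", 950), collapse = "")
  b <- paste(c(rep("V", 32), rep("A", 918)), collapse = "")
  r2 <- count_aa_differences(a, b)
  expect_equal(r2$count, 32L)
  expect_equal(r2$percent, 3.4)
  expect_error(count_aa_differences("-", "A"), "comparable")
})
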