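# Hand-built three-homoeolog amplicon set with known diagnostics and cut
# site, used where randomized references would obscure the expected call.
make_toy_refs <- function() {
  # 60 bp non-repetitive core (a periodic sequence would make indel
  # placement ambiguous); diagnostics at offsets 5 and 12; cut at offset 36
  set.seed(4242)
  base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  put <- function(s, pos0, ch) {
    substr(s, pos0 + 1, pos0 + 1) <- ch
    s
  }
  mk <- function(genome, b1, b2) {
    s <- put(put(base, 5, b1), 12, b2)
    homoeolog_ref(genome, s, cut_site = 36,
                  pam_span = c(39, 42),
                  diagnostics = data.frame(pos = c(5, 12),
                                           base = c(b1, b2),
                                           stringsAsFactors = FALSE))
  }
  list(A = mk("A", "A", "A"), B = mk("B", "C", "C"), D = mk("D", "G", "G"))
}

# delete `len` bases starting at 0-based offset `at` (default: the cut site)
delete_at <- function(seq, at, len) {
  paste0(substring(seq, 1, at), substring(seq, at + len + 1, nchar(seq)))
}

insert_at <- function(seq, at, ins) {
  paste0(substring(seq, 1, at), ins, substring(seq, at + 1, nchar(seq)))
}

# enumeration oracle for the two-tailed Fisher exact test: table
# probabilities from binomial coefficients, probability-mass rule
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; m1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || m1 == 0 || m1 == n) return(1)
  as <- max(0, m1 - r2):min(r1, m1)
  probs <- choose(r1, as) * choose(r2, m1 - as) / choose(n, m1)
  p_obs <- choose(r1, a) * choose(r2, m1 - a) / choose(n, m1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# sample standard error of a percent change between two group means
pct_change_se <- function(x_group, x_ref) {
  mg <- mean(x_group); mr <- mean(x_ref)
  se_g <- stats::sd(x_group) / sqrt(length(x_group))
  se_r <- stats::sd(x_ref) / sqrt(length(x_ref))
  100 * sqrt(se_g^2 / mr^2 + mg^2 * se_r^2 / mr^4)
}
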