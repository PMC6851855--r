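#' Simulate a set of three homoeolog amplicon references
#'
#' Draws a random amplicon sequence and derives the A, B, D copies by placing
#' distinct diagnostic bases at shared positions in the primer-proximal part
#' of the amplicon, upstream of the cut site so that target-site indels do
#' not shift them. The PAM is placed immediately 3' of the protospacer, with
#' the cut site 3 nt upstream of the PAM.
#'
#' @param length amplicon length in bp.
#' @param n_diagnostics number of diagnostic positions.
#' @param cut_site 0-based cut offset (default 60% into the amplicon).
#' @param seed integer seed.
#' @return list of three [homoeolog_ref()] objects named A, B, D.
#' @export
sim_homoeolog_refs <- function(length = 240L, n_diagnostics = 4L,
                               cut_site = as.integer(length * 0.6),
                               seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  core <- sample(bases, length, replace = TRUE)
  # diagnostics confined to [5, cut_site - 30): untouched by target indels
  hi <- cut_site - 30L
  if (hi - 5L < n_diagnostics) stop("amplicon too short for diagnostics")
  dpos <- sort(sample(5:(hi - 1L), n_diagnostics))
  refs <- list()
  for (k in 1:3) {
    g <- c("A", "B", "D")[k]
    s <- core
    for (j in seq_along(dpos)) {
      # three distinct bases per diagnostic column, one per genome
      trio <- bases[(((dpos[j] + j) %% 4) + c(0, 1, 2)) %% 4 + 1]
      s[dpos[j] + 1] <- trio[k]
    }
    seqc <- paste(s, collapse = "")
    refs[[g]] <- homoeolog_ref(
      genome = g, seq = seqc, cut_site = cut_site,
      pam_span = c(cut_site + 3L, cut_site + 6L),
      diagnostics = data.frame(
        pos = dpos,
        base = substring(seqc, dpos + 1, dpos + 1),
        stringsAsFactors = FALSE))
  }
  refs
}

apply_allele <- function(ref_seq, cut_site, net_indel, inserted_seq) {
  n <- nchar(ref_seq)
  if (net_indel < 0) {
    len <- -net_indel
    if (cut_site + len > n)
      stop("programmed deletion exceeds amplicon bounds")
    paste0(substring(ref_seq, 1, cut_site),
           substring(ref_seq, cut_site + len + 1, n))
  } else if (net_indel > 0) {
    ins <- inserted_seq
    if (nchar(ins) != net_indel)
      stop("inserted_seq length must equal net_indel for insertions")
    paste0(substring(ref_seq, 1, cut_site), ins,
           substring(ref_seq, cut_site + 1, n))
  } else ref_seq
}

add_substitution_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(stats::runif(n) < error_rate)
    if (!length(hits)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in hits) ch[i] <- sample(setdiff(bases, ch[i]), 1)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate amplicon reads carrying programmed edit alleles
#'
#' For each homoeolog, draws `cfg$n_reads` reads from the programmed allele
#' mix (`cfg$alleles`): wild type, deletions (`net_indel < 0`, removing bases
#' 3' of the cut) or insertions at the cut site. Independent substitution
#' errors are added at `cfg$error_rate`. The truth table records each read's
#' homoeolog and allele.
#'
#' @param cfg a [sim_config()].
#' @param refs list of three [homoeolog_ref()] (e.g. from
#'   [sim_homoeolog_refs()]).
#' @return list with `reads` (data.frame: read_id, sequence) and `truth`
#'   (data.frame: read_id, genome, net_indel, inserted_seq).
#' @export
sim_amplicon_reads <- function(cfg, refs) {
  stopifnot(inherits(cfg, "sim_config"))
  refs <- check_ref_set(refs)
  set.seed(cfg$seed)
  reads <- list(); truth <- list()
  for (g in c("A", "B", "D")) {
    ref <- refs[[match(g, vapply(refs, `[[`, "", "genome"))]]
    al <- cfg$alleles[[g]]
    # validate programmed deletions against amplicon bounds up front
    for (k in seq_len(nrow(al)))
      apply_allele(ref$seq, ref$cut_site, al$net_indel[k], al$inserted_seq[k])
    idx <- sample.int(nrow(al), cfg$n_reads, replace = TRUE, prob = al$freq)
    seqs <- vapply(idx, function(k)
      apply_allele(ref$seq, ref$cut_site, al$net_indel[k],
                   al$inserted_seq[k]), "")
    seqs <- add_substitution_errors(seqs, cfg$error_rate)
    ids <- sprintf("%s_read_%04d", g, seq_len(cfg$n_reads))
    reads[[g]] <- data.frame(read_id = ids, sequence = seqs,
                             stringsAsFactors = FALSE)
    truth[[g]] <- data.frame(read_id = ids, genome = g,
                             net_indel = al$net_indel[idx],
                             inserted_seq = al$inserted_seq[idx],
                             stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, c(reads, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate per-plant per-spike grain phenotypes under an additive
#' dosage model
#'
#' Each trait is drawn as
#' `baseline * (1 + sum_g effect_g * mutant_alleles_g / 2) + plant noise +
#' spike noise`, with the grain-area effect taken as the sum of the width and
#' length effects. Effects are the per-genome homozygous percentages in
#' `cfg$effect_sizes`. Negative draws are resampled.
#'
#' @param cfg a [sim_config()].
#' @param plants optional data.frame with columns `plant_id` and `code`
#'   (six-letter genotype codes); by default `cfg$n_plants` plants are drawn
#'   uniformly from the nine zygosity combinations of the B and D copies.
#' @return list with `phenotypes` (data.frame: plant_id, genotype, spike,
#'   width, length, area, tgw) and `truth` (per-plant expected trait means
#'   and mutant allele counts).
#' @export
sim_phenotypes <- function(cfg, plants = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  if (is.null(plants)) {
    combos <- as.matrix(expand.grid(b = 0:2, d = 0:2))
    pick <- combos[sample.int(nrow(combos), cfg$n_plants, replace = TRUE), ,
                   drop = FALSE]
    code_b <- c("BB", "Bb", "bb")[pick[, "b"] + 1]
    code_d <- c("DD", "Dd", "dd")[pick[, "d"] + 1]
    plants <- data.frame(plant_id = sprintf("plant_%03d",
                                            seq_len(cfg$n_plants)),
                         code = paste0("AA", code_b, code_d),
                         stringsAsFactors = FALSE)
  }
  mut_alleles <- function(code, letter)
    vapply(strsplit(code, ""), function(ch) sum(ch == letter), 0L)
  mb <- mut_alleles(plants$code, "b")
  md <- mut_alleles(plants$code, "d")
  ma <- mut_alleles(plants$code, "a")
  eff <- cfg$effect_sizes
  eff4 <- function(e) c(e["width"], e["length"],
                        area = unname(e["width"] + e["length"]),
                        e["tgw"]) / 100
  ea <- eff4(eff$A); eb <- eff4(eff$B); ed <- eff4(eff$D)
  traits <- c("width", "length", "area", "tgw")
  n <- nrow(plants)
  expected <- matrix(0, n, 4, dimnames = list(NULL, traits))
  for (t in 1:4) {
    mult <- 1 + ea[t] * ma / 2 + eb[t] * mb / 2 + ed[t] * md / 2
    expected[, t] <- cfg$baselines[t] * mult
  }
  rpos <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x <= 0)
    while (length(bad)) {        # resample negative trait draws
      x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
      bad <- bad[x[bad] <= 0]
    }
    x
  }
  rows <- list()
  plant_level <- matrix(0, n, 4)
  for (t in 1:4)
    plant_level[, t] <- stats::rnorm(n, 0, cfg$noise_sd[t])
  for (s in seq_len(cfg$n_spikes)) {
    vals <- matrix(0, n, 4, dimnames = list(NULL, traits))
    for (t in 1:4)
      vals[, t] <- rpos(n, expected[, t] + plant_level[, t], cfg$spike_sd[t])
    rows[[s]] <- data.frame(plant_id = plants$plant_id,
                            genotype = plants$code, spike = s,
                            vals, stringsAsFactors = FALSE)
  }
  phen <- do.call(rbind, rows)
  phen <- phen[order(phen$plant_id, phen$spike), , drop = FALSE]
  rownames(phen) <- NULL
  truth <- data.frame(plant_id = plants$plant_id, genotype = plants$code,
                      mut_b = mb, mut_d = md, expected,
                      stringsAsFactors = FALSE)
  list(phenotypes = phen, truth = truth)
}

#' Simulate a TPM expression matrix with a planted co-expression module
#'
#' Module genes (the three focal homoeologs plus `cfg$module_size - 3`
#' partners) share a latent factor on log2 scale:
#' `log2 expression = base + loading * factor + noise`; background genes are
#' independent. TPM values are `2^x`, hence nonnegative.
#'
#' @param cfg a [sim_config()].
#' @param loading latent-factor loading for module genes; defaults to
#'   `cfg$module_loading`.
#' @return list with `tpm` (genes x samples matrix), `focal` (ids of the
#'   three focal homoeolog rows) and `truth` (data.frame: gene, in_module).
#' @export
sim_expression <- function(cfg, loading = cfg$module_loading) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  ng <- cfg$n_genes; ns <- cfg$n_samples; ms <- cfg$module_size
  genes <- sprintf("gene_%05d", seq_len(ng))
  focal <- c("focal_A", "focal_B", "focal_D")
  genes[1:3] <- focal
  latent <- stats::rnorm(ns)
  x <- matrix(stats::rnorm(ng * ns, mean = 4, sd = 1.5), ng, ns,
              dimnames = list(genes, sprintf("sample_%03d", seq_len(ns))))
  member <- seq_len(ms)
  x[member, ] <- 4 +
    loading * matrix(latent, ms, ns, byrow = TRUE) +
    matrix(stats::rnorm(ms * ns, 0, cfg$module_noise_sd), ms, ns)
  tpm <- 2^x
  list(tpm = tpm, focal = focal,
       truth = data.frame(gene = genes,
                          in_module = seq_len(ng) %in% member,
                          stringsAsFactors = FALSE))
}

#' Simulate a two-population SNP panel with a planted selective sweep and
#' focal-gene haplotypes
#'
#' Wild-population allele frequencies are Uniform(0.05, 0.95); domesticated
#' frequencies equal the wild ones outside `cfg$sweep_span` and are pushed
#' toward fixation of the wild major allele inside it with strength
#' `cfg$sweep_strength`. Accessions are inbred: genotypes are 0 or 2 copies
#' of the alternate allele, with missing calls at `cfg$missing_rate`. SNPs
#' inside `cfg$gene_region` carry `K = ncol(cfg$hap_freqs)` discrete
#' haplotypes drawn at the programmed per-population frequencies.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno` (accessions x SNPs matrix of 0/2/NA), `positions`
#'   (bp), `chrom`, `pops` (data.frame: accession, population), `gene_region`
#'   and `truth` (list: sweep_span, haplotype id per accession, haplotype
#'   genotype vectors).
#' @export
sim_popgen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  n_snps <- cfg$n_snps
  positions <- sort(sample.int(cfg$chrom_length, n_snps))
  genic <- positions >= cfg$gene_region[1] & positions <= cfg$gene_region[2]
  # ensure the focal gene carries enough SNPs to encode the haplotypes
  need <- cfg$n_hap_snps - sum(genic)
  if (need > 0) {
    pool <- setdiff(seq(cfg$gene_region[1], cfg$gene_region[2]), positions)
    extra <- sort(sample(pool, need))
    positions <- sort(c(positions, extra))
    n_snps <- length(positions)
    genic <- positions >= cfg$gene_region[1] & positions <= cfg$gene_region[2]
  }
  in_sweep <- positions >= cfg$sweep_span[1] & positions <= cfg$sweep_span[2]
  p_wild <- stats::runif(n_snps, 0.05, 0.95)
  p_dom <- p_wild
  major <- round(p_wild)                     # 1 if alt is the major allele
  target <- ifelse(major == 1, 1, 0)
  s <- cfg$sweep_strength
  p_dom[in_sweep] <- p_wild[in_sweep] +
    s * (target[in_sweep] - p_wild[in_sweep])
  pops <- data.frame(
    accession = sprintf("acc_%03d", seq_len(sum(cfg$n_accessions))),
    population = rep(names(cfg$n_accessions), cfg$n_accessions),
    stringsAsFactors = FALSE)
  n_acc <- nrow(pops)
  geno <- matrix(NA_real_, n_acc, n_snps,
                 dimnames = list(pops$accession, NULL))
  for (pn in names(cfg$n_accessions)) {
    rows <- which(pops$population == pn)
    p <- if (pn == names(cfg$n_accessions)[1]) p_wild else p_dom
    # inbred accessions: homozygous at every site
    draws <- matrix(stats::rbinom(length(rows) * n_snps, 1,
                                  rep(p, each = length(rows))) * 2,
                    length(rows), n_snps)
    geno[rows, ] <- draws
  }
  # overwrite the genic SNPs with discrete haplotypes
  K <- ncol(cfg$hap_freqs)
  hap_cols <- which(genic)[seq_len(cfg$n_hap_snps)]
  hap_vectors <- matrix(stats::rbinom(K * length(hap_cols), 1, 0.5) * 2,
                        K, length(hap_cols))
  while (anyDuplicated(apply(hap_vectors, 1, paste, collapse = ""))) {
    hap_vectors <- matrix(stats::rbinom(K * length(hap_cols), 1, 0.5) * 2,
                          K, length(hap_cols))
  }
  hap_id <- integer(n_acc)
  for (pn in names(cfg$n_accessions)) {
    rows <- which(pops$population == pn)
    hap_id[rows] <- sample.int(K, length(rows), replace = TRUE,
                               prob = cfg$hap_freqs[pn, ])
  }
  geno[, hap_cols] <- hap_vectors[hap_id, ]
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n_acc * n_snps) < cfg$missing_rate,
                   n_acc, n_snps)
    geno[miss] <- NA_real_
  }
  list(geno = geno, positions = positions, chrom = "chr2A", pops = pops,
       gene_region = cfg$gene_region,
       truth = list(sweep_span = cfg$sweep_span, hap_id = hap_id,
                    hap_cols = hap_cols, hap_vectors = hap_vectors))
}
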