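#' Simulation configuration for the synthetic-data generators
#'
#' Collects every tunable of the synthetic generators in one validated list.
#' Defaults reproduce the study conditions the pipeline was designed around:
#' a hexaploid wheat editing experiment with mutations segregating in the B
#' and D subgenome copies of a focal grain-shape gene, a 209-sample TPM
#' expression compendium with one planted co-expression module around the
#' focal triad, and an exome-capture SNP panel of wild and domesticated
#' tetraploid accessions with a single domestication sweep.
#'
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @param n_reads reads simulated per homoeolog per plant.
#' @param n_plants number of plants in the phenotype experiment.
#' @param n_genes,n_samples dimensions of the synthetic expression matrix.
#' @param n_accessions named integer vector, accessions per population.
#' @param effect_sizes named list (A, B, D) of per-genome homozygous-mutant
#'   trait effects in percent, each `c(width, length, tgw)`. Defaults are the
#'   single-genome effect magnitudes observed for the B and D copies of the
#'   focal gene (width up, length down for D, TGW up).
#' @param baselines wild-type trait means `c(width, length, area, tgw)` in
#'   mm, mm, mm^2 and g.
#' @param noise_sd per-trait between-plant standard deviations on the same
#'   scale as `baselines`; the per-spike SD defaults to the same values.
#' @param spike_sd per-trait within-plant (between-spike) SDs.
#' @param n_spikes spikes measured per plant.
#' @param alleles named list (A, B, D); each element a data.frame with
#'   columns `net_indel`, `inserted_seq`, `freq` giving the programmed read
#'   allele mix for that homoeolog (net_indel 0 = wild type).
#' @param error_rate per-base substitution sequencing error rate.
#' @param module_size number of genes in the planted co-expression module
#'   (the three focal homoeologs included).
#' @param module_loading,module_noise_sd latent-factor loading and residual
#'   SD of module genes on log2 scale.
#' @param chrom_length simulated chromosome length in bp.
#' @param n_snps number of SNPs on the simulated chromosome.
#' @param sweep_span `c(start, end)` bp interval of the planted sweep.
#' @param sweep_strength in `[0, 1]`; 0 leaves domesticated frequencies equal
#'   to wild, 1 fixes the wild major allele inside the sweep.
#' @param gene_region `c(start, end)` bp interval of the focal gene used for
#'   haplotype simulation; must lie inside `sweep_span`'s chromosome.
#' @param n_hap_snps number of genic SNPs defining the haplotypes.
#' @param hap_freqs matrix (populations x haplotypes) of programmed
#'   haplotype frequencies; rows must sum to 1.
#' @param missing_rate per-genotype missing-call rate in the VCF.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_reads = 200L,
                       n_plants = 116L,
                       n_genes = 10000L,
                       n_samples = 209L,
                       n_accessions = c(wild = 34L, domesticated = 40L),
                       effect_sizes = list(
                         A = c(width = 0,    length = 0,     tgw = 0),
                         B = c(width = 1.91, length = 0.32,  tgw = 1.78),
                         D = c(width = 2.18, length = -2.07, tgw = 2.90)
                       ),
                       baselines = c(width = 3.67, length = 6.27,
                                     area = 16.67, tgw = 42.72),
                       noise_sd = c(width = 0.087, length = 0.168,
                                    area = 0.71, tgw = 2.45),
                       spike_sd = noise_sd,
                       n_spikes = 3L,
                       alleles = list(
                         A = data.frame(net_indel = 0L, inserted_seq = "",
                                        freq = 1, stringsAsFactors = FALSE),
                         B = data.frame(net_indel = c(0L, -10L),
                                        inserted_seq = c("", ""),
                                        freq = c(0.5, 0.5),
                                        stringsAsFactors = FALSE),
                         D = data.frame(net_indel = c(0L, -2L),
                                        inserted_seq = c("", ""),
                                        freq = c(0.5, 0.5),
                                        stringsAsFactors = FALSE)
                       ),
                       error_rate = 0.001,
                       module_size = 50L,
                       module_loading = 1.5,
                       module_noise_sd = 0.4,
                       chrom_length = 5e7,
                       n_snps = 4000L,
                       sweep_span = c(2.0e7, 2.4e7),
                       sweep_strength = 0.9,
                       gene_region = c(2.15e7, 2.16e7),
                       n_hap_snps = 10L,
                       hap_freqs = rbind(
                         wild         = c(6, 14, 11) / 31,
                         domesticated = c(1, 0, 0)
                       ),
                       missing_rate = 0.02) {
  cfg <- list(
    seed = as.integer(seed), n_reads = as.integer(n_reads),
    n_plants = as.integer(n_plants), n_genes = as.integer(n_genes),
    n_samples = as.integer(n_samples), n_accessions = n_accessions,
    effect_sizes = effect_sizes, baselines = baselines,
    noise_sd = noise_sd, spike_sd = spike_sd,
    n_spikes = as.integer(n_spikes), alleles = alleles,
    error_rate = error_rate, module_size = as.integer(module_size),
    module_loading = module_loading, module_noise_sd = module_noise_sd,
    chrom_length = chrom_length, n_snps = as.integer(n_snps),
    sweep_span = sweep_span, sweep_strength = sweep_strength,
    gene_region = gene_region, n_hap_snps = as.integer(n_hap_snps),
    hap_freqs = hap_freqs, missing_rate = missing_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_reads, cfg$n_plants, cfg$n_genes, cfg$n_samples,
              cfg$n_accessions, cfg$n_spikes, cfg$module_size,
              cfg$n_snps, cfg$n_hap_snps)
  if (any(counts <= 0)) stop("all counts in sim_config must be positive")
  fracs <- c(cfg$error_rate, cfg$missing_rate, cfg$sweep_strength)
  if (any(fracs < 0 | fracs > 1))
    stop("error_rate, missing_rate and sweep_strength must lie in [0, 1]")
  if (cfg$module_size >= cfg$n_genes)
    stop("module_size must be smaller than n_genes")
  if (cfg$sweep_span[1] >= cfg$sweep_span[2] ||
      cfg$sweep_span[2] > cfg$chrom_length)
    stop("sweep_span must be a nonempty interval inside the chromosome")
  if (cfg$gene_region[1] >= cfg$gene_region[2] ||
      cfg$gene_region[2] > cfg$chrom_length)
    stop("gene_region must be a nonempty interval inside the chromosome")
  for (g in names(cfg$alleles)) {
    a <- cfg$alleles[[g]]
    if (abs(sum(a$freq) - 1) > 1e-9)
      stop("programmed allele frequencies for genome ", g, " must sum to 1")
  }
  if (any(abs(rowSums(cfg$hap_freqs) - 1) > 1e-9))
    stop("hap_freqs rows must sum to 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration (seed ", x$seed, ")\n", sep = "")
  cat("  reads/homoeolog: ", x$n_reads, ", error rate ", x$error_rate, "\n",
      sep = "")
  cat("  plants: ", x$n_plants, " (", x$n_spikes, " spikes each)\n", sep = "")
  cat("  expression: ", x$n_genes, " genes x ", x$n_samples,
      " samples, module of ", x$module_size, "\n", sep = "")
  cat("  popgen: ", x$n_snps, " SNPs on ", x$chrom_length / 1e6,
      " Mb; sweep ", x$sweep_span[1] / 1e6, "-", x$sweep_span[2] / 1e6,
      " Mb, strength ", x$sweep_strength, "\n", sep = "")
  invisible(x)
}
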