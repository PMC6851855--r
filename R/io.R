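#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `read_id` and `sequence` (and
#'   optionally `quality`; constant Q40 is written when absent).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality
          else vapply(nchar(reads$sequence),
                      function(n) strrep("I", n), "")
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # the reader warns about dropped metadata columns it created itself
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(read_id = names(x), sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write homoeolog references to FASTA plus a targets table
#'
#' @param refs list of [homoeolog_ref()] objects.
#' @param fasta_path,targets_path output paths; the targets TSV holds
#'   genome, cut_site, PAM span and the diagnostic positions/bases.
#' @return invisibly, the two paths.
#' @export
write_refs <- function(refs, fasta_path, targets_path) {
  refs <- check_ref_set(refs)
  seqs <- Biostrings::DNAStringSet(vapply(refs, `[[`, "", "seq"))
  names(seqs) <- vapply(refs, `[[`, "", "genome")
  Biostrings::writeXStringSet(seqs, fasta_path)
  tg <- do.call(rbind, lapply(refs, function(r)
    data.frame(genome = r$genome, cut_site = r$cut_site,
               pam_start = r$pam_span[1], pam_end = r$pam_span[2],
               diagnostics = paste(r$diagnostics$pos, r$diagnostics$base,
                                   sep = ":", collapse = ","),
               stringsAsFactors = FALSE)))
  utils::write.table(tg, targets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, targets_path))
}

#' Write a biallelic SNP genotype matrix to VCF v4.2
#'
#' Inbred-style diploid genotypes: 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`,
#' NA -> `./.`.
#'
#' @param geno accessions x SNPs matrix of 0/1/2/NA (rownames = accession
#'   ids).
#' @param positions 1-based bp positions (one per SNP column).
#' @param chrom chromosome name.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(geno, positions, chrom, path) {
  stopifnot(ncol(geno) == length(positions))
  gt <- matrix("./.", nrow(geno), ncol(geno))
  gt[!is.na(geno) & geno == 0] <- "0/0"
  gt[!is.na(geno) & geno == 1] <- "0/1"
  gt[!is.na(geno) & geno == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", chrom, ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  body <- vapply(seq_along(positions), function(j)
    paste(c(chrom, positions[j], paste0("snp", j), "A", "G", ".", "PASS",
            ".", "GT", gt[, j]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF of biallelic SNPs into a dosage matrix
#'
#' @param path VCF file path.
#' @return list with `geno` (accessions x SNPs matrix of alternate-allele
#'   dosage 0/1/2, NA for missing), `positions` and `chrom`.
#' @export
read_vcf_matrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- t(vcfR::extract.gt(v, element = "GT"))   # accessions x variants
  geno <- matrix(NA_real_, nrow(gt), ncol(gt),
                 dimnames = list(rownames(gt), NULL))
  geno[which(gt %in% c("0/0", "0|0"))] <- 0
  geno[which(gt %in% c("0/1", "1/0", "0|1", "1|0"))] <- 1
  geno[which(gt %in% c("1/1", "1|1"))] <- 2
  list(geno = geno,
       positions = as.numeric(v@fix[, "POS"]),
       chrom = unique(v@fix[, "CHROM"]))
}

#' Write a table as TSV
#' @param x data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
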