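#' Homoeolog amplicon reference
#'
#' Describes one subgenome copy of the amplified target region: its sequence,
#' the Cas9 cut site (3 nt upstream of the PAM), the PAM location, and the
#' diagnostic positions whose bases distinguish this homoeolog from the other
#' two. Coordinates are 0-based half-open internally; `cut_site` is the
#' 0-based offset of the first base 3' of the blunt cut.
#'
#' @param genome one of "A", "B", "D".
#' @param seq amplicon DNA sequence (character).
#' @param cut_site 0-based cut offset, must lie inside the sequence.
#' @param pam_span integer `c(start, end)` 0-based half-open PAM interval.
#' @param diagnostics data.frame with columns `pos` (0-based offset) and
#'   `base` (expected base for this homoeolog).
#' @param cds_frame_offset reading-frame offset 0-2 at the amplicon start.
#' @return an object of class `homoeolog_ref`.
#' @export
homoeolog_ref <- function(genome, seq, cut_site, pam_span = NULL,
                          diagnostics, cds_frame_offset = 0L) {
  genome <- match.arg(genome, c("A", "B", "D"))
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (cut_site <= 0 || cut_site >= n)
    stop("cut_site must lie strictly inside the amplicon")
  if (!all(c("pos", "base") %in% names(diagnostics)))
    stop("diagnostics needs columns pos and base")
  if (any(diagnostics$pos < 0 | diagnostics$pos >= n))
    stop("diagnostic positions outside amplicon")
  ref_bases <- substring(seq, diagnostics$pos + 1, diagnostics$pos + 1)
  if (!all(ref_bases == toupper(diagnostics$base)))
    stop("diagnostic bases disagree with the amplicon sequence")
  structure(list(genome = genome, seq = seq, cut_site = as.integer(cut_site),
                 pam_span = pam_span, diagnostics = diagnostics,
                 cds_frame_offset = as.integer(cds_frame_offset)),
            class = "homoeolog_ref")
}

#' @export
print.homoeolog_ref <- function(x, ...) {
  cat("homoeolog_ref ", x$genome, ": ", nchar(x$seq), " bp, cut at ",
      x$cut_site, ", ", nrow(x$diagnostics), " diagnostic bases\n", sep = "")
  invisible(x)
}

check_ref_set <- function(refs) {
  if (length(refs) != 3 ||
      !setequal(vapply(refs, `[[`, "", "genome"), c("A", "B", "D")))
    stop("refs must be a list of three homoeolog_ref objects (A, B, D)")
  refs[order(vapply(refs, `[[`, "", "genome"))]
}

#' Assign reads to homoeologs by diagnostic bases
#'
#' Reads are primer-anchored, so the first bases share the amplicon
#' coordinate frame. A read is assigned to a subgenome only if every
#' diagnostic position it covers matches the expected base of exactly one
#' reference; conflicting or uninformative reads are left unassigned.
#'
#' @param reads character vector of read sequences.
#' @param refs list of three [homoeolog_ref()] (A, B, D).
#' @param min_diagnostics minimum number of covered diagnostic positions
#'   required for assignment.
#' @return data.frame with columns `read`, `genome` ("A"/"B"/"D" or NA) and
#'   `reason` ("ok", "too_short", "conflict", "no_match", "ambiguous").
#' @export
assign_homoeolog <- function(reads, refs, min_diagnostics = 1L) {
  refs <- check_ref_set(refs)
  nr <- length(reads)
  lens <- nchar(reads)
  genome <- rep(NA_character_, nr)
  reason <- rep("no_match", nr)
  # per-reference logical matrix: does every covered diagnostic match?
  match_mat <- matrix(FALSE, nr, 3)
  ncov_min <- rep(Inf, nr)
  for (k in 1:3) {
    d <- refs[[k]]$diagnostics
    covered <- outer(lens, d$pos + 1, `>=`)        # reads x diagnostics
    obs <- matrix(NA_character_, nr, nrow(d))
    for (j in seq_len(nrow(d)))
      obs[, j] <- substring(reads, d$pos[j] + 1, d$pos[j] + 1)
    agree <- obs == matrix(toupper(d$base), nr, nrow(d), byrow = TRUE)
    ncov <- rowSums(covered)
    ncov_min <- pmin(ncov_min, ncov)
    match_mat[, k] <- ncov > 0 & rowSums(covered & agree) == ncov
  }
  nhit <- rowSums(match_mat)
  too_short <- ncov_min < min_diagnostics
  reason[too_short] <- "too_short"
  ok <- !too_short & nhit == 1
  genome[ok] <- c("A", "B", "D")[apply(match_mat[ok, , drop = FALSE], 1,
                                       which.max)]
  reason[ok] <- "ok"
  reason[!too_short & nhit > 1] <- "ambiguous"
  reason[!too_short & nhit == 0] <- "conflict"
  data.frame(read = reads, genome = genome, reason = reason,
             stringsAsFactors = FALSE)
}

# Left-normalize one indel event against the reference sequence.
# type "del": segment ref[start, start+len) shifts left while the base just
# before equals the last deleted base. type "ins": inserted string at ref
# offset `start` (insertion before that base) rotates left while its last
# base equals the reference base preceding the insertion point.
normalize_indel <- function(type, start, len, seq_inserted, ref) {
  if (type == "del") {
    while (start > 0 &&
           substring(ref, start, start) ==
           substring(ref, start + len, start + len)) {
      start <- start - 1
    }
    list(start = start, seq = "")
  } else {
    ins <- seq_inserted
    while (start > 0 &&
           substring(ins, len, len) == substring(ref, start, start)) {
      ins <- paste0(substring(ins, len, len), substring(ins, 1, len - 1))
      start <- start - 1
    }
    list(start = start, seq = ins)
  }
}

#' Call the edited allele carried by reads against one homoeolog
#'
#' Globally aligns each read to the amplicon (match +2, mismatch -2, gap
#' open -6, gap extend -1), extracts insertion/deletion events,
#' left-normalizes them within repeats (VCF convention) and sums the events
#' falling within `window` bp of the cut site into a net indel. Reads whose
#' alignment identity falls below `min_identity` are discarded.
#'
#' @param reads character vector of read sequences assigned to this
#'   homoeolog.
#' @param ref a [homoeolog_ref()].
#' @param window bp distance from the cut site within which indels are
#'   treated as Cas9-induced (default 20).
#' @param min_identity percent identity below which a read is discarded.
#' @return data.frame with one row per read: `net_indel`, `inserted_seq`,
#'   `normalized_start` (0-based; NA for wild type), `frameshift`, `kept`,
#'   `reason`.
#' @export
call_indel_allele <- function(reads, ref, window = 20L, min_identity = 80) {
  stopifnot(inherits(ref, "homoeolog_ref"))
  nr <- length(reads)
  if (nr == 0)
    return(data.frame(net_indel = integer(), inserted_seq = character(),
                      normalized_start = integer(), frameshift = logical(),
                      kept = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  # identical reads are aligned once and the call reused
  uniq <- unique(reads)
  back <- match(reads, uniq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(uniq), Biostrings::DNAString(ref$seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 1)
  pid <- Biostrings::pid(aln)
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  uout <- data.frame(net_indel = integer(length(uniq)), inserted_seq = "",
                     normalized_start = NA_integer_,
                     frameshift = FALSE, kept = TRUE, reason = "ok",
                     stringsAsFactors = FALSE)
  for (i in seq_along(uniq)) {
    if (pid[i] < min_identity) {
      uout$kept[i] <- FALSE
      uout$reason[i] <- "low_identity"
      next
    }
    events <- extract_indel_events(ap[i], as_[i], ref$seq)
    if (nrow(events)) {
      keep <- abs(events$ref_pos - ref$cut_site) <= window
      events <- events[keep, , drop = FALSE]
    }
    if (nrow(events) == 0) next            # substitutions only -> WT
    net <- sum(ifelse(events$type == "ins", events$len, -events$len))
    uout$net_indel[i] <- net
    uout$inserted_seq[i] <-
      paste(events$seq[events$type == "ins"], collapse = "")
    uout$normalized_start[i] <- min(events$ref_pos)
    uout$frameshift[i] <- net %% 3L != 0L
  }
  out <- uout[back, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Walk a pair of aligned strings and emit left-normalized indel events with
# reference coordinates (0-based). Gaps in the subject are insertions in the
# read; gaps in the pattern are deletions from the reference.
extract_indel_events <- function(aligned_pattern, aligned_subject, ref) {
  p <- strsplit(aligned_pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(aligned_subject, "", fixed = TRUE)[[1]]
  is_del <- p == "-"
  is_ins <- s == "-"
  ref_before <- cumsum(!is_ins)  # ref bases consumed up to & incl column
  runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cbind(start = starts[r$values], end = ends[r$values])
  }
  ev <- list()
  dr <- runs(is_del)
  for (k in seq_len(nrow(dr))) {
    st <- dr[k, 1]; en <- dr[k, 2]
    ref_start0 <- ref_before[st] - 1          # 0-based ref offset of run
    len <- en - st + 1
    nm <- normalize_indel("del", ref_start0, len, "", ref)
    ev[[length(ev) + 1]] <- data.frame(type = "del", ref_pos = nm$start,
                                       len = len, seq = "",
                                       stringsAsFactors = FALSE)
  }
  ir <- runs(is_ins)
  for (k in seq_len(nrow(ir))) {
    st <- ir[k, 1]; en <- ir[k, 2]
    ref_point0 <- ref_before[st]              # insertion before this ref base
    len <- en - st + 1
    ins <- paste(p[st:en], collapse = "")
    nm <- normalize_indel("ins", ref_point0, len, ins, ref)
    ev[[length(ev) + 1]] <- data.frame(type = "ins", ref_pos = nm$start,
                                       len = len, seq = nm$seq,
                                       stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(type = character(), ref_pos = integer(),
                      len = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, ev)
}

#' Tabulate edit alleles and editing efficiency for one homoeolog
#'
#' Groups called reads by (net indel, inserted sequence, normalized start)
#' and reports counts and frequencies sorted by frequency. The editing
#' efficiency is the fraction of assigned reads carrying a non-wild-type
#' allele.
#'
#' @param calls data.frame from [call_indel_allele()] (discarded reads are
#'   ignored).
#' @return list with `alleles` (data.frame: net_indel, inserted_seq,
#'   normalized_start, read_count, frequency, frameshift) and `efficiency`
#'   (percent; NA when no reads remain).
#' @export
summarize_alleles <- function(calls) {
  calls <- calls[calls$kept, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(list(alleles = data.frame(net_indel = integer(),
                                     inserted_seq = character(),
                                     normalized_start = integer(),
                                     read_count = integer(),
                                     frequency = numeric(),
                                     frameshift = logical()),
                efficiency = NA_real_))
  }
  key <- paste(calls$net_indel, calls$inserted_seq,
               ifelse(is.na(calls$normalized_start), ".",
                      calls$normalized_start), sep = "|")
  tab <- table(key)
  first <- calls[match(names(tab), key), , drop = FALSE]
  alleles <- data.frame(net_indel = first$net_indel,
                        inserted_seq = first$inserted_seq,
                        normalized_start = first$normalized_start,
                        read_count = as.integer(tab),
                        frequency = as.integer(tab) / nrow(calls),
                        frameshift = first$frameshift,
                        stringsAsFactors = FALSE)
  alleles <- alleles[order(-alleles$frequency), , drop = FALSE]
  rownames(alleles) <- NULL
  list(alleles = alleles,
       efficiency = 100 * sum(alleles$frequency[alleles$net_indel != 0 |
                                                alleles$inserted_seq != ""]))
}

zygosity_from_fraction <- function(f) {
  if (is.na(f)) return("ambiguous")
  if (f < 0.10) "WT"
  else if (f >= 0.30 && f <= 0.70) "het"
  else if (f > 0.90) "hom"
  else "ambiguous"
}

#' Call the per-plant genotype from homoeolog allele tables
#'
#' Converts the mutant read fraction of each subgenome into a zygosity call
#' (WT below 0.10, heterozygous in 0.30-0.70, homozygous above 0.90,
#' ambiguous in the gaps), assembles the six-letter genotype code
#' (uppercase = wild-type allele, e.g. `AAbbdd`; heterozygotes written
#' uppercase-first, `Bb`) and counts functional (non-mutated) copies.
#'
#' @param mutant_fraction named numeric of length 3 (A, B, D): the fraction
#'   of assigned reads carrying a non-wild-type allele; NA if no reads.
#' @return list of class `plant_genotype`: `zygosity` (named character),
#'   `code` (NA when any call is ambiguous) and `functional_copies`.
#' @export
call_plant_genotype <- function(mutant_fraction) {
  stopifnot(setequal(names(mutant_fraction), c("A", "B", "D")))
  f <- mutant_fraction[c("A", "B", "D")]
  zyg <- vapply(f, zygosity_from_fraction, "")
  letters3 <- c(A = "a", B = "b", D = "d")
  piece <- function(g) {
    up <- toupper(letters3[g]); lo <- letters3[g]
    switch(zyg[g], WT = paste0(up, up), het = paste0(up, lo),
           hom = paste0(lo, lo), ambiguous = NA_character_)
  }
  parts <- vapply(c("A", "B", "D"), piece, "")
  code <- if (anyNA(parts)) NA_character_ else paste(parts, collapse = "")
  fc <- if (is.na(code)) NA_integer_ else
    sum(strsplit(code, "")[[1]] %in% LETTERS)
  structure(list(zygosity = zyg, code = code, functional_copies = fc),
            class = "plant_genotype")
}

#' @export
print.plant_genotype <- function(x, ...) {
  cat("plant genotype: ", ifelse(is.na(x$code), "(ambiguous)", x$code),
      " [", paste(names(x$zygosity), x$zygosity, sep = ":",
                  collapse = " "), "], ",
      x$functional_copies, " functional copies\n", sep = "")
  invisible(x)
}

#' Genotype one plant's amplicon reads end to end
#'
#' Convenience wrapper: assigns reads to homoeologs, calls indel alleles per
#' subgenome, tabulates allele frequencies and derives the plant genotype.
#'
#' @inheritParams assign_homoeolog
#' @inheritParams call_indel_allele
#' @return list with `assignment`, per-genome `alleles` tables, and
#'   `genotype` (a `plant_genotype`).
#' @export
genotype_amplicons <- function(reads, refs, window = 20L,
                               min_identity = 80) {
  refs <- check_ref_set(refs)
  asg <- assign_homoeolog(reads, refs)
  alleles <- list()
  mutant_fraction <- c(A = NA_real_, B = NA_real_, D = NA_real_)
  for (g in c("A", "B", "D")) {
    rd <- asg$read[!is.na(asg$genome) & asg$genome == g]
    ref <- refs[[match(g, vapply(refs, `[[`, "", "genome"))]]
    calls <- call_indel_allele(rd, ref, window = window,
                               min_identity = min_identity)
    summ <- summarize_alleles(calls)
    alleles[[g]] <- summ$alleles
    if (!is.na(summ$efficiency))
      mutant_fraction[g] <- summ$efficiency / 100
  }
  list(assignment = asg, alleles = alleles,
       genotype = call_plant_genotype(mutant_fraction))
}
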