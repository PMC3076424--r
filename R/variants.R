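#' Align one read against a contig
#'
#' Seed-and-extend: exact seeds from the read (start, middle, end) are
#' looked up on both contig strands, each candidate is extended with a
#' banded affine-gap alignment (match +1, mismatch -2, gap open -4, gap
#' extend -1), and the best alignment is returned when its score reaches
#' `min_score_frac` times the read length.
#'
#' @param contig Contig sequence.
#' @param read Read sequence.
#' @param qual Optional integer phred scores (read orientation).
#' @param seed_len Exact seed length (default 17).
#' @param band Band half-width around the seed diagonal.
#' @param min_score_frac Minimum score as a fraction of read length.
#' @return `NULL` if unalignable, else a list with `start` (1-based),
#'   `strand`, `score`, `cigar`, and aligned observations: `ref_pos`,
#'   `base`, `qual` per aligned read base, plus `ins_ref_pos`/`ins_seq`/
#'   `ins_qual` and `del_ref_pos`/`del_len` events (all 1-based).
#' @export
align_read_to_contig <- function(contig, read, qual = NULL, seed_len = 17L,
                                 band = 10L, min_score_frac = 0.6) {
  res <- align_reads_cpp(contig, read,
                         if (is.null(qual)) list(NULL) else list(as.integer(qual)),
                         as.integer(seed_len), as.integer(band), 1L, -2L, -4L,
                         -1L, min_score_frac)[[1]]
  if (is.null(res)) return(NULL)
  shift_alignment(res)
}

shift_alignment <- function(res) {
  res$ref_pos <- res$ref_pos + 1L
  res$ins_ref_pos <- res$ins_ref_pos + 1L
  res$del_ref_pos <- res$del_ref_pos + 1L
  res$base <- strsplit(res$base, "", fixed = TRUE)[[1]]
  class(res) <- "rad_alignment"
  res
}

#' Align a bin's sheared-end reads to its contigs
#'
#' Every read 2 in the bin is aligned against every contig; each read is
#' assigned to its single best-scoring contig, and reads scoring equally
#' well on two contigs are dropped as ambiguous.
#'
#' @param contigs Character vector of contig sequences.
#' @param bin A [rad_pairs] data frame.
#' @param min_base_quality Unused here (kept by the pileup); qualities ride
#'   along with each alignment.
#' @param ... Passed to the aligner (see [align_read_to_contig()]).
#' @return List (one element per contig) of lists of alignments, each with
#'   a `sample` field; attribute `n_ambiguous` counts dropped reads.
#' @export
align_bin_reads <- function(contigs, bin, min_base_quality = 20L, ...) {
  quals <- phred_scores(bin$qual2)
  if (nrow(bin) == 1L) quals <- list(quals)
  per_contig <- lapply(contigs, function(ct)
    align_reads_cpp(ct, bin$seq2, quals, 17L, 10L, 1L, -2L, -4L, -1L, 0.6))
  n <- nrow(bin)
  out <- rep(list(list()), length(contigs))
  n_ambig <- 0L
  for (i in seq_len(n)) {
    scores <- vapply(per_contig, function(al)
      if (is.null(al[[i]])) -Inf else al[[i]]$score, numeric(1))
    best <- max(scores)
    if (!is.finite(best)) next
    hits <- which(scores == best)
    if (length(hits) > 1L) { n_ambig <- n_ambig + 1L; next }
    aln <- shift_alignment(per_contig[[hits]][[i]])
    aln$sample <- bin$sample[i]
    aln$read_id <- bin$id[i]
    out[[hits]][[length(out[[hits]]) + 1L]] <- aln
  }
  attr(out, "n_ambiguous") <- n_ambig
  out
}

#' Build a per-sample pileup over one contig
#'
#' Counts, per contig position and sample, the high-quality observations
#' of each allele.  Base observations below `min_base_quality` are
#' excluded; insertions are counted at the contig base preceding them
#' (allele `"+SEQ"`, filtered on the minimum inserted-base quality) and
#' deletions at the first deleted position (allele `"-L"` for an L-bp
#' deletion).
#'
#' @param contig Contig sequence.
#' @param alignments List of alignments for this contig (see
#'   [align_bin_reads()]), each carrying a `sample`.
#' @param min_base_quality Minimum phred score for a base to count.
#' @return A data frame (`pos`, `sample`, `allele`, `count`) of class
#'   `rad_pileup`.
#' @export
build_pileup <- function(contig, alignments, min_base_quality = 20L) {
  if (!length(alignments)) {
    out <- data.frame(pos = integer(0), sample = character(0),
                      allele = character(0), count = integer(0))
    class(out) <- c("rad_pileup", "data.frame")
    return(out)
  }
  pos <- unlist(lapply(alignments, `[[`, "ref_pos"))
  allele <- unlist(lapply(alignments, `[[`, "base"))
  qual <- unlist(lapply(alignments, `[[`, "qual"))
  sample <- rep(vapply(alignments, `[[`, "", "sample"),
                vapply(alignments, function(a) length(a$ref_pos), 0L))
  keep <- qual >= min_base_quality
  pos <- pos[keep]; allele <- allele[keep]; sample <- sample[keep]

  ins_pos <- unlist(lapply(alignments, `[[`, "ins_ref_pos"))
  if (length(ins_pos)) {
    ins_seq <- unlist(lapply(alignments, `[[`, "ins_seq"))
    ins_qual <- unlist(lapply(alignments, `[[`, "ins_qual"))
    ins_sample <- rep(vapply(alignments, `[[`, "", "sample"),
                      vapply(alignments, function(a) length(a$ins_ref_pos), 0L))
    keep <- ins_qual >= min_base_quality
    pos <- c(pos, ins_pos[keep])
    allele <- c(allele, paste0("+", ins_seq[keep]))
    sample <- c(sample, ins_sample[keep])
  }
  del_pos <- unlist(lapply(alignments, `[[`, "del_ref_pos"))
  if (length(del_pos)) {
    del_len <- unlist(lapply(alignments, `[[`, "del_len"))
    del_sample <- rep(vapply(alignments, `[[`, "", "sample"),
                      vapply(alignments, function(a) length(a$del_ref_pos), 0L))
    pos <- c(pos, del_pos)
    allele <- c(allele, paste0("-", del_len))
    sample <- c(sample, del_sample)
  }
  # indels anchored before the first contig base have no valid column
  ok <- pos >= 1L & pos <= nchar(contig)
  pos <- pos[ok]; allele <- allele[ok]; sample <- sample[ok]
  if (!length(pos)) {
    out <- data.frame(pos = integer(0), sample = character(0),
                      allele = character(0), count = integer(0))
  } else {
    key <- paste(pos, sample, allele, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
                      sample = vapply(parts, `[`, "", 2L),
                      allele = vapply(parts, `[`, "", 3L),
                      count = as.integer(tab), stringsAsFactors = FALSE)
    out <- out[order(out$pos, out$sample, out$allele), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("rad_pileup", "data.frame")
  out
}

#' Threshold genotype call at one pileup column
#'
#' An allele passes when seen at least `min_allele_count` times in a
#' sample.  No passing allele gives a no-call `"-"` (usually low
#' coverage); one gives a homozygote; two give a heterozygote
#' `"[X/Y]"` with the reference allele first when present (otherwise the
#' higher-count allele first, ties alphabetical); three or more passing
#' alleles give a no-call flagged multi-allelic.
#'
#' @param column Data frame (`sample`, `allele`, `count`) for one contig
#'   position (a slice of [build_pileup()] output).
#' @param min_allele_count Threshold separating SNPs from sequencing error
#'   (default 4).
#' @param ref_base Contig base at the position (orders heterozygotes).
#' @param samples Samples to report; absent samples get `"-"`.
#' @return Named character vector of genotype strings.
#' @export
call_site <- function(column, min_allele_count = 4L, ref_base = NULL,
                      samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(column$sample))
  out <- setNames(rep("-", length(samples)), samples)
  for (s in samples) {
    sl <- column[column$sample == s & column$count >= min_allele_count, ,
                 drop = FALSE]
    if (nrow(sl) == 0L || nrow(sl) >= 3L) next
    if (nrow(sl) == 1L) { out[s] <- sl$allele; next }
    al <- sl$allele
    ct <- sl$count
    if (!is.null(ref_base) && ref_base %in% al) {
      first <- ref_base
    } else {
      first <- al[order(-ct, al)][1]
    }
    second <- setdiff(al, first)
    out[s] <- sprintf("[%s/%s]", first, second)
  }
  out
}

record_has_alt <- function(geno, ref_base) {
  if (geno == "-") return(FALSE)
  alleles <- if (grepl("^\\[", geno))
    strsplit(sub("^\\[(.*)\\]$", "\\1", geno), "/", fixed = TRUE)[[1]]
  else geno
  any(alleles != ref_base)
}

#' Call SNPs and small indels for one assembled bin
#'
#' Aligns the bin's reads (all samples) back to the bin's contigs, builds
#' per-sample pileups, and emits one record for every contig position
#' where at least one sample's threshold call contains an allele that
#' differs from the contig consensus.  Indels pass under the same
#' at-least-`min_allele_count` rule.
#'
#' @param result A `rad_assembly` for the bin (assembled from the pooled
#'   samples).
#' @param bin A [rad_pairs] data frame with per-sample labels.
#' @param samples Samples to genotype (default: those present in `bin`).
#' @param min_allele_count Allele count threshold (default 4).
#' @param min_base_quality Pileup base-quality threshold (default 20).
#' @param tag_index Tag index used in the contig headers.
#' @return A data frame of class `snp_records`: `header`, `pos`, `ref`,
#'   then one genotype column per sample.
#' @export
call_bin_snps <- function(result, bin, samples = NULL, min_allele_count = 4L,
                          min_base_quality = 20L, tag_index = NULL) {
  if (is.null(samples)) samples <- sort(unique(bin$sample))
  if (is.null(tag_index)) tag_index <- result$tag_index
  if (is.null(tag_index)) tag_index <- 1L
  headers <- contig_headers(tag_index, result$tag, result$contigs)
  recs <- list()
  if (nrow(result$contigs)) {
    aln <- align_bin_reads(result$contigs$sequence, bin)
    for (ci in seq_len(nrow(result$contigs))) {
      ctg <- result$contigs$sequence[ci]
      pile <- build_pileup(ctg, aln[[ci]], min_base_quality)
      if (!nrow(pile)) next
      refs <- strsplit(ctg, "", fixed = TRUE)[[1]]
      cand <- unique(pile$pos[pile$count >= min_allele_count &
                                pile$allele != refs[pile$pos]])
      for (p in sort(cand)) {
        col <- pile[pile$pos == p, , drop = FALSE]
        gt <- call_site(col, min_allele_count, ref_base = refs[p],
                        samples = samples)
        if (!any(vapply(gt, record_has_alt, TRUE, ref_base = refs[p]))) next
        row <- data.frame(header = headers[ci], pos = p, ref = refs[p],
                          stringsAsFactors = FALSE)
        for (s in samples) row[[s]] <- gt[[s]]
        recs[[length(recs) + 1L]] <- row
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else {
    out0 <- data.frame(header = character(0), pos = integer(0),
                       ref = character(0), stringsAsFactors = FALSE)
    for (s in samples) out0[[s]] <- character(0)
    out0
  }
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  class(out) <- c("snp_records", "data.frame")
  out
}

#' Write the two-line SNP report
#'
#' Each record takes two lines: the contig FASTA header, then
#' `"<pos> <ref> <sample1> <gt1> <sample2> <gt2> ..."` with genotypes
#' rendered as a bare allele, `"[X/Y]"`, or `"-"` for no-call.
#'
#' @param records A `snp_records` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_report <- function(records, path) {
  samples <- attr(records, "samples")
  if (is.null(samples)) samples <- setdiff(names(records),
                                           c("header", "pos", "ref"))
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- character(0)
  if (nrow(records)) {
    gt <- do.call(paste, c(lapply(samples, function(s)
      paste(s, records[[s]])), sep = " "))
    line2 <- paste(records$pos, records$ref, gt)
    lines <- as.vector(rbind(records$header, line2))
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Re-parse a two-line SNP report
#'
#' @param path Report path written by [write_snp_report()].
#' @return A `snp_records` data frame.
#' @export
read_snp_report <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    out <- data.frame(header = character(0), pos = integer(0),
                      ref = character(0), stringsAsFactors = FALSE)
    class(out) <- c("snp_records", "data.frame")
    return(out)
  }
  stopifnot(length(lines) %% 2L == 0L)
  hdr <- lines[seq(1L, length(lines), by = 2L)]
  body <- strsplit(lines[seq(2L, length(lines), by = 2L)], " ", fixed = TRUE)
  samples <- unique(unlist(lapply(body, function(x)
    x[seq(3L, length(x), by = 2L)])))
  out <- data.frame(header = hdr,
                    pos = as.integer(vapply(body, `[`, "", 1L)),
                    ref = vapply(body, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  for (s in samples)
    out[[s]] <- vapply(body, function(x) {
      i <- which(x[seq(3L, length(x), by = 2L)] == s)
      if (!length(i)) "-" else x[2L * i + 2L]
    }, "")
  attr(out, "samples") <- samples
  class(out) <- c("snp_records", "data.frame")
  out
}

vcf_ref_alt <- function(ref, allele, pos, contig_seq) {
  if (substr(allele, 1, 1) == "+") {
    list(pos = pos, ref = ref, alt = paste0(ref, substr(allele, 2,
                                                        nchar(allele))))
  } else if (substr(allele, 1, 1) == "-") {
    len <- as.integer(substr(allele, 2, nchar(allele)))
    if (is.null(contig_seq))
      stop("deletion records need contig sequences for VCF output")
    list(pos = pos - 1L,
         ref = substr(contig_seq, pos - 1L, pos + len - 1L),
         alt = substr(contig_seq, pos - 1L, pos - 1L))
  } else {
    list(pos = pos, ref = ref, alt = allele)
  }
}

geno_alleles <- function(geno) {
  if (geno == "-") return(character(0))
  if (grepl("^\\[", geno))
    strsplit(sub("^\\[(.*)\\]$", "\\1", geno), "/", fixed = TRUE)[[1]]
  else geno
}

#' Write SNP records as minimal VCF 4.2
#'
#' CHROM is the contig header, POS the 1-based contig position (indels
#' anchored on the preceding base), GT the per-sample genotype.
#'
#' @param records A `snp_records` data frame.
#' @param path Output path.
#' @param contig_seqs Named character vector (header -> contig sequence);
#'   required when deletion records are present.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(records, path, contig_seqs = NULL) {
  samples <- attr(records, "samples")
  if (is.null(samples)) samples <- setdiff(names(records),
                                           c("header", "pos", "ref"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(samples, collapse = "\t")))
  rows <- character(0)
  for (i in seq_len(nrow(records))) {
    gts <- lapply(samples, function(s) geno_alleles(records[[s]][i]))
    alts <- setdiff(unique(unlist(gts)), records$ref[i])
    if (!length(alts)) next
    # indel and SNP alts at one site are written per-alt
    prim <- alts[1]
    rep_all <- vcf_ref_alt(records$ref[i], prim, records$pos[i],
                           if (!is.null(contig_seqs))
                             contig_seqs[[records$header[i]]] else NULL)
    allele_idx <- function(a) {
      if (a == records$ref[i]) return(0L)
      match(a, alts)
    }
    gt_str <- vapply(gts, function(g) {
      if (!length(g)) return("./.")
      if (length(g) == 1L) g <- c(g, g)
      paste(vapply(g, allele_idx, 0L), collapse = "/")
    }, "")
    alt_field <- paste(vapply(alts, function(a)
      vcf_ref_alt(records$ref[i], a, records$pos[i],
                  if (!is.null(contig_seqs))
                    contig_seqs[[records$header[i]]] else NULL)$alt, ""),
      collapse = ",")
    rows <- c(rows, paste(records$header[i], rep_all$pos, ".", rep_all$ref,
                          alt_field, ".", "PASS", ".", "GT",
                          paste(gt_str, collapse = "\t"), sep = "\t"))
  }
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' Pair bi-allelic RAD tags into haplotypes
#'
#' A polymorphism inside the RAD tag itself splits one locus into two tags
#' at Hamming distance 1, each assembling a contig specific to one
#' homologous chromosome.  Tags are paired when both passed the count
#' filters, lie at Hamming distance exactly 1, have a pooled count ratio
#' within `[1/3, 3]` (two alleles of one locus are expected near 1:1), and
#' each has no other candidate partner; a tag pairable with two partners
#' is left unpaired and flagged ambiguous.
#'
#' @param bins A filtered `rad_bins` object.
#' @param results Named list of `rad_assembly` objects (names = tags).
#' @param ratio_bounds Allowed count ratio between partners.
#' @return A list of haplotype pairs (`tag_a`, `tag_b`, `count_a`,
#'   `count_b`, `contig_a`, `contig_b`, `variants` data frame of phased
#'   differences); attribute `ambiguous` lists multi-partner tags.
#' @export
pair_biallelic_tags <- function(bins, results, ratio_bounds = c(1 / 3, 3)) {
  tags <- bins$tags
  counts <- bin_counts(bins)
  hits <- hamming1_hits(tags, tags)
  names(hits) <- tags
  ambiguous <- tags[lengths(hits) >= 2L]
  pairs <- list()
  seen <- character(0)
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (length(hits[[i]]) != 1L) next
    partner <- hits[[i]][1]
    if (tg %in% seen || partner %in% seen) next
    if (partner %in% ambiguous) next
    j <- match(partner, tags)
    # mutual exclusivity is symmetric for Hamming distance, but the partner
    # must also have no other candidate
    ratio <- counts[i] / counts[j]
    if (ratio < ratio_bounds[1] || ratio > ratio_bounds[2]) next
    a <- min(tg, partner); b <- max(tg, partner)
    ia <- match(a, tags); ib <- match(b, tags)
    ctg_a <- results[[a]]$contigs
    ctg_b <- results[[b]]$contigs
    variants <- phased_contig_variants(ctg_a, ctg_b)
    pairs[[length(pairs) + 1L]] <- list(
      tag_a = a, tag_b = b, count_a = unname(counts[ia]),
      count_b = unname(counts[ib]),
      contig_a = if (nrow(ctg_a)) ctg_a$sequence[1] else NA_character_,
      contig_b = if (nrow(ctg_b)) ctg_b$sequence[1] else NA_character_,
      variants = variants)
    seen <- c(seen, a, b)
  }
  attr(pairs, "ambiguous") <- ambiguous
  pairs
}

# Differences between the top contigs of the two alleles of one locus,
# phased by construction (each contig comes from one haplotype).
phased_contig_variants <- function(ctg_a, ctg_b) {
  empty <- data.frame(pos_a = integer(0), allele_a = character(0),
                      allele_b = character(0), stringsAsFactors = FALSE)
  if (!nrow(ctg_a) || !nrow(ctg_b)) return(empty)
  a <- ctg_a$sequence[1]
  cands <- c(ctg_b$sequence[1], revcomp(ctg_b$sequence[1]))
  sc <- vapply(cands, function(b)
    Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                  scoreOnly = TRUE), numeric(1))
  b <- cands[which.max(sc)]
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap")
  mm <- Biostrings::mismatchTable(aln)
  if (!nrow(mm)) return(empty)
  data.frame(pos_a = mm$PatternStart,
             allele_a = as.character(mm$PatternSubstring),
             allele_b = as.character(mm$SubjectSubstring),
             stringsAsFactors = FALSE)
}
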