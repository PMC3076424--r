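#' Paired-end read container
#'
#' A `rad_pairs` object is a data frame with one row per read pair and
#' columns `id`, `seq1`, `qual1`, `seq2`, `qual2`, `sample`.  Quality
#' strings are always held phred33-encoded internally, whatever the input
#' encoding was; `sample` is a label or `"UNASSIGNED"`.
#'
#' @param id Read identifiers.
#' @param seq1,seq2 Read sequences (DNA over A/C/G/T/N).
#' @param qual1,qual2 Phred33-encoded quality strings, same lengths as the
#'   sequences.
#' @param sample Sample labels (recycled).
#' @return A `rad_pairs` data frame.
#' @export
rad_pairs <- function(id, seq1, qual1, seq2, qual2, sample = "UNASSIGNED") {
  stopifnot(all(nchar(seq1) == nchar(qual1)),
            all(nchar(seq2) == nchar(qual2)))
  df <- data.frame(id = as.character(id), seq1 = as.character(seq1),
                   qual1 = as.character(qual1), seq2 = as.character(seq2),
                   qual2 = as.character(qual2),
                   sample = rep_len(as.character(sample), length(id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("rad_pairs", "data.frame")
  df
}

quality_offset <- function(encoding) {
  switch(match.arg(encoding, c("phred33", "phred64")),
         phred33 = 33L, phred64 = 64L)
}

#' Decode a quality string into integer phred scores
#'
#' @param qual Quality strings.
#' @param encoding `"phred33"` (offset 33) or `"phred64"` (offset 64,
#'   Illumina 1.5+).
#' @return A list of integer vectors (or a single vector for length-1 input).
#' @examples
#' phred_scores("K", "phred64")  # 11
#' phred_scores("I", "phred33")  # 40
#' @export
phred_scores <- function(qual, encoding = "phred33") {
  off <- quality_offset(encoding)
  out <- lapply(qual, function(q) utf8ToInt(q) - off)
  if (length(out) == 1L) out[[1]] else out
}

read_fastq_lines <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

parse_fastq_file <- function(path, offset) {
  lines <- read_fastq_lines(path)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record %d in %s", length(lines) %/% 4L + 1L,
                 path))
  if (!length(lines))
    return(list(id = character(0), seq = character(0), qual = character(0)))
  idx <- seq(1L, length(lines), by = 4L)
  ids <- lines[idx]
  bad <- which(substr(ids, 1, 1) != "@")
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d in %s: header does not start with '@'",
                 bad[1], path))
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d in %s: sequence/quality length mismatch",
                 bad[1], path))
  if (offset != 33L) {
    shift <- offset - 33L
    quals <- vapply(quals, function(q) intToUtf8(utf8ToInt(q) - shift),
                    character(1), USE.NAMES = FALSE)
  }
  # sanity-check the decoded range on the first record
  if (length(quals)) {
    sc <- utf8ToInt(quals[1]) - 33L
    if (any(sc < 0L))
      stop(sprintf("negative phred score decoded from %s: wrong --encoding?",
                   path))
  }
  list(id = sub("^@", "", ids), seq = seqs, qual = quals)
}

#' Read paired FASTQ files
#'
#' Reads two 4-line FASTQ files (optionally gzipped) record by record and
#' returns a [rad_pairs] data frame.  Qualities are re-encoded to phred33
#' internally.  A truncated or malformed record raises an error naming the
#' record index; differing record counts between the two files raise a
#' pairing error.
#'
#' @param path1,path2 Paths to the read-1 and read-2 FASTQ files.
#' @param encoding Input quality encoding, `"phred33"` or `"phred64"`.
#' @return A [rad_pairs] data frame.
#' @export
read_fastq_pairs <- function(path1, path2, encoding = "phred33") {
  off <- quality_offset(encoding)
  r1 <- parse_fastq_file(path1, off)
  r2 <- parse_fastq_file(path2, off)
  if (length(r1$id) != length(r2$id))
    stop(sprintf("pairing error: %d records in %s but %d in %s",
                 length(r1$id), path1, length(r2$id), path2))
  rad_pairs(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
            seq2 = r2$seq, qual2 = r2$qual)
}

#' Write paired FASTQ files
#'
#' Inverse of [read_fastq_pairs()]; writing then re-reading reproduces
#' sequences and qualities exactly for both encodings.
#'
#' @param pairs A [rad_pairs] data frame.
#' @param path1,path2 Output paths (a `.gz` suffix enables compression).
#' @param encoding Output quality encoding.
#' @return Invisibly, `pairs`.
#' @export
write_fastq_pairs <- function(pairs, path1, path2, encoding = "phred33") {
  off <- quality_offset(encoding)
  enc <- function(q) {
    if (off == 33L) return(q)
    vapply(q, function(x) intToUtf8(utf8ToInt(x) + off - 33L), character(1),
           USE.NAMES = FALSE)
  }
  write_one <- function(path, seqs, quals) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    if (nrow(pairs) == 0L) {
      # create an empty file
      writeLines(character(0), con)
      return(invisible(NULL))
    }
    writeLines(paste0("@", pairs$id, "\n", seqs, "\n+\n", enc(quals)), con,
               sep = "\n")
  }
  write_one(path1, pairs$seq1, pairs$qual1)
  write_one(path2, pairs$seq2, pairs$qual2)
  invisible(pairs)
}

count_poor_bases <- function(qual, poor_max_score) {
  # phred33 chars with score <= poor_max_score form a contiguous ASCII range
  cls <- sprintf("[\\x%02X-\\x%02X]", 33L, 33L + as.integer(poor_max_score))
  nchar(qual) - nchar(gsub(cls, "", qual, perl = TRUE))
}

#' Drop read pairs with too many poor-quality bases
#'
#' A pair is dropped when either read has strictly more than `max_poor`
#' bases at phred score `poor_max_score` or worse; the two mates are always
#' kept or dropped together, since an orphaned mate is useless for binning.
#' The default poor-quality cutoff of 11 is the score of `'K'` under the
#' phred64 (Illumina 1.5+) encoding.
#'
#' @param pairs A [rad_pairs] data frame (phred33 qualities).
#' @param max_poor Maximum tolerated number of poor bases per read.
#' @param poor_max_score Highest phred score still counted as poor.
#' @return The kept pairs, with attribute `n_dropped`.
#' @export
quality_filter <- function(pairs, max_poor = 25L, poor_max_score = 11L) {
  poor1 <- count_poor_bases(pairs$qual1, poor_max_score)
  poor2 <- count_poor_bases(pairs$qual2, poor_max_score)
  keep <- poor1 <= max_poor & poor2 <= max_poor
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rad_pairs", "data.frame")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Assign read pairs to samples by in-line barcode
#'
#' Barcodes sit at the start of read 1 and are matched exactly (no mismatch
#' rescue).  Matching pairs get the barcode label as their sample and the
#' barcode trimmed from read 1; non-matching pairs are labelled
#' `"UNASSIGNED"` and are excluded by downstream binning.
#'
#' @param pairs A [rad_pairs] data frame.
#' @param barcodes Named character vector, label -> barcode sequence; all
#'   barcodes must have equal length.
#' @return `pairs` with `sample` set and matched read-1 sequences trimmed.
#' @examples
#' p <- rad_pairs("r1", "AGAGTTGCAGGAA", strrep("I", 13), "ACGT", "IIII")
#' demultiplex(p, c(H2 = "AGAGT", L2 = "CAGTC"))$sample  # "H2"
#' @export
demultiplex <- function(pairs, barcodes) {
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes))))
    stop("barcodes must be a named character vector (label -> sequence)")
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1L)
    stop("configuration error: barcodes must all have the same length")
  prefix <- substr(pairs$seq1, 1L, blen)
  hit <- match(prefix, toupper(barcodes))
  matched <- !is.na(hit)
  pairs$sample <- ifelse(matched, names(barcodes)[hit], "UNASSIGNED")
  pairs$seq1[matched] <- substr(pairs$seq1[matched], blen + 1L,
                                nchar(pairs$seq1[matched]))
  pairs$qual1[matched] <- substr(pairs$qual1[matched], blen + 1L,
                                 nchar(pairs$qual1[matched]))
  pairs
}

#' Contig FASTA headers
#'
#' Builds the per-contig FASTA header
#' `"<tagIndex>_<tagSequence>_NODE_<n>_length_<L>_cov_<c>"`, where `L` is
#' the contig length and `c` the mean k-mer coverage printed with six
#' decimal places.
#'
#' @param tag_index Integer index of the RAD tag.
#' @param tag RAD tag sequence.
#' @param contigs Data frame with columns `sequence`, `length`, `coverage`.
#' @return Character vector of headers.
#' @export
contig_headers <- function(tag_index, tag, contigs) {
  if (nrow(contigs) == 0L) return(character(0))
  sprintf("%d_%s_NODE_%d_length_%d_cov_%.6f", as.integer(tag_index), tag,
          seq_len(nrow(contigs)), contigs$length, contigs$coverage)
}

#' Write assembled contigs as FASTA
#'
#' One record per contig, with headers from [contig_headers()].  Empty
#' contigs are skipped with a warning.
#'
#' @param results A list of assembly results (see [assemble_bin()]), or a
#'   single result.  Tag indices follow list order unless the list carries a
#'   `tag_index` per element.
#' @param path Output FASTA path.
#' @return Invisibly, the headers written.
#' @export
write_contigs_fasta <- function(results, path) {
  if (inherits(results, "rad_assembly")) results <- list(results)
  headers <- character(0)
  seqs <- character(0)
  for (i in seq_along(results)) {
    res <- results[[i]]
    idx <- if (!is.null(res$tag_index)) res$tag_index else i
    ct <- res$contigs
    if (nrow(ct)) {
      empty <- !nzchar(ct$sequence)
      if (any(empty)) {
        warning(sprintf("skipping %d empty contig(s) for tag %s", sum(empty),
                        res$tag))
        ct <- ct[!empty, , drop = FALSE]
      }
    }
    headers <- c(headers, contig_headers(idx, res$tag, ct))
    seqs <- c(seqs, ct$sequence)
  }
  if (length(seqs)) {
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- headers
    Biostrings::writeXStringSet(dna, path, width = 20000L)
  } else {
    writeLines(character(0), path)
  }
  invisible(headers)
}

#' Read a contig FASTA written by [write_contigs_fasta()]
#'
#' @param path FASTA path.
#' @return Data frame with columns `header`, `tag_index`, `tag`, `node`,
#'   `length`, `coverage`, `sequence`.
#' @export
read_contigs_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  hdr <- names(dna)
  m <- regmatches(hdr, regexec(
    "^([0-9]+)_([ACGTN]+)_NODE_([0-9]+)_length_([0-9]+)_cov_([0-9.]+)$", hdr))
  field <- function(i) vapply(m, function(x) if (length(x) == 6L) x[i]
                              else NA_character_, character(1))
  data.frame(
    header = hdr,
    tag_index = as.integer(field(2L)),
    tag = field(3L),
    node = as.integer(field(4L)),
    length = as.integer(field(5L)),
    coverage = as.numeric(field(6L)),
    sequence = as.character(dna),
    stringsAsFactors = FALSE, row.names = NULL)
}
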