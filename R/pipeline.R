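#' N50 of a set of contig lengths
#'
#' The smallest length L such that contigs of length at least L sum to at
#' least half the total assembled length.  An empty input gives 0.
#'
#' @param lengths Numeric vector of contig lengths.
#' @return The N50 in bp.
#' @examples
#' n50(c(40, 30, 20, 10))  # 30
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Pipeline configuration
#'
#' Mode presets follow the library designs: SNP discovery keeps tags with
#' 30-999 read pairs, partial-digest whole-genome runs keep 25-499, and
#' long-insert runs keep tags with at least 1000 pairs and no repetitive
#' ceiling.  The partial-digest preset assembles without a k-mer coverage
#' cutoff (`cov_cutoff = 1`) because per-tag sheared-end depth is low and
#' even; the other modes drop singleton k-mers as error noise.
#'
#' @param mode `"snp_discovery"`, `"partial_digest"` or `"long_insert"`.
#' @param bin_cfg A [bin_filter_config()]; `NULL` takes the mode preset.
#' @param params An [assembly_params()]; `NULL` takes the mode preset.
#' @param min_allele_count,min_base_quality SNP caller thresholds.
#' @param region_length_estimate Region length for depth estimates;
#'   `NULL` takes the mode preset (800, 1200, 6000 bp).
#' @param tag_length RAD tag length (default 39).
#' @param encoding FASTQ quality encoding for file input.
#' @param barcodes Optional named barcode vector for demultiplexing.
#' @param out_dir Optional output directory for result files.
#' @param seed Optional RNG seed (simulation-driven runs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("snp_discovery", "partial_digest",
                                     "long_insert"),
                            bin_cfg = NULL, params = NULL,
                            min_allele_count = 4L, min_base_quality = 20L,
                            region_length_estimate = NULL, tag_length = 39L,
                            encoding = "phred33", barcodes = NULL,
                            out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(bin_cfg))
    bin_cfg <- switch(mode,
      snp_discovery = bin_filter_config(30L, 1000, tag_length = tag_length),
      partial_digest = bin_filter_config(25L, 500, tag_length = tag_length),
      long_insert = bin_filter_config(1000L, Inf, tag_length = tag_length))
  if (is.null(params))
    params <- switch(mode,
      snp_discovery = assembly_params(),
      partial_digest = assembly_params(cov_cutoff = 1),
      long_insert = assembly_params(cov_cutoff = 2))
  if (is.null(region_length_estimate))
    region_length_estimate <- switch(mode, snp_discovery = 800,
                                     partial_digest = 1200,
                                     long_insert = 6000)
  structure(list(mode = mode, bin_cfg = bin_cfg, params = params,
                 min_allele_count = as.integer(min_allele_count),
                 min_base_quality = as.integer(min_base_quality),
                 region_length_estimate = region_length_estimate,
                 tag_length = as.integer(tag_length), encoding = encoding,
                 barcodes = barcodes, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Place contigs on a truth genome and tally errors
#'
#' Each contig is placed by exact match on either strand when possible,
#' falling back to seed-and-extend banded alignment; per contig the
#' mismatch+indel error count and the errors within 30 bp of a contig end
#' are tallied.  Coverage depth counts distinct contig placements
#' overlapping a base.
#'
#' @param contigs Data frame with a `sequence` column (e.g. from
#'   [read_contigs_fasta()] or an assembly), or a character vector.
#' @param genome A `synthetic_genome` (or DNA string); circular topology
#'   is honoured by allowing placements across the origin.
#' @param min_depths Depths d at which to report the genome fraction
#'   covered by at least d placements.
#' @return List with `placements` (per contig: `start`, `end` 1-based on
#'   the reference, `strand`, `placed`, `error_count`, `errors_near_end`),
#'   `coverage_fraction` (named by depth), and `total_errors`.
#' @export
evaluate_contigs <- function(contigs, genome, min_depths = c(1, 5)) {
  if (is.character(contigs))
    contigs <- data.frame(sequence = contigs, stringsAsFactors = FALSE)
  genome <- as_genome(genome)
  L <- genome$length
  circular <- genome$topology == "circular"
  hay <- if (circular) paste0(genome$sequence, genome$sequence)
         else genome$sequence
  n <- nrow(contigs)
  start <- integer(n); end <- integer(n); strand <- character(n)
  placed <- logical(n); err <- integer(n); err_end <- integer(n)
  for (i in seq_len(n)) {
    sq <- contigs$sequence[i]
    hit <- regexpr(sq, hay, fixed = TRUE)
    strand[i] <- "+"
    if (hit < 0) {
      hit <- regexpr(revcomp(sq), hay, fixed = TRUE)
      strand[i] <- "-"
    }
    if (hit > 0 && hit <= L) {
      start[i] <- hit
      end[i] <- hit + nchar(sq) - 1L
      placed[i] <- TRUE
      next
    }
    # inexact placement by seed-and-extend
    aln <- align_reads_cpp(hay, sq, list(NULL), 17L, 15L, 1L, -2L, -4L, -1L,
                           0.5)[[1]]
    if (is.null(aln)) { placed[i] <- FALSE; next }
    placed[i] <- TRUE
    strand[i] <- aln$strand
    st <- aln$start
    if (st > L) st <- st - L
    start[i] <- st
    end[i] <- st + nchar(sq) - 1L
    # error tally: mismatching aligned bases plus indel events
    ref_at <- substring(hay, aln$ref_pos + 1L, aln$ref_pos + 1L)
    bases <- strsplit(aln$base, "")[[1]]
    mism <- which(bases != ref_at)
    n_ind <- length(aln$ins_ref_pos) + length(aln$del_ref_pos)
    err[i] <- length(mism) + n_ind
    # contig coordinate of the i-th aligned base is its rank (read order)
    cpos <- if (aln$strand == "+") mism else nchar(sq) + 1L - mism
    err_end[i] <- sum(cpos <= 30L | cpos > nchar(sq) - 30L)
  }
  placements <- data.frame(start = start, end = end, strand = strand,
                           placed = placed, error_count = err,
                           errors_near_end = err_end,
                           stringsAsFactors = FALSE)
  cov_frac <- setNames(numeric(length(min_depths)), min_depths)
  ok <- placed
  if (any(ok)) {
    s <- placements$start[ok]; e <- placements$end[ok]
    if (circular) {
      wrap <- e > L
      ir <- c(IRanges::IRanges(start = s, end = pmin(e, L)),
              IRanges::IRanges(start = rep(1L, sum(wrap)),
                               end = e[wrap] - L))
    } else {
      ir <- IRanges::IRanges(start = s, end = pmin(e, L))
    }
    cov <- IRanges::coverage(ir, width = L)
    for (d in seq_along(min_depths))
      cov_frac[d] <- sum(S4Vectors::runLength(cov)[
        S4Vectors::runValue(cov) >= min_depths[d]]) / L
  }
  list(placements = placements, coverage_fraction = cov_frac,
       total_errors = sum(err[placed]))
}

#' Run the RAD paired-end pipeline end to end
#'
#' Demultiplex and quality-filter read pairs, bin them by RAD tag, apply
#' the mode's count thresholds, repetitive-derivative removal and
#' coverage cap, assemble every kept bin (best-of-three word lengths, or
#' the two-pass long-insert strategy), and -- in SNP discovery mode --
#' align reads back, call SNPs under the at-least-four-instances rule and
#' pair bi-allelic tags.  With `truth_genome` the contigs are also placed
#' on the truth for coverage and error metrics.
#'
#' @param config A [pipeline_config()].
#' @param pairs A [rad_pairs] data frame (already in memory), or `NULL`
#'   to read FASTQ files.
#' @param fastq1,fastq2 FASTQ paths when `pairs` is `NULL`.
#' @param truth_genome Optional `synthetic_genome` for evaluation.
#' @return A `rad_run_report` list: per-fate bin counts, assemblies,
#'   contig statistics (N50 over all contigs and over each tag's longest
#'   contig), SNP records, haplotype pairs, coverage fractions, and the
#'   paths of any files written.
#' @export
run_pipeline <- function(config, pairs = NULL, fastq1 = NULL, fastq2 = NULL,
                         truth_genome = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(pairs)) {
    if (is.null(fastq1) || is.null(fastq2))
      stop("configuration error: provide `pairs` or both FASTQ paths")
    pairs <- read_fastq_pairs(fastq1, fastq2, config$encoding)
    if (is.null(config$barcodes)) pairs$sample <- "sample1"
  }
  n_input <- nrow(pairs)
  if (!is.null(config$barcodes)) pairs <- demultiplex(pairs, config$barcodes)
  pairs <- quality_filter(pairs)
  n_lowqual <- attr(pairs, "n_dropped")

  bins <- bin_by_tag(pairs, config$bin_cfg$tag_length)
  fb <- filter_bins(bins, config$bin_cfg, config$region_length_estimate)
  kept <- fb$bins

  assemble_one <- if (config$mode == "long_insert")
    function(b) assemble_long_insert_two_pass(
      b, config$params, config$region_length_estimate)
  else
    function(b) assemble_bin_best_of_three(
      b, config$params, config$region_length_estimate)
  results <- vector("list", length(kept$tags))
  names(results) <- kept$tags
  for (i in seq_along(kept$tags)) {
    res <- assemble_one(kept$bins[[i]])
    res$tag <- kept$tags[i]
    res$tag_index <- i
    results[[i]] <- res
  }

  all_contigs <- do.call(rbind, lapply(results, function(r) r$contigs))
  if (is.null(all_contigs))
    all_contigs <- data.frame(sequence = character(0), length = integer(0),
                              coverage = numeric(0))
  longest_per_tag <- vapply(results, function(r)
    if (nrow(r$contigs)) max(r$contigs$length) else NA_integer_, 0L)
  longest_per_tag <- longest_per_tag[!is.na(longest_per_tag)]

  snps <- NULL
  hap_pairs <- NULL
  if (config$mode == "snp_discovery") {
    samples <- sort(unique(pairs$sample))
    rec_list <- lapply(seq_along(results), function(i)
      call_bin_snps(results[[i]], kept$bins[[i]], samples = samples,
                    min_allele_count = config$min_allele_count,
                    min_base_quality = config$min_base_quality,
                    tag_index = i))
    snps <- do.call(rbind, rec_list)
    if (!is.null(snps)) {
      attr(snps, "samples") <- samples
      class(snps) <- c("snp_records", "data.frame")
    }
    hap_pairs <- pair_biallelic_tags(kept, results)
  }

  evaluation <- NULL
  if (!is.null(truth_genome) && nrow(all_contigs))
    evaluation <- evaluate_contigs(all_contigs, truth_genome)

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(config$out_dir, "contigs.fasta")
    write_contigs_fasta(results, fa)
    tsv <- file.path(config$out_dir, "bins.tsv")
    write_bin_report(fb$report, tsv)
    files <- c(fa, tsv)
    if (!is.null(snps)) {
      rp <- file.path(config$out_dir, "snps.txt")
      write_snp_report(snps, rp)
      vcf <- file.path(config$out_dir, "snps.vcf")
      ctg_seqs <- setNames(
        unlist(lapply(results, function(r)
          r$contigs$sequence), use.names = FALSE),
        unlist(lapply(results, function(r)
          contig_headers(r$tag_index, r$tag, r$contigs)), use.names = FALSE))
      write_vcf(snps, vcf, contig_seqs = ctg_seqs)
      files <- c(files, rp, vcf)
    }
    log <- file.path(config$out_dir, "assembly_log.tsv")
    logdf <- do.call(rbind, lapply(results, function(r)
      data.frame(tag = r$tag, depth = r$depth, chosen_k = r$chosen_k,
                 n_contigs = nrow(r$contigs),
                 total_length = r$total_assembled_length,
                 stringsAsFactors = FALSE)))
    if (!is.null(logdf))
      write.table(logdf, log, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, log)
  }

  fates <- table(factor(fb$report$fate,
                        levels = c("kept", "low", "repetitive",
                                   "derivative")))
  structure(list(
    mode = config$mode,
    n_input_pairs = n_input,
    n_lowqual_dropped = n_lowqual,
    n_short_discarded = bins$n_short,
    bin_fates = as.list(fates),
    n_bins_kept = length(kept$tags),
    results = results,
    bins = kept,
    bin_report = fb$report,
    n_contigs = nrow(all_contigs),
    total_assembled_length = sum(all_contigs$length),
    n50_all = n50(all_contigs$length),
    n50_longest_per_tag = n50(longest_per_tag),
    snps = snps,
    n_snps = if (is.null(snps)) NA_integer_ else nrow(snps),
    haplotype_pairs = hap_pairs,
    evaluation = evaluation,
    files = files), class = "rad_run_report")
}

#' @export
print.rad_run_report <- function(x, ...) {
  cat(sprintf("<rad_run_report> mode %s\n", x$mode))
  cat(sprintf("  read pairs in: %d (low quality dropped: %d)\n",
              x$n_input_pairs, x$n_lowqual_dropped))
  cat(sprintf("  bins: %d kept | %d low | %d repetitive | %d derivative\n",
              x$bin_fates$kept, x$bin_fates$low, x$bin_fates$repetitive,
              x$bin_fates$derivative))
  cat(sprintf("  contigs: %d, total %d bp, N50 %d (longest-per-tag N50 %d)\n",
              x$n_contigs, x$total_assembled_length, x$n50_all,
              x$n50_longest_per_tag))
  if (!is.na(x$n_snps))
    cat(sprintf("  SNP records: %d; haplotype pairs: %d\n", x$n_snps,
                length(x$haplotype_pairs)))
  if (!is.null(x$evaluation)) {
    cf <- x$evaluation$coverage_fraction
    cat(sprintf("  truth coverage: %s; contig errors: %d\n",
                paste(sprintf(">=%sx %.2f%%", names(cf), 100 * cf),
                      collapse = ", "),
                x$evaluation$total_errors))
  }
  invisible(x)
}
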