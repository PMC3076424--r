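#' Bin filter configuration
#'
#' Count thresholds applied to RAD tag bins before assembly.  Bins are kept
#' when `min_count <= count < max_count`, counts pooled over all samples;
#' bins at or above `max_count` are removed as repetitive, and single
#' mismatch derivatives of repetitive tags are removed with them.
#' Mode presets used by [run_pipeline()]: 30/1000 for SNP discovery,
#' 25/500 for partial-digest whole-genome sequencing, 1000/unbounded for
#' long-insert libraries.
#'
#' @param min_count Minimum pooled pair count (inclusive).
#' @param max_count Repetitive-tag threshold (exclusive; `Inf` disables).
#' @param coverage_cap Per-bin fold-coverage cap for [cap_bin_coverage()].
#' @param tag_length RAD tag length in bases taken from the start of read 1.
#' @return A `bin_filter_config` list.
#' @export
bin_filter_config <- function(min_count = 30L, max_count = 1000,
                              coverage_cap = 30, tag_length = 39L) {
  if (!(min_count > 0 && min_count < max_count))
    stop("need 0 < min_count < max_count")
  structure(list(min_count = as.integer(min_count), max_count = max_count,
                 coverage_cap = coverage_cap,
                 tag_length = as.integer(tag_length)),
            class = "bin_filter_config")
}

#' Partition read pairs by RAD tag
#'
#' The tag is the first `tag_length` bases of (barcode-trimmed) read 1;
#' every kept pair lands in exactly one bin, in input order.  Pairs whose
#' read 1 is shorter than the tag length are discarded and counted, as are
#' pairs still labelled `"UNASSIGNED"` after demultiplexing (when other
#' samples are present).
#'
#' @param pairs A [rad_pairs] data frame.
#' @param tag_length Tag length in bases (default 39).
#' @return A `rad_bins` object: a list with `tags` (character), `bins`
#'   (named list of [rad_pairs]), `n_short`, `n_unassigned`.
#' @export
bin_by_tag <- function(pairs, tag_length = 39L) {
  n_unassigned <- 0L
  samples <- unique(pairs$sample)
  if (length(samples) > 1L && "UNASSIGNED" %in% samples) {
    drop <- pairs$sample == "UNASSIGNED"
    n_unassigned <- sum(drop)
    pairs <- pairs[!drop, , drop = FALSE]
  }
  short <- nchar(pairs$seq1) < tag_length
  n_short <- sum(short)
  pairs <- pairs[!short, , drop = FALSE]
  tag <- substr(pairs$seq1, 1L, tag_length)
  idx <- split(seq_len(nrow(pairs)), tag)
  tags <- sort(names(idx))
  bins <- lapply(tags, function(tg) {
    b <- pairs[idx[[tg]], , drop = FALSE]
    rownames(b) <- NULL
    class(b) <- c("rad_pairs", "data.frame")
    b
  })
  names(bins) <- tags
  structure(list(tags = tags, bins = bins, n_short = n_short,
                 n_unassigned = n_unassigned),
            class = "rad_bins")
}

#' @export
print.rad_bins <- function(x, ...) {
  cat(sprintf("<rad_bins> %d tags, %d pairs (%d short read-1 discarded)\n",
              length(x$tags), sum(vapply(x$bins, nrow, 0L)), x$n_short))
  invisible(x)
}

bin_counts <- function(bins) vapply(bins$bins, nrow, integer(1))

#' Apply count thresholds to tag bins
#'
#' Keeps bins whose pooled pair count satisfies
#' `min_count <= count < max_count`.  Bins below the minimum lack the
#' coverage to call polymorphisms; bins at or above the maximum are
#' recorded as repetitive for [remove_mismatch_derivatives()].
#'
#' @param bins A `rad_bins` object from [bin_by_tag()].
#' @param cfg A [bin_filter_config()].
#' @return List with `bins` (filtered `rad_bins`), `repetitive_tags`, and a
#'   `report` data frame (`tag`, `count`, `fate`).
#' @export
apply_count_filters <- function(bins, cfg = bin_filter_config()) {
  counts <- bin_counts(bins)
  fate <- rep("kept", length(counts))
  fate[counts < cfg$min_count] <- "low"
  fate[counts >= cfg$max_count] <- "repetitive"
  report <- data.frame(tag = bins$tags, count = as.integer(counts),
                       fate = fate, stringsAsFactors = FALSE)
  keep <- fate == "kept"
  out <- bins
  out$tags <- bins$tags[keep]
  out$bins <- bins$bins[keep]
  list(bins = out, repetitive_tags = bins$tags[fate == "repetitive"],
       report = report)
}

#' Remove single-mismatch derivatives of repetitive tags
#'
#' Any bin whose tag lies at Hamming distance exactly 1 from a repetitive
#' tag is removed: such tags are overwhelmingly sequencing-error copies of
#' the repetitive sequence, not real loci.
#'
#' @param bins A `rad_bins` object (already count-filtered).
#' @param repetitive_tags Tags removed as repetitive.
#' @return List with `bins` and `removed` (the derivative tags).
#' @export
remove_mismatch_derivatives <- function(bins, repetitive_tags) {
  if (!length(repetitive_tags) || !length(bins$tags))
    return(list(bins = bins, removed = character(0)))
  hits <- hamming1_hits(bins$tags, repetitive_tags)
  doomed <- lengths(hits) > 0L
  out <- bins
  out$tags <- bins$tags[!doomed]
  out$bins <- bins$bins[!doomed]
  list(bins = out, removed = bins$tags[doomed])
}

#' Cap per-bin sheared-end coverage
#'
#' Oversequenced bins are truncated deterministically: pairs are kept in
#' input order until the cumulative read-2 bases divided by the estimated
#' region length would exceed `cap` fold coverage.  Read 1 is the invariant
#' tag and does not count toward assembly substrate.
#'
#' @param bin A [rad_pairs] data frame (one bin).
#' @param cap Fold-coverage cap (default 30).
#' @param region_length_estimate Estimated assembled-region length in bp;
#'   by convention the upper bound of the shear size-selection window.
#' @return The possibly truncated bin.
#' @export
cap_bin_coverage <- function(bin, cap = 30, region_length_estimate = 800) {
  if (cap <= 0) stop("configuration error: coverage cap must be positive")
  if (region_length_estimate <= 0)
    stop("region_length_estimate must be positive")
  cum <- cumsum(nchar(bin$seq2)) / region_length_estimate
  keep <- cum <= cap
  out <- bin[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rad_pairs", "data.frame")
  out
}

#' Filter tag bins: count thresholds, derivatives, coverage cap
#'
#' Convenience wrapper chaining [apply_count_filters()],
#' [remove_mismatch_derivatives()] and [cap_bin_coverage()], producing a
#' reconciled removal report.
#'
#' @param bins A `rad_bins` object.
#' @param cfg A [bin_filter_config()].
#' @param region_length_estimate See [cap_bin_coverage()].
#' @return List with `bins` and `report` (fates `kept`, `low`,
#'   `repetitive`, `derivative`).
#' @export
filter_bins <- function(bins, cfg = bin_filter_config(),
                        region_length_estimate = 800) {
  cf <- apply_count_filters(bins, cfg)
  dv <- remove_mismatch_derivatives(cf$bins, cf$repetitive_tags)
  report <- cf$report
  report$fate[report$tag %in% dv$removed] <- "derivative"
  out <- dv$bins
  out$bins <- lapply(out$bins, cap_bin_coverage, cap = cfg$coverage_cap,
                     region_length_estimate = region_length_estimate)
  list(bins = out, report = report)
}

#' Write the tag removal report as TSV
#'
#' @param report Report data frame from [filter_bins()] or
#'   [apply_count_filters()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bin_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
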