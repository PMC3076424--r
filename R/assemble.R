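#' Assembly parameters
#'
#' Controls the per-bin de Bruijn graph assembly.  `k` values must be odd
#' (so no k-mer equals its own reverse complement) and lie in `[15, 63]`.
#' The best-of-three strategy tries `k_low`, the coverage-predicted k and
#' `k_high`; the defaults 21 and 31 span the word-length range of classic
#' short-read de Bruijn assemblers.
#'
#' @param k Default word length when assembling at a single k.
#' @param k_low,k_high Low and high word lengths for the three-trial run.
#' @param min_contig_length Shortest contig reported (bp).
#' @param tip_max_length Dead-end paths shorter than this are clipped;
#'   `NULL` means `2 * k` at assembly time.
#' @param bubble_identity Minimum identity between two bubble arms for the
#'   lower-coverage arm to be merged away.
#' @param cov_cutoff k-mers with multiplicity below this are dropped during
#'   simplification.  Use 1 (no cutoff) for error-free or very low-depth
#'   data.
#' @param k_pass1 Word length of the first pass in the long-insert
#'   two-pass mode.
#' @return An `assembly_params` list.
#' @export
assembly_params <- function(k = 25L, k_low = 21L, k_high = 31L,
                            min_contig_length = 100L, tip_max_length = NULL,
                            bubble_identity = 0.9, cov_cutoff = 2,
                            k_pass1 = 41L) {
  for (kk in c(k, k_low, k_high, k_pass1)) {
    if (kk %% 2L == 0L) stop("configuration error: word length must be odd")
    if (kk < 15L || kk > 63L) stop("word length must lie in [15, 63]")
  }
  if (!(k_low <= k && k <= k_high)) stop("need k_low <= k <= k_high")
  structure(list(k = as.integer(k), k_low = as.integer(k_low),
                 k_high = as.integer(k_high),
                 min_contig_length = as.integer(min_contig_length),
                 tip_max_length = tip_max_length,
                 bubble_identity = bubble_identity, cov_cutoff = cov_cutoff,
                 k_pass1 = as.integer(k_pass1)),
            class = "assembly_params")
}

#' Build a canonical k-mer graph
#'
#' k-mers are stored canonically (lexicographic minimum of the k-mer and
#' its reverse complement), so a sequence and its reverse complement build
#' identical graphs.  k-mers containing N are skipped.
#'
#' @param seqs Character vector of DNA sequences.
#' @param k Odd word length.
#' @param weights Multiplicity added per k-mer occurrence (scalar or one
#'   value per sequence); long guide sequences are threaded with weight 1.
#' @return A `kmer_graph`: list with `kmer`, `count`, `k`.
#' @export
build_kmer_graph <- function(seqs, k, weights = 1) {
  if (k %% 2L == 0L) stop("configuration error: k must be odd")
  g <- dbg_count_kmers(as.character(seqs), as.integer(k), as.numeric(weights))
  structure(list(kmer = g$kmer, count = g$count, k = as.integer(k)),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("<kmer_graph> k = %d, %d canonical k-mers, total multiplicity %g\n",
              x$k, length(x$kmer), sum(x$count)))
  invisible(x)
}

#' Simplify a k-mer graph
#'
#' Repeats until fixpoint: (a) clip tips (dead-end unbranched paths)
#' shorter than `tip_max_length`, (b) merge bubbles (two unbranched paths
#' sharing endpoints with identity at least `bubble_identity`) keeping the
#' higher-coverage arm, after (c) dropping k-mers with multiplicity below
#' `cov_cutoff`.
#'
#' @param graph A `kmer_graph`.
#' @param params An [assembly_params()].
#' @return The simplified `kmer_graph`.
#' @export
simplify_graph <- function(graph, params = assembly_params()) {
  tip_max <- params$tip_max_length
  if (is.null(tip_max)) tip_max <- 2L * graph$k
  g <- dbg_simplify_cpp(graph$kmer, graph$count, graph$k,
                        as.integer(tip_max), params$bubble_identity,
                        params$cov_cutoff, 50L)
  structure(list(kmer = g$kmer, count = g$count, k = graph$k),
            class = "kmer_graph")
}

#' Extract contigs from a k-mer graph
#'
#' Maximal unbranched paths are spelled out as contigs; the mean k-mer
#' coverage of a contig is the mean node multiplicity along its path.
#' Contigs are reported in a canonical orientation (lexicographic minimum
#' of sequence and reverse complement), sorted by decreasing length.
#'
#' @param graph A (simplified) `kmer_graph`.
#' @param min_contig_length Shortest contig kept.
#' @return Data frame with `sequence`, `length`, `coverage`.
#' @export
extract_contigs <- function(graph, min_contig_length = 100L) {
  ct <- dbg_extract_cpp(graph$kmer, graph$count, graph$k,
                        as.integer(min_contig_length))
  data.frame(sequence = ct$sequence, length = ct$length,
             coverage = ct$coverage, stringsAsFactors = FALSE)
}

#' Predict the assembly word length from sheared-end depth
#'
#' Monotone step map: higher depth supports a longer word length, which
#' bridges short repeats; sparse bins need a short word length so reads
#' still overlap by k.
#'
#' @param depth Estimated fold coverage of the bin's region.
#' @return An odd word length: 21 below 10x, 25 below 30x, 29 below 100x,
#'   31 above.
#' @export
predict_k <- function(depth) {
  stopifnot(depth >= 0)
  if (depth < 10) 21L else if (depth < 30) 25L else if (depth < 100) 29L
  else 31L
}

#' Estimated sheared-end depth of a bin
#'
#' Total read-2 bases divided by the estimated region length (by default
#' the upper bound of the shear size-selection window).
#'
#' @param bin A [rad_pairs] data frame.
#' @param region_length_estimate Region length in bp.
#' @return Fold coverage.
#' @export
estimate_depth <- function(bin, region_length_estimate = 800) {
  sum(nchar(bin$seq2)) / region_length_estimate
}

assemble_seqs <- function(seqs, k, params, long_seqs = NULL) {
  all_seqs <- c(as.character(seqs), as.character(long_seqs))
  weights <- rep(1, length(all_seqs))
  g <- build_kmer_graph(all_seqs, k, weights)
  g <- simplify_graph(g, params)
  extract_contigs(g, params$min_contig_length)
}

new_assembly <- function(tag, contigs, chosen_k, depth, trials = NULL,
                         tag_index = NULL) {
  structure(list(tag = tag, tag_index = tag_index, contigs = contigs,
                 chosen_k = as.integer(chosen_k),
                 total_assembled_length = sum(contigs$length),
                 depth = depth, trials = trials),
            class = "rad_assembly")
}

#' @export
print.rad_assembly <- function(x, ...) {
  cat(sprintf("<rad_assembly> tag %s: %d contig(s), total %d bp, k = %d\n",
              substr(x$tag, 1, 20), nrow(x$contigs),
              x$total_assembled_length, x$chosen_k))
  invisible(x)
}

#' Assemble one bin with three word-length trials
#'
#' Runs a full assembly of the bin's read-2 sequences at `k_low`, at the
#' coverage-predicted word length ([predict_k()]), and at `k_high`, and
#' keeps the trial with the largest total assembled contig length.  Ties
#' are broken by larger contig N50, then by smaller k.  Read 1 is the
#' invariant tag and is never fed to the graph.
#'
#' @param bin A [rad_pairs] data frame (one filtered bin).
#' @param params An [assembly_params()].
#' @param region_length_estimate For the depth estimate.
#' @return A `rad_assembly` with `trials` recording all three totals; a bin
#'   where all trials produce nothing yields a zero-contig result, not an
#'   error.
#' @export
assemble_bin_best_of_three <- function(bin, params = assembly_params(),
                                       region_length_estimate = 800) {
  tag <- if (nrow(bin)) substr(bin$seq1[1], 1L, nchar(bin$seq1[1])) else ""
  depth <- estimate_depth(bin, region_length_estimate)
  ks <- c(params$k_low, predict_k(depth), params$k_high)
  trials <- lapply(unique(ks), function(k) assemble_seqs(bin$seq2, k, params))
  ks <- unique(ks)
  totals <- vapply(trials, function(ct) sum(ct$length), numeric(1))
  n50s <- vapply(trials, function(ct) n50(ct$length), numeric(1))
  ord <- order(-totals, -n50s, ks)
  best <- ord[1]
  new_assembly(tag, trials[[best]], ks[best], depth,
               trials = data.frame(k = ks, total_length = totals,
                                   n50 = n50s, n_contigs =
                                     vapply(trials, nrow, 0L)))
}

#' Two-pass long-insert assembly
#'
#' Pass 1 assembles the bin's read-2 sequences at a long word length
#' (default 41); pass 2 re-assembles at the coverage-predicted word length
#' with the pass-1 contigs threaded through the graph like reads (weight
#' 1), and finally uses the pass-1 contigs as templates to bridge pass-2
#' contigs across repeats longer than the pass-2 word length.
#'
#' @param bin A [rad_pairs] data frame.
#' @param params An [assembly_params()]; `k_pass1` sets the pass-1 word
#'   length.
#' @param region_length_estimate For the depth estimate (long-insert
#'   regions span several kb).
#' @return A `rad_assembly` from pass 2.
#' @export
assemble_long_insert_two_pass <- function(bin, params = assembly_params(),
                                          region_length_estimate = 6000) {
  tag <- if (nrow(bin)) bin$seq1[1] else ""
  depth <- estimate_depth(bin, region_length_estimate)
  pass1 <- assemble_seqs(bin$seq2, params$k_pass1, params)
  k2 <- predict_k(depth)
  pass2 <- assemble_seqs(bin$seq2, k2, params, long_seqs = pass1$sequence)
  merged <- merge_with_templates(pass2, pass1$sequence)
  new_assembly(tag, merged, k2, depth,
               trials = data.frame(k = c(params$k_pass1, k2),
                                   total_length = c(sum(pass1$length),
                                                    sum(merged$length)),
                                   n50 = c(n50(pass1$length),
                                           n50(merged$length)),
                                   n_contigs = c(nrow(pass1), nrow(merged))))
}

# Place a contig on a template by exact match of its terminal anchors.
# Returns NULL, or list(start, end, seq) in template coordinates (0-based
# half-open; may overhang the template).
place_on_template <- function(contig, template, anchor = 40L) {
  L <- nchar(contig)
  if (L < anchor) return(NULL)
  for (o in c(contig, revcomp(contig))) {
    a <- substr(o, 1L, anchor)
    b <- substr(o, L - anchor + 1L, L)
    ha <- gregexpr(a, template, fixed = TRUE)[[1]]
    hb <- gregexpr(b, template, fixed = TRUE)[[1]]
    ha <- ha[ha > 0]
    hb <- hb[hb > 0]
    if (length(ha) > 1L || length(hb) > 1L) next  # ambiguous anchor
    if (length(ha) == 1L && length(hb) == 1L) {
      if (hb - ha != L - anchor) next  # inconsistent placement
      return(list(start = ha - 1L, end = ha - 1L + L, seq = o))
    }
    if (length(ha) == 1L) return(list(start = ha - 1L, end = ha - 1L + L,
                                      seq = o))
    if (length(hb) == 1L) return(list(start = hb - 1L + anchor - L,
                                      end = hb - 1L + anchor, seq = o))
  }
  NULL
}

# Bridge contigs across repeats using longer template sequences assembled
# at a larger word length: contigs placing on one template in compatible,
# non-nested positions are stitched, gaps filled from the template.
merge_with_templates <- function(contigs, templates, anchor = 40L) {
  if (nrow(contigs) < 2L || !length(templates)) return(contigs)
  repeat {
    merged_any <- FALSE
    for (tmpl in templates) {
      if (nrow(contigs) < 2L) break
      pl <- lapply(contigs$sequence, place_on_template, template = tmpl,
                   anchor = anchor)
      placed <- which(!vapply(pl, is.null, logical(1)))
      if (length(placed) < 2L) next
      ord <- placed[order(vapply(pl[placed], `[[`, 0, "start"))]
      run_seq <- NULL; run_start <- NULL; run_end <- NULL
      members <- integer(0); covs <- numeric(0); lens <- numeric(0)
      flush <- function() {
        if (length(members) < 2L) return(NULL)
        data.frame(sequence = run_seq, length = nchar(run_seq),
                   coverage = sum(covs * lens) / sum(lens),
                   stringsAsFactors = FALSE)
      }
      new_rows <- list(); drop_idx <- integer(0)
      for (i in ord) {
        p <- pl[[i]]
        if (is.null(run_seq)) {
          run_seq <- p$seq; run_start <- p$start; run_end <- p$end
          members <- i; covs <- contigs$coverage[i]; lens <- contigs$length[i]
          next
        }
        gap <- p$start - run_end
        if (p$end <= run_end || p$start <= run_start ||
            gap > nchar(tmpl)) {
          fr <- flush()
          if (!is.null(fr)) { new_rows[[length(new_rows) + 1L]] <- fr
                              drop_idx <- c(drop_idx, members) }
          run_seq <- p$seq; run_start <- p$start; run_end <- p$end
          members <- i; covs <- contigs$coverage[i]; lens <- contigs$length[i]
          next
        }
        if (gap >= 0L) {
          filler <- substr(tmpl, run_end + 1L, p$start)
          run_seq <- paste0(run_seq, filler, p$seq)
        } else {
          run_seq <- paste0(run_seq, substr(p$seq, -gap + 1L, nchar(p$seq)))
        }
        run_end <- p$end
        members <- c(members, i)
        covs <- c(covs, contigs$coverage[i])
        lens <- c(lens, contigs$length[i])
      }
      fr <- flush()
      if (!is.null(fr)) { new_rows[[length(new_rows) + 1L]] <- fr
                          drop_idx <- c(drop_idx, members) }
      if (length(drop_idx)) {
        keep <- contigs[-drop_idx, , drop = FALSE]
        contigs <- rbind(keep, do.call(rbind, new_rows))
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  # restore canonical orientation and deterministic order
  canon <- pmin(contigs$sequence, revcomp(contigs$sequence))
  contigs$sequence <- canon
  contigs$length <- nchar(canon)
  contigs <- contigs[order(-contigs$length, contigs$sequence), , drop = FALSE]
  rownames(contigs) <- NULL
  contigs
}
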