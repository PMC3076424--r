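#' Simulation configuration
#'
#' Bundles the library-geometry parameters shared by the simulators.
#' Windows are `(min, max)` in bp; `error_rate` is per base;
#' `partial_cut_prob` is the per-site per-molecule cut probability
#' (1 = complete digest).
#'
#' @param read1_len,read2_len Read lengths in bp (40 x 80 mirrors an
#'   asymmetric paired-end run).
#' @param shear_window Shear size-selection window (bp) applied to sheared
#'   pieces.
#' @param size_select Fragment size-selection window (bp) applied after
#'   digestion (partial-digest and long-insert modes).
#' @param error_rate Per-base substitution error probability.
#' @param depth Target read pairs per RAD tag.
#' @param partial_cut_prob Per-site cut probability per molecule copy.
#' @param molecule_copies Molecule copies per digestion reaction.
#' @param seed Optional RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(read1_len = 40L, read2_len = 80L,
                       shear_window = c(200, 1200),
                       size_select = c(1000, 5000), error_rate = 0,
                       depth = 40L, partial_cut_prob = 0.5,
                       molecule_copies = 50L, seed = NULL) {
  stopifnot(shear_window[1] < shear_window[2],
            size_select[1] < size_select[2],
            error_rate >= 0, error_rate <= 1,
            partial_cut_prob >= 0, partial_cut_prob <= 1)
  structure(list(read1_len = as.integer(read1_len),
                 read2_len = as.integer(read2_len),
                 shear_window = shear_window, size_select = size_select,
                 error_rate = error_rate, depth = as.integer(depth),
                 partial_cut_prob = partial_cut_prob,
                 molecule_copies = as.integer(molecule_copies), seed = seed),
            class = "sim_config")
}

#' Generate a random genome
#'
#' I.i.d. bases at the requested GC fraction; deterministic under `seed`.
#'
#' @param length Genome length in bp (> 0).
#' @param gc_fraction Fraction of G+C bases.
#' @param topology `"linear"` or `"circular"`.
#' @param seed Optional RNG seed.
#' @return A `synthetic_genome`: list with `sequence`, `topology`,
#'   `length`.
#' @export
generate_genome <- function(length, gc_fraction = 0.5,
                            topology = c("linear", "circular"),
                            seed = NULL) {
  topology <- match.arg(topology)
  if (length <= 0) stop("genome length must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
  structure(list(sequence = seq, topology = topology,
                 length = as.integer(length)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d bp, %s\n", x$length, x$topology))
  invisible(x)
}

as_genome <- function(x, topology = "linear") {
  if (inherits(x, "synthetic_genome")) return(x)
  structure(list(sequence = as.character(x), topology = topology,
                 length = nchar(x)), class = "synthetic_genome")
}

#' Overwrite restriction sites at chosen positions
#'
#' Scrubs every pre-existing occurrence of the enzyme's recognition site
#' (by mutating its middle base), then writes the site at the requested
#' 1-based positions.  Used to build test genomes whose cut map is known
#' exactly.
#'
#' @param genome A `synthetic_genome` or DNA string.
#' @param enzyme Enzyme or built-in name.
#' @param positions 1-based site start positions (non-overlapping).
#' @return The modified `synthetic_genome`.
#' @export
plant_restriction_sites <- function(genome, enzyme, positions) {
  genome <- as_genome(genome)
  enz <- resolve_enzyme(enzyme)
  seq <- genome$sequence
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  for (iter in 1:10) {
    hit <- gregexpr(enz$site, seq, fixed = TRUE)[[1]]
    hit <- hit[hit > 0]
    if (!length(hit)) break
    mid <- hit + nchar(enz$site) %/% 2L
    for (m in mid) substr(seq, m, m) <- swap[[substr(seq, m, m)]]
  }
  for (p in positions) {
    stopifnot(p >= 1, p + nchar(enz$site) - 1L <= nchar(seq))
    substr(seq, p, p + nchar(enz$site) - 1L) <- enz$site
  }
  genome$sequence <- seq
  genome
}

#' Plant variants on a genome, producing a diploid truth
#'
#' Variants are placed at distinct positions at least `min_spacing` bp
#' apart; the returned truth holds both haplotype sequences and the
#' variant table (1-based positions on the reference haplotype).
#'
#' @param genome A `synthetic_genome` or DNA string (reference haplotype).
#' @param n_snp,n_ins,n_del Variant counts (insertions/deletions are 1-3
#'   bp).
#' @param min_spacing Minimum distance between variant positions.
#' @param region Optional `(min, max)` 1-based window to confine variants.
#' @param seed Optional RNG seed.
#' @return A `diploid_truth`: list with `ref`, `alt`, `variants`
#'   (`pos`, `ref`, `alt`, `type`).
#' @export
plant_variants <- function(genome, n_snp, n_ins = 0L, n_del = 0L,
                           min_spacing = 10L, region = NULL, seed = NULL) {
  genome <- as_genome(genome)
  if (!is.null(seed)) withr::local_seed(seed)
  L <- genome$length
  n_tot <- n_snp + n_ins + n_del
  if (n_tot > L / 100)
    stop("too many variants for the genome length (need <= length/100)")
  lo <- if (is.null(region)) 1L else max(1L, region[1])
  hi <- if (is.null(region)) L - 4L else min(L - 4L, region[2])
  if (n_tot == 0L)
    return(structure(list(ref = genome$sequence, alt = genome$sequence,
                          variants = data.frame(pos = integer(0),
                                                ref = character(0),
                                                alt = character(0),
                                                type = character(0),
                                                stringsAsFactors = FALSE)),
                     class = "diploid_truth"))
  pos <- integer(0)
  tries <- 0L
  while (length(pos) < n_tot) {
    cand <- sample(lo:hi, 1L)
    if (!length(pos) || all(abs(pos - cand) >= min_spacing))
      pos <- c(pos, cand)
    tries <- tries + 1L
    if (tries > 1000L * n_tot)
      stop("could not place variants with the requested spacing")
  }
  pos <- sort(pos)
  type <- sample(rep(c("snp", "ins", "del"), c(n_snp, n_ins, n_del)))
  bases <- c("A", "C", "G", "T")
  ref_seq <- genome$sequence
  variants <- data.frame(pos = pos, ref = "", alt = "", type = type,
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_tot)) {
    p <- pos[i]
    rb <- substr(ref_seq, p, p)
    if (type[i] == "snp") {
      variants$ref[i] <- rb
      variants$alt[i] <- sample(setdiff(bases, rb), 1L)
    } else if (type[i] == "ins") {
      len <- sample(1:3, 1L)
      variants$ref[i] <- rb
      variants$alt[i] <- paste0(rb, paste(sample(bases, len, replace = TRUE),
                                          collapse = ""))
    } else {
      len <- sample(1:3, 1L)
      variants$ref[i] <- substr(ref_seq, p, p + len)
      variants$alt[i] <- rb
    }
  }
  # build the alternate haplotype by stitching between variant positions
  pieces <- character(0)
  cur <- 1L
  for (i in seq_len(n_tot)) {
    p <- variants$pos[i]
    pieces <- c(pieces, substr(ref_seq, cur, p - 1L), variants$alt[i])
    cur <- p + nchar(variants$ref[i])
  }
  pieces <- c(pieces, substr(ref_seq, cur, nchar(ref_seq)))
  structure(list(ref = ref_seq, alt = paste(pieces, collapse = ""),
                 variants = variants),
            class = "diploid_truth")
}

locate_sites <- function(seq, enz, circular = FALSE) {
  L <- nchar(seq)
  slen <- nchar(enz$site)
  hay <- if (circular) paste0(seq, substr(seq, 1L, slen - 1L)) else seq
  hit <- gregexpr(enz$site, hay, fixed = TRUE)[[1]]
  hit <- hit[hit > 0 & hit <= L]
  hit - 1L  # 0-based site starts
}

#' Digest a genome into restriction fragments
#'
#' Each molecule copy is digested independently: every recognition site is
#' cut with probability `partial_cut_prob`.  Fragments carry their cut
#' ends (`rad` flags with the enzyme and 0-based site start), so the
#' downstream library steps know where the RAD tags sit.  Circular
#' genomes produce no terminal (non-RAD) fragment ends; an uncut circle
#' yields a single fragment with no RAD ends.
#'
#' @param genome A `synthetic_genome` or DNA string.
#' @param enzymes List of enzymes (or built-in names) digesting together.
#' @param partial_cut_prob Per-site cut probability (1 = complete).
#' @param molecule_copies Independent molecule copies.
#' @param seed Optional RNG seed.
#' @return Data frame of fragments: `copy`, `start`, `end` (0-based
#'   half-open, `end` past the sequence length on a circular wrap),
#'   `enz_left`, `site_left`, `enz_right`, `site_right` (NA for sheared or
#'   molecule ends).
#' @export
digest <- function(genome, enzymes, partial_cut_prob = 1,
                   molecule_copies = 1L, seed = NULL) {
  genome <- as_genome(genome)
  if (!is.null(seed)) withr::local_seed(seed)
  if (!length(enzymes)) stop("need at least one enzyme")
  if (inherits(enzymes, "rad_enzyme")) enzymes <- list(enzymes)
  enzymes <- lapply(enzymes, resolve_enzyme)
  circular <- genome$topology == "circular"
  L <- genome$length

  sites <- do.call(rbind, lapply(enzymes, function(e) {
    st <- locate_sites(genome$sequence, e, circular)
    if (!length(st)) return(NULL)
    data.frame(enzyme = e$name, site_start = st, cut = st + e$cut_offset,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(sites)) sites <- sites[order(sites$cut), , drop = FALSE]

  frag_list <- vector("list", molecule_copies)
  for (cp in seq_len(molecule_copies)) {
    if (is.null(sites)) chosen <- integer(0)
    else chosen <- which(runif(nrow(sites)) < partial_cut_prob)
    if (!length(chosen)) {
      frag_list[[cp]] <- data.frame(
        copy = cp, start = 0L, end = L, enz_left = NA_character_,
        site_left = NA_integer_, enz_right = NA_character_,
        site_right = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    cs <- sites[chosen, , drop = FALSE]
    # adjacent sites of different enzymes can share a cut coordinate;
    # a position is cut once
    cs <- cs[!duplicated(cs$cut), , drop = FALSE]
    if (circular) {
      nxt <- c(seq_len(nrow(cs))[-1], 1L)
      start <- cs$cut
      end <- cs$cut[nxt]
      end[end <= start] <- end[end <= start] + L
      frag_list[[cp]] <- data.frame(
        copy = cp, start = start, end = end, enz_left = cs$enzyme,
        site_left = cs$site_start, enz_right = cs$enzyme[nxt],
        site_right = cs$site_start[nxt], stringsAsFactors = FALSE)
    } else {
      bounds <- c(0L, cs$cut, L)
      nfr <- length(bounds) - 1L
      frag_list[[cp]] <- data.frame(
        copy = cp, start = bounds[-length(bounds)], end = bounds[-1],
        enz_left = c(NA_character_, cs$enzyme),
        site_left = c(NA_integer_, cs$site_start),
        enz_right = c(cs$enzyme, NA_character_),
        site_right = c(cs$site_start, NA_integer_),
        stringsAsFactors = FALSE)[seq_len(nfr), , drop = FALSE]
    }
  }
  out <- do.call(rbind, frag_list)
  rownames(out) <- NULL
  out
}

#' Select fragments by size
#'
#' @param fragments Fragment data frame from [digest()].
#' @param window `(min, max)` length window in bp.
#' @return The fragments within the window.
#' @export
size_select_fragments <- function(fragments, window) {
  len <- fragments$end - fragments$start
  out <- fragments[len >= window[1] & len <= window[2], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shear fragments and size-select the RAD-end pieces
#'
#' Each fragment end that carries a restriction cut yields one sheared
#' piece anchored at that end; the kept piece length is uniform over the
#' shear window (gel extraction dominates the retained length
#' distribution), truncated to the fragment length.  Fragments shorter
#' than the window minimum yield nothing; interior pieces carry no RAD tag
#' and are not emitted.
#'
#' @param fragments Fragment data frame from [digest()].
#' @param cfg A [sim_config()]; uses `shear_window`.
#' @return Data frame of pieces: fragment columns plus `rad_end`
#'   (`"left"`/`"right"`), `p_start`, `p_end` (0-based half-open).
#' @export
shear_and_select <- function(fragments, cfg = sim_config()) {
  win <- cfg$shear_window
  rows <- list()
  for (side in c("left", "right")) {
    enz_col <- paste0("enz_", side)
    has <- !is.na(fragments[[enz_col]])
    fr <- fragments[has, , drop = FALSE]
    if (!nrow(fr)) next
    flen <- fr$end - fr$start
    ok <- flen >= win[1]
    fr <- fr[ok, , drop = FALSE]
    flen <- flen[ok]
    if (!nrow(fr)) next
    plen <- floor(runif(nrow(fr), win[1], pmin(win[2], flen) + 1))
    plen <- pmin(plen, flen)
    fr$rad_end <- side
    fr$p_start <- if (side == "left") fr$start else fr$end - plen
    fr$p_end <- if (side == "left") fr$start + plen else fr$end
    rows[[length(rows) + 1L]] <- fr
  }
  if (!length(rows))
    return(cbind(fragments[0, , drop = FALSE],
                 data.frame(rad_end = character(0), p_start = integer(0),
                            p_end = integer(0))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# substring on a (possibly circular) haplotype; 1-based inclusive coords
# that may run past the end of the sequence
circ_substr <- function(seq, start, end) {
  L <- nchar(seq)
  if (end <= L && start >= 1) return(substr(seq, start, end))
  hay <- paste0(seq, seq)
  if (start < 1) { start <- start + L; end <- end + L }
  substr(hay, start, end)
}

mutate_reads <- function(seqs, error_rate, q_good = 40L, q_bad = 15L) {
  quals <- strrep(intToUtf8(33L + q_good), nchar(seqs))
  if (error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    bad_char <- intToUtf8(33L + q_bad)
    for (i in seq_along(seqs)) {
      n <- nchar(seqs[i])
      k <- rbinom(1L, n, error_rate)
      if (k == 0L) next
      at <- sample.int(n, k)
      s <- seqs[i]; q <- quals[i]
      for (p in at) {
        substr(s, p, p) <- sample(setdiff(bases, substr(s, p, p)), 1L)
        substr(q, p, p) <- bad_char
      }
      seqs[i] <- s; quals[i] <- q
    }
  }
  list(seq = seqs, qual = quals)
}

#' Emit read pairs from RAD-end pieces
#'
#' Read 1 starts inside the recognition site at the enzyme's tag offset
#' (after SbfI cutting `CCTGCA^GG`, read 1 begins `"TGCAGG..."`); read 2
#' is the reverse complement of the `read2_len` bases at the sheared end,
#' so the two reads point toward each other.  Substitution errors are
#' applied at `error_rate`, with quality 40 for correct bases and 15 for
#' errored ones.  Pieces shorter than `read1_len + read2_len` are
#' skipped.
#'
#' @param pieces Piece data frame from [shear_and_select()], optionally
#'   with `haplotype` and `sample` columns.
#' @param haplotypes Named character vector of haplotype sequences (or a
#'   single sequence / `synthetic_genome`).
#' @param cfg A [sim_config()].
#' @param sample Sample label when `pieces` has no `sample` column.
#' @param id_prefix Prefix for read identifiers.
#' @return List with `pairs` (a [rad_pairs]) and `truth` (read id,
#'   haplotype, read-2 0-based coords, strand, tag site).
#' @export
make_read_pairs <- function(pieces, haplotypes, cfg = sim_config(),
                            sample = "sample1", id_prefix = "rad") {
  if (inherits(haplotypes, "synthetic_genome"))
    haplotypes <- c(hap1 = haplotypes$sequence)
  if (is.null(names(haplotypes)))
    names(haplotypes) <- paste0("hap", seq_along(haplotypes))
  enz_tab <- rad_enzymes()
  r1 <- cfg$read1_len; r2 <- cfg$read2_len
  plen <- pieces$p_end - pieces$p_start
  keep <- plen >= (r1 + r2)
  pieces <- pieces[keep, , drop = FALSE]
  n <- nrow(pieces)
  if (!n)
    return(list(pairs = rad_pairs(character(0), character(0), character(0),
                                  character(0), character(0)),
                truth = data.frame()))
  hap_id <- if ("haplotype" %in% names(pieces)) pieces$haplotype
            else rep(names(haplotypes)[1], n)
  smp <- if ("sample" %in% names(pieces)) pieces$sample else sample

  seq1 <- character(n); seq2 <- character(n)
  t_start <- integer(n); t_end <- integer(n); t_strand <- character(n)
  for (i in seq_len(n)) {
    hap <- haplotypes[[hap_id[i]]]
    left <- pieces$rad_end[i] == "left"
    enz <- enz_tab[[if (left) pieces$enz_left[i] else pieces$enz_right[i]]]
    s0 <- if (left) pieces$site_left[i] else pieces$site_right[i]
    if (left) {
      a <- s0 + enz$tag_offset + 1L
      seq1[i] <- circ_substr(hap, a, a + r1 - 1L)
      t_start[i] <- pieces$p_end[i] - r2
      t_end[i] <- pieces$p_end[i]
      t_strand[i] <- "-"
      seq2[i] <- revcomp(circ_substr(hap, t_start[i] + 1L, t_end[i]))
    } else {
      b <- s0 + nchar(enz$site) - enz$tag_offset
      seq1[i] <- revcomp(circ_substr(hap, b - r1 + 1L, b))
      t_start[i] <- pieces$p_start[i]
      t_end[i] <- pieces$p_start[i] + r2
      t_strand[i] <- "+"
      seq2[i] <- circ_substr(hap, t_start[i] + 1L, t_end[i])
    }
  }
  ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
  m1 <- mutate_reads(seq1, cfg$error_rate)
  m2 <- mutate_reads(seq2, cfg$error_rate)
  pairs <- rad_pairs(ids, m1$seq, m1$qual, m2$seq, m2$qual, sample = smp)
  truth <- data.frame(id = ids, sample = smp, haplotype = hap_id,
                      read2_start = t_start, read2_end = t_end,
                      strand = t_strand,
                      site = if ("site_left" %in% names(pieces))
                        ifelse(pieces$rad_end == "left", pieces$site_left,
                               pieces$site_right) else NA_integer_,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth)
}

#' Simulate a partial-digest RAD paired-end run
#'
#' Each enzyme digests its own library (separate reactions, as on the
#' bench): `molecule_copies` copies of the genome are partially digested,
#' fragments are size-selected, and every surviving RAD tag (site and
#' facing direction) receives `cfg$depth` read pairs whose sheared-end
#' lengths are drawn uniformly from the shear window across that tag's
#' fragment instances.
#'
#' @param genome A `synthetic_genome`.
#' @param enzymes Enzymes (built-in names accepted); one library each.
#' @param cfg A [sim_config()]; `size_select` filters fragments,
#'   `shear_window` the sheared pieces, `partial_cut_prob`,
#'   `molecule_copies` and `depth` control the digest and coverage.
#' @param sample Sample label.
#' @param seed Optional RNG seed.
#' @return List with `pairs`, `truth`, and `fragments` (the size-selected
#'   digest fragments of all libraries).
#' @export
simulate_partial_digest_run <- function(genome,
                                        enzymes = c("NlaIII", "Sau3AI"),
                                        cfg = sim_config(), sample = "gDNA",
                                        seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  all_pieces <- list()
  all_frags <- list()
  for (ez in enzymes) {
    enz <- resolve_enzyme(ez)
    fr <- digest(genome, list(enz), cfg$partial_cut_prob,
                 cfg$molecule_copies)
    fr <- size_select_fragments(fr, cfg$size_select)
    all_frags[[enz$name]] <- fr
    if (!nrow(fr)) next
    # one row per RAD end instance
    ends <- rbind(
      transform(fr[!is.na(fr$enz_left), , drop = FALSE], rad_end = "left"),
      transform(fr[!is.na(fr$enz_right), , drop = FALSE], rad_end = "right"))
    if (!nrow(ends)) next
    key <- paste(ends$rad_end,
                 ifelse(ends$rad_end == "left", ends$site_left,
                        ends$site_right))
    groups <- split(seq_len(nrow(ends)), key)
    win <- cfg$shear_window
    picked <- lapply(groups, function(ix) {
      sel <- ix[sample.int(length(ix), cfg$depth, replace = TRUE)]
      g <- ends[sel, , drop = FALSE]
      flen <- g$end - g$start
      plen <- floor(runif(nrow(g), win[1], pmin(win[2], flen) + 1))
      plen <- pmin(plen, flen)
      g$p_start <- ifelse(g$rad_end == "left", g$start, g$end - plen)
      g$p_end <- ifelse(g$rad_end == "left", g$start + plen, g$end)
      g
    })
    all_pieces[[enz$name]] <- do.call(rbind, picked)
  }
  pieces <- do.call(rbind, all_pieces)
  if (is.null(pieces) || !nrow(pieces))
    return(list(pairs = rad_pairs(character(0), character(0), character(0),
                                  character(0), character(0)),
                truth = data.frame(), fragments = do.call(rbind, all_frags)))
  rownames(pieces) <- NULL
  rp <- make_read_pairs(pieces, genome, cfg, sample = sample)
  list(pairs = rp$pairs, truth = rp$truth,
       fragments = do.call(rbind, all_frags))
}

#' Simulate stand-alone RAD tag bins
#'
#' Direct per-locus model for assembly and SNP-calling studies: each bin
#' is an independent locus whose sequence begins with the SbfI tag
#' remnant (`"TGCAGG"`), with sheared-end reads tiling the locus uniformly
#' at the requested depth.  Optionally heterozygous SNPs are planted in
#' one sample while the other stays homozygous reference.
#'
#' @param n_bins Number of loci.
#' @param region_range `(min, max)` locus length in bp.
#' @param depth Per-sample read-2 fold coverage of the locus.
#' @param read1_len,read2_len Read lengths.
#' @param error_rate Per-base substitution error rate.
#' @param het_snps Heterozygous SNPs planted per locus in the first
#'   sample (0 disables).
#' @param samples Sample labels; the first carries the heterozygous
#'   variants.
#' @param seed Optional RNG seed.
#' @return List of bins; each has `locus` (reference sequence), `alt`
#'   (alternate haplotype or `NULL`), `variants`, `tag`, and `pairs`.
#' @export
simulate_tag_bins <- function(n_bins, region_range = c(300, 800),
                              depth = 30, read1_len = 60L, read2_len = 80L,
                              error_rate = 0, het_snps = 0L,
                              samples = c("low-110", "high-141"),
                              seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  lapply(seq_len(n_bins), function(b) {
    L <- floor(runif(1, region_range[1], region_range[2] + 1))
    locus <- paste0("TGCAGG",
                    generate_genome(L - 6L, 0.5, "linear")$sequence)
    alt <- NULL; variants <- NULL
    if (het_snps > 0L) {
      tr <- plant_variants(locus, n_snp = het_snps,
                           region = c(read1_len + 10L, L - 30L))
      alt <- tr$alt
      variants <- tr$variants
    }
    per_sample <- lapply(seq_along(samples), function(si) {
      n_reads <- max(1L, round(depth * L / read2_len))
      # the first sample is heterozygous: reads drawn from both haplotypes
      hap_of <- if (si == 1L && !is.null(alt))
        sample(c("ref", "alt"), n_reads, replace = TRUE)
      else rep("ref", n_reads)
      src <- ifelse(hap_of == "alt", alt, locus)
      starts <- floor(runif(n_reads, 0, nchar(src) - read2_len + 1))
      seq2 <- revcomp(substr(src, starts + 1L, starts + read2_len))
      seq1 <- substr(src, 1L, read1_len)
      m1 <- mutate_reads(seq1, error_rate)
      m2 <- mutate_reads(seq2, error_rate)
      list(pairs = rad_pairs(sprintf("bin%d_%s_%04d", b, samples[si],
                                     seq_len(n_reads)),
                             m1$seq, m1$qual, m2$seq, m2$qual,
                             sample = samples[si]),
           starts = starts, hap = hap_of)
    })
    pairs <- do.call(rbind, lapply(per_sample, `[[`, "pairs"))
    class(pairs) <- c("rad_pairs", "data.frame")
    list(locus = locus, alt = alt, variants = variants,
         tag = substr(locus, 1L, 39L), pairs = pairs,
         read_starts = lapply(per_sample, `[[`, "starts"))
  })
}

#' Simulate a long-insert RAD paired-end library
#'
#' Double circularization brings sequence 1-6 kb from the cut site to the
#' far end of a short sequencable fragment.  Per molecule and site: the
#' insert length L is uniform over `size_select`; the second shear offset
#' y is uniform over `(0, shear_mean - read2_len)`; read 2 is the reverse
#' complement of the `read2_len` bases ending at distance `L - y` from
#' the cut site, and read 1 is the usual tag read.  The junction position
#' within each final fragment is recorded.
#'
#' @param genome A `synthetic_genome`.
#' @param enzyme A rare cutter (default SbfI).
#' @param size_select `(min, max)` insert window in bp.
#' @param shear_mean Mean final-fragment length (second shear), bp.
#' @param molecules Molecules per site and facing direction.
#' @param cfg A [sim_config()] for read lengths and error rate.
#' @param sample Sample label.
#' @param seed Optional RNG seed.
#' @return List with `pairs`, `truth` (read-2 coordinates and per-fragment
#'   junction offset), and `sites` (0-based cut-site starts).
#' @export
simulate_long_insert <- function(genome, enzyme = "SbfI",
                                 size_select = c(1000, 6000),
                                 shear_mean = 600, molecules = 100L,
                                 cfg = sim_config(), sample = "longins",
                                 seed = NULL) {
  genome <- as_genome(genome)
  if (!is.null(seed)) withr::local_seed(seed)
  enz <- resolve_enzyme(enzyme)
  circular <- genome$topology == "circular"
  sites <- locate_sites(genome$sequence, enz, circular)
  r1 <- cfg$read1_len; r2 <- cfg$read2_len
  rows <- list()
  for (s0 in sites) {
    cut <- s0 + enz$cut_offset
    for (facing in c("right", "left")) {
      L_ins <- floor(runif(molecules, size_select[1], size_select[2] + 1))
      y <- floor(runif(molecules, 0, max(1, shear_mean - r2)))
      d <- L_ins - y                      # read-2 far-end distance from cut
      ok <- L_ins > (r1 + r2) & d >= r2
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        site = s0, facing = facing, insert_len = L_ins[ok], offset = y[ok],
        dist = d[ok], junction = pmax(0, shear_mean - y[ok] - r2),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(list(pairs = rad_pairs(character(0), character(0), character(0),
                                  character(0), character(0)),
                truth = data.frame(), sites = sites))
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  hap <- genome$sequence
  seq1 <- character(n); seq2 <- character(n)
  t_start <- integer(n); t_end <- integer(n); t_strand <- character(n)
  for (i in seq_len(n)) {
    s0 <- tab$site[i]
    cut <- s0 + enz$cut_offset
    if (tab$facing[i] == "right") {
      a <- s0 + enz$tag_offset + 1L
      seq1[i] <- circ_substr(hap, a, a + r1 - 1L)
      t_end[i] <- cut + tab$dist[i]
      t_start[i] <- t_end[i] - r2
      if (!circular && t_end[i] > genome$length) next  # off the molecule
      t_strand[i] <- "-"
      seq2[i] <- revcomp(circ_substr(hap, t_start[i] + 1L, t_end[i]))
    } else {
      b <- s0 + nchar(enz$site) - enz$tag_offset
      seq1[i] <- revcomp(circ_substr(hap, b - r1 + 1L, b))
      t_start[i] <- cut - tab$dist[i]
      t_end[i] <- t_start[i] + r2
      if (t_start[i] < 0) {
        if (!circular) next
        t_start[i] <- t_start[i] + genome$length
        t_end[i] <- t_end[i] + genome$length
      }
      t_strand[i] <- "+"
      seq2[i] <- circ_substr(hap, t_start[i] + 1L, t_end[i])
    }
  }
  ok <- nzchar(seq2)
  tab <- tab[ok, , drop = FALSE]
  seq1 <- seq1[ok]; seq2 <- seq2[ok]
  t_start <- t_start[ok]; t_end <- t_end[ok]; t_strand <- t_strand[ok]
  ids <- sprintf("li_%06d", seq_len(nrow(tab)))
  m1 <- mutate_reads(seq1, cfg$error_rate)
  m2 <- mutate_reads(seq2, cfg$error_rate)
  truth <- cbind(data.frame(id = ids, sample = sample,
                            read2_start = t_start, read2_end = t_end,
                            strand = t_strand, stringsAsFactors = FALSE),
                 tab)
  list(pairs = rad_pairs(ids, m1$seq, m1$qual, m2$seq, m2$qual,
                         sample = sample),
       truth = truth, sites = sites)
}

#' Monte-Carlo junction-containing read fraction
#'
#' For the long-insert construction the circularization junction sits at a
#' uniformly random position inside each final fragment; a read pair
#' "contains" the junction when it falls within the first `read1_len` or
#' last `read2_len` bases.  With 40+80 bp reads on ~600 bp fragments the
#' closed form is (40+80)/600 = 20%, within the library design bound of
#' 25%.
#'
#' @param n_fragments Number of simulated fragments.
#' @param fragment_len_mean Mean final-fragment length (bp).
#' @param read1_len,read2_len Read lengths (bp).
#' @param fragment_len_sd Normal SD of fragment length (0 = fixed);
#'   lengths are resampled until above `len_min`.
#' @param len_min Lower truncation for fragment lengths.
#' @param seed Optional RNG seed.
#' @return The junction-containing fraction in `[0, 1]`.
#' @export
junction_read_fraction <- function(n_fragments, fragment_len_mean,
                                   read1_len, read2_len,
                                   fragment_len_sd = 0, len_min = 200,
                                   seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (fragment_len_sd > 0) {
    len <- stats::rnorm(n_fragments, fragment_len_mean, fragment_len_sd)
    while (any(bad <- len <= len_min))
      len[bad] <- stats::rnorm(sum(bad), fragment_len_mean, fragment_len_sd)
  } else {
    len <- rep(fragment_len_mean, n_fragments)
  }
  if (read1_len + read2_len <= 0) return(0)
  j <- runif(n_fragments, 0, len)
  mean(j <= read1_len | j >= len - read2_len)
}
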