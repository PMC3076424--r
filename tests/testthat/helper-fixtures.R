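# Fixtures are built in code; no data files.

# read pairs with uniform quality q
toy_pairs <- function(seq1, seq2, sample = "s1", q = 40L) {
  qc <- intToUtf8(33L + q)
  rad_pairs(sprintf("r%04d", seq_along(seq1)), seq1,
            strrep(qc, nchar(seq1)), seq2, strrep(qc, nchar(seq2)),
            sample = sample)
}

# error-free 80 bp reads tiling `region` uniformly at `depth`x
tile_reads <- function(region, depth = 20, read_len = 80L) {
  n <- max(1L, round(depth * nchar(region) / read_len))
  starts <- floor(runif(n, 0, nchar(region) - read_len + 1))
  list(reads = substring(region, starts + 1L, starts + read_len),
       starts = starts)
}

rbind_pairs <- function(lst) {
  out <- do.call(rbind, lst)
  class(out) <- c("rad_pairs", "data.frame")
  out
}

# brute-force N50: largest contig length L such that contigs >= L sum to
# at least half the total
n50_brute <- function(lengths) {
  if (!length(lengths)) return(0)
  cand <- sort(unique(lengths))
  ok <- vapply(cand, function(L) sum(lengths[lengths >= L]) >= sum(lengths) / 2,
               logical(1))
  max(cand[ok])
}

canonical_seq <- function(x) pmin(x, revcomp(x))
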