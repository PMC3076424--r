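err_free_params <- function(...) assembly_params(cov_cutoff = 1, ...)

test_that("k-mer graphs are canonical and skip N", {
  g <- build_kmer_graph("ACGTACG", 5L)
  expect_equal(sum(g$count), 3)            # 3 k-mer occurrences
  g_rc <- build_kmer_graph(revcomp("ACGTACG"), 5L)
  expect_equal(g[c("kmer", "count")], g_rc[c("kmer", "count")])
  expect_equal(length(build_kmer_graph(character(0), 5L)$kmer), 0L)
  expect_equal(sum(build_kmer_graph("ACGNACGTA", 5L)$count), 1)
  expect_error(build_kmer_graph("ACGT", 4L), "odd")
})

test_that("a linear chain of 6 nodes at k=5 spells a 10 bp contig", {
  withr::local_seed(21)
  repeat {
    s <- generate_genome(10L)$sequence
    g <- build_kmer_graph(s, 5L)
    if (length(g$kmer) == 6L) break       # all 6 k-mers distinct
  }
  ct <- extract_contigs(g, min_contig_length = 1L)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$length, 10L)
  expect_equal(ct$sequence, min(s, revcomp(s)))
  expect_equal(nrow(extract_contigs(build_kmer_graph(character(0), 5L), 1L)),
               0L)
})

test_that("clean tiled reads reassemble the region exactly", {
  withr::local_seed(22)
  region <- generate_genome(400L)$sequence
  tl <- tile_reads(region, depth = 20)
  g <- simplify_graph(build_kmer_graph(tl$reads, 21L), err_free_params())
  ct <- extract_contigs(g, 100L)
  span <- substr(region, min(tl$starts) + 1L, max(tl$starts) + 80L)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$sequence, min(span, revcomp(span)))
})

test_that("a terminal sequencing error is clipped as a tip", {
  withr::local_seed(23)
  region <- generate_genome(400L)$sequence
  tl <- tile_reads(region, depth = 20)
  clean <- extract_contigs(
    simplify_graph(build_kmer_graph(tl$reads, 21L), err_free_params()), 100L)
  reads <- tl$reads
  last <- substr(reads[5], 80, 80)
  substr(reads[5], 80, 80) <- setdiff(c("A", "C", "G", "T"), last)[1]
  dirty <- extract_contigs(
    simplify_graph(build_kmer_graph(reads, 21L), err_free_params()), 100L)
  # the error branch is clipped as a tip; the contig sequence is unchanged
  # (mean k-mer coverage differs by the one lost read end)
  expect_equal(dirty$sequence, clean$sequence)
})

test_that("a balanced single-substitution bubble merges to one contig", {
  withr::local_seed(24)
  region <- generate_genome(400L)$sequence
  alt <- region
  old <- substr(alt, 200, 200)
  substr(alt, 200, 200) <- setdiff(c("A", "C", "G", "T"), old)[1]
  tl <- tile_reads(region, depth = 10)
  tl2 <- tile_reads(alt, depth = 10)
  reads <- c(tl$reads, tl2$reads)
  g_raw <- build_kmer_graph(reads, 21L)
  unmerged <- extract_contigs(g_raw, 100L)
  merged <- extract_contigs(simplify_graph(g_raw, err_free_params()), 100L)
  expect_gt(nrow(unmerged), 1L)  # branch before simplification
  expect_equal(nrow(merged), 1L)
})

test_that("predict_k is the documented monotone step map", {
  expect_equal(predict_k(8), 21L)
  expect_equal(predict_k(50), 29L)
  expect_equal(predict_k(500), 31L)
  ks <- vapply(c(0, 5, 9.9, 10, 29, 30, 99, 100, 1e4), predict_k, 0L)
  expect_true(all(diff(ks) >= 0L))
})

test_that("best-of-three keeps the longest total assembly", {
  withr::local_seed(25)
  region <- generate_genome(500L)$sequence
  tl <- tile_reads(region, depth = 25)
  bin <- toy_pairs(rep(strrep("T", 45L), length(tl$reads)), tl$reads)
  res <- assemble_bin_best_of_three(bin, err_free_params())
  expect_s3_class(res, "rad_assembly")
  expect_equal(nrow(res$trials), 3L)
  expect_equal(res$total_assembled_length, max(res$trials$total_length))
  expect_true(res$chosen_k %in% res$trials$k)
  winners <- res$trials[res$trials$total_length ==
                          max(res$trials$total_length), ]
  if (nrow(winners) > 1L) {
    top <- winners[winners$n50 == max(winners$n50), ]
    expect_equal(res$chosen_k, min(top$k))
  }
  # empty bin -> zero contigs, no error
  res0 <- assemble_bin_best_of_three(bin[0, ], err_free_params())
  expect_equal(nrow(res0$contigs), 0L)
  expect_equal(res0$total_assembled_length, 0L)
})

test_that("assembly is strand-invariant and deterministic", {
  withr::local_seed(26)
  for (i in 1:10) {
    region <- generate_genome(sample(300:600, 1))$sequence
    tl <- tile_reads(region, depth = 20)
    a <- extract_contigs(
      simplify_graph(build_kmer_graph(tl$reads, 21L), err_free_params()),
      100L)
    b <- extract_contigs(
      simplify_graph(build_kmer_graph(revcomp(tl$reads), 21L),
                     err_free_params()), 100L)
    expect_equal(a, b)
    a2 <- extract_contigs(
      simplify_graph(build_kmer_graph(tl$reads, 21L), err_free_params()),
      100L)
    expect_identical(a, a2)
  }
})

test_that("two-pass long-insert assembly bridges repeats beyond pass-2 k", {
  gen <- generate_genome(5300L, 0.5, "linear", seed = 15)
  gen <- plant_restriction_sites(gen, "SbfI", 101L)
  s <- gen$sequence
  substr(s, 3500, 3533) <- substr(s, 1500, 1533)  # exact 34 bp repeat
  gen$sequence <- s
  sim <- simulate_long_insert(gen, "SbfI", size_select = c(200, 5100),
                              shear_mean = 600, molecules = 1800,
                              cfg = sim_config(error_rate = 0), seed = 16)
  bins <- bin_by_tag(sim$pairs, 39L)
  bin <- bins$bins[[which.max(vapply(bins$bins, nrow, 0L))]]
  single <- assemble_bin_best_of_three(
    bin, assembly_params(k = 25L, k_low = 25L, k_high = 25L),
    region_length_estimate = 5000)
  two <- assemble_long_insert_two_pass(bin, assembly_params(),
                                       region_length_estimate = 5000)
  expect_lt(nrow(two$contigs), nrow(single$contigs))
  expect_gt(n50(two$contigs$length), n50(single$contigs$length))
})

test_that("a clean non-repetitive 3 kb long-insert region gives one contig", {
  gen <- generate_genome(3200L, 0.5, "linear", seed = 31)
  gen <- plant_restriction_sites(gen, "SbfI", 51L)
  sim <- simulate_long_insert(gen, "SbfI", size_select = c(200, 2900),
                              shear_mean = 600, molecules = 1500,
                              cfg = sim_config(error_rate = 0), seed = 32)
  bins <- bin_by_tag(sim$pairs, 39L)
  bin <- bins$bins[[which.max(vapply(bins$bins, nrow, 0L))]]
  res <- assemble_long_insert_two_pass(bin, assembly_params(),
                                       region_length_estimate = 3000)
  # one dominant contig spans the read-covered region; read density tapers
  # over the last shear_mean - read2_len bases, which may leave a short
  # disconnected tail contig
  expect_lte(nrow(res$contigs), 2L)
  tr <- sim$truth[sim$truth$id %in% bin$id, ]
  span_lo <- min(tr$read2_start); span_hi <- max(tr$read2_end)
  expect_gt(max(res$contigs$length), 0.90 * (span_hi - span_lo))
  # every contig is an exact substring of the genome
  for (sq in res$contigs$sequence)
    expect_true(grepl(sq, gen$sequence, fixed = TRUE) ||
                  grepl(revcomp(sq), gen$sequence, fixed = TRUE))
})
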