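test_that("genome generation is seeded, honours GC, and counts sites as expected", {
  g1 <- generate_genome(1000L, seed = 61)
  g2 <- generate_genome(1000L, seed = 61)
  expect_identical(g1$sequence, g2$sequence)
  g0 <- generate_genome(500L, gc_fraction = 0, seed = 62)
  expect_true(grepl("^[AT]+$", g0$sequence))
  # GATC count on 100 kb at GC 0.5: binomial around L/256
  g <- generate_genome(100000L, seed = 63)
  n_gatc <- length(gregexpr("GATC", g$sequence, fixed = TRUE)[[1]])
  expected <- 100000 / 256
  expect_lt(abs(n_gatc - expected), 3 * sqrt(expected))
  expect_error(generate_genome(0), "positive")
})

test_that("planted variants respect counts and spacing", {
  tr1 <- plant_variants(generate_genome(500L, seed = 64), n_snp = 1L,
                        seed = 65)
  d <- which(strsplit(tr1$ref, "")[[1]] != strsplit(tr1$alt, "")[[1]])
  expect_equal(length(d), 1L)
  expect_equal(d, tr1$variants$pos)
  tr0 <- plant_variants(generate_genome(500L, seed = 64), n_snp = 0L)
  expect_identical(tr0$ref, tr0$alt)
  tr50 <- plant_variants(generate_genome(100000L, seed = 66), n_snp = 50L,
                         seed = 67)
  expect_true(all(diff(sort(tr50$variants$pos)) >= 10L))
  expect_error(plant_variants(generate_genome(200L, seed = 1), n_snp = 50L),
               "too many")
})

test_that("complete digestion conserves the genome and partial digestion thins cuts", {
  gen <- generate_genome(3000L, seed = 68)
  gen <- plant_restriction_sites(gen, "Sau3AI", 1501L)
  fr <- digest(gen, "Sau3AI", partial_cut_prob = 1)
  expect_equal(nrow(fr), 2L)
  expect_equal(paste0(substr(gen$sequence, fr$start[1] + 1, fr$end[1]),
                      substr(gen$sequence, fr$start[2] + 1, fr$end[2])),
               gen$sequence)
  expect_equal(fr$enz_right[1], "Sau3AI")
  expect_true(is.na(fr$enz_left[1]) && is.na(fr$enz_right[2]))
  # probability 0: one uncut fragment per molecule copy
  fr0 <- digest(gen, "Sau3AI", partial_cut_prob = 0, molecule_copies = 3L)
  expect_equal(nrow(fr0), 3L)
  expect_true(all(fr0$end - fr0$start == 3000L))
})

test_that("partial digestion of a circular genome gives geometric fragment lengths", {
  gen <- generate_genome(100000L, 0.5, "circular", seed = 69)
  fr <- digest(gen, c("NlaIII", "Sau3AI"), partial_cut_prob = 0.5,
               molecule_copies = 50L, seed = 70)
  # mean spacing of two 4-cutters ~128 bp; thinning at p = 0.5 doubles it
  expect_lt(abs(mean(fr$end - fr$start) - 256) / 256, 0.1)
  # circular: no terminal (non-RAD) fragment ends
  expect_false(any(is.na(fr$enz_left)))
  expect_false(any(is.na(fr$enz_right)))
})

test_that("shearing keeps RAD-end pieces inside the selection window", {
  gen <- generate_genome(30000L, seed = 71)
  fr <- digest(gen, "NlaIII", partial_cut_prob = 0.3, molecule_copies = 5L,
               seed = 72)
  fr <- size_select_fragments(fr, c(1000, 5000))
  cfg <- sim_config(shear_window = c(300, 800))
  withr::local_seed(73)
  pieces <- shear_and_select(fr, cfg)
  len <- pieces$p_end - pieces$p_start
  expect_true(all(len >= 300 & len <= 800))
  expect_true(all(table(interaction(pieces$copy, pieces$start)) <= 2L))
  # sheared-end distances are close to uniform over the window
  long <- fr[fr$end - fr$start >= 800, , drop = FALSE]
  reps <- do.call(rbind, rep(list(long), 400L))
  lens <- with(shear_and_select(reps, cfg), p_end - p_start)
  ks <- suppressWarnings(stats::ks.test(lens, "punif", 300, 800))
  expect_gt(ks$statistic[["D"]], 0)       # defined
  expect_lt(ks$statistic[["D"]], 0.05)    # near-uniform
})

test_that("read pairs start with the enzyme tag remnant and match the truth", {
  gen <- generate_genome(20000L, seed = 74)
  for (case in list(c("SbfI", "TGCAGG"), c("NlaIII", "CATG"),
                    c("Sau3AI", "GATC"))) {
    gen2 <- plant_restriction_sites(gen, case[1],
                                    c(3001L, 8001L, 14001L))
    fr <- digest(gen2, case[1], partial_cut_prob = 1)
    cfg <- sim_config(shear_window = c(300, 800), error_rate = 0)
    withr::local_seed(75)
    pieces <- shear_and_select(fr, cfg)
    rp <- make_read_pairs(pieces, gen2, cfg)
    expect_gt(nrow(rp$pairs), 0L)
    expect_true(all(startsWith(rp$pairs$seq1, case[2])))
    # error-free reads are exact haplotype substrings (up to revcomp)
    for (i in seq_len(nrow(rp$pairs))) {
      tr <- rp$truth[i, ]
      sub <- substr(gen2$sequence, tr$read2_start + 1L, tr$read2_end)
      expect_equal(rp$pairs$seq2[i],
                   if (tr$strand == "-") revcomp(sub) else sub)
    }
  }
})

test_that("sequencing errors appear at the configured binomial rate", {
  withr::local_seed(76)
  src <- vapply(1:2000, function(i) generate_genome(80L)$sequence, "")
  m <- radpe:::mutate_reads(src, error_rate = 0.01)
  mism <- sum(vapply(seq_along(src), function(i)
    sum(strsplit(m$seq[i], "")[[1]] != strsplit(src[i], "")[[1]]), 0L))
  expected <- 2000 * 80 * 0.01
  expect_lt(abs(mism - expected), 3 * sqrt(expected))
  # errored bases carry the low quality score
  bad <- phred_scores(m$qual[which(m$seq != src)[1]])
  expect_true(any(bad == 15L))
})

test_that("long-insert geometry matches the stated interval arithmetic", {
  gen <- generate_genome(9000L, seed = 77)
  gen <- plant_restriction_sites(gen, "SbfI", 101L)
  cfg <- sim_config(read1_len = 40L, read2_len = 80L, error_rate = 0)
  sim <- simulate_long_insert(gen, "SbfI", size_select = c(1000, 6000),
                              shear_mean = 600, molecules = 600L,
                              cfg = cfg, seed = 78)
  cut <- 100L + 6L  # site at 101 (1-based), SbfI cuts CCTGCA^GG
  right <- sim$truth[sim$truth$facing == "right", ]
  d <- right$read2_end - cut
  expect_true(all(d >= 80L & d <= 6000L))
  expect_gt(max(d), 5000L)
  expect_lt(min(d), 1500L)
  expect_equal(nrow(sim$truth), nrow(sim$pairs))
  expect_true(all(startsWith(sim$pairs$seq1, "TGCAGG")))
  expect_true(all(!is.na(sim$truth$junction)))   # one junction per fragment
  # fixed insert length with zero shear offset: read 2 ends exactly at L
  sim2 <- simulate_long_insert(gen, "SbfI", size_select = c(3000, 3000),
                               shear_mean = 80, molecules = 20L,
                               cfg = cfg, seed = 79)
  r2 <- sim2$truth[sim2$truth$facing == "right", ]
  expect_true(all(r2$read2_end - cut == 3000L))
})

test_that("junction fraction follows the closed form (r1+r2)/len", {
  fr <- junction_read_fraction(100000L, 600, 40L, 80L, seed = 80)
  expect_lt(abs(fr - 120 / 600), 0.01)
  expect_equal(junction_read_fraction(1000L, 600, 0L, 0L, seed = 81), 0)
  expect_equal(junction_read_fraction(1000L, 120, 40L, 80L, seed = 82), 1)
})

test_that("simulators are deterministic under a seed", {
  gen <- generate_genome(20000L, 0.5, "circular", seed = 83)
  cfg <- sim_config(size_select = c(1000, 5000), molecule_copies = 10L,
                    depth = 10L)
  a <- simulate_partial_digest_run(gen, c("NlaIII", "Sau3AI"), cfg, seed = 84)
  b <- simulate_partial_digest_run(gen, c("NlaIII", "Sau3AI"), cfg, seed = 84)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$truth, b$truth)
})
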