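test_that("seed-and-extend alignment recovers exact, reverse and gapped placements", {
  withr::local_seed(41)
  contig <- generate_genome(400L)$sequence
  aln <- align_read_to_contig(contig, substr(contig, 51, 130))
  expect_equal(aln$start, 51L)
  expect_equal(aln$strand, "+")
  expect_equal(aln$cigar, "80M")
  expect_equal(aln$ref_pos, 51:130)
  rc <- align_read_to_contig(contig, revcomp(substr(contig, 51, 130)))
  expect_equal(rc$start, 51L)
  expect_equal(rc$strand, "-")
  # 2 bp insertion at a known point
  rd <- paste0(substr(contig, 51, 90), "GG", substr(contig, 91, 128))
  gapped <- align_read_to_contig(contig, rd)
  expect_equal(gapped$cigar, "40M2I38M")
  expect_equal(gapped$ins_ref_pos, 90L)
  expect_equal(gapped$ins_seq, "GG")
  # junk does not align
  expect_null(align_read_to_contig(contig, strrep("ACAC", 20L)))
})

test_that("pileups count agreeing bases and honour the quality floor", {
  withr::local_seed(40)
  contig <- generate_genome(120L)$sequence
  read <- substr(contig, 11, 50)
  alns <- lapply(1:10, function(i) {
    a <- align_read_to_contig(contig, read)
    a$sample <- "s1"
    a
  })
  pile <- build_pileup(contig, alns)
  expect_equal(unique(pile$count), 10L)
  expect_equal(nrow(pile), 40L)
  # one read with a qual-19 base is excluded at that position
  low <- align_read_to_contig(contig, read, qual = c(19L, rep(40L, 39L)))
  low$sample <- "s1"
  pile2 <- build_pileup(contig, c(alns, list(low)))
  expect_equal(pile2$count[pile2$pos == 11L], 10L)
  expect_equal(unique(pile2$count[pile2$pos > 11L]), 11L)
})

test_that("threshold calls need at least four instances of an allele", {
  col <- data.frame(sample = "low", allele = c("C", "A"), count = c(10L, 4L))
  expect_equal(unname(call_site(col, ref_base = "C")), "[C/A]")
  col$count <- c(10L, 3L)
  expect_equal(unname(call_site(col, ref_base = "C")), "C")
  # total coverage 3 -> no call
  col3 <- data.frame(sample = "low", allele = "C", count = 3L)
  expect_equal(unname(call_site(col3, ref_base = "C")), "-")
  # three passing alleles -> no call (multi-allelic)
  colm <- data.frame(sample = "low", allele = c("A", "C", "G"),
                     count = c(5L, 5L, 5L))
  expect_equal(unname(call_site(colm, ref_base = "C")), "-")
  # non-reference heterozygote orders by count
  colh <- data.frame(sample = "low", allele = c("G", "T"), count = c(4L, 9L))
  expect_equal(unname(call_site(colh, ref_base = "C")), "[T/G]")
})

test_that("call_site is sample-permutation-invariant and monotone in the threshold", {
  withr::local_seed(42)
  col <- data.frame(sample = rep(c("a", "b"), each = 3L),
                    allele = rep(c("A", "C", "T"), 2L),
                    count = sample(0:12, 6L))
  g1 <- call_site(col, ref_base = "A")
  g2 <- call_site(col[sample(nrow(col)), ], ref_base = "A")
  expect_equal(g1, g2[names(g1)])
  # at bi-allelic columns, raising the threshold never adds a genotype allele
  col2 <- data.frame(sample = rep(c("a", "b"), each = 2L),
                     allele = rep(c("A", "C"), 2L),
                     count = c(9L, 4L, 3L, 11L))
  thresholds <- c(1L, 2L, 4L, 6L, 10L, 12L)
  for (s in c("a", "b")) {
    prev <- NULL
    for (th in thresholds) {
      al <- radpe:::geno_alleles(call_site(col2, th, "A")[[s]])
      if (!is.null(prev)) expect_true(all(al %in% prev))
      prev <- al
    }
  }
})

make_het_bin <- function(L = 500L, depth = 30, n_snp = 1L, seed = 43,
                         type = "snp") {
  withr::local_seed(seed)
  locus <- paste0("TGCAGG", generate_genome(L - 6L)$sequence)
  tr <- plant_variants(locus, n_snp = if (type == "snp") n_snp else 0L,
                       n_ins = if (type == "ins") 1L else 0L,
                       region = c(80L, L - 60L))
  mk <- function(src, sample, n) {
    tl <- tile_reads(src, depth = depth)
    toy_pairs(rep(substr(locus, 1, 45), length(tl$reads)),
              revcomp(tl$reads), sample = sample)
  }
  n_each <- round(depth * L / 80)
  pairs <- rbind_pairs(list(mk(tr$ref, "low-110", n_each),
                            mk(tr$alt, "low-110", n_each),
                            mk(tr$ref, "high-141", n_each),
                            mk(tr$ref, "high-141", n_each)))
  list(pairs = pairs, locus = locus, truth = tr)
}

test_that("a planted heterozygous SNP yields exactly one correct record", {
  hb <- make_het_bin(L = 500L, depth = 20, seed = 44)
  res <- assemble_bin_best_of_three(hb$pairs, assembly_params(cov_cutoff = 1))
  res$tag <- substr(hb$locus, 1, 39)
  recs <- call_bin_snps(res, hb$pairs, tag_index = 1L)
  expect_equal(nrow(recs), 1L)
  # map the contig position back to the locus
  ctg <- res$contigs$sequence[1]
  fwd <- regexpr(ctg, hb$locus, fixed = TRUE)
  if (fwd > 0) {
    locus_pos <- as.integer(fwd) + recs$pos - 1L
    alt_seen <- radpe:::geno_alleles(recs$`low-110`)
  } else {
    rcp <- regexpr(revcomp(ctg), hb$locus, fixed = TRUE)
    expect_gt(rcp, 0L)
    locus_pos <- as.integer(rcp) + nchar(ctg) - recs$pos
    alt_seen <- revcomp(radpe:::geno_alleles(recs$`low-110`))
  }
  expect_equal(locus_pos, hb$truth$variants$pos)
  expect_true(hb$truth$variants$alt %in% alt_seen)
  expect_true(hb$truth$variants$ref %in% alt_seen)  # heterozygote
  expect_false(grepl("\\[", recs$`high-141`))       # homozygous sample
})

test_that("identical samples with no variants yield zero records", {
  withr::local_seed(45)
  for (i in 1:5) {
    locus <- paste0("TGCAGG", generate_genome(400L)$sequence)
    tl1 <- tile_reads(locus, 20); tl2 <- tile_reads(locus, 20)
    pairs <- rbind_pairs(list(
      toy_pairs(rep(substr(locus, 1, 45), length(tl1$reads)),
                revcomp(tl1$reads), "low-110"),
      toy_pairs(rep(substr(locus, 1, 45), length(tl2$reads)),
                revcomp(tl2$reads), "high-141")))
    res <- assemble_bin_best_of_three(pairs, assembly_params(cov_cutoff = 1))
    res$tag <- substr(locus, 1, 39)
    expect_equal(nrow(call_bin_snps(res, pairs, tag_index = i)), 0L)
  }
})

test_that("a planted heterozygous insertion is called under the same rule", {
  hb <- make_het_bin(L = 500L, depth = 25, seed = 46, type = "ins")
  res <- assemble_bin_best_of_three(hb$pairs, assembly_params(cov_cutoff = 1))
  res$tag <- substr(hb$locus, 1, 39)
  recs <- call_bin_snps(res, hb$pairs, tag_index = 1L)
  expect_equal(nrow(recs), 1L)
  gt <- c(radpe:::geno_alleles(recs$`low-110`),
          radpe:::geno_alleles(recs$`high-141`))
  expect_true(any(grepl("^[+-]", gt)))
})

test_that("the two-line SNP report matches the published dialect and round-trips", {
  recs <- data.frame(
    header = rep(paste0("32831_TGCAGGAGTATTGACTGAACTTTTAACCCCCATGCTGCT_",
                        "NODE_1_length_338_cov_9.647929"), 3L),
    pos = c(212L, 34L, 76L), ref = c("C", "G", "T"),
    stringsAsFactors = FALSE)
  recs[["low-110"]] <- c("[C/A]", "[G/T]", "[T/A]")
  recs[["high-141"]] <- c("C", "-", "[T/A]")
  attr(recs, "samples") <- c("low-110", "high-141")
  class(recs) <- c("snp_records", "data.frame")
  f <- withr::local_tempfile()
  write_snp_report(recs, f)
  lines <- readLines(f)
  expect_equal(lines[2], "212 C low-110 [C/A] high-141 C")
  expect_equal(lines[4], "34 G low-110 [G/T] high-141 -")
  expect_equal(lines[6], "76 T low-110 [T/A] high-141 [T/A]")
  back <- read_snp_report(f)
  expect_equal(back$pos, recs$pos)
  expect_equal(back[["low-110"]], recs[["low-110"]])
  expect_equal(back[["high-141"]], recs[["high-141"]])
  # no records -> empty file, still parseable
  f0 <- withr::local_tempfile()
  write_snp_report(recs[0, ], f0)
  expect_equal(nrow(read_snp_report(f0)), 0L)
})

test_that("VCF output encodes genotypes and is readable by vcfR", {
  skip_if_not_installed("vcfR")
  recs <- data.frame(header = c("tagA", "tagA"), pos = c(212L, 76L),
                     ref = c("C", "T"), stringsAsFactors = FALSE)
  recs[["low-110"]] <- c("[C/A]", "[T/A]")
  recs[["high-141"]] <- c("C", "[T/A]")
  attr(recs, "samples") <- c("low-110", "high-141")
  class(recs) <- c("snp_records", "data.frame")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(recs, f)
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  expect_equal(unname(gt[1, ]), c("0/1", "0/0"))
  expect_equal(unname(gt[2, ]), c("0/1", "0/1"))
  expect_equal(unname(v@fix[, "REF"]), c("C", "T"))
  expect_equal(unname(v@fix[, "ALT"]), c("A", "A"))
})

test_that("bi-allelic tags pair at Hamming distance 1 with balanced counts", {
  withr::local_seed(47)
  # one locus, SNP inside the tag and one downstream variant
  locus_a <- paste0("TGCAGG", generate_genome(494L)$sequence)
  locus_b <- locus_a
  substr(locus_b, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                     substr(locus_a, 20, 20))[1]
  substr(locus_b, 300, 300) <- setdiff(c("A", "C", "G", "T"),
                                       substr(locus_a, 300, 300))[1]
  mkbin <- function(locus, n) {
    tl <- tile_reads(locus, depth = 20)
    toy_pairs(rep(substr(locus, 1, 45), length(tl$reads)),
              revcomp(tl$reads), sample = "low-110")
  }
  pairs <- rbind_pairs(list(mkbin(locus_a), mkbin(locus_b)))
  bins <- bin_by_tag(pairs, 39L)
  expect_equal(length(bins$tags), 2L)
  results <- lapply(bins$bins, assemble_bin_best_of_three,
                    params = assembly_params(cov_cutoff = 1))
  for (i in seq_along(results)) results[[i]]$tag <- bins$tags[i]
  names(results) <- bins$tags
  hp <- pair_biallelic_tags(bins, results)
  expect_equal(length(hp), 1L)
  expect_equal(sort(c(hp[[1]]$tag_a, hp[[1]]$tag_b)),
               sort(substr(c(locus_a, locus_b), 1, 39)))
  expect_gt(nrow(hp[[1]]$variants), 0L)  # downstream difference is phased
})

test_that("distant or unbalanced tags are not paired", {
  withr::local_seed(48)
  tag_a <- paste(sample(c("A", "C", "G", "T"), 39, replace = TRUE),
                 collapse = "")
  tag_b <- tag_a
  substr(tag_b, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(tag_a, 5, 5))[1]
  substr(tag_b, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(tag_a, 9, 9))[1]
  p <- toy_pairs(paste0(c(rep(tag_a, 40L), rep(tag_b, 40L)), "A"),
                 rep(strrep("G", 60L), 80L))
  bins <- bin_by_tag(p, 39L)
  results <- setNames(vector("list", 2L), bins$tags)
  expect_equal(length(pair_biallelic_tags(bins, results)), 0L)  # Hamming 2
  # Hamming 1 but 6:1 count imbalance
  tag_c <- tag_a
  substr(tag_c, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(tag_a, 5, 5))[1]
  p2 <- toy_pairs(paste0(c(rep(tag_a, 60L), rep(tag_c, 10L)), "A"),
                  rep(strrep("G", 60L), 70L))
  bins2 <- bin_by_tag(p2, 39L)
  results2 <- setNames(vector("list", 2L), bins2$tags)
  expect_equal(length(pair_biallelic_tags(bins2, results2)), 0L)
})
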