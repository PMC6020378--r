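test_that("PAM scan matches a constructed singleton and edge cases", {
  # one valid +strand NGG at the only fitting offset
  g <- c(chrT = paste0(strrep("A", 20), "TGG", "TA"))
  sites <- scan_pam_sites(g)
  plus <- sites[sites$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 0L)
  expect_equal(plus$sequence23, paste0(strrep("A", 20), "TGG"))
  # too short
  expect_equal(nrow(scan_pam_sites(c(x = "ACGTACGT"))), 0L)
  # windows overlapping N are skipped and counted
  gn <- c(chrN = paste0(strrep("A", 10), "N", strrep("A", 9), "TGG"))
  sn <- scan_pam_sites(gn)
  expect_equal(nrow(sn), 0L)
  expect_gte(attr(sn, "n_skipped"), 1L)
})

test_that("PAM scan equals the brute-force oracle on a random genome", {
  genome <- gen_genome(12000, gc = 0.5, seed = 31)
  sites <- scan_pam_sites(genome)
  oracle <- brute_pam_scan(genome)
  expect_equal(nrow(sites), nrow(oracle))
  expect_equal(sites$start, oracle$start)
  expect_equal(sites$strand, oracle$strand)
  expect_equal(sites$sequence23, oracle$sequence23)
})

test_that("strand symmetry: reverse-complementing the genome mirrors the site set", {
  genome <- gen_genome(4000, gc = 0.45, seed = 32)
  L <- nchar(genome[[1]])
  rc <- reverse_complement(genome[[1]])
  s1 <- scan_pam_sites(genome)
  s2 <- scan_pam_sites(stats::setNames(rc, names(genome)))
  # a + site at start s maps to a - site at L - s - 23 on the reverse
  m1 <- s1[order(s1$start, s1$strand), ]
  m2 <- s2[order(s2$start, s2$strand), ]
  remapped <- data.frame(start = L - m2$start - 23L,
                         strand = ifelse(m2$strand == "+", "-", "+"),
                         sequence23 = m2$sequence23)
  remapped <- remapped[order(remapped$start, remapped$strand), ]
  expect_equal(remapped$start, m1$start)
  expect_equal(remapped$strand, m1$strand)
  expect_setequal(remapped$sequence23, m1$sequence23)
})

test_that("candidate enumeration finds a planted guide and respects the cap", {
  genome <- gen_genome(20000, gc = 0.5, seed = 33)
  set.seed(34)
  guide <- random_guide_seq()
  s <- genome[[1]]
  substr(s, 5001, 5023) <- guide
  genome[[1]] <- s
  cand <- enumerate_candidates(guide, genome)
  planted <- cand[cand$mismatch_count == 0L, ]
  expect_true(any(planted$start == 5000L & planted$strand == "+"))
  # a 7-mismatch site is absent at max_mm = 6
  seven <- paste0(chartr("ACGT", "CGTA", substr(guide, 1, 7)),
                  substr(guide, 8, 23))
  expect_gte(brute_hamming20(seven, guide), 7L)
  s2 <- genome[[1]]
  substr(s2, 8001, 8023) <- seven
  genome[[1]] <- s2
  cand2 <- enumerate_candidates(guide, genome)
  expect_false(any(cand2$start == 8000L & cand2$strand == "+"))
})

test_that("per-stratum candidate counts equal a brute-force Hamming scan", {
  genome <- gen_genome(60000, gc = 0.41, seed = 35)
  guide <- scan_pam_sites(genome)$sequence23[10]
  sites <- scan_pam_sites(genome)
  brute_mm <- vapply(sites$sequence23, brute_hamming20, numeric(1), b = guide)
  for (max_mm in 0:6) {
    cand <- enumerate_candidates(guide, genome, max_mm = max_mm,
                                 sites = sites)
    expect_equal(nrow(cand), sum(brute_mm <= max_mm))
    if (nrow(cand)) {
      expect_equal(unname(table(factor(cand$mismatch_count, levels = 0:max_mm))),
                   unname(table(factor(brute_mm[brute_mm <= max_mm],
                                       levels = 0:max_mm))))
    }
  }
})

test_that("mismatch profiles list protospacer substitutions in order", {
  g <- paste0(strrep("A", 20), "AGG")
  expect_equal(nrow(mismatch_profile(g, g)), 0L)
  s <- g
  substr(s, 16, 16) <- "C"
  p <- mismatch_profile(paste0(strrep("A", 15), "G", strrep("A", 4), "AGG"), s)
  expect_equal(p$position, 16L)
  expect_equal(p$from, "G")
  expect_equal(p$to, "C")
  # PAM differences are not mismatches
  s2 <- paste0(strrep("A", 20), "TGG")
  expect_equal(nrow(mismatch_profile(g, s2)), 0L)
  # profile length equals direct Hamming distance on random pairs
  set.seed(36)
  for (i in 1:20) {
    a <- random_guide_seq(); b <- random_guide_seq()
    expect_equal(nrow(mismatch_profile(a, b)), brute_hamming20(a, b))
  }
})

test_that("pair assembly labels detections and reports unmatched rows", {
  set.seed(37)
  cand <- data.frame(guide_id = "g1", chrom = "chr1",
                     start = seq(0, 2490, by = 10), end = seq(23, 2513, by = 10),
                     strand = "+", site_sequence = replicate(250, random_guide_seq()),
                     mismatch_count = sample(0:6, 250, TRUE),
                     mismatch_profile = "", stringsAsFactors = FALSE)
  det <- data.frame(guide_id = "g1", chrom = "chr1", start = 100L,
                    strand = "+", assay = "guideseq",
                    indel_frequency = 0.12, stringsAsFactors = FALSE)
  ds <- assemble_pair_dataset(cand, det)
  expect_equal(sum(ds$detected), 1L)
  expect_equal(sum(ds$detected == 0L), 249L)
  expect_equal(ds$indel_frequency[ds$detected == 1L], 0.12)
  # empty detections -> all zero
  ds0 <- assemble_pair_dataset(cand, det[0, ])
  expect_equal(sum(ds0$detected), 0L)
  # duplicate rows collapse; a stray row is reported, not dropped
  det2 <- rbind(det, det,
                data.frame(guide_id = "g1", chrom = "chr1", start = 99999L,
                           strand = "+", assay = "guideseq",
                           indel_frequency = 0.5))
  ds2 <- assemble_pair_dataset(cand, det2)
  expect_equal(sum(ds2$detected), 1L)
  expect_equal(nrow(attr(ds2, "unmatched")), 1L)
  expect_equal(attr(ds2, "unmatched")$start, 99999L)
})

test_that("leave-guide-out splits keep each guide on one side", {
  sim <- offtarget_fixture()
  rec <- sim$records
  sp <- split_leave_guides_out(rec, k_guides = 3, seed = 5)
  expect_length(sp$held_out, 3L)
  expect_setequal(unique(sp$test$guide_id), sp$held_out)
  expect_length(intersect(sp$train$guide_id, sp$test$guide_id), 0L)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(rec))
  # leave-one-out fold
  sp1 <- split_leave_guides_out(rec, k_guides = 1, seed = 6)
  expect_length(unique(sp1$test$guide_id), 1L)
  expect_error(split_leave_guides_out(rec, k_guides = 1000), "between")
})
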