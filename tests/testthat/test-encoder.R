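test_that("encoding is one-hot and maps channels in the fixed order", {
  g <- paste0(strrep("A", 20), "AGG")
  x <- encode_guide(g)
  expect_equal(dim(x), c(23L, 8L))
  expect_equal(colnames(x), c("A", "C", "G", "T", "CTCF", "DNase",
                              "H3K4me3", "RRBS"))
  expect_equal(unname(x[1:20, "A"]), rep(1, 20))
  expect_equal(unname(x[22:23, "G"]), rep(1, 2))
  expect_equal(sum(x[, 5:8]), 0)
  # per-position one-hot on random guides
  set.seed(41)
  for (i in 1:25) {
    xi <- encode_guide(random_guide_seq())
    expect_equal(unname(rowSums(xi[, 1:4])), rep(1, 23))
  }
})

test_that("epigenetic channels are copied positionally", {
  e <- epi_window(dnase = rep(1, 23), rrbs = seq(0, 1, length.out = 23))
  x <- encode_guide(random_guide_seq(), e)
  expect_equal(unname(x[, "DNase"]), rep(1, 23))
  expect_equal(unname(x[, "RRBS"]), seq(0, 1, length.out = 23))
})

test_that("decode inverts encode for all PAM variants and random guides", {
  set.seed(42)
  pams <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
  for (pam in pams) {
    g <- paste0(paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
                pam)
    expect_identical(decode_guide(encode_guide(g)), g)
  }
  for (i in 1:1000) {
    g <- random_guide_seq()
    expect_identical(decode_guide(encode_guide(g)), g)
  }
})

test_that("invalid sequences and non-one-hot encodings are rejected", {
  expect_error(encode_guide(paste0(strrep("A", 19), "NAGG")),
               "position 20")
  expect_error(encode_guide("ACGT"), "length 23")
  x <- encode_guide(random_guide_seq())
  x[3, 1:4] <- c(0.5, 0.5, 0, 0)
  expect_error(decode_guide(x), "position 3")
})

test_that("guide_sequence validates its invariants", {
  g <- guide_sequence(paste0(strrep("C", 20), "TGG"), "chr2", 100,
                      cell_type = "hek293t")
  expect_s3_class(g, "guide_sequence")
  expect_equal(g$end, 123L)
  expect_error(guide_sequence(paste0(strrep("C", 20), "TAA")), "PAM")
  expect_silent(guide_sequence(paste0(strrep("C", 20), "TAA"),
                               check_pam = FALSE))
  expect_error(guide_sequence(paste0(strrep("C", 20), "TGG"), end = 150),
               "half-open")
})

test_that("extract_epigenetics intersects tracks per position", {
  seqs <- paste0(strrep("A", 20), "AGG")
  tracks <- list(hek = list(
    ctcf = data.frame(chrom = "chr1", start = 0, end = 0),
    dnase = data.frame(chrom = "chr1", start = 105, end = 110, value = 1),
    h3k4me3 = data.frame(chrom = "chr1", start = 90, end = 200, value = 1),
    rrbs = data.frame(chrom = "chr1", start = 101, end = 103, value = 0.73)))
  tracks$hek$ctcf <- tracks$hek$ctcf[0, ]
  g <- guide_sequence(seqs, "chr1", 100, strand = "+", cell_type = "hek")
  e <- extract_epigenetics(g, tracks)
  # peak covering genomic [105,110) on a + strand guide at 100 -> window 6-10
  expect_equal(which(e$dnase == 1), 6:10)
  # full overlap
  expect_equal(e$h3k4me3, rep(1, 23))
  # no records at all
  expect_equal(e$ctcf, rep(0, 23))
  # bedGraph beta lands on the covered positions
  expect_equal(which(e$rrbs > 0), 2:3)
  expect_equal(unique(e$rrbs[2:3]), 0.73)
})

test_that("minus-strand windows are reported in protospacer orientation", {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0))
  tracks <- list(ct = list(
    ctcf = empty,
    dnase = data.frame(chrom = "c", start = 100, end = 101, value = 1),
    h3k4me3 = empty, rrbs = empty))
  gp <- guide_sequence(paste0(strrep("A", 20), "AGG"), "c", 100,
                       strand = "+", cell_type = "ct")
  gm <- guide_sequence(paste0(strrep("A", 20), "AGG"), "c", 100,
                       strand = "-", cell_type = "ct")
  ep <- extract_epigenetics(gp, tracks)
  em <- extract_epigenetics(gm, tracks)
  # genomic position 100 is window position 1 on +, window position 23 on -
  expect_equal(which(ep$dnase == 1), 1L)
  expect_equal(which(em$dnase == 1), 23L)
  expect_equal(em$dnase, rev(ep$dnase))
})

test_that("extract_epigenetics names a missing chromosome", {
  tracks <- list(ct = list(
    dnase = data.frame(chrom = "chr9", start = 1, end = 5, value = 1)))
  g <- guide_sequence(paste0(strrep("A", 20), "AGG"), "chr1", 0,
                      cell_type = "ct")
  expect_error(extract_epigenetics(g, tracks), "chr1")
})

test_that("pair encoding keeps parts separate and enforces the mismatch cap", {
  g <- paste0(strrep("A", 20), "AGG")
  p0 <- encode_pair(g, g)
  expect_identical(p0$guide_part, p0$site_part)
  six <- paste0(strrep("C", 6), strrep("A", 14), "AGG")
  p6 <- encode_pair(g, six)
  expect_s3_class(p6, "encoded_pair")
  seven <- paste0(strrep("C", 7), strrep("A", 13), "AGG")
  expect_error(encode_pair(g, seven), "maximum is 6")
})
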