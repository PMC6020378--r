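test_that("efficacy binarization uses an inclusive cutoff of 1", {
  expect_equal(binarize_efficacy(c(1.5, 0.3, 1.0, -2)), c(1L, 0L, 1L, 0L))
  expect_equal(binarize_efficacy(0.4, cutoff = 0.4), 1L)
  expect_error(binarize_efficacy(c(1, NA)), "finite")
})

test_that("efficacy-matrix normalization matches the hand-worked example", {
  Y <- matrix(c(1, 3, 2, 4), 2, 2)        # rows [[1,2],[3,4]]
  norm <- normalize_efficacy_matrix(Y)
  expect_equal(norm$y_norm, matrix(c(-1, 1/3, -1/3, 1), 2, 2))
  # constant matrix maps to all zeros
  expect_equal(normalize_efficacy_matrix(matrix(7, 3, 4))$y_norm,
               matrix(0, 3, 4))
})

test_that("normalization identities hold on random complete matrices", {
  set.seed(7)
  for (i in 1:20) {
    Y <- matrix(rnorm(6 * 9), 6, 9)
    yn <- normalize_efficacy_matrix(Y)$y_norm
    expect_lt(abs(sum(yn)), 1e-9)
    # adding a constant leaves y_norm unchanged
    yn2 <- normalize_efficacy_matrix(Y + 3.7)$y_norm
    expect_equal(yn, yn2)
  }
})

test_that("normalization handles missing entries and rejects empty margins", {
  Y <- matrix(rnorm(12), 3, 4)
  Y[1, 2] <- NA
  norm <- normalize_efficacy_matrix(Y)
  expect_true(is.na(norm$y_norm[1, 2]))
  expect_equal(norm$m_row[1], mean(Y[1, ], na.rm = TRUE))
  Y[, 3] <- NA
  expect_error(normalize_efficacy_matrix(Y), "column 3")
})

test_that("rank normalization is (rank - 0.5)/n with midrank ties", {
  expect_equal(rank_normalize(c(10, 20, 30)), c(1, 3, 5) / 6)
  expect_equal(rank_normalize(c(5, 5)), c(0.5, 0.5))
  set.seed(3)
  v <- rnorm(50)
  r <- rank_normalize(v)
  expect_true(all(r > 0 & r < 1))
  expect_equal(cor(v, r, method = "spearman"), 1)
  expect_error(rank_normalize(numeric(0)), "empty")
})

test_that("augmentation emits 9 double-mismatch variants confined to positions 1-2", {
  seed <- data.frame(sequence23 = paste0(strrep("A", 20), "TGG"),
                     cell_type = "hl60", binary_label = 1L,
                     raw_efficacy = 2.5, stringsAsFactors = FALSE)
  aug <- augment_guides(seed)
  expect_equal(nrow(aug), 10L)             # seed + 3x3 variants
  expect_equal(sum(aug$sequence23 == seed$sequence23), 1L)
  variants <- aug$sequence23[aug$sequence23 != seed$sequence23]
  for (v in variants) {
    expect_equal(brute_hamming20(v, seed$sequence23), 2L)
    expect_identical(substr(v, 3, 23), substr(seed$sequence23, 3, 23))
  }
  # labels are copied unchanged
  expect_true(all(aug$binary_label == 1L))
  expect_true(all(aug$raw_efficacy == 2.5))
  # without the seed: exactly the 9 variants
  expect_equal(nrow(augment_guides(seed, include_seed = FALSE)), 9L)
  # identical seeds deduplicate
  expect_equal(augment_guides(rbind(seed, seed)), aug)
})

test_that("single-mismatch augmentation mode adds the 6 singles", {
  seed <- data.frame(sequence23 = paste0(strrep("G", 20), "AGG"),
                     cell_type = "x", stringsAsFactors = FALSE)
  aug <- augment_guides(seed, include_singles = TRUE)
  expect_equal(nrow(aug), 16L)             # 1 + 6 + 9
  d <- vapply(aug$sequence23, brute_hamming20, numeric(1), b = seed$sequence23)
  expect_equal(as.vector(table(factor(d, levels = 0:2))), c(1L, 6L, 9L))
})

test_that("stratified splits preserve proportions and block augmentation leakage", {
  set.seed(11)
  base <- data.frame(
    sequence23 = replicate(100, random_guide_seq()),
    cell_type = rep(c("a", "b"), each = 50),
    binary_label = rep(c(0L, 1L), 50),
    stringsAsFactors = FALSE)
  sp <- split_stratified(base, test_fraction = 0.2, seed = 9)
  expect_equal(nrow(sp$test), 20L)
  tab <- table(sp$test$cell_type, sp$test$binary_label)
  expect_true(all(abs(tab - 5) <= 1))
  expect_length(intersect(sp$train$sequence23, sp$test$sequence23), 0L)
  # determinism
  sp2 <- split_stratified(base, test_fraction = 0.2, seed = 9)
  expect_identical(sp$test$sequence23, sp2$test$sequence23)
  # augmented variants of a test seed never reach the training side
  aug <- augment_guides(base)
  spa <- split_stratified(aug, test_fraction = 0.2, seed = 9)
  key <- function(df) paste(substr(df$sequence23, 3, 23), df$cell_type)
  expect_length(intersect(key(spa$train), key(spa$test)), 0L)
  expect_length(intersect(spa$train$sequence23, spa$test$sequence23), 0L)
})

test_that("leave-one-cell-type-out splits partition the data", {
  set.seed(12)
  recs <- data.frame(
    sequence23 = replicate(80, random_guide_seq()),
    cell_type = rep(c("hct116", "hek293t", "hela", "hl60"), 20),
    binary_label = rbinom(80, 1, 0.5),
    stringsAsFactors = FALSE)
  held_all <- character(0)
  for (ct in unique(recs$cell_type)) {
    sp <- split_leave_cell_type_out(recs, ct)
    expect_true(all(sp$test$cell_type == ct))
    expect_false(any(sp$train$cell_type == ct))
    expect_length(intersect(sp$train$sequence23, sp$test$sequence23), 0L)
    held_all <- c(held_all, sp$test$sequence23)
  }
  # union of the four folds' test sets is the full dataset
  expect_setequal(held_all, recs$sequence23)
  expect_error(split_leave_cell_type_out(recs, "k562"), "unknown")
  expect_error(split_leave_cell_type_out(recs[recs$cell_type == "hela", ],
                                         "hela"), "2 cell types")
})
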